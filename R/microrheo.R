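#' Construct a particle track
#'
#' @param particle_id Identifier.
#' @param t Frame times in seconds, strictly increasing, uniformly spaced
#'   (irregular sampling is rejected unless `allow_irregular`).
#' @param x,y Positions in micrometres.
#' @param allow_irregular Accept non-uniform frame intervals.
#' @return A `particle_track` list.
#' @export
particle_track <- function(particle_id, t, x, y, allow_irregular = FALSE) {
  stopifnot(length(t) >= 2L, length(x) == length(t), length(y) == length(t))
  dt <- diff(t)
  if (any(dt <= 0)) stop("frame times must be strictly increasing",
                         call. = FALSE)
  if (!allow_irregular &&
      (max(dt) - min(dt)) > 1e-6 * stats::median(dt)) {
    stop("irregular frame interval; set allow_irregular = TRUE to override",
         call. = FALSE)
  }
  structure(list(particle_id = particle_id, t = t, x = x, y = y),
            class = "particle_track")
}

#' Read particle tracks from delimited text
#'
#' Expects columns `particle`, `t`, `x`, `y` (header required; comment lines
#' starting with `#` may declare units).
#'
#' @param path File path.
#' @param allow_irregular Passed to [particle_track()].
#' @return List of `particle_track` objects.
#' @export
read_tracks <- function(path, allow_irregular = FALSE) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  stopifnot(all(c("particle", "t", "x", "y") %in% names(df)))
  lapply(split(df, df$particle), function(d) {
    d <- d[order(d$t), ]
    particle_track(d$particle[1], d$t, d$x, d$y,
                   allow_irregular = allow_irregular)
  })
}

#' Ensemble time-averaged mean-squared displacement
#'
#' Per particle, the time-averaged MSD over all overlapping windows at each
#' lag; then the ensemble mean across particles. Lags run up to
#' `max_lag_fraction` of the track length; lags supported by fewer than
#' `min_pairs` displacement pairs (summed over particles) are dropped.
#'
#' @param tracks List of `particle_track` objects on a common frame
#'   interval.
#' @param max_lag_fraction Longest lag as a fraction of track length
#'   (default 1/4).
#' @param min_pairs Minimum displacement pairs per lag (default 10).
#' @param cure_time Optional cure-time label in hours.
#' @return An `msd_curve`: `tau` (s), `msd` (square micrometres), `n_pairs`,
#'   `cure_time`.
#' @export
compute_msd <- function(tracks, max_lag_fraction = 0.25, min_pairs = 10L,
                        cure_time = NA_real_) {
  if (inherits(tracks, "particle_track")) tracks <- list(tracks)
  if (length(tracks) == 0L) stop("no tracks", call. = FALSE)
  dt <- diff(tracks[[1]]$t)[1]
  max_frames <- max(vapply(tracks, function(tr) length(tr$t), integer(1)))
  max_lag <- max(1L, floor(max_frames * max_lag_fraction))
  msd_sum <- numeric(max_lag)
  msd_cnt <- integer(max_lag)   # number of particles contributing
  n_pairs <- integer(max_lag)
  for (tr in tracks) {
    n <- length(tr$t)
    for (lag in seq_len(min(max_lag, n - 1L))) {
      i <- seq_len(n - lag)
      sq <- (tr$x[i + lag] - tr$x[i])^2 + (tr$y[i + lag] - tr$y[i])^2
      msd_sum[lag] <- msd_sum[lag] + mean(sq)
      msd_cnt[lag] <- msd_cnt[lag] + 1L
      n_pairs[lag] <- n_pairs[lag] + length(sq)
    }
  }
  keep <- msd_cnt > 0L & n_pairs >= min_pairs
  if (!any(keep)) stop("no lag satisfies the minimum pair count",
                       call. = FALSE)
  structure(
    list(tau = (seq_len(max_lag) * dt)[keep],
         msd = (msd_sum / pmax(msd_cnt, 1L))[keep],
         n_pairs = n_pairs[keep], cure_time = cure_time),
    class = "msd_curve"
  )
}

#' Log-log slope of an MSD curve
#'
#' Least-squares slope of `log10(msd)` versus `log10(tau)` over a lag-time
#' window: 1 indicates free diffusion, 0 an arrested (plateaued) probe.
#'
#' @param curve An `msd_curve`.
#' @param fit_window Length-2 lag-time range in seconds (default: all lags).
#' @return Dimensionless slope.
#' @export
msd_log_slope <- function(curve, fit_window = NULL) {
  tau <- curve$tau
  msd <- curve$msd
  if (!is.null(fit_window)) {
    keep <- tau >= fit_window[1] & tau <= fit_window[2]
    tau <- tau[keep]
    msd <- msd[keep]
  }
  if (length(tau) < 3L) stop("need at least 3 lags in the fit window",
                             call. = FALSE)
  if (any(msd <= 0)) stop("MSD must be positive in the fit window",
                          call. = FALSE)
  unname(ls_line(log10(tau), log10(msd))[2])
}

#' Sigmoidal gel-time fit to a relaxation-exponent series
#'
#' Fits a four-parameter logistic (upper asymptote, lower plateau, midpoint,
#' steepness) to the MSD log-slope (relaxation exponent) versus cure time.
#' The gel time is defined as the fitted midpoint; the lower asymptote is
#' the gelation plateau.
#'
#' @param cure_times Cure times in hours (at least 5, spanning the
#'   transition).
#' @param slopes Relaxation exponents at those times.
#' @return List with `t_gel` (h), `plateau` (lower asymptote), `upper`,
#'   `steepness` (h), `fitted`, `r_squared`, `method = "sigmoid"`.
#' @export
fit_gelation_sigmoid <- function(cure_times, slopes) {
  stopifnot(length(cure_times) == length(slopes), length(cure_times) >= 5L)
  upper0 <- max(slopes)
  lower0 <- min(slopes)
  if (upper0 - lower0 < 1e-8) {
    stop("no gel point: relaxation exponent series shows no transition",
         call. = FALSE)
  }
  mid0 <- cure_times[which.min(abs(slopes - (upper0 + lower0) / 2))]
  s0 <- diff(range(cure_times)) / 8
  df <- data.frame(t = cure_times, y = slopes)
  # multi-start: four-parameter logistics are sensitive to the initial
  # midpoint/steepness, so try a small grid and keep the best fit
  starts <- expand.grid(mid = unique(c(mid0, stats::median(cure_times))),
                        steep = s0 * c(1, 1 / 3, 3))
  fit <- NULL
  for (k in seq_len(nrow(starts))) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        y ~ lower + (upper - lower) / (1 + exp((t - mid) / steep)),
        data = df,
        start = list(lower = lower0, upper = upper0,
                     mid = starts$mid[k], steep = starts$steep[k]),
        lower = c(-Inf, -Inf, min(cure_times) - diff(range(cure_times)),
                  1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) || stats::deviance(cand) < stats::deviance(fit))) {
      fit <- cand
    }
  }
  if (is.null(fit)) {
    stop("no gel point: sigmoid fit failed from every starting point",
         call. = FALSE)
  }
  cf <- stats::coef(fit)
  fitted_y <- stats::fitted(fit)
  resid_sd <- stats::sd(df$y - fitted_y)
  if ((cf[["upper"]] - cf[["lower"]]) < 3 * resid_sd) {
    stop("no gel point: fitted asymptotes are within noise", call. = FALSE)
  }
  list(t_gel = unname(cf[["mid"]]), plateau = unname(cf[["lower"]]),
       upper = unname(cf[["upper"]]), steepness = unname(cf[["steep"]]),
       fitted = fitted_y, r_squared = r_squared(df$y, fitted_y),
       method = "sigmoid")
}

# Interpolate a log-log master point cloud at query x; NA outside range.
interp_master <- function(mx, my, xq) {
  o <- order(mx)
  stats::approx(mx[o], my[o], xout = xq, ties = mean)$y
}

# Optimal (vertical, horizontal) log10 shift of curve (lx, ly) onto a master
# cloud; returns c(log_a, log_b, cost). Positive log_b shifts the curve to
# larger lag times on the master axis.
fit_shift <- function(master_x, master_y, lx, ly) {
  # a candidate shift must keep at least half the curve on the master:
  # sparse-overlap "solutions" are spurious minima of the mean residual
  min_overlap <- max(5L, ceiling(0.5 * length(lx)))
  cost <- function(p) {
    yq <- interp_master(master_x, master_y, lx + p[2])
    ok <- !is.na(yq)
    if (sum(ok) < min_overlap) return(1e6 + sum(p^2))
    mean((ly[ok] + p[1] - yq[ok])^2)
  }
  # coarse grid then Nelder-Mead polish
  grid <- expand.grid(a = seq(-4, 4, by = 0.25), b = seq(-4, 4, by = 0.25))
  cc <- apply(grid, 1L, cost)
  p0 <- as.numeric(grid[which.min(cc), ])
  opt <- stats::optim(p0, cost, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  c(log_a = opt$par[1], log_b = opt$par[2], cost = opt$value)
}

# Superpose one branch of curves onto its reference. A first sequential
# pass aligns curves starting from the one nearest the reference,
# accumulating a master point cloud; refinement sweeps then re-fit each
# curve's shift against the master built from all OTHER curves, which
# removes the drift a purely sequential alignment accumulates along the
# local power-law degeneracy direction. Returns shift factors plus a
# per-curve collapse cost (mean squared log10 residual to the master).
superpose_branch <- function(curves, ref_index, order_by_distance,
                             n_sweeps = 3L) {
  lx <- lapply(curves, function(cv) log10(cv$tau))
  ly <- lapply(curves, function(cv) log10(cv$msd))
  n <- length(curves)
  log_a <- numeric(n)
  log_b <- numeric(n)
  master_x <- lx[[ref_index]]
  master_y <- ly[[ref_index]]
  for (i in order_by_distance) {
    if (i == ref_index) next
    sh <- fit_shift(master_x, master_y, lx[[i]], ly[[i]])
    if (sh[["cost"]] >= 1e6) {
      stop("superposition error: curve at cure time ", curves[[i]]$cure_time,
           " does not overlap the master curve", call. = FALSE)
    }
    # both stored as the shift added to the curve's log coordinates to land
    # on the master (y: log_a, x: log_b); references stay at 0
    log_a[i] <- sh[["log_a"]]
    log_b[i] <- sh[["log_b"]]
    master_x <- c(master_x, lx[[i]] + sh[["log_b"]])
    master_y <- c(master_y, ly[[i]] + sh[["log_a"]])
  }
  # alternate between a smoothing-spline master through the pooled shifted
  # points and per-curve shift re-estimation; the smooth master removes the
  # chord bias a piecewise-linear interpolant has in curved regions
  cost <- numeric(n)
  for (sweep in seq_len(n_sweeps)) {
    mx <- unlist(lapply(seq_len(n), function(j) lx[[j]] + log_b[j]))
    my <- unlist(lapply(seq_len(n), function(j) ly[[j]] + log_a[j]))
    sp <- tryCatch(stats::smooth.spline(mx, my), error = function(e) NULL)
    master_fun <- if (is.null(sp)) {
      function(xq) interp_master(mx, my, xq)
    } else {
      rng <- range(mx)
      function(xq) {
        out <- stats::predict(sp, xq)$y
        out[xq < rng[1] | xq > rng[2]] <- NA_real_
        out
      }
    }
    for (i in seq_len(n)) {
      min_overlap <- max(5L, ceiling(0.5 * length(lx[[i]])))
      cost_fun <- function(p) {
        yq <- master_fun(lx[[i]] + p[2])
        ok <- !is.na(yq)
        if (sum(ok) < min_overlap) return(1e6)
        mean((ly[[i]][ok] + p[1] - yq[ok])^2)
      }
      if (i == ref_index) {
        cost[i] <- cost_fun(c(0, 0))
        next
      }
      opt <- stats::optim(c(log_a[i], log_b[i]), cost_fun,
                          method = "Nelder-Mead",
                          control = list(maxit = 300, reltol = 1e-10))
      log_a[i] <- opt$par[1]
      log_b[i] <- opt$par[2]
      cost[i] <- opt$value
    }
  }
  pooled_y <- unlist(lapply(seq_len(n), function(j) ly[[j]] + log_a[j]))
  list(shifts = data.frame(
         cure_time = vapply(curves, function(cv) cv$cure_time, numeric(1)),
         log_a = log_a, log_b = log_b),
       cost = cost,
       collapse_r2 = max(0, 1 - mean(cost) / stats::var(pooled_y)))
}

#' Time-cure superposition gel-point analysis
#'
#' Collapses MSD curves taken at different cure times onto pre- and post-gel
#' master curves by log-log shifting (vertical shift `log_a`, horizontal
#' shift `log_b`; the latest pre-gel curve and earliest post-gel curve are
#' the branch references with zero shift). Candidate gel times are the
#' midpoints of the observed cure-time grid; the selected `t_c` maximizes
#' the joint linearity (R-squared) of `log_b` and `log_a` versus
#' `log10 |t - t_c|`. The critical relaxation exponent is the ratio of the
#' fitted log-log slopes, horizontal over vertical.
#'
#' @param curves List of `msd_curve` objects with `cure_time` labels; at
#'   least 4 on each side of the transition.
#' @return List with `t_gel` (= `t_c`, h), `n_c`, `shift_factors`
#'   (data.frame: cure_time, branch, log_a, log_b), `slope_log_a`,
#'   `slope_log_b`, `quality` (mean R-squared), `candidates`,
#'   `method = "superposition"`.
#' @export
time_cure_superposition <- function(curves) {
  stopifnot(length(curves) >= 8L)
  times <- vapply(curves, function(cv) cv$cure_time, numeric(1))
  if (anyNA(times)) stop("every curve needs a cure_time label",
                         call. = FALSE)
  o <- order(times)
  curves <- curves[o]
  times <- times[o]
  if (any(diff(times) <= 0)) stop("duplicate cure times", call. = FALSE)
  mids <- (times[-1] + times[-length(times)]) / 2
  # keep candidates with >= 4 curves per side
  mids <- mids[vapply(mids, function(tc) {
    sum(times < tc) >= 4L && sum(times > tc) >= 4L
  }, logical(1))]
  if (length(mids) == 0L) {
    stop("superposition error: need at least 4 curves on each side of the ",
         "candidate transition", call. = FALSE)
  }
  evaluate <- function(tc) {
    pre_i <- which(times < tc)
    post_i <- which(times > tc)
    pre <- superpose_branch(curves[pre_i], ref_index = length(pre_i),
                            order_by_distance = rev(seq_along(pre_i)))
    post <- superpose_branch(curves[post_i], ref_index = 1L,
                             order_by_distance = seq_along(post_i))
    sf <- rbind(cbind(pre$shifts, branch = "pre", is_ref = FALSE),
                cbind(post$shifts, branch = "post", is_ref = FALSE))
    sf$is_ref[c(length(pre_i), length(pre_i) + 1L)] <- TRUE
    if (max(abs(c(sf$log_a, sf$log_b))) < 1e-3) {
      return(list(quality = -Inf, degenerate = TRUE))
    }
    # the gauge (which curve has zero shift) is arbitrary: only slopes of
    # the shift factors are observable, and a reference misaligned along
    # the master's power-law valley displaces every other shift by a
    # constant. Fit slopes with free per-branch intercepts on the
    # non-reference curves, whose relative shifts are well determined.
    fit_sf <- sf[!sf$is_ref, ]
    leps <- log10(abs(fit_sf$cure_time - tc))
    br <- factor(fit_sf$branch)
    xa <- stats::model.matrix(~ br + leps)
    fa <- stats::lm.fit(xa, fit_sf$log_a)
    fb <- stats::lm.fit(xa, fit_sf$log_b)
    sa <- fa$coefficients[["leps"]]
    sb <- fb$coefficients[["leps"]]
    qa <- r_squared(fit_sf$log_a, fit_sf$log_a - fa$residuals)
    qb <- r_squared(fit_sf$log_b, fit_sf$log_b - fb$residuals)
    # quality blends how linearly the shifts diverge with how well the
    # curves actually collapse: a wrong split can fake the former but not
    # the latter
    collapse <- (pre$collapse_r2 + post$collapse_r2) / 2
    list(quality = (qa + qb + 2 * collapse) / 4,
         slope_log_a = sa, slope_log_b = sb,
         shift_factors = sf, degenerate = FALSE)
  }
  evals <- lapply(mids, evaluate)
  quality <- vapply(evals, `[[`, numeric(1), "quality")
  if (all(!is.finite(quality))) {
    stop("superposition error: shift factors do not diverge ",
         "(degenerate curve family)", call. = FALSE)
  }
  best_q <- max(quality, na.rm = TRUE)
  near <- which(quality >= best_q - 1e-6)
  if (length(near) > 1L) {
    warning("multiple candidate gel times of equal quality; ",
            "choosing the lowest")
  }
  k <- near[1]
  ev <- evals[[k]]
  if (abs(ev$slope_log_a) < 1e-12) {
    stop("superposition error: vertical shift factors do not diverge",
         call. = FALSE)
  }
  list(t_gel = mids[k], n_c = ev$slope_log_b / ev$slope_log_a,
       shift_factors = ev$shift_factors,
       slope_log_a = ev$slope_log_a, slope_log_b = ev$slope_log_b,
       quality = ev$quality,
       candidates = data.frame(t_c = mids, quality = quality),
       method = "superposition")
}

# Fractional Gaussian noise covariance (Toeplitz) Cholesky factor.
fgn_chol <- function(n, hurst) {
  k <- 0:(n - 1)
  g <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                abs(k - 1)^(2 * hurst))
  chol(stats::toeplitz(g))
}

#' Generate synthetic particle tracks
#'
#' Seeded two-dimensional trajectory generator standing in for microscopy:
#'
#' * `brownian`: independent Gaussian steps with variance `2 * d * dt` per
#'   axis, so the ensemble 2D MSD is `4 d tau`;
#' * `subdiffusive`: fractional Gaussian noise increments with Hurst index
#'   `alpha / 2`, giving MSD proportional to `tau^alpha`;
#' * `arrested`: an Ornstein--Uhlenbeck probe in a harmonic well whose
#'   stationary variance sets a long-lag MSD plateau of `plateau` square
#'   micrometres.
#'
#' Gaussian localization noise of standard deviation `noise_sd` per axis is
#' added to every position (it contributes `4 * noise_sd^2` to the MSD).
#'
#' @param mode One of `"brownian"`, `"subdiffusive"`, `"arrested"`.
#' @param n_particles,n_frames Counts (at least 1 / 2).
#' @param dt Frame interval, seconds.
#' @param d Diffusion coefficient, square micrometres per second
#'   (brownian; also the generalized coefficient for subdiffusive).
#' @param alpha Anomalous exponent in (0, 1] (subdiffusive).
#' @param plateau Long-lag MSD plateau, square micrometres (arrested).
#' @param relax_time Well relaxation time, seconds (arrested).
#' @param noise_sd Localization noise standard deviation, micrometres.
#' @param seed Integer seed.
#' @return List of `particle_track` objects.
#' @export
generate_tracks <- function(mode = c("brownian", "subdiffusive", "arrested"),
                            n_particles = 100L, n_frames = 1000L, dt = 0.1,
                            d = 0.1, alpha = 0.5, plateau = 0.1,
                            relax_time = 1, noise_sd = 0, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_particles >= 1L, n_frames >= 2L, dt > 0)
  if (mode == "subdiffusive" && (alpha <= 0 || alpha > 1)) {
    stop("anomalous exponent must be in (0, 1]", call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  t <- (seq_len(n_frames) - 1L) * dt
  ch <- if (mode == "subdiffusive") fgn_chol(n_frames - 1L, alpha / 2) else
    NULL
  tracks <- vector("list", n_particles)
  for (p in seq_len(n_particles)) {
    if (mode == "brownian") {
      x <- cumsum(c(0, stats::rnorm(n_frames - 1L, sd = sqrt(2 * d * dt))))
      y <- cumsum(c(0, stats::rnorm(n_frames - 1L, sd = sqrt(2 * d * dt))))
    } else if (mode == "subdiffusive") {
      # fBm with MSD_x(tau) = 2 * d * tau^alpha
      scale <- sqrt(2 * d) * dt^(alpha / 2)
      x <- cumsum(c(0, scale * drop(stats::rnorm(n_frames - 1L) %*% ch)))
      y <- cumsum(c(0, scale * drop(stats::rnorm(n_frames - 1L) %*% ch)))
    } else {
      sig <- sqrt(plateau / 4)
      rho <- exp(-dt / relax_time)
      innov_sd <- sig * sqrt(1 - rho^2)
      x <- numeric(n_frames)
      y <- numeric(n_frames)
      x[1] <- stats::rnorm(1, sd = sig)
      y[1] <- stats::rnorm(1, sd = sig)
      for (k in 2:n_frames) {
        x[k] <- x[k - 1] * rho + stats::rnorm(1, sd = innov_sd)
        y[k] <- y[k - 1] * rho + stats::rnorm(1, sd = innov_sd)
      }
    }
    if (noise_sd > 0) {
      x <- x + stats::rnorm(n_frames, sd = noise_sd)
      y <- y + stats::rnorm(n_frames, sd = noise_sd)
    }
    tracks[[p]] <- particle_track(p, t, x, y)
  }
  tracks
}

#' Generate a synthetic critical-gel MSD curve family
#'
#' Builds MSD curves at several cure times from pre- and post-gel master
#' curves shifted by power laws of the distance to the gel point, the
#' scaling structure that time-cure superposition assumes. The horizontal
#' and vertical log-shifts scale with exponents `z_a * n` and `z_a` of the
#' distance to the gel point, so the recoverable critical relaxation
#' exponent (their slope ratio) equals `n`.
#'
#' Default cure times stay within about 40% of the gel time on either side:
#' superposition presumes the critical regime, and curves taken too far from
#' the gel point leave the crossover window of the lag grid, making their
#' shifts unidentifiable.
#'
#' @param n Critical relaxation exponent in (0, 1).
#' @param t_c Gel time, hours.
#' @param cure_times Cure times, hours (excluding `t_c`).
#' @param tau Lag-time grid, seconds (log-spaced recommended).
#' @param z_a Vertical divergence exponent (default 2.5).
#' @param noise_sd_log10 Multiplicative log10 noise on the MSD.
#' @param seed Integer seed (used only when noise is added).
#' @return List of `msd_curve` objects.
#' @export
synth_msd_family <- function(n = 0.5, t_c = 7.5,
                             cure_times = c(seq(4.5, 7, by = 0.5),
                                            seq(8, 10.5, by = 0.5)),
                             tau = 10^seq(-2, 2, length.out = 35),
                             z_a = 2.5, noise_sd_log10 = 0, seed = 1L) {
  stopifnot(n > 0, n < 1, all(cure_times != t_c))
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  z_b <- z_a * n
  m_sol <- function(x) x^n * (1 + x)^(1 - n)
  m_gel <- function(x) x^n / (1 + x^n)
  lapply(cure_times, function(tt) {
    eps <- abs(tt - t_c) / t_c
    a <- eps^(-z_a)
    b <- eps^(-z_b)
    msd <- if (tt < t_c) a * m_sol(tau / b) else a * m_gel(tau / b)
    if (noise_sd_log10 > 0) {
      msd <- msd * 10^stats::rnorm(length(tau), sd = noise_sd_log10)
    }
    structure(list(tau = tau, msd = msd,
                   n_pairs = rep(Inf, length(tau)), cure_time = tt),
              class = "msd_curve")
  })
}

#' Generate a synthetic relaxation-exponent cure series
#'
#' Logistic decay of the MSD log-slope from free diffusion (upper) to an
#' arrested plateau (lower) with additive Gaussian noise; the input for
#' [fit_gelation_sigmoid()] recovery studies.
#'
#' @param cure_times Hours.
#' @param midpoint Gel time (logistic midpoint), hours.
#' @param upper,lower Asymptotes (defaults 1.00 and 0.03).
#' @param steepness Hours.
#' @param noise_sd Additive noise standard deviation.
#' @param seed Integer seed.
#' @return Data frame with `cure_time`, `slope`.
#' @export
synth_relaxation_series <- function(cure_times = seq(2, 14, length.out = 12),
                                    midpoint = 8.1, upper = 1.0,
                                    lower = 0.03, steepness = 0.8,
                                    noise_sd = 0.05, seed = 1L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  mu <- lower + (upper - lower) / (1 + exp((cure_times - midpoint) /
                                             steepness))
  data.frame(cure_time = cure_times,
             slope = mu + stats::rnorm(length(cure_times), sd = noise_sd))
}
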