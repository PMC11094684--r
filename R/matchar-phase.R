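#' Fit a UCST phase boundary to tube-inversion observations
#'
#' Binary-response (logistic) regression of the gel/no-gel outcome on
#' temperature and concentration; the phase boundary is the 50% response
#' contour `b0 + bT*T + bc*c = 0`. Reports both readings of the boundary's
#' thermal behaviour: the regression coefficient on temperature (`bT`, per
#' degree C) and the boundary slope `dT/dc = -bc / bT` (degrees C per mM).
#'
#' Coefficients are estimated by Firth's bias-reduced penalized likelihood
#' rather than plain maximum likelihood: phase grids are small and often
#' completely separable (every gel observation colder than every non-gel
#' one), where the MLE diverges, and even without separation the MLE's
#' O(1/n) bias is material at tube-inversion sample sizes. Firth estimates
#' stay finite under separation; a `separation` flag still reports when the
#' classes are linearly separable.
#'
#' @param temperature_c Temperatures, degrees C.
#' @param conc_mM Concentrations, mM.
#' @param gelled Logical (or 0/1) tube-inversion outcome.
#' @return A `phase_boundary` list: `coefficients` (b0, bT, bc),
#'   `dT_dc`, `separation`, `conc_range`, `ucst` (function of
#'   concentration).
#' @export
fit_phase_boundary <- function(temperature_c, conc_mM, gelled) {
  gelled <- as.integer(gelled)
  stopifnot(length(temperature_c) == length(conc_mM),
            length(gelled) == length(conc_mM))
  if (length(unique(gelled)) < 2L) {
    stop("need both gel and non-gel observations", call. = FALSE)
  }
  x <- cbind(1, temperature_c, conc_mM)
  cf <- firth_logistic(x, gelled)
  names(cf) <- c("b0", "bT", "bc")
  # separability check at the fitted boundary direction
  eta <- drop(x %*% cf)
  sep <- min(eta[gelled == 1L]) > max(eta[gelled == 0L]) ||
    max(eta[gelled == 1L]) < min(eta[gelled == 0L])
  conc_range <- range(conc_mM)
  ucst <- function(conc, extrapolate = FALSE) {
    if (!extrapolate &&
        any(conc < conc_range[1] | conc > conc_range[2])) {
      stop("concentration outside the observed range [",
           conc_range[1], ", ", conc_range[2],
           "] mM; set extrapolate = TRUE to override", call. = FALSE)
    }
    -(cf[["b0"]] + cf[["bc"]] * conc) / cf[["bT"]]
  }
  structure(
    list(coefficients = cf, dT_dc = -cf[["bc"]] / cf[["bT"]],
         separation = sep, conc_range = conc_range, ucst = ucst),
    class = "phase_boundary"
  )
}

# Firth bias-reduced logistic regression (Newton iteration on the modified
# score with hat-value adjustment). Finite under complete separation.
firth_logistic <- function(x, y, maxit = 200L, tol = 1e-10) {
  beta <- numeric(ncol(x))
  for (it in seq_len(maxit)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    xw <- x * sqrt(w)
    xtwx <- crossprod(xw)
    h <- rowSums((xw %*% solve(xtwx)) * xw)
    u <- crossprod(x, y - mu + h * (0.5 - mu))
    step <- drop(solve(xtwx, u))
    # dampen very large steps for stability near separation
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

#' Generate synthetic tube-inversion phase observations
#'
#' Bernoulli gel outcomes from a logistic model in temperature and
#' concentration, for phase-boundary recovery studies.
#'
#' The default design is a factorial grid of concentration and temperature
#' pairings -- how tube-inversion phase diagrams are actually collected --
#' with 5 concentrations and `n / 5` temperatures; `design = "uniform"`
#' samples both axes uniformly instead. Default coefficients place the 50%
#' boundary at 15 degrees C for 3 mM with a boundary slope dT/dc of +1.5
#' degrees C per mM, and a transition band (20--80% response) about 7
#' degrees C wide -- a gradual boundary of the kind these grids can resolve
#' at typical sample sizes.
#'
#' @param n Number of observations.
#' @param b0,bT,bc True coefficients (intercept, per degree C, per mM).
#' @param t_range,c_range Ranges for temperature (degrees C) and
#'   concentration (mM).
#' @param design `"grid"` (default) or `"uniform"`.
#' @param seed Integer seed.
#' @return Data frame with `temperature_c`, `conc_mM`, `gelled`, and the
#'   true coefficients as attributes.
#' @export
synth_phase_observations <- function(n = 60L, b0 = 4.2, bT = -0.4,
                                     bc = 0.6, t_range = c(5, 40),
                                     c_range = c(1, 5),
                                     design = c("grid", "uniform"),
                                     seed = 1L) {
  design <- match.arg(design)
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (design == "grid") {
    n_conc <- 5L
    n_temp <- max(2L, floor(n / n_conc))
    tt <- rep(seq(t_range[1], t_range[2], length.out = n_temp),
              times = n_conc)
    cc <- rep(seq(c_range[1], c_range[2], length.out = n_conc),
              each = n_temp)
    n <- length(tt)
  } else {
    tt <- stats::runif(n, t_range[1], t_range[2])
    cc <- stats::runif(n, c_range[1], c_range[2])
  }
  p <- stats::plogis(b0 + bT * tt + bc * cc)
  out <- data.frame(temperature_c = tt, conc_mM = cc,
                    gelled = stats::rbinom(n, 1L, p))
  attr(out, "true_coefficients") <- c(b0 = b0, bT = bT, bc = bc)
  out
}

#' Exponential gel-time model in the patch-difference objective
#'
#' Fits `t_gel = A * exp(B * dee_bcf)` by ordinary least squares on
#' `log(t_gel)` and exposes the inverse: the patch difference required to
#' reach a target gel time.
#'
#' @param dee_bcf Patch-difference objective values, kJ/mol.
#' @param t_gel Gel times, hours (positive).
#' @return List with `A`, `B`, `r_squared`, `predict(dee)`,
#'   `invert(target_t_gel)`.
#' @export
fit_tgel_exponential <- function(dee_bcf, t_gel) {
  stopifnot(length(dee_bcf) == length(t_gel), length(t_gel) >= 2L)
  if (any(t_gel <= 0)) stop("gel times must be positive", call. = FALSE)
  cf <- unname(ls_line(dee_bcf, log(t_gel)))
  a <- exp(cf[1])
  b <- cf[2]
  fitted_log <- cf[1] + b * dee_bcf
  list(A = a, B = b,
       r_squared = r_squared(log(t_gel), fitted_log),
       predict = function(dee) a * exp(b * dee),
       invert = function(target_t_gel) {
         stopifnot(all(target_t_gel > 0))
         (log(target_t_gel) - log(a)) / b
       })
}
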