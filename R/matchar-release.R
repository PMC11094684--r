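#' Fit a linear absorbance standard curve
#'
#' Least-squares line (not forced through the origin) mapping absorbance to
#' concentration; used to convert 490 nm readings of removed drug and
#' washes.
#'
#' @param absorbance Calibration absorbances.
#' @param conc_mM Known concentrations, mM.
#' @return List with `intercept`, `slope`, and `to_conc(absorbance)` which
#'   clips negative fitted concentrations to 0 with a warning.
#' @export
standard_curve <- function(absorbance, conc_mM) {
  stopifnot(length(absorbance) == length(conc_mM), length(conc_mM) >= 2L)
  cf <- ls_line(absorbance, conc_mM)
  if (cf[2] <= 0) stop("standard curve is not monotone increasing",
                       call. = FALSE)
  list(intercept = unname(cf[1]), slope = unname(cf[2]),
       to_conc = function(a) {
         out <- cf[1] + cf[2] * a
         if (any(out < 0)) {
           warning("negative fitted concentration clipped to 0")
           out <- pmax(out, 0)
         }
         unname(out)
       })
}

#' Drug loading mass balance
#'
#' Loaded amount = applied amount minus everything recovered in the removal
#' and wash fractions: `loaded = applied_conc * applied_vol - sum(recovered
#' conc * vol)`. The in-gel concentration divides by the gel volume.
#'
#' @param applied_conc_mM,applied_vol_uL Applied drug solution.
#' @param recovered_conc_mM,recovered_vol_uL Vectors over removal + wash
#'   fractions (concentrations may come from [standard_curve()]).
#' @param gel_vol_uL Hydrogel volume.
#' @return List with `applied_nmol`, `recovered_nmol`, `loaded_nmol`,
#'   `loaded_conc_mM`.
#' @export
compute_loading <- function(applied_conc_mM, applied_vol_uL,
                            recovered_conc_mM, recovered_vol_uL,
                            gel_vol_uL) {
  stopifnot(length(recovered_conc_mM) == length(recovered_vol_uL),
            applied_conc_mM >= 0, applied_vol_uL > 0, gel_vol_uL > 0,
            all(recovered_conc_mM >= 0), all(recovered_vol_uL >= 0))
  applied <- applied_conc_mM * applied_vol_uL      # nmol (mM * uL)
  recovered <- sum(recovered_conc_mM * recovered_vol_uL)
  if (recovered > applied * (1 + 1e-9)) {
    stop("mass-balance error: recovered (", signif(recovered, 6),
         " nmol) exceeds applied (", signif(applied, 6), " nmol)",
         call. = FALSE)
  }
  loaded <- applied - recovered
  list(applied_nmol = applied, recovered_nmol = recovered,
       loaded_nmol = loaded, loaded_conc_mM = loaded / gel_vol_uL)
}

#' Withdrawal-corrected cumulative release
#'
#' Full-replacement sampling: at each timepoint the supernatant is
#' withdrawn, measured, and replaced with fresh buffer, so the analyte
#' removed at each withdrawal is `conc * withdrawn_vol` and the cumulative
#' release is the running sum of those increments (replacement re-zeroes the
#' supernatant).
#'
#' @param time_h Timepoints, hours, strictly increasing.
#' @param supernatant_conc_mM Measured supernatant concentrations, mM.
#' @param withdrawn_vol_uL Withdrawn volume per timepoint (scalar or
#'   vector), positive.
#' @param loaded_nmol Loaded amount for the release fraction; optional.
#' @param tolerance Relative tolerance on cumulative release exceeding the
#'   loaded amount (default 0.01).
#' @return A `release_series` data.frame: `time_h`, `conc_mM`,
#'   `released_nmol` (increment), `cumulative_nmol`, and
#'   `cumulative_fraction` when `loaded_nmol` is given.
#' @export
cumulative_release <- function(time_h, supernatant_conc_mM,
                               withdrawn_vol_uL, loaded_nmol = NULL,
                               tolerance = 0.01) {
  n <- length(time_h)
  stopifnot(length(supernatant_conc_mM) == n)
  if (any(diff(time_h) <= 0)) stop("timepoints must be strictly increasing",
                                   call. = FALSE)
  if (any(supernatant_conc_mM < 0)) stop("negative concentration",
                                         call. = FALSE)
  vol <- rep_len(withdrawn_vol_uL, n)
  if (any(vol <= 0)) stop("withdrawn volumes must be positive",
                          call. = FALSE)
  inc <- supernatant_conc_mM * vol
  cum <- cumsum(inc)
  out <- data.frame(time_h = time_h, conc_mM = supernatant_conc_mM,
                    released_nmol = inc, cumulative_nmol = cum)
  if (!is.null(loaded_nmol)) {
    if (cum[n] > loaded_nmol * (1 + tolerance)) {
      stop("mass-balance error: cumulative release (", signif(cum[n], 6),
           " nmol) exceeds loaded amount (", signif(loaded_nmol, 6),
           " nmol) beyond tolerance", call. = FALSE)
    }
    out$cumulative_fraction <- cum / loaded_nmol
  }
  class(out) <- c("release_series", "data.frame")
  out
}

#' Generate a synthetic release experiment
#'
#' First-order (burst-like) release from a loaded depot sampled with full
#' supernatant replacement; measured concentrations get multiplicative
#' lognormal noise. For mass-balance property tests.
#'
#' @param loaded_nmol Loaded amount.
#' @param k_per_h First-order release rate constant.
#' @param time_h Sampling times, hours.
#' @param vol_uL Supernatant volume (withdrawn and replaced).
#' @param noise_cv Coefficient of variation of the concentration readout.
#' @param seed Integer seed.
#' @return List with the inputs of [cumulative_release()] plus
#'   `residual_nmol` (left in the depot at the end, noise-free).
#' @export
synth_release_series <- function(loaded_nmol = 300, k_per_h = 0.2,
                                 time_h = c(1, 2, 4, 8, 12, 18, 24),
                                 vol_uL = 300, noise_cv = 0, seed = 1L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  remaining <- loaded_nmol
  prev_t <- 0
  conc <- numeric(length(time_h))
  for (i in seq_along(time_h)) {
    frac <- 1 - exp(-k_per_h * (time_h[i] - prev_t))
    released <- remaining * frac
    remaining <- remaining - released
    conc[i] <- released / vol_uL
    prev_t <- time_h[i]
  }
  if (noise_cv > 0) {
    conc <- conc * exp(stats::rnorm(length(conc), sd = noise_cv) -
                         noise_cv^2 / 2)
  }
  list(time_h = time_h, supernatant_conc_mM = conc,
       withdrawn_vol_uL = vol_uL, loaded_nmol = loaded_nmol,
       residual_nmol = remaining)
}

#' Caliper ellipsoid tumor volume
#'
#' Simplified ellipsoid volume from the greatest longitudinal diameter `L`
#' and transverse width `W` (both mm): `V = L * W^2 / 2` in cubic mm. Warns
#' (without failing) when `W > L`.
#'
#' @param l_mm Length, mm.
#' @param w_mm Width, mm.
#' @return Volume, cubic mm.
#' @export
#' @examples
#' ellipsoid_volume(10, 6)  # 180
ellipsoid_volume <- function(l_mm, w_mm) {
  if (any(l_mm < 0) || any(w_mm < 0)) {
    stop("caliper measurements must be non-negative", call. = FALSE)
  }
  if (any(w_mm > l_mm)) {
    warning("width exceeds length; check caliper axis assignment")
  }
  l_mm * w_mm^2 / 2
}
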