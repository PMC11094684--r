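# Kyte-Doolittle hydropathy index, used by the stability surrogate and
# register inference.
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

KCAL_TO_J <- 4184    # J per kcal
KJ_TO_J <- 1000      # J per kJ

assert_finite <- function(x, name = deparse(substitute(x))) {
  if (!all(is.finite(x))) stop(name, " must be finite", call. = FALSE)
  invisible(x)
}

# Least-squares slope of y on x (with intercept); returns c(intercept, slope).
ls_line <- function(x, y) {
  f <- stats::lm.fit(cbind(1, x), y)
  f$coefficients
}

r_squared <- function(observed, fitted) {
  ss_res <- sum((observed - fitted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else 0)
  1 - ss_res / ss_tot
}
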