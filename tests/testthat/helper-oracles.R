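# Independent oracles and toy fixtures shared across test files.

# Exhaustive pairwise MSD oracle: double loop over every frame pair of every
# particle, binned by lag. Deliberately naive.
msd_oracle <- function(tracks, max_lag) {
  dt <- diff(tracks[[1]]$t)[1]
  acc <- vector("list", max_lag)
  for (tr in tracks) {
    n <- length(tr$t)
    per_lag <- vector("list", max_lag)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        lag <- j - i
        if (lag <= max_lag) {
          per_lag[[lag]] <- c(per_lag[[lag]],
                              (tr$x[j] - tr$x[i])^2 + (tr$y[j] - tr$y[i])^2)
        }
      }
    }
    for (lag in seq_len(max_lag)) {
      if (!is.null(per_lag[[lag]])) {
        acc[[lag]] <- c(acc[[lag]], mean(per_lag[[lag]]))
      }
    }
  }
  list(tau = seq_len(max_lag) * dt,
       msd = vapply(acc, mean, numeric(1)),
       n_pairs = vapply(acc, function(a) NA_integer_, integer(1)))
}

# Toy design space: 7-residue coiled-coil (one heptad, no His-tag), with
# b, c, and e mutable over {K, E, A} and every other class pinned to the
# current residue. The two scored surface positions (b, c) sit in the
# N-terminal half, position e is never scored, so CE_bcf is constant and the
# patch-difference objective is greedily minimizable.
toy_seq <- function(bcf = c("K", "K", "K")) {
  # classes: a b c d e f g -> residues I [b] [c] L [e] A A
  cc_seq(paste0("I", bcf[1], bcf[2], "L", bcf[3], "A", "A"),
         his_tag_region = NULL, register_offset = 0L, id = "toy")
}

toy_alphabets <- function() {
  list(a = "I", b = c("K", "E", "A"), c = c("K", "E", "A"), d = "L",
       e = c("K", "E", "A"), f = "A", g = "A")
}

# Constant-stability scorer: isolates the electrostatic gates.
toy_scorer <- function() {
  function(seq) {
    score_bundle(rs = 0,
                 ne_bcf = surrogate_ebcf(seq, "N"),
                 ce_bcf = surrogate_ebcf(seq, "C"),
                 scorer_id = "toy")
  }
}

# Exhaustive enumeration of the 27 toy states.
toy_enumerate <- function() {
  letters3 <- c("K", "E", "A")
  sc <- toy_scorer()
  grid <- expand.grid(b = letters3, c = letters3, e = letters3,
                      stringsAsFactors = FALSE)
  grid$dee <- apply(grid, 1L, function(r) sc(toy_seq(unname(r)))$dee_bcf)
  grid
}
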