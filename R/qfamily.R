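#' Synthetic Q-family reference sequences
#'
#' Deterministic stand-ins for the Q, Q4, and Q8 coiled-coil hydrogel
#' sequences. The real sequences are published only as a figure; these
#' synthetic constructs reproduce every printed sequence-level constraint and
#' are clearly labelled synthetic:
#'
#' * 16-residue His-tag leader (`MRGSHHHHHHGSGSGS`, excluded from mutation
#'   and scoring) followed by a 38-residue coiled-coil domain at register
#'   offset 0;
#' * the designed variant Q8 draws every coiled-coil residue from the
#'   position-class alphabets (a/d from V,I,M,T,Q,L; b,c,e,f,g from
#'   A,E,K,Q,N,T,D) and carries a positively charged N-terminal and
#'   negatively charged C-terminal b/c/f surface patch;
#' * Q differs from Q8 at exactly 25 of the 38 coiled-coil sites (34%
#'   identity);
#' * the search input Q4 differs from Q8 at exactly 7 sites, each drawn from
#'   the same alphabets.
#'
#' A copy ships as `inst/extdata/q_family_synthetic.fasta`.
#'
#' @return Named list of `cc_seq` objects `Q`, `Q4`, `Q8`.
#' @export
#' @examples
#' qs <- q_family_sequences()
#' identity_fraction(qs$Q, qs$Q8)$substitution_count  # 25
q_family_sequences <- function() {
  tag <- "MRGSHHHHHHGSGSGS"
  cc <- c(
    Q  = "IRELQREMASVQRELERVEEKVKNLSEKINEVKGSIQD",
    Q4 = "IKKLQEAMKEIQEALKKTQETMKDLNETIKELNKTIED",
    Q8 = "IKKLQKAMKKIQKALKKIQETMEDLNETIDELNETIED"
  )
  out <- lapply(names(cc), function(nm) {
    cc_seq(paste0(tag, cc[[nm]]), his_tag_region = c(1L, 16L),
           cc_region = c(17L, 54L), register_offset = 0L,
           id = paste0(nm, "_synthetic"))
  })
  names(out) <- names(cc)
  out
}
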