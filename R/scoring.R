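#' Formal charge model for surface electrostatics
#'
#' Per-residue formal charges at the working pH (default pH 8: D, E carry -1;
#' K, R carry +1; H is neutral since its pKa ~ 6), plus the Debye screening
#' length of the buffer.
#'
#' @param ph Working pH (only 'H neutral above ~6.5' is pH-dependent here).
#' @param screening_length_nm Debye length in nm; default 0.43 nm
#'   (approximately 500 mM 1:1 salt, the assembly buffer).
#' @param dielectric Relative dielectric constant of the medium.
#' @return List with `charges` (named numeric over the 20 residues),
#'   `screening_length_nm`, `dielectric`, `ph`.
#' @export
charge_model <- function(ph = 8, screening_length_nm = 0.43, dielectric = 80) {
  stopifnot(screening_length_nm > 0, dielectric > 0)
  q <- stats::setNames(numeric(20), CANONICAL_AA)
  q[c("D", "E")] <- -1
  q[c("K", "R")] <- +1
  q["H"] <- if (ph < 6.5) +1 else 0
  list(charges = q, screening_length_nm = screening_length_nm,
       dielectric = dielectric, ph = ph)
}

#' Surrogate stability score
#'
#' A fast, additive stand-in for an all-atom stability score (it is not
#' Rosetta and its absolute values are not comparable to Rosetta energies).
#' Lower is more stable. Two terms over the coiled-coil region, His-tag
#' excluded by construction:
#'
#' * core packing: `-w_core * KD(res)` summed over a/d positions
#'   (Kyte--Doolittle hydropathy, so burying hydrophobics is rewarded);
#' * surface salt bridges: `w_pair * q_i * q_j` summed over surface-position
#'   pairs at sequence separation 3 or 4 (opposite charges are rewarded).
#'
#' @param seq A `cc_seq` with a valid register.
#' @param w_core,w_pair Positive term weights (kcal/mol per unit).
#' @param model A [charge_model()] for the pair term.
#' @return Score in kcal/mol (nominal units).
#' @export
surrogate_rs <- function(seq, w_core = 1, w_pair = 0.5,
                         model = charge_model()) {
  res <- cc_residues(seq)
  if (length(res) == 0L) return(0)
  cls <- assign_register(seq)
  core <- cls %in% c("a", "d")
  e_core <- -w_core * sum(KD_HYDROPATHY[res[core]])
  q <- model$charges[res]
  q[core] <- 0  # pair term is surface-only
  e_pair <- 0
  n <- length(res)
  for (d in c(3L, 4L)) {
    if (n > d) {
      i <- seq_len(n - d)
      e_pair <- e_pair + w_pair * sum(q[i] * q[i + d])
    }
  }
  e_core + e_pair
}

# Idealized alpha-helix backbone coordinates (Angstrom) for residue indices
# i (1-based): rise 1.5 A/residue, 100 degrees/residue, configurable radius.
helix_coords <- function(idx, radius = 6, rise = 1.5, twist_deg = 100) {
  th <- (idx - 1) * twist_deg * pi / 180
  cbind(x = radius * cos(th), y = radius * sin(th), z = (idx - 1) * rise)
}

#' Surrogate terminal electrostatic-patch potential (E_bcf)
#'
#' Screened-Coulomb energy of the charged residues at surface wheel positions
#' b, c, f within one terminal half of the coiled-coil region, on idealized
#' helix coordinates. A stand-in for a Poisson--Boltzmann surface potential
#' (documented: it is not APBS). The terminal half is the first (N) or last
#' (C) `ceiling(L/2)` coiled-coil positions.
#'
#' The documented formula, in kJ/mol with distances in Angstrom:
#' \deqn{E = \sum_i \frac{k_e q_i^2}{2 r_{self}} +
#'       \sum_{i<j} \frac{k_e q_i q_j}{\epsilon_r r_{ij}} e^{-r_{ij}/\lambda}}
#' with `k_e = 1389.35` kJ A/mol (Coulomb constant for unit charges), a
#' Born-type self term with radius `r_self` (also divided by the dielectric),
#' and Debye length `lambda`. A net positive patch yields a positive
#' potential.
#'
#' @param seq A `cc_seq`.
#' @param terminus `"N"` or `"C"`.
#' @param model A [charge_model()].
#' @param radius Helix radius at which side-chain charges sit (Angstrom).
#' @param r_self Self-energy radius (Angstrom).
#' @return Potential in kJ/mol.
#' @export
surrogate_ebcf <- function(seq, terminus = c("N", "C"),
                           model = charge_model(), radius = 6, r_self = 2) {
  terminus <- match.arg(terminus)
  res <- cc_residues(seq)
  n <- length(res)
  if (n == 0L) stop("terminus half is empty", call. = FALSE)
  cls <- assign_register(seq)
  half_len <- ceiling(n / 2)
  idx <- if (terminus == "N") seq_len(half_len) else (n - half_len + 1L):n
  surf <- idx[cls[idx] %in% c("b", "c", "f")]
  q <- model$charges[res[surf]]
  keep <- q != 0
  surf <- surf[keep]
  q <- q[keep]
  if (length(q) == 0L) return(0)
  ke <- 1389.35  # kJ*Angstrom/mol for unit charges in vacuum
  eps <- model$dielectric
  lambda <- model$screening_length_nm * 10  # nm -> Angstrom
  e <- sum(ke * q^2 / (2 * r_self * eps))
  if (length(q) > 1L) {
    xyz <- helix_coords(surf, radius = radius)
    dmat <- as.matrix(stats::dist(xyz))
    pairs <- which(upper.tri(dmat), arr.ind = TRUE)
    r <- dmat[pairs]
    e <- e + sum(ke * q[pairs[, 1]] * q[pairs[, 2]] * exp(-r / lambda) /
                   (eps * r))
  }
  e
}

#' Combine terminal potentials into the patch-difference objective
#'
#' @param ne_bcf,ce_bcf N- and C-terminal potentials (kJ/mol).
#' @param convention `"N_minus_C"` (default), `"C_minus_N"`, or `"abs_diff"`.
#' @return Difference in kJ/mol under the chosen convention.
#' @export
delta_ee <- function(ne_bcf, ce_bcf,
                     convention = c("N_minus_C", "C_minus_N", "abs_diff")) {
  convention <- match.arg(convention)
  assert_finite(ne_bcf)
  assert_finite(ce_bcf)
  switch(convention,
         N_minus_C = ne_bcf - ce_bcf,
         C_minus_N = ce_bcf - ne_bcf,
         abs_diff = abs(ne_bcf - ce_bcf))
}

#' Bundle the scores of one sequence
#'
#' @param rs Stability score, kcal/mol.
#' @param ne_bcf,ce_bcf Terminal potentials, kJ/mol.
#' @param scorer_id Provenance label.
#' @param convention Passed to [delta_ee()].
#' @return A `score_bundle` list with fields `rs`, `ne_bcf`, `ce_bcf`,
#'   `dee_bcf`, `scorer_id`, `convention`, and explicit `units`.
#' @export
score_bundle <- function(rs, ne_bcf, ce_bcf, scorer_id = "surrogate",
                         convention = "N_minus_C") {
  assert_finite(c(rs, ne_bcf, ce_bcf))
  structure(
    list(rs = rs, ne_bcf = ne_bcf, ce_bcf = ce_bcf,
         dee_bcf = delta_ee(ne_bcf, ce_bcf, convention),
         scorer_id = scorer_id, convention = convention,
         units = list(rs = "kcal/mol", ne_bcf = "kJ/mol", ce_bcf = "kJ/mol",
                      dee_bcf = "kJ/mol")),
    class = "score_bundle"
  )
}

#' Built-in deterministic surrogate scorer
#'
#' Packages [surrogate_rs()] and [surrogate_ebcf()] behind the scorer
#' contract used by the Monte Carlo search: a function `seq -> score_bundle`,
#' deterministic, His-tag region excluded by construction.
#'
#' @param model A [charge_model()].
#' @param convention Patch-difference convention for `dee_bcf`.
#' @param w_core,w_pair,radius,r_self Surrogate parameters.
#' @return A function of one `cc_seq` returning a `score_bundle`.
#' @export
surrogate_scorer <- function(model = charge_model(),
                             convention = "N_minus_C",
                             w_core = 1, w_pair = 0.5,
                             radius = 6, r_self = 2) {
  force(model)
  function(seq) {
    score_bundle(
      rs = surrogate_rs(seq, w_core = w_core, w_pair = w_pair, model = model),
      ne_bcf = surrogate_ebcf(seq, "N", model, radius = radius,
                              r_self = r_self),
      ce_bcf = surrogate_ebcf(seq, "C", model, radius = radius,
                              r_self = r_self),
      scorer_id = "surrogate", convention = convention
    )
  }
}

#' Parse an externally computed score table
#'
#' Ingests stability scores and terminal potentials computed by external
#' tools as delimited text (comma or whitespace) with a header row naming at
#' least `id`, `rs`, `ne_bcf`, `ce_bcf`. Units may be declared in comment
#' lines of the form `# units: rs=kcal/mol ne_bcf=kJ/mol ce_bcf=kJ/mol`; a
#' declaration that contradicts the expected units is an error. A missing
#' `dee_bcf` column is computed from the convention.
#'
#' @param path Path to the table (or a character vector of its lines via
#'   `text`).
#' @param text Optional literal table text instead of `path`.
#' @param convention Passed to [delta_ee()].
#' @return Named list of `score_bundle` objects keyed by sequence id.
#' @export
parse_score_table <- function(path = NULL, text = NULL,
                              convention = "N_minus_C") {
  stopifnot(xor(is.null(path), is.null(text)))
  lines <- if (is.null(text)) readLines(path) else {
    if (length(text) == 1L) strsplit(text, "\n")[[1]] else text
  }
  expected <- c(rs = "kcal/mol", ne_bcf = "kJ/mol", ce_bcf = "kJ/mol")
  unit_lines <- grep("^#\\s*units:", lines, value = TRUE)
  for (ul in unit_lines) {
    decls <- regmatches(ul, gregexpr("[A-Za-z_]+=[^ \t]+", ul))[[1]]
    for (d in decls) {
      kv <- strsplit(d, "=")[[1]]
      if (kv[1] %in% names(expected) && kv[2] != expected[[kv[1]]]) {
        stop("unit mismatch for column '", kv[1], "': declared '", kv[2],
             "', expected '", expected[[kv[1]]], "'", call. = FALSE)
      }
    }
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  sep <- if (grepl(",", body[1])) "," else ""
  df <- utils::read.table(text = body, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  for (col in c("rs", "ne_bcf", "ce_bcf")) {
    if (!col %in% names(df)) {
      stop("score table is missing required column '", col, "'",
           call. = FALSE)
    }
  }
  ids <- if ("id" %in% names(df)) as.character(df$id) else
    as.character(seq_len(nrow(df)))
  out <- lapply(seq_len(nrow(df)), function(i) {
    b <- score_bundle(as.numeric(df$rs[i]), as.numeric(df$ne_bcf[i]),
                      as.numeric(df$ce_bcf[i]),
                      scorer_id = "external", convention = convention)
    if ("dee_bcf" %in% names(df)) b$dee_bcf <- as.numeric(df$dee_bcf[i])
    b
  })
  stats::setNames(out, ids)
}
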