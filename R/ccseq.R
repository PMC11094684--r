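#' @keywords internal
"_PACKAGE"

CANONICAL_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

WHEEL_CLASSES <- c("a", "b", "c", "d", "e", "f", "g")

#' Default heptad position alphabets
#'
#' Allowed substitutions per helical-wheel class used by the design search:
#' core positions (a, d) draw from hydrophobic/polar residues favoured in
#' homopentameric coiled-coils; surface positions (b, c, e, f, g) draw from a
#' charged/neutral set.
#'
#' @return Named list mapping each wheel class `a`--`g` to a character vector
#'   of allowed one-letter residue codes.
#' @export
#' @examples
#' default_alphabets()$a
default_alphabets <- function() {
  core <- c("V", "I", "M", "T", "Q", "L")
  surf <- c("A", "E", "K", "Q", "N", "T", "D")
  list(a = core, b = surf, c = surf, d = core, e = surf, f = surf, g = surf)
}

validate_alphabets <- function(alphabets) {
  stopifnot(is.list(alphabets), all(WHEEL_CLASSES %in% names(alphabets)))
  for (cl in WHEEL_CLASSES) {
    bad <- setdiff(alphabets[[cl]], CANONICAL_AA)
    if (length(bad) > 0L) {
      stop("non-canonical residue(s) in alphabet for class '", cl, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(alphabets)
}

#' Construct a coiled-coil sequence object
#'
#' Wraps a protein sequence together with the index bookkeeping the design
#' search needs: an excluded His-tag region (default residues 1--16, which are
#' never mutated or scored), the coiled-coil domain (default the 38 residues
#' following the tag), and the heptad register offset that maps the first
#' coiled-coil residue onto a wheel class.
#'
#' All index ranges are 1-based and inclusive.
#'
#' @param residues Character scalar (one-letter codes) or character vector of
#'   single residues. Lowercase input is uppercased.
#' @param his_tag_region Integer length-2 vector, inclusive range of the
#'   His-tag region excluded from mutation and scoring; `NULL` for none.
#' @param cc_region Integer length-2 vector, inclusive range of the
#'   coiled-coil domain. Defaults to everything after the His-tag region.
#' @param register_offset Integer in 0..6; 0 places the first coiled-coil
#'   residue at wheel class `a`.
#' @param id Sequence identifier carried through FASTA I/O.
#' @return An object of class `cc_seq`.
#' @export
#' @examples
#' s <- cc_seq("MRGSHHHHHHGSGSGSIKKLQKAMKKIQKALKKIQETMEDLNETIDELNETIED")
#' length(cc_residues(s))
cc_seq <- function(residues,
                   his_tag_region = c(1L, 16L),
                   cc_region = NULL,
                   register_offset = 0L,
                   id = "seq") {
  if (is.character(residues) && length(residues) == 1L && nchar(residues) > 1L) {
    residues <- strsplit(residues, "")[[1]]
  }
  residues <- toupper(residues)
  bad <- which(!residues %in% CANONICAL_AA)
  if (length(bad) > 0L) {
    stop("non-canonical residue '", residues[bad[1]], "' at position ", bad[1],
         call. = FALSE)
  }
  n <- length(residues)
  if (!is.null(his_tag_region)) {
    his_tag_region <- as.integer(his_tag_region)
    stopifnot(length(his_tag_region) == 2L,
              his_tag_region[1] >= 1L, his_tag_region[2] <= n,
              his_tag_region[1] <= his_tag_region[2])
  }
  if (is.null(cc_region)) {
    start <- if (is.null(his_tag_region)) 1L else his_tag_region[2] + 1L
    cc_region <- c(start, n)
  }
  cc_region <- as.integer(cc_region)
  stopifnot(length(cc_region) == 2L, cc_region[1] >= 1L, cc_region[2] <= n,
            cc_region[1] <= cc_region[2])
  if (!is.null(his_tag_region) &&
      cc_region[1] <= his_tag_region[2] && his_tag_region[1] <= cc_region[2]) {
    stop("his_tag_region and cc_region overlap", call. = FALSE)
  }
  register_offset <- as.integer(register_offset)
  if (register_offset < 0L || register_offset > 6L) {
    stop("register_offset must be in 0..6", call. = FALSE)
  }
  structure(
    list(residues = residues, his_tag_region = his_tag_region,
         cc_region = cc_region, register_offset = register_offset, id = id),
    class = "cc_seq"
  )
}

#' @export
print.cc_seq <- function(x, ...) {
  cat("<cc_seq> ", x$id, " (", length(x$residues), " aa)\n", sep = "")
  cat("  coiled-coil region: ", x$cc_region[1], "-", x$cc_region[2],
      " (offset ", x$register_offset, ")\n", sep = "")
  if (!is.null(x$his_tag_region)) {
    cat("  His-tag region:     ", x$his_tag_region[1], "-",
        x$his_tag_region[2], " (excluded)\n", sep = "")
  }
  cat("  ", paste(x$residues, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Residues of the coiled-coil region
#' @param seq A `cc_seq`.
#' @return Character vector of one-letter codes over the coiled-coil domain.
#' @export
cc_residues <- function(seq) {
  stopifnot(inherits(seq, "cc_seq"))
  seq$residues[seq$cc_region[1]:seq$cc_region[2]]
}

#' Assign the heptad register over the coiled-coil region
#'
#' Wheel classes a--g cycle with period 7 along the coiled-coil region;
#' position i (1-based within the region) gets class
#' `letters[((i - 1 + register_offset) mod 7) + 1]`.
#'
#' @param seq A `cc_seq`.
#' @return Character vector of wheel classes, one per coiled-coil position.
#' @export
#' @examples
#' s <- cc_seq("IKKLQKA", his_tag_region = NULL)
#' assign_register(s)  # a b c d e f g
assign_register <- function(seq) {
  stopifnot(inherits(seq, "cc_seq"))
  n <- seq$cc_region[2] - seq$cc_region[1] + 1L
  WHEEL_CLASSES[((seq_len(n) - 1L + seq$register_offset) %% 7L) + 1L]
}

#' Infer the register offset maximizing core hydrophobicity
#'
#' Tries all 7 offsets and returns the one placing the most hydrophobic
#' residues (by Kyte--Doolittle index) at the a/d core positions. Useful when
#' the register of a sequence is not annotated.
#'
#' @param seq A `cc_seq` (its `register_offset` is ignored).
#' @return Integer offset in 0..6.
#' @export
infer_register_offset <- function(seq) {
  res <- cc_residues(seq)
  kd <- KD_HYDROPATHY[res]
  best <- 0L
  best_val <- -Inf
  for (off in 0:6) {
    cls <- WHEEL_CLASSES[((seq_along(res) - 1L + off) %% 7L) + 1L]
    val <- sum(kd[cls %in% c("a", "d")])
    if (val > best_val) {
      best_val <- val
      best <- off
    }
  }
  best
}

#' Propose a single mutation under the position-class alphabets
#'
#' Samples a mutable coiled-coil position uniformly, then a target residue
#' uniformly from the position's wheel-class alphabet minus the current
#' residue. Positions inside the His-tag region are never proposed;
#' self-mutations are excluded.
#'
#' @param seq A `cc_seq`.
#' @param alphabets Named list as from [default_alphabets()].
#' @return List with `position` (1-based index within the coiled-coil
#'   region), `from_res`, `to_res`, `wheel_class`.
#' @export
propose_mutation <- function(seq, alphabets = default_alphabets()) {
  validate_alphabets(alphabets)
  res <- cc_residues(seq)
  cls <- assign_register(seq)
  n_alt <- vapply(seq_along(res), function(i) {
    length(setdiff(alphabets[[cls[i]]], res[i]))
  }, integer(1))
  mutable <- which(n_alt > 0L)
  if (length(mutable) == 0L) {
    stop("no valid proposal: no position has an alternative residue",
         call. = FALSE)
  }
  pos <- mutable[sample.int(length(mutable), 1L)]
  choices <- setdiff(alphabets[[cls[pos]]], res[pos])
  to <- choices[sample.int(length(choices), 1L)]
  list(position = pos, from_res = res[pos], to_res = to,
       wheel_class = cls[pos])
}

#' Apply a mutation proposal to a sequence
#' @param seq A `cc_seq`.
#' @param proposal As returned by [propose_mutation()].
#' @return New `cc_seq` with the substitution applied.
#' @export
apply_mutation <- function(seq, proposal) {
  stopifnot(inherits(seq, "cc_seq"))
  idx <- seq$cc_region[1] + proposal$position - 1L
  if (!is.null(seq$his_tag_region) &&
      idx >= seq$his_tag_region[1] && idx <= seq$his_tag_region[2]) {
    stop("proposal falls inside the His-tag region", call. = FALSE)
  }
  if (!identical(seq$residues[idx], proposal$from_res)) {
    stop("proposal from_res does not match current residue", call. = FALSE)
  }
  seq$residues[idx] <- proposal$to_res
  seq
}

#' Ungapped identity between two sequences over a region
#'
#' Position-by-position comparison (no alignment is performed); regions of
#' unequal length are an error.
#'
#' @param a,b `cc_seq` objects.
#' @param region Which region to compare: `"cc"` (default, coiled-coil
#'   region of each sequence) or `"full"`.
#' @return List with `match_count`, `fraction`, `substitution_count`,
#'   `length`.
#' @export
#' @examples
#' qs <- q_family_sequences()
#' identity_fraction(qs$Q, qs$Q8)
identity_fraction <- function(a, b, region = c("cc", "full")) {
  region <- match.arg(region)
  ra <- if (region == "cc") cc_residues(a) else a$residues
  rb <- if (region == "cc") cc_residues(b) else b$residues
  if (length(ra) != length(rb)) {
    stop("regions have unequal lengths (", length(ra), " vs ", length(rb),
         "); gapped alignment is not performed", call. = FALSE)
  }
  m <- sum(ra == rb)
  list(match_count = m, fraction = m / length(ra),
       substitution_count = length(ra) - m, length = length(ra))
}

#' Read protein sequences from FASTA
#'
#' Parses via Biostrings and validates that every residue is one of the 20
#' canonical amino acids (lowercase is uppercased); the error names the first
#' offending position. Region annotations (His-tag, coiled-coil, register
#' offset) are not part of FASTA and are supplied as arguments.
#'
#' @param path Path to a FASTA file.
#' @param his_tag_region,cc_region,register_offset Passed to [cc_seq()].
#' @return A list of `cc_seq` objects, named by FASTA header.
#' @export
read_fasta <- function(path, his_tag_region = c(1L, 16L), cc_region = NULL,
                       register_offset = 0L) {
  set <- Biostrings::readAAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    cc_seq(as.character(set[[i]]),
           his_tag_region = his_tag_region, cc_region = cc_region,
           register_offset = register_offset, id = names(set)[i])
  })
  names(out) <- names(set)
  out
}

#' Write sequences to FASTA
#' @param seqs A `cc_seq` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "cc_seq")) seqs <- list(seqs)
  set <- Biostrings::AAStringSet(
    vapply(seqs, function(s) paste(s$residues, collapse = ""), character(1))
  )
  names(set) <- vapply(seqs, function(s) s$id, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
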