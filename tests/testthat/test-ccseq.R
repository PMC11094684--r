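test_that("register assignment cycles a-g with the configured offset", {
  s7 <- cc_seq("IKKLQKA", his_tag_region = NULL)
  expect_identical(assign_register(s7), c("a", "b", "c", "d", "e", "f", "g"))

  s7_off <- cc_seq("IKKLQKA", his_tag_region = NULL, register_offset = 3)
  expect_identical(assign_register(s7_off),
                   c("d", "e", "f", "g", "a", "b", "c"))

  qs <- q_family_sequences()
  reg <- assign_register(qs$Q8)
  # brute-force modular enumeration oracle
  expect_identical(reg, letters[1:7][((seq_len(38) - 1) %% 7) + 1])
  expect_identical(sum(reg == "a"), 6L)

  expect_error(cc_seq("IKKLQKA", his_tag_region = NULL,
                      register_offset = 7), "register_offset")
})

test_that("sequence construction validates residues and regions", {
  expect_error(cc_seq("IKXLQKA", his_tag_region = NULL),
               "non-canonical residue 'X' at position 3")
  # lowercase is normalized
  s <- cc_seq("ikklqka", his_tag_region = NULL)
  expect_identical(paste(s$residues, collapse = ""), "IKKLQKA")
  # overlapping regions rejected
  expect_error(cc_seq(strrep("A", 20), his_tag_region = c(1, 16),
                      cc_region = c(10, 20)), "overlap")
})

test_that("mutation proposals respect alphabets, His-tag, and uniformity", {
  # forced choice: single mutable position with a two-letter alphabet
  s <- toy_seq(c("K", "A", "A"))
  alph <- list(a = "I", b = c("K", "V"), c = "A", d = "L",
               e = "A", f = "A", g = "A")
  p <- propose_mutation(s, alph)
  expect_identical(p$position, 2L)
  expect_identical(p$from_res, "K")
  expect_identical(p$to_res, "V")

  # no mutable position -> error
  expect_error(propose_mutation(toy_seq(c("K", "A", "A")),
                                list(a = "I", b = "K", c = "A", d = "L",
                                     e = "A", f = "A", g = "A")),
               "no valid proposal")

  # class-a proposals always draw from the core alphabet
  qs <- q_family_sequences()
  set.seed(42)
  core <- default_alphabets()$a
  for (i in 1:200) {
    pr <- propose_mutation(qs$Q8)
    if (pr$wheel_class %in% c("a", "d")) expect_true(pr$to_res %in% core)
    # proposals never land in the His-tag region and never self-mutate
    expect_true(pr$to_res != pr$from_res)
    expect_true(pr$position >= 1 && pr$position <= 38)
  }

  # positions sampled uniformly among mutable positions (chi-square)
  s14 <- cc_seq(strrep("IKKLQKA", 2), his_tag_region = NULL)
  set.seed(7)
  pos <- replicate(1e5, propose_mutation(s14)$position)
  tab <- tabulate(pos, nbins = 14)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("proposal stream under a fixed seed is exactly reproducible", {
  qs <- q_family_sequences()
  set.seed(123)
  a <- replicate(50, propose_mutation(qs$Q4), simplify = FALSE)
  set.seed(123)
  b <- replicate(50, propose_mutation(qs$Q4), simplify = FALSE)
  expect_identical(a, b)
})

test_that("identity_fraction counts substitutions exactly and symmetrically", {
  qs <- q_family_sequences()
  self <- identity_fraction(qs$Q8, qs$Q8)
  expect_identical(self$match_count, 38L)
  expect_identical(self$fraction, 1)
  expect_identical(self$substitution_count, 0L)

  qq8 <- identity_fraction(qs$Q, qs$Q8)
  expect_identical(qq8$substitution_count, 25L)
  expect_equal(qq8$fraction, 13 / 38, tolerance = 1e-12)

  # brute-force position-by-position oracle on a random pair
  set.seed(5)
  r1 <- sample(c("A", "K", "E", "L"), 38, replace = TRUE)
  r2 <- sample(c("A", "K", "E", "L"), 38, replace = TRUE)
  s1 <- cc_seq(paste(r1, collapse = ""), his_tag_region = NULL)
  s2 <- cc_seq(paste(r2, collapse = ""), his_tag_region = NULL)
  brute <- sum(vapply(1:38, function(i) r1[i] == r2[i], logical(1)))
  expect_identical(identity_fraction(s1, s2)$match_count, brute)
  expect_identical(identity_fraction(s1, s2), identity_fraction(s2, s1))

  # no gapped alignment: unequal lengths are an error
  s3 <- cc_seq("IKKLQKA", his_tag_region = NULL)
  expect_error(identity_fraction(s1, s3), "unequal lengths")
})

test_that("FASTA round trip preserves residues and headers", {
  qs <- q_family_sequences()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(qs, path)
  back <- read_fasta(path)
  expect_identical(
    unname(vapply(back, function(s) paste(s$residues, collapse = ""),
                  character(1))),
    unname(vapply(qs, function(s) paste(s$residues, collapse = ""),
                  character(1))))
  expect_identical(unname(names(back)),
                   unname(vapply(qs, `[[`, character(1), "id")))

  # lowercase FASTA input normalizes to canonical uppercase
  p2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">lc", "mkvlaa"), p2)
  lc <- read_fasta(p2, his_tag_region = NULL)[[1]]
  expect_identical(paste(lc$residues, collapse = ""), "MKVLAA")

  # non-canonical residue named by position
  p3 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">bad", "MKXLAA"), p3)
  expect_error(read_fasta(p3, his_tag_region = NULL), "position 3")
})

test_that("packaged synthetic FASTA matches the in-code fixtures", {
  path <- system.file("extdata", "q_family_synthetic.fasta",
                      package = "coilgel")
  seqs <- read_fasta(path, his_tag_region = c(1, 16), cc_region = c(17, 54))
  qs <- q_family_sequences()
  expect_identical(paste(cc_residues(seqs[[3]]), collapse = ""),
                   paste(cc_residues(qs$Q8), collapse = ""))
})

test_that("register inference recovers the constructed offset", {
  qs <- q_family_sequences()
  expect_identical(infer_register_offset(qs$Q8), 0L)
  shifted <- cc_seq(paste(c("A", "A", "A", cc_residues(qs$Q8)),
                          collapse = ""),
                    his_tag_region = NULL, register_offset = 0L)
  # true register of the appended design now starts 3 positions later
  expect_identical(infer_register_offset(shifted), 4L)
})
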