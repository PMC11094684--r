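test_that("acceptance probability is Metropolis-like in the score delta", {
  expect_identical(p_accept_rs(0), 1)
  expect_identical(p_accept_rs(-5000), 1)
  # default constants give exp(-c * delta) for worsening moves
  expect_equal(p_accept_rs(10000, c = 3.93e-5), exp(-3.93e-5 * 10000),
               tolerance = 1e-12)
  expect_equal(p_accept_ebcf(10000, c = 1.31e-4), exp(-1.31e-4 * 10000),
               tolerance = 1e-12)
  # monotone non-increasing on a grid
  grid <- seq(-1e4, 1e5, length.out = 200)
  p <- vapply(grid, p_accept_rs, numeric(1))
  expect_true(all(diff(p) <= 1e-15))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(p_accept_rs(NaN), "non-finite")
})

test_that("empirical acceptance frequency matches the analytic probability", {
  # seeded Bernoulli draws against the analytic gate probability
  set.seed(99)
  for (delta in c(5e3, 2e4, 6e4)) {
    p <- p_accept_rs(delta)
    n <- 1e5
    acc <- mean(stats::runif(n) < p)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(acc - p), 3 * se)
  }
})

test_that("a step accepts iff every gate passes, and rejection is a no-op", {
  cfg <- search_config(seed = 1, alphabets = toy_alphabets())
  sc <- toy_scorer()
  # improving start: fully charged surface relaxes toward neutral
  state <- list(seq = toy_seq(c("K", "K", "K")),
                scores = sc(toy_seq(c("K", "K", "K"))))
  set.seed(4)
  for (i in 1:50) {
    out <- mc_step(state, sc, cfg)
    r <- out$record
    expect_true(all(r$gate_probabilities >= 0 & r$gate_probabilities <= 1))
    if (all(r$gate_probabilities == 1)) expect_true(r$accepted)
    if (!r$accepted) {
      expect_identical(out$state$seq$residues, state$seq$residues)
      expect_identical(out$state$scores, state$scores)
    }
    state <- out$state
  }
})

test_that("long-run step acceptance equals the product of gate probabilities", {
  # single mutable position, two-letter alphabet: the only proposal worsens
  # the N-terminal patch (A -> K adds a charge)
  alph <- list(a = "I", b = c("A", "K"), c = "A", d = "L",
               e = "A", f = "A", g = "A")
  # gate constant scaled so the worsening move has mid-range probability
  cfg <- search_config(c_ne = 2e-4, seed = 1, alphabets = alph)
  sc <- toy_scorer()
  state <- list(seq = toy_seq(c("A", "A", "A")),
                scores = sc(toy_seq(c("A", "A", "A"))))
  set.seed(11)
  n <- 2e4
  acc <- logical(n)
  p_prod <- NULL
  for (i in seq_len(n)) {
    out <- mc_step(state, sc, cfg)
    acc[i] <- out$record$accepted
    p_prod <- prod(out$record$gate_probabilities)
  }
  expect_gt(p_prod, 0.05)
  expect_lt(p_prod, 0.95)
  se <- sqrt(p_prod * (1 - p_prod) / n)
  expect_lt(abs(mean(acc) - p_prod), 3 * se)
})

test_that("search trajectories replay byte-identically from the seed", {
  cfg <- search_config(min_mutations = 20, seed = 33,
                       alphabets = toy_alphabets(),
                       counting_mode = "attempted")
  sc <- toy_scorer()
  t1 <- run_search(cfg, sc, toy_seq(c("K", "K", "K")))
  t2 <- run_search(cfg, sc, toy_seq(c("K", "K", "K")))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_trajectory(t1, f1)
  write_trajectory(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("greedy-limit chains are monotone in every gated objective", {
  # huge gate constants: worsening moves are never accepted
  cfg <- search_config(c_rs = 1e3, c_ne = 1e3, c_ce = 1e3,
                       min_mutations = 60, counting_mode = "attempted",
                       seed = 5)
  qs <- q_family_sequences()
  tr <- run_search(cfg, surrogate_scorer(), qs$Q4)
  acc <- Filter(function(r) r$accepted, tr$records)
  for (field in c("rs", "ne_bcf", "ce_bcf")) {
    vals <- vapply(acc, function(r) r$scores_after[[field]], numeric(1))
    prev <- vapply(acc, function(r) r$scores_before[[field]], numeric(1))
    expect_true(all(vals <= prev + 1e-9))
  }
})

test_that("toy-space search reaches the exhaustively enumerated optimum", {
  enum <- toy_enumerate()
  best_dee <- min(enum$dee)
  cfg <- search_config(c_rs = 1e3, c_ne = 1e3, c_ce = 1e3,
                       min_mutations = 300, counting_mode = "attempted",
                       seed = 1, alphabets = toy_alphabets())
  sc <- toy_scorer()
  hits <- vapply(1:20, function(s) {
    cfg$seed <- s
    tr <- run_search(cfg, sc, toy_seq(c("K", "K", "K")))
    abs(tr$best$scores$dee_bcf - best_dee) < 1e-9
  }, logical(1))
  expect_gte(sum(hits), 19L)
})

test_that("design selection follows fewest-mutations-then-lowest-dee", {
  mk <- function(id, dee, count) {
    structure(list(simulation_id = id, seed = id, records = list(),
                   n_accepted = count, n_attempts = count,
                   best = list(seq = toy_seq(), success_index = count,
                               scores = score_bundle(0, dee, 0))),
              class = "search_trajectory")
  }
  # per-trajectory minima reached at mutation counts 12, 9, 30
  sel <- select_design(list(mk(1L, -5, 12L), mk(2L, -4, 9L),
                            mk(3L, -9, 30L)))
  expect_identical(sel$simulation_id, 2L)
  expect_identical(sel$mutation_count, 9L)

  # single trajectory, single accepted mutation
  sel1 <- select_design(list(mk(7L, -2, 1L)))
  expect_identical(sel1$simulation_id, 7L)

  # equal counts: lower dee wins
  sel2 <- select_design(list(mk(1L, -5, 10L), mk(2L, -8, 10L)))
  expect_identical(sel2$simulation_id, 2L)
  # full tie: lower simulation id
  sel3 <- select_design(list(mk(2L, -5, 10L), mk(1L, -5, 10L)))
  expect_identical(sel3$simulation_id, 1L)
  expect_error(select_design(list()), "no trajectories")
})

test_that("a full campaign runs from the packaged input and selects a design", {
  qs <- q_family_sequences()
  cfg <- search_config(min_mutations = 25, n_simulations = 3, seed = 2)
  out <- run_design_campaign(cfg, surrogate_scorer(), qs$Q4)
  expect_length(out$trajectories, 3L)
  expect_true(all(vapply(out$trajectories, function(tr) {
    tr$n_accepted >= 25
  }, logical(1))))
  dees <- vapply(out$trajectories, function(tr) tr$best$scores$dee_bcf,
                 numeric(1))
  expect_true(out$selection$scores$dee_bcf %in% dees)
  # running best really is the minimum over accepted states
  tr <- out$trajectories[[1]]
  acc_dee <- vapply(Filter(function(r) r$accepted, tr$records),
                    function(r) r$scores_after$dee_bcf, numeric(1))
  input_dee <- surrogate_scorer()(qs$Q4)$dee_bcf
  expect_equal(tr$best$scores$dee_bcf, min(c(acc_dee, input_dee)),
               tolerance = 1e-12)
})
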