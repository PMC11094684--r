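#' Search configuration for the trimodal Monte Carlo design search
#'
#' Three acceptance gates act per proposed mutation: one on the stability
#' score and one on each terminal surface-patch potential. Each gate accepts
#' an improving (non-increasing) move with probability 1 and a worsening move
#' with probability `exp(-C * delta)` where `delta` is the score increase in
#' J/mol and `C` is the gate's empirical constant in mol/J. A proposal is
#' accepted only if all three gates pass (independent Bernoulli draws).
#'
#' `rt` (gas constant times temperature, J/mol) is carried for unit
#' bookkeeping; in the dimensionless exponent `C * RT * (delta/RT)` it
#' cancels, so it does not change the acceptance probability.
#'
#' @param c_rs Gate constant for the stability score, mol/J (default
#'   3.93e-5).
#' @param c_ne,c_ce Gate constants for the N- and C-terminal potentials,
#'   mol/J (defaults 1.31e-4 and 1.96e-4).
#' @param temperature_k Temperature in kelvin for `rt` (default 298.15).
#' @param min_mutations Stop after this many mutations (default 150),
#'   counted per `counting_mode`.
#' @param n_simulations Number of independent simulations for
#'   [run_design_campaign()] (default 5).
#' @param counting_mode `"accepted"` (default; successful mutations) or
#'   `"attempted"`.
#' @param max_attempts Safety cap on proposal attempts per simulation.
#' @param seed Integer seed; each simulation derives its own stream.
#' @param alphabets Position alphabets for proposals.
#' @param convention Patch-difference convention used for trajectory
#'   book-keeping.
#' @return A `search_config` list.
#' @export
search_config <- function(c_rs = 3.93e-5, c_ne = 1.31e-4, c_ce = 1.96e-4,
                          temperature_k = 298.15, min_mutations = 150L,
                          n_simulations = 5L,
                          counting_mode = c("accepted", "attempted"),
                          max_attempts = 100000L, seed = 1L,
                          alphabets = default_alphabets(),
                          convention = "N_minus_C") {
  counting_mode <- match.arg(counting_mode)
  stopifnot(c_rs > 0, c_ne > 0, c_ce > 0, temperature_k > 0,
            min_mutations >= 1L, n_simulations >= 1L, max_attempts >= 1L)
  validate_alphabets(alphabets)
  list(c_rs = c_rs, c_ne = c_ne, c_ce = c_ce,
       rt = 8.314462618 * temperature_k,
       min_mutations = as.integer(min_mutations),
       n_simulations = as.integer(n_simulations),
       counting_mode = counting_mode,
       max_attempts = as.integer(max_attempts),
       seed = as.integer(seed), alphabets = alphabets,
       convention = convention)
}

p_accept <- function(delta_j_mol, c_mol_j, rt_j_mol) {
  if (!is.finite(delta_j_mol)) stop("non-finite score delta", call. = FALSE)
  stopifnot(c_mol_j > 0, rt_j_mol > 0)
  if (delta_j_mol <= 0) return(1)
  min(1, exp(-c_mol_j * delta_j_mol))
}

#' Acceptance probability for a stability-score change
#'
#' Probability of accepting a mutant whose stability score worsens
#' (increases) by `delta_rs` J/mol: 1 for improving or neutral moves,
#' `exp(-c * delta_rs)` otherwise, clamped to `[0, 1]`. `rt` cancels in the
#' dimensionless exponent and is validated only.
#'
#' @param delta_rs Score change in J/mol (convert kcal/mol upstream).
#' @param c Gate constant, mol/J.
#' @param rt Gas constant times temperature, J/mol.
#' @return Probability in `[0, 1]`.
#' @export
p_accept_rs <- function(delta_rs, c = 3.93e-5, rt = 8.314462618 * 298.15) {
  p_accept(delta_rs, c, rt)
}

#' Acceptance probability for a terminal-potential change
#'
#' Same functional form as [p_accept_rs()], with the per-terminus constants
#' (N: 1.31e-4, C: 1.96e-4 mol/J).
#'
#' @param delta_e Potential change in J/mol.
#' @param c Gate constant, mol/J.
#' @param rt Gas constant times temperature, J/mol.
#' @return Probability in `[0, 1]`.
#' @export
p_accept_ebcf <- function(delta_e, c = 1.31e-4, rt = 8.314462618 * 298.15) {
  p_accept(delta_e, c, rt)
}

#' One Monte Carlo step
#'
#' Proposes a mutation, scores it, evaluates the three gates (stability in
#' kcal/mol and both terminal potentials in kJ/mol, each converted to J/mol
#' before the exponent), draws one Bernoulli per gate, and accepts only if
#' all pass. Uses the current R RNG stream.
#'
#' @param state List with `seq` (a `cc_seq`) and `scores` (its
#'   `score_bundle`).
#' @param scorer Function `cc_seq -> score_bundle` (deterministic).
#' @param config A [search_config()].
#' @return List with `state` (updated or unchanged) and `record` (the
#'   mutation record: proposal, both score bundles, per-gate probabilities
#'   and draws, `accepted`).
#' @export
mc_step <- function(state, scorer, config) {
  prop <- propose_mutation(state$seq, config$alphabets)
  cand <- apply_mutation(state$seq, prop)
  sc <- scorer(cand)
  d_rs <- (sc$rs - state$scores$rs) * KCAL_TO_J
  d_ne <- (sc$ne_bcf - state$scores$ne_bcf) * KJ_TO_J
  d_ce <- (sc$ce_bcf - state$scores$ce_bcf) * KJ_TO_J
  p <- c(rs = p_accept_rs(d_rs, config$c_rs, config$rt),
         ne = p_accept_ebcf(d_ne, config$c_ne, config$rt),
         ce = p_accept_ebcf(d_ce, config$c_ce, config$rt))
  draws <- stats::runif(3L)
  accepted <- all(draws < p)
  record <- list(proposal = prop, scores_before = state$scores,
                 scores_after = sc, gate_probabilities = p,
                 gate_draws = draws, accepted = accepted)
  if (accepted) state <- list(seq = cand, scores = sc)
  list(state = state, record = record)
}

#' Run one Monte Carlo design simulation
#'
#' Repeats [mc_step()] until `min_mutations` mutations have been made
#' (counted as accepted mutations by default, or as attempts), tracking the
#' running best state by minimum patch-difference objective `dee_bcf`.
#' Identical `seed` + config + input reproduce the trajectory exactly.
#'
#' @param config A [search_config()].
#' @param scorer Function `cc_seq -> score_bundle`.
#' @param input_seq Starting `cc_seq`.
#' @param simulation_id Integer label stored in the trajectory.
#' @return A `search_trajectory`: `simulation_id`, `seed`, `records` (one
#'   per attempt), `n_accepted`, `best` (sequence, scores, `success_index` at
#'   which the best state was first reached; index 0 is the input state).
#' @export
run_search <- function(config, scorer, input_seq, simulation_id = 1L) {
  # fail early if nothing can be proposed
  res <- cc_residues(input_seq)
  cls <- assign_register(input_seq)
  any_mutable <- any(vapply(seq_along(res), function(i) {
    length(setdiff(config$alphabets[[cls[i]]], res[i])) > 0L
  }, logical(1)))
  if (!any_mutable) stop("no mutable position in input sequence",
                         call. = FALSE)

  seed <- config$seed + simulation_id - 1L
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  state <- list(seq = input_seq, scores = scorer(input_seq))
  best <- list(seq = state$seq, scores = state$scores, success_index = 0L)
  records <- vector("list", 0L)
  n_accepted <- 0L
  attempts <- 0L
  repeat {
    done <- if (config$counting_mode == "accepted") {
      n_accepted >= config$min_mutations
    } else {
      attempts >= config$min_mutations
    }
    if (done || attempts >= config$max_attempts) break
    step <- mc_step(state, scorer, config)
    attempts <- attempts + 1L
    state <- step$state
    rec <- step$record
    rec$attempt_index <- attempts
    if (rec$accepted) {
      n_accepted <- n_accepted + 1L
      rec$success_index <- n_accepted
      if (state$scores$dee_bcf < best$scores$dee_bcf) {
        best <- list(seq = state$seq, scores = state$scores,
                     success_index = n_accepted)
      }
    }
    records[[attempts]] <- rec
  }
  structure(
    list(simulation_id = simulation_id, seed = seed, records = records,
         n_accepted = n_accepted, n_attempts = attempts, best = best),
    class = "search_trajectory"
  )
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.search_trajectory <- function(x, ...) {
  cat("<search_trajectory> simulation", x$simulation_id,
      "| seed", x$seed, "\n")
  cat("  attempts:", x$n_attempts, " accepted:", x$n_accepted, "\n")
  cat("  best dee_bcf:", format(x$best$scores$dee_bcf),
      "kJ/mol at success", x$best$success_index, "\n")
  invisible(x)
}

#' Run a multi-simulation design campaign
#'
#' Runs `config$n_simulations` independent simulations (seeds derived from
#' `config$seed`) from the same input and selects the final design with
#' [select_design()].
#'
#' @inheritParams run_search
#' @return List with `trajectories` and `selection`.
#' @export
run_design_campaign <- function(config, scorer, input_seq) {
  trajectories <- lapply(seq_len(config$n_simulations), function(i) {
    run_search(config, scorer, input_seq, simulation_id = i)
  })
  list(trajectories = trajectories, selection = select_design(trajectories))
}

#' Select the final design from a set of trajectories
#'
#' For each trajectory, take the state with the minimum patch-difference
#' objective and the (accepted-)mutation count at which it was first
#' reached. The chosen design is the candidate reached with the fewest
#' mutations; ties break by lower `dee_bcf`, then by lower simulation id.
#'
#' @param trajectories Non-empty list of `search_trajectory` objects.
#' @return List with `seq`, `scores`, `simulation_id`, `mutation_count`.
#' @export
select_design <- function(trajectories) {
  if (length(trajectories) == 0L) stop("no trajectories", call. = FALSE)
  cand <- lapply(trajectories, function(tr) {
    list(seq = tr$best$seq, scores = tr$best$scores,
         simulation_id = tr$simulation_id,
         mutation_count = tr$best$success_index)
  })
  ord <- order(vapply(cand, `[[`, numeric(1), "mutation_count"),
               vapply(cand, function(x) x$scores$dee_bcf, numeric(1)),
               vapply(cand, `[[`, integer(1), "simulation_id"))
  cand[[ord[1]]]
}

#' Serialize a trajectory to JSON
#'
#' One record per attempt with the proposal, per-gate probabilities, and the
#' outcome; suitable for replay auditing.
#'
#' @param trajectory A `search_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  recs <- lapply(trajectory$records, function(r) {
    list(attempt = r$attempt_index, position = r$proposal$position,
         from = r$proposal$from_res, to = r$proposal$to_res,
         wheel_class = r$proposal$wheel_class,
         p_rs = r$gate_probabilities[["rs"]],
         p_ne = r$gate_probabilities[["ne"]],
         p_ce = r$gate_probabilities[["ce"]],
         accepted = r$accepted,
         dee_bcf_after = r$scores_after$dee_bcf)
  })
  obj <- list(simulation_id = trajectory$simulation_id,
              seed = trajectory$seed,
              n_attempts = trajectory$n_attempts,
              n_accepted = trajectory$n_accepted,
              best = list(
                sequence = paste(trajectory$best$seq$residues, collapse = ""),
                dee_bcf = trajectory$best$scores$dee_bcf,
                rs = trajectory$best$scores$rs,
                success_index = trajectory$best$success_index),
              records = recs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
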