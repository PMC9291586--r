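# Parameter sweeps: seeded sampling of SA and epistasis coefficients,
# replicate transition runs, and tidy result tables.

#' Configure a parameter sweep
#'
#' A sweep runs `n_replicates` independent transition scenarios for one
#' (transition, epistasis type, epistasis partner) cell, sampling the SA
#' effect magnitudes `s_Y`, `s_new` and the epistasis effect size epsilon
#' independently and uniformly from their ranges (default `(0, 0.05)`,
#' with `sM = -sF` enforced at every active SA locus). Each replicate gets
#' a recorded sub-seed derived from the master seed by a counter-based
#' scheme, so parameter draws are reproducible replicate-by-replicate and
#' independent of execution order.
#'
#' @inheritParams scenario_spec
#' @param n_replicates Number of replicates (default 1000).
#' @param s_range,eps_range Sampling ranges `c(lo, hi)` with
#'   `0 <= lo <= hi`; a degenerate range `c(x, x)` pins the coefficient to
#'   `x` (e.g. `eps_range = c(0, 0)` for the no-epistasis validation set).
#' @param seed Master seed (integer).
#' @return An object of class `sweep_config`.
#' @examples
#' sweep_config("Y_to_A", "dominance", "SAY", n_replicates = 10, seed = 42,
#'               profile = "desk")
#' @export
sweep_config <- function(transition = c("Y_to_A", "Y_to_W"),
                         epi_type = "dominance", epi_partner = "SAY",
                         n_replicates = 1000L,
                         s_range = c(0, 0.05), eps_range = c(0, 0.05),
                         seed = 1L,
                         burn_in = 10000L, total_generations = 200000L,
                         profile = NULL,
                         intro_freq = 1e-4, init_freq = 0.25,
                         rates = recombination_rates(),
                         outcome_read = c("within_sex", "pool")) {
  check_range <- function(r, nm) {
    if (length(r) != 2L || r[1] < 0 || r[2] < r[1]) {
      stop(nm, " must be c(lo, hi) with 0 <= lo <= hi")
    }
  }
  check_range(s_range, "s_range")
  check_range(eps_range, "eps_range")
  stopifnot(n_replicates >= 0, length(seed) == 1L)
  template <- scenario_spec(transition, epi_type, epi_partner,
                            s_Y = 0, s_new = 0, epsilon = 0,
                            burn_in = burn_in,
                            total_generations = total_generations,
                            intro_freq = intro_freq, init_freq = init_freq,
                            rates = rates, outcome_read = outcome_read,
                            profile = profile)
  structure(list(template = template,
                 n_replicates = as.integer(n_replicates),
                 s_range = s_range, eps_range = eps_range,
                 seed = as.integer(seed)),
            class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  cat(sprintf("<sweep_config> %s, %s epistasis on %s\n",
              x$template$transition, x$template$epi_type,
              x$template$epi_partner))
  cat(sprintf("  %d replicates, seed %d, s in (%g, %g), epsilon in (%g, %g)\n",
              x$n_replicates, x$seed, x$s_range[1], x$s_range[2],
              x$eps_range[1], x$eps_range[2]))
  cat(sprintf("  burn-in %d / horizon %d generations\n",
              x$template$burn_in, x$template$total_generations))
  invisible(x)
}

# Run code under a temporary RNG state, restoring the caller's stream.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Counter-based sub-seed: a fixed affine map of the replicate index modulo
# a Mersenne prime, so any replicate's draws can be reproduced in
# isolation and results are independent of scheduling.
replicate_seed <- function(master_seed, replicate_index) {
  as.integer((as.double(master_seed) %% 2147483647 +
                48271 * as.double(replicate_index)) %% 2147483647)
}

#' Sample one replicate's coefficients
#'
#' Independent uniform draws of `s_Y`, `s_new` and epsilon on the open
#' sampling intervals, deterministic given the master seed and replicate
#' index. Degenerate ranges return the pinned value.
#'
#' @param config A [sweep_config()].
#' @param replicate_index Positive integer replicate index.
#' @return A one-row tibble with `replicate`, `sub_seed`, `s_Y`, `s_new`,
#'   `epsilon`.
#' @export
sample_parameters <- function(config, replicate_index) {
  stopifnot(inherits(config, "sweep_config"), replicate_index >= 1)
  sub_seed <- replicate_seed(config$seed, replicate_index)
  draw_open <- function(r) {
    if (r[1] == r[2]) return(r[1])
    repeat {
      x <- stats::runif(1, r[1], r[2])
      if (x > r[1] && x < r[2]) return(x)
    }
  }
  with_local_seed(sub_seed, {
    tibble::tibble(replicate = as.integer(replicate_index),
                   sub_seed = sub_seed,
                   s_Y = draw_open(config$s_range),
                   s_new = draw_open(config$s_range),
                   epsilon = draw_open(config$eps_range))
  })
}

sweep_record_columns <- function() {
  c("transition", "epi_type", "epi_partner", "replicate", "sub_seed",
    "s_Y", "s_new", "epsilon", "outcome", "read_frequency",
    paste0("p_", LOCUS_NAMES), "generations_run", "error")
}

#' Run a parameter sweep
#'
#' Runs every replicate of a [sweep_config()] and collects one row per
#' replicate. Individual replicate failures are recorded in the `error`
#' column (with `NA` outcome) without aborting the sweep. The table is a
#' pure function of the config, including the master seed.
#'
#' @param config A [sweep_config()].
#' @param progress Print a progress message every 100 replicates.
#' @return A tibble with columns `transition`, `epi_type`, `epi_partner`,
#'   `replicate`, `sub_seed`, `s_Y`, `s_new`, `epsilon`, `outcome`
#'   (0 = ancestral SD maintained, 1 = turnover), `read_frequency`,
#'   `p_Y` ... `p_EPI` (final focal-allele frequencies), `generations_run`
#'   and `error`.
#' @export
run_sweep <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  empty <- tibble::tibble(
    transition = character(0), epi_type = character(0),
    epi_partner = character(0), replicate = integer(0),
    sub_seed = integer(0), s_Y = numeric(0), s_new = numeric(0),
    epsilon = numeric(0), outcome = integer(0), read_frequency = numeric(0),
    p_Y = numeric(0), p_SAY = numeric(0), p_A = numeric(0),
    p_SAA = numeric(0), p_W = numeric(0), p_SAW = numeric(0),
    p_EPI = numeric(0), generations_run = integer(0), error = character(0)
  )[, sweep_record_columns()]
  if (config$n_replicates == 0L) return(empty)

  rows <- purrr::map(seq_len(config$n_replicates), function(i) {
    params <- sample_parameters(config, i)
    tpl <- config$template
    base <- tibble::tibble(
      transition = tpl$transition, epi_type = tpl$epi_type,
      epi_partner = tpl$epi_partner, replicate = params$replicate,
      sub_seed = params$sub_seed, s_Y = params$s_Y, s_new = params$s_new,
      epsilon = params$epsilon
    )
    res <- tryCatch({
      spec <- scenario_spec(tpl$transition, tpl$epi_type, tpl$epi_partner,
                            s_Y = params$s_Y, s_new = params$s_new,
                            epsilon = params$epsilon,
                            burn_in = tpl$burn_in,
                            total_generations = tpl$total_generations,
                            intro_freq = tpl$intro_freq,
                            init_freq = tpl$init_freq, rates = tpl$rates,
                            outcome_read = tpl$outcome_read)
      run_transition(spec)
    }, error = function(e) e)
    if (progress && i %% 100L == 0L) {
      message(sprintf("replicate %d / %d", i, config$n_replicates))
    }
    if (inherits(res, "error")) {
      dplyr::bind_cols(base, tibble::tibble(
        outcome = NA_integer_, read_frequency = NA_real_,
        p_Y = NA_real_, p_A = NA_real_, p_W = NA_real_, p_SAY = NA_real_,
        p_SAA = NA_real_, p_SAW = NA_real_, p_EPI = NA_real_,
        generations_run = NA_integer_, error = conditionMessage(res)
      ))
    } else {
      fr <- res$final_freqs
      dplyr::bind_cols(base, tibble::tibble(
        outcome = res$outcome_bit, read_frequency = res$read_frequency,
        p_Y = fr[["Y"]], p_A = fr[["A"]], p_W = fr[["W"]],
        p_SAY = fr[["SAY"]], p_SAA = fr[["SAA"]], p_SAW = fr[["SAW"]],
        p_EPI = fr[["EPI"]], generations_run = res$generations_run,
        error = NA_character_
      ))
    }
  })
  dplyr::bind_rows(rows)[, sweep_record_columns()]
}
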