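# Transition scenarios: ancestral XY population, burn-in, introduction of
# a novel SD allele, and outcome classification.

#' Specify a sex-determination transition scenario
#'
#' A scenario starts from an ancestral XY system, runs a burn-in so the SA
#' and EPI allele frequencies approach equilibrium, introduces the novel
#' SD allele (A for `Y_to_A`, W for `Y_to_W`) at a low frequency, and runs
#' to a fixed horizon. The active SA loci are the two linked to the SD
#' loci involved (`SAY` plus `SAA` or `SAW`); the third SA locus is inert
#' (`s = 0`, focal allele absent). `s_Y` and `s_new` are the magnitudes of
#' the sexually antagonistic effects, with `sM = -sF` at each active locus
#' and the sign convention of [fitness_scheme()].
#'
#' @param transition `"Y_to_A"` or `"Y_to_W"`.
#' @param epi_type Epistasis type; see [epistasis_sigma()].
#' @param epi_partner SA locus read by the EPI locus. `Y_to_A` permits
#'   `"SAY"` or `"SAA"`; `Y_to_W` permits `"SAY"` or `"SAW"`.
#' @param s_Y,s_new Homozygous SA effect magnitudes of the ancestral-linked
#'   (`SAY`) and novel-linked (`SAA`/`SAW`) locus; non-negative.
#' @param epsilon Epistasis effect size (>= 0).
#' @param burn_in Generations before the novel allele is introduced
#'   (default 10,000).
#' @param total_generations Total horizon including burn-in (default
#'   200,000).
#' @param intro_freq Introduction frequency of the novel SD allele
#'   (default 1e-4).
#' @param init_freq Initial frequency of the active SA and EPI focal
#'   alleles in both pools (default 0.25, linkage equilibrium).
#' @param rates A [recombination_rates()] object.
#' @param hM_sa,hF_sa Dominance of the male-beneficial SA loci (`SAY`,
#'   `SAA`); the female-beneficial `SAW` uses the mirrored values.
#' @param outcome_read `"within_sex"` (default) reads the focal SD allele
#'   among the parent-of-origin copies of the relevant sex (paternal
#'   copies of males for A, maternal copies of females for W), for which
#'   complete turnover gives frequency 1; `"pool"` reads the
#'   origin-specific pool frequency directly.
#' @param profile Optional run-length preset overriding `burn_in` and
#'   `total_generations`: `"full"` (10,000 / 200,000) or `"desk"`
#'   (2,000 / 20,000), the reduced profile used for tests and sweeps at
#'   desk scale.
#' @param record_every Record the trajectory every this many generations
#'   (0 disables recording).
#' @param converge_tol If positive, stop the post-introduction phase early
#'   once the L-infinity change of both pools stays below this tolerance
#'   for 100 consecutive generations. Disabled (0) by default to mirror
#'   the fixed-horizon design.
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec("Y_to_A", "dominance", "SAY", s_Y = 0.02, s_new = 0.04,
#'               epsilon = 0.01, profile = "desk")
#' @export
scenario_spec <- function(transition = c("Y_to_A", "Y_to_W"),
                          epi_type = "dominance",
                          epi_partner = "SAY",
                          s_Y = 0, s_new = 0, epsilon = 0,
                          burn_in = 10000L, total_generations = 200000L,
                          intro_freq = 1e-4, init_freq = 0.25,
                          rates = recombination_rates(),
                          hM_sa = 0.6, hF_sa = 0.4,
                          outcome_read = c("within_sex", "pool"),
                          profile = NULL, record_every = 0L,
                          converge_tol = 0) {
  transition <- match.arg(transition)
  epi_type <- match.arg(epi_type, c("dominance", "overdominance", "coadaptation"))
  allowed <- if (transition == "Y_to_A") c("SAY", "SAA") else c("SAY", "SAW")
  epi_partner <- match.arg(epi_partner, c("SAY", "SAA", "SAW"))
  if (!epi_partner %in% allowed) {
    stop(sprintf("transition %s permits epi_partner in {%s}", transition,
                 paste(allowed, collapse = ", ")))
  }
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("full", "desk"))
    if (profile == "full") {
      burn_in <- 10000L; total_generations <- 200000L
    } else {
      burn_in <- 2000L; total_generations <- 20000L
    }
  }
  stopifnot(s_Y >= 0, s_new >= 0, epsilon >= 0,
            intro_freq > 0, intro_freq < 0.1,
            init_freq > 0, init_freq < 1,
            burn_in >= 0, total_generations > burn_in,
            inherits(rates, "recombination_rates"))
  structure(list(transition = transition, epi_type = epi_type,
                 epi_partner = epi_partner, s_Y = s_Y, s_new = s_new,
                 epsilon = epsilon, burn_in = as.integer(burn_in),
                 total_generations = as.integer(total_generations),
                 intro_freq = intro_freq, init_freq = init_freq,
                 rates = rates, hM_sa = hM_sa, hF_sa = hF_sa,
                 outcome_read = match.arg(outcome_read),
                 record_every = as.integer(record_every),
                 converge_tol = converge_tol),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s, %s epistasis on %s\n",
              x$transition, x$epi_type, x$epi_partner))
  cat(sprintf("  s_Y = %g, s_new = %g, epsilon = %g\n", x$s_Y, x$s_new, x$epsilon))
  cat(sprintf("  burn-in %d, horizon %d generations, introduction at %g\n",
              x$burn_in, x$total_generations, x$intro_freq))
  invisible(x)
}

# The SD locus invading in this scenario and its linked SA locus.
novel_locus <- function(spec) if (spec$transition == "Y_to_A") "A" else "W"
novel_sa <- function(spec) if (spec$transition == "Y_to_A") "SAA" else "SAW"

# Fitness and epistasis schemes implied by a scenario.
scenario_scheme <- function(spec) {
  male_ben <- function(s) {
    if (s == 0) sa_params(0, 0, spec$hM_sa, spec$hF_sa)
    else sa_params(sM = s, sF = -s, hM = spec$hM_sa, hF = spec$hF_sa)
  }
  fem_ben <- function(s) {
    if (s == 0) sa_params(0, 0, spec$hF_sa, spec$hM_sa)
    else sa_params(sM = -s, sF = s, hM = spec$hF_sa, hF = spec$hM_sa)
  }
  if (spec$transition == "Y_to_A") {
    fitness_scheme(SAY = male_ben(spec$s_Y), SAA = male_ben(spec$s_new),
                   SAW = fem_ben(0))
  } else {
    fitness_scheme(SAY = male_ben(spec$s_Y), SAA = male_ben(0),
                   SAW = fem_ben(spec$s_new))
  }
}

scenario_epi <- function(spec) {
  epistasis_scheme(spec$epi_type, spec$epi_partner, spec$epsilon)
}

# Loci that ever segregate in this scenario (support mask).
scenario_loci <- function(spec) {
  c("Y", "SAY", novel_locus(spec), novel_sa(spec), "EPI")
}

#' Ancestral XY population state
#'
#' Builds the starting state: zygotes are 50% Y/+ males with Y on the
#' paternally inherited copy and 50% +/+ females, so the sperm pool
#' carries Y at frequency 0.5 and the egg pool none. The two active SA
#' focal alleles and EPI start at `init_freq` in both pools, combined
#' independently across loci (linkage equilibrium); the novel SD allele
#' and the inert SA locus are absent.
#'
#' @param spec A [scenario_spec()].
#' @return A [population_state()] at generation 0.
#' @export
initialize_ancestral <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  p_core <- c(Y = 0, SAY = spec$init_freq, A = 0, SAA = 0, W = 0, SAW = 0,
              EPI = spec$init_freq)
  p_core[novel_sa(spec)] <- spec$init_freq
  a <- gamete_alleles(0:127)
  pool <- function(p) {
    apply(a, 1L, function(bits) prod(ifelse(bits == 1L, p, 1 - p)))
  }
  egg <- pool(p_core)
  p_sperm <- p_core
  p_sperm["Y"] <- 0.5
  sperm <- pool(p_sperm)
  population_state(egg, sperm, 0L)
}

#' Introduce the novel SD allele by proportional mutation
#'
#' In each pool, a fraction `intro_freq` of the mass of every gamete type
#' carrying `+` at the target SD locus is moved to the corresponding
#' focal-allele-carrying type (mutation across all genotypes present), so
#' the pool sums are unchanged and the focal frequency at the target locus
#' equals `intro_freq` in each pool.
#'
#' @param state A post-burn-in [population_state()].
#' @param spec A [scenario_spec()]; the target locus is `A` for `Y_to_A`
#'   and `W` for `Y_to_W`.
#' @return The mutated [population_state()] (same generation counter).
#' @export
introduce_sd_allele <- function(state, spec) {
  stopifnot(inherits(state, "population_state"), inherits(spec, "scenario_spec"))
  target <- novel_locus(spec)
  tbit <- bitwShiftL(1L, match(target, LOCUS_NAMES) - 1L)
  if (allele_frequency(state, target, "maternal") > 0 ||
      allele_frequency(state, target, "paternal") > 0) {
    stop("the novel SD allele ", target, " is already present")
  }
  mutate_pool <- function(pool) {
    g <- 0:127
    noncarrier <- bitwAnd(g, tbit) == 0L
    out <- pool
    moved <- pool[noncarrier] * spec$intro_freq
    out[noncarrier] <- pool[noncarrier] - moved
    out[which(noncarrier) + tbit] <- out[which(noncarrier) + tbit] + moved
    out
  }
  population_state(mutate_pool(state$egg), mutate_pool(state$sperm),
                   state$generation)
}

#' Classify the end state of a transition run
#'
#' For `Y_to_A` the read is the frequency of A among the paternally
#' inherited copies of males; for `Y_to_W`, the frequency of W among the
#' maternally inherited copies of females (zygotes formed from the final
#' pools). The rounded read (`>= 0.5` classifies as turnover, ties
#' included) gives the outcome bit: 1 = turnover, 0 = ancestral SD
#' maintained.
#'
#' @param state The final [population_state()].
#' @param spec A [scenario_spec()].
#' @return A list with `outcome_bit`, `read_frequency`, and `final_freqs`
#'   (named focal-allele frequencies at all 7 loci, averaged over origin
#'   and sexes).
#' @export
classify_outcome <- function(state, spec) {
  stopifnot(inherits(state, "population_state"), inherits(spec, "scenario_spec"))
  target <- novel_locus(spec)
  freq <- if (spec$outcome_read == "within_sex") {
    if (spec$transition == "Y_to_A") {
      allele_frequency(state, "A", origin = "paternal", within_sex = "males")
    } else {
      allele_frequency(state, "W", origin = "maternal", within_sex = "females")
    }
  } else {
    if (spec$transition == "Y_to_A") {
      allele_frequency(state, "A", origin = "paternal")
    } else {
      allele_frequency(state, "W", origin = "maternal")
    }
  }
  final_freqs <- vapply(LOCUS_NAMES, function(l) allele_frequency(state, l),
                        numeric(1))
  list(outcome_bit = as.integer(freq >= 0.5), read_frequency = freq,
       final_freqs = final_freqs)
}

#' Run one transition scenario
#'
#' Initialises the ancestral XY population, runs the burn-in, introduces
#' the novel SD allele, runs to the horizon, and classifies the outcome.
#' The recursion is fully deterministic: identical specs give identical
#' results.
#'
#' @param spec A [scenario_spec()].
#' @return An object of class `sd_transition` with elements `spec`,
#'   `outcome_bit` (1 = turnover), `read_frequency`, `final_freqs`,
#'   `generations_run`, `converged_early`, `trajectory` (a tibble when
#'   `record_every > 0`, else `NULL`) and `state` (the final
#'   [population_state()]).
#' @examples
#' spec <- scenario_spec("Y_to_A", s_Y = 0.001, s_new = 0.05,
#'                       burn_in = 200, total_generations = 2000)
#' res <- run_transition(spec)
#' res$outcome_bit
#' @export
run_transition <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  tables <- model_tables(scenario_scheme(spec), scenario_epi(spec),
                         spec$rates,
                         support_closure(loci_mask(scenario_loci(spec))))
  state <- initialize_ancestral(spec)

  rec <- list()
  if (spec$record_every > 0L) {
    rec[[1]] <- pools_row(state, tables$support)
  }
  phase1 <- iterate_state(state, tables, spec$burn_in,
                          record_every = spec$record_every)
  state <- introduce_sd_allele(phase1$state, spec)
  phase2 <- iterate_state(state, tables,
                          spec$total_generations - spec$burn_in,
                          record_every = spec$record_every,
                          conv_tol = spec$converge_tol)
  state <- phase2$state

  trajectory <- NULL
  if (spec$record_every > 0L) {
    trajectory <- dplyr::bind_rows(
      rec[[1]],
      pools_to_trajectory(phase1$rec_gen, phase1$rec_egg, phase1$rec_sperm,
                          tables$support),
      pools_to_trajectory(phase2$rec_gen, phase2$rec_egg, phase2$rec_sperm,
                          tables$support)
    ) |> dplyr::distinct(.data$generation, .keep_all = TRUE)
  }

  cls <- classify_outcome(state, spec)
  structure(list(spec = spec,
                 outcome_bit = cls$outcome_bit,
                 read_frequency = cls$read_frequency,
                 final_freqs = cls$final_freqs,
                 generations_run = spec$burn_in + phase2$generations_run,
                 converged_early = isTRUE(phase2$converged_early),
                 trajectory = trajectory,
                 state = state),
            class = "sd_transition")
}

loci_mask <- function(loci) {
  Reduce(bitwOr, bitwShiftL(1L, match(loci, LOCUS_NAMES) - 1L), 0L)
}

pools_row <- function(state, support) {
  idx <- support + 1L
  pools_to_trajectory(state$generation,
                      matrix(state$egg[idx], 1L),
                      matrix(state$sperm[idx], 1L), support)
}

#' @export
print.sd_transition <- function(x, ...) {
  cat(sprintf("<sd_transition> %s, %s epistasis on %s\n",
              x$spec$transition, x$spec$epi_type, x$spec$epi_partner))
  cat(sprintf("  s_Y = %g, s_new = %g, epsilon = %g\n",
              x$spec$s_Y, x$spec$s_new, x$spec$epsilon))
  cat(sprintf("  outcome: %s (read frequency %.4g after %d generations)\n",
              if (x$outcome_bit == 1L) "turnover" else "ancestral SD maintained",
              x$read_frequency, x$generations_run))
  invisible(x)
}

#' Tidy a transition result into per-locus final frequencies
#'
#' @param x An `sd_transition` object.
#' @param ... Unused.
#' @return A tibble with columns `locus`, `linkage_group`,
#'   `final_frequency`.
#' @export
tidy.sd_transition <- function(x, ...) {
  sd_loci() |>
    dplyr::select("locus", "linkage_group") |>
    dplyr::mutate(final_frequency = unname(x$final_freqs[.data$locus]))
}

#' One-row summary of a transition result
#'
#' @param x An `sd_transition` object.
#' @param ... Unused.
#' @return A one-row tibble with the scenario parameters, the outcome bit,
#'   the classification read frequency, and run-length bookkeeping.
#' @export
glance.sd_transition <- function(x, ...) {
  tibble::tibble(transition = x$spec$transition,
                 epi_type = x$spec$epi_type,
                 epi_partner = x$spec$epi_partner,
                 s_Y = x$spec$s_Y, s_new = x$spec$s_new,
                 epsilon = x$spec$epsilon,
                 outcome = x$outcome_bit,
                 read_frequency = x$read_frequency,
                 generations_run = x$generations_run,
                 converged_early = x$converged_early)
}

#' Plot the allele-frequency trajectory of a transition run
#'
#' Requires the run to have been made with `record_every > 0`.
#'
#' @param object An `sd_transition` object with a recorded trajectory.
#' @param ... Unused.
#' @return A ggplot object: focal-allele frequency against generation,
#'   one line per locus, with the introduction generation marked.
#' @export
autoplot.sd_transition <- function(object, ...) {
  if (is.null(object$trajectory)) {
    stop("no trajectory recorded; rerun with record_every > 0")
  }
  long <- tidyr::pivot_longer(object$trajectory, -"generation",
                              names_to = "locus", values_to = "frequency",
                              names_prefix = "p_")
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$frequency,
                                     colour = .data$locus)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$spec$burn_in, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "generation", y = "focal-allele frequency",
                  colour = "locus") +
    ggplot2::theme_minimal()
}
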