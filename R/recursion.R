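# Two-sex gamete-pool recursion: state containers, gametogenesis with
# recombination, and the one-generation update.

#' Recombination rates of the three two-locus linkage groups
#'
#' Each of XY, I^A and II^W carries an SD and an SA locus separated by a
#' recombination fraction in `[0, 0.5]`. Linkage groups assort
#' independently; the single-locus EPI group has no recombination
#' parameter. The default 0.01 reflects the tight SD-SA linkage the
#' sexually antagonistic turnover mechanism requires; all three rates are
#' configurable.
#'
#' @param r_XY,r_A,r_W Recombination fractions in `[0, 0.5]`.
#' @return An object of class `recombination_rates`.
#' @examples
#' recombination_rates(r_XY = 0.005)
#' @export
recombination_rates <- function(r_XY = 0.01, r_A = 0.01, r_W = 0.01) {
  r <- c(r_XY = r_XY, r_A = r_A, r_W = r_W)
  if (any(r < 0) || any(r > 0.5)) {
    stop("recombination fractions must lie in [0, 0.5]")
  }
  structure(as.list(r), class = "recombination_rates")
}

#' @export
print.recombination_rates <- function(x, ...) {
  cat(sprintf("<recombination_rates> r_XY = %g, r_A = %g, r_W = %g\n",
              x$r_XY, x$r_A, x$r_W))
  invisible(x)
}

#' Population state: egg- and sperm-pool haplotype frequencies
#'
#' The infinite-population state is the pair of frequency vectors over the
#' 128 gamete types: the egg pool (maternally transmitted haplotypes of
#' the next generation) and the sperm pool (paternally transmitted ones),
#' plus a generation counter. Each pool must be non-negative and sum to 1.
#'
#' @param egg,sperm Numeric vectors of length 128 (frequencies over gamete
#'   indices `0:127`).
#' @param generation Non-negative integer generation counter.
#' @return An object of class `population_state`.
#' @export
population_state <- function(egg, sperm, generation = 0L) {
  stopifnot(length(egg) == N_GAMETES, length(sperm) == N_GAMETES)
  if (any(egg < 0) || any(sperm < 0)) stop("pool frequencies must be non-negative")
  if (abs(sum(egg) - 1) > 1e-8 || abs(sum(sperm) - 1) > 1e-8) {
    stop("each pool must sum to 1")
  }
  egg <- egg / sum(egg)
  sperm <- sperm / sum(sperm)
  names(egg) <- names(sperm) <- gamete_label(0:127)
  structure(list(egg = egg, sperm = sperm,
                 generation = as.integer(generation)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> generation %d\n", x$generation))
  show <- function(pool, nm) {
    nz <- which(pool > 1e-6)
    nz <- nz[order(pool[nz], decreasing = TRUE)]
    top <- utils::head(nz, 6L)
    cat(sprintf("  %s pool (%d segregating types): %s\n", nm, length(nz),
                paste(sprintf("%s=%.4g", names(pool)[top], pool[top]),
                      collapse = ", ")))
  }
  show(x$egg, "egg")
  show(x$sperm, "sperm")
  invisible(x)
}

# Per-group gametogenesis tables ----------------------------------------

# 16 x 4 table for a two-locus group: row index hm*4 + hp + 1 (maternal and
# paternal haplotypes coded a_SD + 2*a_SA in 0:3), entry = probability of
# producing each haplotype. Parental haplotypes get mass (1-r)/2 each,
# recombinants r/2 each.
group_gamete_table <- function(r) {
  tab <- matrix(0, 16L, 4L)
  for (hm in 0:3) {
    for (hp in 0:3) {
      row <- hm * 4L + hp + 1L
      rec1 <- (hm %% 2L) + 2L * (hp %/% 2L)  # maternal SD, paternal SA
      rec2 <- (hp %% 2L) + 2L * (hm %/% 2L)
      tab[row, hm + 1L] <- tab[row, hm + 1L] + (1 - r) / 2
      tab[row, hp + 1L] <- tab[row, hp + 1L] + (1 - r) / 2
      tab[row, rec1 + 1L] <- tab[row, rec1 + 1L] + r / 2
      tab[row, rec2 + 1L] <- tab[row, rec2 + 1L] + r / 2
    }
  }
  tab
}

# 4 x 2 table for the single-locus EPI group: fair segregation.
epi_gamete_table <- function() {
  tab <- matrix(0, 4L, 2L)
  for (hm in 0:1) {
    for (hp in 0:1) {
      row <- hm * 2L + hp + 1L
      tab[row, hm + 1L] <- tab[row, hm + 1L] + 0.5
      tab[row, hp + 1L] <- tab[row, hp + 1L] + 0.5
    }
  }
  tab
}

# Group haplotype codes (0:3 for two-locus groups, 0:1 for EPI) for a set
# of gamete indices.
group_haplotypes <- function(gametes) {
  a <- gamete_alleles(gametes)
  list(XY = a[, "Y"] + 2L * a[, "SAY"],
       IA = a[, "A"] + 2L * a[, "SAA"],
       IIW = a[, "W"] + 2L * a[, "SAW"],
       EPI = a[, "EPI"])
}

#' Gamete distribution produced by one genotype
#'
#' Mendelian segregation with recombination: within each two-locus linkage
#' group the two parental haplotypes each receive mass `(1 - r)/2` and the
#' two recombinants `r/2`; the single-locus EPI group segregates 1/2-1/2;
#' linkage groups assort independently, so the full gamete distribution is
#' the product across groups.
#'
#' @param maternal,paternal Single gamete indices in `0:127`.
#' @param rates A [recombination_rates()] object.
#' @return Named numeric vector of length 128 summing to 1.
#' @examples
#' d <- gametogenesis(gamete("Y", "SAY"), gamete(), recombination_rates(0.1))
#' d[d > 0]
#' @export
gametogenesis <- function(maternal, paternal, rates = recombination_rates()) {
  stopifnot(length(maternal) == 1L, length(paternal) == 1L,
            inherits(rates, "recombination_rates"))
  hp <- group_haplotypes(c(as.integer(maternal), as.integer(paternal)))
  hg <- group_haplotypes(0:127)
  tXY <- group_gamete_table(rates$r_XY)[hp$XY[1] * 4L + hp$XY[2] + 1L, ]
  tIA <- group_gamete_table(rates$r_A)[hp$IA[1] * 4L + hp$IA[2] + 1L, ]
  tIIW <- group_gamete_table(rates$r_W)[hp$IIW[1] * 4L + hp$IIW[2] + 1L, ]
  tEPI <- epi_gamete_table()[hp$EPI[1] * 2L + hp$EPI[2] + 1L, ]
  out <- tXY[hg$XY + 1L] * tIA[hg$IA + 1L] * tIIW[hg$IIW + 1L] *
    tEPI[hg$EPI + 1L]
  names(out) <- gamete_label(0:127)
  out
}

# Precomputed per-run tables over a support set ---------------------------

# The segregating support is the set of gamete types composed only of
# alleles that can ever be present in a run. Restricting all tables to it
# makes the recursion O(m^2 * m) per generation with m << 128, and is
# exact because a product set over per-locus allele sets is closed under
# segregation and recombination.
support_closure <- function(mask) {
  g <- 0:127
  g[bitwAnd(g, bitwNot(as.integer(mask))) == 0L]
}

support_mask <- function(state, extra_loci = character(0)) {
  present <- bitwOr(Reduce(bitwOr, as.integer(which(state$egg > 0)) - 1L, 0L),
                    Reduce(bitwOr, as.integer(which(state$sperm > 0)) - 1L, 0L))
  extra <- 0L
  for (loc in extra_loci) {
    extra <- bitwOr(extra, bitwShiftL(1L, match(loc, LOCUS_NAMES) - 1L))
  }
  bitwOr(present, extra)
}

# Build the sex mask, fitness matrices and gametogenesis matrix restricted
# to a support set of gamete indices.
model_tables <- function(scheme, epi, rates, support) {
  m <- length(support)
  a <- gamete_alleles(support)
  both <- outer(as.integer(support), as.integer(support), bitwOr)
  has_w <- bitwAnd(both, bitwShiftL(1L, 4L)) > 0L
  has_male <- bitwAnd(both, bitwOr(1L, bitwShiftL(1L, 2L))) > 0L
  is_female <- has_w | !has_male

  copies <- function(locus) outer(a[, locus], a[, locus], "+")
  wtab <- function(params, sex) locus_fitness(0:2, sex, params)
  wsex <- function(sex) {
    w <- wtab(scheme$SAY, sex)[copies("SAY") + 1L] *
      wtab(scheme$SAA, sex)[copies("SAA") + 1L] *
      wtab(scheme$SAW, sex)[copies("SAW") + 1L]
    matrix(w, m, m)
  }
  WF <- wsex("female")
  sigma <- epistasis_sigma(epi$epi_type, copies("EPI"), copies(epi$partner))
  WM <- wsex("male") * (1 + matrix(sigma, m, m) * epi$epsilon)

  hg <- group_haplotypes(support)
  pXY <- group_gamete_table(rates$r_XY)
  pIA <- group_gamete_table(rates$r_A)
  pIIW <- group_gamete_table(rates$r_W)
  pEPI <- epi_gamete_table()
  rowXY <- outer(hg$XY, hg$XY, function(a, b) a * 4L + b) + 1L
  rowIA <- outer(hg$IA, hg$IA, function(a, b) a * 4L + b) + 1L
  rowIIW <- outer(hg$IIW, hg$IIW, function(a, b) a * 4L + b) + 1L
  rowEPI <- outer(hg$EPI, hg$EPI, function(a, b) a * 2L + b) + 1L

  G <- matrix(0, m * m, m)
  for (k in seq_len(m)) {
    gk <- matrix(pXY[cbind(as.vector(rowXY), hg$XY[k] + 1L)], m, m) *
      matrix(pIA[cbind(as.vector(rowIA), hg$IA[k] + 1L)], m, m) *
      matrix(pIIW[cbind(as.vector(rowIIW), hg$IIW[k] + 1L)], m, m) *
      matrix(pEPI[cbind(as.vector(rowEPI), hg$EPI[k] + 1L)], m, m)
    G[, k] <- as.vector(t(gk))  # row index = (i-1)*m + j, i maternal
  }
  if (max(abs(rowSums(G) - 1)) > 1e-12) {
    stop("support set is not closed under gametogenesis")
  }

  list(support = as.integer(support), is_female = is_female,
       WF = WF, WM = WM, G = G)
}

# Run the compiled recursion for n_gen generations over a support set.
iterate_state <- function(state, tables, n_gen, record_every = 0L,
                          conv_tol = 0, conv_streak = 100L) {
  idx <- tables$support + 1L
  if (n_gen == 0L) {
    return(list(state = state, generations_run = 0L, converged_early = FALSE,
                rec_gen = integer(0), rec_egg = NULL, rec_sperm = NULL))
  }
  out <- iterate_pools_cpp(state$egg[idx], state$sperm[idx],
                           tables$WF, tables$WM,
                           matrix(as.integer(tables$is_female),
                                  length(idx), length(idx)),
                           tables$G, as.integer(n_gen),
                           as.integer(state$generation),
                           as.integer(record_every),
                           conv_tol, as.integer(conv_streak))
  egg <- numeric(N_GAMETES)
  sperm <- numeric(N_GAMETES)
  egg[idx] <- out$egg
  sperm[idx] <- out$sperm
  list(state = population_state(egg, sperm,
                                state$generation + out$generations_run),
       generations_run = out$generations_run,
       converged_early = out$converged_early,
       max_drift = out$max_drift,
       rec_gen = out$rec_gen, rec_egg = out$rec_egg, rec_sperm = out$rec_sperm)
}

#' Advance the population by one generation
#'
#' Zygotes are formed as the outer product of the egg and sperm pools
#' (random mating in an infinite population), assigned a sex with
#' [sex_of()], and subjected to viability selection within each sex
#' separately; the new egg pool is the fitness-weighted mixture of female
#' gametogenesis distributions and the new sperm pool the same over males.
#' Each sex contributes half the gene pool regardless of the
#' post-selection sex ratio. Both pools are renormalised every generation.
#'
#' @param state A [population_state()].
#' @param scheme A [fitness_scheme()].
#' @param epi An [epistasis_scheme()].
#' @param rates A [recombination_rates()].
#' @return The updated [population_state()] with `generation`
#'   incremented.
#' @export
next_generation <- function(state, scheme = fitness_scheme(),
                            epi = epistasis_scheme(),
                            rates = recombination_rates()) {
  stopifnot(inherits(state, "population_state"))
  support <- support_closure(support_mask(state))
  tables <- model_tables(scheme, epi, rates, support)
  iterate_state(state, tables, 1L)$state
}

#' Advance the population by many generations
#'
#' Runs the recursion for `n` generations with the model tables built
#' once, optionally recording a thinned trajectory of focal-allele
#' frequencies. Equivalent to `n` calls of [next_generation()].
#'
#' @inheritParams next_generation
#' @param n Number of generations to run.
#' @param record_every Record the trajectory every this many generations
#'   (0 disables recording).
#' @return A list with `state` (the advanced [population_state()]) and
#'   `trajectory` (a tibble, or `NULL` when not recorded).
#' @export
iterate_generations <- function(state, n, scheme = fitness_scheme(),
                                epi = epistasis_scheme(),
                                rates = recombination_rates(),
                                record_every = 0L) {
  stopifnot(inherits(state, "population_state"), n >= 0)
  support <- support_closure(support_mask(state))
  tables <- model_tables(scheme, epi, rates, support)
  out <- iterate_state(state, tables, as.integer(n),
                       record_every = as.integer(record_every))
  trajectory <- pools_to_trajectory(out$rec_gen, out$rec_egg, out$rec_sperm,
                                    tables$support)
  list(state = out$state, trajectory = trajectory)
}

#' Focal-allele frequency in a population state
#'
#' Reads the frequency of a locus's focal allele among a designated class
#' of haplotype copies. `origin = "maternal"` reads egg-derived copies,
#' `"paternal"` sperm-derived copies, `"both"` their average. When
#' `within_sex` is `"males"` or `"females"`, zygotes are formed from the
#' current pools and the read is restricted to that sex (pre-selection).
#'
#' @param state A [population_state()].
#' @param locus Locus name: one of `"Y"`, `"SAY"`, `"A"`, `"SAA"`, `"W"`,
#'   `"SAW"`, `"EPI"`.
#' @param origin `"both"` (default), `"maternal"` or `"paternal"`.
#' @param within_sex `"all"` (default), `"males"` or `"females"`.
#' @return A frequency in `[0, 1]`.
#' @export
allele_frequency <- function(state, locus,
                             origin = c("both", "maternal", "paternal"),
                             within_sex = c("all", "males", "females")) {
  stopifnot(inherits(state, "population_state"))
  origin <- match.arg(origin)
  within_sex <- match.arg(within_sex)
  locus <- match.arg(locus, LOCUS_NAMES)
  a <- gamete_alleles(0:127)[, locus]
  if (within_sex == "all") {
    pm <- sum(state$egg * a)
    pp <- sum(state$sperm * a)
    return(switch(origin, maternal = pm, paternal = pp, both = (pm + pp) / 2))
  }
  support <- support_closure(support_mask(state))
  idx <- support + 1L
  z <- outer(state$egg[idx], state$sperm[idx])
  sx <- matrix(sex_of(rep(support, times = length(support)),
                      rep(support, each = length(support))),
               length(support), length(support))
  keep <- sx == if (within_sex == "males") "male" else "female"
  tot <- sum(z[keep])
  if (tot <= 0) {
    stop("no zygotes in the requested sex class")
  }
  asub <- a[idx]
  pm <- sum((z * keep) * asub) / tot            # maternal copies: rows
  pp <- sum(t(t(z * keep) * asub)) / tot        # paternal copies: cols
  switch(origin, maternal = pm, paternal = pp, both = (pm + pp) / 2)
}

# Trajectory assembly from recorded pools --------------------------------

pools_to_trajectory <- function(rec_gen, rec_egg, rec_sperm, support) {
  if (length(rec_gen) == 0L) return(NULL)
  a <- gamete_alleles(support)
  p <- (rec_egg %*% a + rec_sperm %*% a) / 2
  colnames(p) <- paste0("p_", LOCUS_NAMES)
  tibble::as_tibble(as.data.frame(p)) |>
    dplyr::mutate(generation = as.integer(rec_gen), .before = 1) |>
    dplyr::select("generation", "p_Y", "p_A", "p_W", "p_SAY", "p_SAA",
                  "p_SAW", "p_EPI")
}

#' Write a trajectory table to TSV
#'
#' Columns: `generation`, `p_Y`, `p_A`, `p_W`, `p_SAY`, `p_SAA`, `p_SAW`,
#' `p_EPI` (focal-allele frequencies averaged over parental origin and
#' sexes).
#'
#' @param trajectory A trajectory tibble as stored on a
#'   [run_transition()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(is.data.frame(trajectory))
  readr::write_tsv(trajectory, path)
  invisible(path)
}
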