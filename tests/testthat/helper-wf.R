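# Independent individual-based Wright-Fisher simulator used as a
# stochastic oracle for the deterministic recursion. It applies the same
# sex, fitness and segregation rules (via the reference implementations
# in helper-oracle.R) to finite gamete pools of size N with multinomial
# sampling at the zygote and gamete stages.

wf_simulate <- function(state, n_gen, N, params, epi,
                        r = c(0.01, 0.01, 0.01), seed = 1) {
  set.seed(seed)
  support <- which(state$egg > 0 | state$sperm > 0) - 1L
  # close the support over the segregating allele set
  mask <- Reduce(bitwOr, as.integer(support), 0L)
  support <- (0:127)[bitwAnd(0:127, bitwNot(mask)) == 0L]
  m <- length(support)

  # per-genotype tables (plain loops over the m x m ordered pairs)
  G <- matrix(0, m * m, m)
  wF <- numeric(m * m); wM <- numeric(m * m); fem <- logical(m * m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      row <- (i - 1L) * m + j
      gm <- support[i]; gp <- support[j]
      sex <- ref_sex(gm, gp)
      fem[row] <- sex == "female"
      wF[row] <- ref_fitness(gm, gp, "female", params, epi)
      wM[row] <- ref_fitness(gm, gp, "male", params, epi)
      G[row, ] <- ref_gamete_dist(gm, gp, r)[support + 1L]
    }
  }

  alle <- vapply(1:7, function(l) ref_allele(support, l), numeric(m))
  egg <- as.vector(stats::rmultinom(1, N, state$egg[support + 1L]))
  sperm <- as.vector(stats::rmultinom(1, N, state$sperm[support + 1L]))

  traj <- matrix(NA_real_, n_gen + 1L, 7L)
  colnames(traj) <- c("Y", "SAY", "A", "SAA", "W", "SAW", "EPI")
  freqs <- function(egg, sperm) {
    (as.vector(egg %*% alle) + as.vector(sperm %*% alle)) / (2 * N)
  }
  traj[1L, ] <- freqs(egg, sperm)

  for (gen in seq_len(n_gen)) {
    zp <- as.vector(t(outer(egg / N, sperm / N)))  # row = (i-1)*m + j
    zc <- as.vector(stats::rmultinom(1, N, zp))
    wf_cell <- zc * wF * fem
    wm_cell <- zc * wM * !fem
    stopifnot(sum(wf_cell) > 0, sum(wm_cell) > 0)
    p_egg <- as.vector(crossprod(G, wf_cell))
    p_sperm <- as.vector(crossprod(G, wm_cell))
    egg <- as.vector(stats::rmultinom(1, N, p_egg / sum(p_egg)))
    sperm <- as.vector(stats::rmultinom(1, N, p_sperm / sum(p_sperm)))
    traj[gen + 1L, ] <- freqs(egg, sperm)
  }
  traj
}
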