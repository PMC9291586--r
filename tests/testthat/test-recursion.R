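# The one-generation recursion: oracle equivalence, conservation,
# neutrality, Y transmission, linkage decay, support-restriction
# exactness.

make_scheme <- function() {
  fitness_scheme(SAY = sa_params(sM = 0.03, sF = -0.03),
                 SAA = sa_params(sM = 0.05, sF = -0.05),
                 SAW = sa_params(sM = -0.02, sF = 0.02, hM = 0.4, hF = 0.6))
}
ref_params <- list(list(sM = 0.03, sF = -0.03, hM = 0.6, hF = 0.4),
                   list(sM = 0.05, sF = -0.05, hM = 0.6, hF = 0.4),
                   list(sM = -0.02, sF = 0.02, hM = 0.4, hF = 0.6))

test_that("one generation matches brute-force enumeration, with selection", {
  rates <- recombination_rates(0.02, 0.05, 0.01)
  epi <- epistasis_scheme("dominance", "SAY", 0.04)
  repi <- list(type = "dominance", partner_num = 2, eps = 0.04)
  for (seed in 1:3) {
    st <- random_state(c(1, 2, 4, 7), seed)  # Y, SAY, SAA, EPI segregate
    got <- next_generation(st, make_scheme(), epi, rates)
    want <- ref_next_generation(st$egg, st$sperm, ref_params, repi,
                                c(0.02, 0.05, 0.01))
    expect_equal(unname(got$egg), want$egg, tolerance = 1e-12)
    expect_equal(unname(got$sperm), want$sperm, tolerance = 1e-12)
    expect_identical(got$generation, st$generation + 1L)
  }
  # W-bearing states and a different epistasis wiring
  epi_w <- epistasis_scheme("coadaptation", "SAW", 0.03)
  repi_w <- list(type = "coadaptation", partner_num = 6, eps = 0.03)
  for (seed in 4:5) {
    st <- random_state(c(1, 2, 5, 6, 7), seed)
    got <- next_generation(st, make_scheme(), epi_w, rates)
    want <- ref_next_generation(st$egg, st$sperm, ref_params, repi_w,
                                c(0.02, 0.05, 0.01))
    expect_equal(unname(got$egg), want$egg, tolerance = 1e-12)
    expect_equal(unname(got$sperm), want$sperm, tolerance = 1e-12)
  }
})

test_that("neutral dynamics conserve focal-allele frequencies exactly", {
  # Conservation requires the selected/EPI loci to be independent of the
  # sex-determining loci (product-form pools, as at initialization);
  # associations with Y would shift pooled frequencies through
  # sex-biased transmission even without selection.
  product_state <- function(p) {
    a <- gamete_alleles(0:127)
    pool <- function(pv) {
      apply(a, 1L, function(bits) prod(ifelse(bits == 1L, pv, 1 - pv)))
    }
    p_egg <- c(Y = 0, SAY = p[1], A = 0, SAA = p[2], W = 0, SAW = 0,
               EPI = p[3])
    p_sperm <- p_egg
    p_sperm["Y"] <- 0.5
    population_state(pool(p_egg), pool(p_sperm))
  }
  set.seed(42)
  for (k in 1:4) {
    p <- stats::runif(3, 0.1, 0.9)
    st <- product_state(p)
    for (step in 1:3) st <- next_generation(st)  # all s = 0, epsilon = 0
    after <- vapply(c("SAY", "SAA", "EPI"),
                    function(l) allele_frequency(st, l), numeric(1))
    expect_equal(unname(after), p, tolerance = 1e-12)
  }
})

test_that("pools stay normalised and non-negative along a selected run", {
  spec <- scenario_spec("Y_to_A", s_Y = 0.02, s_new = 0.03, epsilon = 0.04,
                        burn_in = 50, total_generations = 300)
  st <- initialize_ancestral(spec)
  out <- iterate_generations(st, 300, make_scheme(),
                             epistasis_scheme("dominance", "SAY", 0.04))
  expect_lt(abs(sum(out$state$egg) - 1), 1e-12)
  expect_lt(abs(sum(out$state$sperm) - 1), 1e-12)
  expect_true(all(out$state$egg >= 0))
  expect_true(all(out$state$sperm >= 0))
})

test_that("ancestral XY system: Y is never maternal and the sex ratio is 1/2", {
  spec <- scenario_spec("Y_to_A", s_Y = 0.02, s_new = 0, epsilon = 0.01,
                        burn_in = 10, total_generations = 100)
  st <- initialize_ancestral(spec)
  sch <- fitness_scheme(SAY = sa_params(sM = 0.02, sF = -0.02))
  epi <- epistasis_scheme("dominance", "SAY", 0.01)
  for (g in 1:25) {
    st <- next_generation(st, sch, epi)
    expect_identical(allele_frequency(st, "Y", origin = "maternal"), 0)
    expect_equal(zygote_male_fraction(st), 0.5, tolerance = 1e-12)
  }
})

test_that("within-group disequilibrium decays by (1 - r) per generation", {
  # To observe the classic neutral decay law, the XY pair must be
  # transmitted identically through both sexes: fix A (so every W-free
  # zygote is male regardless of Y) and let the dominant W segregate
  # maternally at 1/2, which pins the sex ratio while Y and SAY recombine
  # as an ordinary autosomal pair.
  build <- function(w_freq) {
    pool <- numeric(128)
    for (xy in list(c("Y", "SAY"), character(0))) {
      p_xy <- if (length(xy)) 0.3 else 0.7
      for (w in list("W", character(0))) {
        p_w <- if (length(w)) w_freq else 1 - w_freq
        if (p_w == 0) next
        g <- do.call(gamete, as.list(c(xy, "A", w)))
        pool[g + 1] <- p_xy * p_w
      }
    }
    pool
  }
  st <- population_state(build(0.5), build(0))
  r <- 0.12
  rates <- recombination_rates(r_XY = r)
  D_xy <- function(pool) {
    a <- gamete_alleles(0:127)
    sum(pool * a[, "Y"] * a[, "SAY"]) -
      sum(pool * a[, "Y"]) * sum(pool * a[, "SAY"])
  }
  d0 <- D_xy(st$egg)
  expect_equal(d0, 0.3 - 0.09)
  for (t in 1:8) {
    st <- next_generation(st, rates = rates)
    expect_equal(D_xy(st$egg), d0 * (1 - r)^t, tolerance = 1e-12)
    expect_equal(D_xy(st$sperm), d0 * (1 - r)^t, tolerance = 1e-12)
    expect_identical(allele_frequency(st, "W", origin = "paternal"), 0)
  }
})

test_that("cross-group disequilibrium halves every generation", {
  # SAA and EPI on independently assorting groups, perfectly coupled at
  # start; D(t) = D(0) / 2^t under neutrality.
  egg <- numeric(128); sperm <- numeric(128)
  coupled <- gamete("SAA", "EPI") + 1
  egg[coupled] <- 0.3; egg[gamete() + 1] <- 0.7
  sperm[coupled] <- 0.3 * 0.5; sperm[gamete("Y", "SAA", "EPI") + 1] <- 0.3 * 0.5
  sperm[gamete() + 1] <- 0.7 * 0.5; sperm[gamete("Y") + 1] <- 0.7 * 0.5
  st <- population_state(egg, sperm)
  D <- function(state) {
    a <- gamete_alleles(0:127)
    pool <- (state$egg + state$sperm) / 2
    sum(pool * a[, "SAA"] * a[, "EPI"]) -
      sum(pool * a[, "SAA"]) * sum(pool * a[, "EPI"])
  }
  d0 <- D(st)
  expect_gt(d0, 0.1)
  for (t in 1:6) {
    st <- next_generation(st)
    expect_equal(D(st), d0 / 2^t, tolerance = 1e-12)
  }
})

test_that("support restriction is exact against the dense 128-type computation", {
  spec <- scenario_spec("Y_to_A", s_Y = 0.02, s_new = 0.04, epsilon = 0.03,
                        burn_in = 10, total_generations = 100)
  st <- initialize_ancestral(spec)
  st <- introduce_sd_allele(st, spec)
  sch <- sdturnover:::scenario_scheme(spec)
  epi <- sdturnover:::scenario_epi(spec)
  sparse_tab <- sdturnover:::model_tables(sch, epi, spec$rates,
    sdturnover:::support_closure(sdturnover:::support_mask(st)))
  dense_tab <- sdturnover:::model_tables(sch, epi, spec$rates, 0:127)
  sparse <- sdturnover:::iterate_state(st, sparse_tab, 100L)$state
  dense <- sdturnover:::iterate_state(st, dense_tab, 100L)$state
  expect_equal(unname(sparse$egg), unname(dense$egg), tolerance = 1e-13)
  expect_equal(unname(sparse$sperm), unname(dense$sperm), tolerance = 1e-13)
})

test_that("allele_frequency reads parent-of-origin and sex-restricted classes", {
  spec <- scenario_spec("Y_to_A", s_Y = 0.01, s_new = 0.01,
                        burn_in = 10, total_generations = 100)
  st <- initialize_ancestral(spec)
  expect_equal(allele_frequency(st, "Y", "paternal", "males"), 1)
  expect_identical(allele_frequency(st, "Y", "maternal"), 0)
  expect_identical(allele_frequency(st, "Y", "maternal", "females"), 0)
  expect_identical(allele_frequency(st, "W"), 0)   # inert locus
  expect_equal(allele_frequency(st, "SAY", "maternal"), 0.25)
  # all-female state has no male zygote class
  egg <- numeric(128); egg[1] <- 1
  sperm <- numeric(128); sperm[1] <- 1
  allfem <- population_state(egg, sperm)
  expect_error(allele_frequency(allfem, "SAY", within_sex = "males"),
               "no zygotes")
})

test_that("a sex-less population is flagged as degenerate", {
  egg <- numeric(128); egg[1] <- 1
  sperm <- numeric(128); sperm[1] <- 1
  expect_error(next_generation(population_state(egg, sperm)), "degenerate")
})
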