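# Transition scenarios: initialization, introduction, classification,
# full runs.

desk_corners <- function(transition, s_Y, s_new) {
  scenario_spec(transition, s_Y = s_Y, s_new = s_new, epsilon = 0,
                profile = "desk")
}

test_that("scenario specs validate the four permitted transition cells", {
  expect_no_error(scenario_spec("Y_to_A", epi_partner = "SAY"))
  expect_no_error(scenario_spec("Y_to_A", epi_partner = "SAA"))
  expect_no_error(scenario_spec("Y_to_W", epi_partner = "SAY"))
  expect_no_error(scenario_spec("Y_to_W", epi_partner = "SAW"))
  expect_error(scenario_spec("Y_to_A", epi_partner = "SAW"), "permits")
  expect_error(scenario_spec("Y_to_W", epi_partner = "SAA"), "permits")
  expect_error(scenario_spec("Y_to_A", burn_in = 300, total_generations = 200))
})

test_that("ancestral initialization matches the XY starting conditions", {
  for (transition in c("Y_to_A", "Y_to_W")) {
    spec <- scenario_spec(transition, s_Y = 0.02, s_new = 0.02,
                          burn_in = 10, total_generations = 100)
    st <- initialize_ancestral(spec)
    expect_equal(zygote_male_fraction(st), 0.5, tolerance = 1e-12)
    expect_equal(allele_frequency(st, "SAY", "maternal"), 0.25)
    expect_equal(allele_frequency(st, "SAY", "paternal"), 0.25)
    expect_equal(allele_frequency(st, "EPI", "maternal"), 0.25)
    expect_equal(allele_frequency(st, "EPI", "paternal"), 0.25)
    expect_identical(allele_frequency(st, "A"), 0)
    expect_identical(allele_frequency(st, "W"), 0)
    expect_identical(allele_frequency(st, "Y", "maternal"), 0)
    expect_equal(allele_frequency(st, "Y", "paternal", "males"), 1)
    active_sa <- if (transition == "Y_to_A") "SAA" else "SAW"
    inert_sa <- if (transition == "Y_to_A") "SAW" else "SAA"
    expect_equal(allele_frequency(st, active_sa), 0.25)
    expect_identical(allele_frequency(st, inert_sa), 0)
  }
})

test_that("introduction mutates a 1e-4 fraction of every non-carrier type", {
  spec <- scenario_spec("Y_to_A", s_Y = 0.02, s_new = 0.03,
                        burn_in = 50, total_generations = 500)
  st0 <- initialize_ancestral(spec)
  st1 <- iterate_generations(st0, 50, sdturnover:::scenario_scheme(spec),
                             sdturnover:::scenario_epi(spec), spec$rates)$state
  st2 <- introduce_sd_allele(st1, spec)
  expect_equal(allele_frequency(st2, "A", "maternal"), 1e-4, tolerance = 1e-12)
  expect_equal(allele_frequency(st2, "A", "paternal"), 1e-4, tolerance = 1e-12)
  expect_equal(sum(st2$egg), 1, tolerance = 1e-12)
  expect_equal(sum(st2$sperm), 1, tolerance = 1e-12)
  # relative proportions among the +-carrying types are unchanged
  abit <- gamete("A")
  non <- which(bitwAnd(0:127, abit) == 0L & st1$egg > 0)
  expect_equal(unname(st2$egg[non] / st1$egg[non]),
               rep(1 - 1e-4, length(non)),
               tolerance = 1e-12)
  expect_error(introduce_sd_allele(st2, spec), "already present")
})

test_that("outcome classification reads parent-of-origin frequencies", {
  spec_a <- scenario_spec("Y_to_A", burn_in = 10, total_generations = 100,
                          s_Y = 0.01, s_new = 0.01)
  # complete Y -> A turnover: males are A/+ with A paternal, Y lost
  egg <- numeric(128); egg[gamete() + 1] <- 1
  sperm <- numeric(128)
  sperm[gamete("A") + 1] <- 0.5; sperm[gamete() + 1] <- 0.5
  st <- population_state(egg, sperm)
  out <- classify_outcome(st, spec_a)
  expect_identical(out$outcome_bit, 1L)
  expect_equal(out$read_frequency, 1)
  # A numerically extinct
  sperm2 <- numeric(128)
  sperm2[gamete("A") + 1] <- 1e-30
  sperm2[gamete("Y") + 1] <- 0.5
  sperm2[gamete() + 1] <- 0.5 - 1e-30
  out2 <- classify_outcome(population_state(egg, sperm2), spec_a)
  expect_identical(out2$outcome_bit, 0L)
  expect_lt(out2$read_frequency, 1e-29)
})

test_that("the fixed Y-plus-W state is classified as complete turnover and persists", {
  spec_w <- scenario_spec("Y_to_W", burn_in = 10, total_generations = 100,
                          s_Y = 0.01, s_new = 0.01)
  # Y fixed; every female W/+ with W maternal
  egg <- numeric(128)
  egg[gamete("Y", "W") + 1] <- 0.5; egg[gamete("Y") + 1] <- 0.5
  sperm <- numeric(128); sperm[gamete("Y") + 1] <- 1
  st <- population_state(egg, sperm)
  out <- classify_outcome(st, spec_w)
  expect_identical(out$outcome_bit, 1L)
  expect_equal(out$read_frequency, 1)
  expect_equal(out$final_freqs[["Y"]], 1)
  # the state is a fixed point of the neutral dynamics
  st2 <- st
  for (g in 1:5) st2 <- next_generation(st2)
  expect_equal(allele_frequency(st2, "W", "maternal", "females"), 1)
  expect_equal(unname(st2$egg), unname(st$egg), tolerance = 1e-12)
})

test_that("strong novel SA linkage drives turnover; strong ancestral linkage prevents it", {
  win <- run_transition(desk_corners("Y_to_A", s_Y = 0.001, s_new = 0.05))
  expect_identical(win$outcome_bit, 1L)
  expect_gt(win$read_frequency, 0.99)
  lose <- run_transition(desk_corners("Y_to_A", s_Y = 0.05, s_new = 0.001))
  expect_identical(lose$outcome_bit, 0L)
  expect_lt(lose$read_frequency, 0.01)
})

test_that("identical specs give bitwise-identical results", {
  spec <- scenario_spec("Y_to_W", "overdominance", "SAW",
                        s_Y = 0.013, s_new = 0.037, epsilon = 0.021,
                        burn_in = 300, total_generations = 3000)
  a <- run_transition(spec)
  b <- run_transition(spec)
  expect_identical(a$outcome_bit, b$outcome_bit)
  expect_identical(a$read_frequency, b$read_frequency)
  expect_identical(a$final_freqs, b$final_freqs)
  expect_identical(a$state$egg, b$state$egg)
  expect_identical(a$state$sperm, b$state$sperm)
})

test_that("Y/Y never arises in Y_to_A runs and W never enters the sperm pool", {
  spec <- scenario_spec("Y_to_A", s_Y = 0.02, s_new = 0.03, epsilon = 0.02,
                        burn_in = 200, total_generations = 2000,
                        record_every = 100)
  res <- run_transition(spec)
  expect_identical(allele_frequency(res$state, "Y", "maternal"), 0)
  expect_identical(allele_frequency(res$state, "W"), 0)

  spec_w <- scenario_spec("Y_to_W", s_Y = 0.01, s_new = 0.04,
                          burn_in = 200, total_generations = 2000)
  st <- initialize_ancestral(spec_w)
  st <- iterate_generations(st, 200, sdturnover:::scenario_scheme(spec_w),
                            sdturnover:::scenario_epi(spec_w),
                            spec_w$rates)$state
  st <- introduce_sd_allele(st, spec_w)
  expect_equal(allele_frequency(st, "W", "paternal"), 1e-4)
  st <- next_generation(st, sdturnover:::scenario_scheme(spec_w),
                        sdturnover:::scenario_epi(spec_w), spec_w$rates)
  # W carriers are female: the sperm pool purges W in one generation
  expect_identical(allele_frequency(st, "W", "paternal"), 0)
})

test_that("trajectories are recorded, tidied and plotted", {
  spec <- scenario_spec("Y_to_A", s_Y = 0.005, s_new = 0.04,
                        burn_in = 100, total_generations = 1000,
                        record_every = 50)
  res <- run_transition(spec)
  tr <- res$trajectory
  expect_s3_class(tr, "tbl_df")
  expect_identical(names(tr), c("generation", "p_Y", "p_A", "p_W", "p_SAY",
                                "p_SAA", "p_SAW", "p_EPI"))
  expect_identical(tr$generation[1], 0L)
  expect_identical(tr$generation[nrow(tr)], 1000L)
  expect_true(all(tr$p_A[tr$generation < 100] == 0))
  expect_true(all(tr$p_W == 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12)

  td <- tidy(res)
  expect_identical(td$locus, c("Y", "SAY", "A", "SAA", "W", "SAW", "EPI"))
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$outcome, res$outcome_bit)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
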