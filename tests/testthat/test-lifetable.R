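test_that("build_life_table applies the lx/mx definitions day by day", {
  s <- build_life_table(tiny_cohort())
  expect_equal(s$x, 1:3)
  expect_equal(s$l_x, c(1, 1, 0))
  expect_equal(s$m_x, c(0, 2, 0))

  # a cohort extinct by day 3 with no offspring: all m_x are zero
  dead <- cohort("d", 10, day = 1:3, n_alive = c(6, 2, 0),
                 n_offspring = c(0, 0, 0))
  expect_true(all(build_life_table(dead)$m_x == 0))
})

test_that("skipped observation days are carried forward with m_x = 0", {
  ch <- cohort("gap", 10, day = c(1, 2, 5, 6), n_alive = c(10, 8, 8, 4),
               n_offspring = c(0, 16, 8, 0))
  s <- build_life_table(ch)
  expect_equal(s$x, 1:6)
  expect_equal(s$l_x, c(1, 0.8, 0.8, 0.8, 0.8, 0.4))
  expect_equal(s$m_x, c(0, 2, 0, 0, 1, 0))
})

test_that("cohort invariant violations are rejected with the offending day", {
  expect_error(
    cohort("bad", 10, day = 1:3, n_alive = c(8, 6, 7),
           n_offspring = c(0, 0, 0)),
    "increases on day 3"
  )
  expect_error(
    cohort("bad", 5, day = 1:2, n_alive = c(6, 5), n_offspring = c(0, 0)),
    "exceeds initial_n on day 1"
  )
  expect_error(
    cohort("bad", 5, day = 1:2, n_alive = c(5, 0), n_offspring = c(0, 3)),
    "no survivors on day 2"
  )
  expect_error(
    cohort("bad", 5, day = integer(), n_alive = integer(),
           n_offspring = integer()),
    "empty observation"
  )
})

test_that("R0, T and rm match their defining formulas", {
  s <- build_life_table(tiny_cohort())
  expect_equal(net_reproductive_rate(s), 2.0)
  expect_equal(generation_time(s), 2.0)

  one_row <- tibble::tibble(x = 1, l_x = 1, m_x = 5)
  expect_equal(net_reproductive_rate(one_row), 5.0)
  expect_equal(generation_time(one_row), 1)

  # reproduction concentrated on one day: T is that day
  conc <- tibble::tibble(x = 1:5, l_x = rep(1, 5), m_x = c(0, 0, 0, 2, 0))
  expect_equal(generation_time(conc), 4)

  # no reproduction: R0 = 0, T and rm undefined
  none <- tibble::tibble(x = 1:3, l_x = c(1, 0.5, 0), m_x = c(0, 0, 0))
  expect_equal(net_reproductive_rate(none), 0)
  expect_true(is.na(generation_time(none)))
  p <- demographic_params(none)
  expect_false(p$defined)
  expect_true(is.na(p$rm))

  expect_equal(intrinsic_rate_of_increase(1, 7), 0)
  expect_error(intrinsic_rate_of_increase(2, 0), "positive")
})

test_that("rm identity and sign law hold on random schedules", {
  set.seed(42)
  for (i in 1:50) {
    s <- random_schedule()
    bf <- brute_force_params(s)
    r0 <- net_reproductive_rate(s)
    expect_equal(r0, bf$R0, tolerance = 1e-12)
    if (r0 > 0) {
      tt <- generation_time(s)
      rm <- intrinsic_rate_of_increase(r0, tt)
      expect_equal(rm, bf$rm, tolerance = 1e-12)
      # T lies within the reproductive window
      repro <- s$x[s$l_x * s$m_x > 0]
      expect_gte(tt, min(repro))
      expect_lte(tt, max(repro))
      # sign of rm is the sign of log R0
      expect_equal(sign(rm), sign(log(r0)))
    }
  }
})

test_that("lx, mx and the parameters are invariant to doubling all counts", {
  ch <- cohort("a", 10, day = 1:4, n_alive = c(10, 8, 6, 0),
               n_offspring = c(0, 16, 12, 0))
  doubled <- cohort("a2", 20, day = 1:4, n_alive = c(20, 16, 12, 0),
                    n_offspring = c(0, 32, 24, 0))
  s1 <- build_life_table(ch)
  s2 <- build_life_table(doubled)
  expect_equal(s1$l_x, s2$l_x)
  expect_equal(s1$m_x, s2$m_x)
  expect_equal(demographic_params(ch)[, -1], demographic_params(doubled)[, -1])
})

test_that("treatment aggregation averages replicates, excluding undefined T/rm", {
  reproducing <- cohort("r", 1, day = 1:2, n_alive = c(1, 1),
                        n_offspring = c(0, 2)) # R0 = 2, T = 2
  sterile <- cohort("s", 1, day = 1:2, n_alive = c(1, 0),
                    n_offspring = c(0, 0)) # R0 = 0
  smry <- replicate_parameters(list(reproducing, reproducing, sterile),
                               label = "mix")
  s <- smry$summary
  expect_equal(s$R0_mean, 4 / 3) # the R0 = 0 replicate counts as 0
  expect_equal(s$rm_mean, log(2) / 2) # over the two defined replicates
  expect_equal(s$T_mean, 2)
  expect_equal(s$n_undefined, 1)

  # identical replicates: zero SD everywhere
  twin <- replicate_parameters(list(reproducing, reproducing), label = "twin")
  expect_equal(twin$summary$R0_sd, 0)
  expect_equal(twin$summary$T_sd, 0)
  expect_equal(twin$summary$rm_sd, 0)
})

test_that("survival_percent reproduces hand-computed means and is monotone", {
  full <- cohort("f", 10, day = 1:3, n_alive = c(10, 10, 10),
                 n_offspring = c(0, 0, 0))
  half <- cohort("h", 10, day = 1:3, n_alive = c(10, 5, 5),
                 n_offspring = c(0, 0, 0))
  sp <- survival_percent(list(full, half), day = 2)
  expect_equal(sp$mean, 75)

  # all replicates fully alive: 100.0 +/- 0.0
  sp1 <- survival_percent(list(full, full, full), day = 1)
  expect_equal(sp1$mean, 100)
  expect_equal(sp1$sd, 0)

  # single replicate: SD = 0
  expect_equal(survival_percent(list(half), day = 3)$sd, 0)

  # per-replicate series non-increasing over days; last value carried forward
  sp_all <- survival_percent(list(half), day = 1:5)
  series <- vapply(sp_all$percent, `[[`, numeric(1), 1)
  expect_true(all(diff(series) <= 0))
  expect_equal(series[4:5], c(50, 50))

  expect_error(survival_percent(list(half), day = 0), "precedes")
})

test_that("per-replicate and pooled modes agree for identical replicates", {
  ch <- cohort("r", 10, day = 1:4, n_alive = c(10, 10, 8, 0),
               n_offspring = c(0, 10, 16, 0))
  smry <- replicate_parameters(list(ch, ch), pooled = TRUE, label = "x")
  expect_equal(smry$pooled$R0, smry$summary$R0_mean)
  expect_equal(smry$pooled$T, smry$summary$T_mean)
  expect_equal(smry$pooled$rm, smry$summary$rm_mean)
})

test_that("cohort CSV round-trips through write_cohorts/read_cohorts", {
  chs <- list(
    cohort("a", 10, day = 1:3, n_alive = c(10, 6, 0),
           n_offspring = c(0, 12, 0), treatment = "t1"),
    cohort("b", 8, day = 1:2, n_alive = c(8, 0),
           n_offspring = c(0, 0), treatment = "t2")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohorts(chs, path)
  back <- read_cohorts(path, treatment_col = "treatment")
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$observations, chs[[1]]$observations)
  expect_equal(back[[1]]$initial_n, 10L) # inferred from first-day n_alive
  expect_equal(back[[2]]$treatment, "t2")
})
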