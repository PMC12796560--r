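test_that("model-based DT finds the screening-limit crossing", {
  p <- fx_typical()
  reg <- dosing_regimen(1.1)
  dt <- dt_model(p, reg, "plasma", 1)
  expect_equal(dt$DT, 51.4956, tolerance = 1e-3)  # frozen bisection oracle
  expect_equal(dt$censored, "none")
  # crossing bracketed by direct curve evaluation
  expect_gt(plasma_concentration(p, reg, dt$DT - 0.05), 1)
  expect_lt(plasma_concentration(p, reg, dt$DT + 0.05), 1)
  # SL above C0: never above -> DT 0 with flag
  hi <- dt_model(p, reg, "plasma", 1e4)
  expect_equal(hi$DT, 0)
  expect_equal(hi$censored, "never-above")
  # monotone nonincreasing in SL, for plasma and urine
  dts <- vapply(c(1, 2, 3, 4, 5), function(s)
    dt_model(p, reg, "plasma", s)$DT, 0)
  expect_true(all(diff(dts) < 0))
  u <- vapply(c(70, 100), function(s) dt_model(p, reg, "urine", s)$DT, 0)
  expect_true(all(diff(u) < 0))
  # multiple dosing prolongs the DT at the same SL
  reg5 <- dosing_regimen(1.1, n_doses = 5, interval = 24)
  expect_gt(dt_model(p, reg5, "plasma", 1)$DT, dt$DT)
})

test_that("log-linear interpolation matches its closed form and flags censoring", {
  d <- make_records(1, times = c(48, 72), dvs = c(1.3, 0.4))
  dt <- dt_interpolated(d, "plasma", 1)
  expect_equal(dt$DT, 48 + 24 * log(1.3 / 1) / log(1.3 / 0.4),
               tolerance = 1e-9)
  expect_equal(round(dt$DT, 1), 53.3)
  # observation exactly at the SL: DT is that time
  d2 <- make_records(1, times = c(48, 72), dvs = c(1.0, 0.4))
  expect_equal(dt_interpolated(d2, "plasma", 1)$DT, 48)
  # all below the SL: censored-low (NC)
  d3 <- make_records(1, times = c(48, 72), dvs = c(0.8, 0.4))
  expect_equal(dt_interpolated(d3, "plasma", 1)$censored, "censored-low")
  expect_true(is.na(dt_interpolated(d3, "plasma", 1)$DT))
  # never falls below within sampling: censored-high
  d4 <- make_records(1, times = c(48, 72), dvs = c(4, 2))
  expect_equal(dt_interpolated(d4, "plasma", 1)$censored, "censored-high")
  # multiple dosing: DT measured from the last administration
  d5 <- make_records(1, times = c(96 + 48, 96 + 72), dvs = c(1.3, 0.4))
  d5$TIME[d5$EVID == 1] <- 0
  extra <- d5[1, ]; extra$TIME <- 96   # second dose row
  d5 <- rbind(d5, extra)
  class(d5) <- c("pk_dataset", "data.frame")
  expect_equal(dt_interpolated(d5, "plasma", 1)$DT,
               48 + 24 * log(1.3) / log(1.3 / 0.4), tolerance = 1e-9)
})

test_that("model and interpolated DT agree on a dense noise-free grid", {
  p <- fx_typical()
  reg <- dosing_regimen(1.1)
  tt <- seq(1, 120, by = 1)
  d <- make_records(1, times = tt, dvs = plasma_concentration(p, reg, tt))
  for (s in c(1, 3, 5)) {
    expect_lt(abs(dt_interpolated(d, "plasma", s)$DT -
                    dt_model(p, reg, "plasma", s)$DT), 1)
  }
})

test_that("EHSLC cohort DT is the grid rule", {
  # two horses on a 24/48/72/96 grid; last above-SL observation at 48 h
  d <- rbind(make_records(1, times = c(24, 48, 72, 96),
                          dvs = c(5, 1.2, 0.6, 0.3)),
             make_records(2, times = c(24, 48, 72, 96),
                          dvs = c(4, 0.9, 0.5, 0.2)))
  class(d) <- c("pk_dataset", "data.frame")
  dt <- dt_ehslc(d, "plasma", 1)
  expect_equal(dt$DT, 72)
  # all observations below the SL: first scheduled time
  expect_equal(dt_ehslc(d, "plasma", 10)$DT, 24)
  # still above at the last sample: censored-high
  expect_equal(dt_ehslc(d, "plasma", 0.1)$censored, "censored-high")
})

test_that("EHSLC DT lies on the schedule and dominates interpolated DTs", {
  coh <- fx_cohort()
  arm <- coh[coh$ARM == "japan-single", ]
  class(arm) <- class(coh)
  sched <- sort(unique(arm$TIME[arm$EVID == 0 & arm$MATRIX == "plasma"]))
  for (s in screening_limits()$plasma_SL) {
    dt <- dt_ehslc(arm, "plasma", s)
    if (dt$censored == "censored-high") next
    expect_true(any(abs(sched - dt$DT) < 1e-6))
    indiv <- vapply(unique(arm$ID), function(id) {
      r <- dt_interpolated(arm[arm$ID == id, ], "plasma", s)
      if (is.na(r$DT)) 0 else r$DT
    }, 0)
    expect_gte(dt$DT + 1e-9, max(indiv))
  }
})

test_that("Monte Carlo DT study is reproducible and degenerates correctly", {
  pop <- fx_pop()
  reg <- dosing_regimen(1.1)
  a <- mcs_population_dt(pop, reg, n = 300, seed = 13)
  b <- mcs_population_dt(pop, reg, n = 300, seed = 13)
  expect_identical(a$summary, b$summary)
  # quantile rows nondecreasing across percentiles
  qcols <- grep("^p", names(a$summary))
  for (r in seq_len(nrow(a$summary)))
    expect_true(all(diff(unlist(a$summary[r, qcols])) >= 0))
  # DT monotone in SL horse by horse
  expect_true(all(a$plasma[, "1"] >= a$plasma[, "5"]))
  # omega = 0: every virtual horse equals the typical horse
  pz <- population_params(pop$theta, matrix(0, 7, 7), pop$sigma)
  z <- mcs_population_dt(pz, reg, n = 50, seed = 13)
  expect_lt(diff(range(z$plasma[, "1"])), 1e-9)
  expect_equal(unname(z$plasma[1, "1"]),
               dt_model(fx_typical(), reg, "plasma", 1)$DT, tolerance = 1e-3)
})

test_that("agreement summaries follow the Bland-Altman arithmetic", {
  ag <- dt_agreement(c(50, 60), c(40, 45))
  expect_equal(ag$differences, c(10, 15))
  expect_equal(ag$mean_diff, 12.5)
  expect_equal(unname(ag$loa),
               c(12.5 - 1.96 * sd(c(10, 15)), 12.5 + 1.96 * sd(c(10, 15))))
  same <- dt_agreement(c(50, 60), c(50, 60))
  expect_equal(unname(same$loa), c(0, 0))
  expect_true(all(same$differences == 0))
  expect_error(dt_agreement(1:3, 1:2), "paired")
})
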