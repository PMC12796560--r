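test_that("no observations returns the prior mode and the typical-horse DT", {
  pop <- fx_pop()
  reg <- dosing_regimen(1.1)
  empty <- make_records(1, times = numeric(0), dvs = numeric(0))
  est <- map_estimate(pop, empty, regimen = reg)
  expect_equal(unname(est$eta_hat), rep(0, 7))
  expect_equal(est$flag, "prior-mode")
  expect_equal(unlist(est$params), pop$theta)
  wt <- ibwt(est, screening_limits()[1, ])
  expect_equal(wt$plasma$DT, dt_model(fx_typical(), reg, "plasma", 1)$DT,
               tolerance = 1e-3)
  expect_equal(wt$plasma$DT, 51.50, tolerance = 0.01)
  expect_equal(wt$urine$DT, 37.54, tolerance = 0.01)   # frozen oracle values
})

test_that("uninformative data (huge sigmas) shrinks the posterior to the prior", {
  pop <- fx_pop()
  vague <- population_params(pop$theta, pop$omega,
                             c(plasma_prop = 50, plasma_add = 1e6,
                               urine_prop = 50, urine_add = 1e6))
  d <- make_records(1, times = c(9, 24, 48), dvs = c(200, 40, 2))
  est <- map_estimate(vague, d)
  expect_lt(max(abs(est$eta_hat)), 0.02)
})

test_that("a slow clearer gets a longer plasma IBWT than the typical horse", {
  pop <- fx_pop()
  reg <- dosing_regimen(1.1)
  eta <- stats::setNames(rep(0, 7), popkdt:::.PARAM_NAMES)
  eta["Cl"] <- -0.4
  slow <- do.call(disposition_params, as.list(pop$theta * exp(eta)))
  expect_gt(dt_model(slow, reg, "plasma", 1)$DT,
            dt_model(fx_typical(), reg, "plasma", 1)$DT)
})

test_that("the posterior mode is deterministic given data and prior", {
  pop <- fx_pop()
  coh <- generate_cohort(list(fx_rich_arm(2)), pop, seed = 17)
  a <- map_estimate(pop, coh[coh$ID == 1, ])
  b <- map_estimate(pop, coh[coh$ID == 1, ])
  expect_identical(a$eta_hat, b$eta_hat)
})

test_that("censored-only observations are rejected with a clear message", {
  pop <- fx_pop()
  d <- make_records(1, times = 24, dvs = 0.05, loq = 0.1)
  expect_error(map_estimate(pop, d), "below the LOQ")
})

test_that("perfect-data limit: zero BSV and zero noise give near-zero DT error", {
  pop <- fx_pop()
  pz <- population_params(pop$theta, matrix(0, 7, 7),
                          c(plasma_prop = 0, plasma_add = 0,
                            urine_prop = 0, urine_add = 0))
  coh <- generate_cohort(list(fx_rich_arm(4)), pz, seed = 21)
  prior <- population_params(pop$theta, pop$omega,
                             c(plasma_prop = 0.01, plasma_add = 0.01,
                               urine_prop = 0.01, urine_add = 0.01))
  se <- scenario_eval(coh, "rich", screening_limits()[1, ], prior)
  expect_lt(se$summary$mae[se$summary$matrix == "plasma"], 1)
  expect_lt(se$summary$mae[se$summary$matrix == "urine"], 1)
})

test_that("rich sampling improves the clearance random effect over the prior", {
  pop <- fx_pop()
  coh <- generate_cohort(list(fx_rich_arm(40)), pop, seed = 22)
  red <- scenario_sampling(coh, "rich")
  tr <- attr(coh, "truth")
  err_post <- err_prior <- c()
  for (id in unique(red$ID)) {
    est <- map_estimate(pop, red[red$ID == id, ])
    et <- tr$eta_Cl[tr$ID == id]
    err_post <- c(err_post, abs(est$eta_hat[["Cl"]] - et))
    err_prior <- c(err_prior, abs(et))
  }
  expect_lt(mean(err_post), mean(err_prior))
  expect_gt(mean(err_post < err_prior), 0.6)
})

test_that("posterior-informed withdrawal times beat the population value", {
  pop <- fx_pop()
  sl <- screening_limits()[1, ]
  coh <- generate_cohort(list(fx_rich_arm(30)), pop, seed = 25)
  se <- scenario_eval(coh, "rich", sl, pop)
  # population (typical-horse) DT as the uninformed predictor
  tr <- attr(coh, "truth")
  reg <- dosing_regimen(1.1)
  typ <- dt_model(fx_typical(), reg, "plasma", sl$plasma_SL)$DT
  prior_mae <- mean(abs(typ - se$table$ref_plasma))
  expect_lt(se$summary$mae[se$summary$matrix == "plasma"], prior_mae)
})

test_that("posterior clearance shrinks between the data and the prior", {
  pop <- fx_pop()
  coh <- generate_cohort(list(fx_rich_arm(25)), pop, seed = 26)
  red <- scenario_sampling(coh, "rich")
  flat <- population_params(pop$theta, diag(25, 7), pop$sigma)
  d_map <- d_ls <- c()
  for (id in unique(red$ID)) {
    est <- map_estimate(pop, red[red$ID == id, ])
    ls <- map_estimate(flat, red[red$ID == id, ])  # near-flat prior = naive fit
    d_map <- c(d_map, abs(est$params$Cl - pop$theta[["Cl"]]))
    d_ls <- c(d_ls, abs(ls$params$Cl - pop$theta[["Cl"]]))
  }
  expect_lte(mean(d_map), mean(d_ls))
})
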