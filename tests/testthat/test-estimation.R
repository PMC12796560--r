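# a fit-shaped list with just the fields compare_models needs
fake_fit <- function(ll, k, n, theta_names = popkdt:::.PARAM_NAMES) {
  structure(list(logLik = ll, k = k, n_obs = n,
                 BIC = -2 * ll + k * log(n),
                 theta = stats::setNames(rep(1, length(theta_names)),
                                         theta_names)),
            class = "fitted_model")
}

test_that("noise-free zero-omega data recovers the generating typicals", {
  pop <- fx_pop()
  pz <- population_params(pop$theta, matrix(0, 7, 7),
                          c(plasma_prop = 0, plasma_add = 0,
                            urine_prop = 0, urine_add = 0))
  arm <- study_arm_design("z", "Japan", 4, dose_mg_kg = 1.1, plasma_loq = 0.1,
                          urine_loq = 3, age_range = c(4, 10),
                          bw_range = c(428, 506))
  coh <- generate_cohort(list(arm), pz, seed = 23)
  cens <- suppressWarnings(censor_loq(coh))
  fit <- fit_population(cens$data,
                        init_from_nca(nca_initial_estimates(cens$data),
                                      cens$data),
                        fit_settings(max_iter = 40, rel_tol = 1e-6))
  expect_lt(max(abs(fit$theta / pop$theta - 1)), 0.001)
  expect_true(fit$convergence$converged)
})

test_that("BIC follows -2 lnL + k ln n and model comparison uses the chi-square", {
  f <- fake_fit(-100, 10, 200)
  expect_equal(f$BIC, -2 * -100 + 10 * log(200), tolerance = 1e-9)
  # identical fits: LRT 0, p 1
  same <- compare_models(fake_fit(-100, 10, 200), fake_fit(-100, 10, 200))
  expect_equal(same$lrt, 0)
  expect_equal(same$p_value, 1)
  # delta(-2lnL) = 6 at 2 df -> p = 0.0498 (chi-square CDF oracle)
  cmp <- compare_models(fake_fit(-103, 10, 200), fake_fit(-100, 12, 200))
  expect_equal(cmp$lrt, 6)
  expect_equal(cmp$df, 2L)
  expect_equal(cmp$p_value, pchisq(6, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(cmp$p_value, 4), 0.0498)
  # non-nested (reversed k): refuse the LRT, report the BIC delta
  expect_message(rev <- compare_models(fake_fit(-100, 12, 200),
                                       fake_fit(-103, 10, 200)), "not nested")
  expect_true(is.na(rev$lrt))
  expect_false(is.na(rev$delta_BIC))
})

test_that("three-compartment fit beats the nested two-compartment fit", {
  pop <- fx_pop()
  coh <- generate_cohort(flunixin_study_arms()[1], pop, seed = 19)
  cens <- suppressWarnings(censor_loq(coh))
  init <- init_from_nca(nca_initial_estimates(cens$data), cens$data)
  f3 <- fit_population(cens$data, init, fit_settings(max_iter = 8))
  f2 <- fit_population(cens$data, init,
                       fit_settings(model = "two_cpt", max_iter = 8))
  cmp <- compare_models(f2, f3)
  expect_gt(cmp$lrt, qchisq(0.95, cmp$df))
  expect_lt(cmp$p_value, 0.05)
})

test_that("diagnostics reproduce the CV%, shrinkage and residual identities", {
  fit <- fx_fit()
  dg <- diagnostics(fit, fx_censored(), n_vpc = 200)
  expect_equal(dg$cv_percent, cv_percent(diag(fit$omega)))
  # shrinkage identity: EBE SD equal to omega -> shrinkage 0
  expect_equal(dg$shrinkage,
               1 - apply(fit$ebe, 2, sd) / sqrt(diag(fit$omega)))
  # CWRES behave as N(0,1) residuals on well-specified data
  expect_lt(abs(mean(dg$table$CWRES)), 0.1)
  expect_gt(sd(dg$table$CWRES), 0.85)
  expect_lt(sd(dg$table$CWRES), 1.15)
  # VPC band contains about 80% of the observations
  inside <- with(merge(dg$table, dg$vpc,
                       by.x = c("MATRIX", "TAD"), by.y = c("matrix", "tad")),
                 mean(DV >= sim_p10 & DV <= sim_p90))
  expect_gt(inside, 0.73)
  expect_lt(inside, 0.87)
})

test_that("population fit recovers the cohort it was generated from", {
  fit <- fx_fit()
  coh <- fx_cohort()
  tr <- attr(coh, "truth")
  sample_gm <- fx_pop()$theta *
    exp(colMeans(tr[, paste0("eta_", popkdt:::.PARAM_NAMES)]))
  expect_lt(max(abs(fit$theta / sample_gm - 1)), 0.20)
  expect_lt(abs(cv_percent(fit$omega["Cl", "Cl"]) - 29.8), 10)
  expect_true(fit$convergence$converged)
})

test_that("bootstrap on degenerate data collapses to the point estimates", {
  pop <- fx_pop()
  pz <- population_params(pop$theta, matrix(0, 7, 7),
                          c(plasma_prop = 0, plasma_add = 0,
                            urine_prop = 0, urine_add = 0))
  arm <- study_arm_design("z", "Japan", 4, dose_mg_kg = 1.1, plasma_loq = 0.1,
                          urine_loq = 3, age_range = c(4, 10),
                          bw_range = c(428, 506),
                          plasma_times = c(0.25, 1, 4, 12, 24, 48, 96),
                          urine_times = c(24, 48, 96))
  coh <- generate_cohort(list(arm), pz, seed = 29)
  cens <- suppressWarnings(censor_loq(coh))
  fit <- fit_population(cens$data,
                        init_from_nca(nca_initial_estimates(cens$data),
                                      cens$data),
                        fit_settings(max_iter = 15, rel_tol = 1e-5))
  bs <- bootstrap_ci(cens$data, fit, n_boot = 5, seed = 2)
  tab <- bs$table
  expect_equal(bs$n_success, 5L)
  # identical horses -> every replicate equals the original fit
  sel <- tab$parameter %in% c("V1", "Cl", "Rss", "EPC", "IPC", "IUC")
  expect_lt(max((tab$upper - tab$lower)[sel] / tab$estimate[sel]), 0.01)
  expect_setequal(tab$parameter,
                  c(popkdt:::.PARAM_NAMES, names(pop$sigma),
                    "EPC", "IPC", "IUC"))
  expect_true(all(c("estimate", "se", "cv_percent", "lower", "upper")
                  %in% names(tab)))
})

test_that("bootstrap CI brackets the generating clearance", {
  fit <- fx_fit()
  bs <- bootstrap_ci(fx_censored(), fit, n_boot = 12, seed = 4)
  cl <- bs$table[bs$table$parameter == "Cl", ]
  expect_gt(47.36, cl$lower * 0.98)
  expect_lt(47.36, cl$upper * 1.02)
})
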