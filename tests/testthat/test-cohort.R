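test_that("the packaged six-arm design yields a 65-horse dataset", {
  coh <- generate_cohort(flunixin_study_arms(), fx_pop(), seed = 3)
  expect_equal(length(unique(coh$ID)), 65L)
  expect_setequal(unique(coh$COUNTRY), c("Japan", "USA", "UK", "Australia"))
  tr <- attr(coh, "truth")
  expect_equal(nrow(tr), 65L)
  # every horse has at least one dose row; q24h arm has five
  doses <- table(coh$ID[coh$EVID == 1])
  expect_true(all(doses >= 1))
  expect_equal(as.integer(doses[as.character(11:20)]), rep(5L, 10))
  # fixed-dose arm converts 500 mg/horse through the drawn body weight
  us2 <- coh[coh$ARM == "usa-fixed" & coh$EVID == 1, ]
  expect_equal(us2$AMT, 500e6 / us2$BW, tolerance = 1e-12)
  # covariates respect the arm ranges
  jp <- coh[coh$ARM == "japan-single", ]
  expect_true(all(jp$BW >= 428 & jp$BW <= 506))
  expect_true(all(jp$AGE >= 4 & jp$AGE <= 10))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_cohort(flunixin_study_arms(), fx_pop(), seed = 12)
  b <- generate_cohort(flunixin_study_arms(), fx_pop(), seed = 12)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "truth"), attr(b, "truth"))
})

test_that("degenerate generator (zero omega, zero sigma) gives identical curves", {
  pop <- fx_pop()
  pz <- population_params(pop$theta, matrix(0, 7, 7),
                          c(plasma_prop = 0, plasma_add = 0,
                            urine_prop = 0, urine_add = 0))
  coh <- generate_cohort(flunixin_study_arms()[1], pz, seed = 5)
  obs <- coh[coh$EVID == 0 & coh$MATRIX == "plasma", ]
  dv_by_time <- split(obs$DV, obs$TIME)
  expect_true(all(vapply(dv_by_time, function(x) diff(range(x)) == 0, TRUE)))
  expect_error(generate_cohort(list(), pop), "empty design")
})

test_that("the below-LOQ rule excludes under 5% and retains-with-flags above", {
  few <- make_records(1, times = 1:100, dvs = c(rep(10, 97), rep(0.05, 3)))
  out <- censor_loq(few)
  expect_equal(sum(out$data$EVID == 0), 97L)
  rep_p <- out$report[out$report$matrix == "plasma", ]
  expect_equal(rep_p$fraction, 0.03)
  expect_equal(rep_p$action, "excluded")
  many <- make_records(1, times = 1:100, dvs = c(rep(10, 90), rep(0.05, 10)))
  expect_warning(out2 <- censor_loq(many), "retained with flags")
  expect_equal(sum(out2$data$EVID == 0), 100L)
  expect_equal(out2$report$action[out2$report$matrix == "plasma"],
               "retained-flagged (>=5%)")
  clean <- make_records(1, times = 1:10, dvs = rep(10, 10))
  out3 <- censor_loq(clean)
  expect_equal(as.data.frame(out3$data), as.data.frame(clean))
  expect_equal(out3$report$action[out3$report$matrix == "plasma"], "none")
})

test_that("scenario sampling selects the clinical sampling designs", {
  pop <- fx_pop()
  coh <- generate_cohort(list(fx_rich_arm(3)), pop, seed = 8)
  rich <- scenario_sampling(coh, "rich")
  expect_equal(sum(rich$EVID == 0), 3L * 4L)  # plasma 9/24/48 + urine 48
  expect_setequal(rich$TIME[rich$EVID == 0 & rich$MATRIX == "plasma" &
                              rich$ID == 1], c(9, 24, 48))
  sparse <- scenario_sampling(coh, "sparse")
  expect_equal(sum(sparse$EVID == 0), 3L)
  expect_true(all(sparse$TIME[sparse$EVID == 0] == 24))
  r72 <- scenario_sampling(coh, "rich72")
  expect_setequal(r72$TIME[r72$EVID == 0 & r72$MATRIX == "plasma" &
                             r72$ID == 1], c(9, 24, 72))
  # multiple dosing: the sparse sample sits 24 h after the fifth dose
  coh5 <- generate_cohort(list(fx_rich_arm(2, n_doses = 5)), pop, seed = 8)
  sp5 <- scenario_sampling(coh5, "sparse")
  expect_true(all(sp5$TIME[sp5$EVID == 0] == 120))
  # horses missing a required time are excluded with a message
  noneat9 <- coh[!(coh$EVID == 0 & coh$TIME == 9 & coh$ID == 2), ]
  class(noneat9) <- class(coh)
  expect_message(out <- scenario_sampling(noneat9, "rich"), "excluded")
  expect_false(2 %in% out$ID)
})

test_that("generated noise magnitudes recover the input sigmas", {
  pop <- fx_pop()
  coh <- fx_cohort()
  tr <- attr(coh, "truth")
  rel <- c()
  for (id in unique(coh$ID)) {
    o <- coh[coh$ID == id & coh$EVID == 0 & coh$MATRIX == "plasma", ]
    p <- do.call(disposition_params,
                 as.list(unlist(tr[tr$ID == id, popkdt:::.PARAM_NAMES])))
    prd <- plasma_concentration(p, dosing_regimen(1.1), o$TIME)
    rel <- c(rel, (o$DV - prd)[prd > 50] / prd[prd > 50])
  }
  # on high concentrations the relative residual SD approaches sigma_prop
  expect_equal(sd(rel), 0.15, tolerance = 0.15)
})
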