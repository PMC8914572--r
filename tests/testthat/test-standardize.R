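test_that("an intercept-only model standardizes to the observed proportion", {
  co <- gformula_cohort()
  sp <- gformula_spec()
  fit <- fit_outcome_model(co, sp, formula = death_90d ~ 1)
  for (s in c(2, 5)) {
    expect_equal(standardize_risk(fit, co, list(surgeon_volume = s), sp),
                 mean(co$death_90d), tolerance = 1e-12)
  }
})

test_that("a saturated model reproduces the nonparametric g-formula exactly", {
  co <- gformula_cohort()
  sp <- gformula_spec()
  fit <- fit_outcome_model(co, sp,
                           formula = death_90d ~ factor(surgeon_volume_arm) *
                             z1 * z2)
  for (s in c(2, 5)) {
    got <- standardize_risk(fit, co, list(surgeon_volume = s), sp)
    # hand enumeration: sum_z P(Y=1 | A=s, z) P(z)
    strata <- expand.grid(z1 = 0:1, z2 = 0:1)
    gf <- sum(vapply(seq_len(nrow(strata)), function(i) {
      z <- strata[i, ]
      inz <- co$z1 == z$z1 & co$z2 == z$z2
      mean(co$death_90d[inz & co$surgeon_volume_arm == s]) * mean(inz)
    }, numeric(1)))
    expect_equal(got, gf, tolerance = 1e-10)
  }
})

test_that("arms off the grid are rejected", {
  co <- gformula_cohort()
  sp <- gformula_spec()
  fit <- fit_outcome_model(co, sp)
  expect_error(standardize_risk(fit, co, list(surgeon_volume = 7), sp),
               "off the trial grid")
})

test_that("with every patient beyond threshold all arms equal observed mortality", {
  co <- gformula_cohort()
  co$beyond_threshold <- TRUE
  co$hospital_volume <- rep(c(10, 14), length.out = nrow(co))
  co$hospital_volume_arm <- 12
  sp <- emulation_spec(3, surgeon_volume_grid = c(2, 5),
                       report_surgeon_volumes = c(2, 5),
                       patient_covariates = c("z1", "z2"),
                       model = list(surgeon_form = "indicators",
                                    hospital_form = "linear",
                                    interaction = FALSE))
  fit <- fit_outcome_model(co, sp)
  r <- vapply(c(2, 5), function(s)
    standardize_risk(fit, co, list(surgeon_volume = s, hospital_volume = 12),
                     sp), numeric(1))
  expect_equal(r[1], r[2], tolerance = 1e-12)
  expect_equal(r[1], mean(co$death_90d), tolerance = 1e-10)
})

test_that("risk differences are zero at the reference and plain subtraction elsewhere", {
  sp <- emulation_spec(1, report_surgeon_volumes = c(2, 25))
  risks <- data.frame(surgeon_volume_arm = c(2, 25),
                      hospital_volume_arm = NA_real_,
                      risk = c(0.10, 0.08))
  out <- risk_difference_table(risks, sp)
  expect_identical(out$risk_difference[out$is_reference], 0)
  expect_equal(out$risk_difference[out$surgeon_volume_arm == 25], -0.02)
  expect_error(risk_difference_table(risks[2, , drop = FALSE], sp),
               "missing reference arm")
})

test_that("grid risk differences equal brute-force pairwise differences", {
  cl <- small_claims("null", n_hospitals = 30, n_surgeons = 60,
                     n_patients = 1200, seed = 52)
  g <- suppressWarnings(emulate_trial(cl, emulation_spec(2,
                                                         model = linear_model)))
  for (h in unique(g$hospital_volume_arm)) {
    sub <- g[g$hospital_volume_arm == h, ]
    ref <- sub$risk[sub$surgeon_volume_arm == 2]
    expect_equal(sub$risk_difference, sub$risk - ref, tolerance = 1e-12)
  }
  hc <- attr(g, "hospital_contrasts")
  a <- g$risk[g$surgeon_volume_arm == 5 & g$hospital_volume_arm == 12]
  b <- g$risk[g$surgeon_volume_arm == 5 & g$hospital_volume_arm == 2]
  expect_equal(hc$risk_difference[hc$surgeon_volume_arm == 5 &
                                    hc$contrast == "median_vs_low"],
               a - b, tolerance = 1e-12)
})

test_that("uniform provider assignment makes standardized and empirical risks agree", {
  cl <- small_claims("null", n_hospitals = 40, n_surgeons = 80,
                     n_patients = 4000, seed = 53, travel_decay = 0,
                     quality_attraction = 0, volume_capacity_weight = 0)
  sp <- emulation_spec(1, model = list(surgeon_form = "indicators"))
  g <- suppressWarnings(emulate_trial(cl, sp))
  co <- suppressWarnings(build_cohort(cl, sp))
  for (s in c(2, 5)) {
    emp <- mean(co$death_90d[co$surgeon_volume_arm == s])
    n_cell <- sum(co$surgeon_volume_arm == s)
    tol <- 3 * sqrt(emp * (1 - emp) / n_cell) + 0.01
    expect_lt(abs(g$risk[g$surgeon_volume_arm == s] - emp), tol)
  }
})

test_that("trial 4 standardization averages provider traits over the arm neighborhood", {
  cl <- small_claims("savvy_patient", n_hospitals = 40, n_surgeons = 80,
                     n_patients = 1500, seed = 54)
  sp <- emulation_spec(4, model = smooth_model)
  g <- suppressWarnings(emulate_trial(cl, sp))
  expect_true(all(is.finite(g$risk)))
  expect_true(all(g$risk > 0 & g$risk < 1))
  # the double standardization changes the answer relative to trial 3
  g3 <- suppressWarnings(emulate_trial(cl, emulation_spec(3,
                                                          model = smooth_model)))
  expect_false(isTRUE(all.equal(g$risk, g3$risk, tolerance = 1e-8)))
  # provider tables are required
  co <- suppressWarnings(build_cohort(cl, sp))
  fit <- fit_outcome_model(co, sp)
  expect_error(standardize_risk(fit, co,
                                list(surgeon_volume = 5, hospital_volume = 12),
                                sp, providers = NULL),
               "provider tables")
})
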