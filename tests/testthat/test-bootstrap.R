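test_that("a single cluster yields degenerate zero-width intervals", {
  cl <- suppressWarnings(small_claims(n_hospitals = 1, n_surgeons = 4,
                                      n_patients = 250, seed = 61))
  sp <- emulation_spec(1, model = linear_model,
                       patient_covariates = c("age", "male"))
  g <- suppressWarnings(cluster_bootstrap(cl, sp,
                                          bootstrap_config(n_resamples = 50,
                                                           seed = 1)))
  expect_equal(g$ci_lower, g$ci_upper, tolerance = 1e-12)
  expect_equal(g$ci_lower, g$risk, tolerance = 1e-12)
})

test_that("the default configuration uses 1000 resamples and warns below 40", {
  expect_identical(bootstrap_config()$n_resamples, 1000L)
  expect_warning(bootstrap_config(n_resamples = 25), "unreliable")
})

test_that("identical seeds give identical interval bounds", {
  cl <- small_claims(n_hospitals = 20, n_surgeons = 40, n_patients = 600,
                     seed = 62)
  sp <- emulation_spec(2, model = linear_model)
  g1 <- suppressWarnings(cluster_bootstrap(cl, sp,
                                           bootstrap_config(80, seed = 9)))
  g2 <- suppressWarnings(cluster_bootstrap(cl, sp,
                                           bootstrap_config(80, seed = 9)))
  expect_identical(g1$ci_lower, g2$ci_lower)
  expect_identical(g1$rd_ci_upper, g2$rd_ci_upper)
  g3 <- suppressWarnings(cluster_bootstrap(cl, sp,
                                           bootstrap_config(80, seed = 10)))
  expect_false(identical(g1$ci_lower, g3$ci_lower))
})

test_that("interval bounds bracket the point estimates on a well-behaved run", {
  cl <- small_claims("null", n_hospitals = 40, n_surgeons = 80,
                     n_patients = 2000, seed = 63)
  sp <- emulation_spec(2, model = linear_model)
  g <- suppressWarnings(cluster_bootstrap(cl, sp,
                                          bootstrap_config(200, seed = 2)))
  expect_true(all(g$ci_lower <= g$risk & g$risk <= g$ci_upper))
  expect_true(all(g$rd_ci_lower <= g$risk_difference &
                    g$risk_difference <= g$rd_ci_upper))
  # degenerate resamples are rare and never exceed the warning threshold
  expect_lt(max(attr(g, "n_excluded")), 0.2 * 200)
})

test_that("ignoring clustering narrows intervals under intra-cluster correlation", {
  # strong unmeasured hospital-quality effect induces within-hospital
  # outcome correlation
  oc <- eval(formals(scm_params)$outcome_coefs)
  oc[c("surgeon_volume", "hospital_volume", "surgeon_quality")] <- 0
  oc["hospital_quality"] <- -1.2
  cl <- small_claims(n_hospitals = 25, n_surgeons = 50, n_patients = 1500,
                     seed = 64, outcome_coefs = oc, quality_volume_corr = 0,
                     quality_attraction = 0)
  sp <- emulation_spec(1, model = linear_model)
  g_cl <- suppressWarnings(cluster_bootstrap(
    cl, sp, bootstrap_config(150, cluster_unit = "hospital", seed = 3)))
  g_pt <- suppressWarnings(cluster_bootstrap(
    cl, sp, bootstrap_config(150, cluster_unit = "patient", seed = 3)))
  w_cl <- mean(g_cl$ci_upper - g_cl$ci_lower)
  w_pt <- mean(g_pt$ci_upper - g_pt$ci_lower)
  expect_gt(w_cl, w_pt)
})

test_that("fast index-level refits agree with full estimator re-runs", {
  cl <- small_claims(n_hospitals = 15, n_surgeons = 30, n_patients = 500,
                     seed = 65)
  sp <- emulation_spec(2, model = linear_model)
  g_fast <- suppressWarnings(cluster_bootstrap(
    cl, sp, bootstrap_config(40, seed = 4, mode = "fast")))
  g_full <- suppressWarnings(cluster_bootstrap(
    cl, sp, bootstrap_config(40, seed = 4, mode = "full")))
  expect_equal(g_fast$ci_lower, g_full$ci_lower, tolerance = 1e-6)
  expect_equal(g_fast$ci_upper, g_full$ci_upper, tolerance = 1e-6)
})

test_that("surgeon-level resampling is available as an alternative", {
  cl <- small_claims(n_hospitals = 15, n_surgeons = 30, n_patients = 500,
                     seed = 66)
  sp <- emulation_spec(1, model = linear_model)
  g <- suppressWarnings(cluster_bootstrap(
    cl, sp, bootstrap_config(50, cluster_unit = "surgeon", seed = 5)))
  expect_true(all(g$ci_lower <= g$ci_upper))
})
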