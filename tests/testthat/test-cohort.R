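test_that("trial specifications have the published arm structure", {
  expect_identical(n_arms(emulation_spec(1)), 26L)
  for (tr in 2:4) expect_identical(n_arms(emulation_spec(tr)), 1196L)
  expect_error(emulation_spec(4, provider_covariates = character()),
               "nonempty")
  expect_error(emulation_spec(2, provider_covariates = "h_cardiac_icu"),
               "only used in trial 4")
  expect_error(emulation_spec(5), "must be 1, 2, 3 or 4")
})

test_that("eligibility keeps the over-65, non-metastatic, no-chemo subset", {
  p <- data.frame(
    age = c(70, 64, 66, 80, 65, 72, 90, 66.5, 70, 75),
    metastatic = c(0, 1, 1, 0, 0, 0, 1, 0, 0, 0),
    preop_chemo = c(0, 1, 0, 1, 0, 0, 1, 0, 1, 0)
  )
  out <- apply_eligibility(p)
  # brute force over the fixture
  keep <- with(p, age > 65 & metastatic == 0 & preop_chemo == 0)
  expect_identical(nrow(out), sum(keep))
  tally <- attr(out, "exclusions")
  expect_identical(tally[["age_le_65"]], sum(!(p$age > 65)))
  expect_identical(tally[["metastatic"]],
                   sum(p$age > 65 & p$metastatic == 1))
  expect_identical(tally[["preop_chemo"]],
                   sum(p$age > 65 & p$metastatic == 0 & p$preop_chemo == 1))
  # age 64 with no other flags is excluded on age alone
  one <- apply_eligibility(data.frame(age = 64, metastatic = 0,
                                      preop_chemo = 0))
  expect_identical(nrow(one), 0L)
  # empty input: empty output and zero tallies
  empty <- apply_eligibility(p[0, ])
  expect_identical(nrow(empty), 0L)
  expect_true(all(attr(empty, "exclusions") == 0L))
  expect_error(apply_eligibility(data.frame(x = 1)), "age")
})

test_that("trailing-year volume counts the half-open window before the index", {
  idx <- as.Date("2015-06-01")
  log <- data.frame(provider_id = "S1", date = idx + c(-400, -200, -1, 0))
  expect_identical(compute_trailing_volume(log, "S1", idx), 2L)
  expect_identical(compute_trailing_volume(log, "S1", idx, window_days = 0), 0L)
  expect_identical(compute_trailing_volume(log[0, ], "S1", idx), 0L)
  expect_error(compute_trailing_volume(log, "S1", idx, window_days = -1),
               "nonnegative")
})

test_that("a simulated operation log reproduces the configured annual volumes", {
  prov <- data.frame(surgeon_id = c("A", "B", "C", "D"),
                     annual_volume = c(4, 12, 24, 52))
  log <- simulate_operation_log(prov, seed = 31)
  idx <- as.Date("2015-06-01")
  got <- vapply(prov$surgeon_id, compute_trailing_volume,
                integer(1), operation_log = log, index_date = idx)
  expect_gt(cor(got, prov$annual_volume), 0.98)
  expect_equal(mean(got), mean(prov$annual_volume), tolerance = 0.2)
})

test_that("nearest matched volume minimizes distance with ties toward smaller", {
  expect_identical(nearest_matched_volume(25, c(3, 18)), 18)
  expect_identical(nearest_matched_volume(10, c(5, 15)), 5)
  expect_identical(nearest_matched_volume(7, c(2, 7, 30)), 7)
  expect_error(nearest_matched_volume(5, numeric()), "no reachable provider")
  # brute force over random sets
  set.seed(41)
  for (i in 1:20) {
    v <- sample(1:40, 6)
    a <- sample(0:30, 1)
    best <- min(v[abs(v - a) == min(abs(v - a))])
    expect_identical(nearest_matched_volume(a, v), best)
  }
})

test_that("arm assignment mirrors observed volumes and flags distant patients", {
  cl <- small_claims("travel_confounding", n_hospitals = 40, n_surgeons = 80,
                     n_patients = 800, seed = 32)
  elig <- apply_eligibility(cl$patients)
  a3 <- assign_arms(elig, cl, emulation_spec(3))
  sv <- cl$surgeons$annual_volume[match(elig$surgeon_id,
                                        cl$surgeons$surgeon_id)]
  expect_equal(a3$surgeon_volume_arm, pmin(pmax(sv, 0), 25))
  # a patient operated by a volume-12 surgeon lands in arm "surgeon volume 12"
  i <- which(sv == 12)[1]
  expect_equal(a3$surgeon_volume_arm[i], 12)
  # beyond-threshold patients keep their observed (natural) volumes
  orc <- attr(cl$patients, "oracle")
  expect_identical(a3$beyond_threshold, unname(orc$remote))
  expect_true(all(a3$surgeon_volume_arm[a3$beyond_threshold] %in% c(1, 3)))
  # co-located patients are never beyond any threshold
  co <- elig$location_id %in% cl$surgeons$location_id
  expect_true(all(!a3$beyond_threshold[co]))
})

test_that("raising the travel threshold weakly shrinks the beyond set", {
  # 30 metro hospitals plus the remote block's outlying hospitals exceed the
  # surgeon count here, which the generator legitimately warns about
  cl <- suppressWarnings(
    small_claims("travel_confounding", n_hospitals = 30, n_surgeons = 60,
                 n_patients = 600, seed = 33))
  n_beyond <- vapply(c(1.5, 3, 6), function(th)
    sum(beyond_threshold(cl$patients, cl, th)), numeric(1))
  expect_true(all(diff(n_beyond) <= 0))
})

test_that("trial 2 arm labels refine trial 1 labels exactly", {
  cl <- small_claims(seed = 34, n_patients = 400)
  elig <- apply_eligibility(cl$patients)
  a1 <- suppressWarnings(assign_arms(elig, cl, emulation_spec(1)))
  a2 <- suppressWarnings(assign_arms(elig, cl, emulation_spec(2)))
  expect_identical(a2$surgeon_volume_arm, a1$surgeon_volume_arm)
  expect_true(all(is.na(a1$hospital_volume_arm)))
  expect_false(anyNA(a2$hospital_volume_arm))
  # assignment is deterministic
  expect_identical(a2, suppressWarnings(assign_arms(elig, cl,
                                                    emulation_spec(2))))
})

test_that("out-of-grid observed volumes are clamped for labels but kept raw", {
  cl <- small_claims(seed = 35, n_hospitals = 120, n_surgeons = 240,
                     n_patients = 2500)
  expect_warning(co <- build_cohort(cl, emulation_spec(2)), "clamped")
  expect_true(max(co$hospital_volume) > max(co$hospital_volume_arm))
  expect_true(all(co$hospital_volume_arm <= 45))
})
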