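test_that("default configuration reproduces the cohort's provider counts", {
  pr <- generate_providers(scm_params(seed = 2))
  expect_identical(nrow(pr$hospitals), 697L)
  expect_identical(nrow(pr$surgeons), 1358L)
  # provider-weighted volume means near the published tables
  expect_equal(mean(pr$surgeons$annual_volume), 3, tolerance = 0.15)
  expect_equal(mean(pr$hospitals$annual_volume), 6, tolerance = 0.15)
  # every surgeon affiliated with >= 1 hospital; multi iff > 1
  aff <- strsplit(pr$surgeons$hospital_ids, ";", fixed = TRUE)
  expect_true(all(lengths(aff) >= 1))
  expect_identical(pr$surgeons$multi_hospital == 1L, lengths(aff) > 1L)
})

test_that("latent quality decouples from volume when the correlation is zero", {
  pr <- generate_providers(scm_params(n_hospitals = 300, n_surgeons = 1000,
                                      n_patients = 10, quality_volume_corr = 0,
                                      seed = 3))
  expect_lt(abs(cor(pr$surgeons$latent_quality,
                    log(pr$surgeons$annual_volume))), 0.1)
  expect_lt(abs(cor(pr$hospitals$latent_quality,
                    log(pr$hospitals$annual_volume))), 0.2)
})

test_that("patient-weighted volumes are size-biased relative to providers", {
  cl <- small_claims(n_hospitals = 200, n_surgeons = 400, n_patients = 6000,
                     seed = 4, travel_decay = 0, quality_attraction = 0)
  pv <- cl$surgeons$annual_volume[match(cl$patients$surgeon_id,
                                        cl$surgeons$surgeon_id)]
  # resampling oracle: draw providers proportional to volume
  set.seed(99)
  sb <- sample(cl$surgeons$annual_volume, 6000, replace = TRUE,
               prob = cl$surgeons$annual_volume)
  expect_equal(mean(pv), mean(sb), tolerance = 0.1)
  # provider-weighted mean ~3 while the patient-weighted median exceeds it
  expect_gt(median(pv), mean(cl$surgeons$annual_volume))
})

test_that("covariate prevalences and mortality match their configuration", {
  cl <- small_claims(n_patients = 4000, n_hospitals = 60, n_surgeons = 120,
                     seed = 5)
  expect_equal(mean(cl$patients$diabetes), 0.45, tolerance = 0.03)
  expect_equal(mean(cl$patients$cad), 0.47, tolerance = 0.03)
  expect_equal(mean(cl$patients$male), 0.51, tolerance = 0.03)
  expect_equal(mean(cl$patients$death_90d), 0.075, tolerance = 0.015)
  expect_true(all(cl$patients$death_90d %in% 0:1))
  # exactly one surgeon and hospital per patient, all known providers
  expect_true(all(cl$patients$surgeon_id %in% cl$surgeons$surgeon_id))
  expect_true(all(cl$patients$hospital_id %in% cl$hospitals$hospital_id))
})

test_that("extreme travel decay sends every patient to the nearest provider", {
  cl <- small_claims(n_hospitals = 20, n_surgeons = 40, n_patients = 300,
                     seed = 6, travel_decay = 60, quality_attraction = 0,
                     volume_capacity_weight = 0)
  ploc <- cl$patients$location_id
  chosen <- cl$hospitals$location_id[match(cl$patients$hospital_id,
                                           cl$hospitals$hospital_id)]
  H <- travel_matrix(cl$travel, unique(ploc),
                     unique(cl$hospitals$location_id))
  nearest <- apply(H, 1, min)[match(ploc, unique(ploc))]
  got <- travel_hours(cl$travel, ploc, chosen)
  # softmax choice: a provider within Gumbel noise of the nearest can win,
  # so allow the tiny utility-equivalent slack 5/decay hours
  expect_true(all(got <= nearest + 5 / 60))
  expect_gt(mean(got <= nearest + 1e-8), 0.9)
})

test_that("severity is unrelated to chosen provider quality without savvy selection", {
  cl <- small_claims(n_hospitals = 40, n_surgeons = 80, n_patients = 3000,
                     seed = 7, travel_decay = 0, quality_attraction = 0,
                     volume_capacity_weight = 0,
                     severity_selection_strength = 0)
  comorb <- c("acute_mi", "dementia", "afib", "ckd", "copd", "chf",
              "diabetes", "cad", "stroke_tia")
  sev <- rowSums(cl$patients[comorb])
  q <- cl$surgeons$latent_quality[match(cl$patients$surgeon_id,
                                        cl$surgeons$surgeon_id)]
  expect_lt(abs(cor(sev, q)), 3.5 / sqrt(3000))
  # positive control: savvy selection induces the association
  cls <- small_claims("savvy_patient", n_hospitals = 40, n_surgeons = 80,
                      n_patients = 3000, seed = 7)
  sev2 <- rowSums(cls$patients[comorb])
  q2 <- cls$surgeons$latent_quality[match(cls$patients$surgeon_id,
                                          cls$surgeons$surgeon_id)]
  expect_lt(cor(sev2, q2), -0.03)
})

test_that("identical parameters and seed give byte-identical claims", {
  a <- small_claims(seed = 8, n_patients = 300)
  b <- small_claims(seed = 8, n_patients = 300)
  expect_identical(a$patients, b$patients)
  expect_identical(a$surgeons, b$surgeons)
  expect_identical(a$hospitals, b$hospitals)
})

test_that("travel geography rejects unknown locations and is symmetric", {
  cl <- small_claims(seed = 9, n_patients = 50)
  expect_error(travel_hours(cl$travel, "nowhere", cl$hospitals$location_id[1]),
               "missing location")
  ids <- cl$travel$locations$location_id[1:4]
  H <- travel_matrix(cl$travel, ids, ids)
  expect_equal(H, t(H))
  expect_true(all(diag(H) == 0))
})
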