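# Shared fixtures, all generated in code at test time.

small_claims <- function(scenario = "baseline", n_hospitals = 25,
                         n_surgeons = 50, n_patients = 500, seed = 1, ...) {
  simulate_claims(scm_scenario(scenario, n_hospitals = n_hospitals,
                               n_surgeons = n_surgeons,
                               n_patients = n_patients, seed = seed, ...))
}

# Deterministic cohort with two binary covariates and two surgeon-volume
# levels; every (arm, z1, z2) cell has a controlled death count strictly
# between 0 and the cell size, so the saturated logistic model is the cell
# means exactly.
gformula_cohort <- function(cell_n = 40,
                            deaths = c(4, 7, 9, 12, 6, 10, 13, 18)) {
  cells <- expand.grid(surgeon_volume = c(2, 5), z1 = 0:1, z2 = 0:1)
  stopifnot(length(deaths) == nrow(cells), all(deaths > 0),
            all(deaths < cell_n))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    data.frame(
      surgeon_volume = cells$surgeon_volume[i],
      surgeon_volume_arm = cells$surgeon_volume[i],
      z1 = cells$z1[i], z2 = cells$z2[i],
      beyond_threshold = FALSE,
      death_90d = rep(c(1, 0), c(deaths[i], cell_n - deaths[i]))
    )
  })
  do.call(rbind, rows)
}

# Three-covariate variant: 16 (arm, z1, z2, z3) cells of 20 patients with
# death counts strictly inside (0, 20).
gformula_cohort3 <- function() {
  cells <- expand.grid(surgeon_volume = c(2, 5), z1 = 0:1, z2 = 0:1,
                       z3 = 0:1)
  deaths <- c(2, 4, 3, 6, 5, 8, 4, 9, 3, 5, 7, 10, 6, 11, 8, 13)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    data.frame(
      surgeon_volume = cells$surgeon_volume[i],
      surgeon_volume_arm = cells$surgeon_volume[i],
      z1 = cells$z1[i], z2 = cells$z2[i], z3 = cells$z3[i],
      beyond_threshold = FALSE,
      death_90d = rep(c(1, 0), c(deaths[i], 20 - deaths[i]))
    )
  })
  do.call(rbind, rows)
}

gformula_spec <- function() {
  emulation_spec(1, surgeon_volume_grid = c(2, 5),
                 reference_surgeon_volume = 2,
                 report_surgeon_volumes = c(2, 5),
                 patient_covariates = c("z1", "z2"),
                 model = list(surgeon_form = "indicators"))
}

# Risk difference between two report arms of a risk grid.
grid_rd <- function(g, s, h = NA) {
  ref <- attr(g, "spec")$reference_surgeon_volume
  if (is.na(h)) {
    g$risk[g$surgeon_volume_arm == s & is.na(g$hospital_volume_arm)] -
      g$risk[g$surgeon_volume_arm == ref & is.na(g$hospital_volume_arm)]
  } else {
    g$risk[g$surgeon_volume_arm == s & g$hospital_volume_arm == h] -
      g$risk[g$surgeon_volume_arm == ref & g$hospital_volume_arm == h]
  }
}

# Linear / indicator treatment forms used by the scenario contrasts, chosen
# to match each scenario's structural functional form.
linear_model <- list(surgeon_form = "linear", hospital_form = "linear",
                     interaction = FALSE)
indicator_model <- list(surgeon_form = "indicators",
                        hospital_form = "linear", interaction = FALSE)
smooth_model <- list(surgeon_form = "spline", hospital_form = "spline",
                     interaction = FALSE)
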