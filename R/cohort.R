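#' Specification of an emulated target trial
#'
#' Fixes the design of one of the four target trials: the intervention grid,
#' the driving-time threshold (trials 3-4), the covariate adjustment sets and
#' the reporting layout.
#'
#' @param trial integer 1-4.
#' @param travel_threshold_hours driving-time threshold in hours for trials
#'   3-4 (1.5 by default; 3 and 6 are the sensitivity values).
#' @param surgeon_volume_grid,hospital_volume_grid intervention grids
#'   (operations/year); defaults 0:25 and 0:45 so trial 1 has 26 arms and
#'   trials 2-4 have 26 x 46 = 1196 joint arms.
#' @param reference_surgeon_volume surgeon-volume reference arm (2/y).
#' @param reference_hospital_volumes hospital strata reported (2, 12, 43/y:
#'   the observed 10th percentile, median and 90th percentile).
#' @param report_surgeon_volumes surgeon volumes reported (2, 5, 18, 25/y).
#' @param patient_covariates names of baseline patient covariates entering
#'   the outcome model.
#' @param provider_covariates names of surgeon/hospital covariates; must be
#'   nonempty exactly when `trial = 4`.
#' @param model list controlling the outcome-model treatment terms:
#'   `surgeon_form` / `hospital_form` in `"spline"` (restricted cubic,
#'   default), `"linear"`, or `"indicators"`; `df` spline degrees of freedom;
#'   `interaction` include the surgeon x hospital volume product term;
#'   `ridge` optional ridge penalty (0 = plain maximum likelihood).
#' @param threshold_level `"surgeon"` (default: beyond-threshold means no
#'   surgeon within reach, as in the emulation's wording) or `"pair"`
#'   (no affiliated surgeon-hospital pair within reach).
#' @return An object of class `emulation_spec`.
#' @examples
#' n_arms(emulation_spec(1))   # 26
#' n_arms(emulation_spec(3))   # 1196
#' @export
emulation_spec <- function(trial,
                           travel_threshold_hours = 1.5,
                           surgeon_volume_grid = 0:25,
                           hospital_volume_grid = 0:45,
                           reference_surgeon_volume = 2,
                           reference_hospital_volumes = c(2, 12, 43),
                           report_surgeon_volumes = c(2, 5, 18, 25),
                           patient_covariates = c(
                             "age", "male", "acute_mi", "dementia", "afib",
                             "ckd", "copd", "chf", "diabetes", "cad",
                             "stroke_tia", "inpatient"),
                           provider_covariates = if (trial == 4) c(
                             "s_age", "s_male", "s_multi_hospital", "h_cardiac_icu",
                             "h_ownership", "h_teaching", "h_size_large") else character(),
                           model = list(),
                           threshold_level = c("surgeon", "pair")) {
  trial <- .assert_count(trial, "trial")
  if (!trial %in% 1:4) stop("trial must be 1, 2, 3 or 4", call. = FALSE)
  if (trial == 4 && length(provider_covariates) == 0L) {
    stop("trial 4 requires a nonempty provider_covariates set", call. = FALSE)
  }
  if (trial != 4 && length(provider_covariates) > 0L) {
    stop("provider_covariates are only used in trial 4", call. = FALSE)
  }
  model <- modifyList(
    list(surgeon_form = "spline", hospital_form = "spline", df = 3,
         interaction = TRUE, ridge = 0),
    model)
  spec <- structure(list(
    trial = trial,
    travel_threshold_hours = if (trial >= 3) travel_threshold_hours else NULL,
    surgeon_volume_grid = sort(unique(surgeon_volume_grid)),
    hospital_volume_grid = sort(unique(hospital_volume_grid)),
    reference_surgeon_volume = reference_surgeon_volume,
    reference_hospital_volumes = reference_hospital_volumes,
    report_surgeon_volumes = report_surgeon_volumes,
    patient_covariates = patient_covariates,
    provider_covariates = provider_covariates,
    model = model,
    threshold_level = match.arg(threshold_level)
  ), class = "emulation_spec")
  spec
}

#' Number of intervention arms of an emulated trial
#'
#' Trial 1 intervenes on surgeon volume only (one arm per grid value); trials
#' 2-4 intervene jointly on surgeon and hospital volume.
#'
#' @param spec an [emulation_spec()].
#' @return Integer arm count.
#' @export
n_arms <- function(spec) {
  ns <- length(spec$surgeon_volume_grid)
  if (spec$trial == 1) ns else ns * length(spec$hospital_volume_grid)
}

#' @export
print.emulation_spec <- function(x, ...) {
  cat(sprintf("<emulation_spec> trial %d: %d arms%s\n", x$trial, n_arms(x),
              if (!is.null(x$travel_threshold_hours))
                sprintf(", %.1f h driving-time threshold",
                        x$travel_threshold_hours) else ""))
  invisible(x)
}

#' Apply the trial eligibility criteria
#'
#' Retains patients older than 65 years, without evidence of metastatic
#' disease, and not expected to receive preoperative chemotherapy.  Exclusions
#' are tallied by the first failing criterion, applied in that order.
#'
#' @param patients patient data frame with columns `age` and (optionally)
#'   `metastatic`, `preop_chemo`; missing flag columns are treated as all
#'   zero, but a missing or NA `age` is an error.
#' @return The eligible subset, with attribute `exclusions`: a named integer
#'   vector of per-criterion exclusion counts.
#' @examples
#' p <- data.frame(age = c(70, 64), metastatic = 0, preop_chemo = 0)
#' attr(apply_eligibility(p), "exclusions")
#' @export
apply_eligibility <- function(patients) {
  if (!"age" %in% names(patients) || anyNA(patients$age)) {
    stop("apply_eligibility: field 'age' is required and must be complete",
         call. = FALSE)
  }
  n <- nrow(patients)
  met <- patients$metastatic %||% rep(0L, n)
  chemo <- patients$preop_chemo %||% rep(0L, n)
  fail_age <- !(patients$age > 65)
  fail_met <- !fail_age & met == 1
  fail_chemo <- !fail_age & !fail_met & chemo == 1
  keep <- !(fail_age | fail_met | fail_chemo)
  out <- patients[keep, , drop = FALSE]
  orc <- attr(patients, "oracle")
  if (!is.null(orc)) attr(out, "oracle") <- orc[keep, , drop = FALSE]
  attr(out, "exclusions") <- c(age_le_65 = sum(fail_age),
                               metastatic = sum(fail_met),
                               preop_chemo = sum(fail_chemo))
  out
}

#' Trailing-year operative volume from an operation log
#'
#' Counts a provider's operations in the half-open window
#' `[index_date - window_days, index_date)`; the index operation itself
#' (and anything else on the index date) is excluded.
#'
#' @param operation_log data frame with columns `provider_id` and `date`.
#' @param provider_id provider to count for.
#' @param index_date the index operation date.
#' @param window_days nonnegative window length (default 365).
#' @return Integer count.
#' @examples
#' log <- data.frame(provider_id = "S1",
#'                   date = as.Date("2015-06-01") + c(-400, -200, -1, 0))
#' compute_trailing_volume(log, "S1", as.Date("2015-06-01"))  # 2
#' @export
compute_trailing_volume <- function(operation_log, provider_id, index_date,
                                    window_days = 365) {
  if (window_days < 0) stop("window_days must be nonnegative", call. = FALSE)
  index_date <- as.Date(index_date)
  d <- as.Date(operation_log$date[operation_log$provider_id == provider_id])
  sum(d >= index_date - window_days & d < index_date)
}

#' Simulate an operation log consistent with provider annual volumes
#'
#' Optional operation-log mode: scatters, for each provider, `annual_volume`
#' operations per year uniformly over the given period, so that
#' [compute_trailing_volume()] applied at interior dates recovers the
#' configured volumes up to Poisson-like fluctuation.
#'
#' @param providers data frame with `*_id` column (first column) and
#'   `annual_volume`.
#' @param from,to period covered.
#' @param seed RNG seed.
#' @return Data frame with columns `provider_id`, `date`.
#' @export
simulate_operation_log <- function(providers, from = as.Date("2011-01-01"),
                                   to = as.Date("2016-12-31"), seed = 1L) {
  set.seed(sub_seed(seed, "operation-log"))
  years <- as.numeric(to - from) / 365.25
  ids <- providers[[1]]
  n_ops <- round(providers$annual_volume * years)
  data.frame(
    provider_id = rep(ids, n_ops),
    date = from + round(runif(sum(n_ops), 0, as.numeric(to - from)))
  )
}

#' Nearest available volume within reach
#'
#' The element of `reachable_provider_volumes` minimizing the absolute
#' distance to the assigned volume; ties break toward the smaller volume.
#' An empty reachable set signals "no reachable provider" (the caller then
#' uses the natural value of treatment).
#'
#' @param assigned_volume the volume assigned by the strategy.
#' @param reachable_provider_volumes volumes of providers within the
#'   driving-time threshold.
#' @return A single volume.
#' @examples
#' nearest_matched_volume(25, c(3, 18))   # 18
#' nearest_matched_volume(10, c(5, 15))   # 5 (tie toward smaller)
#' @export
nearest_matched_volume <- function(assigned_volume,
                                   reachable_provider_volumes) {
  v <- sort(reachable_provider_volumes)
  if (length(v) == 0L) {
    stop("no reachable provider: use the natural value of treatment",
         call. = FALSE)
  }
  v[which.min(abs(v - assigned_volume))]
}

#' Which patients are beyond the driving-time threshold?
#'
#' A patient is beyond the threshold when no surgeon (default) or no
#' affiliated surgeon-hospital pair practices within `threshold_hours`
#' driving time of the patient's home location.
#'
#' @param patients patient data frame with `location_id`.
#' @param claims a `volemu_claims` bundle (providers + travel geography).
#' @param threshold_hours driving-time threshold in hours.
#' @param level `"surgeon"` or `"pair"` (identical here because surgeons are
#'   located at their hospitals, but kept distinct for other geographies).
#' @return Logical vector along `patients`.
#' @export
beyond_threshold <- function(patients, claims, threshold_hours,
                             level = c("surgeon", "pair")) {
  level <- match.arg(level)
  prov_loc <- if (level == "surgeon") {
    unique(claims$surgeons$location_id)
  } else {
    hl <- claims$hospitals$location_id[
      match(unlist(strsplit(claims$surgeons$hospital_ids, ";", fixed = TRUE)),
            claims$hospitals$hospital_id)]
    unique(hl)
  }
  pat_loc <- unique(patients$location_id)
  H <- travel_matrix(claims$travel, pat_loc, prov_loc)
  nearest <- apply(H, 1L, min)
  unname(nearest[match(patients$location_id, pat_loc)] > threshold_hours)
}

#' Assign eligible patients to emulated-trial arms
#'
#' Each patient is assigned to the strategy consistent with their observed
#' data: trial 1 labels patients by their surgeon's observed annual volume
#' (hospital volume left at its natural value); trials 2-4 by the observed
#' (surgeon, hospital) volume pair; trials 3-4 additionally flag patients
#' beyond the driving-time threshold of any surgeon, whose strategy leaves
#' treatment at its natural value.  Observed volumes outside the grids are
#' clamped to the grid boundary for arm labelling (with a warning) but are
#' retained raw in the cohort for model fitting.
#'
#' @param patients eligible patient data frame.
#' @param claims a `volemu_claims` bundle.
#' @param spec an [emulation_spec()].
#' @return Data frame with columns `patient_id`, `surgeon_volume_arm`,
#'   `hospital_volume_arm` (NA for trial 1, whose hospital value is natural)
#'   and `beyond_threshold`.
#' @export
assign_arms <- function(patients, claims, spec) {
  sv <- claims$surgeons$annual_volume[match(patients$surgeon_id,
                                            claims$surgeons$surgeon_id)]
  hv <- claims$hospitals$annual_volume[match(patients$hospital_id,
                                             claims$hospitals$hospital_id)]
  if (anyNA(sv) || anyNA(hv)) {
    stop("assign_arms: patients reference unknown providers", call. = FALSE)
  }
  clamp <- function(x, grid, what) {
    lo <- min(grid); hi <- max(grid)
    n_out <- sum(x < lo | x > hi)
    if (n_out > 0) {
      warning(sprintf("%d observed %s volume(s) outside the grid [%d, %d]; clamped for arm labels",
                      n_out, what, lo, hi), call. = FALSE)
    }
    pmin(pmax(x, lo), hi)
  }
  arm <- data.frame(
    patient_id = patients$patient_id,
    surgeon_volume_arm = clamp(sv, spec$surgeon_volume_grid, "surgeon"),
    hospital_volume_arm = if (spec$trial == 1) NA_real_ else
      clamp(hv, spec$hospital_volume_grid, "hospital"),
    beyond_threshold = FALSE,
    stringsAsFactors = FALSE
  )
  if (spec$trial >= 3) {
    arm$beyond_threshold <- beyond_threshold(
      patients, claims, spec$travel_threshold_hours, spec$threshold_level)
  }
  arm
}

## Model-facing provider covariate columns (shared by the cohort build and
## trial 4's neighborhood standardization).  Hospital size enters as a
## binary large-vs-other indicator: the "small" category is too rare (~2%)
## to support a stable indicator of its own.
#' @keywords internal
.surgeon_covs <- function(s) {
  data.frame(s_age = s$age, s_male = s$male,
             s_multi_hospital = s$multi_hospital)
}

#' @keywords internal
.hospital_covs <- function(h) {
  data.frame(h_cardiac_icu = h$cardiac_icu, h_ownership = h$ownership,
             h_teaching = h$teaching,
             h_size_large = as.integer(h$size == "large"))
}

#' Assemble the analysis cohort for one emulated trial
#'
#' Applies eligibility, assigns arms, and joins the raw observed volumes and
#' (for trial 4) the provider characteristics onto the patient records.
#'
#' @param claims a `volemu_claims` bundle.
#' @param spec an [emulation_spec()].
#' @return The cohort data frame, with attributes `exclusions` (eligibility
#'   tally) and `oracle` (carried through when present).
#' @export
build_cohort <- function(claims, spec) {
  elig <- apply_eligibility(claims$patients)
  arms <- assign_arms(elig, claims, spec)
  s <- claims$surgeons[match(elig$surgeon_id, claims$surgeons$surgeon_id), ]
  h <- claims$hospitals[match(elig$hospital_id, claims$hospitals$hospital_id), ]
  cohort <- cbind(
    elig,
    arms[c("surgeon_volume_arm", "hospital_volume_arm", "beyond_threshold")],
    surgeon_volume = s$annual_volume,
    hospital_volume = h$annual_volume,
    .surgeon_covs(s),
    .hospital_covs(h)
  )
  attr(cohort, "exclusions") <- attr(elig, "exclusions")
  attr(cohort, "oracle") <- attr(elig, "oracle")
  cohort
}
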