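#' Structural-model parameters for the synthetic claims generator
#'
#' Bundles every coefficient of the data-generating structural causal model:
#' provider counts and volume distributions, the surgeon-hospital volume
#' coupling, latent provider quality, patient covariate prevalences, the
#' travel/quality/severity provider-choice model, and the logistic 90-day
#' mortality model.  The defaults emulate the published Medicare
#' pancreatectomy cohort: 9136 patients, 1358 surgeons, 697 hospitals,
#' provider-weighted mean annual volumes of about 3 (surgeons, range 1-50) and
#' 6 (hospitals, range 1-139), Table-1 comorbidity prevalences (for example
#' diabetes 45%), and a 90-day mortality around 7.5%.
#'
#' @param n_hospitals,n_surgeons,n_patients positive integer counts.
#' @param hospital_volume_dist,surgeon_volume_dist annual-volume distribution
#'   spec: `list(family = "ztnb", mu, size)` (zero-truncated negative
#'   binomial, the right-skewed default; `mu` is the untruncated mean, and
#'   the defaults give truncated provider-weighted means of about 3 for
#'   surgeons and 6 for hospitals) or
#'   `list(family = "levels", levels, probs)` for discrete support.
#' @param surgeon_hospital_volume_corr Gaussian-copula correlation between a
#'   surgeon's volume and the volume of their primary hospital, in `[-1, 1]`.
#' @param quality_volume_corr correlation of latent provider quality with
#'   (standardized log) volume, in `[-1, 1]`.
#' @param quality_sd_decay nonnegative; residual quality dispersion shrinks as
#'   `exp(-decay * zlog(volume))`, so low-volume providers are more
#'   heterogeneous in quality when positive.
#' @param covariate_prevalences named probabilities for the binary patient
#'   covariates (sex and the nine comorbidity flags plus inpatient status).
#' @param eligibility_prevalences named probabilities for the two exclusion
#'   flags `metastatic` and `preop_chemo` (default 0: the generator emulates
#'   the post-eligibility operated cohort).
#' @param age_dist `list(family = "shifted_gamma", shift, shape, scale)`;
#'   the default reproduces a median age near 73 with all patients over 65.
#' @param travel_decay positive utility decay per driving hour in the
#'   discrete-choice provider-selection model.
#' @param quality_attraction baseline weight of latent quality in selection.
#' @param severity_selection_strength coefficient coupling the (centered)
#'   measured comorbidity count to the quality term of the choice model;
#'   negative values encode savvy healthier patients seeking better providers.
#' @param frailty_selection_strength,frailty_outcome_coef coupling of a latent
#'   standard-normal patient frailty to provider selection (via the quality
#'   term, with negative selection strength meaning frail patients are less
#'   selective) and to the mortality linear predictor.  Both default to 0.
#' @param volume_capacity_weight weight on `log(surgeon volume)` in choice
#'   utility; 1 makes selection probability proportional to caseload, which
#'   reproduces size-biased sampling of providers by patients.
#' @param outcome_coefs named numeric vector of logistic coefficients for
#'   90-day death: `intercept` (NA to calibrate against
#'   `target_baseline_risk`), `age` (per year, centered at 73), one per binary
#'   covariate, `surgeon_volume`, `hospital_volume` (per operation/year), and
#'   `surgeon_quality`, `hospital_quality` (per latent-quality SD).  Setting
#'   the volume and quality coefficients to 0 gives the null scenario.
#' @param target_baseline_risk marginal 90-day mortality used to calibrate the
#'   intercept when `outcome_coefs["intercept"]` is `NA`.
#' @param geometry plane geography: `list(n_locations, side, hours_per_unit,
#'   centrality)`; locations are points on a `side x side` plane, driving
#'   hours are Euclidean distance times `hours_per_unit`, and positive
#'   `centrality` concentrates high-volume hospitals near the plane's center.
#' @param multi_hospital_prob probability a surgeon holds a second affiliation.
#' @param quality_proxy_strength logit scale linking latent quality to the
#'   observed provider characteristics (cardiac ICU, teaching status, size,
#'   surgeon age/sex/multi-hospital); larger values make trial 4's measured
#'   provider covariates better proxies for quality.
#' @param remote optional positivity-violation block:
#'   `list(frac, hours, volumes, outcome_shift)`.  A fraction `frac` of
#'   patient locations is placed `hours` driving hours away from every
#'   provider; those patients can only use dedicated outlying providers whose
#'   volumes are drawn from `volumes`, and their mortality linear predictor is
#'   shifted by the unmeasured `outcome_shift`.
#' @param seed integer RNG seed.
#' @return An object of class `scm_params` (a validated named list).
#' @seealso [scm_scenario()] for the preset scenarios used throughout the
#'   package's bias demonstrations, [simulate_claims()] to draw data.
#' @examples
#' p <- scm_params(n_patients = 500, n_surgeons = 80, n_hospitals = 40)
#' p$covariate_prevalences[["diabetes"]]
#' @export
scm_params <- function(n_hospitals = 697L,
                       n_surgeons = 1358L,
                       n_patients = 9136L,
                       hospital_volume_dist = list(family = "ztnb", mu = 3.8, size = 0.45),
                       surgeon_volume_dist = list(family = "ztnb", mu = 1.58, size = 0.55),
                       surgeon_hospital_volume_corr = 0.6,
                       quality_volume_corr = 0.4,
                       quality_sd_decay = 0,
                       covariate_prevalences = c(
                         male = 0.51, acute_mi = 0.03, dementia = 0.05,
                         afib = 0.13, ckd = 0.27, copd = 0.21, chf = 0.19,
                         diabetes = 0.45, cad = 0.47, stroke_tia = 0.09,
                         inpatient = 0.06),
                       eligibility_prevalences = c(metastatic = 0, preop_chemo = 0),
                       age_dist = list(family = "shifted_gamma", shift = 65.2,
                                       shape = 1.6, scale = 6.3),
                       travel_decay = 2,
                       quality_attraction = 0.5,
                       severity_selection_strength = 0,
                       frailty_selection_strength = 0,
                       frailty_outcome_coef = 0,
                       volume_capacity_weight = 1,
                       outcome_coefs = c(
                         intercept = NA_real_, age = 0.05, male = 0.10,
                         acute_mi = 0.50, dementia = 0.50, afib = 0.30,
                         ckd = 0.40, copd = 0.30, chf = 0.60, diabetes = 0.20,
                         cad = 0.20, stroke_tia = 0.30, inpatient = 0.70,
                         surgeon_volume = -0.012, hospital_volume = -0.015,
                         surgeon_quality = -0.15, hospital_quality = -0.15),
                       target_baseline_risk = 0.075,
                       geometry = list(n_locations = 120L, side = 10,
                                       hours_per_unit = 0.35, centrality = 1),
                       multi_hospital_prob = 0.17,
                       quality_proxy_strength = 2,
                       remote = NULL,
                       seed = 1L) {
  p <- list(
    n_hospitals = .assert_count(n_hospitals, "n_hospitals"),
    n_surgeons = .assert_count(n_surgeons, "n_surgeons"),
    n_patients = .assert_count(n_patients, "n_patients"),
    hospital_volume_dist = hospital_volume_dist,
    surgeon_volume_dist = surgeon_volume_dist,
    surgeon_hospital_volume_corr = surgeon_hospital_volume_corr,
    quality_volume_corr = quality_volume_corr,
    quality_sd_decay = quality_sd_decay,
    covariate_prevalences = covariate_prevalences,
    eligibility_prevalences = eligibility_prevalences,
    age_dist = age_dist,
    travel_decay = travel_decay,
    quality_attraction = quality_attraction,
    severity_selection_strength = severity_selection_strength,
    frailty_selection_strength = frailty_selection_strength,
    frailty_outcome_coef = frailty_outcome_coef,
    volume_capacity_weight = volume_capacity_weight,
    outcome_coefs = outcome_coefs,
    target_baseline_risk = target_baseline_risk,
    geometry = geometry,
    multi_hospital_prob = multi_hospital_prob,
    quality_proxy_strength = quality_proxy_strength,
    remote = remote,
    seed = as.integer(seed)
  )
  class(p) <- "scm_params"
  validate_scm_params(p)
}

#' Validate structural-model parameters
#'
#' @param p an [scm_params()] object (or plain list with the same fields).
#' @return `p`, invisibly classed as `scm_params`, or an error describing the
#'   first violated invariant.
#' @export
validate_scm_params <- function(p) {
  .assert_scalar_prob(p$covariate_prevalences, "covariate_prevalences")
  .assert_scalar_prob(p$eligibility_prevalences, "eligibility_prevalences")
  if (abs(p$surgeon_hospital_volume_corr) > 1 || abs(p$quality_volume_corr) > 1) {
    stop("correlation parameters must lie in [-1, 1]", call. = FALSE)
  }
  if (!is.numeric(p$travel_decay) || p$travel_decay < 0) {
    stop("travel_decay must be a nonnegative rate (per hour)", call. = FALSE)
  }
  if (p$quality_sd_decay < 0) stop("quality_sd_decay must be >= 0", call. = FALSE)
  for (d in list(p$hospital_volume_dist, p$surgeon_volume_dist)) {
    if (!d$family %in% c("ztnb", "levels")) {
      stop("volume distribution family must be 'ztnb' or 'levels'", call. = FALSE)
    }
    if (d$family == "ztnb" && (d$mu <= 0 || d$size <= 0)) {
      stop("ztnb volume distribution needs mu > 0 and size > 0", call. = FALSE)
    }
    if (d$family == "levels" && any(d$levels < 1)) {
      stop("volume levels must be >= 1", call. = FALSE)
    }
  }
  need <- c("intercept", "age", names(p$covariate_prevalences),
            "surgeon_volume", "hospital_volume",
            "surgeon_quality", "hospital_quality")
  missing <- setdiff(need, names(p$outcome_coefs))
  if (length(missing)) {
    stop("outcome_coefs is missing terms: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(p$remote)) {
    .assert_scalar_prob(p$remote$frac, "remote$frac")
    if (p$remote$hours <= 0 || any(p$remote$volumes < 1)) {
      stop("remote block needs hours > 0 and volumes >= 1", call. = FALSE)
    }
  }
  if (p$n_surgeons < p$n_hospitals) {
    warning("n_surgeons < n_hospitals: unusual provider geometry",
            call. = FALSE)
  }
  class(p) <- "scm_params"
  invisible(p)
}

#' Is this the null scenario?
#'
#' The null scenario sets the surgeon-volume, hospital-volume and both
#' latent-quality outcome coefficients to zero, so no intervention on volume
#' can move the true risk and every downstream risk difference is truly 0.
#'
#' @param p an [scm_params()] object.
#' @return Logical scalar.
#' @export
is_null_scenario <- function(p) {
  all(p$outcome_coefs[c("surgeon_volume", "hospital_volume",
                        "surgeon_quality", "hospital_quality")] == 0) &&
    p$frailty_outcome_coef == 0 && is.null(p$remote)
}

#' Preset structural scenarios for the bias demonstrations
#'
#' Each scenario is a complete [scm_params()] configuration expressing one of
#' the causal structures the four trial designs react to differently:
#'
#' \describe{
#'   \item{`baseline`}{the package defaults: modest true surgeon- and
#'     hospital-volume effects plus quality effects, calibrated to the
#'     published cohort's marginals and a ~7.5% mortality baseline.}
#'   \item{`null`}{no causal path from volume or quality to death; every
#'     design should estimate risk differences centered on 0.}
#'   \item{`hospital_confounding`}{hospital volume has a direct protective
#'     effect and surgeon volume is strongly correlated with hospital volume
#'     but has no effect of its own.  A surgeon-volume-only analysis (trial 1)
#'     absorbs the hospital effect; the joint analysis (trial 2) does not.}
#'   \item{`travel_confounding`}{a remote stratum of patients lies beyond any
#'     driving-time threshold, carries unmeasured excess risk, and can only
#'     reach dedicated low-volume outlying providers (a positivity violation).
#'     Trial 2's everyone-to-every-volume estimand is biased; trial 3's
#'     thresholded estimand, which leaves remote patients at their natural
#'     value of treatment, is not.}
#'   \item{`savvy_patient`}{latent provider quality affects mortality, is
#'     only partially determined by volume (low-volume providers are very
#'     heterogeneous), and healthier patients - in both measured and
#'     unmeasured ways - select higher-quality providers.  Trial 3 conflates
#'     quality with volume; trial 4's adjustment for and standardization over
#'     measured provider characteristics removes the explained part.}
#' }
#'
#' @param name one of `"baseline"`, `"null"`, `"hospital_confounding"`,
#'   `"travel_confounding"`, `"savvy_patient"`.
#' @param ... overrides passed to [scm_params()] on top of the preset.
#' @return An [scm_params()] object.
#' @examples
#' is_null_scenario(scm_scenario("null"))
#' @export
scm_scenario <- function(name = c("baseline", "null", "hospital_confounding",
                                  "travel_confounding", "savvy_patient"),
                         ...) {
  name <- match.arg(name)
  base <- list()
  zero_fx <- c(surgeon_volume = 0, hospital_volume = 0,
               surgeon_quality = 0, hospital_quality = 0)
  oc <- function(...) {
    d <- formals(scm_params)$outcome_coefs
    out <- eval(d)
    repl <- c(...)
    out[names(repl)] <- repl
    out
  }
  presets <- switch(name,
    baseline = list(),
    null = list(
      outcome_coefs = oc(zero_fx),
      surgeon_volume_dist = list(
        family = "levels", levels = c(1, 2, 3, 5, 8, 12, 18, 25),
        probs = c(0.20, 0.17, 0.15, 0.13, 0.11, 0.10, 0.08, 0.06)),
      hospital_volume_dist = list(
        family = "levels", levels = c(2, 5, 12, 20, 30, 43),
        probs = c(0.25, 0.20, 0.20, 0.15, 0.12, 0.08)),
      quality_volume_corr = 0.4),
    hospital_confounding = list(
      outcome_coefs = oc(c(surgeon_volume = 0, hospital_volume = -0.025,
                           surgeon_quality = 0, hospital_quality = 0)),
      hospital_volume_dist = list(family = "ztnb", mu = 8, size = 1.2),
      surgeon_hospital_volume_corr = 0.7,
      quality_volume_corr = 0,
      quality_attraction = 0,
      severity_selection_strength = 0
    ),
    travel_confounding = list(
      outcome_coefs = oc(c(surgeon_volume = -0.020, hospital_volume = 0,
                           surgeon_quality = 0, hospital_quality = 0)),
      surgeon_volume_dist = list(family = "levels",
                                 levels = c(2, 5, 12, 18, 25)),
      hospital_volume_dist = list(family = "ztnb", mu = 8, size = 1),
      surgeon_hospital_volume_corr = 0,
      quality_volume_corr = 0,
      quality_attraction = 0,
      travel_decay = 4,
      volume_capacity_weight = 0,
      remote = list(frac = 0.25, hours = 2.2, volumes = c(1, 3),
                    outcome_shift = 1.5)
    ),
    savvy_patient = list(
      outcome_coefs = oc(c(surgeon_volume = 0, hospital_volume = 0,
                           surgeon_quality = -0.45, hospital_quality = -0.45)),
      surgeon_volume_dist = list(
        family = "levels", levels = c(1, 2, 3, 5, 8, 12, 18, 25),
        probs = c(0.20, 0.17, 0.15, 0.13, 0.11, 0.10, 0.08, 0.06)),
      hospital_volume_dist = list(
        family = "levels", levels = c(2, 5, 12, 20, 30, 43),
        probs = c(0.25, 0.20, 0.20, 0.15, 0.12, 0.08)),
      quality_volume_corr = 0.45,
      quality_sd_decay = 0.6,
      quality_attraction = 0.8,
      severity_selection_strength = -0.25,
      frailty_selection_strength = -0.6,
      frailty_outcome_coef = 0.5,
      quality_proxy_strength = 3
    )
  )
  do.call(scm_params, modifyList(presets, list(...)))
}

#' @export
print.scm_params <- function(x, ...) {
  cat("<scm_params>", if (is_null_scenario(x)) "(null scenario)" else "", "\n")
  cat(sprintf("  providers: %d hospitals, %d surgeons; patients: %d\n",
              x$n_hospitals, x$n_surgeons, x$n_patients))
  cat(sprintf("  surgeon volume: %s; hospital volume: %s\n",
              .dist_label(x$surgeon_volume_dist),
              .dist_label(x$hospital_volume_dist)))
  cat(sprintf("  corr(surgeon, hospital volume) = %.2f; corr(quality, volume) = %.2f\n",
              x$surgeon_hospital_volume_corr, x$quality_volume_corr))
  cat(sprintf("  selection: travel decay %.2f/h, quality weight %.2f, severity %.2f\n",
              x$travel_decay, x$quality_attraction,
              x$severity_selection_strength))
  if (!is.null(x$remote)) {
    cat(sprintf("  remote stratum: %.0f%% of locations at %.1f h, volumes {%s}\n",
                100 * x$remote$frac, x$remote$hours,
                paste(x$remote$volumes, collapse = ",")))
  }
  invisible(x)
}

#' @keywords internal
.dist_label <- function(d) {
  if (d$family == "ztnb") sprintf("ZTNB(mu=%.3g, size=%.3g)", d$mu, d$size)
  else sprintf("levels {%s}", paste(d$levels, collapse = ","))
}
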