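#' Intervention arm specification for the counterfactual oracle
#'
#' @param surgeon_volume surgeon annual volume to intervene on.
#' @param hospital_volume hospital annual volume, or `NULL` to leave hospital
#'   volume at its natural (observed) value, as in trial 1.
#' @param threshold_hours optional driving-time threshold: patients farther
#'   than this from every surgeon keep the natural value of treatment (their
#'   observed surgeon and hospital), as in trials 3 and 4.
#' @return A list of class `volemu_arm`.
#' @export
arm_spec <- function(surgeon_volume, hospital_volume = NULL,
                     threshold_hours = NULL) {
  stopifnot(is.numeric(surgeon_volume), length(surgeon_volume) == 1L)
  structure(list(surgeon_volume = surgeon_volume,
                 hospital_volume = hospital_volume,
                 threshold_hours = threshold_hours),
            class = "volemu_arm")
}

## Conditional latent-quality distribution given an intervened volume:
## N(rho * zlog(v), (1 - rho^2) * sigma(v)^2) with sigma(v) the residual
## heterogeneity of the generator.
#' @keywords internal
.quality_given_volume <- function(v, rho, decay, mlog, sdlog, n_mc) {
  z <- .zlog(v, mlog, sdlog)
  rho * z + sqrt(1 - rho^2) * exp(-decay * z) * rnorm(n_mc)
}

## Recover the log-volume standardization for the quality model: from the
## claims bundle when available, otherwise approximated from the configured
## volume distributions (internal fixed substream so results are stable).
#' @keywords internal
.quality_transform <- function(params, population) {
  qt <- attr(population, "quality_transform")
  if (!is.null(qt)) return(qt)
  set.seed(sub_seed(params$seed, "quality-transform"))
  vs <- .r_volume(20000L, params$surgeon_volume_dist)
  vh <- .r_volume(20000L, params$hospital_volume_dist)
  list(mlog_s = mean(log(vs)), sdlog_s = max(sd(log(vs)), 1e-8),
       mlog_h = mean(log(vh)), sdlog_h = max(sd(log(vh)), 1e-8))
}

#' True counterfactual 90-day mortality risk under a volume intervention
#'
#' Computes, from the structural model itself, the Monte-Carlo mean of the
#' outcome model's death probability with volume inputs set to the arm's
#' values: each patient keeps their own covariates (and latent frailty), the
#' intervened volumes replace the observed ones, and the latent provider
#' qualities are marginalized over the provider-quality distribution implied
#' by the arm's volume (the generator's conditional quality-given-volume
#' law).  For thresholded arms, patients beyond the driving-time threshold of
#' every surgeon keep their natural value of treatment: observed volumes and
#' observed provider qualities.  This is the estimand each emulation is
#' judged against.
#'
#' @param params the [scm_params()] that generated the population.
#' @param arm an [arm_spec()].
#' @param population a `volemu_claims` bundle (required for thresholded arms)
#'   or a patient data frame.  Patient frames either carry the oracle
#'   attribute written by [generate_patients()], or plain covariate columns
#'   (then `params$outcome_coefs["intercept"]` must be set and the linear
#'   predictor is rebuilt from the columns).
#' @param n_mc number of Monte-Carlo draws for the quality marginalization
#'   (exact, no draws, when both quality coefficients are zero).
#' @param seed RNG seed for the Monte-Carlo draws.
#' @return A single risk in `[0, 1]`.
#' @examples
#' cl <- simulate_claims(scm_scenario("null", n_hospitals = 20,
#'                                    n_surgeons = 40, n_patients = 300))
#' true_counterfactual_risk(cl$params, arm_spec(25, 43), cl)
#' @export
true_counterfactual_risk <- function(params, arm, population, n_mc = 1000L,
                                     seed = 1L) {
  n_mc <- .assert_count(n_mc, "n_mc")
  stopifnot(inherits(arm, "volemu_arm"))
  oc <- params$outcome_coefs

  claims <- NULL
  if (inherits(population, "volemu_claims")) {
    claims <- population
    patients <- claims$patients
    qt <- attr(claims, "quality_transform")
  } else {
    patients <- population
    qt <- NULL
  }
  orc <- attr(patients, "oracle")
  if (is.null(orc)) {
    if (is.na(oc[["intercept"]])) {
      stop("population lacks an oracle attribute; supply explicit ",
           "outcome_coefs['intercept'] to rebuild linear predictors",
           call. = FALSE)
    }
    prev_names <- names(params$covariate_prevalences)
    flags <- as.matrix(patients[, prev_names, drop = FALSE])
    age <- if ("age" %in% names(patients)) patients$age else 73
    orc <- data.frame(
      lp_base = oc[["intercept"]] + oc[["age"]] * (age - 73) +
        drop(flags %*% oc[prev_names]),
      surgeon_volume_obs = patients$surgeon_volume %||% NA_real_,
      hospital_volume_obs = patients$hospital_volume %||% NA_real_,
      surgeon_quality_obs = 0, hospital_quality_obs = 0
    )
  }
  if (is.null(qt)) qt <- .quality_transform(params, population)

  beyond <- rep(FALSE, nrow(orc))
  if (!is.null(arm$threshold_hours)) {
    if (is.null(claims)) {
      stop("thresholded arms need a volemu_claims population ",
           "(travel geography required)", call. = FALSE)
    }
    beyond <- beyond_threshold(claims$patients, claims, arm$threshold_hours)
  }

  b_qs <- oc[["surgeon_quality"]]
  b_qh <- oc[["hospital_quality"]]
  lp_nat <- orc$lp_base +
    oc[["surgeon_volume"]] * orc$surgeon_volume_obs +
    oc[["hospital_volume"]] * orc$hospital_volume_obs +
    b_qs * orc$surgeon_quality_obs + b_qh * orc$hospital_quality_obs

  ## intervened linear predictor (quality terms handled below)
  h_nat <- is.null(arm$hospital_volume)
  lp_int <- orc$lp_base + oc[["surgeon_volume"]] * arm$surgeon_volume +
    if (h_nat) {
      oc[["hospital_volume"]] * orc$hospital_volume_obs +
        b_qh * orc$hospital_quality_obs
    } else {
      oc[["hospital_volume"]] * arm$hospital_volume
    }

  set.seed(sub_seed(seed, "oracle-mc"))
  need_mc <- (b_qs != 0) || (!h_nat && b_qh != 0)
  if (!need_mc) {
    p_int <- plogis(lp_int)
  } else {
    qs <- if (b_qs != 0) {
      .quality_given_volume(arm$surgeon_volume, params$quality_volume_corr,
                            params$quality_sd_decay, qt$mlog_s, qt$sdlog_s,
                            n_mc)
    } else rep(0, n_mc)
    qh <- if (!h_nat && b_qh != 0) {
      .quality_given_volume(arm$hospital_volume, params$quality_volume_corr,
                            params$quality_sd_decay, qt$mlog_h, qt$sdlog_h,
                            n_mc)
    } else rep(0, n_mc)
    shift <- b_qs * qs + b_qh * qh
    p_int <- rowMeans(plogis(outer(lp_int, shift, "+")))
  }
  mean(ifelse(beyond, plogis(lp_nat), p_int))
}
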