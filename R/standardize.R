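## Model-matrix column indices belonging to provider-covariate terms.
#' @keywords internal
.provider_cols <- function(fit, spec) {
  lab <- fit$term_labels[fit$assign]        # assign 0 = intercept
  lab[fit$assign == 0] <- "(Intercept)"
  which(lab %in% spec$provider_covariates)
}

#' Standardized (g-formula) risk under one intervention arm
#'
#' Plug-in standardization to the overall population: the mean over patients
#' of the model's predicted death probability with the treatment set to the
#' arm's volumes and each patient's own covariates retained.  Two
#' modifications implement the later trials' designs: (trials 3-4) patients
#' beyond the driving-time threshold keep their observed treatment (the
#' natural value) in the prediction; (trial 4) the provider characteristics
#' entering the prediction are averaged over the empirical distribution of
#' providers whose volume lies in the arm's nearest-match neighborhood
#' (within +/-1 operation/year, widened until nonempty), emulating the second
#' randomization to a particular surgeon and hospital among available ones.
#'
#' @param fit a [fit_outcome_model()] object.
#' @param cohort the cohort the model was fit on (from [build_cohort()]).
#' @param arm an [arm_spec()] or list with `surgeon_volume` and (trials 2-4)
#'   `hospital_volume`; volumes must lie on the spec's grids.
#' @param spec the [emulation_spec()].
#' @param providers for trial 4, the provider tables (a `volemu_claims`
#'   bundle or list with `surgeons` and `hospitals`).
#' @return A single standardized risk in `[0, 1]` (`NA` if the arm is
#'   inestimable under an indicator parameterization).
#' @export
standardize_risk <- function(fit, cohort, arm, spec, providers = NULL) {
  s <- arm$surgeon_volume
  if (!s %in% spec$surgeon_volume_grid) {
    stop(sprintf("surgeon volume %s is off the trial grid", format(s)),
         call. = FALSE)
  }
  h <- arm$hospital_volume
  if (spec$trial >= 2) {
    if (is.null(h)) stop("trials 2-4 require a hospital_volume in the arm",
                         call. = FALSE)
    if (!h %in% spec$hospital_volume_grid) {
      stop(sprintf("hospital volume %s is off the trial grid", format(h)),
           call. = FALSE)
    }
  }
  nd <- cohort
  set <- !(cohort$beyond_threshold %||% rep(FALSE, nrow(cohort)))
  nd$surgeon_volume[set] <- s
  nd$surgeon_volume_arm[set] <- s
  if (spec$trial >= 2) {
    nd$hospital_volume[set] <- h
    nd$hospital_volume_arm[set] <- h
  }
  if (spec$trial == 4) {
    if (is.null(providers)) {
      stop("trial 4 standardization needs the provider tables", call. = FALSE)
    }
    return(.standardize_trial4(fit, nd, set, s, h, spec, providers))
  }
  mean(predict_risk(fit, nd))
}

## Trial 4: double standardization.  Predictions are additive in the provider
## covariate terms, so the average over the neighborhood's empirical provider
## distribution factorizes into patient-level offsets plus surgeon- and
## hospital-level contributions, each compressed to <= 16 quantile points.
#' @keywords internal
.standardize_trial4 <- function(fit, nd, set, s, h, spec, providers) {
  cf0 <- ifelse(is.na(fit$coef), 0, fit$coef)
  X <- .fit_mm(fit, nd)
  lp_full <- drop(X %*% cf0)
  pcols <- .provider_cols(fit, spec)
  s_vars <- grep("^s_", spec$provider_covariates, value = TRUE)
  h_vars <- grep("^h_", spec$provider_covariates, value = TRUE)
  lab <- fit$term_labels[fit$assign]
  lab[fit$assign == 0] <- "(Intercept)"
  s_cols <- which(lab %in% s_vars)
  h_cols <- which(lab %in% h_vars)

  neighborhood <- function(tab, target, what) {
    for (w in c(1, 2, 4, 8, 16, 32, Inf)) {
      hit <- abs(tab$annual_volume - target) <= w
      if (any(hit)) {
        if (!any(abs(tab$annual_volume - target) <= 1) && w > 8) {
          warning(sprintf("trial 4: %s-volume neighborhood around %s widened to +/-%s; consider a coarser grid",
                          what, format(target), format(w)), call. = FALSE)
        }
        return(tab[hit, , drop = FALSE])
      }
    }
    stop(sprintf("no %s provider near volume %s; coarsen the grid", what,
                 format(target)), call. = FALSE)
  }
  contrib <- function(tab, cols) {
    if (length(cols) == 0L || nrow(tab) == 0L) return(0)
    ## drop providers whose factor levels never occurred in the fitted data
    for (v in intersect(names(tab), names(fit$xlevels))) {
      tab <- tab[tab[[v]] %in% fit$xlevels[[v]], , drop = FALSE]
    }
    if (nrow(tab) == 0L) return(0)
    proto <- nd[rep(1L, nrow(tab)), , drop = FALSE]
    for (v in intersect(names(tab), names(proto))) proto[[v]] <- tab[[v]]
    Xp <- .fit_mm(fit, proto)
    drop(Xp[, cols, drop = FALSE] %*% cf0[cols])
  }
  sg <- .surgeon_covs(neighborhood(providers$surgeons, s, "surgeon"))
  hg <- .hospital_covs(neighborhood(providers$hospitals, h, "hospital"))
  b_s <- .compress_quantiles(contrib(sg, s_cols))
  b_h <- .compress_quantiles(contrib(hg, h_cols))

  own_prov <- drop(X[, pcols, drop = FALSE] %*% cf0[pcols])
  a <- lp_full - own_prov
  shifts <- as.vector(outer(b_s, b_h, "+"))
  p <- numeric(nrow(nd))
  p[set] <- rowMeans(plogis(outer(a[set], shifts, "+")))
  p[!set] <- plogis(lp_full[!set])
  if (anyNA(fit$coef)) {
    used <- X[, is.na(fit$coef), drop = FALSE] != 0
    p[rowSums(used) > 0] <- NA_real_
  }
  mean(p)
}

#' Risk differences against the reference arms
#'
#' Adds, within each hospital-volume stratum, the risk difference against the
#' lowest-volume (reference) surgeon arm; the reference row's difference is
#' exactly zero.  Hospital-volume contrasts within surgeon strata
#' (median vs low, high vs low, high vs median) are attached as attribute
#' `hospital_contrasts`.
#'
#' @param risks data frame with columns `surgeon_volume_arm`,
#'   `hospital_volume_arm` (NA for trial 1) and `risk`.
#' @param spec the [emulation_spec()].
#' @return `risks` with columns `risk_difference` and `is_reference`, of
#'   class `volemu_risk_grid`.
#' @export
risk_difference_table <- function(risks, spec) {
  ref_s <- spec$reference_surgeon_volume
  key <- ifelse(is.na(risks$hospital_volume_arm), "natural",
                as.character(risks$hospital_volume_arm))
  ref_risk <- setNames(rep(NA_real_, length(unique(key))), unique(key))
  for (k in unique(key)) {
    i <- which(key == k & risks$surgeon_volume_arm == ref_s)
    if (length(i) == 0L) {
      stop(sprintf("missing reference arm (surgeon volume %s) in hospital stratum %s",
                   format(ref_s), k), call. = FALSE)
    }
    ref_risk[k] <- risks$risk[i[1]]
  }
  risks$risk_difference <- risks$risk - ref_risk[key]
  risks$is_reference <- risks$surgeon_volume_arm == ref_s
  risks$risk_difference[risks$is_reference] <- 0

  hc <- NULL
  if (spec$trial >= 2 && length(spec$reference_hospital_volumes) >= 3) {
    hv <- sort(spec$reference_hospital_volumes)
    pairs <- list(median_vs_low = c(hv[2], hv[1]),
                  high_vs_low = c(hv[3], hv[1]),
                  high_vs_median = c(hv[3], hv[2]))
    hc <- do.call(rbind, lapply(unique(risks$surgeon_volume_arm), function(sv) {
      do.call(rbind, lapply(names(pairs), function(nm) {
        a <- risks$risk[risks$surgeon_volume_arm == sv &
                          risks$hospital_volume_arm == pairs[[nm]][1]]
        b <- risks$risk[risks$surgeon_volume_arm == sv &
                          risks$hospital_volume_arm == pairs[[nm]][2]]
        if (!length(a) || !length(b)) return(NULL)
        data.frame(surgeon_volume_arm = sv, contrast = nm,
                   risk_difference = a - b)
      }))
    }))
  }
  attr(risks, "hospital_contrasts") <- hc
  class(risks) <- c("volemu_risk_grid", "data.frame")
  risks
}

#' Emulate one target trial end to end
#'
#' Composes eligibility, arm assignment, outcome-model fitting and
#' standardization over the reporting grid (surgeon volumes 2/5/18/25 by
#' hospital strata 2/12/43 for trials 2-4; the surgeon grid alone, hospital at
#' its natural value, for trial 1), then tabulates risk differences against
#' the reference arms.  Confidence intervals are added separately by
#' [cluster_bootstrap()].
#'
#' @param claims a `volemu_claims` bundle.
#' @param spec an [emulation_spec()].
#' @param grid `"report"` (default), `"figure"` (surgeon volumes from the 5th
#'   to the 95th percentile of observed surgeon volume, by hospital strata),
#'   or a data frame with columns `surgeon_volume_arm`, `hospital_volume_arm`.
#' @return A `volemu_risk_grid` data frame (trial, arms, standardized risks,
#'   risk differences) carrying the fitted model, cohort, eligibility tally
#'   and a refit payload for the cluster bootstrap as attributes.
#' @examples
#' cl <- simulate_claims(scm_params(n_hospitals = 30, n_surgeons = 60,
#'                                  n_patients = 1500))
#' emulate_trial(cl, emulation_spec(1))
#' @export
emulate_trial <- function(claims, spec, grid = "report") {
  cohort <- build_cohort(claims, spec)
  fit <- tryCatch(fit_outcome_model(cohort, spec),
                  error = function(e) stop("outcome-model stage: ",
                                           conditionMessage(e), call. = FALSE))
  arms <- .arm_grid(claims, spec, grid, cohort)
  risks <- vapply(seq_len(nrow(arms)), function(i) {
    tryCatch(standardize_risk(
      fit, cohort,
      list(surgeon_volume = arms$surgeon_volume_arm[i],
           hospital_volume = if (spec$trial >= 2) arms$hospital_volume_arm[i]),
      spec, providers = claims),
      error = function(e) stop("standardization stage: ",
                               conditionMessage(e), call. = FALSE))
  }, numeric(1))
  out <- data.frame(trial = spec$trial, arms, risk = risks)
  out <- risk_difference_table(out, spec)
  attr(out, "fit") <- fit
  attr(out, "spec") <- spec
  attr(out, "cohort") <- cohort
  attr(out, "exclusions") <- attr(cohort, "exclusions")
  attr(out, "payload") <- .bootstrap_payload(fit, cohort, spec, out, claims)
  out
}

#' @keywords internal
.arm_grid <- function(claims, spec, grid, cohort) {
  if (is.data.frame(grid)) return(grid)
  sv <- switch(grid,
    report = spec$report_surgeon_volumes,
    figure = {
      q <- quantile(cohort$surgeon_volume, c(0.05, 0.95), type = 1)
      vals <- spec$surgeon_volume_grid
      vals[vals >= q[1] & vals <= q[2]]
    },
    stop("grid must be 'report', 'figure' or a data frame", call. = FALSE))
  if (spec$trial == 1) {
    data.frame(surgeon_volume_arm = sv, hospital_volume_arm = NA_real_)
  } else {
    expand.grid(surgeon_volume_arm = sv,
                hospital_volume_arm = spec$reference_hospital_volumes,
                KEEP.OUT.ATTRS = FALSE)
  }
}

## Precompute everything an index-level cluster-bootstrap refit needs: the
## design matrix, outcome, cluster keys and per-arm prediction matrices
## (natural-value rows already substituted).  Trial 4's provider
## standardization depends on the resampled provider tables, so it opts out
## and the bootstrap re-runs the full estimator instead.
#' @keywords internal
.bootstrap_payload <- function(fit, cohort, spec, grid_df, claims) {
  if (spec$trial == 4) return(NULL)
  X <- .fit_mm(fit, cohort)
  arm_X <- lapply(seq_len(nrow(grid_df)), function(i) {
    nd <- cohort
    set <- !(cohort$beyond_threshold %||% rep(FALSE, nrow(cohort)))
    s <- grid_df$surgeon_volume_arm[i]
    nd$surgeon_volume[set] <- s
    nd$surgeon_volume_arm[set] <- s
    if (spec$trial >= 2) {
      h <- grid_df$hospital_volume_arm[i]
      nd$hospital_volume[set] <- h
      nd$hospital_volume_arm[set] <- h
    }
    .fit_mm(fit, nd)
  })
  list(X = X, y = cohort$death_90d,
       hospital = cohort$hospital_id, surgeon = cohort$surgeon_id,
       arm_X = arm_X, ridge = spec$model$ridge %||% 0)
}

#' @export
print.volemu_risk_grid <- function(x, digits = 3, ...) {
  cat(sprintf("<volemu_risk_grid> trial %d, %d arms\n", x$trial[1], nrow(x)))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
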