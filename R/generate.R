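#' Travel-time structure over a plane geography
#'
#' Locations are points on a plane; driving hours between two locations are
#' Euclidean distance times a configurable hours-per-unit factor.  The object
#' is symmetric by construction and zero only for co-located points.
#'
#' @param locations data frame with columns `location_id`, `x`, `y` (and
#'   optionally a logical `remote` flag).
#' @param hours_per_unit positive scalar converting plane distance to hours.
#' @return An object of class `volemu_travel`.
#' @export
make_travel <- function(locations, hours_per_unit) {
  stopifnot(all(c("location_id", "x", "y") %in% names(locations)),
            is.numeric(hours_per_unit), hours_per_unit > 0)
  if (anyDuplicated(locations$location_id)) {
    stop("duplicate location_id in travel geography", call. = FALSE)
  }
  structure(list(locations = locations, hours_per_unit = hours_per_unit),
            class = "volemu_travel")
}

#' Driving hours between location sets
#'
#' @param travel a [make_travel()] object.
#' @param from,to vectors of location ids.
#' @return `travel_hours()` returns the elementwise vector of driving hours
#'   (recycling the shorter argument); `travel_matrix()` the full
#'   `length(from) x length(to)` matrix.
#' @export
travel_hours <- function(travel, from, to) {
  H <- travel_matrix(travel, unique(from), unique(to))
  H[cbind(match(from, rownames(H)), match(to, colnames(H)))]
}

#' @rdname travel_hours
#' @export
travel_matrix <- function(travel, from, to) {
  loc <- travel$locations
  i <- match(from, loc$location_id)
  j <- match(to, loc$location_id)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(from[is.na(i)], to[is.na(j)]))
    stop("travel geography is missing location(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  dx <- outer(loc$x[i], loc$x[j], "-")
  dy <- outer(loc$y[i], loc$y[j], "-")
  H <- sqrt(dx^2 + dy^2) * travel$hours_per_unit
  dimnames(H) <- list(from, to)
  H
}

#' @export
print.volemu_travel <- function(x, ...) {
  cat(sprintf("<volemu_travel> %d locations (%d remote), %.2f h/unit\n",
              nrow(x$locations), sum(x$locations$remote %||% FALSE),
              x$hours_per_unit))
  invisible(x)
}

## Build the plane geography implied by the params: metro locations uniform on
## the square, plus (optionally) paired remote patient / outlying provider
## locations on rings far enough out that no remote patient is within the
## remote block's driving time of any other provider.
#' @keywords internal
.make_geography <- function(params) {
  g <- params$geometry
  n_met <- g$n_locations
  cx <- g$side / 2
  met <- data.frame(
    location_id = sprintf("L%04d", seq_len(n_met)),
    x = runif(n_met, 0, g$side), y = runif(n_met, 0, g$side),
    remote = FALSE, outlying_provider = FALSE,
    stringsAsFactors = FALSE
  )
  if (is.null(params$remote)) return(met)
  rm <- params$remote
  k <- max(1L, round(rm$frac * n_met / (1 - rm$frac)))
  theta <- seq(0, 2 * pi, length.out = k + 1L)[-1L]
  ## outlying providers sit two reach-radii past the plane's corner so that
  ## metro providers are far costlier than the local one for remote patients
  r_reach <- rm$hours / params$geometry$hours_per_unit
  r_prov <- sqrt(2) * g$side / 2 + 2 * r_reach
  r_pat <- r_prov + r_reach
  prov <- data.frame(
    location_id = sprintf("LO%03d", seq_len(k)),
    x = cx + r_prov * cos(theta), y = cx + r_prov * sin(theta),
    remote = FALSE, outlying_provider = TRUE, stringsAsFactors = FALSE
  )
  pat <- data.frame(
    location_id = sprintf("LR%03d", seq_len(k)),
    x = cx + r_pat * cos(theta), y = cx + r_pat * sin(theta),
    remote = TRUE, outlying_provider = FALSE, stringsAsFactors = FALSE
  )
  rbind(met, prov, pat)
}

#' Generate the surgeon and hospital tables of the structural model
#'
#' Draws hospitals with right-skewed annual volumes (placed more centrally
#' when the geometry's `centrality` is positive), surgeons with volumes
#' coupled to their primary hospital's volume through a Gaussian copula at
#' `surgeon_hospital_volume_corr`, latent provider qualities correlated with
#' standardized log-volume at `quality_volume_corr`, and observed provider
#' characteristics (surgeon age/sex/multi-hospital practice; hospital cardiac
#' ICU, ownership, teaching category, size) whose distributions match the
#' published provider tables and which act as proxies for latent quality at
#' strength `quality_proxy_strength`.
#'
#' Latent qualities are carried in the returned tables for oracle use only;
#' [write_claims()] strips them from every analysis-facing file.
#'
#' @param params an [scm_params()] object.
#' @return A list of class `volemu_providers` with elements `surgeons`,
#'   `hospitals`, `travel` (a [make_travel()] geography) and an attribute
#'   `quality_transform` holding the log-volume standardization used by the
#'   quality model.
#' @examples
#' pr <- generate_providers(scm_params(n_hospitals = 30, n_surgeons = 60,
#'                                     n_patients = 100))
#' nrow(pr$hospitals)
#' @export
generate_providers <- function(params) {
  params <- validate_scm_params(params)
  set.seed(sub_seed(params$seed, "providers"))
  geo <- .make_geography(params)
  travel <- make_travel(geo, params$geometry$hours_per_unit)

  ## ---- hospitals -----------------------------------------------------------
  n_h <- params$n_hospitals
  v_h <- .r_volume(n_h, params$hospital_volume_dist)
  met_loc <- geo[!geo$remote & !geo$outlying_provider, ]
  cx <- params$geometry$side / 2
  zc <- -sqrt((met_loc$x - cx)^2 + (met_loc$y - cx)^2)
  zc <- (zc - mean(zc)) / max(sd(zc), 1e-8)
  zv <- qnorm(rank(v_h, ties.method = "random") / (n_h + 1))
  loc_idx <- vapply(seq_len(n_h), function(i) {
    w <- exp(params$geometry$centrality * zv[i] * zc)
    sample.int(nrow(met_loc), 1L, prob = w)
  }, integer(1))
  hospitals <- data.frame(
    hospital_id = sprintf("H%04d", seq_len(n_h)),
    annual_volume = as.integer(v_h),
    location_id = met_loc$location_id[loc_idx],
    outlying = FALSE,
    stringsAsFactors = FALSE
  )

  ## outlying hospitals serving the remote stratum, one per outlying location
  if (!is.null(params$remote)) {
    out_loc <- geo[geo$outlying_provider, ]
    k <- nrow(out_loc)
    hospitals <- rbind(hospitals, data.frame(
      hospital_id = sprintf("H%04d", n_h + seq_len(k)),
      annual_volume = as.integer(sample(params$remote$volumes, k, replace = TRUE)),
      location_id = out_loc$location_id,
      outlying = TRUE, stringsAsFactors = FALSE
    ))
  }
  n_h_all <- nrow(hospitals)

  ## latent hospital quality: rho * zlog(volume) + residual
  mlog_h <- mean(log(hospitals$annual_volume))
  sdlog_h <- sd(log(hospitals$annual_volume))
  if (!is.finite(sdlog_h) || sdlog_h < 1e-8) sdlog_h <- 1
  zlog_h <- .zlog(hospitals$annual_volume, mlog_h, sdlog_h)
  rho_q <- params$quality_volume_corr
  sig_h <- exp(-params$quality_sd_decay * zlog_h)
  hospitals$latent_quality <-
    rho_q * zlog_h + sqrt(1 - rho_q^2) * sig_h * rnorm(n_h_all)

  ## observed hospital characteristics, proxying quality at configured strength
  k_q <- params$quality_proxy_strength
  q_h <- hospitals$latent_quality
  hospitals$cardiac_icu <- rbinom(n_h_all, 1, plogis(qlogis(0.72) + k_q * q_h))
  own_p <- c(for_profit = 0.13, nonprofit = 0.76, government_nonfederal = 0.11)
  hospitals$ownership <- sample(names(own_p), n_h_all, TRUE, prob = own_p)
  grade3 <- function(lat, probs, labels) {
    br <- unique(c(-Inf, quantile(lat, probs), Inf))
    if (length(br) < 4) return(rep(labels[2], length(lat)))
    as.character(cut(lat, br, labels = labels[seq_len(length(br) - 1L)]))
  }
  hospitals$teaching <- grade3(k_q * q_h + rnorm(n_h_all) * pi / sqrt(3),
                               c(0.30, 0.70),
                               c("nonteaching", "minor", "major"))
  hospitals$size <- grade3(k_q * q_h + rnorm(n_h_all) * pi / sqrt(3),
                           c(0.02, 0.51), c("small", "medium", "large"))

  ## ---- surgeons ------------------------------------------------------------
  n_s <- params$n_surgeons
  if (n_s < n_h_all) {
    warning("fewer surgeons than hospitals; some hospitals get no surgeon",
            call. = FALSE)
    primary_idx <- sample.int(n_h_all, n_s,
                              prob = hospitals$annual_volume, replace = TRUE)
  } else {
    ## every hospital staffed, remaining surgeons allocated by caseload
    extra <- sample.int(n_h_all, n_s - n_h_all,
                        prob = hospitals$annual_volume, replace = TRUE)
    primary_idx <- c(seq_len(n_h_all), extra)
  }
  prim <- hospitals[primary_idx, ]
  u_h <- pnorm(qnorm(rank(prim$annual_volume, ties.method = "random") / (n_s + 1)))
  rho_sh <- params$surgeon_hospital_volume_corr
  z_s <- rho_sh * qnorm(u_h) + sqrt(1 - rho_sh^2) * rnorm(n_s)
  v_s <- .q_volume(pnorm(z_s), params$surgeon_volume_dist)
  if (!is.null(params$remote)) {
    out <- prim$outlying
    v_s[out] <- sample(params$remote$volumes, sum(out), replace = TRUE)
  }

  mlog_s <- mean(log(v_s))
  sdlog_s <- sd(log(v_s))
  if (!is.finite(sdlog_s) || sdlog_s < 1e-8) sdlog_s <- 1
  zlog_s <- .zlog(v_s, mlog_s, sdlog_s)
  sig_s <- exp(-params$quality_sd_decay * zlog_s)
  q_s <- rho_q * zlog_s + sqrt(1 - rho_q^2) * sig_s * rnorm(n_s)

  multi <- rbinom(n_s, 1, plogis(qlogis(params$multi_hospital_prob) +
                                   0.5 * q_s)) == 1
  multi <- multi & !prim$outlying   # outlying surgeons stay at their outpost
  second <- rep(NA_character_, n_s)
  if (any(multi)) {
    metro_h <- which(!hospitals$outlying)
    second[multi] <- hospitals$hospital_id[
      sample(metro_h, sum(multi), TRUE, prob = hospitals$annual_volume[metro_h])]
    same <- !is.na(second) & second == prim$hospital_id
    second[same] <- NA_character_
    multi <- !is.na(second)
  }
  surgeons <- data.frame(
    surgeon_id = sprintf("S%05d", seq_len(n_s)),
    annual_volume = as.integer(v_s),
    age = as.integer(pmin(84, pmax(31, round(
      50 - 0.6 * params$quality_proxy_strength * q_s + rnorm(n_s, 0, 5.5))))),
    male = rbinom(n_s, 1, 0.92),
    multi_hospital = as.integer(multi),
    primary_hospital_id = prim$hospital_id,
    hospital_ids = ifelse(multi, paste(prim$hospital_id, second, sep = ";"),
                          prim$hospital_id),
    location_id = hospitals$location_id[match(prim$hospital_id,
                                              hospitals$hospital_id)],
    latent_quality = q_s,
    stringsAsFactors = FALSE
  )

  out <- structure(
    list(surgeons = surgeons, hospitals = hospitals, travel = travel),
    class = "volemu_providers",
    quality_transform = list(mlog_s = mlog_s, sdlog_s = sdlog_s,
                             mlog_h = mlog_h, sdlog_h = sdlog_h)
  )
  out
}

#' @export
print.volemu_providers <- function(x, ...) {
  cat(sprintf("<volemu_providers> %d hospitals, %d surgeons\n",
              nrow(x$hospitals), nrow(x$surgeons)))
  cat(sprintf("  surgeon volume mean %.1f (range %d-%d); hospital mean %.1f (range %d-%d)\n",
              mean(x$surgeons$annual_volume), min(x$surgeons$annual_volume),
              max(x$surgeons$annual_volume), mean(x$hospitals$annual_volume),
              min(x$hospitals$annual_volume), max(x$hospitals$annual_volume)))
  invisible(x)
}

## Enumerate the surgeon-hospital choice pairs with their utility components.
## The quality term of the choice utility uses the within-volume quality
## residual (quality net of its volume-predicted component): savvy patients
## pick the best provider among those comparable in volume, which leaves the
## chosen volume distribution itself undistorted.
#' @keywords internal
.choice_pairs <- function(providers, params) {
  s <- providers$surgeons
  h <- providers$hospitals
  qt <- attr(providers, "quality_transform")
  rho <- params$quality_volume_corr
  resid_s <- s$latent_quality -
    rho * .zlog(s$annual_volume, qt$mlog_s, qt$sdlog_s)
  resid_h <- h$latent_quality -
    rho * .zlog(h$annual_volume, qt$mlog_h, qt$sdlog_h)
  aff <- strsplit(s$hospital_ids, ";", fixed = TRUE)
  n_aff <- lengths(aff)
  pair <- data.frame(
    surgeon_idx = rep(seq_len(nrow(s)), n_aff),
    hospital_id = unlist(aff), stringsAsFactors = FALSE
  )
  pair$hospital_idx <- match(pair$hospital_id, h$hospital_id)
  pair$n_aff <- n_aff[pair$surgeon_idx]
  pair$base <- params$volume_capacity_weight *
    log(s$annual_volume[pair$surgeon_idx]) - log(pair$n_aff)
  pair$q_sum <- resid_s[pair$surgeon_idx] + resid_h[pair$hospital_idx]
  pair$loc <- h$location_id[pair$hospital_idx]
  pair
}

#' Generate patient-level synthetic claims from the structural model
#'
#' Patients receive a home location, independent binary covariates at the
#' configured prevalences, age, a latent standard-normal frailty, a
#' surgeon-hospital pair drawn from a softmax discrete-choice model (utility
#' falling in driving time at rate `travel_decay`, rising in log surgeon
#' volume, and rising in latent provider quality with a weight modified by
#' measured severity and latent frailty), and a 90-day death indicator drawn
#' from the logistic structural outcome model.  When
#' `outcome_coefs["intercept"]` is `NA` the intercept is calibrated so the
#' realized marginal mortality equals `target_baseline_risk`.
#'
#' @param params an [scm_params()] object.
#' @param providers output of [generate_providers()] built from `params`.
#' @param travel a [make_travel()] geography; defaults to the providers' own.
#' @return A data frame of patient records (one row per operated patient)
#'   with attribute `oracle`: a patient-level table of the latent quantities
#'   (frailty, chosen providers' latent qualities, observed volumes, and the
#'   linear-predictor component excluding volume and quality terms) needed by
#'   [true_counterfactual_risk()].  Latent fields never appear in the
#'   analysis-facing columns.
#' @export
generate_patients <- function(params, providers, travel = providers$travel) {
  params <- validate_scm_params(params)
  set.seed(sub_seed(params$seed, "patients"))
  n <- params$n_patients
  geo <- travel$locations

  loc_idx <- sample.int(nrow(geo[!geo$outlying_provider, , drop = FALSE]), n,
                        replace = TRUE)
  pat_geo <- geo[!geo$outlying_provider, , drop = FALSE]
  location_id <- pat_geo$location_id[loc_idx]
  remote <- pat_geo$remote[loc_idx] %||% rep(FALSE, n)

  prev <- params$covariate_prevalences
  flags <- vapply(names(prev), function(nm) rbinom(n, 1, prev[[nm]]),
                  numeric(n))
  colnames(flags) <- names(prev)
  elig <- vapply(names(params$eligibility_prevalences),
                 function(nm) rbinom(n, 1, params$eligibility_prevalences[[nm]]),
                 numeric(n))
  colnames(elig) <- names(params$eligibility_prevalences)
  ad <- params$age_dist
  age <- round(ad$shift + rgamma(n, shape = ad$shape, scale = ad$scale), 1)
  frailty <- rnorm(n)

  comorb <- setdiff(names(prev), c("male", "inpatient"))
  severity <- rowSums(flags[, comorb, drop = FALSE])
  severity_c <- severity - sum(prev[comorb])

  ## discrete choice of (surgeon, hospital) by Gumbel-max softmax sampling
  pair <- .choice_pairs(providers, params)
  H <- travel_matrix(travel, pat_geo$location_id, unique(pair$loc))
  tcol <- match(pair$loc, colnames(H))
  qw <- params$quality_attraction +
    params$severity_selection_strength * severity_c +
    params$frailty_selection_strength * frailty
  choice <- integer(n)
  blk <- 2000L
  for (st in seq(1L, n, by = blk)) {
    ix <- st:min(st + blk - 1L, n)
    U <- matrix(pair$base, nrow = length(ix), ncol = nrow(pair), byrow = TRUE)
    U <- U - params$travel_decay * H[loc_idx[ix], tcol, drop = FALSE]
    U <- U + qw[ix] %o% pair$q_sum
    U <- U - log(-log(matrix(runif(length(U)), nrow = nrow(U))))
    choice[ix] <- max.col(U, ties.method = "first")
  }
  s_idx <- pair$surgeon_idx[choice]
  h_idx <- pair$hospital_idx[choice]
  sv <- providers$surgeons$annual_volume[s_idx]
  hv <- providers$hospitals$annual_volume[h_idx]
  sq <- providers$surgeons$latent_quality[s_idx]
  hq <- providers$hospitals$latent_quality[h_idx]

  ## structural outcome model
  oc <- params$outcome_coefs
  lp_base <- oc[["age"]] * (age - 73) +
    drop(flags %*% oc[names(prev)]) +
    params$frailty_outcome_coef * frailty +
    if (!is.null(params$remote)) params$remote$outcome_shift * remote else 0
  lp_fx <- oc[["surgeon_volume"]] * sv + oc[["hospital_volume"]] * hv +
    oc[["surgeon_quality"]] * sq + oc[["hospital_quality"]] * hq
  if (is.na(oc[["intercept"]])) {
    f <- function(b0) mean(plogis(b0 + lp_base + lp_fx)) -
      params$target_baseline_risk
    b0 <- uniroot(f, c(-12, 4))$root
  } else {
    b0 <- oc[["intercept"]]
  }
  lp_base <- lp_base + b0
  death <- rbinom(n, 1, plogis(lp_base + lp_fx))

  dates <- seq(as.Date("2012-01-01"), as.Date("2016-09-30"), by = "day")
  patients <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = age,
    as.data.frame(flags),
    as.data.frame(elig),
    operation_date = sample(dates, n, replace = TRUE),
    location_id = location_id,
    surgeon_id = providers$surgeons$surgeon_id[s_idx],
    hospital_id = providers$hospitals$hospital_id[h_idx],
    death_90d = death,
    stringsAsFactors = FALSE
  )
  attr(patients, "oracle") <- data.frame(
    patient_id = patients$patient_id,
    frailty = frailty, remote = remote,
    lp_base = lp_base,
    surgeon_volume_obs = sv, hospital_volume_obs = hv,
    surgeon_quality_obs = sq, hospital_quality_obs = hq,
    stringsAsFactors = FALSE
  )
  attr(patients, "intercept") <- b0
  patients
}

#' Simulate a full synthetic claims bundle
#'
#' Convenience wrapper running [generate_providers()] and
#' [generate_patients()] and packaging the result with the travel geography.
#'
#' @param params an [scm_params()] object.
#' @return A list of class `volemu_claims` with elements `patients`,
#'   `surgeons`, `hospitals`, `travel` and `params`.  The patient table
#'   carries the oracle attribute documented in [generate_patients()].
#' @examples
#' cl <- simulate_claims(scm_params(n_hospitals = 25, n_surgeons = 50,
#'                                  n_patients = 400))
#' mean(cl$patients$death_90d)
#' @export
simulate_claims <- function(params) {
  providers <- generate_providers(params)
  patients <- generate_patients(params, providers)
  structure(list(patients = patients,
                 surgeons = providers$surgeons,
                 hospitals = providers$hospitals,
                 travel = providers$travel,
                 params = params),
            quality_transform = attr(providers, "quality_transform"),
            class = "volemu_claims")
}

#' @export
print.volemu_claims <- function(x, ...) {
  cat(sprintf("<volemu_claims> %d patients, %d surgeons, %d hospitals; 90-day mortality %.1f%%\n",
              nrow(x$patients), nrow(x$surgeons), nrow(x$hospitals),
              100 * mean(x$patients$death_90d)))
  invisible(x)
}
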