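#' Configuration of the nonparametric cluster bootstrap
#'
#' @param n_resamples number of bootstrap resamples (default 1000, the
#'   published analysis's choice; values below 40 trigger a warning because
#'   percentile intervals become meaningless).
#' @param cluster_unit resampling unit: `"hospital"` (default, the coarsest
#'   cluster; surgeons and patients are carried along), `"surgeon"`, or
#'   `"patient"` (a diagnostic mode that ignores clustering).
#' @param ci_method only `"percentile"` is implemented: risks near zero make
#'   symmetric normal-approximation intervals invalid.
#' @param seed RNG seed for resampling.
#' @param mode `"auto"` (index-level refits for trials 1-3, full estimator
#'   re-runs for trial 4), `"fast"`, or `"full"`.
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_resamples = 1000L,
                             cluster_unit = c("hospital", "surgeon", "patient"),
                             ci_method = "percentile",
                             seed = 1L,
                             mode = c("auto", "fast", "full")) {
  n_resamples <- .assert_count(n_resamples, "n_resamples")
  if (n_resamples < 40) {
    warning("n_resamples < 40: percentile CIs will be unreliable",
            call. = FALSE)
  }
  stopifnot(identical(ci_method, "percentile"))
  structure(list(n_resamples = n_resamples,
                 cluster_unit = match.arg(cluster_unit),
                 ci_method = ci_method, seed = as.integer(seed),
                 mode = match.arg(mode)),
            class = "bootstrap_config")
}

#' Percentile cluster-bootstrap confidence intervals for a risk grid
#'
#' Resamples clusters (hospitals by default, carrying all nested surgeons and
#' patients; multi-hospital surgeons belong to their primary affiliation)
#' with replacement to the original cluster count, re-runs the full estimator
#' on each resample - duplicated clusters receive fresh identifiers so model
#' fitting treats them as distinct - and returns the 2.5th/97.5th percentiles
#' of the resample distribution for every standardized risk and risk
#' difference.  Resamples in which a reported arm has no patients (or is
#' inestimable) are recorded as missing for that arm, excluded from the
#' percentiles, and counted; arms with more than 20% exclusions trigger a
#' warning.
#'
#' @param claims a `volemu_claims` bundle.
#' @param spec an [emulation_spec()].
#' @param config a [bootstrap_config()].
#' @param estimator the arm-level functional to bootstrap; defaults to
#'   [emulate_trial()].
#' @param grid passed to the estimator (see [emulate_trial()]).
#' @return The estimator's risk grid with columns `ci_lower`, `ci_upper`,
#'   `rd_ci_lower`, `rd_ci_upper` appended, plus attributes `resamples` (the
#'   per-resample risk matrix) and `n_excluded` (per-arm exclusion counts).
#' @export
cluster_bootstrap <- function(claims, spec, config = bootstrap_config(),
                              estimator = emulate_trial, grid = "report") {
  point <- estimator(claims, spec, grid = grid)
  payload <- attr(point, "payload")
  mode <- config$mode
  if (mode == "auto") mode <- if (is.null(payload)) "full" else "fast"
  if (mode == "fast" && is.null(payload)) mode <- "full"

  set.seed(sub_seed(config$seed, "bootstrap"))
  B <- config$n_resamples
  n_arm <- nrow(point)
  R <- matrix(NA_real_, nrow = B, ncol = n_arm)

  if (mode == "fast") {
    ## cluster order must match the provider tables so that fast index-level
    ## refits and full estimator re-runs draw identical resamples
    cl_levels <- switch(config$cluster_unit,
                        hospital = unique(claims$hospitals$hospital_id),
                        surgeon = unique(claims$surgeons$surgeon_id),
                        patient = NULL)
    cl_key <- switch(config$cluster_unit,
                     hospital = payload$hospital,
                     surgeon = payload$surgeon,
                     patient = seq_along(payload$y))
    rows_by <- if (is.null(cl_levels)) split(seq_along(cl_key), cl_key) else
      split(seq_along(cl_key), factor(cl_key, levels = cl_levels))
    n_cl <- length(rows_by)
    for (b in seq_len(B)) {
      idx <- unlist(rows_by[sample.int(n_cl, n_cl, replace = TRUE)],
                    use.names = FALSE)
      Xb <- payload$X[idx, , drop = FALSE]
      keep <- colSums(abs(Xb)) > 0
      fb <- tryCatch(.logit_fit(Xb[, keep, drop = FALSE], payload$y[idx],
                                ridge = payload$ridge),
                     error = function(e) NULL)
      if (is.null(fb) || !fb$converged) next
      if (payload$ridge == 0 &&
          length(.separated_terms(Xb[, keep, drop = FALSE], fb$coef))) next
      cf <- rep(NA_real_, ncol(payload$X))
      cf[keep] <- fb$coef
      for (a in seq_len(n_arm)) {
        Xa <- payload$arm_X[[a]][idx, , drop = FALSE]
        if (any(is.na(cf) & colSums(abs(Xa)) > 0)) next
        cf0 <- ifelse(is.na(cf), 0, cf)
        R[b, a] <- mean(plogis(drop(Xa %*% cf0)))
      }
    }
  } else {
    for (b in seq_len(B)) {
      claims_b <- .resample_claims(claims, config$cluster_unit)
      gb <- tryCatch(estimator(claims_b, spec, grid = grid),
                     error = function(e) NULL)
      if (is.null(gb)) next
      m <- match(interaction(point$surgeon_volume_arm,
                             point$hospital_volume_arm, drop = FALSE),
                 interaction(gb$surgeon_volume_arm,
                             gb$hospital_volume_arm, drop = FALSE))
      R[b, ] <- gb$risk[m]
    }
  }

  excl <- as.integer(colSums(is.na(R)))
  if (any(excl > 0.2 * B)) {
    warning(sprintf("bootstrap: %d arm(s) excluded in >20%% of resamples",
                    sum(excl > 0.2 * B)), call. = FALSE)
  }
  qs <- apply(R, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE,
              names = FALSE)
  point$ci_lower <- qs[1, ]
  point$ci_upper <- qs[2, ]

  ## risk-difference resamples share the per-resample reference risk
  key <- ifelse(is.na(point$hospital_volume_arm), "natural",
                as.character(point$hospital_volume_arm))
  ref_col <- vapply(key, function(k) {
    which(key == k & point$surgeon_volume_arm ==
            attr(point, "spec")$reference_surgeon_volume)[1]
  }, integer(1))
  RD <- R - R[, ref_col, drop = FALSE]
  qd <- apply(RD, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE,
              names = FALSE)
  point$rd_ci_lower <- qd[1, ]
  point$rd_ci_upper <- qd[2, ]
  attr(point, "resamples") <- R
  attr(point, "rd_resamples") <- RD
  attr(point, "n_excluded") <- excl
  attr(point, "bootstrap_config") <- config
  point
}

## Rebuild a claims bundle from resampled clusters, giving duplicated
## clusters fresh identifiers so downstream joins treat them as distinct.
#' @keywords internal
.resample_claims <- function(claims, cluster_unit) {
  if (cluster_unit == "patient") {
    idx <- sample.int(nrow(claims$patients), replace = TRUE)
    out <- claims
    out$patients <- claims$patients[idx, , drop = FALSE]
    orc <- attr(claims$patients, "oracle")
    if (!is.null(orc)) attr(out$patients, "oracle") <- orc[idx, , drop = FALSE]
    out$patients$patient_id <- sprintf("PB%07d", seq_len(nrow(out$patients)))
    return(out)
  }
  if (cluster_unit == "surgeon") {
    ids <- unique(claims$surgeons$surgeon_id)
    take <- sample(ids, length(ids), replace = TRUE)
    pat_by <- split(seq_len(nrow(claims$patients)), claims$patients$surgeon_id)
    pieces_p <- list(); pieces_s <- list()
    orc <- attr(claims$patients, "oracle")
    orc_pieces <- list()
    for (k in seq_along(take)) {
      sid <- take[k]
      rows <- pat_by[[sid]]
      p <- claims$patients[rows, , drop = FALSE]
      new_sid <- sprintf("%s.%d", sid, k)
      p$surgeon_id <- new_sid
      pieces_p[[k]] <- p
      if (!is.null(orc)) orc_pieces[[k]] <- orc[rows, , drop = FALSE]
      srow <- claims$surgeons[claims$surgeons$surgeon_id == sid, , drop = FALSE]
      srow$surgeon_id <- new_sid
      pieces_s[[k]] <- srow
    }
    out <- claims
    out$patients <- do.call(rbind, pieces_p)
    out$patients$patient_id <- sprintf("PB%07d", seq_len(nrow(out$patients)))
    if (!is.null(orc)) attr(out$patients, "oracle") <- do.call(rbind, orc_pieces)
    out$surgeons <- do.call(rbind, pieces_s)
    return(out)
  }
  ## hospital-level (default): patients follow their operating hospital;
  ## surgeons follow their primary affiliation, plus any surgeon referenced
  ## by the copy's patients so provider joins stay complete.
  ids <- unique(claims$hospitals$hospital_id)
  take <- sample(ids, length(ids), replace = TRUE)
  pat_by <- split(seq_len(nrow(claims$patients)), claims$patients$hospital_id)
  surg_by <- split(seq_len(nrow(claims$surgeons)),
                   claims$surgeons$primary_hospital_id)
  orc <- attr(claims$patients, "oracle")
  pieces_p <- list(); pieces_s <- list(); pieces_h <- list(); orc_pieces <- list()
  for (k in seq_along(take)) {
    hid <- take[k]
    suffix <- function(x) sprintf("%s.%d", x, k)
    rows <- pat_by[[hid]] %||% integer()
    p <- claims$patients[rows, , drop = FALSE]
    srows <- union(surg_by[[hid]] %||% integer(),
                   match(unique(p$surgeon_id), claims$surgeons$surgeon_id))
    s <- claims$surgeons[srows, , drop = FALSE]
    hrow <- claims$hospitals[claims$hospitals$hospital_id == hid, ,
                             drop = FALSE]
    old_sid <- s$surgeon_id
    s$surgeon_id <- suffix(old_sid)
    s$primary_hospital_id <- suffix(s$primary_hospital_id)
    hrow$hospital_id <- suffix(hid)
    if (nrow(p)) {
      p$hospital_id <- suffix(p$hospital_id)
      p$surgeon_id <- suffix(p$surgeon_id)
    }
    pieces_p[[k]] <- p
    pieces_s[[k]] <- s
    pieces_h[[k]] <- hrow
    if (!is.null(orc)) orc_pieces[[k]] <- orc[rows, , drop = FALSE]
  }
  out <- claims
  out$patients <- do.call(rbind, pieces_p)
  out$patients$patient_id <- sprintf("PB%07d", seq_len(nrow(out$patients)))
  if (!is.null(orc)) attr(out$patients, "oracle") <- do.call(rbind, orc_pieces)
  out$surgeons <- do.call(rbind, pieces_s)
  out$hospitals <- do.call(rbind, pieces_h)
  out
}
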