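## Right-hand side of the outcome model implied by a spec; covariates listed
## in `drop` (constant in the cohort at hand) are omitted.
#' @keywords internal
.model_rhs <- function(spec, drop = character()) {
  m <- spec$model
  term_for <- function(form, var, arm_var, df) {
    switch(form,
      spline = sprintf("splines::ns(%s, df = %d)", var, df),
      linear = var,
      indicators = sprintf("factor(%s)", arm_var),
      stop("unknown treatment form: ", form, call. = FALSE))
  }
  rhs <- term_for(m$surgeon_form, "surgeon_volume", "surgeon_volume_arm", m$df)
  if (spec$trial >= 2) {
    rhs <- c(rhs, term_for(m$hospital_form, "hospital_volume",
                           "hospital_volume_arm", m$df))
    if (isTRUE(m$interaction)) {
      rhs <- c(rhs, "surgeon_volume:hospital_volume")
    }
  }
  c(rhs, setdiff(c(spec$patient_covariates, spec$provider_covariates), drop))
}

#' Fit the logistic outcome model of an emulated trial
#'
#' Maximum-likelihood logistic regression of 90-day death on the treatment
#' terms (surgeon volume; hospital volume for trials 2-4; restricted cubic
#' splines by default, indicators or linear terms by configuration, plus a
#' surgeon x hospital product term) and the baseline patient covariates, with
#' provider characteristics added for trial 4.  Perfect separation is
#' surfaced as an explicit error naming the separating term; an optional
#' ridge penalty (`spec$model$ridge > 0`, never applied by default) is
#' available for degenerate fixtures.
#'
#' @param cohort data frame from [build_cohort()] (or any frame with the
#'   model's variables and a binary `death_90d`).
#' @param spec an [emulation_spec()].
#' @param formula optional explicit model formula overriding the spec (used
#'   e.g. for saturated-model checks).
#' @return An object of class `volemu_fit`: coefficient vector, frozen terms
#'   and factor levels for prediction, and convergence diagnostics.
#' @export
fit_outcome_model <- function(cohort, spec, formula = NULL) {
  if (nrow(cohort) == 0L) stop("empty cohort", call. = FALSE)
  if (!all(cohort$death_90d %in% 0:1)) {
    stop("death_90d must be binary 0/1", call. = FALSE)
  }
  covs <- c(spec$patient_covariates, spec$provider_covariates)
  const <- covs[vapply(covs, function(v)
    !is.null(cohort[[v]]) && length(unique(cohort[[v]])) < 2L, logical(1))]
  if (length(const) && is.null(formula)) {
    warning("dropping covariate(s) constant in this cohort: ",
            paste(const, collapse = ", "), call. = FALSE)
  }
  ff <- formula %||% as.formula(
    paste("death_90d ~", paste(.model_rhs(spec, drop = const),
                               collapse = " + ")))
  mf <- model.frame(ff, cohort, na.action = na.fail)
  tt <- terms(mf)
  X <- model.matrix(tt, mf)
  y <- model.response(mf)
  ridge <- spec$model$ridge %||% 0
  fit <- .logit_fit(X, y, ridge = ridge)
  if (!fit$converged) {
    stop(sprintf("outcome model did not converge in %d IRLS iterations (max |score| = %.3g)",
                 fit$iter, fit$max_score), call. = FALSE)
  }
  if (ridge == 0) {
    sep <- .separated_terms(X, fit$coef)
    if (length(sep)) {
      stop("apparent separation in the outcome model; diverging term(s): ",
           paste(sep, collapse = ", "),
           " (consider spec$model$ridge > 0 or coarser treatment terms)",
           call. = FALSE)
    }
  }
  structure(list(
    coef = setNames(fit$coef, colnames(X)),
    terms = delete.response(tt),
    xlevels = .getXlevels(tt, mf),
    contrasts = attr(X, "contrasts"),
    assign = attr(X, "assign"),
    term_labels = attr(tt, "term.labels"),
    converged = fit$converged,
    n_used = nrow(X),
    ridge = ridge,
    formula = ff
  ), class = "volemu_fit")
}

## Separation heuristic shared by the full fit and the bootstrap refits:
## diverging non-intercept coefficients together with fitted probabilities
## numerically pinned at 0 or 1.
#' @keywords internal
.separated_terms <- function(X, coef) {
  cf0 <- ifelse(is.na(coef), 0, coef)
  mu <- plogis(drop(X %*% cf0))
  if (!any(mu < 1e-8 | mu > 1 - 1e-8)) return(character())
  colnames(X)[is.finite(coef) & abs(coef) > 12 &
                colnames(X) != "(Intercept)"]
}

## IRLS for (optionally ridge-penalized) logistic regression via glm.fit for
## the unpenalized case and a small Newton loop otherwise.  Aliased columns
## get NA coefficients (as in glm), which predictions treat as "arm absent".
#' @keywords internal
.logit_fit <- function(X, y, ridge = 0) {
  if (ridge == 0) {
    g <- suppressWarnings(glm.fit(X, y, family = binomial(),
                                  control = glm.control(epsilon = 1e-12,
                                                        maxit = 100)))
    cf <- g$coefficients
    eta <- drop(X[, !is.na(cf), drop = FALSE] %*% cf[!is.na(cf)])
    score <- drop(crossprod(X[, !is.na(cf), drop = FALSE], y - plogis(eta)))
    return(list(coef = cf, converged = g$converged, iter = g$iter,
                max_score = max(abs(score))))
  }
  p <- ncol(X)
  pen <- diag(rep(ridge, p)); pen[1, 1] <- 0  # no penalty on intercept
  beta <- rep(0, p)
  for (it in 1:100) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    score <- drop(crossprod(X, y - mu)) - drop(pen %*% beta)
    H <- crossprod(X, X * w) + pen
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(score)) < 1e-8) break
  }
  list(coef = beta, converged = max(abs(score)) < 1e-6, iter = it,
       max_score = max(abs(score)))
}

#' @export
print.volemu_fit <- function(x, ...) {
  cat(sprintf("<volemu_fit> logistic outcome model, %d terms, n = %d%s\n",
              sum(!is.na(x$coef)), x$n_used,
              if (x$ridge > 0) sprintf(", ridge = %g", x$ridge) else ""))
  invisible(x)
}

#' Model matrix for new data under a frozen fit
#' @keywords internal
.fit_mm <- function(fit, newdata) {
  mf <- model.frame(fit$terms, newdata, na.action = na.fail,
                    xlev = fit$xlevels)
  model.matrix(fit$terms, mf, contrasts.arg = fit$contrasts)
}

#' Predicted 90-day death probabilities
#'
#' @param fit a [fit_outcome_model()] object.
#' @param newdata data frame with the model's variables.
#' @return Vector of probabilities in `(0, 1)` (never truncated); `NA` where
#'   the prediction involves an aliased (inestimable) term.
#' @export
predict_risk <- function(fit, newdata) {
  X <- .fit_mm(fit, newdata)
  cf <- fit$coef
  if (anyNA(cf)) {
    used <- X[, is.na(cf), drop = FALSE] != 0
    bad <- rowSums(used) > 0
    cf0 <- ifelse(is.na(cf), 0, cf)
    out <- plogis(drop(X %*% cf0))
    out[bad] <- NA_real_
    return(out)
  }
  plogis(drop(X %*% cf))
}
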