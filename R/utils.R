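#' Derive a reproducible substream seed from a global seed and a stream name
#'
#' All randomness in a multi-stage run flows from one global seed; each stage
#' draws from its own named substream so that adding or reordering stages does
#' not perturb the others.
#'
#' @param seed integer global seed.
#' @param name character scalar naming the substream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @examples
#' sub_seed(1, "simulate")
#' @export
sub_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 2654435 %% 2147483647) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expit <- stats::plogis

#' @keywords internal
.assert_scalar_prob <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must be probabilities in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
.assert_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop(sprintf("%s must be an integer >= %d", what, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

## Sample a zero-truncated negative binomial via inverse-cdf; guarantees >= 1.
#' @keywords internal
.rztnb <- function(n, mu, size) {
  p0 <- dnbinom(0, mu = mu, size = size)
  u <- runif(n, min = p0, max = 1)
  pmax(1L, qnbinom(u, mu = mu, size = size))
}

## Quantile function of the zero-truncated negative binomial, used to couple
## provider volumes through a Gaussian copula.
#' @keywords internal
.qztnb <- function(p, mu, size) {
  p0 <- pnbinom(0, mu = mu, size = size)
  pmax(1L, qnbinom(p0 + p * (1 - p0), mu = mu, size = size))
}

## Draw volumes from a distribution spec: list(family = "ztnb", mu, size) or
## list(family = "levels", levels, probs).
#' @keywords internal
.r_volume <- function(n, dist) {
  switch(dist$family,
    ztnb = .rztnb(n, dist$mu, dist$size),
    levels = sample(dist$levels, n, replace = TRUE,
                    prob = dist$probs %||% rep(1, length(dist$levels))),
    stop("unknown volume distribution family: ", dist$family, call. = FALSE)
  )
}

## Map a uniform quantile to a volume for copula coupling.
#' @keywords internal
.q_volume <- function(p, dist) {
  switch(dist$family,
    ztnb = .qztnb(p, dist$mu, dist$size),
    levels = {
      pr <- dist$probs %||% rep(1, length(dist$levels))
      lv <- dist$levels[order(dist$levels)]
      pr <- (pr / sum(pr))[order(dist$levels)]
      lv[pmin(length(lv), findInterval(p, cumsum(pr), left.open = TRUE) + 1L)]
    },
    stop("unknown volume distribution family: ", dist$family, call. = FALSE)
  )
}

## Standardized log-volume given reference moments; the latent-quality model
## is quality = rho * zlog(volume) + sqrt(1 - rho^2) * sigma(volume) * eps.
#' @keywords internal
.zlog <- function(v, mlog, sdlog) (log(v) - mlog) / max(sdlog, 1e-8)

#' @keywords internal
.compress_quantiles <- function(x, k = 16L) {
  x <- x[is.finite(x)]
  if (length(x) <= k) return(x)
  unname(quantile(x, probs = (seq_len(k) - 0.5) / k, type = 8))
}
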