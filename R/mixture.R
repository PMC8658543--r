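#' Fit a two-component normal mixture by EM
#'
#' Marker-intensity distributions over a culture are bimodal: a negative
#' population and a (dimmer or brighter) positive one. The mixture is fitted
#' by maximum likelihood with expectation-maximization, components are
#' returned ordered by mean, and the per-iteration log-likelihood trace is
#' kept (it is nondecreasing, a property the tests check).
#'
#' Initialization splits the sample at its median; iteration stops when the
#' log-likelihood improves by less than `tol` or after `max_iter` iterations
#' (then `converged = FALSE` and the best iterate is returned).
#'
#' @param values numeric intensity values (>= 10, nonconstant).
#' @param tol convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter maximum EM iterations (default 500).
#' @return object of class `mixture_fit`: `mu_neg`, `sigma_neg`, `mu_pos`,
#'   `sigma_pos`, `weight_neg`, `converged`, `log_likelihood`,
#'   `loglik_trace`, `n_iter`.
#' @export
fit_two_normal_mixture <- function(values, tol = 1e-6, max_iter = 500L) {
  values <- as.numeric(values[!is.na(values)])
  if (length(values) < 10L)
    stop("need at least 10 values to fit a mixture", call. = FALSE)
  if (diff(range(values)) == 0)
    stop("degenerate input: all intensity values are identical", call. = FALSE)
  n <- length(values)
  sd_floor <- max(stats::sd(values) * 1e-6, .Machine$double.eps)

  med <- stats::median(values)
  lo <- values[values <= med]
  hi <- values[values > med]
  if (length(hi) < 2L) { hi <- sort(values)[(n - 1):n]; lo <- values }
  mu <- c(mean(lo), mean(hi))
  sg <- pmax(c(stats::sd(lo), stats::sd(hi)), sd_floor)
  if (anyNA(sg)) sg <- rep(max(stats::sd(values) / 4, sd_floor), 2)
  w <- c(0.5, 0.5)

  loglik <- function(mu, sg, w) {
    sum(log(w[1] * stats::dnorm(values, mu[1], sg[1]) +
              w[2] * stats::dnorm(values, mu[2], sg[2]) +
              .Machine$double.xmin))
  }
  ll_trace <- loglik(mu, sg, w)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    d1 <- w[1] * stats::dnorm(values, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(values, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot                     # responsibility of component 1
    n1 <- sum(r); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break # a component died; keep best iterate
    mu <- c(sum(r * values) / n1, sum((1 - r) * values) / n2)
    sg <- c(sqrt(sum(r * (values - mu[1])^2) / n1),
            sqrt(sum((1 - r) * (values - mu[2])^2) / n2))
    sg <- pmax(sg, sd_floor)
    w <- c(n1, n2) / n
    ll <- loglik(mu, sg, w)
    ll_trace <- c(ll_trace, ll)
    if (ll - ll_trace[length(ll_trace) - 1L] < tol) { converged <- TRUE; break }
  }

  o <- order(mu)
  fit <- structure(list(
    mu_neg = mu[o[1]], sigma_neg = sg[o[1]],
    mu_pos = mu[o[2]], sigma_pos = sg[o[2]],
    weight_neg = w[o[1]], converged = converged,
    log_likelihood = ll_trace[length(ll_trace)],
    loglik_trace = ll_trace, n_iter = iter
  ), class = "mixture_fit")
  if (fit$mu_pos - fit$mu_neg < max(fit$sigma_neg, fit$sigma_pos))
    warning("mixture components collapse (means within 1 SD); ",
            "the sample may come from a single population", call. = FALSE)
  fit
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "<mixture_fit: neg N(%.4g, %.3g) w=%.3f | pos N(%.4g, %.3g) | %s, logLik %.4g>\n",
    x$mu_neg, x$sigma_neg, x$weight_neg, x$mu_pos, x$sigma_pos,
    if (x$converged) "converged" else "NOT converged", x$log_likelihood))
  invisible(x)
}

#' Positivity threshold from a mixture fit
#'
#' A cell counts as positive above 99.7% of the negative population, i.e.
#' three standard deviations above the negative component's mean:
#' `mu_neg + 3 * sigma_neg`. Positivity is strict (`intensity > threshold`).
#'
#' @param fit a `mixture_fit` (or any list with `mu_neg` and `sigma_neg`).
#' @return the intensity threshold.
#' @export
positivity_threshold <- function(fit) {
  stopifnot(is.numeric(fit$mu_neg), is.numeric(fit$sigma_neg),
            fit$sigma_neg >= 0)
  fit$mu_neg + 3 * fit$sigma_neg
}
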