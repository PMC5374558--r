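#' Fit a beta component by the method of moments
#'
#' From the sample mean `m` and (population, denominator n) variance `v` of
#' scores in (0, 1): `alpha = m (m (1 - m) / v - 1)`,
#' `beta = (1 - m) (m (1 - m) / v - 1)`. This is how the infectious and
#' non-infectious score components are fitted from held-out positive and
#' negative testing scores before the mixing fraction is estimated.
#'
#' @param scores Numeric vector of scores; values outside (0, 1) are clamped
#'   to `[eps, 1 - eps]` with `eps = 1 / (2 n)` (probability-type scores can
#'   hit 0 or 1 exactly, where beta densities are undefined).
#' @return An object of class `beta_component`: list with `alpha`, `beta`,
#'   `n`, `n_clamped`.
#' @examples
#' # exact moments of Beta(2, 2): mean .5, variance .05
#' beta_moment_fit(c(0.5 + sqrt(0.05) * c(-1, 1), 0.5 - 1e-9, 0.5 + 1e-9))
#' @export
beta_moment_fit <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 scores")
  cl <- clamp_scores(scores)
  s <- cl$scores
  m <- mean(s)
  v <- mean((s - m)^2)
  if (v == 0) stop("scores have zero variance; moment estimator undefined")
  if (v >= m * (1 - m)) {
    stop("moment estimator invalid: variance ", signif(v, 4),
         " >= m(1-m) = ", signif(m * (1 - m), 4),
         " (scores too dispersed for a beta fit)")
  }
  common <- m * (1 - m) / v - 1
  structure(list(alpha = m * common, beta = (1 - m) * common,
                 n = length(s), n_clamped = cl$n_clamped),
            class = "beta_component")
}

#' Construct a beta component from known parameters
#'
#' @param alpha,beta Positive shape parameters.
#' @return A `beta_component`.
#' @export
beta_component <- function(alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  structure(list(alpha = alpha, beta = beta, n = NA_integer_, n_clamped = 0L),
            class = "beta_component")
}

#' @export
print.beta_component <- function(x, ...) {
  cat(sprintf("beta component: alpha = %.3f, beta = %.3f\n", x$alpha, x$beta))
  invisible(x)
}

clamp_scores <- function(scores, eps = NULL) {
  if (anyNA(scores)) stop("scores contain NA")
  n <- length(scores)
  eps <- eps %||% (1 / (2 * n))
  out <- pmin(pmax(scores, eps), 1 - eps)
  list(scores = out, n_clamped = sum(out != scores))
}

#' Log-likelihood of a two-component beta mixture
#'
#' `sum_i log[(1 - gamma) f0(s_i) + gamma f1(s_i)]` where f0, f1 are the beta
#' densities of the non-infectious and infectious components. Concave in
#' `gamma` for fixed components.
#'
#' @param gamma Mixing fraction in \[0, 1\] (fraction from the infectious
#'   component).
#' @param scores Scores in (0, 1) (clamped as in [beta_moment_fit()]).
#' @param comp0,comp1 `beta_component` objects.
#' @return The log-likelihood.
#' @export
mixture_loglik <- function(gamma, scores, comp0, comp1) {
  stopifnot(gamma >= 0, gamma <= 1)
  s <- clamp_scores(scores)$scores
  f0 <- dbeta(s, comp0$alpha, comp0$beta)
  f1 <- dbeta(s, comp1$alpha, comp1$beta)
  sum(log((1 - gamma) * f0 + gamma * f1))
}

#' Maximum-likelihood estimate of the infectious fraction
#'
#' Maximizes the mixture log-likelihood over `gamma` in \[0, 1\] with the two
#' beta components held fixed (the two-stage procedure: components fitted
#' once from reference score sets, then frozen). The likelihood is concave in
#' `gamma`, so golden-section search suffices; endpoints are checked
#' explicitly so boundary maxima are exact. The confidence interval is the
#' profile-likelihood set `{gamma : 2 (ll(gamma_hat) - ll(gamma)) <=
#' chi^2_1(ci_level)}` truncated to \[0, 1\]; a Wald interval is available
#' for comparison.
#'
#' @param scores Query scores (e.g. viral-tagging candidates) in (0, 1).
#' @param comp0,comp1 Fitted `beta_component`s for the non-infectious and
#'   infectious populations.
#' @param ci_level Confidence level, default 0.95.
#' @param ci_method `"profile"` (default) or `"wald"`.
#' @param tol Optimizer tolerance on gamma.
#' @return An object of class `beta_mixture_fit`: list with `comp0`, `comp1`,
#'   `gamma_hat`, `ci_low`, `ci_high`, `log_likelihood`, `n`, `n_clamped`.
#' @export
estimate_gamma <- function(scores, comp0, comp1, ci_level = 0.95,
                           ci_method = c("profile", "wald"), tol = 1e-8) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(comp0, "beta_component"), inherits(comp1, "beta_component"))
  cl <- clamp_scores(scores)
  s <- cl$scores
  f0 <- dbeta(s, comp0$alpha, comp0$beta)
  f1 <- dbeta(s, comp1$alpha, comp1$beta)
  ll <- function(g) sum(log((1 - g) * f0 + g * f1))
  opt <- optimize(ll, c(0, 1), maximum = TRUE, tol = tol)
  cand_g <- c(opt$maximum, 0, 1)
  cand_ll <- c(opt$objective, ll(0), ll(1))
  best <- which.max(cand_ll)
  gamma_hat <- cand_g[best]
  ll_hat <- cand_ll[best]

  if (ci_method == "profile") {
    crit <- qchisq(ci_level, df = 1)
    dev <- function(g) 2 * (ll_hat - ll(g)) - crit
    ci_low <- if (gamma_hat > 0 && dev(0) > 0)
      uniroot(dev, c(0, gamma_hat), tol = 1e-6)$root else 0
    ci_high <- if (gamma_hat < 1 && dev(1) > 0)
      uniroot(dev, c(gamma_hat, 1), tol = 1e-6)$root else 1
  } else {
    # observed Fisher information in gamma
    num <- (f1 - f0) / ((1 - gamma_hat) * f0 + gamma_hat * f1)
    info <- sum(num^2)
    se <- if (info > 0) 1 / sqrt(info) else Inf
    z <- qnorm(1 - (1 - ci_level) / 2)
    ci_low <- max(0, gamma_hat - z * se)
    ci_high <- min(1, gamma_hat + z * se)
  }
  structure(list(comp0 = comp0, comp1 = comp1, gamma_hat = gamma_hat,
                 ci_low = ci_low, ci_high = ci_high,
                 ci_level = ci_level, ci_method = ci_method,
                 log_likelihood = ll_hat, n = length(s),
                 n_clamped = cl$n_clamped),
            class = "beta_mixture_fit")
}

#' @export
print.beta_mixture_fit <- function(x, ...) {
  cat(sprintf(
    "beta mixture fit (n = %d): gamma_hat = %.3f, %d%% CI [%.3f, %.3f]\n",
    x$n, x$gamma_hat, round(100 * x$ci_level), x$ci_low, x$ci_high))
  cat(sprintf("  comp0 (non-infectious): Beta(%.2f, %.2f)\n",
              x$comp0$alpha, x$comp0$beta))
  cat(sprintf("  comp1 (infectious):     Beta(%.2f, %.2f)\n",
              x$comp1$alpha, x$comp1$beta))
  invisible(x)
}

#' Estimate the infectious fraction from three score sets
#'
#' Convenience wrapper for the full two-stage procedure: fit the infectious
#' component from positive reference scores, the non-infectious component
#' from negative reference scores, then estimate `gamma` on the query scores.
#'
#' @param pos_scores,neg_scores Reference score vectors (held-out positives /
#'   non-training negatives).
#' @param query_scores Scores of the candidate set whose infectious fraction
#'   is wanted.
#' @inheritParams estimate_gamma
#' @return A `beta_mixture_fit`.
#' @export
estimate_fraction <- function(pos_scores, neg_scores, query_scores,
                              ci_level = 0.95,
                              ci_method = c("profile", "wald")) {
  comp1 <- beta_moment_fit(pos_scores)
  comp0 <- beta_moment_fit(neg_scores)
  estimate_gamma(query_scores, comp0, comp1, ci_level = ci_level,
                 ci_method = match.arg(ci_method))
}

#' Simulate scores from a two-component beta mixture
#'
#' @param n Number of scores.
#' @param gamma True infectious fraction.
#' @param comp0,comp1 `beta_component`s.
#' @param seed Optional seed.
#' @return Numeric vector of `n` scores.
#' @export
simulate_mixture_scores <- function(n, gamma, comp0, comp1, seed = NULL) {
  run <- function() {
    from1 <- rbinom(n, 1, gamma) == 1
    out <- numeric(n)
    out[from1] <- rbeta(sum(from1), comp1$alpha, comp1$beta)
    out[!from1] <- rbeta(sum(!from1), comp0$alpha, comp0$beta)
    out
  }
  if (is.null(seed)) run() else with_preserved_seed({ set.seed(seed); run() })
}
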