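# Effect estimators for 2x2 tables and proportions.
#
# Conventions follow standard smoking-trial reporting: Wald intervals on
# the log-odds scale for odds ratios, Newcombe's hybrid Wilson-score
# method for differences of proportions, Wald intervals for feasibility
# proportions with Clopper-Pearson available for degenerate cells, Pearson
# chi-square without continuity correction, and a flat-prior
# normal-approximation posterior for odds-ratio exceedance probabilities.

#' A 2x2 contingency table
#'
#' @param a exposed events.
#' @param b exposed non-events.
#' @param c unexposed events.
#' @param d unexposed non-events.
#' @return an object of class `two_by_two`.
#' @examples
#' two_by_two(12, 92, 3, 102)  # 12/104 vs 3/105
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop_jitai("cells must be nonnegative integers", class = "jitai_validation")
  }
  structure(as.list(cells), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("<2x2> events %d/%d vs %d/%d\n",
              x$a, x$a + x$b, x$c, x$c + x$d))
  invisible(x)
}

effect_estimate <- function(estimate, ci_low, ci_high, method,
                            alpha = 0.05, ...) {
  stopifnot(method %in% c("wald_or", "newcombe_rd", "wald_prop",
                          "clopper_pearson_prop", "chi_square",
                          "posterior_prob"))
  structure(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 method = method, alpha = alpha, ...),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<%s> %.4g (%.4g, %.4g) [%g%% CI]\n", x$method, x$estimate,
              x$ci_low, x$ci_high, 100 * (1 - x$alpha)))
  invisible(x)
}

#' Odds ratio with Wald confidence interval
#'
#' Point estimate \eqn{(ad)/(bc)} with the interval
#' \eqn{\exp(\ln OR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})}.  Zero cells are
#' an explicit error: continuity corrections are out of scope.
#'
#' @param t a [two_by_two()].
#' @param alpha two-sided error rate (default 0.05).
#' @return an `effect_estimate`, with the Wald `p_value` attached.
#' @examples
#' odds_ratio_wald(two_by_two(16, 88, 5, 100))  # 3.64 (1.28, 10.33)
#' @export
odds_ratio_wald <- function(t, alpha = 0.05) {
  stopifnot(inherits(t, "two_by_two"))
  if (any(unlist(t[c("a", "b", "c", "d")]) == 0)) {
    stop_jitai("odds ratio undefined with a zero cell",
               class = "jitai_degenerate")
  }
  or <- (t$a * t$d) / (t$b * t$c)
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  z <- stats::qnorm(1 - alpha / 2)
  effect_estimate(or, exp(log(or) - z * se), exp(log(or) + z * se),
                  "wald_or", alpha,
                  p_value = 2 * stats::pnorm(-abs(log(or)) / se))
}

wilson_limits <- function(k, n, alpha = 0.05) {
  z <- stats::qnorm(1 - alpha / 2)
  p <- k / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(ctr - hw, ctr + hw)
}

#' Risk difference with Newcombe hybrid score interval
#'
#' Difference of proportions \eqn{p_1 - p_2} with Newcombe's method 10
#' interval: Wilson score limits \eqn{(l_i, u_i)} are computed per group
#' and combined as lower \eqn{= \hat d - \sqrt{(p_1-l_1)^2 + (u_2-p_2)^2}}
#' and upper \eqn{= \hat d + \sqrt{(u_1-p_1)^2 + (p_2-l_2)^2}}.
#'
#' @param t a [two_by_two()].
#' @param alpha two-sided error rate.
#' @return an `effect_estimate` on the proportion scale.
#' @examples
#' risk_difference_newcombe(two_by_two(12, 92, 3, 102))  # 8.7% (1.6, 16.5)
#' @export
risk_difference_newcombe <- function(t, alpha = 0.05) {
  stopifnot(inherits(t, "two_by_two"))
  n1 <- t$a + t$b; n2 <- t$c + t$d
  if (n1 == 0 || n2 == 0) {
    stop_jitai("both group sizes must be positive", class = "jitai_degenerate")
  }
  p1 <- t$a / n1; p2 <- t$c / n2
  w1 <- wilson_limits(t$a, n1, alpha)
  w2 <- wilson_limits(t$c, n2, alpha)
  d <- p1 - p2
  effect_estimate(d,
                  d - sqrt((p1 - w1[1])^2 + (w2[2] - p2)^2),
                  d + sqrt((w1[2] - p1)^2 + (p2 - w2[1])^2),
                  "newcombe_rd", alpha)
}

#' Wald interval for a proportion
#'
#' \eqn{\hat p \pm z \sqrt{\hat p (1-\hat p)/n}}.  Degenerate counts
#' (`k = 0` or `k = n`) are an error directing to
#' [proportion_ci_clopper_pearson()].
#'
#' @param k successes.
#' @param n trials.
#' @param alpha error rate.
#' @return an `effect_estimate` on the proportion scale.
#' @export
proportion_ci_wald <- function(k, n, alpha = 0.05) {
  stopifnot(n > 0, k >= 0, k <= n)
  if (k == 0 || k == n) {
    stop_jitai("Wald interval degenerate at k=%d, n=%d; use Clopper-Pearson",
               k, n, class = "jitai_degenerate")
  }
  p <- k / n
  z <- stats::qnorm(1 - alpha / 2)
  hw <- z * sqrt(p * (1 - p) / n)
  effect_estimate(p, p - hw, p + hw, "wald_prop", alpha)
}

#' Clopper-Pearson exact interval for a proportion
#'
#' Exact beta-quantile limits; the lower limit is 0 when `k = 0` and the
#' upper limit 1 when `k = n`.
#'
#' @param k successes.
#' @param n trials.
#' @param alpha error rate.
#' @return an `effect_estimate` on the proportion scale.
#' @export
proportion_ci_clopper_pearson <- function(k, n, alpha = 0.05) {
  stopifnot(n > 0, k >= 0, k <= n)
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  effect_estimate(k / n, lo, hi, "clopper_pearson_prop", alpha)
}

#' Pearson chi-square test for a 2x2 table
#'
#' \eqn{\sum (O-E)^2 / E} without continuity correction, 1 degree of
#' freedom.
#'
#' @param t a [two_by_two()].
#' @return `list(statistic =, df = 1, p_value =)`.
#' @export
pearson_chi_square <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  o <- matrix(c(t$a, t$b, t$c, t$d), nrow = 2, byrow = TRUE)
  if (any(rowSums(o) == 0) || any(colSums(o) == 0)) {
    stop_jitai("chi-square undefined with a zero margin",
               class = "jitai_degenerate")
  }
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  stat <- sum((o - e)^2 / e)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Posterior probability that the odds ratio exceeds a threshold
#'
#' Under a flat prior on the log odds ratio, the posterior is approximated
#' as Normal with mean \eqn{\ln \hat{OR}} and variance
#' \eqn{1/a + 1/b + 1/c + 1/d}; the returned value is the upper tail
#' beyond \eqn{\ln c}.  Intended for translating preliminary-trial effect
#' estimates into the probability that the true OR clears a planning
#' threshold (e.g. 1.5, 1.7, 2.0).
#'
#' @param t a [two_by_two()].
#' @param threshold odds-ratio threshold `c > 0`.
#' @param prior only `"flat_log_or"` is implemented.
#' @return a probability.
#' @export
posterior_prob_or_exceeds <- function(t, threshold,
                                      prior = "flat_log_or") {
  stopifnot(inherits(t, "two_by_two"), threshold > 0,
            prior == "flat_log_or")
  if (any(unlist(t[c("a", "b", "c", "d")]) == 0)) {
    stop_jitai("posterior undefined with a zero cell",
               class = "jitai_degenerate")
  }
  mu <- log((t$a * t$d) / (t$b * t$c))
  se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  stats::pnorm(log(threshold), mean = mu, sd = se, lower.tail = FALSE)
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of a binary-response logistic model.  An
#' intercept is always included.  Convergence requires the maximum
#' absolute score component to fall below `tol`; (quasi-)complete
#' separation is detected and raised as an error rather than returning
#' silently diverging estimates.
#'
#' @param design numeric matrix or data.frame of covariates (no intercept
#'   column).
#' @param response 0/1 (or logical) vector.
#' @param tol score convergence tolerance.
#' @param max_iter iteration cap.
#' @return `list(coefficients =, se =, converged =, iterations =,
#'   fitted =)`; coefficient names are `(Intercept)` plus the design
#'   column names.
#' @export
logistic_fit <- function(design, response, tol = 1e-8, max_iter = 50L) {
  X <- as.matrix(cbind(`(Intercept)` = 1, design))
  storage.mode(X) <- "double"
  y <- as.numeric(response)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (all(y == 0) || all(y == 1)) {
    stop_jitai("degenerate response: all %d", y[1], class = "jitai_separation")
  }
  beta <- numeric(ncol(X))
  beta[1] <- stats::qlogis(mean(y))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) {
      info <- crossprod(X, X * (mu * (1 - mu)))
      se <- sqrt(diag(solve(info)))
      return(list(coefficients = stats::setNames(beta, colnames(X)),
                  se = stats::setNames(se, colnames(X)),
                  converged = TRUE, iterations = it, fitted = mu))
    }
    w <- mu * (1 - mu)
    if (any(w < 1e-10 & (abs(eta) > 12))) {
      # fitted probabilities pinned at 0/1 with diverging linear predictor
      stop_jitai("complete or quasi-complete separation detected",
                 class = "jitai_separation")
    }
    info <- crossprod(X, X * pmax(w, 1e-10))
    step <- tryCatch(solve(info, score), error = function(e)
      stop_jitai("singular information matrix (separation or collinearity)",
                 class = "jitai_separation"))
    beta <- beta + step
    if (max(abs(beta)) > 30) {
      stop_jitai("complete or quasi-complete separation detected",
                 class = "jitai_separation")
    }
  }
  stop_jitai("IRLS failed to converge in %d iterations", max_iter,
             class = "jitai_separation")
}
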