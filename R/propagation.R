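# Bounds of the 1-D dispersion search; k at K_CAP is reported as the
# Poisson boundary (variance equal to the mean).
K_MIN <- 1e-4
K_CAP <- 1e6

validate_counts <- function(counts, what = "counts") {
  if (length(counts) == 0L || any(!is.finite(counts)) ||
      any(counts < 0) || any(counts != round(counts))) {
    stop("`", what, "` must be non-negative integers")
  }
  as.numeric(counts)
}

#' Negative-binomial log-likelihood of retweet counts
#'
#' Sum of log probability masses under the negative binomial with mean `mu`
#' and dispersion `k` (variance `mu + mu^2/k`). In the degenerate limit
#' `mu = 0` the distribution is a point mass at zero.
#'
#' @param mu Mean, `>= 0` (`mu = 0` requires all counts zero).
#' @param k Dispersion, `> 0`.
#' @param counts Non-negative integer counts.
#' @return Log-likelihood (scalar; `-Inf` if a zero-mean model sees a
#'   positive count).
#' @export
negbin_loglik <- function(mu, k, counts) {
  counts <- validate_counts(counts)
  if (k <= 0) stop("`k` must be > 0")
  if (mu < 0) stop("`mu` must be >= 0")
  if (mu == 0) return(if (all(counts == 0)) 0 else -Inf)
  sum(dnbinom(counts, size = k, mu = mu, log = TRUE))
}

#' Fit a negative binomial to retweet counts by maximum likelihood
#'
#' The MLE of the mean is the sample mean (the mean score equation is free
#' of `k`), so `mu` is set analytically and the dispersion maximizes the
#' 1-D profile log-likelihood by bounded search over `log k` in
#' `[1e-4, 1e6]`. `mu` is the rate of propagation: the mean number of times
#' a message is retweeted, the message-spread analogue of an effective
#' reproduction number. Samples with variance at or below the mean sit on
#' the Poisson boundary and are reported with `k` at the cap; an all-zero
#' sample is flagged degenerate.
#'
#' @param counts At least 2 non-negative integer retweet counts.
#' @return Object of class `negbin_fit`: `mu`, `k`, `loglik`,
#'   `aic` (`= 2 * n_params - 2 * loglik`, `n_params = 2`), `n`,
#'   `n_params`, `converged`, `boundary`, `degenerate`.
#' @examples
#' fit_negbin(c(0, 0, 1, 2, 5, 0, 3))
#' @export
fit_negbin <- function(counts) {
  counts <- validate_counts(counts)
  if (length(counts) < 2L) stop("need at least 2 counts to fit")
  mu <- mean(counts)
  new_fit <- function(k, loglik, boundary, degenerate, converged = TRUE) {
    structure(list(mu = mu, k = k, loglik = loglik,
                   aic = 2 * 2 - 2 * loglik, n = length(counts),
                   n_params = 2L, converged = converged,
                   boundary = boundary, degenerate = degenerate),
              class = "negbin_fit")
  }
  if (mu == 0) {
    return(new_fit(K_CAP, 0, boundary = TRUE, degenerate = TRUE))
  }
  if (var(counts) <= mu) {
    # no overdispersion: profile likelihood increases toward the Poisson
    # limit, report the boundary fit
    return(new_fit(K_CAP, negbin_loglik(mu, K_CAP, counts),
                   boundary = TRUE, degenerate = FALSE))
  }
  opt <- optimize(function(logk) negbin_loglik(mu, exp(logk), counts),
                  interval = c(log(K_MIN), log(K_CAP)),
                  maximum = TRUE, tol = 1e-8)
  k <- exp(opt$maximum)
  boundary <- opt$maximum <= log(K_MIN) + 1e-6 ||
    opt$maximum >= log(K_CAP) - 1e-6
  new_fit(k, opt$objective, boundary = boundary, degenerate = FALSE)
}

#' @export
print.negbin_fit <- function(x, ...) {
  cat(sprintf(
    "Negative-binomial fit (n = %d): rate of propagation mu = %.3f, dispersion k = %.3g\n",
    x$n, x$mu, x$k))
  cat(sprintf("  log-likelihood %.2f, AIC %.2f%s\n", x$loglik, x$aic,
              if (x$degenerate) " [degenerate: all counts zero]"
              else if (x$boundary) " [k at Poisson boundary]" else ""))
  invisible(x)
}

#' Compare rates of propagation between positive and negative messages
#'
#' Fits the negative binomial separately to each sentiment group and once
#' to the pooled counts, then compares the shared (2-parameter) model with
#' the separate (4-parameter) model: `delta_aic = aic_shared - (aic_pos +
#' aic_neg)` (positive values prefer the separate model) and the
#' likelihood-ratio statistic `2 * (loglik_pos + loglik_neg -
#' loglik_shared)` referred to a chi-square with 2 degrees of freedom (both
#' mean and dispersion sentiment-specific under the separate model).
#'
#' @param counts_pos,counts_neg Retweet counts of positively and negatively
#'   classified messages (each at least 2).
#' @return Object of class `propagation_comparison`: `fit_shared`,
#'   `fit_pos`, `fit_neg`, `delta_aic`, `lr_stat`, `df`, `p`,
#'   `separate_preferred` (`delta_aic > 0`).
#' @export
compare_propagation <- function(counts_pos, counts_neg) {
  if (length(counts_pos) < 2L) stop("positive group has fewer than 2 counts")
  if (length(counts_neg) < 2L) stop("negative group has fewer than 2 counts")
  fit_pos <- fit_negbin(counts_pos)
  fit_neg <- fit_negbin(counts_neg)
  fit_shared <- fit_negbin(c(counts_pos, counts_neg))
  lr <- 2 * (fit_pos$loglik + fit_neg$loglik - fit_shared$loglik)
  delta_aic <- fit_shared$aic - (fit_pos$aic + fit_neg$aic)
  structure(list(
    fit_shared = fit_shared, fit_pos = fit_pos, fit_neg = fit_neg,
    delta_aic = delta_aic, lr_stat = lr, df = 2L,
    p = pchisq(max(lr, 0), df = 2L, lower.tail = FALSE),
    separate_preferred = delta_aic > 0
  ), class = "propagation_comparison")
}

#' @export
print.propagation_comparison <- function(x, ...) {
  cat(sprintf(
    "Rate of propagation: positive mu = %.3f (n = %d), negative mu = %.3f (n = %d)\n",
    x$fit_pos$mu, x$fit_pos$n, x$fit_neg$mu, x$fit_neg$n))
  cat(sprintf(
    "  shared vs separate model: delta AIC = %.2f (%s), LR = %.2f, df = %d, p = %s\n",
    x$delta_aic,
    if (x$separate_preferred) "separate preferred" else "shared preferred",
    x$lr_stat, x$df, format.pval(x$p, digits = 3)))
  invisible(x)
}

#' Exact test for equal Poisson incidence of new messages
#'
#' Under equal Poisson rates of introducing new original messages,
#' conditional on the total `T = n_new_pos + n_new_neg` the positive count
#' is Binomial(`T`, 1/2); the two-sided exact p-value sums the
#' probabilities of all outcomes no more probable than the observed one.
#'
#' @param n_new_pos,n_new_neg Counts of new (original) positive and
#'   negative messages; non-negative, not both zero.
#' @return Object of class `incidence_test`: `n_new_pos`, `n_new_neg`, `p`.
#' @examples
#' incidence_test(5, 5)$p    # 1
#' incidence_test(0, 20)$p   # 2 * (1/2)^20
#' @export
incidence_test <- function(n_new_pos, n_new_neg) {
  n_new_pos <- validate_counts(n_new_pos, "n_new_pos")
  n_new_neg <- validate_counts(n_new_neg, "n_new_neg")
  stopifnot(length(n_new_pos) == 1L, length(n_new_neg) == 1L)
  total <- n_new_pos + n_new_neg
  if (total == 0) stop("both counts are zero; the incidence test is undefined")
  structure(list(n_new_pos = as.integer(n_new_pos),
                 n_new_neg = as.integer(n_new_neg),
                 p = binom.test(n_new_pos, total, p = 0.5)$p.value),
            class = "incidence_test")
}

#' @export
print.incidence_test <- function(x, ...) {
  cat(sprintf(
    "New-message incidence: %d positive vs %d negative, exact two-sided p = %s\n",
    x$n_new_pos, x$n_new_neg, format.pval(x$p, digits = 3)))
  invisible(x)
}
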