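#' Estimate the classified-to-true correction kernel from a confusion table
#'
#' Column `c` of the kernel is the conditional distribution of the manual
#' (true) label given pipeline label `c`, obtained by normalizing column `c`
#' of the held-out confusion table by its sum. A classified label never
#' produced on the test set (zero column sum) falls back to the identity
#' distribution (treated as correctly classified), so the kernel is always
#' column-stochastic.
#'
#' @param confusion 3x3 non-negative integer matrix, rows = manual (true)
#'   label, columns = pipeline (classified) label, in the order positive,
#'   negative, neutral.
#' @return 3x3 column-stochastic matrix `P(true = r | classified = c)`.
#' @examples
#' estimate_kernel(diag(3) * 10)  # perfect classifier -> identity kernel
#' @export
estimate_kernel <- function(confusion) {
  stopifnot(is.matrix(confusion), all(dim(confusion) == 3L))
  if (any(confusion < 0)) stop("confusion table entries must be >= 0")
  if (sum(confusion) == 0) stop("confusion table must have a positive total")
  kernel <- matrix(0, 3L, 3L,
                   dimnames = list(true = SENTIMENTS, classified = SENTIMENTS))
  for (j in 1:3) {
    cs <- sum(confusion[, j])
    kernel[, j] <- if (cs > 0) confusion[, j] / cs else as.numeric(1:3 == j)
  }
  kernel
}

#' Draw corrected true-label counts for one bootstrap replicate
#'
#' Step 2 of the two-step bootstrap: given resampled classified counts,
#' draws a true label for each resampled classification from the kernel
#' column of its classified label, and returns the summed true-label
#' counts. Deterministic when the kernel is the identity.
#'
#' @param classified_counts Length-3 counts (positive, negative, neutral).
#' @param kernel Column-stochastic matrix from [estimate_kernel()].
#' @return Named length-3 integer vector of true-label counts (sums to
#'   `sum(classified_counts)`).
#' @export
draw_true_counts <- function(classified_counts, kernel) {
  counts <- as_sentiment_vector(classified_counts)
  out <- c(0, 0, 0)
  for (j in 1:3) {
    if (counts[j] > 0) {
      out <- out + as.numeric(rmultinom(1L, counts[j], kernel[, j]))
    }
  }
  setNames(as.integer(out), SENTIMENTS)
}

# Vectorized bootstrap engine: returns a 3 x n_boot matrix of corrected
# true-label counts. Step 1 resamples n_total classified labels i.i.d. from
# the observed classified distribution; step 2 relabels each draw through
# the kernel. The per-column multinomial is decomposed into sequential
# binomials so all replicates are drawn at once.
boot_corrected_counts <- function(counts, kernel, n_boot) {
  n_total <- sum(counts)
  cls <- rmultinom(n_boot, n_total, counts / n_total)
  true <- matrix(0, 3L, n_boot)
  for (j in 1:3) {
    sz <- cls[j, ]
    p <- kernel[, j]
    x1 <- rbinom(n_boot, sz, p[1L])
    rem <- sz - x1
    p2 <- if (p[1L] < 1) min(1, p[2L] / (1 - p[1L])) else 0
    x2 <- rbinom(n_boot, rem, p2)
    true <- true + rbind(x1, x2, rem - x2)
  }
  rownames(true) <- SENTIMENTS
  true
}

#' Misclassification-corrected sentiment proportions via the 2-step bootstrap
#'
#' Each replicate (1) resamples `n_total` classified labels with replacement
#' from the observed classified distribution and (2) relabels every
#' resampled classification with a true label drawn from the correction
#' kernel, yielding corrected counts and a corrected negative:positive
#' ratio. The point estimate is the bootstrap median of the replicate
#' ratios, the confidence interval the 2.5/97.5 percentile. Replicates with
#' a zero corrected positive count (infinite ratio) are dropped and
#' reported; if they exceed 1% of replicates the regime is considered
#' unstable and the call aborts with a diagnostic.
#'
#' @param counts Length-3 observed classified counts (positive, negative,
#'   neutral); positive and negative must not both be zero.
#' @param kernel Correction kernel from [estimate_kernel()].
#' @param n_boot Number of bootstrap replicates (default 10000).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return Object of class `ratio_estimate`: `proportions` (mean corrected
#'   proportions), `ratio_point`, `ci_low`, `ci_high`, `n_boot`, `seed`,
#'   `dropped_replicates`, and the replicate ratios in `replicates`.
#' @export
bootstrap_proportions <- function(counts, kernel, n_boot = 10000, seed = 1L) {
  counts <- as_sentiment_vector(counts)
  if (any(counts < 0)) stop("classified counts must be >= 0")
  if (counts["positive"] + counts["negative"] == 0) {
    stop("corpus has no positively or negatively classified messages")
  }
  if (sum(counts) < 1) stop("corpus is empty")
  if (n_boot < 1) stop("`n_boot` must be >= 1")
  true <- with_seed(derive_seed(seed, "bootstrap"),
                    boot_corrected_counts(counts, kernel, n_boot))
  ratio <- true["negative", ] / true["positive", ]
  bad <- true["positive", ] == 0
  if (mean(bad) > 0.01) {
    stop(sprintf(paste0("unstable regime: %.1f%% of bootstrap replicates ",
                        "have zero corrected positive count (limit 1%%)"),
                 100 * mean(bad)))
  }
  keep <- !bad
  ratio <- ratio[keep]
  props <- rowMeans(true[, keep, drop = FALSE] / sum(counts))
  ci <- unname(quantile(ratio, c(0.025, 0.975)))
  structure(list(
    proportions = props,
    ratio_point = median(ratio),
    ci_low = ci[1L], ci_high = ci[2L],
    n_boot = as.integer(n_boot), seed = as.integer(seed),
    dropped_replicates = as.integer(sum(bad)),
    replicates = ratio
  ), class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf(
    "Corrected negative:positive ratio %.2f (95%% CI %.2f-%.2f), %d bootstrap replicates\n",
    x$ratio_point, x$ci_low, x$ci_high, x$n_boot))
  cat(sprintf("Corrected proportions: positive %.3f, negative %.3f, neutral %.3f\n",
              x$proportions["positive"], x$proportions["negative"],
              x$proportions["neutral"]))
  if (x$dropped_replicates > 0) {
    cat(sprintf("(%d replicates with zero positive count dropped)\n",
                x$dropped_replicates))
  }
  invisible(x)
}

#' Two-sided bootstrap test against an equal-proportion null
#'
#' Constructs a null dataset with the observed number of neutral messages
#' but positive and negative counts equalized at `m = (n_pos + n_neg) / 2`
#' (an odd total allocates the extra unit by a fair coin flip per
#' replicate, keeping the null symmetric while preserving the exact total
#' size). Each replicate resamples the full dataset with replacement from
#' the null in ONE step - the null classifications are taken as 100%
#' accurate, so no correction kernel is applied - and records its
#' negative:positive ratio. The two-sided p-value uses the add-one rule
#' `p = min(1, 2 * min(#(ratio >= observed) + 1, #(ratio <= observed) + 1)
#' / (n_boot + 1))`.
#'
#' @param counts Length-3 observed classified counts; positive + negative
#'   must be positive.
#' @param observed_ratio Observed (corrected) negative:positive ratio,
#'   finite and positive.
#' @param n_boot Number of replicates (default 10000).
#' @param seed Integer seed.
#' @return Object of class `null_ratio_test` with elements `p_two_sided`,
#'   `observed_ratio`, `n_boot`, `seed`.
#' @export
null_ratio_test <- function(counts, observed_ratio, n_boot = 10000,
                            seed = 1L) {
  counts <- as_sentiment_vector(counts)
  m2 <- counts["positive"] + counts["negative"]
  if (m2 == 0) stop("corpus has no positively or negatively classified messages")
  if (!is.finite(observed_ratio) || observed_ratio <= 0) {
    stop("`observed_ratio` must be a finite positive number")
  }
  if (n_boot < 1) stop("`n_boot` must be >= 1")
  n_total <- sum(counts)
  n_neu <- counts["neutral"]
  ratio <- with_seed(derive_seed(seed, "null"), {
    m_lo <- floor(m2 / 2)
    extra <- if (m2 %% 2 == 1) rbinom(n_boot, 1L, 0.5) else 0
    m_pos <- m_lo + extra
    m_neg <- m2 - m_pos
    p_pos <- m_pos / n_total
    x_pos <- rbinom(n_boot, n_total, p_pos)
    p_neg_rem <- ifelse(n_total - m_pos > 0, m_neg / (n_total - m_pos), 0)
    x_neg <- rbinom(n_boot, n_total - x_pos, p_neg_rem)
    x_neg / x_pos
  })
  n_ge <- sum(ratio >= observed_ratio, na.rm = TRUE)
  n_le <- sum(ratio <= observed_ratio, na.rm = TRUE)
  p <- min(1, 2 * (min(n_ge, n_le) + 1) / (n_boot + 1))
  structure(list(p_two_sided = p, observed_ratio = observed_ratio,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "null_ratio_test")
}

#' @export
print.null_ratio_test <- function(x, ...) {
  cat(sprintf(
    "Equal-proportion null test: observed ratio %.3f, two-sided p %s (%d replicates)\n",
    x$observed_ratio,
    format.pval(x$p_two_sided, digits = 3), x$n_boot))
  invisible(x)
}
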