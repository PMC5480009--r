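#' Built-in English stopword list
#'
#' A compact list of about 150 English function words excluded from
#' word-frequency rankings (overridable by passing any character vector to
#' [word_frequencies()]).
#'
#' @return Character vector of lowercase stopwords.
#' @export
builtin_stopwords <- function() {
  c("a", "about", "above", "after", "again", "against", "all", "am", "an",
    "and", "any", "are", "as", "at", "be", "because", "been", "before",
    "being", "below", "between", "both", "but", "by", "can", "cannot",
    "could", "did", "do", "does", "doing", "down", "during", "each", "few",
    "for", "from", "further", "get", "got", "had", "has", "have", "having",
    "he", "her", "here", "hers", "herself", "him", "himself", "his", "how",
    "if", "in", "into", "is", "it", "its", "itself", "just", "me", "more",
    "most", "my", "myself", "no", "nor", "not", "now", "of", "off", "on",
    "once", "only", "or", "other", "our", "ours", "ourselves", "out",
    "over", "own", "same", "she", "should", "so", "some", "such", "than",
    "that", "the", "their", "theirs", "them", "themselves", "then",
    "there", "these", "they", "this", "those", "through", "to", "too",
    "under", "until", "up", "very", "was", "we", "were", "what", "when",
    "where", "which", "while", "who", "whom", "why", "will", "with",
    "would", "you", "your", "yours", "yourself", "yourselves", "also",
    "via", "rt", "im", "dont", "cant", "its", "ive", "youre", "us", "it",
    "one", "two", "my", "amp", "may", "might", "must", "shall", "let")
}

#' Modality query terms excluded from frequency rankings
#'
#' The keywords used to collect each modality's messages (and close
#' variants) dominate raw token counts trivially and are always removed
#' from word-frequency tables.
#'
#' @param modality Optional modality name; when omitted, the full named
#'   list is returned.
#' @return Character vector (or named list) of query terms.
#' @export
modality_query_terms <- function(modality = NULL) {
  terms <- list(
    colonoscopy = c("colonoscopy", "colonoscopies"),
    mammography = c("mammogram", "mammograms", "mammography"),
    pap_smear = c("pap", "smear", "smears", "paptest", "papanicolaou")
  )
  if (is.null(modality)) return(terms)
  terms[[match.arg(modality, MODALITIES)]]
}

#' Word-frequency table of original messages for one sentiment
#'
#' Counts tokenized words over messages whose pipeline label matches
#' `sentiment` AND that are original (retweet echoes are excluded from the
#' lexical analysis but retained for propagation). Stopwords and the
#' supplied query terms are removed. The top `top_k` tokens are returned
#' ranked by descending count, ties broken lexicographically.
#'
#' @param tweets Classified corpus data.frame with `text`, `is_original`
#'   and the label column.
#' @param sentiment Sentiment class to tabulate.
#' @param stopwords Tokens to exclude (default [builtin_stopwords()]).
#' @param exclude Additional tokens to exclude (e.g.
#'   [modality_query_terms()]).
#' @param top_k Maximum number of entries (>= 1); if larger than the
#'   vocabulary, the whole vocabulary is returned.
#' @param label_col Name of the label column (default `"label"`).
#' @return Data.frame with columns `sentiment`, `rank`, `token`, `count`
#'   (zero rows when no message matches); attribute `n_docs` gives the
#'   number of contributing messages.
#' @export
word_frequencies <- function(tweets, sentiment,
                             stopwords = builtin_stopwords(),
                             exclude = character(), top_k = 25,
                             label_col = "label") {
  stopifnot(is.data.frame(tweets),
            all(c("text", "is_original", label_col) %in% names(tweets)))
  sentiment <- match.arg(sentiment, SENTIMENTS)
  if (top_k < 1) stop("`top_k` must be >= 1")
  sel <- tweets[[label_col]] == sentiment & tweets$is_original
  empty <- data.frame(sentiment = character(), rank = integer(),
                      token = character(), count = integer(),
                      stringsAsFactors = FALSE)
  if (!any(sel)) {
    attr(empty, "n_docs") <- 0L
    return(empty)
  }
  tokens <- unlist(tokenize(tweets$text[sel]), use.names = FALSE)
  tokens <- tokens[!(tokens %in% stopwords) & !(tokens %in% exclude)]
  if (!length(tokens)) {
    attr(empty, "n_docs") <- sum(sel)
    return(empty)
  }
  tab <- table(tokens)
  ord <- order(-as.integer(tab), names(tab))
  n_keep <- min(top_k, length(tab))
  out <- data.frame(
    sentiment = sentiment,
    rank = seq_len(n_keep),
    token = names(tab)[ord][seq_len(n_keep)],
    count = as.integer(tab)[ord][seq_len(n_keep)],
    stringsAsFactors = FALSE
  )
  attr(out, "n_docs") <- sum(sel)
  out
}

# Convert stage objects into plain lists for the JSON report; absent stages
# are marked rather than failing.
report_block <- function(x) {
  if (is.null(x)) return(list(available = FALSE))
  x
}

#' Assemble stage outputs into a single machine-readable study report
#'
#' Collects, per modality, the classified counts, confusion table and
#' accuracy, corrected proportions with ratio estimate, null-test p-value,
#' propagation comparison, incidence test and frequency tables into one
#' JSON-serializable document. A missing stage is marked
#' `available = FALSE` rather than failing.
#'
#' @param modality_results Named list (one element per modality) of stage
#'   results; each element is a list that may contain `classified_counts`,
#'   `confusion`, `accuracy`, `ratio_estimate`, `null_test`, `propagation`,
#'   `incidence`, `word_frequencies`.
#' @param seed Top-level seed of the run.
#' @param config_echo Optional list echoing the generating configuration.
#' @return Object of class `study_report` (a nested list).
#' @export
build_report <- function(modality_results, seed, config_echo = NULL) {
  stopifnot(is.list(modality_results), length(modality_results) >= 1L,
            !is.null(names(modality_results)))
  stages <- c("classified_counts", "confusion", "accuracy", "ratio_estimate",
              "null_test", "propagation", "incidence", "word_frequencies")
  modalities <- lapply(modality_results, function(res) {
    out <- lapply(stages, function(st) report_block(res[[st]]))
    names(out) <- stages
    out
  })
  structure(list(
    software = list(package = "screensent",
                    version = as.character(packageVersion("screensent"))),
    seed = as.integer(seed),
    config = if (is.null(config_echo)) list(available = FALSE) else config_echo,
    modalities = modalities
  ), class = "study_report")
}

#' Serialize a study report to pretty-printed JSON
#'
#' Serialization is deterministic: the same report writes byte-identical
#' JSON (full numeric precision, no timestamps).
#'
#' @param report A `study_report` (or any JSON-serializable list).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

# Strip non-serializable bulk (bootstrap replicate vectors, fitted count
# vectors) and flatten S3 stage objects into plain lists for the report.
ratio_estimate_block <- function(est) {
  list(proportions = as.list(est$proportions),
       ratio_point = est$ratio_point, ci_low = est$ci_low,
       ci_high = est$ci_high, n_boot = est$n_boot, seed = est$seed,
       dropped_replicates = est$dropped_replicates)
}

negbin_fit_block <- function(fit) {
  list(mu = fit$mu, k = fit$k, loglik = fit$loglik, aic = fit$aic,
       n = fit$n, converged = fit$converged, boundary = fit$boundary,
       degenerate = fit$degenerate)
}

propagation_block <- function(cmp) {
  list(fit_shared = negbin_fit_block(cmp$fit_shared),
       fit_pos = negbin_fit_block(cmp$fit_pos),
       fit_neg = negbin_fit_block(cmp$fit_neg),
       delta_aic = cmp$delta_aic, lr_stat = cmp$lr_stat, df = cmp$df,
       p = cmp$p, separate_preferred = cmp$separate_preferred)
}

#' Run the full synthetic study pipeline
#'
#' End-to-end, per modality: generate the synthetic corpus; take the first
#' `n_labeled` records as the manually labeled pool; split it 75/25
#' stratified by label; train the dual naive Bayes classifiers on the
#' training part; validate on the held-out part (confusion table +
#' accuracy); classify the whole corpus; correct the classified sentiment
#' proportions by the two-step bootstrap; test the corrected ratio against
#' the equal-proportion null; compare rates of propagation
#' (negative-binomial AIC / likelihood ratio); test the incidence of new
#' original messages; and tabulate word frequencies. All randomness derives
#' from `seed`; the same seed yields a byte-identical report.
#'
#' @param configs Named list of [corpus_config()]s (default
#'   [default_study_configs()]).
#' @param seed Top-level integer seed.
#' @param n_labeled Size of the manually labeled pool per modality
#'   (default 500).
#' @param train_fraction Training fraction of the labeled pool (default 0.75).
#' @param n_boot Bootstrap replicates for proportion inference and the null
#'   test (default 10000).
#' @param top_k Entries per word-frequency table (default 10).
#' @param alpha Naive Bayes smoothing (default 1).
#' @return A `study_report`; the underlying per-modality stage objects are
#'   attached in the `"details"` attribute.
#' @export
run_study <- function(configs = default_study_configs(seed = seed),
                      seed = 1L, n_labeled = 500, train_fraction = 0.75,
                      n_boot = 10000, top_k = 10, alpha = 1) {
  stopifnot(is.list(configs), length(configs) >= 1L)
  results <- list()
  details <- list()
  for (mod in names(configs)) {
    config <- configs[[mod]]
    corpus <- generate_corpus(config)
    if (nrow(corpus) < n_labeled) {
      stop("corpus '", mod, "' is smaller than `n_labeled`")
    }
    labeled <- corpus[seq_len(n_labeled), , drop = FALSE]
    split <- split_train_test(labeled, train_fraction,
                              seed = derive_seed(seed, paste0("split/", mod)))
    models <- train_sentiment_classifiers(split$train$text,
                                          split$train$true_sentiment,
                                          alpha = alpha)
    eval <- evaluate_classifier(models, split$test)
    classified <- classify_corpus(models, corpus)
    counts <- classified_counts(classified)
    kernel <- estimate_kernel(eval$confusion)
    est <- bootstrap_proportions(counts, kernel, n_boot = n_boot,
                                 seed = derive_seed(seed, paste0("boot/", mod)))
    null_test <- null_ratio_test(counts, est$ratio_point, n_boot = n_boot,
                                 seed = derive_seed(seed, paste0("null/", mod)))
    prop_cmp <- compare_propagation(
      classified$retweet_count[classified$label == "positive"],
      classified$retweet_count[classified$label == "negative"])
    incid <- incidence_test(
      sum(classified$label == "positive" & classified$is_original),
      sum(classified$label == "negative" & classified$is_original))
    query <- modality_query_terms(config$modality)
    freqs <- lapply(setNames(c("positive", "negative"),
                             c("positive", "negative")),
                    function(s) {
                      word_frequencies(classified, s, exclude = query,
                                       top_k = top_k)
                    })
    results[[mod]] <- list(
      classified_counts = as.list(counts),
      confusion = list(true_labels = SENTIMENTS,
                       classified_labels = SENTIMENTS,
                       counts = unname(apply(eval$confusion, 1L, as.list))),
      accuracy = eval$accuracy,
      ratio_estimate = ratio_estimate_block(est),
      null_test = list(p_two_sided = null_test$p_two_sided,
                       observed_ratio = null_test$observed_ratio,
                       n_boot = null_test$n_boot),
      propagation = propagation_block(prop_cmp),
      incidence = list(n_new_pos = incid$n_new_pos,
                       n_new_neg = incid$n_new_neg, p = incid$p),
      word_frequencies = lapply(freqs, function(f) {
        list(n_docs = attr(f, "n_docs"),
             entries = unname(apply(f, 1L, function(row) {
               list(rank = as.integer(row[["rank"]]),
                    token = row[["token"]],
                    count = as.integer(row[["count"]]))
             })))
      })
    )
    details[[mod]] <- list(models = models, evaluation = eval,
                           classified = classified, kernel = kernel,
                           ratio_estimate = est, null_test = null_test,
                           propagation = prop_cmp, incidence = incid,
                           word_frequencies = freqs)
  }
  config_echo <- lapply(configs, function(cfg) {
    list(n_tweets = cfg$n_tweets, modality = cfg$modality,
         true_proportions = as.list(cfg$true_proportions),
         mix_weight = cfg$mix_weight, tweet_length = cfg$tweet_length,
         retweet_params = cfg$retweet_params,
         arrival_rates = as.list(cfg$arrival_rates), seed = cfg$seed)
  })
  report <- build_report(results, seed = seed, config_echo = config_echo)
  attr(report, "details") <- details
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("screensent study report (seed", x$seed, ")\n")
  for (mod in names(x$modalities)) {
    m <- x$modalities[[mod]]
    if (isFALSE(m$ratio_estimate$available)) {
      cat(sprintf("  %s: stage outputs absent\n", mod))
      next
    }
    cat(sprintf(
      "  %-12s accuracy %.1f%%; corrected neg:pos ratio %.2f (95%% CI %.2f-%.2f, p %s); propagation LR p %s\n",
      mod, 100 * m$accuracy, m$ratio_estimate$ratio_point,
      m$ratio_estimate$ci_low, m$ratio_estimate$ci_high,
      format.pval(m$null_test$p_two_sided, digits = 2),
      format.pval(m$propagation$p, digits = 2)))
  }
  invisible(x)
}
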