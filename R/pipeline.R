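#' Stratified train/test split of manually labeled records
#'
#' Partitions labeled records into disjoint, exhaustive train and test sets,
#' stratified by the manual label so all classes appear on both sides even
#' at small n. Within each stratum of size `n_s`, `round(train_fraction *
#' n_s)` records (clamped to `[1, n_s - 1]`) go to training after a seeded
#' shuffle.
#'
#' @param records Data.frame of labeled records.
#' @param train_fraction Fraction assigned to training, in (0, 1);
#'   default 0.75 (the conventional 75/25 validation split).
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @param label_col Name of the manual-label column.
#' @return List with data.frames `train` and `test`.
#' @export
split_train_test <- function(records, train_fraction = 0.75, seed = 1L,
                             label_col = "true_sentiment") {
  stopifnot(is.data.frame(records), label_col %in% names(records))
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be strictly between 0 and 1")
  }
  if (nrow(records) < 2L) stop("need at least 2 records to split")
  labels <- as.character(records[[label_col]])
  train_idx <- integer(0)
  for (s in sort(unique(labels))) {
    idx <- which(labels == s)
    if (length(idx) < 2L) {
      stop("label stratum '", s, "' has fewer than 2 records")
    }
    n_train <- min(max(round(train_fraction * length(idx)), 1L),
                   length(idx) - 1L)
    shuffled <- with_seed(derive_seed(seed, paste0("split/", s)), sample(idx))
    train_idx <- c(train_idx, shuffled[seq_len(n_train)])
  }
  train_idx <- sort(train_idx)
  list(train = records[train_idx, , drop = FALSE],
       test = records[setdiff(seq_len(nrow(records)), train_idx), ,
                      drop = FALSE])
}

#' Combine the two binary classifier verdicts into one sentiment label
#'
#' Positive-and-nonnegative is labeled positive; negative-and-nonpositive is
#' labeled negative; nonpositive-and-nonnegative is neutral. The (in
#' practice unobserved) both-positive-and-negative case falls back to
#' neutral, the conservative tie rule.
#'
#' @param is_positive,is_negative Logical vectors: verdicts of the
#'   positive-vs-nonpositive and negative-vs-nonnegative classifiers.
#' @return Character vector of `"positive"`, `"negative"`, `"neutral"`.
#' @examples
#' combine_binary(c(TRUE, FALSE, FALSE, TRUE), c(FALSE, TRUE, FALSE, TRUE))
#' @export
combine_binary <- function(is_positive, is_negative) {
  stopifnot(is.logical(is_positive), is.logical(is_negative),
            length(is_positive) == length(is_negative))
  ifelse(is_positive & !is_negative, "positive",
         ifelse(is_negative & !is_positive, "negative", "neutral"))
}

#' Train the dual binary sentiment classifiers
#'
#' Trains two multinomial naive Bayes models on the SAME labeled pool:
#' one dichotomized as positive vs nonpositive, one as negative vs
#' nonnegative. Ties in either model resolve toward its "non" class so that
#' ambiguous messages drift to neutral rather than acquiring polar
#' sentiment.
#'
#' @param texts Character vector of raw training messages.
#' @param labels Manual sentiment labels (`positive`/`negative`/`neutral`).
#' @param alpha Laplace smoothing pseudo-count (default 1).
#' @return An object of class `sentiment_classifiers`: list with `nb_model`s
#'   `positive` and `negative` and the smoothing `alpha`.
#' @export
train_sentiment_classifiers <- function(texts, labels, alpha = 1) {
  labels <- as.character(labels)
  stopifnot(length(texts) == length(labels),
            all(labels %in% SENTIMENTS))
  docs <- tokenize(texts)
  pos <- nb_train(docs, ifelse(labels == "positive", "positive", "nonpositive"),
                  alpha = alpha, tie_class = "nonpositive")
  neg <- nb_train(docs, ifelse(labels == "negative", "negative", "nonnegative"),
                  alpha = alpha, tie_class = "nonnegative")
  structure(list(positive = pos, negative = neg, alpha = alpha),
            class = "sentiment_classifiers")
}

#' Classify a corpus with the dual-classifier scheme
#'
#' Tokenizes each message once, runs both binary models, and combines their
#' verdicts via [combine_binary()].
#'
#' @param models A `sentiment_classifiers` object.
#' @param tweets Corpus data.frame with a `text` column.
#' @return The input data.frame with an added character column `label`.
#' @seealso [classified_counts()]
#' @export
classify_corpus <- function(models, tweets) {
  stopifnot(inherits(models, "sentiment_classifiers"),
            is.data.frame(tweets), "text" %in% names(tweets))
  docs <- tokenize(tweets$text)
  is_pos <- predict(models$positive, docs) == "positive"
  is_neg <- predict(models$negative, docs) == "negative"
  tweets$label <- combine_binary(is_pos, is_neg)
  tweets
}

#' Tally pipeline-classified sentiment counts
#'
#' @param labels Character vector of sentiment labels (or a classified
#'   corpus data.frame with a `label` column).
#' @return Named integer vector (positive, negative, neutral).
#' @export
classified_counts <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  counts <- table(factor(labels, levels = SENTIMENTS))
  setNames(as.integer(counts), SENTIMENTS)
}

#' Validate the classifiers on a held-out labeled test set
#'
#' Produces the 3x3 contingency (confusion) table of manual (rows) versus
#' pipeline (columns) labels, and the overall accuracy (trace / total).
#' This table drives the misclassification correction in
#' [estimate_kernel()].
#'
#' @param models A `sentiment_classifiers` object.
#' @param test Data.frame of held-out records (must be disjoint from
#'   training) with `text` and the manual label column.
#' @param label_col Name of the manual-label column.
#' @return Object of class `classifier_evaluation`: list with `confusion`
#'   (3x3 integer matrix, dimnames `true` x `classified`), `accuracy`, and
#'   `n_test`.
#' @export
evaluate_classifier <- function(models, test, label_col = "true_sentiment") {
  stopifnot(is.data.frame(test), label_col %in% names(test))
  if (nrow(test) == 0L) stop("test set is empty")
  classified <- classify_corpus(models, test)
  confusion <- table(
    true = factor(test[[label_col]], levels = SENTIMENTS),
    classified = factor(classified$label, levels = SENTIMENTS))
  confusion <- matrix(as.integer(confusion), nrow = 3L,
                      dimnames = list(true = SENTIMENTS,
                                      classified = SENTIMENTS))
  structure(list(confusion = confusion,
                 accuracy = sum(diag(confusion)) / sum(confusion),
                 n_test = nrow(test)),
            class = "classifier_evaluation")
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat(sprintf("Held-out validation on %d labeled messages, accuracy %.1f%%\n",
              x$n_test, 100 * x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Read and write 3x3 confusion tables as CSV
#'
#' CSV layout: header row of classified labels, one row per manual (true)
#' label.
#'
#' @param confusion 3x3 integer matrix (rows = true, columns = classified).
#' @param path CSV file path.
#' @return `write_confusion_csv` returns `path` invisibly;
#'   `read_confusion_csv` the matrix.
#' @export
write_confusion_csv <- function(confusion, path) {
  stopifnot(is.matrix(confusion), all(dim(confusion) == 3L))
  write.csv(as.data.frame(confusion), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_confusion_csv
#' @export
read_confusion_csv <- function(path) {
  df <- read.csv(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(true = rownames(m), classified = colnames(m))
  m
}
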