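#' Train a binary multinomial naive Bayes classifier
#'
#' Fits the multinomial event model with Laplace (add-alpha) smoothing over a
#' vocabulary fixed at training time. Class priors are the training class
#' frequencies; the conditional probability of token `t` in class `c` is
#' `(count(t, c) + alpha) / (tokens(c) + alpha * |V|)`.
#'
#' @param docs List of token vectors, as produced by [tokenize()].
#' @param labels Character vector of class labels, exactly two distinct values.
#' @param alpha Positive smoothing pseudo-count (default 1, Laplace).
#' @param tie_class Class returned when the two log-posteriors are exactly
#'   equal. Defaults to the second class in sorted order; the sentiment
#'   pipeline sets it to the "non" (negative-evidence) class so that ties
#'   never manufacture polar sentiment.
#' @return An object of class `nb_model` with elements `classes`,
#'   `log_priors`, `vocabulary`, `log_likelihoods` (2 x |V| matrix, rows =
#'   classes), `alpha`, `tie_class`.
#' @examples
#' m <- nb_train(list(c("good", "good"), "bad"), c("A", "B"), alpha = 1)
#' exp(m$log_likelihoods["A", "good"])  # 3/4
#' @seealso [predict.nb_model()], [nb_write_json()]
#' @export
nb_train <- function(docs, labels, alpha = 1, tie_class = NULL) {
  stopifnot(is.list(docs), length(docs) == length(labels), alpha > 0)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) {
    stop("naive Bayes training requires exactly 2 distinct classes, got ",
         length(classes))
  }
  n_by_class <- table(factor(labels, levels = classes))
  if (any(n_by_class == 0L)) {
    stop("class '", classes[which(n_by_class == 0L)[1L]],
         "' has zero training documents")
  }
  if (is.null(tie_class)) tie_class <- classes[2L]
  stopifnot(tie_class %in% classes)

  vocab <- sort(unique(unlist(docs, use.names = FALSE)))
  v <- length(vocab)
  loglik <- matrix(numeric(0), nrow = 2L, ncol = v,
                   dimnames = list(classes, vocab))
  if (v > 0L) {
    tok <- unlist(docs, use.names = FALSE)
    tok_class <- rep(labels, lengths(docs))
    for (cl in classes) {
      cnt <- tabulate(match(tok[tok_class == cl], vocab), nbins = v)
      loglik[cl, ] <- log(cnt + alpha) - log(sum(cnt) + alpha * v)
    }
  }
  structure(list(
    classes = classes,
    log_priors = setNames(log(as.numeric(n_by_class) / length(labels)), classes),
    vocabulary = vocab,
    log_likelihoods = loglik,
    alpha = alpha,
    tie_class = tie_class
  ), class = "nb_model")
}

#' Score documents under a trained naive Bayes model
#'
#' The log-posterior score of class `c` for a document is
#' `log_prior(c) + sum over in-vocabulary tokens of log P(token | c)`.
#' Out-of-vocabulary tokens are skipped (the vocabulary is fixed at
#' training). The predicted label is the argmax; exact ties go to the
#' model's `tie_class`.
#'
#' @param object An `nb_model`.
#' @param docs List of token vectors.
#' @param type `"class"` for predicted labels, `"score"` for the n x 2
#'   matrix of per-class log-posterior scores.
#' @param ... Unused.
#' @return Character vector of labels, or a numeric score matrix.
#' @export
predict.nb_model <- function(object, docs, type = c("class", "score"), ...) {
  type <- match.arg(type)
  stopifnot(is.list(docs))
  n <- length(docs)
  scores <- matrix(rep(object$log_priors, each = n), nrow = n,
                   dimnames = list(NULL, object$classes))
  lens <- lengths(docs)
  if (n > 0L && sum(lens) > 0L && length(object$vocabulary) > 0L) {
    tok <- unlist(docs, use.names = FALSE)
    doc_of <- rep.int(seq_len(n), lens)
    idx <- match(tok, object$vocabulary)
    keep <- !is.na(idx)
    if (any(keep)) {
      contrib <- rowsum(
        cbind(object$log_likelihoods[1L, idx[keep]],
              object$log_likelihoods[2L, idx[keep]]),
        group = doc_of[keep])
      rows <- as.integer(rownames(contrib))
      scores[rows, 1L] <- scores[rows, 1L] + contrib[, 1L]
      scores[rows, 2L] <- scores[rows, 2L] + contrib[, 2L]
    }
  }
  if (type == "score") return(scores)
  unname(ifelse(scores[, 1L] > scores[, 2L], object$classes[1L],
                ifelse(scores[, 2L] > scores[, 1L], object$classes[2L],
                       object$tie_class)))
}

#' @export
print.nb_model <- function(x, ...) {
  cat("Binary multinomial naive Bayes model\n")
  cat("  classes   :", paste(x$classes, collapse = " vs "),
      sprintf("(tie -> %s)\n", x$tie_class))
  cat("  vocabulary:", length(x$vocabulary), "tokens\n")
  cat("  priors    :", paste(sprintf("%s=%.3f", x$classes, exp(x$log_priors)),
                             collapse = ", "), "\n")
  cat("  smoothing : alpha =", x$alpha, "\n")
  invisible(x)
}

#' Serialize / reload a naive Bayes model as JSON
#'
#' Writes the full model (classes, log-priors, vocabulary, per-class token
#' log-likelihoods, smoothing alpha, tie class) as one JSON document so a
#' trained model can be reloaded and gives identical predictions.
#'
#' @param model An `nb_model`.
#' @param path File path to write to / read from.
#' @return `nb_write_json` returns `path` invisibly; `nb_read_json` returns
#'   the reconstructed `nb_model`.
#' @export
nb_write_json <- function(model, path) {
  stopifnot(inherits(model, "nb_model"))
  payload <- list(
    classes = model$classes,
    log_priors = as.numeric(model$log_priors),
    vocabulary = model$vocabulary,
    log_likelihoods = lapply(seq_along(model$classes), function(i) {
      as.numeric(model$log_likelihoods[i, ])
    }),
    alpha = model$alpha,
    tie_class = model$tie_class
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname nb_write_json
#' @export
nb_read_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- length(p$vocabulary)
  # simplifyVector may return the per-class rows as a 2 x V matrix already
  loglik <- if (is.matrix(p$log_likelihoods)) {
    p$log_likelihoods
  } else {
    matrix(as.numeric(unlist(p$log_likelihoods)), nrow = 2L, ncol = v,
           byrow = TRUE)
  }
  dimnames(loglik) <- list(p$classes, if (v) p$vocabulary else NULL)
  structure(list(
    classes = p$classes,
    log_priors = setNames(as.numeric(p$log_priors), p$classes),
    vocabulary = as.character(p$vocabulary),
    log_likelihoods = loglik,
    alpha = p$alpha,
    tie_class = p$tie_class
  ), class = "nb_model")
}
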