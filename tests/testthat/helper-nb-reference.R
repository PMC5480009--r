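# Independent reference implementation of binary multinomial naive Bayes,
# used as a cross-check oracle. Deliberately written in a different style
# from the package (linear-space probabilities, per-document loops, named
# vectors instead of matrices) so the two routes share no code.

ref_nb_scores <- function(docs, labels, alpha, test_docs) {
  classes <- sort(unique(labels))
  stopifnot(length(classes) == 2L)
  vocab <- sort(unique(unlist(docs)))
  lik <- list()
  for (cl in classes) {
    cnt <- setNames(rep(0, length(vocab)), vocab)
    for (i in seq_along(docs)) {
      if (labels[i] == cl) {
        for (tok in docs[[i]]) cnt[tok] <- cnt[tok] + 1
      }
    }
    lik[[cl]] <- (cnt + alpha) / (sum(cnt) + alpha * length(vocab))
  }
  prior <- c(mean(labels == classes[1]), mean(labels == classes[2]))
  names(prior) <- classes
  scores <- matrix(0, length(test_docs), 2, dimnames = list(NULL, classes))
  for (i in seq_along(test_docs)) {
    for (cl in classes) {
      s <- log(prior[[cl]])
      for (tok in test_docs[[i]]) {
        if (tok %in% vocab) s <- s + log(lik[[cl]][[tok]])
      }
      scores[i, cl] <- s
    }
  }
  scores
}

ref_nb_labels <- function(scores, tie_class) {
  classes <- colnames(scores)
  out <- character(nrow(scores))
  for (i in seq_len(nrow(scores))) {
    if (scores[i, 1] > scores[i, 2]) out[i] <- classes[1]
    else if (scores[i, 2] > scores[i, 1]) out[i] <- classes[2]
    else out[i] <- tie_class
  }
  out
}
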