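#' Default sentiment-loaded and neutral lexicons
#'
#' Small, pairwise-disjoint token sets used by the synthetic corpus
#' generator: a positive-loaded lexicon (benefits of early detection,
#' encouragement), a negative-loaded lexicon (pain, fear, preparation
#' complaints) and a generic neutral vocabulary. All tokens survive
#' [tokenize()] unchanged (lowercase, alphanumeric, length >= 2).
#'
#' @return A list with character vectors `positive`, `negative`, `neutral`.
#' @export
default_lexicons <- function() {
  list(
    positive = c("awareness", "screening", "detection", "early", "prevention",
                 "recommend", "saves", "lives", "health", "healthy", "proud",
                 "brave", "encourage", "benefit", "protect", "grateful",
                 "important", "relief"),
    negative = c("painful", "pain", "hurts", "worried", "fear", "scared",
                 "dread", "awful", "embarrassing", "uncomfortable", "horrible",
                 "anxiety", "prep", "dehydration", "worst", "hate", "nasty",
                 "unpleasant"),
    neutral = c("today", "doctor", "appointment", "week", "year", "time",
                "people", "going", "just", "about", "because", "think",
                "really", "know", "first", "next", "getting", "results",
                "office", "clinic", "nurse", "morning", "afternoon",
                "tomorrow", "yesterday", "family", "friend", "mother",
                "father", "sister", "brother", "insurance", "cost",
                "hospital", "visit", "waiting", "room", "phone", "call",
                "online", "news", "article", "read", "story", "share",
                "talk", "question", "answer", "maybe", "probably", "little",
                "long", "short", "done", "finished", "start", "again",
                "another", "every", "since")
  )
}

# Query term(s) prepended to every synthetic tweet of a modality, mirroring
# keyword-based collection.
modality_prefix <- function(modality) {
  switch(modality,
         colonoscopy = "colonoscopy",
         mammography = "mammogram",
         pap_smear = "pap smear")
}

#' Configuration for one synthetic sub-corpus
#'
#' Describes a modality-specific corpus with known latent sentiment
#' structure: latent per-tweet sentiment drawn from `true_proportions`,
#' lexicon-mixture text, sentiment-specific negative-binomial retweet
#' counts (mean `mu`, dispersion `k`, variance `mu + mu^2/k`), and Poisson
#' arrival of new original tweets.
#'
#' @param n_tweets Non-negative integer, number of records to generate.
#' @param modality One of `"colonoscopy"`, `"mammography"`, `"pap_smear"`.
#' @param true_proportions Length-3 probabilities (positive, negative,
#'   neutral); must sum to 1 within 1e-9.
#' @param lexicons List with disjoint character vectors `positive`,
#'   `negative`, `neutral` (see [default_lexicons()]).
#' @param mix_weight Probability that a token of a positive/negative tweet is
#'   drawn from its sentiment-loaded lexicon rather than the neutral
#'   vocabulary; default 0.4 yields classifiable-but-imperfect corpora.
#' @param tweet_length Mean tokens per tweet (Poisson, floored at 3), not
#'   counting the modality query prefix.
#' @param retweet_params Named list `positive`/`negative`/`neutral`, each a
#'   list with `mu >= 0` and `k > 0`.
#' @param arrival_rates Length-3 non-negative Poisson rates (expected number
#'   of new ORIGINAL tweets per sentiment over the corpus window).
#' @param seed Integer seed; identical configuration and seed reproduce a
#'   byte-identical corpus.
#' @return An object of class `corpus_config`.
#' @export
corpus_config <- function(n_tweets, modality, true_proportions,
                          lexicons = default_lexicons(), mix_weight = 0.4,
                          tweet_length = 12,
                          retweet_params = list(
                            positive = list(mu = 1, k = 0.7),
                            negative = list(mu = 1, k = 0.7),
                            neutral = list(mu = 1, k = 0.7)),
                          arrival_rates = c(positive = 0, negative = 0,
                                            neutral = 0),
                          seed = 1L) {
  if (length(n_tweets) != 1L || n_tweets < 0 || n_tweets != round(n_tweets)) {
    stop("`n_tweets` must be a single non-negative integer")
  }
  modality <- match.arg(modality, MODALITIES)
  true_proportions <- as_sentiment_vector(as.numeric(true_proportions),
                                          "true_proportions")
  if (any(true_proportions < 0) || any(true_proportions > 1)) {
    stop("`true_proportions` entries must lie in [0, 1]")
  }
  if (abs(sum(true_proportions) - 1) > 1e-9) {
    stop("`true_proportions` must sum to 1 (got ",
         format(sum(true_proportions), digits = 12), ")")
  }
  stopifnot(is.list(lexicons), all(SENTIMENTS %in% names(lexicons)))
  for (a in 1:2) for (b in (a + 1):3) {
    overlap <- intersect(lexicons[[SENTIMENTS[a]]], lexicons[[SENTIMENTS[b]]])
    if (length(overlap)) {
      stop("`lexicons` must be pairwise disjoint; '", overlap[1L],
           "' appears in both ", SENTIMENTS[a], " and ", SENTIMENTS[b])
    }
  }
  if (mix_weight < 0 || mix_weight > 1) stop("`mix_weight` must be in [0, 1]")
  if (tweet_length <= 0) stop("`tweet_length` must be positive")
  stopifnot(is.list(retweet_params), all(SENTIMENTS %in% names(retweet_params)))
  for (s in SENTIMENTS) {
    p <- retweet_params[[s]]
    if (is.null(p$mu) || p$mu < 0) {
      stop("`retweet_params$", s, "$mu` must be >= 0")
    }
    if (is.null(p$k) || p$k <= 0) {
      stop("`retweet_params$", s, "$k` must be > 0")
    }
  }
  arrival_rates <- as_sentiment_vector(as.numeric(arrival_rates),
                                       "arrival_rates")
  if (any(arrival_rates < 0)) stop("`arrival_rates` must be >= 0")
  structure(list(
    n_tweets = as.integer(n_tweets), modality = modality,
    true_proportions = true_proportions, lexicons = lexicons,
    mix_weight = mix_weight, tweet_length = tweet_length,
    retweet_params = retweet_params, arrival_rates = arrival_rates,
    seed = as.integer(seed)
  ), class = "corpus_config")
}

#' Sample negative-binomial retweet counts
#'
#' Draws from the negative binomial with mean `mu` and dispersion `k`
#' (variance `mu + mu^2/k`); `k -> Inf` recovers the Poisson, small `k`
#' models heterogeneous "superspreading" of messages.
#'
#' @param mu Mean retweets per message, `>= 0` (`mu = 0` gives all zeros).
#' @param k Dispersion, `> 0`.
#' @param n Number of draws.
#' @param seed Optional integer; when supplied the draw is made on an
#'   isolated, reproducible stream.
#' @return Integer vector of `n` non-negative counts.
#' @export
sample_retweet_counts <- function(mu, k, n, seed = NULL) {
  if (mu < 0) stop("`mu` must be >= 0")
  if (k <= 0) stop("`k` must be > 0")
  if (n < 0 || n != round(n)) stop("`n` must be a non-negative integer")
  draw <- function() {
    if (mu == 0) integer(n) else as.integer(rnbinom(n, size = k, mu = mu))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Generate a synthetic tweet corpus with known latent sentiment
#'
#' Produces exactly `n_tweets` records. Each record's latent sentiment is
#' drawn from `true_proportions`; its text is the modality query term
#' followed by tokens drawn i.i.d. from a mixture of the sentiment's loaded
#' lexicon (weight `mix_weight`) and the neutral vocabulary; its retweet
#' count comes from the sentiment's negative binomial. Within each
#' sentiment, the number of ORIGINAL tweets is `min(group size,
#' Poisson(arrival_rate))`, assigned to a uniformly chosen subset; the
#' remaining records represent retweet echoes of circulating messages.
#'
#' @param config A [corpus_config()].
#' @return A data.frame with columns `id`, `text`, `modality`,
#'   `retweet_count`, `is_original`, `true_sentiment`.
#' @examples
#' cfg <- corpus_config(5, "colonoscopy", c(1, 0, 0), seed = 7)
#' generate_corpus(cfg)$true_sentiment
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  n <- config$n_tweets
  if (n == 0L) {
    return(data.frame(id = character(), text = character(),
                      modality = character(), retweet_count = integer(),
                      is_original = logical(), true_sentiment = character(),
                      stringsAsFactors = FALSE))
  }
  seed <- config$seed
  sent <- with_seed(derive_seed(seed, "sentiment"),
                    sample(SENTIMENTS, n, replace = TRUE,
                           prob = config$true_proportions))
  lens <- with_seed(derive_seed(seed, "length"),
                    pmax(3L, rpois(n, config$tweet_length)))
  text <- with_seed(derive_seed(seed, "tokens"), {
    total <- sum(lens)
    tok_sent <- rep(sent, lens)
    loaded <- runif(total) < ifelse(tok_sent == "neutral", 0, config$mix_weight)
    tokens <- character(total)
    for (s in c("positive", "negative")) {
      sel <- loaded & tok_sent == s
      if (any(sel)) {
        tokens[sel] <- sample(config$lexicons[[s]], sum(sel), replace = TRUE)
      }
    }
    if (any(!loaded)) {
      tokens[!loaded] <- sample(config$lexicons$neutral, sum(!loaded),
                                replace = TRUE)
    }
    body <- vapply(split(tokens, factor(rep(seq_len(n), lens),
                                        levels = seq_len(n))),
                   paste, character(1L), collapse = " ")
    paste(modality_prefix(config$modality), body)
  })
  retweets <- integer(n)
  for (s in SENTIMENTS) {
    idx <- which(sent == s)
    if (length(idx)) {
      p <- config$retweet_params[[s]]
      retweets[idx] <- sample_retweet_counts(
        p$mu, p$k, length(idx), seed = derive_seed(seed, paste0("retweets/", s)))
    }
  }
  is_original <- logical(n)
  for (s in SENTIMENTS) {
    idx <- which(sent == s)
    if (length(idx)) {
      n_orig <- with_seed(derive_seed(seed, paste0("arrivals/", s)),
                          min(length(idx), rpois(1L, config$arrival_rates[[s]])))
      if (n_orig > 0L) {
        chosen <- with_seed(derive_seed(seed, paste0("originals/", s)),
                            sample(idx, n_orig))
        is_original[chosen] <- TRUE
      }
    }
  }
  data.frame(
    id = sprintf("%s-%06d", config$modality, seq_len(n)),
    text = text,
    modality = config$modality,
    retweet_count = retweets,
    is_original = is_original,
    true_sentiment = sent,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Study-regime corpus configurations for the three screening modalities
#'
#' Returns the package's default synthetic study: three modality sub-corpora
#' whose latent structure mirrors the qualitative regime of public
#' screening discourse. Colonoscopy skews negative (true negative:positive
#' ratio 1.67) with negative messages both arriving more often and
#' propagating more; mammography skews positive (ratio 0.44) but its few
#' negative messages propagate more; Pap smear is symmetric in proportions,
#' propagation and arrivals. Retweet dispersion is `k = 0.7` throughout
#' (strongly overdispersed), and roughly 45% of records are original tweets.
#'
#' @param n_tweets Records per modality sub-corpus (default 3000).
#' @param seed Top-level integer seed; each sub-corpus gets a derived
#'   sub-seed.
#' @return Named list of three [corpus_config()] objects.
#' @export
default_study_configs <- function(n_tweets = 3000, seed = 1L) {
  regime <- list(
    colonoscopy = list(
      props = c(positive = 0.12, negative = 0.20, neutral = 0.68),
      mu = c(positive = 0.5, negative = 2.0, neutral = 1.0),
      orig_frac = c(positive = 0.35, negative = 0.55, neutral = 0.45)),
    mammography = list(
      props = c(positive = 0.25, negative = 0.11, neutral = 0.64),
      mu = c(positive = 0.5, negative = 2.0, neutral = 1.0),
      orig_frac = c(positive = 0.55, negative = 0.35, neutral = 0.45)),
    pap_smear = list(
      props = c(positive = 0.15, negative = 0.15, neutral = 0.70),
      mu = c(positive = 1.0, negative = 1.0, neutral = 1.0),
      orig_frac = c(positive = 0.45, negative = 0.45, neutral = 0.45))
  )
  configs <- lapply(names(regime), function(mod) {
    r <- regime[[mod]]
    corpus_config(
      n_tweets = n_tweets, modality = mod, true_proportions = r$props,
      retweet_params = lapply(setNames(SENTIMENTS, SENTIMENTS), function(s) {
        list(mu = unname(r$mu[s]), k = 0.7)
      }),
      arrival_rates = r$orig_frac * r$props * n_tweets,
      seed = derive_seed(seed, paste0("corpus/", mod))
    )
  })
  names(configs) <- names(regime)
  configs
}

#' Read and write corpora as JSON Lines
#'
#' One record per line with the `TweetRecord` fields (`id`, `text`,
#' `modality`, `retweet_count`, `is_original`, and `true_sentiment` when
#' present), UTF-8.
#'
#' @param corpus Corpus data.frame.
#' @param path File path.
#' @return `write_corpus_jsonl` returns `path` invisibly; `read_corpus_jsonl`
#'   returns the corpus data.frame.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  stopifnot(is.data.frame(corpus))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(corpus)) {
    jsonlite::stream_out(corpus, con, verbose = FALSE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  jsonlite::stream_in(con, verbose = FALSE)
}

#' Write the latent-truth companion table of a synthetic corpus
#'
#' @param corpus Corpus data.frame containing `id` and `true_sentiment`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(corpus, path) {
  stopifnot(all(c("id", "true_sentiment") %in% names(corpus)))
  write.csv(corpus[, c("id", "true_sentiment")], path, row.names = FALSE)
  invisible(path)
}
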