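# screensent

Public reluctance toward cancer screening is hard to measure with surveys:
they are slow, expensive, and constrain what respondents can say. Short
social-media posts about colonoscopy, mammography and Pap smear offer a
large, continuously refreshed record of how these interventions are
actually talked about. `screensent` is an R package for analysts of such
corpora: it classifies message sentiment, corrects the resulting
proportions for classifier error, and models how positive and negative
messages spread.

## What it computes

**Sentiment classification.** Two binary multinomial naive Bayes
classifiers (Laplace smoothing, bag-of-words over a tokenizer that strips
URLs, mentions and hashtag marks) are trained on one manually labeled
pool: positive-vs-nonpositive and negative-vs-nonnegative. Their verdicts
combine to a three-way label: positive ∧ nonnegative → *positive*,
negative ∧ nonpositive → *negative*, otherwise *neutral*.

**Misclassification-corrected proportions.** A held-out 3×3 contingency
table of manual × pipeline labels is column-normalized into a correction
kernel K, with K[r, c] = P(true = r | classified = c). A two-step
bootstrap then (1) resamples the observed classified labels with
replacement and (2) redraws a true label for every resampled
classification from K, yielding the corrected negative:positive ratio
θ = p̂neg / p̂pos with a percentile 95% CI. A constructed null dataset —
same size, same neutral count, positive and negative equalized — gives a
two-sided bootstrap p-value for θ ≠ 1.

**Propagation.** The *rate of propagation* is the mean number of retweets
per message, the message-spread analogue of an effective reproduction
number. Retweet counts are modelled as negative binomial with mean μ and
dispersion k (variance μ + μ²/k); μ̂ is the sample mean (exact MLE) and k̂
maximizes the profile likelihood. Positive and negative groups are
compared by ΔAIC and the likelihood-ratio statistic 2·(ℓpos + ℓneg −
ℓshared) ~ χ²(2). The incidence of *new* (original) messages is compared
by the exact binomial test: conditional on the total, the positive count
is Binomial(T, ½) under equal Poisson rates.

**Synthetic corpora.** Because real tweet streams are ephemeral, the
package ships a seeded generator (`generate_corpus`, `default_study_configs`)
with known latent sentiment proportions, lexicon-mixture text,
negative-binomial retweet counts and Poisson arrivals of original tweets,
so every stage is validated by parameter recovery.

## Worked example

```r
library(screensent)
report <- run_study(configs = default_study_configs(n_tweets = 3000, seed = 1L),
                    seed = 1L, n_boot = 10000)
print(report)
#> screensent study report (seed 1 )
#>   colonoscopy  accuracy 97.6%; corrected neg:pos ratio 1.60 (95% CI 1.42-1.82, p 2e-04); propagation LR p <2e-16
#>   mammography  accuracy 98.4%; corrected neg:pos ratio 0.44 (95% CI 0.38-0.49, p 2e-04); propagation LR p <2e-16
#>   pap_smear    accuracy 98.4%; corrected neg:pos ratio 1.08 (95% CI 0.95-1.23, p 0.25); propagation LR p 0.2

d <- attr(report, "details")
print(d$colonoscopy$propagation)
#> Rate of propagation: positive mu = 0.467 (n = 368), negative mu = 2.165 (n = 581)
#>   shared vs separate model: delta AIC = 163.85 (separate preferred), LR = 167.85, df = 2, p = <2e-16
print(d$colonoscopy$incidence)
#> New-message incidence: 140 positive vs 316 negative, exact two-sided p = <2e-16
```

Reading this: in the default synthetic regime, colonoscopy messages are
about 1.6× more likely to be negative than positive after correcting for
classifier error (the CI excludes 1, null-test p = 2e-04), and negative
messages both arrive more often (316 vs 140 originals) and propagate more
(μ̂ 2.17 vs 0.47 retweets/message; the separate-rates model is strongly
preferred). Mammography shows the mirror-image proportion imbalance while
negative messages still spread more; Pap smear is symmetric on both axes.

Individual stages are available as plain functions — `tokenize()`,
`nb_train()`/`predict()`, `split_train_test()`, `classify_corpus()`,
`evaluate_classifier()`, `estimate_kernel()`, `bootstrap_proportions()`,
`null_ratio_test()`, `fit_negbin()`, `compare_propagation()`,
`incidence_test()`, `word_frequencies()` — and a thin CLI wrapper lives in
`inst/cli/screensent.R` (`simulate` and `run` subcommands).

## Vignette

`vignettes/screening-sentiment-methods.Rmd` documents the statistical
methods, the generator's design and defaults, numerical choices and known
limitations.
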