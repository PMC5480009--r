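---
title: "Methods: sentiment classification, corrected proportions and propagation of cancer-screening messages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sentiment classification, corrected proportions and propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screensent)
```

`screensent` analyses short social-media messages about cancer-screening
interventions (colonoscopy, mammography, Pap smear) along two axes: *what*
sentiment the public expresses, and *how* that sentiment spreads. This
vignette documents the statistical machinery, the tunable parameters, the
synthetic-data design, and the numerical choices, so that results can be
interpreted — and distrusted — correctly.

## 1. The two-classifier labeling scheme

Messages are labeled positive, negative or neutral by combining two
binary multinomial naive Bayes classifiers trained on the same manually
labeled pool: one distinguishing positive from nonpositive, one negative
from nonnegative. The combination rule is

* positive ∧ nonnegative → **positive**
* negative ∧ nonpositive → **negative**
* nonpositive ∧ nonnegative → **neutral**
* positive ∧ negative → **neutral** (a tie rule; with sensible training
  data this case does not occur, and in each binary model an exact
  log-posterior tie already resolves to the "non" class, so ambiguity
  never manufactures polar sentiment).

Each binary model is the standard multinomial event model: class priors
are training frequencies; the probability of token $t$ in class $c$ is
$(n_{tc} + \alpha) / (n_c + \alpha |V|)$ with Laplace smoothing $\alpha =
1$ by default. The vocabulary is fixed at training; unseen tokens are
skipped at prediction rather than smoothed in, so a message with no known
tokens is decided by the priors. Tokenization lowercases, removes URLs
and @-mentions, strips `#` from hashtags, splits on non-alphanumeric runs
and drops single-character tokens. These are deliberate, conventional
choices for short informal text; the package does not attempt n-grams,
negation scoping or emoji handling, so sarcasm and negated phrases
("not painful at all") are systematically misread — a real limitation of
bag-of-words sentiment analysis.

The labeled pool is split 75/25 into training and held-out validation,
stratified by manual label so all three classes appear on both sides even
with few labeled messages (strata with fewer than two records are
rejected). Within each stratum of size $n_s$, $\mathrm{round}(0.75\,
n_s)$ records (clamped to leave at least one on each side) are assigned to
training after a seeded shuffle.

## 2. Misclassification-corrected proportions

Raw classified counts are biased by classifier error. The held-out
validation produces a 3×3 contingency table $C$ of manual (rows) ×
pipeline (columns) labels; column-normalizing $C$ gives the correction
kernel $K_{rc} = \widehat{P}(\text{true}=r \mid \text{classified}=c)$.
The direction of conditioning matters: the kernel relabels *classified*
draws with *true* labels, which is exactly the operation the two-step
bootstrap needs. A pipeline label never produced on the validation set
(zero column) falls back to the identity distribution, i.e. is taken at
face value.

The two-step bootstrap then repeats, `n_boot` times (default 10,000):

1. resample $n$ classified labels i.i.d. from the observed classified
   distribution;
2. for each resampled label $c$, draw a true label from $K_{\cdot c}$;
3. record the replicate's corrected negative:positive ratio.

The point estimate is the bootstrap **median** (the replicate ratio is
right-skewed, and the median is insensitive to that skew; the plug-in
corrected ratio is an equally defensible estimator and agrees closely at
study sizes), and the 95% CI is the 2.5/97.5 percentile interval.
Replicates with zero corrected positives have an infinite ratio; they are
dropped and counted, and if they exceed 1% of replicates the regime is
deemed unstable and the computation aborts with a diagnostic rather than
reporting a quietly truncated interval.

Significance of the ratio uses a *constructed null*: a dataset with the
same total size and the same neutral count, but positive and negative
equalized at $m = (n_{pos} + n_{neg})/2$. When $n_{pos} + n_{neg}$ is
odd, the extra unit is allocated positive or negative by a fair coin flip
independently per replicate, preserving the exact total while keeping the
null symmetric. Null classification is treated as perfectly accurate, so
resampling is one-step (no kernel). The two-sided p-value uses the
add-one rule $p = \min\!\big(1,\; 2\,(\min(\#\{\hat\theta^* \ge
\theta\}, \#\{\hat\theta^* \le \theta\}) + 1)/(B + 1)\big)$, so $p$ is
never exactly zero. Because the null resampling does not propagate kernel
estimation noise (the null is assumed perfectly classified), this test is
mildly anticonservative when the validation set is small relative to the
corpus; the type-I calibration check in the test suite runs in the
perfectly-classified regime the construction assumes.

## 3. Propagation as a contagion analogue

The *rate of propagation* is the mean number of retweets per message —
the analogue of an effective reproduction number for information spread.
Retweet counts are heavily overdispersed (a few messages spread widely,
most not at all), so each sentiment group is modelled as negative
binomial with mean $\mu$ and dispersion $k$, variance $\mu + \mu^2/k$;
$k \to \infty$ recovers the Poisson and small $k$ means heterogeneous
"superspreading".

Fitting exploits the fact that the NB mean MLE is the sample mean
regardless of $k$, leaving a 1-D profile likelihood in $k$, maximized by
bounded golden-section search over $\log k \in [\log 10^{-4}, \log
10^6]$ (tolerance $10^{-8}$). Samples with variance at or below the mean
have their profile supremum at $k = \infty$; they are reported at the cap
$k = 10^6$ and flagged `boundary`. An all-zero sample is flagged
`degenerate` with $\mu = 0$ and log-likelihood 0.

Groups are compared by fitting positive, negative, and pooled counts:
$\Delta\mathrm{AIC} = \mathrm{AIC}_{shared} - (\mathrm{AIC}_{pos} +
\mathrm{AIC}_{neg})$ (positive values prefer separate rates) and the LR
statistic $2(\ell_{pos} + \ell_{neg} - \ell_{shared})$ referred to
$\chi^2_2$ — two degrees of freedom because the separate model frees both
$\mu$ and $k$ per group. Freeing only $\mu$ (df = 1) is a defensible
alternative nesting; df = 2 is the conservative choice consistent with
fitting both parameters per group, and both AIC and LR views are always
reported together.

The incidence of *new* messages assumes original tweets of each sentiment
arrive as independent Poisson processes. Conditional on the total $T$,
the positive count is $\mathrm{Binomial}(T, 1/2)$ under equal rates, and
the p-value is the exact two-sided binomial tail (sum of outcome
probabilities not exceeding the observed outcome's), via
`stats::binom.test`. This is exact at small counts, where a Wald Poisson
comparison would misbehave.

## 4. The synthetic corpus generator

Real tweet streams are ephemeral and cannot be redistributed, so the
package validates itself on synthetic corpora with known latent
structure. Each record draws a latent sentiment from configured
proportions; its text is the modality query term (mirroring
keyword-based collection) followed by $\max(3, \mathrm{Poisson}(L))$
tokens, each drawn from the sentiment's loaded lexicon with probability
$w$ and from the neutral vocabulary otherwise; its retweet count is
negative binomial with sentiment-specific $(\mu, k)$; and within each
sentiment group, $\min(n_s, \mathrm{Poisson}(\lambda_s))$ records are
flagged as original tweets (the rest represent retweet echoes of
circulating messages). Defaults: $w = 0.4$, $L = 12$ tokens, lexicons of
18 loaded words per polar sentiment against a 60-word neutral
vocabulary, pairwise disjoint by construction.

One top-level seed drives everything; every stage (sentiment draws,
token draws, retweet draws, splits, bootstraps) runs on a sub-stream
derived deterministically from the seed and a stage name, so identical
configuration and seed reproduce byte-identical corpora and reports
without coupling unrelated stages.

`default_study_configs()` encodes the package's reference regime at 3000
tweets and 500 labeled records per modality (labeled pools of a few
hundred per modality are what a single investigator can realistically
annotate; the 75/25 split then validates on ~125): colonoscopy with true
proportions (0.12, 0.20, 0.68) — a true negative:positive ratio of 1.67 —
and negative messages both arriving more often and propagating more
($\mu_{neg} = 2.0$ vs $\mu_{pos} = 0.5$); mammography with proportions
(0.25, 0.11, 0.64) — ratio 0.44 — where negative messages are rarer but
still propagate more; and Pap smear symmetric on every axis
(proportions 0.15/0.15/0.70, all $\mu = 1$). Dispersion is $k = 0.7$
throughout, and arrival rates make roughly 45% of records original with
the per-sentiment imbalances just described.

**What the generator does not emulate.** Token draws are i.i.d. given the
sentiment — no syntax, negation, sarcasm, or topic drift — and the loaded
lexicons are disjoint from the neutral vocabulary. A consequence worth
stating plainly: with ~12-token messages, almost every polar message
contains at least one perfectly diagnostic token, so held-out accuracy on
synthetic corpora is in the mid-to-high 90s — cleaner than the ~80%
typical of real short-text sentiment pipelines. Passing tests therefore
demonstrate the *correctness of the machinery* (estimators recover known
parameters, intervals cover, tests calibrate), not the field accuracy of
naive Bayes on real tweets. The correction kernel, in particular, is
exercised hardest not by the generator's clean corpora but by the test
suite's explicit misclassification matrices (~80% accuracy, errors
concentrated polar↔neutral, no positive↔negative reversal).

## 5. Numerical and degenerate-input choices

* Proportions must sum to 1 within $10^{-9}$; kernel columns are
  stochastic within $10^{-9}$.
* Dispersion search bracketed in $[10^{-4}, 10^6]$; $k$ within $10^{-6}$
  (log scale) of a bracket end is flagged `boundary`.
* The LR statistic is clamped at 0 for the $\chi^2$ tail (nesting
  guarantees non-negativity up to optimizer tolerance $\sim 10^{-6}$).
* Word-frequency ties break lexicographically; only original messages
  count, and stopwords (a built-in ~150-word function-word list,
  overridable) plus the modality query terms are excluded — the query
  terms appear in essentially every collected message and would
  trivially dominate.
* Empty test sets, single-class training pools, all-neutral corpora, and
  degenerate kernels are rejected with messages naming the offending
  input rather than propagating NaNs.
* Reports are pretty-printed JSON at full numeric precision with no
  timestamps, so a fixed seed yields byte-identical files.

## 6. Problem sizes used in validation

The test suite validates at sizes chosen to make Monte Carlo noise
negligible relative to the tolerance being asserted: classifier oracle
equivalence on 100 random mini-corpora ($\le$ 10 documents each);
exhaustive enumeration of all $5^5$ resamples of a 5-message corpus
against closed-form multinomial probabilities; interval coverage over
300 simulated pipelines (2000-message corpora, 1000 bootstrap
replicates); null-test calibration over 500 null corpora; propagation
power and type-I over 100 + 200 simulations at 2000 counts per group;
and 50 end-to-end studies at the reference regime for the qualitative
directionality of all three modalities. The full suite runs in a few
minutes on one CPU.

## 7. Known limitations

* Bag-of-words naive Bayes misreads negation and sarcasm; the package is
  faithful to that method, not a fix for it.
* The correction kernel is estimated from a one-shot validation set; its
  sampling noise is not propagated into the bootstrap CI, which can
  undercover when the validation set is very small relative to the
  corpus.
* The null-ratio test assumes perfectly classified null data by
  construction.
* The propagation model treats retweet counts as i.i.d. within group —
  no follower-graph structure, no cascades, no time dynamics.
* Synthetic corpora are a validation instrument, not a simulation of
  Twitter; see §4.
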