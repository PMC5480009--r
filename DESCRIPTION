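Package: screensent
Title: Sentiment Classification and Propagation Analysis of Cancer-Screening Microblog Posts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for characterizing public sentiment toward cancer-screening
    interventions (colonoscopy, mammography, Pap smear) in short social-media
    messages. Implements a from-scratch multinomial naive Bayes tokenizer and
    classifier pair (positive-vs-nonpositive and negative-vs-nonnegative,
    combined into positive/negative/neutral labels), misclassification-corrected
    estimation of sentiment proportions via a two-step bootstrap with percentile
    confidence intervals and a constructed equal-proportion null test,
    contagion-style negative-binomial modelling of message propagation with
    AIC and likelihood-ratio comparison, an exact Poisson-rate test for the
    incidence of new messages, word-frequency reporting, and a seeded synthetic
    corpus generator so the whole pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
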