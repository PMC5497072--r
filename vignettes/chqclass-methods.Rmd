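---
title: "Methods: classifying Chinese consumer health questions"
author: "chqclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying Chinese consumer health questions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chqclass)
```

## The problem

Health questions posted online by laypeople are short, noisy, written
through a site template, and frequently bundle several information needs
("what disease is this, and what should I take for it?"). A question
answering system needs the *topic* of such a question before it can narrow
its answer search. `chqclass` classifies Chinese consumer health questions
(the bundled vocabulary targets hypertension) into six primary topics —
Diagnosis, Treatment, Condition management, Epidemiology, Healthy
lifestyle, Health provider choice — plus a residual Other, treating the
task as multi-label: one question may carry several topics.

## Question extraction

Messages written through the website template end with a "what kind of
help do you want" field (`想得到怎样的帮助`). `extract_question()` takes
everything after the *last* occurrence of the marker, strips one leading
colon (ASCII or fullwidth) and surrounding whitespace, and falls back to
the whole message when the marker is absent (or nothing follows it). The
suffix rule is deliberate: the field is the last of the three template
fields, and suffix capture needs no sentence segmenter, so the rule is
fully deterministic. An optional exclusion-term filter
(`filter_exclusion_terms()`) can drop messages that merely *look* relevant
(高压氧, 高压舱, 高压电, 高压锅 — hyperbaric oxygen and friends); it is off
by default because such filtering is a corpus-curation judgement, not part
of the classifier.

## Tokenization

All feature extractors work on tokenized questions. Segmentation and POS
tagging sit behind a pluggable contract (`tokenize_question(segmenter =)`),
so a statistical CJK segmenter can be swapped in for production use. The
bundled fallback is greedy forward maximum matching over a term dictionary
(longest dictionary term at each position, single characters otherwise),
with dictionary POS lookup and a small tagset: `n` noun, `v` verb, `int`
interrogative, `m` numeral, `x` unknown. Interrogative-list membership
takes precedence over the POS dictionary, because the grammatical chunk
features are *defined* relative to interrogative positions. Offsets are
0-based half-open Unicode code-point spans — the only unambiguous
convention for CJK text. The bundled interrogative list (42 entries, 什么 /
怎么 / 为什么 / 哪 / 几 / 多少 / 吗 / 是不是 …) is a reconstruction of the
common Chinese interrogatives and is fully configurable.

## Feature families

Seventeen families, all binary presence indicators except the statistical
family:

| group | families |
|---|---|
| lexical | `bow`; `pos` keyed `surface/tag` |
| grammatical | `interrogative`; noun/verb head and rear chunks; 4 combinations |
| semantic | `concept`, `semantic_type` from the medical lexicon |
| lexical–statistical | `keyword_tf`, `keyword_idf`, `keyword_tfidf` |
| statistical | 13 real-valued summaries |

Chunks anchor at the **first** interrogative word: the head chunk is the
first noun (or verb) after it, the rear chunk the last noun (or verb)
before it. Combination keys encode Chinese word order — `q|chunk` for
interrogative+head, `chunk|q` for rear+interrogative. When a question has
no interrogative token, the grammatical families are simply absent. `pos`
features key on the (surface, tag) pair rather than the bare tag: the pair
space is strictly richer than the bag-of-words space, which matches the
observation that a POS family can outnumber the word family.

Numerical conventions, each isolated behind one function so a different
dialect can be substituted:

* `tf(t) = count(t) / L` for a question of `L` tokens — normalising by
  length makes the max/mean TF statistics comparable across questions;
* `idf(t) = ln(N / df(t))`, natural log, no smoothing, `df` floored at 1
  for terms unseen in the background corpus;
* keyword count `k = min(10, ceil(L / 10))` — the only property we commit
  to is monotonicity in question length, and at the observed average length
  of consumer questions (~48 words) it yields 5 keywords; both constants
  are arguments of `keyword_count()`;
* keyword ties are broken by earlier first occurrence in the question,
  then lexicographically — deterministic and favouring the words the asker
  led with.

## Φ-score feature selection

For one feature with values split into n⁺ positive and n⁻ negative
training instances,

$$\Phi = \frac{(\bar x^+ - \bar x)^2 + (\bar x^- - \bar x)^2}
            {s^2_+ + s^2_-}$$

with overall mean $\bar x$ and within-class *sample* variances (divisor
n−1). Degenerate cases: if both classes are constant but their means
differ, the feature separates perfectly and receives the sentinel `+Inf`
(always selected, excluded from threshold means, since averaging an
infinity is meaningless); if the whole column is constant, it carries no
information and scores 0.

Selection is per *type*: each family's threshold is the mean Φ of its own
features, and features with Φ ≥ that mean (inclusive, so a family of
identical scores keeps everything) survive. The per-type threshold matters
because Φ magnitudes differ by two orders of magnitude between families —
a single global threshold would annihilate the bag-of-words family while
keeping every statistical feature. A useful consequence, covered by a
property test: every non-empty family keeps at least its best feature.

Φ is computed on the balanced training split of each binary task, and —
inside cross-validation — on the nine training folds only. Recomputing
selection per fold is the leakage-safe default (`select_features` on a full
sample is still available for whole-sample reporting); the test suite
asserts that permuting a held-out fold's labels cannot change the features
selected from the training folds.

## Classification and evaluation

One binary classifier per topic (one-vs-rest); a question receives every
topic whose classifier fires, and `Other` exactly when none does. The
default classifier is a linear-kernel SVM with C = 1 (via e1071/libsvm) —
the algorithm family that consistently wins on this task — with naive
Bayes and logistic-regression baselines behind the same contract. No
hyperparameter search is performed.

Class skew is severe (the rarest topic is ~2% of questions), so each
binary task is balanced by under-sampling the majority class — whichever
class that is; for a prevalent topic the *positives* are the majority — to
the minority's size, keeping the minority verbatim. Evaluation is 10-fold
cross-validation. Fold assignment is a random permutation dealt
round-robin, *stratified by label*: each class is dealt separately with
rotated fold offsets, so every fold tests on a near-equal number of
positives and negatives while fold sizes still differ by at most one (272
balanced instances give two folds of 28 and eight of 27). Stratification
is what keeps the balanced-train/balanced-test property true per fold; on
very small balanced tasks an unstratified fold can contain no positive at
all, where the zero-denominator convention would score even a perfect
classifier 0.

Metrics: `p = tp/(tp+fp)`, `r = tp/(tp+fn)`, `F1 = 2pr/(p+r)`, each 0 when
its denominator is 0. Macro averages are unweighted means over the six
topics (macro-F1 is the mean of per-topic F1s, *not* the harmonic mean of
macro-p and macro-r). Because fold means of topic means and topic means of
fold means coincide for equal-weight folds only, the report keeps both the
per-fold values and their mean/sd per topic, and computes the macro row
from the per-topic means.

Annotation agreement uses kappa `(Po − Pe)/(1 − Pe)`. With dozens of
categories the chance agreement Pe is near zero, so `Pe = 0` is the
default and kappa reduces to the observed agreement. Matching is liberal —
any shared major or minor code counts — with codes truncated to a chosen
hierarchy depth before comparison, so agreement can be read at the
primary, secondary or full four-level specificity; truncation to coarser
depths can only increase agreement, a monotonicity the tests verify. With
more than two annotators the per-question score is the mean over annotator
pairs, averaged over questions; for two annotators this is just the
fraction of matching questions.

## The synthetic corpus generator

`generate_corpus()` emulates the statistical structure the classifier
assumes, not real language: each question samples a primary topic from
skewed priors (defaults proportional to the observed topic distribution of
2000 hypertension questions, with a 0.25% residual Other mass), adds a
second topic with probability `multi_label_rate` (default 0.2635, the
observed multi-topic rate), instantiates one template per gold topic with
slot fillers (symptom / disease / drug / food / activity / department
pools shared across topics), and wraps the result in the three-field
posting template with probability `marker_rate` (default 0.7, so both
extraction branches are exercised).

`vocabulary_separation` is the single recovery knob: with probability `s`
a clause's template and topic keyword come from its gold topic's bank,
otherwise from the pooled banks of all topics. At `s = 1` the text fully
determines the topic and a sound pipeline should approach F1 = 1; at
`s = 0` the text is independent of the gold label and F1 must fall to
0.5 ± binomial noise on balanced tasks. Both extremes are asserted in the
acceptance tests (corpus size 600, the scale at which the rarest topic
still yields a viable balanced task of ≥ 20 instances; the multi-label
rate is checked at n = 2000).

What the generator does **not** emulate: real questions average ~48 words
with free-form grammar, typos, and out-of-template structure; synthetic
questions are shorter, perfectly grammatical instantiations of ~30
patterns. Passing the recovery test therefore shows the pipeline's
machinery is sound — extraction, features, selection, balancing, CV
bookkeeping — and says nothing about performance on real consumer text
with a realistic segmenter and lexicon.

## Problem sizes and runtime

The test suite runs the full pipeline at corpus sizes 120–600 and the
oracle-equivalence suites at 1000 random instances each; the acceptance
script generates one 600-question corpus for recovery and one
2000-question corpus for the multi-label rate. These sizes were chosen as
the smallest at which every binary task is viable and binomial intervals
are tight enough to be meaningful.

## Known limitations

* Φ-score treats features independently; correlated families (keywords
  duplicate bag-of-words terms by construction) are selected redundantly.
* The bundled maximum-matching segmenter has no OOV model beyond
  single-character fallback; real deployments should plug in a statistical
  segmenter and a full medical lexicon.
* Only the six primary topics are classified; the deeper three levels of
  the topic-code hierarchy are modelled (`parse_topic_code()`,
  depth-truncated agreement) but not predicted.
* The residual Other topic is a prediction-time convention (no classifier
  fires), not a trained class.
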