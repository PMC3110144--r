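---
title: "Mining literature abstracts for drug characteristics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining literature abstracts for drug characteristics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugchar)
```

## The problem

Clinically useful binary properties of drugs — membership in a therapeutic
class, liability for an adverse effect, potential to perturb another drug's
metabolism — are catalogued slowly and by hand. `drugchar` implements an
example-based alternative: given only a list of *positive-example* drugs for
a characteristic, it mines a corpus of biomedical abstracts for tokens whose
per-drug frequencies discriminate the positives from the rest of the drug
list, and trains classifiers on those token scores so that *any* drug can be
scored for the characteristic.

The method needs no curated ontology and no labelled documents: the unit of
supervision is the drug, labels come free from existing drug lists, and the
text features come from whatever abstracts mention each drug.

## The model

### Per-drug token scores

Every abstract matched to a drug is reduced to an unordered bag of tokens
(split on whitespace, comma and semicolon; lower-cased; sentence punctuation
stripped from token edges; hyphenated expressions such as `st-segment` and
digit-bearing tokens such as `pge2` kept whole; stop words removed). For a
drug $d$ with $N_d$ matched abstracts, of which $df_{w,d}$ contain token $w$,
the package computes one of three scores:

* **cdf** (conditional document frequency): $\mathrm{cdf}_{w,d} = df_{w,d} / N_d \in [0,1]$,
  the workhorse measure — the fraction of the drug's literature that mentions
  the token at least once;
* **ctf** (conditional term frequency): $c_{w,d} / T_d$, where $c_{w,d}$
  counts occurrences with multiplicity and $T_d$ is the drug's total token
  count;
* **ctf-icdf**: $\mathrm{ctf}_{w,d} \cdot \ln(N_d / df_{w,d})$, tf-idf
  restricted to the drug's own abstract sub-corpus.

The measures deliberately disagree: duplicating a token inside one abstract
moves ctf but not cdf, and a token present in *every* abstract of a drug has
cdf $= 1$ but ctf-icdf $= 0$. Global (drug-independent) tf/df weights are
constants across drugs and are not offered.

### Feature selection

Two label-free filters prune the vocabulary before ranking:

* tokens occurring in fewer than 2 abstracts *summed over all drugs* are
  removed (they cannot generalize);
* tokens whose cdf vector across drugs correlates with corpus size $N_d$
  (Pearson $r^2 > 0.33$) are removed — these are function words and generic
  scientific vocabulary whose apparent frequency tracks how much literature a
  drug has, not what kind.

Surviving tokens are ranked by the ROC AUC of their per-drug scores against
the positive set (Mann–Whitney with half credit for ties; missing scores are
0; ties in AUC break lexicographically for determinism), and the top 20
become classifier features. Twenty is fixed rather than tuned: it keeps
results comparable across characteristics with very different signal
strengths.

### Classification

Four families, chosen for their complementary inductive biases on 20
bounded numeric features:

* **NB** — Gaussian naive Bayes, per-class per-feature likelihoods with
  variances floored at $10^{-6}$ so constant columns survive;
* **IBk** — k-nearest neighbour with inverse-distance weighting; $k$ is
  chosen by an internal stratified 5-fold search over $k \in \{1,\dots,10\}$
  maximizing internal AUC, ties to the smaller $k$;
* **SVM (linear, RBF)** — cost 1; RBF $\gamma = 1/(p \cdot
  \mathrm{Var}(x))$ with $p$ features. cdf features are used as-is (already
  in $[0,1]$); for ctf/ctf-icdf the SVMs standardize each column and replay
  the standardization at prediction time.

All scores are continuous and oriented so higher means "more likely
positive". NB and IBk emit probability-like scores in $[0,1]$; the SVMs emit
decision values (margins), which are deterministic and monotone-equivalent
for ROC purposes — we prefer a reproducible margin over a Platt-scaled
probability whose internal calibration adds simulation noise to every
evaluation.

### Evaluation

Generalization is estimated by stratified cross-validation. With $|C| \ge
10$ positives: five cycles of stratified 10-fold CV (positives and negatives
shuffled independently and dealt round-robin, so per-fold positive counts
differ by at most one). With $2 \le |C| < 10$: one cycle of $|C|$ folds, one
positive per test fold. Characteristics with fewer than two positives are
refused with an explicit non-evaluable status — no fold scheme can keep a
positive on both sides of the split, and we prefer a refusal to an invented
scheme.

The entire selection pipeline — both elimination filters and the AUC ranking
— is re-run inside every training split. The correlation screen uses no
labels, but is recomputed per split anyway; the cost is negligible and the
hygiene is absolute. A deliberate "leak" mode (`leak_features = TRUE`)
selects features once on all data; it exists only to demonstrate, in tests,
how strongly that bug inflates null performance.

Test-fold scores are pooled within each cycle into one ROC AUC; the headline
estimate is the arithmetic mean over cycles (per-fold AUCs are kept for
audit). A per-fold average is ill-defined in the small-$|C|$ regime where a
test fold holds a single positive, which is why pooling is the primary
aggregation. The Hanley–McNeil closed form supplies a standard error at
$n_{pos} = |C|$, $n_{neg} = |D \setminus C|$:
$Q_1 = A/(2-A)$, $Q_2 = 2A^2/(1+A)$,
$SE = \sqrt{(A(1-A) + (n_{pos}-1)(Q_1-A^2) + (n_{neg}-1)(Q_2-A^2)) /
(n_{pos} n_{neg})}$, and a characteristic is flagged significant when
$A - 1.645\,SE > 0.5$ (one-sided, $\alpha = 0.05$).

## The synthetic-data generator

Real literature corpora are large and license-encumbered; the package
therefore ships a generator that reproduces the *statistical shape* the
method relies on, with a truth manifest for every planted token. Defaults
(the reference conditions used throughout the test suite):

| parameter | default | why |
|---|---|---|
| drugs | 200 | large enough for 10-fold CV strata and a stable $r^2$ screen |
| abstracts per drug | LogNormal(median 30, sdlog 0.4), floored at 2, capped at $+3$ log-sd | heavy-tailed like real per-drug literatures; the floor guarantees every drug can contribute, the cap bounds any one drug's share of the $N_d$ variance and the corpus size |
| abstract length | Poisson(80) background tokens | abstract-scale documents |
| background vocabulary | 2000 tokens, Zipf(1) | heavy-tailed token frequencies exercise both filters realistically |
| rare tokens | 20, one abstract each | must be removed by the rare filter |
| common tokens | 20, occurrence probability $0.15 + 0.75\,\mathrm{rank}(N_d)/n$ | cdf rises linearly with corpus-size rank, so $r^2$ against $N_d$ lands well above the 0.33 cutoff |
| characteristic | 20 positives, 20 signal tokens, $p_{pos} = 0.6$ vs $p_{neg} = 0.05$ | a clear but noisy signal: per-drug cdf of a signal token is a binomial proportion around 0.6 or 0.05 |

Each drug's name is inserted into each of its abstracts, so the index is
guaranteed to match it; the expected cdf of any planted token equals its
abstract-level occurrence probability, which is what the generator's
manifest-based tests assert. A null-characteristic helper draws positives
uniformly at random for calibration studies.

What the generator does **not** emulate: grammar and sentence structure,
correlated token co-occurrence (topics), synonym structure in the corpus
itself, query expansion of a real retrieval engine, and the 30-fold larger
per-drug corpus sizes of real literature. Passing tests on this generator
show the pipeline's statistical machinery is correct; they do not certify
retrieval quality against a real bibliographic database.

## Numerical and design choices

* **Matching rule.** Offline, a drug "matches" an abstract when its
  lower-cased name occurs as a contiguous token run (or hyphen-joined token)
  in title + body — the closest reproducible analogue of a keyword query.
  Multi-word generic names match as sequences; trade-name synonyms are
  normalized by stripping trailing strength/formulation suffixes ("Zydol SR
  100" → "zydol") against a packaged, editable suffix list.
* **Stop words** ship as a packaged editable list (a conventional English
  list), overridable per call; determinism and auditability over cleverness.
* **Porter stemmer.** Implemented in-package from the published five-step
  rule tables (longest match within a step; step ends when the longest
  match's condition fails). Tokens of $\le 2$ characters and tokens whose
  suffixes fire no rule (e.g. `pge2`) pass through unchanged.
* **ctf normalization.** The per-drug total token count $T_d$ is the
  denominator, making ctf comparable across drugs of different corpus sizes
  (as cdf is); an unnormalized count would trivially correlate with $N_d$
  and be eliminated wholesale by the common-token filter.
* **icdf** uses the natural log; absent tokens ($df = 0$) carry no evidence
  and are simply absent rather than imputed.
* **Zero-variance tokens** in the $r^2$ screen are retained (undefined $r$
  is treated as no evidence of corpus-size dependence).
* **Ties.** AUC ties get half credit (Mann–Whitney convention); ranking ties
  break lexicographically; the IBk $k$-search breaks ties toward smaller $k$;
  all platform-independent.
* **Seeds.** A master seed drives everything: cycle seeds are drawn once
  from it, per-fold classifier seeds derive from cycle seeds by a fixed
  counter scheme, and all seeds are recorded in result objects.
* **Problem sizes.** The shipped tests and the acceptance script run the
  reference conditions above (200 drugs, ~6,500 abstracts, vocabulary
  ~2,300); these sizes exercise every code path at full fidelity while a
  complete run stays in the minutes range on one CPU.

## Known limitations

* The Hanley–McNeil significance flag is **anti-conservative under the
  null** for the full pipeline at small positive counts: across repeated
  null label sets (20 positives of 200 drugs) the one-sided flag fires at
  roughly 10–12% rather than the nominal 5%, because per-fold feature
  selection and the pooling of differently-calibrated fold models add
  variance that the closed form (derived for a single fixed ROC) does not
  model. The flag is faithful to the published machinery; treat it as a
  screen, not a test with exact size. The package's calibration runs
  (`null_characteristic()` + `cross_validate()`) quantify this directly.
* Offline literal matching cannot reproduce a retrieval engine's query
  expansion; synonym matching recovers part of the gap and is always a
  superset of generic-name matching.
* Single-word tokens only (plus hyphenated compounds); no phrases,
  ontologies or concept normalization.
* With very few positives ($|C| < 10$) estimates are high-variance; with
  $|C| < 2$ the package refuses to evaluate rather than guess.

## A worked example

```{r example, eval = FALSE}
library(drugchar)

# a corpus with known planted structure
sim <- simulate_corpus(synthetic_config(seed = 1))
idx <- build_drug_index(sim$records, sim$lexicon)
fm  <- frequency_matrix(idx, measure = "cdf")

# feature selection
vocab <- eliminate_common(fm, vocab = eliminate_rare(fm))
rk    <- rank_tokens(fm, sim$labels$char01, top_n = 20, vocab = vocab)
head(rk)

# fit one classifier and score all drugs
model  <- drug_classifier(feature_table(fm, rk$token, sim$labels$char01), "NB")
scores <- predict(model, feature_table(fm, rk$token, sim$labels$char01))

# honest performance estimate: leakage-free cross-validation
cv <- cross_validate(fm, sim$labels$char01, "NB", seed = 1)
cv
```
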