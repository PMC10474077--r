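---
title: "Federated Tree-Augmented Naive Bayes: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated Tree-Augmented Naive Bayes: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedtan)
```

## The problem

Food-fraud surveillance records — who reported an incident, what product,
from which origin country, in which year, and what *type* of fraud it was —
are collected by many parties (national alert systems, regulators,
industry) that cannot pool raw records: the data are commercially and
politically sensitive. Each party alone holds an incomplete, imbalanced
slice: one may have no cases at all of a given fraud type, another may
hold a single case of it. `fedtan` trains a Tree-Augmented Naive Bayes
(TAN) classifier of fraud type across such *data stations* so that only
aggregate statistics ever leave a station, and proves (by construction
and by test) that the resulting model is *identical* to the one that
would have been trained on the pooled records.

## The model

All five variables are categorical. A TAN model over class $C$ (fraud
type) and features $X_1,\dots,X_m$ (product, year, origin country,
reporting country) is a Bayesian network in which every feature has $C$
as a parent plus at most one other feature parent, the feature–feature
edges forming a tree:

$$P(c, x_1, \dots, x_m) = P(c) \prod_i \theta(x_i \mid x_{pa(i)}, c).$$

**Structure.** The feature tree is the maximum-weight spanning tree under
the class-conditional mutual information plug-in estimate

$$\hat I(X_i; X_j \mid C) = \sum_{c,a,b} \frac{N_{abc}}{N}
 \ln \frac{N_{abc}\,N_c}{N_{ac}\,N_{bc}},$$

in nats, with zero-count cells contributing 0. Only the *ordering* of
edge weights matters for the tree, so the log base is a documentation
choice, not a modelling one. Kruskal's algorithm is used; equal-weight
edges are taken in lexicographic order of their (min name, max name) key
and zero-weight edges stay eligible, so the learner always returns a
spanning tree and repeated runs are identical. The root is the first
feature in canonical schema order (configurable). Fixing root and
tie-breaks trades fidelity to any particular library default — which the
method this package implements does not pin down — for determinism,
which the federation equivalence tests require.

**Parameters.** Conditional probability tables are posterior means under
a uniform Dirichlet prior whose total pseudo-count, the *imaginary sample
size* (`iss`, default 1, dimensionless), is spread evenly over each
table:

$$\hat\theta(k \mid pa) = \frac{N(k, pa) + iss/(rq)}{N(pa) + iss/q},$$

with $r$ child states and $q$ parent configurations. As `iss` $\to$ 0
this recovers empirical frequencies; large `iss` pulls rows toward
uniform (both directions are property-tested). Any positive `iss` makes
every entry strictly positive — which is not a technicality here: it is
what lets a station whose records never contained a fraud type still
carry that class in its model and receive real information about it from
the federation.

**Prediction** evaluates $P(c \mid x)$ in log space and normalizes;
argmax ties break toward the canonically first class state. Records must
be complete — ingestion rejects (and counts) records with missing or
undeclared values, so the complete-data assumptions of the counting math
hold by construction.

## The federated protocol

The object that crosses the station boundary is the set of
class-conditional contingency counts: the class marginal, one
(class × state) table per feature and one (class × state × state) tensor
per feature pair. These are *sufficient* for both structure learning and
parameter fitting, and they are *additive* across disjoint record sets.
A federation round is therefore:

1. **Handshake**: each station publishes variable names and locally
   observed state lists (no counts).
2. **Harmonization**: the coordinator takes, per variable, the
   lexicographically sorted union of states. The result is deterministic
   and independent of station order (property-tested for commutativity,
   associativity, idempotence).
3. **Local statistics**: each station counts over the harmonized state
   space (zero-filled for states it never saw) and sends one versioned,
   fingerprint-stamped JSON message.
4. **Pooling and training**: the coordinator sums the tensors and runs
   the same structure learner and fitter it would run on pooled data.

Because pooled counts equal the counts of the pooled data, federated
training equals centralized training *exactly* — structure identical,
parameters to machine precision. The test suite asserts this for random
datasets under random partitions into 1–4 stations at a $10^{-12}$
sup-norm tolerance; it is the package's headline property, and it is the
precise version of the looser empirical observation that combined-model
performance with and without a federation infrastructure is very close.

Design choices worth recording:

* **Counts, not fitted CPTs.** A protocol could instead ship each
  station's fitted tables and average them; there is no averaging rule
  that reproduces the centralized model, and any n-weighted scheme is
  lossy wherever local parent-configuration counts differ. That mode is
  implemented (`combine = "average_cpt"`) purely as a comparison and is
  non-default; a test verifies it does *not* reproduce centralized
  training, which is the point.
* **Privacy is a policy, not noise.** Counts still leak small-cell
  information (a class count of 1 is nearly a record). Stations
  therefore carry a minimum-cell-count threshold: below it they abstain
  entirely rather than perturb counts. The default is off, and no
  differential-privacy noise is added — the protocol's contract is
  exactness, and the knob makes the residual leakage explicit instead of
  hiding it. A byte-level test scans all serialized traffic for full
  record tuples.
* **Transport is in-process.** Messages are canonical JSON (sorted keys,
  explicit tensor shapes, schema fingerprint = MD5 of the canonical
  schema JSON); a network broker, containers and authentication are
  deployment concerns a real installation would add around the same
  message format.

## The synthetic scenario

`simulate_case_study()` generates the three-station composition this
package uses throughout its tests and experiments: per-station fraud-type
counts of {105, 97}, {1, 135, 8} and {21, 23, 51} (totals 202/144/95,
pooled 441), year spans 2008–2013, 2014–2018 and 2008–2018, and the full
heterogeneity the federation must cope with — STATION-1 lacking one
fraud type entirely and STATION-2 holding a single case of it. One
source document gives STATION-3's span as ending 2017 in prose and 2018
in its summary table; the generator follows the table.

Class counts are **exact**, not sampled, because surveillance summaries
report exact case counts; only feature values are stochastic. Feature
distributions are built-in class-shifted multinomials over 6 products, 8
origin countries and 6 reporting countries (peak weight 6 — or 4 for the
deliberately more diffuse Substitution–Dilution class — against a floor
of 1, normalized), chosen once so that fraud type is learnable from the
features and individual-vs-combined differences are visible. They do
**not** attempt to reproduce real RASFF/EMA product or country
marginals, which are not published at that granularity. Consequently,
passing tests show that the *pipeline and protocol* behave correctly
under realistic composition, imbalance and heterogeneity — not that any
particular AUC on the real incident data would be reproduced. Feature
values are drawn independently per record given the class, so the
generator's true feature tree is uninformative; tree *recovery* is
instead tested against `simulate_tan()`, the ancestral sampler from an
explicit TAN with strong dependence (0.9 parent-copy probability,
conditional mutual information ≈ 0.37 nats per tree edge).

Each generator call consumes a single seeded stream column-by-column in
canonical variable order (then shuffles record order once), so the same
seed is byte-identical across runs and appending a variable never
perturbs earlier columns.

## Evaluation

* One-vs-rest **sensitivity and specificity** per class at the argmax
  decision; the reported averages are unweighted (macro) means over
  classes observed in the test set — classes with no observed positives
  have undefined sensitivity and are flagged and excluded rather than
  imputed. (Weighted averaging is a one-line `dplyr` step over the
  per-class `tidy()` output, so no flag is provided.)
* **Micro-average ROC/AUC**: all (record, class) one-vs-rest decisions
  pooled into one binary problem, thresholds swept over distinct scores
  with ties grouped, area by the trapezoidal rule — equal to concordance
  with ties counted ½, which an independent brute-force oracle and the
  pROC package both confirm in tests. When a model's class space exceeds
  the test label space, binarization uses the model's space and the
  never-observed classes contribute negatives only.
* **Design 1** (`run_experiment_individual_vs_combined`): per station,
  a stratified seeded 80/20 split; the individual model trains on the
  local training partition, the combined model federates over *all*
  stations' training partitions, and both are scored on the local test
  partition. Stratification is the default here because STATION-2's
  single-record class would otherwise vanish from training in 20% of
  splits; the single record is forced into train with a warning.
* **Design 2** (`run_experiment_centralized_vs_federated`): one plain
  unstratified 80/20 split of the pooled records; centralized training on
  the pooled training partition versus federation over its per-station
  slices, both scored on the pooled test partition. Under statistic
  pooling the two rows coincide exactly — a stronger statement than the
  near-equality one observes when the two arms use different random
  splits.

Train-set sizes are `round(fraction * n)` (so 441 pooled records give
353/88), with a deterministic largest-remainder correction across
classes in the stratified case.

## Numerical and degenerate-input choices

* All state and label ordering uses byte-order (`radix`) sorting,
  immune to locale collation differences.
* CMI terms with zero joint counts contribute 0; tiny negative rounding
  residues are clamped to 0.
* Posteriors are computed in log space with a per-record max shift;
  `iss = 0` is allowed but yields `-Inf` log-likelihoods for unseen
  cells, so the smoothed default is recommended for prediction.
* A station observing a single class still trains (CMI conditions on one
  class; the other classes live on prior mass) — this is precisely the
  situation of predicting a fraud type never seen locally.
* Empty statistics are the aggregation identity; fitting on them with
  `iss > 0` gives the uniform model, and with `iss = 0` it is an error.
* Schema fingerprints use MD5 of the canonical schema JSON; the
  fingerprint's role is mismatch detection at aggregation time, not
  cryptographic commitment.

## Problem sizes used by the test suite

Deterministic oracle comparisons run at 20–500 records; the
federation-equivalence property is checked on 50 random dataset/partition
draws; parameter recovery uses 20 replicates of 5,000 sampled records
(structure correct and CPT sup-norm ≤ 0.05 required in ≥ 95% of
replicates); generator frequency checks use 10,000 records. These sizes
were chosen as the smallest at which each property is sharply testable.

## Known limitations

* Complete-data only: records with missing values are rejected at
  ingestion, never imputed; there is no missing-data EM.
* No general structure search beyond the TAN family, and no continuous
  variables.
* The minimum-cell-count policy is refusal-based; there is no formal
  privacy guarantee (no differential privacy, no secure aggregation).
* The RDF reader covers N-Triples and a pragmatic Turtle subset
  (prefixes, `;`/`,` continuation, literals and opaque IRIs); it is an
  ingestion convenience, not a semantic-web stack — ontology terms are
  treated as opaque identifiers.
* Synthetic feature distributions are stylized; absolute metric values
  on the synthetic scenario characterize the scenario, not any real
  surveillance database.
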