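---
title: "Inferring sex and biogeographical ancestry from routine forensic markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring sex and biogeographical ancestry from routine forensic markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strbga)
```

## The problem

When skeletal remains cannot be identified, investigators build a
biological profile — sex and ancestry above all — to narrow the pool of
candidate missing persons. Physical anthropology reads these from pelvic
and cranial morphology; a forensic genetics laboratory, meanwhile, already
types autosomal STRs, often Y-STRs, and sometimes the mitogenome for
identification purposes. None of these markers was designed for ancestry
inference (STRs carry far less population information than ancestry
SNP panels), but they are what casework actually produces. This package
implements a complete workflow for extracting the sex and
biogeographical-ancestry signal those markers do carry, and for auditing
the result against physical and antemortem findings.

## The classifier

Ancestry assignment is partial least squares discriminant analysis
(PLS-DA). Class membership over $c$ population classes is dummy-coded into
an $n \times c$ indicator matrix $Y$ and regressed on the feature matrix
$X$ by NIPALS PLS2. Features are autoscaled with training-set statistics
only (queries reuse the stored means and scales), and $Y$ is column-centred.
Each latent variable (LV) $a$ finds a unit weight vector $w_a$ whose score
$t_a = X_{a-1} w_a$ has maximal covariance with the response; $X$ and $Y$
are deflated by the rank-one contribution of $t_a$ before the next LV.
After $A$ components the regression coefficients

$$B = W (P^\top W)^{-1} Q^\top$$

(with $P$, $Q$ the X- and Y-loadings) give per-class *prediction values*
$\hat y = \bar y + x^\top B$ for a scaled query $x$. Three properties make
PLS-DA a good fit for STR data: it tolerates the strong collinearity of
one-hot allele dosages, it behaves sensibly when $p$ approaches $n$, and at
$A = \operatorname{rank}(X)$ it coincides exactly with ordinary
least-squares dummy regression — an identity the test suite checks to
$10^{-8}$, along with the mutual orthogonality of score vectors.

Prediction values are deliberately left uncalibrated: they are not forced
onto a probability simplex, so values like 0.64 or 0.49 can and do occur
for correct calls. The assigned class is the argmax (ties broken by class
order, with a warning), and a call is flagged *reliable* when the winning
value reaches the `threshold` parameter, default **0.8**. The threshold is
a reading rule, not part of the fit, and is configurable per model and per
prediction.

A pooled-covariance linear discriminant on the LV scores
(`lda_on_scores()`) is provided as an alternative decision rule: with equal
priors its boundary between two classes passes through the midpoint of the
class centroids, and under a spherical covariance it reduces to nearest
centroid. The default reading remains the raw argmax of prediction values;
both routes are exposed because either is a defensible reading of the
latent space.

## Feature encodings

Profile encodings are a design decision of this package (there is no
community standard for feeding STR profiles to a latent-variable
classifier), chosen so that each marker system keeps its natural metric:

* **Autosomal STRs** — one feature per (locus, allele) with dosage values
  0/1/2. Microvariant alleles (9.3) are distinct features from their
  integer neighbours. Within one typed locus the dosages sum to 2, a
  structural collinearity PLS absorbs without trouble.
* **Y-STRs** — one numeric slot per locus copy holding the repeat count
  itself; multi-copy loci (DYS385) occupy two sorted slots. Keeping counts
  numeric preserves the single-step mutation distance and keeps the
  feature count small relative to large haplotype reference sets.
* **mtDNA** — binary presence/absence of a variant at each catalogued rCRS
  position; positions read as N are masked. Records carrying only a
  haplogroup label cannot be encoded and are routed to the
  haplogroup-mapping module instead.

Missingness is explicit everywhere: an untyped locus masks all its
features, masked entries are excluded from scaling and fitting, and nothing
is ever imputed as zero. The vocabulary's `min_count` support filter
defaults to 1, appropriate for the desk-scale panels the simulators
produce; larger panels may raise it to shed singleton alleles.

## Honest accuracy: repeated double cross-validation

A single cross-validation that both picks the LV count and reports its
accuracy is optimistically biased. The package therefore uses repeated
double CV: an inner venetian-blind 5-fold loop on each outer-training set
selects the LV count minimising held-out misclassification (ties to the
smaller model), the outer 5-fold loop scores a refit with that choice, and
the whole procedure repeats over `n_repeats = 20` random permutations of
the sample order. Venetian blinds (samples ordered by class, every $k$-th
sample to the same fold) keep class proportions balanced and the assignment
deterministic; all randomness enters through the single `seed`, from which
the full report is bit-reproducible. `a_max` defaults to
$\min(15, \operatorname{rank})$ — with per-locus collinearity the effective
rank is roughly the feature count minus the locus count, and the inner
selection routinely picks far fewer LVs than the cap. The production model
is refit on all samples with the median selected LV count.

## Partial profiles: adaptation, not imputation

Degraded bone yields partial profiles. `adapt_and_predict()` restricts the
reference panel to exactly the features the query carries, re-runs the
same LV-selection CV on the restricted matrix, refits and predicts. This
per-query refit is preferred over imputation because missing loci in
casework are not missing at random and any imputation model would leak
reference-panel structure into the query.

Below `min_loci` typed loci the answer is an explicit `NO_CALL` rather
than a low-quality guess. Casework experience brackets the sensible floor
without pinning it — nine typed Y loci produced no usable prediction while
thirteen autosomal loci usually did — so the defaults are 10 loci for
autosomal and Y profiles and 100 called vocabulary positions for mtDNA,
all configurable and recorded in the prediction output. On separable
synthetic panels the mean prediction value of the true class decays
monotonically (in expectation) as loci are removed, which the test suite
verifies over 50 degraded replicates per dropout level.

## Haplogroup mapping

Y and mtDNA haplogroup labels assigned by external tools resolve to
regions by longest-prefix lookup in an editable JSON table seeded from the
built-in casework annotations. Two entries are phylogeographically
surprising and are kept verbatim on purpose: mt haplogroup U6a — common in
North Africa — is annotated "Europe", and R0 is annotated "South Asian"
(spelled differently from the "South Asia" used for M5a, M1a and R9c).
Reproducing the recorded annotations exactly takes precedence over
phylogeographic completeness; users wanting a corrected table can supply
their own JSON via `haplogroup_table(path = ...)`.

## Concordance scoring

The concordance engine compares, per case, the physical estimate, the
three molecular calls and (for identified cases) the antemortem record,
after collapsing all labels onto European/African/Asian macro groups. A
case is ancestry-discrepant if any non-missing genetic call disagrees with
the physical macro group or if the genetic calls disagree among
themselves; missing calls (NA/ND) never create discrepancy. Accuracy
against antemortem data is scored on the identified subset only: sex
requires both disciplines to match the known sex; physical ancestry
requires the physical macro group to match the known provenance;
molecular ancestry requires *all* non-missing marker calls to match.
Rates are truncated — not rounded — to one decimal (6/9 reports as 66.6%),
matching the reporting convention of the built-in casebook. The built-in
24-case casebook reproduces: 12 male / 10 female molecular sex, five
discrepant cases, 100% sex accuracy, 88.8% physical and 66.6% molecular
ancestry accuracy on the nine identified cases.

## The synthetic-data generators

No public population reference panels ship with the package, so the
simulators create labelled panels with the statistical structure the
analysis assumes:

* **Autosomal** — Balding–Nichols: ancestral allele frequencies from a flat
  Dirichlet, class frequencies from a Dirichlet centred on them with
  concentration $(1-\theta)/\theta$, genotypes under Hardy–Weinberg.
  $\theta$ is the FST-indexed separability knob; the test suite confirms a
  Weir–Cockerham estimate recovers it within ±0.05. Defaults (181/49/171
  samples, classes Eur_Am/Asian/Afr_Am) mirror at half scale the
  composition of a standard three-population forensic STR dataset;
  23 loci and 8 alleles per locus reflect a modern autosomal multiplex.
  The default $\theta = 0.05$ is at the upper end of realistic continental
  STR differentiation.
* **Y-STR** — per-class founder haplotypes with symmetric ±1 stepwise
  mutations at rate 0.05 per locus; default class sizes scale a
  five-continent haplotype reference set down by 50.
* **mtDNA** — per-class blocks of diagnostic positions at frequency 0.9
  in-class and 0.05 outside, plus Poisson private variants; defaults scale
  a five-continent mitogenome set down by 100.

What the simulations do *not* capture: linkage, locus-specific mutation
rates, allelic dropout correlated with fragment length, population
admixture, and database misrepresentation — the very factors the casework
concordance analysis shows to matter. Passing the synthetic benchmarks
therefore demonstrates that the machinery is correct and well-calibrated
under its stated model, not that routine STR markers are a reliable
ancestry instrument for real casework; the built-in casebook, where
molecular ancestry succeeded in only two thirds of identified cases, is
the sobering empirical counterpart.

## Numerical choices and degenerate inputs

* NIPALS convergence: relative score change below $10^{-10}$, at most 500
  iterations per LV; requesting more LVs than the rank of the scaled
  training matrix is an error (internal CV fits cap silently).
* Zero-variance features are dropped with a warning before scaling.
* Ties in the argmax are broken by class-set order with a warning; a query
  at the centroid of a balanced two-class problem ties exactly.
* Zero-denominator sensitivities/specificities are reported as `NA`,
  never as 0.
* A class that vanishes from an inner training fold skips that rdCV repeat
  with a warning; the pooled confusion then counts only completed repeats.
* Allele designations are exact decimal strings compared numerically, so
  file round-trips cannot silently turn 9.3 into 9.

## Problem sizes used in validation

The shipped tests and the acceptance script exercise: rdCV on 3 × 100
samples × 10 loci Balding–Nichols panels at $\theta = 0.3$ (accuracy
$\ge 0.95$) and $\theta = 0$ (accuracy within ±0.07 of 1/3, 20 repeats
each); adaptation on a 3 × 100 × 23-locus panel with queries degraded to
13 of 23 loci (accuracy $\ge 0.90$) and to 9 loci (always `NO_CALL` under
the 10-locus floor); PLS/OLS equivalence on ten random full-rank
instances. These sizes make the whole suite run in a couple of minutes on a
single core while keeping Monte-Carlo error well inside the asserted
margins.

## Known limitations

* Prediction values are uncalibrated regression outputs; the 0.8
  reliability rule is a practical convention, not a probability statement.
* The per-query adaptation refit re-selects the LV count on the restricted
  panel, so two queries with different missing loci are scored by models of
  possibly different complexity — intended, but worth remembering when
  comparing prediction values across queries.
* Longest-prefix haplogroup matching has no notion of tree topology; a
  label absent from the table returns `NO_MATCH` rather than climbing to a
  parent clade not listed.
* The macro-group map ships with exactly the labels and countries the
  built-in casebook needs; other casebooks must extend it explicitly
  (unknown labels raise an error rather than guessing).
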