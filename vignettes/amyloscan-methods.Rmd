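---
title: "amyloscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{amyloscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Amyloids are insoluble fibrillar aggregates with a cross-β core, associated
with Alzheimer's, Parkinson's and type II diabetes. Aggregation of a whole
protein is typically promoted and guided by short "hotspot" segments —
amyloidogenic regions — whose minimum length is taken here to be six
residues, the commonest hotspot size. amyloscan predicts such regions from
sequence alone: it trains a classifier on labeled hexapeptides and slides a
six-residue window along query proteins, turning window calls into
per-residue hotspot masks and maximal regions.

## Feature encoding

Each (hexa)peptide is encoded by the concatenation of two blocks.

**Type 2 pseudo amino acid composition (PseAAC, series-correlation form).**
Nine physicochemical property scales — hydrophobicity, hydrophilicity,
residue mass, pK1 (α-COOH), pK2 (α-NH3+), isoelectric point, rigidity,
flexibility, irreplaceability — are each standardized over the 20 amino
acids to mean 0 and population standard deviation 1 (divisor 20). For a
sequence $R_1 \dots R_L$ and lag $d = 1 \dots \lambda$, the correlation
factor of scale $k$ is

$$\theta_{k,d} = \frac{1}{L-d} \sum_{i=1}^{L-d} h^k(R_i)\, h^k(R_{i+d}),$$

and the encoded vector is

$$P_u = \frac{f_u}{\sum_i f_i + w \sum_j \theta_j}\ (u \le 20), \qquad
  P_{20+j} = \frac{w\, \theta_j}{\sum_i f_i + w \sum_j \theta_j},$$

with $f_u$ the composition numerators and $w = 0.7$ by default. With nine
scales and $\lambda = 2$ this is the standard 38-component vector. The
components always sum to 1 because the numerators sum to the denominator.

**Tripeptide composition (TPC).** The 8000 overlapping 3-mers are counted
over the $L-2$ windows and divided by $L-2$; tripeptides are indexed by the
alphabetical base-20 code ($\mathrm{AAA}=0,\dots,\mathrm{YYY}=7999$), a
fixed, reproducible bijection.

### Composition numerators: counts, not relative frequencies

The classical presentation leaves open whether $f_u$ are raw counts or
relative frequencies (both appear in the PseAAC literature, and both are
available via `pseaac_params(freq_mode=)`). The two differ only by a common
rescaling of the composition block against the correlation block — but that
rescaling matters numerically at hexapeptide length. Correlation factors of
standardized scales may be negative, and with nine scales, $\lambda = 2$ and
$w = 0.7$ the term $w\sum_j \theta_j$ frequently falls below $-1$: with
relative frequencies ($\sum f_u = 1$) the denominator is then non-positive
for a substantial fraction of random hexapeptides, whereas with raw counts
($\sum f_u = L = 6$) this degeneracy becomes rare. amyloscan therefore
defaults to `freq_mode = "count"`. A non-positive denominator is still
possible and is treated as a hard error by `encode_pseaac()` — it signals a
pathological scale/sequence combination rather than something to clamp
silently. Batch prediction (`predict_proba(..., policy = "skip")`) and the
protein scanner skip such windows (the window abstains); the synthetic
generator redraws the rare degenerate sequence so generated benchmarks lie
in the encoder's domain.

### The default property table

The six classic scales ship with textbook reference values (Kyte–Doolittle
hydropathy, Hopp–Woods hydrophilicity, average residue mass, pK1, pK2, pI).
The remaining three columns are documented proxies rather than canonical
indices of those names: flexibility uses the Bhaskaran–Ponnuswamy average
flexibility index, rigidity is proxied by the Chou–Fasman helix
conformational parameter, and irreplaceability by the negated Dayhoff
relative mutability. Standardization removes location and scale, so only
each column's shape matters; any column can be replaced by supplying a TSV
to `load_property_scales()`. No numeric correctness check in the package
depends on the default table — encoder tests use toy scales and a naive
direct-evaluation oracle.

## Tripeptide selection by binomial confidence

For tripeptide $i$ with $n_{ij}$ occurrences in class $j$ out of $N_i$
total, and $q_j$ the class's share of all tripeptide tokens,

$$P_{ij} = \sum_{k=n_{ij}}^{N_i} \binom{N_i}{k} q_j^k (1-q_j)^{N_i-k},
\qquad CL_i = \max_j\, (1 - P_{ij}).$$

A small $P_{ij}$ means the tripeptide is concentrated in class $j$ far
beyond what its overall abundance predicts. Choices made where the
formulation is silent:

* $q_j$ is computed from tripeptide *tokens*, not sequence counts, following
  the definition as a ratio of tripeptide numbers.
* A tripeptide never observed ($N_i = 0$) carries no evidence: $CL = 0$.
* Ranking ties are broken deterministically: $CL$ descending, then $N_i$
  descending (more evidence first), then alphabetically. The same inputs
  always yield the same selection, byte for byte.
* Selection modes: keep $CL \ge$ a threshold (default 0.85) or keep the top
  $k$. `candidate_cutoffs()` enumerates the ranks where $CL$ crosses values
  in $[0.80, 0.90]$ (capped at 20 evenly spaced candidates) and
  `tune_cutoff()` picks the candidate maximizing cross-validated accuracy —
  accuracy because it is the customary headline training metric; the
  criterion is configurable — preferring the smaller feature set on ties.

The full PseAAC block is always retained; selection applies to the 8000
tripeptides only.

## Classifier

The default learner is a probability random forest (`ranger`), 500 trees,
per-split feature subsample $\sqrt{p}$, no depth cap, single-threaded with
a fixed seed so results are reproducible. These are conventional defaults;
the forest settings behind published variants of this kind of predictor are
generally unreported, so all of them are exposed in `training_config()`.
The classifier sits behind a two-function contract (`fit`,
`predict_proba`), and `register_classifier()` makes any other learner a
drop-in replacement for training, cross-validation and scanning alike.

Cross-validation is stratified (class ratios preserved within one sample
per fold) with fold assignment fixed by the seed. Pooled metrics are
computed from the concatenated out-of-fold predictions rather than averaged
per fold: pooling is well-defined for every metric including AUC and makes
run-to-run numbers directly comparable; per-fold values are reported
alongside.

## Region scanning

Every protein of length $L \ge 6$ yields $L-5$ hexapeptide windows, step 1.
A window is called positive when its probability reaches the decision
threshold (default 0.5, configurable). Window calls map to residues by the
*union rule*: a residue is a hotspot iff at least one covering window is
positive. The union rule is the most permissive mapping, consistent with
worked examples in which a predicted region overruns the annotated hotspot;
a majority-of-covering-windows rule is available
(`scan_protein(aggregate = "majority")`). The per-residue score is the
maximum of the covering windows' scores (mean available), and predicted
regions are the maximal runs of the mask. Raising the threshold can only
shrink the mask.

Whole peptides (length ≥ 6) are classified amyloidogenic iff at least one
window is positive; peptides shorter than six residues cannot host a
hotspot and are rejected.

Window resolution smears signal: a window overlapping a hotspot by a single
residue may legitimately score high, so predicted regions typically extend
a few residues beyond the true hotspot and flanking residues inherit high
scores. This bounds per-residue precision from above no matter the
aggregation rule; it is the expected behavior of any fixed-window scanner.

## Evaluation

Per-residue confusion counts (TP/FP/TN/FN) feed the five headline metrics
ACC, SE, SP, $Q = (SE+SP)/2$ and MCC. Hotspot residues are rare, so the
balanced accuracy $Q$ is the preferred summary: a trivial all-negative
prediction can have high ACC but always gets $Q = 0.5$. Conventions: MCC is
0 when a denominator factor vanishes; SE (SP) is NaN when no positive
(negative) items were evaluated; reports print three decimals with
half-away-from-zero rounding (`round_half_up()`: $26/32 = 0.8125$ prints as
0.813), full precision retained internally. AUC is the rank (Mann–Whitney)
area, ties counting one half.

For multi-method comparison, a methods × items rank matrix is tested with
the Friedman chi-square (tie-corrected, mid-ranks; default α = 0.1) and, on
rejection, Nemenyi's critical difference
$CD = q_\alpha \sqrt{k(k+1)/(6n)}$ with $q_\alpha$ from the studentized
range distribution, flags each pair whose mean ranks differ by more than
CD. What per-protein score to rank is left to the caller.

## The synthetic benchmark generator

Real training data for this problem are curated hexapeptides (on the order
of 500 amyloidogenic and 900 non-amyloidogenic) plus proteins with
literature-annotated hotspot intervals. The generator emulates their
*structure* with two controllable signal channels chosen to mirror what
separates real classes:

* **planted tripeptides** — disjoint class-exclusive 3-mers (defaults:
  V/I-rich in positives, N/G/Q-rich in negatives) inserted at a random
  in-window offset with probability `plant_rate` (default 0.8), the
  discriminative features selection should recover;
* **composition bias** — a softmax log-odds tilt (default 1) enriching
  valine/isoleucine in positives and asparagine/glycine/glutamine in
  negatives, mirroring the residue preferences reported for amyloidogenic
  versus non-amyloidogenic fragments.

Default class sizes are 200/200; the real ~1:1.8 imbalance can be emulated
via `n_pos`/`n_neg`. Annotated proteins use negative-distribution
background with planted positive hexapeptides separated by at least six
background residues, so true regions are unambiguous maximal runs; the
annotations are exactly the planted intervals. All outputs are
bit-reproducible given the seed, and the generators restore the caller's
RNG state.

`plant_rate = 0` with zero bias gives exchangeable classes — the null
construction under which cross-validated AUC must hover at chance.

What the generator does **not** emulate: real aggregation physics,
position-specific effects, homology structure between sequences, or the
label noise of experimental assays. Passing recovery tests on this
benchmark shows the pipeline's machinery is sound (selection finds planted
discriminative features, the scanner localizes planted regions); it does
not certify accuracy on real amylome data.

## Problem sizes and numerical tolerances used by the test suite

The suite exercises the pipeline at sizes chosen to make the statistical
assertions stable: hexapeptide sets of 400 (200/200) for selection and
10-fold cross-validation, 12 annotated proteins (24 planted hotspots,
lengths 60–100) for region recovery, and 1000 random sequences for the
conservation invariants. Oracle equivalence is asserted at 1e-12 for the
binomial tail (against term-by-term summation), 1e-10 for PseAAC (against
a naive loop evaluation) and 1e-12 for AUC (against the pairwise
statistic). Scale standardization is checked at 1e-9.

## Known limitations

* The nine-property default table mixes canonical scales with documented
  proxies (see above); users wanting a specific published index set should
  supply their own TSV.
* Window length is fixed at six; longer minimum hotspot definitions are out
  of scope.
* Probabilities are raw forest votes, not calibrated.
* Region boundaries are window-resolution approximations (see the smearing
  note); no post-hoc merging or smoothing beyond maximal runs is applied.
* The model archive stores the fitted forest via R serialization; the
  feature specification travels as a portable text file, but the classifier
  state itself is R-version-portable only as far as the learner's own
  serialization is.
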