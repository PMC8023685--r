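---
title: "Scoring structural disruption by synonymous variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring structural disruption by synonymous variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A synonymous single-nucleotide variant (sSNV) leaves the protein unchanged
but can still reshape the secondary structure of the mRNA around it —
altering transcript stability, translation speed and half-life. If such
disruption is deleterious, structure-disrupting sSNVs should be depleted
from population allele-frequency databases. `rnasurf` implements the full
desk-scale machinery for testing and exploiting that idea: per-variant
folding-disruption metrics, mutational-context constraint regressions with
mediator decomposition, and two Phred-scaled summary scores (SPI and SURF).

## Window protocol

Every possible SNV of a transcript is represented by a pair of 101-nt
folding windows. For interior positions the window is centred on the
variant (offset 51); positions within 50 nt of either transcript end take
the leading or trailing 101 nt, with the offset shifted accordingly, so
windows always have exactly 101 nt. Transcripts shorter than 101 nt are
skipped with a logged warning rather than folded at a different window
size: every downstream metric then refers to a uniform folding problem.
Coordinates are 1-based and inclusive throughout transcript space, and the
mRNA alphabet uses `T` (thymine convention); the folding backend treats
`T` as `U`.

```{r}
library(rnasurf)
tx <- simulate_transcripts(n_transcripts = 2, mean_length = 300, seed = 1)
snvs <- enumerate_snvs(tx)   # 3 alternates per position
```

## Folding backend

Structure prediction is delegated to an installed nearest-neighbour
thermodynamic engine (the ViennaRNA suite: `RNAfold` with partition
function, centroid and MEA output; `RNApdist` for pair-probability
ensemble distances), at 37 °C with the default energy parameter set and no
dangling-end overrides — there is no reason to deviate from defaults, and
the backend name and version are recorded in the run manifest so energies
can be tied to a parameter-set version. Results are memoised by sequence
content: the four windows per position and overlapping windows across
positions are folded once per run. A fixture backend replays recorded
results keyed by sequence, for pipeline tests that must not depend on a
live engine; the pipeline's output is identical under either backend for
the same recordings.

## The ten disruption metrics

For each SNV the wild-type and mutant windows are folded and compared:

* four stability deltas, in kcal/mol — `dMFE` (minimum free energy),
  `dCFE` (centroid), `dEFE` (ensemble free energy), `dMEAFE` (MEA);
* four structure distances — `MFEED`, `CED`, `MEAED` (edit distances
  between the MFE / centroid / MEA structures) and `EED` (distance between
  the two sequences' base-pair-probability ensembles);
* two diversity deltas — `dCD` (the centroid's expected distance to the
  ensemble) and `dEND` (ensemble diversity).

All deltas are `mutant − wild-type`, so a destabilising variant has
`dMFE > 0`. The subtraction order is never ambiguous in the code, and a
designed-hairpin test (destroying a G≡C stack must raise the free energy)
pins the convention.

### Structure edit distance

The default comparison mode is a character-level alignment of the two
dot-bracket strings with indel cost 1, bracket↔dot substitution cost 1 and
`(`↔`)` substitution cost 2. Under this model destroying or creating a
base pair always costs exactly 2 edits, which is the semantics the scores
are built on; on structures with realistic hairpin loops (≥ 3 nt, the only
kind a thermodynamic engine emits) it coincides exactly with the full-
structure *string alignment* of the standard comparison program. Note that
the comparison program's out-of-the-box default is *tree editing*, which
charges 4 for a pair removal; the string-alignment semantics was chosen
because it matches the 2-edits-per-pair property the analysis relies on.
A base-pair-set mode (symmetric difference of the two pair sets) is
available as a configuration alternative. Whether edit distances can take
odd values depends on the comparison mode, so the package records observed
values rather than enforcing an even-parity rule.

## Variant annotation

Coding effects are classified by direct translation with the standard
genetic code: `start_loss`, `stop_gain`, `start_gain`, `stop_loss`,
`missense`, `synonymous`, `utr5`, `utr3`, ranked in that order of
decreasing deleteriousness. `start_gain` — never formally defined in the
constraint literature we follow — is implemented as a 5′-UTR substitution
that creates a new `ATG` trinucleotide overlapping the variant; this is a
documented interpretation, not a canonical rule. Canonical transcripts are
selected by MANE flag, then longest CDS, then longest transcript, with a
lexicographic tie-break, so selection is order-invariant.

Each SNV falls in exactly one of 14 mutational contexts: the 12 plain
`REF>ALT` classes plus `CpG>TpG` (a `C>T` immediately 5′ of `G`) and
`CpG>CpA` (a `G>A` immediately 3′ of `C`, i.e. deamination on the
antisense strand). Boundary positions lacking the needed neighbour fall
back to the plain class.

Local sequence content tiles the transcript into 40-nt windows from the 5′
end and, for each position, aggregates the previous, own and next tiles —
a symmetric 120-nt neighbourhood, which is also the natural reading of
"the surrounding 120 nucleotides" used by the SPI features. Dinucleotides
(`CG`, `AT`) are counted within tiles on the given strand and divided by
(concatenation length − 1).

Splice effects are handled positionally: the pipeline accepts an optional
per-transcript exclusion mask (BED-like, transcript coordinates) and flags
masked variants out of the constraint analysis instead of re-implementing
a splice annotator. When an externally supplied effect annotation
disagrees with the internal classification, the variant is flagged
excluded rather than silently trusted either way.

## Population constraint

Frequency records pass four quality filters: random-forest filter status,
inbreeding coefficient, reference-is-minor (`MAF ≥ 0.5`) and coverage
(≥ 70% of samples at ≥ 20× depth). The inbreeding threshold is `< −0.3`:
the positive-threshold reading sometimes quoted would remove nearly every
variant and contradicts the filter's purpose, so the negative bound is the
default (configurable). Every dropped record is tallied under the first
rule it fails, and `input = retained + Σ drops` is asserted in tests.

WGS and WES datasets are combined under the intersection-pass /
union-positive scheme: a variant is analyzed only if it passed all filters
in both datasets, and counts as `MAF > 0` if positive in either; analyzed
variants positive in neither are "constrained". The five alternative
combination schemes are available as configuration options but are not the
tested path.

For a context and metric, the constraint curve bins the metric — energies
and `EED` at the backend's 0.1 kcal/mol output resolution, `dCD` and
`dEND` rounded to integers, edit distances as-is — and regresses the
per-bin proportion with `MAF > 0` on the bin value, weighted by bin count,
linearly and quadratically. The quadratic fit is reported when its
weighted pseudo-R² (1 − SS~res~/SS~tot~, which the source analysis never
defines, so this standard definition is used) exceeds the linear R² by a
factor of ≥ 5. The normalized slope divides the linear slope by the mean
P(MAF > 0) and multiplies by the metric range covering its central 90% of
variants. Bins with fewer positive-MAF variants than a configurable
threshold are excluded, mirroring the bin-exclusion counts used in the
source plots at transcriptome scale; the default threshold is 1 and tests
scale it with their sample sizes.

A caution established by simulation during development: excluding bins by
their *positive-MAF count* conditions the surviving bins on the outcome —
a small tail bin survives only when its empirical proportion is high — so
under the null the surviving curve acquires a U-shape, the quadratic model
gets selected, and its p-value rejects far above nominal. The weighted
linear fit itself is well calibrated (empirical rejection ≈ 0.5% at
α = 0.005 with no exclusion). Bin exclusion should therefore be treated as
a plotting and robustness device; the package's type-I verification runs
the fit without exclusion, and effect estimates from excluded fits should
be read as conditional on the exclusion rule.

The mediator decomposition asks how much of the binned constraint signal a
single sequence feature explains: fit a one-feature logistic model for
P(MAF > 0 | feature), then
`r2 = 1 − V_feature / V_null` with
`V_feature = Σ_x n_x (E[P_est | x] − P(MAF>0 | x))²` and
`V_null = Σ_x n_x (P(MAF>0) − P(MAF>0 | x))²`. Within a bin, predictions
are averaged with equal weight per variant (the natural reading; nothing
in the formulas suggests covariate weighting). The mediator of a
context–metric pair is the candidate with the highest r², ties broken
lexicographically, signed to correlate positively with `MAF > 0`.

## SPI

Within each context two regularized logistic models predict `MAF > 0`: a
null model over sequence features only (nine nucleotides of the home and
adjacent codons, six local-content proportions, codon position, transcript
length plus gene grouping key, wild-type and mutant codon tAI) and an
active model that adds the ten metrics and the paired/unpaired status of
the variant base in both MFE structures. How "its transcript" should enter
the model is not specified anywhere; length plus a grouping factor is this
package's documented guess. Training uses 5-fold cross-validation with
every fold-model scoring every variant and the five probabilities
averaged — the literal reading of the averaging rule — with a strict
out-of-fold mode available for honest evaluation. The models are ridge
logistic fits (light L2, `lambda = 1e-3`, convergence tolerance 1e-6);
unpenalised fits separate on small contexts and tree ensembles are
deliberately out of scope.

`spi_raw = log10(p_active / p_null)` is z-scored within context and
percentile-ranked by *decreasing* raw value: the variants whose structure
most lowers the predicted survival probability earn the highest
percentiles, so that after Phred scaling a high SPI means predicted
structural constraint. (Ranking by increasing raw value would invert the
score's relationship with constraint and contradict how the score is used
and plotted; this directional choice is deliberate and documented.) The
Phred map is `−10·log10(1 − percentile)` capped at 50 — of the two
formulas printed in the source analysis, only this one maps larger
disruption to larger scores.

## SURF

Each metric is percentile-ranked and Phred-scaled with the same cap.
Signed deltas are ranked two-tailed: negatives by increasing magnitude
among negatives, non-negatives among non-negatives, so both strong
stabilisation and strong destabilisation score high; zero sits at the
bottom of the non-negative tail. Distances are ranked ascending. Ranks use
the midpoint (average-tie) convention — `(rank − 0.5)/n` — which is why
the median of an odd-length sample scores exactly `−10·log10(0.5) ≈ 3.01`.
SURF summaries are group maxima: stability (`dMFE`, `dCFE`, `dMEAFE`,
`dEFE`), edit (`MFEED`, `CED`, `EED`, `MEAED`), diversity (`dCD`,
`dEND`), and the overall maximum including the SPI Phred, with the argmax
metric recorded (fixed-order tie-break). A Phred of 5 — the 70th
percentile roughly, and the suggested minimum pathogenicity cut-off — is
exposed as a configuration default, not hard-coded into outputs.

## Synthetic data: what it emulates and what it does not

The generator produces transcripts from a first-order Markov chain with a
requested GC fraction and a CpG enrichment factor applied to the C→G
transition, with a valid CDS (ATG start, stop end, no premature stops).
Population labels are Bernoulli draws from a logistic model over *planted
coefficients on the computed metrics and features* — the windows are
actually folded before labels are drawn, so every end-to-end test
exercises the folding path and would catch a sign inversion between
metric computation and constraint fitting. Positive variants get a
log-uniform (heavy-tailed) MAF on (0, 0.5); configurable fractions of
records receive failing quality fields on disjoint subsets so each filter
rule can be checked against exactly its planted records.

The generator does *not* emulate splicing signals, demography-aware allele
frequencies, mutation-rate heterogeneity beyond the CpG dinucleotide
level, linkage, or realistic coverage structure. Passing tests therefore
demonstrate that the machinery recovers planted statistical structure
through the real folding pipeline — not that the biological effect sizes
or the transcriptome-scale regression tables are reproduced, which would
require the full RefSeq and population callsets.

Study conditions fixed in the generator and tests: a global
P(MAF > 0) of 13.8% (the reference rate for synonymous variants with
adequate coverage), 101-nt windows, and the filter thresholds above.

## Problem sizes and numerical choices

The test-suite and acceptance script run two dataset scales, chosen so a
complete run folds in minutes on a single core: a *screening* set (8
transcripts × ~540 nt, MFE-only folding, ~13k SNVs) for label-model
recovery and type-I control, where only `dMFE` is needed; and a *full* set
(4 transcripts × ~360 nt, partition-function folding with all ten metrics,
~4.5k SNVs) for SPI and SURF behaviour. Statistical sample sizes are
raised where needed by drawing several independent label replicates per
variant — metric values are shared, labels are not, which is exactly the
quantity that matters for binned proportions and model recovery.

Other numerical choices: energies are compared and binned at the backend's
0.1 kcal/mol output resolution; weighted central-90% ranges use the
inverse-CDF quantile of the raw metric values; degenerate cases are
explicit (constant mediator feature → r² = 0 with a warning; fewer than 3
usable bins → context skipped with a log entry; single-class SPI context →
skipped; degenerate CV fold → base-rate fallback). All randomness flows
from user-supplied seeds; reruns are byte-identical.

## Known limitations

* Folding energies depend on the backend's parameter-set version; the
  manifest records the version, and worked-example energies are expected
  to reproduce only within ~0.1–0.2 kcal/mol across versions.
* Transcript-space only: no genome liftover, exon structure or indels.
* The constraint regressions treat bins as independent binomial
  proportions; at desk scale the weighted-least-squares p-values are
  approximate, which is why the type-I property is verified by simulation.
* SPI context models need a few hundred variants per context; contexts
  below the floor are skipped rather than pooled.
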