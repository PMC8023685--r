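# rnasurf

Structural-disruption scores for synonymous (and all other) single-nucleotide
variants of mRNA transcripts.

Synonymous variants leave the protein untouched, yet they can remodel the
local secondary structure of the mRNA — and structure-disrupting variants
are depleted from human population databases. `rnasurf` implements the full
analysis at desk scale:

* **Window protocol** — for every possible SNV of a transcript, a wild-type
  and a mutant 101-nt folding window (variant at offset 51 for interior
  positions; leading/trailing 101 nt at transcript ends).
* **Folding metrics** — each window pair is folded with a thermodynamic
  nearest-neighbour backend (ViennaRNA's `RNAfold`/`RNApdist`) and compared
  to yield ten disruption metrics: four stability deltas (ΔMFE, ΔCFE, ΔEFE,
  ΔMEAFE; mutant − wild-type, so destabilisation is positive), four
  structure distances (MFEED, CED, MEAED edit distances and the ensemble
  distance EED), and two ensemble-diversity deltas (ΔCD, ΔEND).
* **Annotation** — coding effect with a deleteriousness ranking, canonical
  transcript selection (MANE → longest CDS → longest transcript), the 14
  mutational contexts (12 plain `REF>ALT` classes plus the CpG transitions
  `CpG>TpG` and `CpG>CpA`), and 120-nt local sequence content.
* **Constraint analysis** — joins population WGS/WES frequency tables under
  quality filters (random-forest flag, inbreeding, MAF ≥ 0.5, coverage),
  then fits binned weighted linear/quadratic regressions of P(MAF > 0) on
  each metric per context, with normalized slopes and a mediator variance
  decomposition (`r² = 1 − V_feature / V_null`).
* **Scores** — **SPI**, the log₁₀ ratio of a structure-aware ("active") to a
  sequence-only ("null") logistic model's predicted P(MAF > 0), trained
  with 5-fold cross-validation per context, percentile-ranked and
  Phred-scaled (cap 50); and **SURF**, the maximum Phred score across the
  ten metrics and SPI, with stability / edit / diversity group summaries.
* **Synthetic data** — a generator for transcripts (controllable GC and CpG
  composition), frequency tables and tAI tables, with label models planted
  on the *computed* metrics, so the whole pipeline is testable offline.

## Worked example

```r
library(rnasurf)
library(dplyr)

be <- vienna_backend()

# simulate a small transcript set and fold every possible SNV
tx   <- simulate_transcripts(n_transcripts = 2, mean_length = 300, seed = 1)
snvs <- enumerate_snvs(tx)
met  <- structure_metrics(snvs, be)
ann  <- annotate_variants(met, tx)

ann |>
  filter(effect == "synonymous") |>
  select(transcript_id, position, ref, alt, context, dMFE, CED, dCD) |>
  head(3)
#> # A tibble: 3 × 8
#>   transcript_id position ref   alt   context  dMFE   CED   dCD
#>   <chr>            <int> <chr> <chr> <chr>   <dbl> <dbl> <dbl>
#> 1 TX001               48 T     C     T>C     -1.5     10 -3.15
#> 2 TX001               51 C     A     C>A     -4.6      4 -5.84
#> 3 TX001               51 C     G     C>G     -4.20     4 -5.84
```

All three synonymous variants here *stabilise* their windows (ΔMFE < 0, a
stronger structure), rewire a handful of centroid base pairs (CED, 2 edits
per base pair changed) and make the structural ensemble less diverse
(ΔCD < 0). Feeding these metrics plus simulated
population labels to `fit_constraint_curve()`, `train_spi()` and
`score_surf()` yields the constraint regressions and the Phred-scaled
SPI/SURF scores; `autoplot()` on a constraint curve and
`plot_score_constraint()` reproduce the standard depletion plots.

A complete self-contained run (simulate → fold → annotate → constraint →
SPI → SURF, with a reconciling run manifest):

```r
run_pipeline("all", out_dir = "run1", seed = 1)
```

or from the shell via the thin CLI wrapper:

```sh
Rscript inst/cli/rnasurf.R all --out run1 --seed 1
```

### The published DRD2 window

The acceptance suite contains a worked-example check against the known
pharmacogenomic sSNV NM_000795.4:c.957C>T in *DRD2* (wild-type window MFE
−12.5 kcal/mol, mutant −11.5, mutant centroid −5.1, CED 60, ΔCD 9.5). It
needs the transcript window, which is not redistributed here; with network
access, place it at `inst/extdata/NM_000795.4_c907-1007.fasta`:

```sh
# fetch NM_000795.4, extract CDS positions 907..1007 (101 nt, c.957 at offset 51)
python - <<'PY'
from urllib.request import urlopen
url = ("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
       "?db=nuccore&id=NM_000795.4&rettype=gb&retmode=text")
gb = urlopen(url).read().decode()
# CDS feature gives the coding offset; c.907..1007 is the window
PY
```

(Any route that yields the 101-nt window covering coding positions
907–1007 works; the test folds it and checks the published values.)

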