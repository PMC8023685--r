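# Shared fixtures, built once per test run and memoised. Folding results are
# additionally memoised inside the backend, so overlapping requests across
# tests never refold a window.

the <- new.env(parent = emptyenv())

shared_backend <- function() {
  if (is.null(the$backend)) the$backend <- rnasurf::vienna_backend()
  the$backend
}

# Fast screening dataset for label-model recovery: MFE-only folding of every
# SNV of 8 transcripts (~13k SNVs), annotated. Used for the constraint slope
# and type-I checks, where only dMFE matters.
screening_dataset <- function() {
  if (is.null(the$screening)) {
    tx <- rnasurf::simulate_transcripts(n_transcripts = 8, mean_length = 540,
                                        seed = 42)
    snvs <- rnasurf::enumerate_snvs(tx)
    met <- rnasurf::structure_metrics(snvs, shared_backend(),
                                      pf = FALSE, eed = FALSE)
    ann <- rnasurf::annotate_variants(met, tx)
    the$screening <- list(transcripts = tx,
                          synonymous = dplyr::filter(ann, effect == "synonymous"))
  }
  the$screening
}

# Full-metric dataset: partition-function folding (all ten metrics) of every
# SNV of 4 transcripts (~4.5k SNVs), annotated. Used for SPI / SURF checks.
full_dataset <- function() {
  if (is.null(the$full)) {
    tx <- rnasurf::simulate_transcripts(n_transcripts = 4, mean_length = 360,
                                        cpg_factor = 1.5, seed = 7)
    snvs <- rnasurf::enumerate_snvs(tx)
    met <- rnasurf::structure_metrics(snvs, shared_backend(), pf = TRUE)
    ann <- rnasurf::annotate_variants(met, tx)
    the$full <- list(transcripts = tx, variants = ann,
                     synonymous = dplyr::filter(ann, effect == "synonymous"),
                     tai = rnasurf::simulate_tai(seed = 7))
  }
  the$full
}

# Intercept for planted-effect label models that keeps the global
# P(MAF > 0) near the 13.8% study condition despite non-centred metrics.
centered_beta <- function(data, slopes, p_global = 0.138) {
  shift <- sum(vapply(names(slopes), function(nm) {
    slopes[[nm]] * mean(data[[nm]])
  }, numeric(1)))
  c("(Intercept)" = stats::qlogis(p_global) - shift, slopes)
}

weighted_spearman <- function(x, y) {
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

# Binned P(MAF>0) over integer score bins with a minimum bin size.
score_bins <- function(data, score, min_n = 200) {
  data |>
    dplyr::mutate(bin = floor(.data[[score]])) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(n = dplyr::n(), p = mean(maf_positive),
                     .groups = "drop") |>
    dplyr::filter(n >= min_n)
}
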