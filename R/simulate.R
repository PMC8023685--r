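stop_codons <- c("TAA", "TAG", "TGA")

#' Simulate mRNA transcripts with controllable composition
#'
#' Sequences are drawn from a first-order Markov chain whose stationary base
#' composition matches the requested GC fraction and whose C-to-G transition
#' is multiplied by the CpG enrichment factor (dinucleotide-level control of
#' CpG content). Each transcript carries a CDS beginning with `ATG`, ending
#' in a stop codon and free of premature stops, flanked by 5' and 3' UTRs.
#'
#' @param n_transcripts Number of transcripts (default 20, the desk-scale
#'   preset).
#' @param mean_length,length_sd Transcript length distribution (nt);
#'   lengths are truncated below at 150 nt.
#' @param gc GC fraction in `[0, 1]`.
#' @param cpg_factor Multiplier on the C-to-G transition probability
#'   (1 = no enrichment). Requesting enrichment with `gc = 0` is infeasible
#'   and raises a config error.
#' @param utr5_frac,utr3_frac Fractions of the transcript length assigned to
#'   the UTRs.
#' @param seed Random seed; the same seed reproduces the dataset exactly.
#' @return Transcript tibble as from [read_transcripts()].
#' @export
simulate_transcripts <- function(n_transcripts = 20, mean_length = 600,
                                 length_sd = 0.1 * mean_length,
                                 gc = 0.5, cpg_factor = 1,
                                 utr5_frac = 0.15, utr3_frac = 0.25,
                                 seed = 1) {
  if (gc < 0 || gc > 1) abort("gc must lie in [0, 1]")
  if (gc == 0 && cpg_factor > 1) {
    abort("infeasible composition: CpG enrichment requires gc > 0")
  }
  bases <- c("A", "C", "G", "T")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  trans <- matrix(rep(p, 4), nrow = 4, byrow = TRUE,
                  dimnames = list(bases, bases))
  trans["C", "G"] <- trans["C", "G"] * cpg_factor
  trans["C", ] <- trans["C", ] / sum(trans["C", ])
  withr::with_seed(seed, {
    lens <- pmax(150L, as.integer(round(rnorm(n_transcripts, mean_length,
                                              length_sd))))
    tx <- purrr::map(seq_len(n_transcripts), function(i) {
      len <- lens[i]
      s <- character(len)
      s[1] <- sample(bases, 1, prob = p)
      for (j in 2:len) {
        s[j] <- sample(bases, 1, prob = trans[s[j - 1], ])
      }
      u5 <- max(1L, round(utr5_frac * len))
      u3 <- max(1L, round(utr3_frac * len))
      cds_len <- len - u5 - u3
      cds_len <- cds_len - cds_len %% 3L
      cds_start <- u5 + 1L
      cds_end <- cds_start + cds_len - 1L
      s[cds_start:(cds_start + 2L)] <- c("A", "T", "G")
      s[(cds_end - 2L):cds_end] <- strsplit(sample(stop_codons, 1), "")[[1]]
      # remove premature stops (third-base swap keeps composition close)
      for (cs in seq(cds_start + 3L, cds_end - 3L, by = 3L)) {
        if (paste(s[cs:(cs + 2L)], collapse = "") %in% stop_codons) {
          s[cs + 2L] <- "T"
        }
      }
      tibble(
        transcript_id = sprintf("TX%03d", i),
        gene_id = sprintf("G%03d", i),
        sequence = paste(s, collapse = ""),
        cds_start = cds_start, cds_end = cds_end,
        is_mane = TRUE
      )
    }) |> bind_rows()
    validate_transcripts(tx)
    tx
  })
}

#' Simulate MAF > 0 labels from planted coefficients
#'
#' Draws a Bernoulli label per variant (optionally replicated) with
#' `logit P(MAF > 0) = beta' x` over the named columns of the variant
#' table, so planted effects act on the *computed* structural metrics, not
#' on surrogate columns.
#'
#' @param variants Variant tibble carrying every column named in `beta`.
#' @param beta Named numeric vector of coefficients; the name
#'   `"(Intercept)"` is the intercept, all other names must be columns of
#'   `variants`.
#' @param seed Random seed.
#' @param replicates Independent label draws per variant (rows are repeated
#'   with a `replicate` column); metric values are shared, labels are not.
#' @return `variants` expanded by `replicate`, with `p_true` and the drawn
#'   logical `maf_positive`.
#' @export
simulate_labels <- function(variants, beta, seed = 1, replicates = 1) {
  nm <- setdiff(names(beta), "(Intercept)")
  miss <- setdiff(nm, names(variants))
  if (length(miss) > 0) {
    abort(paste0("beta names not in variant table: ",
                 paste(miss, collapse = ", ")))
  }
  eta <- rep(beta[["(Intercept)"]] %||% 0, nrow(variants))
  for (v in nm) eta <- eta + beta[[v]] * variants[[v]]
  if (anyNA(eta)) abort("NA in linear predictor: check beta columns")
  out <- variants[rep(seq_len(nrow(variants)), times = replicates), ]
  out$replicate <- rep(seq_len(replicates), each = nrow(variants))
  out$p_true <- plogis(rep(eta, times = replicates))
  withr::with_seed(seed, {
    out$maf_positive <- runif(nrow(out)) < out$p_true
  })
  out
}

#' Simulate WGS and WES population-frequency tables
#'
#' Labels are drawn with [simulate_labels()]; positive variants receive a
#' heavy-tailed (log-uniform) MAF on (0, 0.5). Both datasets share the same
#' underlying population truth, and each independently receives a
#' configurable fraction of records with failing quality fields (random
#' forest, inbreeding, reference-is-minor MAF, low coverage) on *disjoint*
#' record subsets, to exercise the filter rules.
#'
#' @param variants Variant tibble with metric/feature columns.
#' @param beta Planted coefficients, see [simulate_labels()].
#' @param seed Random seed.
#' @param frac_rf_fail,frac_inbreeding,frac_high_maf,frac_low_coverage
#'   Fractions of records planted to fail each filter.
#' @return List with `wgs`, `wes` (frequency record tibbles) and `truth`
#'   (the label table).
#' @export
simulate_frequencies <- function(variants, beta = c("(Intercept)" = qlogis(0.138)),
                                 seed = 1, frac_rf_fail = 0.01,
                                 frac_inbreeding = 0.002,
                                 frac_high_maf = 0.001,
                                 frac_low_coverage = 0.02) {
  truth <- simulate_labels(variants, beta, seed = seed, replicates = 1)
  n <- nrow(truth)
  key <- truth[, c("transcript_id", "position", "ref", "alt")]
  withr::with_seed(seed + 1L, {
    maf <- ifelse(truth$maf_positive, 10^runif(n, -5, log10(0.49)), 0)
    make_set <- function(ds_seed) {
      withr::with_seed(ds_seed, {
        rec <- bind_cols(key, tibble(
          maf = maf,
          rf_fail = FALSE,
          inbreeding_coeff = runif(n, -0.1, 0.1),
          coverage_frac_ge20x = runif(n, 0.85, 1)
        ))
        pool <- sample(n)
        take <- function(frac) {
          k <- round(frac * n)
          out <- head(pool, k)
          pool <<- tail(pool, length(pool) - k)
          out
        }
        i_rf <- take(frac_rf_fail)
        i_ib <- take(frac_inbreeding)
        i_maf <- take(frac_high_maf)
        i_cov <- take(frac_low_coverage)
        rec$rf_fail[i_rf] <- TRUE
        rec$inbreeding_coeff[i_ib] <- runif(length(i_ib), -0.9, -0.45)
        rec$maf[i_maf] <- runif(length(i_maf), 0.5, 0.95)
        rec$coverage_frac_ge20x[i_cov] <- runif(length(i_cov), 0.2, 0.65)
        attr(rec, "planted") <- list(rf_fail = i_rf, inbreeding = i_ib,
                                     maf_ge_0.5 = i_maf, low_coverage = i_cov)
        rec
      })
    }
    wgs <- make_set(seed + 2L) |> mutate(dataset = "WGS", .before = "maf")
    wes <- make_set(seed + 3L) |> mutate(dataset = "WES", .before = "maf")
    pl_wgs <- attr(wgs, "planted")
    pl_wes <- attr(wes, "planted")
    attr(wgs, "planted") <- pl_wgs
    attr(wes, "planted") <- pl_wes
    list(wgs = wgs, wes = wes, truth = truth)
  })
}

#' Simulate a codon adaptivity (tAI) table
#'
#' Sense codons receive uniform adaptivities; stop codons are included with
#' adaptivity 0 (no tRNA reads them) so that stop-retaining synonymous
#' substitutions in the stop codon remain scoreable.
#'
#' @param seed Random seed.
#' @return Tibble `(codon, tai)` over all 64 codons.
#' @export
simulate_tai <- function(seed = 1) {
  bases <- c("A", "C", "G", "T")
  codons <- sort(as.vector(outer(outer(bases, bases, paste0), bases, paste0)))
  withr::with_seed(seed, {
    tai <- round(runif(length(codons), 0.05, 1), 3)
    tai[codons %in% stop_codons] <- 0
    tibble(codon = codons, tai = tai)
  })
}

#' Simulate a complete desk-scale dataset through the real pipeline
#'
#' Generates transcripts, enumerates and folds every SNV (planted effects
#' act on the *computed* metrics), annotates them, and simulates
#' population-frequency tables — exercising every stage of the pipeline
#' with no external inputs.
#'
#' @inheritParams simulate_transcripts
#' @param beta Planted label coefficients (default: intercept-only with a
#'   global P(MAF > 0) of 13.8%).
#' @param backend Folding backend (default [vienna_backend()]).
#' @param pf,eed Folding options, see [structure_metrics()].
#' @param seed Master seed (stage seeds are derived from it).
#' @return List with `transcripts`, `variants` (annotated with metrics),
#'   `wgs`, `wes`, `truth` and `tai`.
#' @export
simulate_dataset <- function(n_transcripts = 20, mean_length = 600,
                             gc = 0.5, cpg_factor = 1,
                             beta = c("(Intercept)" = qlogis(0.138)),
                             backend = vienna_backend(),
                             pf = TRUE, eed = pf, seed = 1) {
  tx <- simulate_transcripts(n_transcripts = n_transcripts,
                             mean_length = mean_length, gc = gc,
                             cpg_factor = cpg_factor, seed = seed)
  snvs <- enumerate_snvs(tx)
  met <- structure_metrics(snvs, backend, pf = pf, eed = eed)
  ann <- annotate_variants(met, tx)
  freqs <- simulate_frequencies(ann, beta = beta, seed = seed + 1000L)
  list(transcripts = tx, variants = ann, wgs = freqs$wgs, wes = freqs$wes,
       truth = freqs$truth, tai = simulate_tai(seed + 2000L))
}
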