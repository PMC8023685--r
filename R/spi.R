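#' Midpoint percentile rank
#'
#' Fraction of values strictly below each value plus half the ties (average
#' ranks shifted by one half), so ranks lie strictly inside (0, 1) and the
#' median of an odd-length sample sits exactly at 0.5.
#'
#' @param x Numeric vector.
#' @return Percentile ranks in (0, 1).
#' @export
percentile_rank <- function(x) {
  (rank(x, ties.method = "average") - 0.5) / length(x)
}

#' Phred-scale a percentile rank
#'
#' `-10 * log10(1 - percentile)`, capped at 50 (the 99.999th percentile and
#' above all map to 50), so larger predicted disruption maps to a larger
#' score.
#'
#' @param percentile Percentile ranks in `[0, 1)`.
#' @return Phred scores in `[0, 50]`.
#' @export
phred_scale <- function(percentile) {
  pmin(50, -10 * log10(1 - percentile))
}

#' Phred-scale a structural metric
#'
#' For signed delta metrics, negative values are percentile-ranked by
#' increasing magnitude among the negatives and non-negative values among
#' the non-negatives, so both tails of the distribution (strong
#' stabilisation or destabilisation) receive high scores. Distance metrics
#' are ranked ascending over all values.
#'
#' @param values Metric values.
#' @param kind `"signed"` (delta metrics) or `"distance"`.
#' @return Phred scores in `[0, 50]`.
#' @export
phred_scale_metric <- function(values, kind = c("signed", "distance")) {
  kind <- match.arg(kind)
  if (length(values) == 0) abort("phred_scale_metric: empty input")
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  if (kind == "distance") {
    out[ok] <- phred_scale(percentile_rank(values[ok]))
    return(out)
  }
  neg <- ok & values < 0
  pos <- ok & values >= 0
  if (any(neg)) out[neg] <- phred_scale(percentile_rank(abs(values[neg])))
  if (any(pos)) out[pos] <- phred_scale(percentile_rank(values[pos]))
  out
}

metric_kind <- c(
  dMFE = "signed", dCFE = "signed", dEFE = "signed", dMEAFE = "signed",
  MFEED = "distance", CED = "distance", EED = "distance", MEAED = "distance",
  dCD = "signed", dEND = "signed"
)

#' Null and active feature sets for the SPI models
#'
#' The null model sees only sequence features: the nine nucleotides of the
#' variant's home and adjacent codons, the six local-content proportions
#' over the surrounding 120 nt, the position in the codon, the transcript
#' (its length plus the gene grouping key) and the tRNA adaptivity of the
#' wild-type and mutant codons. The active model adds the ten structural
#' metrics and the binding statuses of the variant base in the wild-type
#' and mutant MFE structures.
#'
#' @param data Annotated, metric-bearing synonymous-SNV tibble (from
#'   [structure_metrics()] then [annotate_variants()]).
#' @param tai_table Tibble `(codon, tai)`; a codon without an entry is a
#'   hard error.
#' @return List with tibbles `null` and `active` (the active set has the
#'   null columns plus 10 metrics plus 2 binding statuses) and `key`, the
#'   variant key columns.
#' @export
build_spi_features <- function(data, tai_table) {
  stopifnot(all(c("ref_codon", "alt_codon", "codon_position") %in% names(data)))
  tai <- setNames(tai_table$tai, tai_table$codon)
  lookup_tai <- function(codons) {
    v <- tai[codons]
    if (anyNA(v)) {
      abort(paste0("no tAI entry for codon: ", codons[which(is.na(v))[1]]))
    }
    unname(v)
  }
  nt_cols <- paste0("nt", 1:9)
  null_features <- bind_cols(
    data[, nt_cols],
    data[, c("prop_A", "prop_C", "prop_G", "prop_T", "prop_CpG", "prop_AT")],
    tibble(
      codon_position = factor(data$codon_position, levels = 1:3),
      transcript_length = data$transcript_length,
      gene_key = factor(data$transcript_id),
      tai_wt = lookup_tai(data$ref_codon),
      tai_mut = lookup_tai(data$alt_codon)
    )
  )
  null_features[nt_cols] <- lapply(null_features[nt_cols],
                                   factor, levels = c("A", "C", "G", "T", "X"))
  active_features <- bind_cols(
    null_features,
    data[, metric_names],
    tibble(wt_paired = data$wt_paired, mut_paired = data$mut_paired)
  )
  list(null = null_features, active = active_features,
       key = data[, intersect(c("transcript_id", "position", "ref", "alt",
                                "replicate"), names(data))])
}

design_matrix <- function(features) {
  # drop constant columns (single-level factors break model.matrix)
  keep <- vapply(features, function(col) length(unique(col)) > 1, logical(1))
  f <- features[, keep, drop = FALSE]
  if (ncol(f) == 0) abort("no informative features")
  stats::model.matrix(~ ., data = f)[, -1, drop = FALSE]
}

fit_ridge <- function(x, y, lambda, thresh = 1e-6) {
  glmnet::glmnet(x, y, family = "binomial", alpha = 0, lambda = lambda,
                 standardize = TRUE, thresh = thresh)
}

#' Train the Structural Predictivity Index (SPI)
#'
#' Within each mutational context, fits a null (sequence-only) and an active
#' (sequence + structure) regularized logistic model for the event
#' MAF > 0 using 5-fold cross-validation; each variant's two probabilities
#' are the averages of the predictions of all fold models (set
#' `out_of_fold = TRUE` for strict held-out predictions). The raw score is
#' `spi_raw = log10(p_active / p_null)`; within each context it is z-scored
#' and percentile-ranked by *decreasing* `spi_raw` (so structure-predicted
#' depletion earns a high score) and Phred-scaled with cap 50.
#'
#' @param data Annotated synonymous-SNV tibble with metrics and a logical
#'   `maf_positive` label column.
#' @param tai_table Codon adaptivity table `(codon, tai)`.
#' @param n_folds Number of cross-validation folds (default 5).
#' @param seed Seed controlling fold assignment (results are bit-identical
#'   for a fixed seed).
#' @param min_context_size Contexts with fewer variants are skipped.
#' @param lambda Ridge penalty for the logistic models.
#' @param out_of_fold Average only the held-out fold's prediction.
#' @return An `spi_fit` object; [tidy()] returns the per-variant score
#'   table, [glance()] per-context summaries.
#' @export
train_spi <- function(data, tai_table, n_folds = 5, seed = 1,
                      min_context_size = 200, lambda = 1e-3,
                      out_of_fold = FALSE) {
  stopifnot("maf_positive" %in% names(data), "context" %in% names(data))
  scores <- withr::with_seed(seed, {
    purrr::map(split(data, data$context), function(d) {
      if (nrow(d) < min_context_size) {
        warn(paste0("SPI: context ", d$context[[1]], " skipped (",
                    nrow(d), " < ", min_context_size, " variants)"))
        return(NULL)
      }
      y <- as.numeric(d$maf_positive)
      if (length(unique(y)) < 2) {
        warn(paste0("SPI: context ", d$context[[1]],
                    " skipped (single-class labels)"))
        return(NULL)
      }
      feats <- build_spi_features(d, tai_table)
      x_null <- design_matrix(feats$null)
      x_active <- design_matrix(feats$active)
      folds <- sample(rep_len(seq_len(n_folds), nrow(d)))
      p_null <- matrix(NA_real_, nrow(d), n_folds)
      p_active <- matrix(NA_real_, nrow(d), n_folds)
      for (k in seq_len(n_folds)) {
        train <- folds != k
        if (min(table(factor(y[train], levels = c(0, 1)))) < 2) {
          # degenerate fold (tiny context): fall back to the base rate
          p_null[, k] <- p_active[, k] <- mean(y[train])
        } else {
          m_null <- fit_ridge(x_null[train, , drop = FALSE], y[train], lambda)
          m_active <- fit_ridge(x_active[train, , drop = FALSE], y[train], lambda)
          p_null[, k] <- as.vector(predict(m_null, x_null, type = "response"))
          p_active[, k] <- as.vector(predict(m_active, x_active, type = "response"))
        }
        if (out_of_fold) {
          p_null[train, k] <- NA_real_
          p_active[train, k] <- NA_real_
        }
      }
      pn <- rowMeans(p_null, na.rm = TRUE)
      pa <- rowMeans(p_active, na.rm = TRUE)
      spi_raw <- log10(pa / pn)
      s <- sd(spi_raw)
      if (!is.finite(s) || s == 0) s <- 1
      spi_z <- (spi_raw - mean(spi_raw)) / s
      spi_percentile <- percentile_rank(-spi_raw)
      bind_cols(
        feats$key,
        tibble(
          context = d$context,
          maf_positive = d$maf_positive,
          p_null = pn, p_active = pa,
          spi_raw = spi_raw, spi_z = spi_z,
          spi_percentile = spi_percentile,
          spi_phred = phred_scale(spi_percentile)
        )
      )
    }) |> bind_rows()
  })
  if (nrow(scores) == 0) abort("SPI: no context could be trained")
  structure(
    list(scores = scores, n_folds = n_folds, seed = seed, lambda = lambda,
         out_of_fold = out_of_fold),
    class = "spi_fit"
  )
}

#' @export
print.spi_fit <- function(x, ...) {
  cat("SPI fit:", nrow(x$scores), "variants in",
      length(unique(x$scores$context)), "contexts (",
      x$n_folds, "-fold CV, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

auc_rank <- function(score, label) {
  # Wilcoxon AUC
  r <- rank(score)
  n1 <- sum(label)
  n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
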