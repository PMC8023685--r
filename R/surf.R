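surf_groups <- list(
  stability = c("dMFE", "dCFE", "dMEAFE", "dEFE"),
  edit = c("MFEED", "CED", "EED", "MEAED"),
  diversity = c("dCD", "dEND")
)

# fixed argmax tie-break order: the ten metrics then SPI
surf_metric_order <- c("dMFE", "dCFE", "dMEAFE", "dEFE",
                       "MFEED", "CED", "EED", "MEAED", "dCD", "dEND", "SPI")

#' Summarise per-metric Phred scores into SURF scores
#'
#' For each variant, takes the maximum Phred score across the four stability
#' metrics (`surf_stability`), the four edit-distance metrics (`surf_edit`),
#' the two diversity metrics (`surf_diversity`), and across all ten metrics
#' plus SPI (`surf`), recording which metric attained the overall maximum
#' (ties break by a fixed metric order).
#'
#' @param phreds Tibble with Phred columns `phred_dMFE`, `phred_dCFE`,
#'   `phred_dEFE`, `phred_dMEAFE`, `phred_MFEED`, `phred_CED`, `phred_EED`,
#'   `phred_MEAED`, `phred_dCD`, `phred_dEND` and `spi_phred`. A missing
#'   column is a hard error.
#' @return Tibble with `surf_stability`, `surf_edit`, `surf_diversity`,
#'   `surf`, `surf_argmax`.
#' @export
summarize_surf <- function(phreds) {
  cols <- c(paste0("phred_", metric_names), "spi_phred")
  miss <- setdiff(cols, names(phreds))
  if (length(miss) > 0) {
    abort(paste0("summarize_surf: missing Phred column(s): ",
                 paste(miss, collapse = ", ")))
  }
  grp_max <- function(metrics) {
    do.call(pmax, c(unname(as.list(phreds[, paste0("phred_", metrics)])),
                    list(na.rm = FALSE)))
  }
  surf_stability <- grp_max(surf_groups$stability)
  surf_edit <- grp_max(surf_groups$edit)
  surf_diversity <- grp_max(surf_groups$diversity)
  surf <- pmax(surf_stability, surf_edit, surf_diversity, phreds$spi_phred)
  all_cols <- c(paste0("phred_", surf_metric_order[1:10]), "spi_phred")
  m <- as.matrix(phreds[, all_cols])
  argmax <- surf_metric_order[apply(m, 1, which.max)]
  tibble(
    surf_stability = surf_stability,
    surf_edit = surf_edit,
    surf_diversity = surf_diversity,
    surf = surf,
    surf_argmax = argmax
  )
}

#' Score a metric table with per-metric Phreds and SURF summaries
#'
#' Phred-scales each of the ten structural metrics over the supplied table
#' (signed deltas two-tailed, distances one-tailed; see
#' [phred_scale_metric()]), joins the SPI Phred when given, and appends the
#' SURF group maxima. Without an SPI fit, SURF is the maximum over the ten
#' metric Phreds only.
#'
#' @param data Metric-bearing SNV tibble.
#' @param spi Optional `spi_fit` object (or a tibble with the variant key
#'   and `spi_phred`).
#' @return `data` with `phred_*` columns, `spi_phred` (0 where unavailable)
#'   and the SURF columns appended.
#' @export
score_surf <- function(data, spi = NULL) {
  out <- data
  for (m in metric_names) {
    out[[paste0("phred_", m)]] <- phred_scale_metric(out[[m]],
                                                     metric_kind[[m]])
  }
  if (is.null(spi)) {
    out$spi_phred <- 0
  } else {
    sc <- if (inherits(spi, "spi_fit")) spi$scores else spi
    key <- intersect(c("transcript_id", "position", "ref", "alt", "replicate"),
                     intersect(names(out), names(sc)))
    out <- left_join(out, sc[, c(key, "spi_phred")], by = key)
    out$spi_phred <- dplyr::coalesce(out$spi_phred, 0)
  }
  bind_cols(out, summarize_surf(out))
}
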