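#' Quality and coverage filters for population-frequency records
#'
#' Applies, in order: record completeness, random-forest filter status,
#' inbreeding coefficient, reference-is-minor (`maf >= 0.5`) and coverage
#' (fraction of samples at >= 20x depth). Each dropped record is tallied
#' under the first rule it fails, so input count = retained + sum of drops.
#'
#' @param records Tibble with columns `transcript_id`, `position`, `ref`,
#'   `alt`, `dataset`, `maf`, `rf_fail`, `inbreeding_coeff`,
#'   `coverage_frac_ge20x`.
#' @param inbreeding_threshold Minimum inbreeding coefficient (default -0.3).
#' @param maf_max Records with `maf >=` this are dropped (default 0.5).
#' @param min_coverage Minimum `coverage_frac_ge20x` (default 0.70).
#' @return A list with `records` (retained tibble) and `tally` (tibble of
#'   `rule`, `n` including `"retained"`).
#' @export
apply_filters <- function(records, inbreeding_threshold = -0.3,
                          maf_max = 0.5, min_coverage = 0.70) {
  needed <- c("maf", "rf_fail", "inbreeding_coeff", "coverage_frac_ge20x")
  miss_col <- setdiff(needed, names(records))
  if (length(miss_col) > 0) {
    abort(paste0("frequency records are missing column(s): ",
                 paste(miss_col, collapse = ", ")))
  }
  reason <- rep(NA_character_, nrow(records))
  incomplete <- !complete.cases(records[, needed])
  reason[incomplete] <- "missing_field"
  flag <- function(cond, label) {
    hit <- is.na(reason) & cond
    reason[hit] <<- label
  }
  flag(records$rf_fail, "rf_fail")
  flag(records$inbreeding_coeff < inbreeding_threshold, "inbreeding")
  flag(records$maf >= maf_max, "maf_ge_0.5")
  flag(records$coverage_frac_ge20x < min_coverage, "low_coverage")
  tally <- tibble(rule = c("retained", "missing_field", "rf_fail",
                           "inbreeding", "maf_ge_0.5", "low_coverage")) |>
    mutate(n = vapply(.data$rule, function(r) {
      if (r == "retained") sum(is.na(reason)) else sum(reason == r, na.rm = TRUE)
    }, numeric(1)))
  list(records = records[is.na(reason), ], tally = tally)
}

#' Joint WGS/WES allele-frequency call for one variant
#'
#' Under the default intersection-pass/union-positive scheme a variant is
#' analyzed only if it passed all filters in both datasets, and has
#' `maf_positive = TRUE` if its MAF is positive in either. A variant that is
#' analyzed with `maf_positive = FALSE` is "constrained" (absent from both
#' datasets). A missing record is treated as a covered reference-monomorphic
#' site (MAF 0, passing).
#'
#' @param wgs_record,wes_record One-row tibbles of filtered records (or
#'   `NULL` when the dataset has no record), carrying an attribute-free
#'   `maf` column; pass `passed = FALSE` rows via `wgs_pass`/`wes_pass`.
#' @param wgs_pass,wes_pass Did the record pass the filters (default `TRUE`
#'   when the record is `NULL`/absent).
#' @param scheme Combination scheme, see [combine_frequencies()].
#' @return A list with `analyzed` and `maf_positive` logicals.
#' @export
joint_maf_flag <- function(wgs_record = NULL, wes_record = NULL,
                           wgs_pass = TRUE, wes_pass = TRUE,
                           scheme = "intersect_pass_union_positive") {
  wgs_maf <- if (is.null(wgs_record)) 0 else wgs_record$maf[[1]]
  wes_maf <- if (is.null(wes_record)) 0 else wes_record$maf[[1]]
  res <- combine_maf(wgs_maf, wes_maf, wgs_pass, wes_pass, scheme)
  list(analyzed = res$analyzed, maf_positive = res$maf_positive)
}

scheme_names <- c("intersect_pass_union_positive",
                  "intersect_pass_intersect_positive",
                  "union_pass_union_positive",
                  "union_pass_intersect_positive",
                  "wgs_only", "wes_only")

combine_maf <- function(wgs_maf, wes_maf, wgs_pass, wes_pass, scheme) {
  scheme <- match.arg(scheme, scheme_names)
  analyzed <- switch(scheme,
    intersect_pass_union_positive = ,
    intersect_pass_intersect_positive = wgs_pass & wes_pass,
    union_pass_union_positive = ,
    union_pass_intersect_positive = wgs_pass | wes_pass,
    wgs_only = wgs_pass,
    wes_only = wes_pass
  )
  maf_positive <- switch(scheme,
    intersect_pass_union_positive = ,
    union_pass_union_positive = (wgs_maf > 0) | (wes_maf > 0),
    intersect_pass_intersect_positive = ,
    union_pass_intersect_positive = (wgs_maf > 0) & (wes_maf > 0),
    wgs_only = wgs_maf > 0,
    wes_only = wes_maf > 0
  )
  tibble(analyzed = analyzed, maf_positive = analyzed & maf_positive)
}

#' Combine filtered WGS and WES frequency tables into joint labels
#'
#' Applies [apply_filters()] to each dataset and derives, per variant, the
#' joint `analyzed` and `maf_positive` flags under the chosen combination
#' scheme (default: must pass filters in both datasets; positive if positive
#' in either). Variants absent from a dataset's table are treated as covered
#' MAF-0 sites in that dataset.
#'
#' @param wgs,wes Frequency record tibbles (see [apply_filters()]).
#' @param scheme One of `r paste0('\x60', scheme_names, '\x60', collapse = ", ")`.
#' @param universe Optional tibble of variant keys (`transcript_id`,
#'   `position`, `ref`, `alt`) defining all variants under study; keys absent
#'   from both frequency tables are covered MAF-0 sites (constrained).
#'   Defaults to the keys present in either table.
#' @param ... Passed to [apply_filters()].
#' @return A tibble keyed by `transcript_id`, `position`, `ref`, `alt` with
#'   `analyzed` and `maf_positive`, plus the two filter tallies as
#'   attributes `tally_wgs` / `tally_wes`.
#' @export
combine_frequencies <- function(wgs, wes,
                                scheme = "intersect_pass_union_positive",
                                universe = NULL, ...) {
  key <- c("transcript_id", "position", "ref", "alt")
  f_wgs <- apply_filters(wgs, ...)
  f_wes <- apply_filters(wes, ...)
  all_keys <- if (is.null(universe)) {
    dplyr::bind_rows(wgs[, key], wes[, key]) |> distinct()
  } else {
    universe[, key] |> distinct()
  }
  wgs_pass_keys <- f_wgs$records[, key] |> mutate(.wgs_pass = TRUE)
  wes_pass_keys <- f_wes$records[, key] |> mutate(.wes_pass = TRUE)
  wgs_maf <- f_wgs$records[, c(key, "maf")] |> rename(.wgs_maf = "maf")
  wes_maf <- f_wes$records[, c(key, "maf")] |> rename(.wes_maf = "maf")
  present_wgs <- wgs[, key] |> distinct() |> mutate(.wgs_present = TRUE)
  present_wes <- wes[, key] |> distinct() |> mutate(.wes_present = TRUE)
  out <- all_keys |>
    left_join(present_wgs, by = key) |>
    left_join(present_wes, by = key) |>
    left_join(wgs_pass_keys, by = key) |>
    left_join(wes_pass_keys, by = key) |>
    left_join(wgs_maf, by = key) |>
    left_join(wes_maf, by = key) |>
    mutate(
      # absent record = covered MAF-0 site, passes by definition
      .wgs_pass = if_else(is.na(.data$.wgs_present), TRUE,
                          !is.na(.data$.wgs_pass)),
      .wes_pass = if_else(is.na(.data$.wes_present), TRUE,
                          !is.na(.data$.wes_pass)),
      .wgs_maf = dplyr::coalesce(.data$.wgs_maf, 0),
      .wes_maf = dplyr::coalesce(.data$.wes_maf, 0)
    )
  flags <- combine_maf(out$.wgs_maf, out$.wes_maf,
                       out$.wgs_pass, out$.wes_pass, scheme)
  res <- bind_cols(out[, key], flags)
  attr(res, "tally_wgs") <- f_wgs$tally
  attr(res, "tally_wes") <- f_wes$tally
  res
}

#' Metric binning used throughout the constraint analysis
#'
#' Energy metrics (`dMFE`, `dCFE`, `dEFE`, `dMEAFE`) and the continuous
#' ensemble distance `EED` are binned at the folding backend's 0.1 kcal/mol
#' output resolution; the diversity metrics `dCD` and `dEND` are rounded to
#' the nearest integer; the edit distances are already integer-valued.
#'
#' @param x Metric values.
#' @param metric Metric name.
#' @return Binned values.
#' @export
bin_metric <- function(x, metric) {
  if (metric %in% c("dCD", "dEND")) {
    round(x)
  } else if (metric %in% c("MFEED", "CED", "MEAED")) {
    x
  } else {
    round(x * 10) / 10
  }
}

#' Binned weighted constraint regression of P(MAF > 0) on a structural metric
#'
#' Bins the metric (see [bin_metric()]), computes the per-bin proportion of
#' variants with positive MAF, and fits weighted linear and quadratic
#' regressions of that proportion on the bin value, weighted by the number
#' of variants per bin. The quadratic model is reported instead of the
#' linear one when its (weighted) pseudo-R-squared exceeds the linear
#' R-squared by a factor of at least `quadratic_factor`. The normalized
#' slope divides the linear slope by the mean P(MAF > 0) in the data and
#' multiplies by the metric range covering its central 90% of variants.
#'
#' @param data Tibble with the metric column and a logical `maf_positive`.
#' @param metric Metric column name (e.g. `"dMFE"`).
#' @param min_positive_per_bin Bins with fewer positive-MAF variants than
#'   this are excluded from the fit (default 1).
#' @param context Optional context label stored in the result.
#' @param quadratic_factor Selection factor for the quadratic model
#'   (default 5).
#' @return A `constraint_curve` object (see [tidy()], [glance()],
#'   [autoplot.constraint_curve()]), or `NULL` with a warning when fewer
#'   than 3 usable bins remain.
#' @export
fit_constraint_curve <- function(data, metric, min_positive_per_bin = 1,
                                 context = NULL, quadratic_factor = 5) {
  stopifnot(metric %in% names(data), "maf_positive" %in% names(data))
  x_raw <- bin_metric(data[[metric]], metric)
  y <- data$maf_positive
  keep <- !is.na(x_raw) & !is.na(y)
  x_raw <- x_raw[keep]
  y <- y[keep]
  bins <- tibble(x = x_raw, y = as.numeric(y)) |>
    group_by(.data$x) |>
    summarise(n = n(), k = sum(.data$y), .groups = "drop") |>
    mutate(p = .data$k / .data$n,
           excluded = .data$k < min_positive_per_bin)
  usable <- bins[!bins$excluded, ]
  if (nrow(usable) < 3) {
    warn(paste0("constraint fit skipped", if (!is.null(context))
      paste0(" for context ", context), ": fewer than 3 usable bins"))
    return(NULL)
  }
  lin <- lm(p ~ x, data = usable, weights = usable$n)
  quad <- lm(p ~ x + I(x^2), data = usable, weights = usable$n)
  s_lin <- summary(lin)
  wt <- usable$n
  ss_tot <- sum(wt * (usable$p - sum(wt * usable$p) / sum(wt))^2)
  pseudo_r2 <- 1 - sum(wt * stats::residuals(quad)^2) / ss_tot
  quad_coefs <- coef(quad)
  quad_p <- summary(quad)$coefficients["I(x^2)", 4]
  lin_p <- if (nrow(usable) > 2) s_lin$coefficients["x", 4] else NA_real_
  chosen <- if (is.finite(pseudo_r2) && is.finite(s_lin$r.squared) &&
                pseudo_r2 >= quadratic_factor * s_lin$r.squared) {
    "quadratic"
  } else {
    "linear"
  }
  mean_p <- sum(bins$n * bins$p) / sum(bins$n)
  qs <- weighted_quantile(x_raw, c(0.05, 0.95))
  central_range <- diff(qs)
  slope <- unname(coef(lin)["x"])
  normalized_slope <- slope / mean_p * central_range
  leading <- if (chosen == "quadratic") unname(quad_coefs["I(x^2)"]) else slope
  structure(
    list(
      context = context, metric = metric, bins = bins,
      linear = list(slope = slope, intercept = unname(coef(lin)["(Intercept)"]),
                    r2 = s_lin$r.squared, p_value = lin_p),
      quadratic = list(coefficients = quad_coefs, pseudo_r2 = pseudo_r2,
                       p_value = quad_p),
      chosen = chosen,
      normalized_slope = normalized_slope,
      direction = if (leading >= 0) "positive" else "negative",
      mean_p = mean_p, central_range = central_range,
      n = sum(bins$n), min_positive_per_bin = min_positive_per_bin
    ),
    class = "constraint_curve"
  )
}

weighted_quantile <- function(x, probs) {
  x <- sort(x)
  n <- length(x)
  vapply(probs, function(p) x[[max(1L, ceiling(p * n))]], numeric(1))
}

#' @export
print.constraint_curve <- function(x, ...) {
  cat("Constraint curve", if (!is.null(x$context)) paste0("[", x$context, "]"),
      "for", x$metric, "\n")
  cat("  bins:", nrow(x$bins), " variants:", x$n,
      " mean P(MAF>0):", signif(x$mean_p, 3), "\n")
  cat("  linear slope:", signif(x$linear$slope, 4),
      " R2:", signif(x$linear$r2, 3),
      " p:", format(x$linear$p_value, digits = 3), "\n")
  cat("  chosen model:", x$chosen,
      " normalized slope:", signif(x$normalized_slope, 4),
      " direction:", x$direction, "\n")
  invisible(x)
}

#' Variance-decomposition R-squared of a candidate mediator feature
#'
#' Fits a single-feature logistic model for P(MAF > 0 | feature), then
#' measures how much of the metric-binned variation in P(MAF > 0) the
#' feature's predictions recover:
#' `V_feature = sum_x n_x (E[P_est | x] - P(MAF>0 | x))^2`,
#' `V_null = sum_x n_x (P(MAF>0) - P(MAF>0 | x))^2`, and
#' `r2 = 1 - V_feature / V_null`. The sign is set so the feature correlates
#' positively with the MAF > 0 event.
#'
#' @param data Tibble with the metric column, the feature column and
#'   `maf_positive`.
#' @param metric Structural metric column name (defines the bins).
#' @param feature Candidate feature column name (numeric, logical or
#'   factor; a factor fits one probability per level).
#' @param context Optional context label.
#' @return One-row tibble: `context`, `metric`, `feature`, `sign`, `r2`.
#' @export
mediator_r2 <- function(data, metric, feature, context = NULL) {
  stopifnot(metric %in% names(data), feature %in% names(data))
  y <- as.numeric(data$maf_positive)
  f <- data[[feature]]
  if (length(unique(f[!is.na(f)])) < 2) {
    warn(paste0("degenerate (constant) feature '", feature, "': r2 = 0"))
    return(tibble(context = context %||% NA_character_, metric = metric,
                  feature = feature, sign = NA_character_, r2 = 0))
  }
  df <- tibble(y = y, f = f,
               x = bin_metric(data[[metric]], metric))
  fit <- suppressWarnings(glm(y ~ f, data = df, family = binomial()))
  df$p_est <- predict(fit, type = "response")
  p_global <- mean(df$y)
  per_bin <- df |>
    group_by(.data$x) |>
    summarise(n = n(), p = mean(.data$y), e_est = mean(.data$p_est),
              .groups = "drop")
  v_feature <- sum(per_bin$n * (per_bin$e_est - per_bin$p)^2)
  v_null <- sum(per_bin$n * (p_global - per_bin$p)^2)
  r2 <- 1 - v_feature / v_null
  fnum <- suppressWarnings(as.numeric(f))
  sgn <- if (all(is.na(fnum))) {
    NA_character_
  } else if (isTRUE(cor(fnum, y) >= 0)) "+" else "-"
  tibble(context = context %||% NA_character_, metric = metric,
         feature = feature, sign = sgn, r2 = r2)
}

#' Select the mediator: the candidate feature with the highest r2
#'
#' @inheritParams mediator_r2
#' @param candidates Character vector of candidate feature column names
#'   (local-content proportions, flanking nucleotides, codon-position
#'   bases, ...). Ties break lexicographically on the feature name.
#' @return One-row tibble as from [mediator_r2()] for the winning feature.
#' @export
select_mediator <- function(data, metric, candidates, context = NULL) {
  stopifnot(length(candidates) >= 1)
  res <- purrr::map(sort(candidates),
                    function(f) mediator_r2(data, metric, f, context)) |>
    bind_rows()
  res[order(-res$r2, res$feature), ][1, ]
}
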