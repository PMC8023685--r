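freq_rec <- function(n = 1, maf = 0.001, rf_fail = FALSE, inb = 0,
                     cov = 0.95, dataset = "WGS") {
  tibble::tibble(
    transcript_id = paste0("TX", seq_len(n)), position = seq_len(n),
    ref = "C", alt = "T", dataset = dataset, maf = maf, rf_fail = rf_fail,
    inbreeding_coeff = inb, coverage_frac_ge20x = cov
  )
}

test_that("each quality filter fires on its rule and the tally reconciles", {
  recs <- dplyr::bind_rows(
    freq_rec(maf = 0.6),                       # reference is minor
    freq_rec(maf = 0.001, cov = 0.65),         # low coverage
    freq_rec(maf = 0.001, rf_fail = TRUE),     # random-forest fail
    freq_rec(maf = 0.001, inb = -0.5),         # inbreeding
    freq_rec(maf = 0.001),                     # clean
    freq_rec(maf = NA_real_)                   # incomplete record
  )
  res <- apply_filters(recs)
  expect_equal(nrow(res$records), 1L)
  tally <- setNames(res$tally$n, res$tally$rule)
  expect_equal(unname(tally["retained"]), 1)
  expect_equal(unname(tally["maf_ge_0.5"]), 1)
  expect_equal(unname(tally["low_coverage"]), 1)
  expect_equal(unname(tally["rf_fail"]), 1)
  expect_equal(unname(tally["inbreeding"]), 1)
  expect_equal(unname(tally["missing_field"]), 1)
  expect_equal(sum(res$tally$n), nrow(recs))
  # boundary: maf 0.49 and coverage exactly 0.70 are retained
  ok <- apply_filters(dplyr::bind_rows(freq_rec(maf = 0.49, cov = 0.70)))
  expect_equal(nrow(ok$records), 1L)
})

test_that("joint WGS/WES flags follow the intersection-pass union-positive rule", {
  # MAF positive in one passing set only -> analyzed and positive
  r <- joint_maf_flag(wgs_record = freq_rec(maf = 0),
                      wes_record = freq_rec(maf = 0.001, dataset = "WES"))
  expect_true(r$analyzed)
  expect_true(r$maf_positive)
  # one set fails filters -> not analyzed
  r2 <- joint_maf_flag(wgs_record = freq_rec(maf = 0.001),
                       wes_record = freq_rec(maf = 0, dataset = "WES"),
                       wes_pass = FALSE)
  expect_false(r2$analyzed)
  # both zero, both pass -> analyzed and constrained
  r3 <- joint_maf_flag(wgs_record = freq_rec(maf = 0),
                       wes_record = freq_rec(maf = 0, dataset = "WES"))
  expect_true(r3$analyzed)
  expect_false(r3$maf_positive)
})

test_that("combine_frequencies joins variants, fills the universe and keeps tallies", {
  wgs <- dplyr::bind_rows(freq_rec(3), freq_rec(1, cov = 0.5)) |>
    dplyr::mutate(position = c(1, 2, 3, 4))
  wes <- freq_rec(4, maf = c(0, 0.01, 0, 0), dataset = "WES") |>
    dplyr::mutate(transcript_id = wgs$transcript_id, position = wgs$position)
  universe <- dplyr::bind_rows(
    wgs[, c("transcript_id", "position", "ref", "alt")],
    tibble::tibble(transcript_id = "TX9", position = 9, ref = "C", alt = "T")
  )
  out <- combine_frequencies(wgs, wes, universe = universe)
  expect_equal(nrow(out), 5L)
  row4 <- out[out$position == 4, ]
  expect_false(row4$analyzed) # WGS record failed coverage
  row2 <- out[out$position == 2, ]
  expect_true(row2$analyzed)
  expect_true(row2$maf_positive)
  row9 <- out[out$transcript_id == "TX9", ]
  expect_true(row9$analyzed)   # absent from both tables: covered MAF-0 site
  expect_false(row9$maf_positive)
  expect_s3_class(attr(out, "tally_wgs"), "tbl_df")
})

test_that("exact linear data is recovered perfectly and quadratic data selects the quadratic", {
  # plant p_x = 0.2 - 0.01 x exactly, with equal bin sizes
  xs <- 0:9
  n_per <- 100
  rows <- lapply(xs, function(x) {
    k <- round((0.2 - 0.01 * x) * n_per)
    tibble::tibble(dMFE = x, maf_positive = rep(c(TRUE, FALSE),
                                                c(k, n_per - k)))
  })
  d <- dplyr::bind_rows(rows)
  cc <- fit_constraint_curve(d, "dMFE")
  expect_equal(cc$linear$slope, -0.01, tolerance = 1e-10)
  expect_equal(cc$linear$r2, 1, tolerance = 1e-10)
  expect_equal(cc$chosen, "linear")
  expect_equal(cc$direction, "negative")
  # normalized slope = slope / mean p * central-90% range
  expect_equal(cc$normalized_slope,
               -0.01 / mean(d$maf_positive) * cc$central_range)

  # pure quadratic p_x = 0.02 * (x - 4.5)^2 + 0.05
  rows_q <- lapply(xs, function(x) {
    k <- round((0.02 * (x - 4.5)^2 + 0.05) * n_per)
    tibble::tibble(dMFE = x, maf_positive = rep(c(TRUE, FALSE),
                                                c(k, n_per - k)))
  })
  ccq <- fit_constraint_curve(dplyr::bind_rows(rows_q), "dMFE")
  expect_equal(ccq$chosen, "quadratic")
  expect_gt(ccq$quadratic$pseudo_r2, 5 * ccq$linear$r2)

  # too few bins -> skipped with a warning
  expect_warning(
    out <- fit_constraint_curve(dplyr::bind_rows(rows[1:2]), "dMFE"),
    "fewer than 3"
  )
  expect_null(out)
})

test_that("with equal bin weights the weighted fit equals closed-form OLS on bin means", {
  set.seed(51)
  xs <- seq(-3, 3, by = 0.5)
  n_per <- 40
  d <- dplyr::bind_rows(lapply(xs, function(x) {
    tibble::tibble(dMFE = x, maf_positive = runif(n_per) < plogis(-1 + 0.3 * x))
  }))
  cc <- fit_constraint_curve(d, "dMFE", min_positive_per_bin = 0)
  bins <- cc$bins
  # closed-form OLS on the bin means
  beta <- cov(bins$x, bins$p) / var(bins$x)
  alpha <- mean(bins$p) - beta * mean(bins$x)
  expect_equal(cc$linear$slope, beta, tolerance = 1e-12)
  expect_equal(cc$linear$intercept, alpha, tolerance = 1e-12)
})

test_that("metric binning: energies at 0.1, diversity metrics to integers", {
  expect_equal(bin_metric(c(-1.2499, 0.051), "dMFE"), c(-1.2, 0.1))
  expect_equal(bin_metric(c(2.4, 2.6, -0.5), "dCD"), c(2, 3, 0))
  expect_equal(bin_metric(c(4, 10), "CED"), c(4, 10))
})

test_that("the self-mediator attains r2 = 1 and an independent feature attains r2 near 0", {
  set.seed(52)
  n <- 100000
  x <- sample(seq(-2, 2, by = 0.5), n, replace = TRUE)
  y <- runif(n) < plogis(-1.5 - 0.4 * x)
  d <- tibble::tibble(dMFE = x, maf_positive = y,
                      self = factor(bin_metric(x, "dMFE")),
                      noise = rnorm(n))
  m_self <- mediator_r2(d, "dMFE", "self")
  expect_equal(m_self$r2, 1, tolerance = 1e-6)
  m_noise <- mediator_r2(d, "dMFE", "noise")
  expect_lt(abs(m_noise$r2), 0.05)
  # degenerate feature: r2 reported as 0 with a warning
  d$flat <- 1
  expect_warning(m_flat <- mediator_r2(d, "dMFE", "flat"), "degenerate")
  expect_equal(m_flat$r2, 0)
})

test_that("mediator_r2 equals the explicit-summation oracle", {
  set.seed(53)
  n <- 5000
  cpg <- runif(n)
  x <- round(2 * cpg + rnorm(n, sd = 0.4), 1)
  y <- runif(n) < plogis(-1 + 1.5 * cpg)
  d <- tibble::tibble(dMFE = x, maf_positive = y, prop_CpG = cpg)
  m <- mediator_r2(d, "dMFE", "prop_CpG")
  fit <- glm(y ~ cpg, family = binomial())
  oracle <- oracle_mediator_r2(as.numeric(y), predict(fit, type = "response"),
                               bin_metric(x, "dMFE"))
  expect_equal(m$r2, oracle, tolerance = 1e-8)
  expect_equal(m$sign, "+")
  expect_gt(m$r2, 0.2)
})

test_that("select_mediator picks the planted driver over noise, order-independently", {
  set.seed(54)
  n <- 4000
  cpg <- runif(n)
  x <- round(2 * cpg + rnorm(n, sd = 0.3), 1)
  y <- runif(n) < plogis(-1 + 2 * cpg)
  d <- tibble::tibble(dMFE = x, maf_positive = y, prop_CpG = cpg,
                      noise_a = rnorm(n), noise_b = rnorm(n))
  cands <- c("noise_a", "prop_CpG", "noise_b")
  win <- select_mediator(d, "dMFE", cands)
  expect_equal(win$feature, "prop_CpG")
  win2 <- select_mediator(d, "dMFE", rev(cands))
  expect_equal(win2, win)
  # single candidate returns that candidate
  expect_equal(select_mediator(d, "dMFE", "noise_a")$feature, "noise_a")
})
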