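test_that("percentile ranks use midpoint ties and the Phred map caps at 50", {
  p <- percentile_rank(c(10, 20, 30))
  expect_equal(p, c(0.5, 1.5, 2.5) / 3)
  # ties take the average rank: (2.5 - 0.5) / 4
  expect_equal(percentile_rank(c(1, 2, 2, 3))[2:3], rep(0.5, 2))
  # a value at or above the 99.999th percentile scores exactly 50
  expect_equal(phred_scale(1 - 1e-5), 50)
  expect_equal(phred_scale(1 - 1e-7), 50)
  big <- phred_scale_metric(seq_len(200001), kind = "distance")
  expect_equal(max(big), 50)
  # the median of an all-positive distance metric scores -10*log10(0.5)
  vals <- seq_len(999)
  expect_equal(phred_scale_metric(vals, "distance")[500], -10 * log10(0.5))
  expect_error(phred_scale_metric(numeric(0), "distance"), "empty")
})

test_that("signed metrics rank the two tails separately; zero lands low", {
  set.seed(61)
  x <- c(rnorm(4999), 0) # symmetric with an exact zero
  ph <- phred_scale_metric(x, "signed")
  expect_true(all(ph >= 0 & ph <= 50))
  # zero is the smallest magnitude among the non-negatives -> low score
  expect_lt(ph[length(x)], 5)
  # the most extreme values in each tail get the highest scores
  expect_equal(which.max(ph[x < 0]), which.min(x[x < 0]))
  expect_equal(which.max(ph[x >= 0]), which.max(x[x >= 0]))
  # monotone within each tail
  neg <- x < 0
  expect_true(all(diff(ph[neg][order(abs(x[neg]))]) >= 0))
  expect_true(all(diff(ph[!neg][order(x[!neg])]) >= 0))
})

test_that("SURF is the maximum of the three group maxima and SPI, with argmax names", {
  phreds <- tibble::tibble(
    phred_dMFE = 0, phred_dCFE = 0, phred_dEFE = 0, phred_dMEAFE = 0,
    phred_MFEED = 0, phred_CED = 9.7, phred_EED = 0, phred_MEAED = 0,
    phred_dCD = 0, phred_dEND = 0, spi_phred = 0
  )
  s <- summarize_surf(phreds)
  expect_equal(s$surf, 9.7)
  expect_equal(s$surf_argmax, "CED")
  expect_equal(s$surf_edit, 9.7)
  expect_equal(s$surf_stability, 0)
  # all equal -> surf equals that value
  all5 <- phreds |> dplyr::mutate(dplyr::across(dplyr::everything(), ~5))
  expect_equal(summarize_surf(all5)$surf, 5)
  # random vectors: surf = max over the groups and SPI
  set.seed(62)
  rnd <- tibble::as_tibble(matrix(runif(11 * 20, 0, 50), ncol = 11,
                                  dimnames = list(NULL, names(phreds))))
  sr <- summarize_surf(rnd)
  expect_equal(sr$surf,
               pmax(sr$surf_stability, sr$surf_edit, sr$surf_diversity,
                    rnd$spi_phred))
  expect_equal(sr$surf, apply(as.matrix(rnd), 1, max))
  expect_error(summarize_surf(phreds[, -2]), "missing Phred")
})

test_that("active SPI features are the null features plus 10 metrics plus 2 binding statuses", {
  ds <- full_dataset()
  syn <- head(ds$synonymous, 50)
  feats <- build_spi_features(syn, ds$tai)
  expect_equal(ncol(feats$active), ncol(feats$null) + 12L)
  expect_true(all(c("dMFE", "wt_paired", "mut_paired") %in%
                    names(feats$active)))
  expect_false(any(c("dMFE", "wt_paired") %in% names(feats$null)))
  # codon position is a 3-level factor feature
  expect_s3_class(feats$null$codon_position, "factor")
  expect_equal(levels(feats$null$codon_position), c("1", "2", "3"))
  # toy tAI lookup
  toy <- syn[1, ]
  toy$ref_codon <- "CTG"
  toy$alt_codon <- "CTA"
  tai <- tibble::tibble(codon = c("CTG", "CTA"), tai = c(0.5, 0.2))
  f <- build_spi_features(toy, tai)
  expect_equal(f$null$tai_wt, 0.5)
  expect_equal(f$null$tai_mut, 0.2)
  # missing codon entry is a hard error naming the codon
  expect_error(build_spi_features(toy, tai[1, ]), "CTA")
})

test_that("SPI is identically zero when the active features add nothing", {
  ds <- full_dataset()
  syn <- ds$synonymous
  d <- simulate_labels(syn, c("(Intercept)" = qlogis(0.3)), seed = 63,
                       replicates = 2)
  # flatten the structural features so active == null up to constant columns
  d[rnasurf:::metric_names] <- 0
  d$wt_paired <- TRUE
  d$mut_paired <- TRUE
  fit <- suppressWarnings(train_spi(d, ds$tai, seed = 63,
                                    min_context_size = 100))
  expect_true(all(abs(tidy(fit)$spi_raw) < 0.02))
  expect_equal(tidy(fit)$spi_raw, rep(0, nrow(tidy(fit))))
})

test_that("SPI training is deterministic for a fixed seed", {
  ds <- full_dataset()
  syn <- ds$synonymous
  beta <- centered_beta(syn, c(dMFE = -0.3))
  d <- simulate_labels(syn, beta, seed = 64, replicates = 3)
  f1 <- suppressWarnings(train_spi(d, ds$tai, seed = 99, min_context_size = 150))
  f2 <- suppressWarnings(train_spi(d, ds$tai, seed = 99, min_context_size = 150))
  expect_identical(tidy(f1), tidy(f2))
  # spi_phred honours its defining formula and bounds
  sc <- tidy(f1)
  expect_equal(sc$spi_phred, pmin(50, -10 * log10(1 - sc$spi_percentile)))
  expect_true(all(sc$spi_phred >= 0 & sc$spi_phred <= 50))
})

test_that("score_surf appends per-metric phreds and group summaries to a metric table", {
  ds <- full_dataset()
  scored <- score_surf(ds$synonymous)
  expect_true(all(c("phred_dMFE", "phred_CED", "surf", "surf_argmax")
                  %in% names(scored)))
  expect_true(all(scored$surf >= 0 & scored$surf <= 50))
  expect_equal(scored$spi_phred, rep(0, nrow(scored)))
  expect_equal(scored$surf,
               pmax(scored$surf_stability, scored$surf_edit,
                    scored$surf_diversity, scored$spi_phred))
})
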