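rand_tx <- function(len, cds_start, cds_len, seed, id = "TX1", gene = "G1") {
  set.seed(seed)
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  cds_end <- cds_start + cds_len - 1
  s[cds_start:(cds_start + 2)] <- c("A", "T", "G")
  s[(cds_end - 2):cds_end] <- c("T", "A", "A")
  for (cs in seq(cds_start + 3, cds_end - 3, by = 3)) {
    if (paste(s[cs:(cs + 2)], collapse = "") %in% c("TAA", "TAG", "TGA")) {
      s[cs + 2] <- "T"
    }
  }
  tibble::tibble(transcript_id = id, gene_id = gene,
                 sequence = paste(s, collapse = ""),
                 cds_start = cds_start, cds_end = cds_end, is_mane = TRUE)
}

test_that("hand-checked coding effects: synonymous, stop gain, start loss", {
  # CDS: ATG CTG TGG TAA  -> M L W *
  s <- paste0("GGG", "ATGCTGTGGTAA", "CCC")
  tx <- tibble::tibble(transcript_id = "T", gene_id = "G", sequence = s,
                       cds_start = 4, cds_end = 15, is_mane = TRUE)
  # CTG -> CTA at codon position 3 (Leu -> Leu)
  expect_equal(classify_effect(tx, 9, "G", "A"), "synonymous")
  # TGG -> TGA (Trp -> stop)
  expect_equal(classify_effect(tx, 12, "G", "A"), "stop_gain")
  # ATG -> GTG (start loss)
  expect_equal(classify_effect(tx, 4, "A", "G"), "start_loss")
  # TAA -> CAA (stop loss)
  expect_equal(classify_effect(tx, 13, "T", "C"), "stop_loss")
  # UTR5 creating an ATG -> start gain: GGG...A>T? construct directly
  s2 <- paste0("GAG", "ATGTGGTAA")
  tx2 <- tibble::tibble(transcript_id = "T", gene_id = "G", sequence = s2,
                        cds_start = 4, cds_end = 12, is_mane = TRUE)
  expect_equal(classify_effect(tx2, 2, "A", "T"), "utr5")
  # ref mismatch is a data-integrity error
  expect_error(classify_effect(tx, 4, "C", "G"), "mismatch")
})

test_that("classify_effect agrees with a whole-CDS translation oracle", {
  for (seed in c(101, 202)) {
    tx <- rand_tx(180, 22, 120, seed)
    bases <- c("A", "C", "G", "T")
    for (pos in seq_len(180)) {
      ref <- substr(tx$sequence, pos, pos)
      for (alt in setdiff(bases, ref)) {
        expect_equal(
          classify_effect(tx, pos, ref, alt),
          oracle_effect(tx, pos, ref, alt),
          info = paste("seed", seed, "pos", pos, ref, ">", alt)
        )
      }
    }
  }
})

test_that("the deleteriousness order runs start_loss(1) .. utr3(8)", {
  expect_equal(rank_effect("start_loss"), 1L)
  expect_equal(rank_effect("stop_gain"), 2L)
  expect_equal(rank_effect("start_gain"), 3L)
  expect_equal(rank_effect("stop_loss"), 4L)
  expect_equal(rank_effect("missense"), 5L)
  expect_equal(rank_effect("synonymous"), 6L)
  expect_equal(rank_effect("utr5"), 7L)
  expect_equal(rank_effect("utr3"), 8L)
  expect_error(rank_effect("splice"), "unknown")
})

test_that("canonical transcript selection: MANE, then CDS length, then length; order-invariant", {
  tx <- function(id, mane, cds_len, len) {
    tibble::tibble(transcript_id = id, gene_id = "G1",
                   sequence = strrep("ACGT", len / 4),
                   cds_start = 10, cds_end = 10 + cds_len - 1, is_mane = mane)
  }
  a <- tx("A", TRUE, 300, 2000)
  b <- tx("B", FALSE, 600, 1500)
  expect_equal(select_canonical(dplyr::bind_rows(a, b))$transcript_id, "A")
  a2 <- tx("A", FALSE, 300, 2000)
  expect_equal(select_canonical(dplyr::bind_rows(a2, b))$transcript_id, "B")
  b2 <- tx("B", FALSE, 300, 1500)
  expect_equal(select_canonical(dplyr::bind_rows(a2, b2))$transcript_id, "A")
  # invariance to input ordering
  expect_equal(select_canonical(dplyr::bind_rows(b2, a2))$transcript_id, "A")
  # lexicographic tie-break when everything else ties
  c2 <- tx("C", FALSE, 300, 2000)
  expect_equal(select_canonical(dplyr::bind_rows(c2, a2))$transcript_id, "A")
})

test_that("the 14 mutational-context classes partition all SNVs", {
  s <- "TACGTT"
  tx <- tibble::tibble(transcript_id = "T", gene_id = "G", sequence = s,
                       cds_start = 1, cds_end = 6, is_mane = TRUE)
  # C of the CG dinucleotide, C>T -> CpG>TpG
  expect_equal(classify_context(tx, 3, "C", "T"), "CpG>TpG")
  # G of the CG dinucleotide, G>A -> CpG>CpA
  expect_equal(classify_context(tx, 4, "G", "A"), "CpG>CpA")
  # same C with a different alt stays plain
  expect_equal(classify_context(tx, 3, "C", "A"), "C>A")
  expect_equal(classify_context(tx, 2, "A", "G"), "A>G")
  # every possible SNV maps to exactly one of the 14 classes
  set.seed(40)
  tx2 <- rand_tx(150, 16, 90, 303)
  bases <- c("A", "C", "G", "T")
  all_ctx <- unlist(lapply(seq_len(150), function(pos) {
    ref <- substr(tx2$sequence, pos, pos)
    classify_context(tx2, rep(pos, 3), rep(ref, 3), setdiff(bases, ref))
  }))
  expect_equal(length(all_ctx), 450L)
  expect_true(all(all_ctx %in% rnasurf:::context_levels))
  # a C>T change 5' of a G is always the CpG subclass, never the plain class
  chars <- strsplit(tx2$sequence, "")[[1]]
  cpg_c <- which(chars == "C" & dplyr::lead(chars, default = "N") == "G")
  for (pos in cpg_c) {
    expect_equal(classify_context(tx2, pos, "C", "T"), "CpG>TpG")
  }
})

test_that("boundary positions without the needed neighbour fall back to the plain class", {
  s <- "CGGGGC"
  tx <- tibble::tibble(transcript_id = "T", gene_id = "G", sequence = s,
                       cds_start = 1, cds_end = 6, is_mane = TRUE)
  # a terminal G>A lacks a preceding base only at position 1
  expect_equal(classify_context(tx, 2, "G", "A"), "CpG>CpA")
  s2 <- "GAAAAA"
  tx2 <- tibble::tibble(transcript_id = "T", gene_id = "G", sequence = s2,
                        cds_start = 1, cds_end = 6, is_mane = TRUE)
  expect_equal(classify_context(tx2, 1, "G", "A"), "G>A")
})

test_that("local content matches brute-force counts on designed sequences", {
  polyA <- tibble::tibble(transcript_id = "T", gene_id = "G",
                          sequence = strrep("A", 120),
                          cds_start = 1, cds_end = 120, is_mane = TRUE)
  lc <- local_content(polyA, 60)
  expect_equal(lc$prop_A, 1)
  expect_equal(lc$prop_CpG, 0)
  expect_equal(lc$prop_A + lc$prop_C + lc$prop_G + lc$prop_T, 1)

  cg <- tibble::tibble(transcript_id = "T", gene_id = "G",
                       sequence = strrep("CG", 60),
                       cds_start = 1, cds_end = 120, is_mane = TRUE)
  lc2 <- local_content(cg, 60)
  # 20 within-tile CG occurrences per 40-nt tile, three tiles, denominator 119
  expect_equal(lc2$prop_CpG, 60 / 119)
  expect_equal(lc2$prop_C, 0.5)
  expect_equal(lc2$prop_G, 0.5)

  # boundary tile: only two tiles exist for a position in the first tile
  lc3 <- local_content(cg, 5)
  expect_equal(lc3$prop_CpG, 40 / 79)

  # proportions sum to one at arbitrary positions of a random transcript
  tx <- rand_tx(200, 31, 120, 77)
  lcr <- local_content(tx, c(1, 57, 123, 200))
  expect_equal(lcr$prop_A + lcr$prop_C + lcr$prop_G + lcr$prop_T, rep(1, 4))
})

test_that("annotate_variants integrates effects, contexts, masks and external disagreement", {
  tx <- rand_tx(160, 19, 105, 55)
  snvs <- enumerate_snvs(tx)
  mask <- tibble::tibble(transcript_id = "TX1", start = 30, end = 32,
                         reason = "splice_site")
  ext <- tibble::tibble(transcript_id = "TX1", position = 60,
                        ref = substr(tx$sequence, 60, 60),
                        alt = setdiff(c("A", "C", "G", "T"),
                                      substr(tx$sequence, 60, 60))[1],
                        effect = "definitely_wrong")
  ann <- annotate_variants(snvs, tx, exclusion_mask = mask,
                           external_effects = ext)
  expect_equal(nrow(ann), nrow(snvs))
  expect_true(all(ann$excluded[ann$position %in% 30:32]))
  hit <- ann$position == 60 & ann$alt == ext$alt
  expect_true(all(ann$excluded[hit]))
  expect_equal(unique(ann$exclusion_reason[hit]), "effect_disagreement")
  expect_true(all(ann$is_canonical))
  # codon fields only inside the CDS
  expect_true(all(is.na(ann$codon_position[ann$effect %in% c("utr5", "utr3")])))
  in_cds <- !ann$effect %in% c("utr5", "utr3", "start_gain")
  expect_true(all(ann$codon_position[in_cds] %in% 1:3))
  expect_true(all(nchar(ann$ref_codon[in_cds]) == 3))
})
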