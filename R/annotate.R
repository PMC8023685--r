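effect_levels <- c("start_loss", "stop_gain", "start_gain", "stop_loss",
                   "missense", "synonymous", "utr5", "utr3")

context_levels <- c(
  "A>C", "A>G", "A>T", "C>A", "C>G", "C>T", "G>A", "G>C", "G>T",
  "T>A", "T>C", "T>G", "CpG>TpG", "CpG>CpA"
)

translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa) & !is.na(codons)] <- "X"
  aa
}

#' Coding effect of a substitution
#'
#' Positions 5' of the CDS are `utr5` unless the substitution creates a new
#' `ATG` trinucleotide overlapping the variant (`start_gain`); positions 3'
#' of the CDS are `utr3`. CDS positions are classified by translating the
#' reference and alternate codons with the standard genetic code:
#' `start_loss` (first codon loses its `ATG`), `stop_gain`, `stop_loss`,
#' `missense` or `synonymous`.
#'
#' @param transcript One-row transcript tibble (or named list with
#'   `sequence`, `cds_start`, `cds_end`).
#' @param position,ref,alt Parallel vectors describing substitutions; `ref`
#'   must match the transcript sequence (data-integrity check).
#' @return Character vector of effects.
#' @export
classify_effect <- function(transcript, position, ref, alt) {
  if (is.data.frame(transcript)) transcript <- as.list(transcript[1, ])
  s <- transcript$sequence
  cs <- transcript$cds_start
  ce <- transcript$cds_end
  len <- nchar(s)
  seq_ref <- substring(s, position, position)
  if (any(seq_ref != ref)) {
    i <- which(seq_ref != ref)[1]
    abort(paste0("ref allele mismatch at position ", position[i],
                 ": sequence has ", seq_ref[i], ", got ", ref[i]))
  }
  n <- length(position)
  eff <- character(n)
  in_utr5 <- position < cs
  in_utr3 <- position > ce
  in_cds <- !in_utr5 & !in_utr3

  if (any(in_utr5)) {
    idx <- which(in_utr5)
    gains <- vapply(idx, function(k) {
      p <- position[k]
      starts <- max(1L, p - 2L):p
      starts <- starts[starts + 2L <= len]
      any(vapply(starts, function(st) {
        tri <- substr(s, st, st + 2L)
        mut_tri <- tri
        substr(mut_tri, p - st + 1L, p - st + 1L) <- alt[k]
        mut_tri == "ATG" && tri != "ATG"
      }, logical(1)))
    }, logical(1))
    eff[idx] <- if_else(gains, "start_gain", "utr5")
  }
  eff[in_utr3] <- "utr3"

  if (any(in_cds)) {
    idx <- which(in_cds)
    codon_index <- (position[idx] - cs) %/% 3L
    cpos <- (position[idx] - cs) %% 3L + 1L
    codon_start <- cs + 3L * codon_index
    ref_codon <- substring(s, codon_start, codon_start + 2L)
    alt_codon <- ref_codon
    substr(alt_codon, cpos, cpos) <- alt[idx]
    aa_ref <- translate_codons(ref_codon)
    aa_alt <- translate_codons(alt_codon)
    e <- character(length(idx))
    is_start <- codon_index == 0L & ref_codon == "ATG" & alt_codon != "ATG"
    e[is_start] <- "start_loss"
    rest <- !is_start
    e[rest & aa_ref != "*" & aa_alt == "*"] <- "stop_gain"
    e[rest & aa_ref == "*" & aa_alt != "*"] <- "stop_loss"
    same <- rest & aa_ref == aa_alt & e == ""
    e[same] <- "synonymous"
    e[e == ""] <- "missense"
    eff[idx] <- e
  }
  eff
}

#' Deleteriousness rank of a coding effect
#'
#' Total order used to assign each site its most deleterious role across
#' transcripts: start loss (1), stop gain (2), start gain (3), stop loss (4),
#' missense (5), synonymous (6), 5' UTR (7), 3' UTR (8).
#'
#' @param effect Character vector of effects.
#' @return Integer ranks (1 = most deleterious).
#' @export
rank_effect <- function(effect) {
  r <- match(effect, effect_levels)
  if (anyNA(r)) {
    abort(paste0("unknown effect: ", effect[which(is.na(r))[1]]))
  }
  r
}

#' Select the canonical transcript of each gene
#'
#' Preference order: MANE representation, then longest CDS, then longest
#' transcript, with a deterministic lexicographic tie-break on transcript id.
#'
#' @param transcripts Transcript tibble (one or more genes).
#' @return Tibble with `gene_id` and the canonical `transcript_id` per gene.
#' @export
select_canonical <- function(transcripts) {
  transcripts |>
    mutate(
      cds_len = .data$cds_end - .data$cds_start + 1L,
      tx_len = nchar(.data$sequence)
    ) |>
    group_by(.data$gene_id) |>
    arrange(dplyr::desc(.data$is_mane), dplyr::desc(.data$cds_len),
            dplyr::desc(.data$tx_len), .data$transcript_id,
            .by_group = TRUE) |>
    summarise(transcript_id = first(.data$transcript_id), .groups = "drop")
}

#' Mutational context of a substitution (14 classes)
#'
#' The 12 plain `REF>ALT` classes plus the two CpG-transition classes:
#' `CpG>TpG` when a `C>T` change sits immediately 5' of a `G`, and `CpG>CpA`
#' when a `G>A` change sits immediately 3' of a `C` (deamination on the
#' antisense strand). Boundary positions lacking the needed neighbour fall
#' back to the plain class.
#'
#' @inheritParams classify_effect
#' @return Character vector of context labels.
#' @export
classify_context <- function(transcript, position, ref, alt) {
  if (is.data.frame(transcript)) transcript <- as.list(transcript[1, ])
  s <- transcript$sequence
  len <- nchar(s)
  nxt <- ifelse(position < len, substring(s, position + 1L, position + 1L), "")
  prv <- ifelse(position > 1L, substring(s, position - 1L, position - 1L), "")
  ctx <- paste0(ref, ">", alt)
  ctx[ref == "C" & alt == "T" & nxt == "G"] <- "CpG>TpG"
  ctx[ref == "G" & alt == "A" & prv == "C"] <- "CpG>CpA"
  ctx
}

str_count_fixed <- function(x, pattern) {
  lengths(gregexpr(pattern, x, fixed = TRUE)) -
    (regexpr(pattern, x, fixed = TRUE) == -1L)
}

#' Local sequence content around a position
#'
#' The transcript is tiled into 40-nt windows from its 5' end; the local
#' content of a position is computed over the concatenation of its own tile
#' and the immediately flanking tiles (a symmetric 120-nt neighbourhood for
#' interior tiles; boundary tiles use whichever neighbours exist).
#' Dinucleotides are counted within each tile on the given strand and the
#' proportions use (concatenation length - 1) as denominator.
#'
#' @inheritParams classify_effect
#' @param position 1-based transcript positions.
#' @return Tibble with `prop_A`, `prop_C`, `prop_G`, `prop_T` (summing to 1)
#'   and `prop_CpG`, `prop_AT`.
#' @export
local_content <- function(transcript, position) {
  if (is.data.frame(transcript)) transcript <- as.list(transcript[1, ])
  s <- transcript$sequence
  len <- nchar(s)
  n_tiles <- ceiling(len / 40)
  tile_starts <- (seq_len(n_tiles) - 1L) * 40L + 1L
  tile_ends <- pmin(tile_starts + 39L, len)
  tiles <- substring(s, tile_starts, tile_ends)
  tile_stats <- tibble(
    n = nchar(tiles),
    A = str_count_fixed(tiles, "A"),
    C = str_count_fixed(tiles, "C"),
    G = str_count_fixed(tiles, "G"),
    T = str_count_fixed(tiles, "T"),
    CpG = str_count_fixed(tiles, "CG"),
    AT = str_count_fixed(tiles, "AT")
  )
  tidx <- (position - 1L) %/% 40L + 1L
  agg <- function(col) {
    v <- tile_stats[[col]]
    v_prev <- c(0, v)[tidx]          # tile t-1 (0 when absent)
    v_next <- c(v, 0)[tidx + 1L]     # tile t+1 (0 when absent)
    v[tidx] + ifelse(tidx > 1L, v_prev, 0) + ifelse(tidx < n_tiles, v_next, 0)
  }
  tot <- agg("n")
  tibble(
    prop_A = agg("A") / tot,
    prop_C = agg("C") / tot,
    prop_G = agg("G") / tot,
    prop_T = agg("T") / tot,
    prop_CpG = agg("CpG") / (tot - 1L),
    prop_AT = agg("AT") / (tot - 1L)
  )
}

#' Annotate an SNV table with effect, context and sequence features
#'
#' Adds the coding effect and its deleteriousness rank, the 14-class
#' mutational context, codon information, canonical-transcript flag, the
#' flanking nucleotides, the nine bases of the home and adjacent codons
#' (CDS variants), local sequence content, and exclusion flags.
#'
#' @param variants SNV tibble (from [enumerate_snvs()] or
#'   [structure_metrics()]).
#' @param transcripts Transcript tibble.
#' @param exclusion_mask Optional tibble `(transcript_id, start, end,
#'   reason)` in transcript coordinates; variants inside a masked interval
#'   (e.g. near exon junctions) are flagged `excluded`.
#' @param external_effects Optional tibble `(transcript_id, position, ref,
#'   alt, effect)` from an external annotator; variants whose predicted
#'   effect disagrees are flagged `excluded` with reason
#'   `"effect_disagreement"`.
#' @return `variants` with annotation columns appended.
#' @export
annotate_variants <- function(variants, transcripts, exclusion_mask = NULL,
                              external_effects = NULL) {
  canon <- select_canonical(transcripts) |>
    mutate(is_canonical = TRUE) |>
    select("transcript_id", "is_canonical")
  out <- purrr::map(unique(variants$transcript_id), function(id) {
    v <- variants[variants$transcript_id == id, ]
    tx <- as.list(transcripts[transcripts$transcript_id == id, ][1, ])
    eff <- classify_effect(tx, v$position, v$ref, v$alt)
    ctx <- classify_context(tx, v$position, v$ref, v$alt)
    lc <- local_content(tx, v$position)
    s <- tx$sequence
    len <- nchar(s)
    in_cds <- v$position >= tx$cds_start & v$position <= tx$cds_end
    codon_index <- ifelse(in_cds, (v$position - tx$cds_start) %/% 3L, NA_integer_)
    cpos <- ifelse(in_cds, (v$position - tx$cds_start) %% 3L + 1L, NA_integer_)
    codon_start <- tx$cds_start + 3L * codon_index
    ref_codon <- ifelse(in_cds, substring(s, codon_start, codon_start + 2L),
                        NA_character_)
    alt_codon <- ref_codon
    ok <- which(in_cds)
    substr(alt_codon[ok], cpos[ok], cpos[ok]) <- v$alt[ok]
    # nine bases of the previous, home and next codons ("X" beyond the ends)
    nono <- ifelse(in_cds, substring(paste0("XXX", s, "XXX"),
                                     codon_start, codon_start + 8L),
                   NA_character_)
    nt <- matrix(NA_character_, nrow = nrow(v), ncol = 9)
    if (length(ok) > 0) {
      nt[ok, ] <- t(vapply(strsplit(nono[ok], "", fixed = TRUE),
                           identity, character(9)))
    }
    colnames(nt) <- paste0("nt", 1:9)
    bind_cols(
      v,
      tibble(
        effect = eff,
        effect_rank = rank_effect(eff),
        context = ctx,
        codon_position = cpos,
        ref_codon = ref_codon,
        alt_codon = alt_codon,
        upstream_base = ifelse(v$position > 1L,
                               substring(s, v$position - 1L, v$position - 1L), "X"),
        downstream_base = ifelse(v$position < len,
                                 substring(s, v$position + 1L, v$position + 1L), "X"),
        transcript_length = len
      ),
      as_tibble(nt),
      lc
    )
  }) |> bind_rows()
  out <- left_join(out, canon, by = "transcript_id")
  out$is_canonical <- !is.na(out$is_canonical)
  out$excluded <- FALSE
  out$exclusion_reason <- NA_character_
  if (!is.null(exclusion_mask)) {
    for (i in seq_len(nrow(exclusion_mask))) {
      m <- exclusion_mask[i, ]
      hit <- out$transcript_id == m$transcript_id &
        out$position >= m$start & out$position <= m$end
      out$excluded[hit] <- TRUE
      out$exclusion_reason[hit] <- m$reason %||% "masked"
    }
  }
  if (!is.null(external_effects)) {
    ext <- external_effects |>
      rename(external_effect = "effect")
    out <- left_join(out, ext, by = c("transcript_id", "position", "ref", "alt"))
    disagree <- !is.na(out$external_effect) & out$external_effect != out$effect
    out$excluded[disagree] <- TRUE
    out$exclusion_reason[disagree] <- "effect_disagreement"
    out$external_effect <- NULL
  }
  out
}
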