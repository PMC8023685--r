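#' Read transcripts from FASTA plus an annotation table
#'
#' Loads mRNA sequences (sense strand, thymine convention: any `U` in the
#' input is normalised to `T`) and joins the per-transcript annotation giving
#' CDS boundaries and the MANE flag. Every FASTA record must have an
#' annotation row; records violating the transcript invariants are reported
#' as a hard error, never silently dropped.
#'
#' @param fasta_path Path to a (multi-record) FASTA file.
#' @param annotation_path Path to a TSV with header columns
#'   `transcript_id`, `gene_id`, `cds_start`, `cds_end`, `is_mane`.
#'   Coordinates are 1-based inclusive transcript positions.
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `sequence`, `cds_start`, `cds_end`, `is_mane`.
#' @examples
#' \dontrun{
#' tx <- read_transcripts("transcripts.fa", "transcripts.tsv")
#' }
#' @export
read_transcripts <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  ann <- readr::read_tsv(annotation_path, show_col_types = FALSE,
                         col_types = readr::cols(
                           transcript_id = readr::col_character(),
                           gene_id = readr::col_character(),
                           cds_start = readr::col_integer(),
                           cds_end = readr::col_integer(),
                           is_mane = readr::col_logical()
                         ))
  missing <- setdiff(ids, ann$transcript_id)
  if (length(missing) > 0) {
    abort(paste0("no annotation row for transcript(s): ",
                 paste(missing, collapse = ", ")))
  }
  tx <- tibble(
    transcript_id = ids,
    sequence = unname(toupper(as.character(seqs)))
  )
  tx$sequence <- gsub("U", "T", tx$sequence, fixed = TRUE)
  tx <- dplyr::left_join(tx, ann, by = "transcript_id")
  tx <- tx[, c("transcript_id", "gene_id", "sequence",
               "cds_start", "cds_end", "is_mane")]
  validate_transcripts(tx)
  tx
}

#' Validate a transcript table
#'
#' Checks the transcript invariants: the sequence is non-empty and restricted
#' to `A`,`C`,`G`,`T`; `1 <= cds_start < cds_end <= length(sequence)`; and the
#' CDS length is a multiple of 3. Violations raise an error naming the
#' transcript (and the position of the first offending character for alphabet
#' violations).
#'
#' @param transcripts A tibble as returned by [read_transcripts()].
#' @return The input, invisibly, if valid.
#' @export
validate_transcripts <- function(transcripts) {
  required <- c("transcript_id", "gene_id", "sequence",
                "cds_start", "cds_end", "is_mane")
  miss <- setdiff(required, names(transcripts))
  if (length(miss) > 0) {
    abort(paste0("transcript table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  for (i in seq_len(nrow(transcripts))) {
    id <- transcripts$transcript_id[[i]]
    s <- transcripts$sequence[[i]]
    if (is.na(s) || nchar(s) == 0) {
      abort(paste0("transcript ", id, ": empty sequence"))
    }
    bad <- regexpr("[^ACGT]", s)
    if (bad > 0) {
      abort(paste0("transcript ", id, ": invalid character '",
                   substr(s, bad, bad), "' at position ", bad))
    }
    cs <- transcripts$cds_start[[i]]
    ce <- transcripts$cds_end[[i]]
    if (is.na(cs) || is.na(ce) || cs < 1 || cs >= ce || ce > nchar(s)) {
      abort(paste0("transcript ", id, ": invalid CDS bounds [", cs, ", ", ce,
                   "] for length ", nchar(s)))
    }
    if ((ce - cs + 1) %% 3 != 0) {
      abort(paste0("transcript ", id, ": CDS length ", ce - cs + 1,
                   " is not a multiple of 3"))
    }
  }
  invisible(transcripts)
}

#' Write transcripts to FASTA and annotation TSV
#'
#' The inverse of [read_transcripts()]; used to emit synthetic transcript
#' sets in exactly the formats the pipeline consumes.
#'
#' @param transcripts Transcript tibble.
#' @param fasta_path,annotation_path Output paths.
#' @return `transcripts`, invisibly.
#' @export
write_transcripts <- function(transcripts, fasta_path, annotation_path) {
  validate_transcripts(transcripts)
  lines <- as.vector(rbind(paste0(">", transcripts$transcript_id),
                           transcripts$sequence))
  writeLines(lines, fasta_path)
  readr::write_tsv(
    transcripts[, c("transcript_id", "gene_id", "cds_start", "cds_end", "is_mane")],
    annotation_path
  )
  invisible(transcripts)
}
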