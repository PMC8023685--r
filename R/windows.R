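#' Extract the 101-nt folding window around a transcript position
#'
#' Interior positions (at least 50 bases from both ends) get the subsequence
#' `[position - 50, position + 50]` with the variant at window offset 51.
#' Positions within 50 bases of the 5' end get the leading 101 nt (offset =
#' position); positions within 50 bases of the 3' end get the trailing 101 nt
#' (offset = position - (length - 101)).
#'
#' @param sequence A transcript sequence (single string, length >= 101), or a
#'   one-row transcript tibble with a `sequence` column.
#' @param position 1-based transcript position(s).
#' @return A tibble with columns `window` (101-nt string) and `offset`
#'   (1-based index of `position` within the window).
#' @examples
#' build_window(strrep("ACGT", 50), 100)
#' @export
build_window <- function(sequence, position) {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1L)
    sequence <- sequence$sequence
  }
  len <- nchar(sequence)
  if (len < 101) {
    abort(paste0("transcript of length ", len,
                 " is shorter than the 101-nt window"))
  }
  if (any(position < 1 | position > len)) {
    abort("position out of transcript bounds")
  }
  start <- pmin(pmax(position - 50L, 1L), len - 100L)
  tibble(
    window = substring(sequence, start, start + 100L),
    offset = as.integer(position - start + 1L)
  )
}

#' Enumerate every possible SNV of each transcript with its folding windows
#'
#' Yields 3 alternate alleles per position, each with the wild-type 101-nt
#' window and the mutant window (alt base substituted at the window offset).
#' Transcripts shorter than 101 nt are skipped with a warning, keeping all
#' downstream metrics on a uniform window size.
#'
#' @param transcripts Transcript tibble from [read_transcripts()] or
#'   [simulate_transcripts()].
#' @return A tibble with one row per SNV: `transcript_id`, `position`, `ref`,
#'   `alt`, `wt_window`, `mut_window`, `window_offset`. Exactly
#'   `3 * nchar(sequence)` rows per retained transcript.
#' @export
enumerate_snvs <- function(transcripts) {
  validate_transcripts(transcripts)
  short <- nchar(transcripts$sequence) < 101
  if (any(short)) {
    warn(paste0("skipping ", sum(short), " transcript(s) shorter than 101 nt: ",
                paste(transcripts$transcript_id[short], collapse = ", ")))
    transcripts <- transcripts[!short, ]
  }
  bases <- c("A", "C", "G", "T")
  out <- purrr::map(seq_len(nrow(transcripts)), function(i) {
    seq_i <- transcripts$sequence[[i]]
    len <- nchar(seq_i)
    pos <- seq_len(len)
    w <- build_window(seq_i, pos)
    refs <- strsplit(seq_i, "", fixed = TRUE)[[1]]
    # three alternates per position
    alt_mat <- vapply(refs, function(r) bases[bases != r], character(3))
    pos3 <- rep(pos, each = 3L)
    idx3 <- rep(seq_along(pos), each = 3L)
    alts <- as.vector(alt_mat)
    mut <- w$window[idx3]
    substr(mut, w$offset[idx3], w$offset[idx3]) <- alts
    tibble(
      transcript_id = transcripts$transcript_id[[i]],
      position = pos3,
      ref = refs[idx3],
      alt = alts,
      wt_window = w$window[idx3],
      mut_window = mut,
      window_offset = w$offset[idx3]
    )
  })
  bind_rows(out)
}
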