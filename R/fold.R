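#' Thermodynamic folding backend (ViennaRNA executables)
#'
#' Creates a folding backend that delegates single-window secondary-structure
#' prediction to the installed ViennaRNA command-line suite (`RNAfold` with
#' partition function, centroid and MEA output; `RNApdist` for pair-probability
#' ensemble distances). Folding uses the backend's default energy parameter
#' set at 37 degrees C with no dangling-end overrides. Results are memoised by
#' sequence content, so the four windows per position and overlapping windows
#' across positions are never folded twice in a run.
#'
#' @return An object of class `vienna_backend`.
#' @examples
#' \dontrun{
#' be <- vienna_backend()
#' fold(be, "GGGAAACCC")
#' }
#' @export
vienna_backend <- function() {
  rnafold <- Sys.which("RNAfold")
  rnapdist <- Sys.which("RNApdist")
  if (!nzchar(rnafold) || !nzchar(rnapdist)) {
    abort("folding backend unavailable: RNAfold and RNApdist must be on the PATH")
  }
  ver <- tryCatch(
    system2(rnafold, "--version", stdout = TRUE, stderr = FALSE)[1],
    error = function(e) "RNAfold (unknown version)"
  )
  cache <- new.env(parent = emptyenv())
  cache$folds <- new.env(parent = emptyenv())
  cache$pdist <- new.env(parent = emptyenv())
  structure(
    list(name = "ViennaRNA", version = ver, rnafold = rnafold,
         rnapdist = rnapdist, cache = cache),
    class = c("vienna_backend", "fold_backend")
  )
}

#' Fixture folding backend (replay recorded results)
#'
#' Replays fold and ensemble-distance results recorded with
#' [write_fold_fixtures()] / [write_pdist_fixtures()], keyed by sequence
#' content. The pipeline produces identical output whether fed by the live or
#' the fixture backend for the same recordings; a lookup miss is a hard error.
#'
#' @param fold_file TSV of recorded fold results.
#' @param pdist_file Optional TSV of recorded pairwise ensemble distances.
#' @return An object of class `fixture_backend`.
#' @export
fixture_backend <- function(fold_file, pdist_file = NULL) {
  folds <- readr::read_tsv(fold_file, show_col_types = FALSE)
  cache <- new.env(parent = emptyenv())
  cache$folds <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(folds))) {
    assign(folds$sequence[[i]], folds[i, ], envir = cache$folds)
  }
  cache$pdist <- new.env(parent = emptyenv())
  if (!is.null(pdist_file)) {
    pd <- readr::read_tsv(pdist_file, show_col_types = FALSE)
    for (i in seq_len(nrow(pd))) {
      key <- pdist_key(pd$seq_a[[i]], pd$seq_b[[i]])
      assign(key, pd$dist[[i]], envir = cache$pdist)
    }
  }
  structure(
    list(name = "fixture", version = "recorded", cache = cache),
    class = c("fixture_backend", "fold_backend")
  )
}

fold_result_cols <- c(
  "sequence", "mfe_structure", "mfe_energy",
  "centroid_structure", "centroid_energy", "centroid_distance",
  "mea_structure", "mea_energy", "ensemble_free_energy", "ensemble_diversity"
)

pdist_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# ViennaRNA programs may drop auxiliary files in the working directory;
# always run them from a scratch directory.
run_vienna <- function(cmd, args, input) {
  old <- setwd(tempdir())
  on.exit(setwd(old), add = TRUE)
  system2(cmd, args, input = input, stdout = TRUE, stderr = FALSE)
}

#' Fold sequences into secondary-structure predictions
#'
#' @param backend A folding backend ([vienna_backend()] or
#'   [fixture_backend()]).
#' @param sequences Character vector of sequences over `A,C,G,T,U`.
#' @param pf Compute partition-function quantities (ensemble free energy,
#'   centroid, MEA, ensemble diversity). With `pf = FALSE` only the MFE
#'   structure and energy are computed (about three times faster); the other
#'   columns are `NA`.
#' @return A tibble with one row per input sequence and columns `sequence`,
#'   `mfe_structure`, `mfe_energy` (kcal/mol), `centroid_structure`,
#'   `centroid_energy`, `centroid_distance`, `mea_structure`, `mea_energy`,
#'   `ensemble_free_energy`, `ensemble_diversity`.
#' @export
fold <- function(backend, sequences, pf = TRUE) {
  UseMethod("fold")
}

#' @export
fold.vienna_backend <- function(backend, sequences, pf = TRUE) {
  stopifnot(is.character(sequences), length(sequences) >= 1)
  if (any(is.na(sequences) | nchar(sequences) == 0)) {
    abort("fold: sequences must be non-empty strings")
  }
  bad <- grepl("[^ACGTUacgtu]", sequences)
  if (any(bad)) {
    abort(paste0("fold: sequence contains non-ACGTU characters: ",
                 sequences[which(bad)[1]]))
  }
  key_prefix <- if (pf) "pf:" else "mfe:"
  keys <- paste0(key_prefix, sequences)
  todo <- unique(sequences[!vapply(keys, exists, logical(1),
                                   envir = backend$cache$folds)])
  if (length(todo) > 0) {
    res <- rnafold_run(backend, todo, pf = pf)
    for (i in seq_len(nrow(res))) {
      assign(paste0(key_prefix, res$sequence[[i]]), res[i, ],
             envir = backend$cache$folds)
    }
  }
  rows <- lapply(keys, get, envir = backend$cache$folds)
  bind_rows(rows)
}

#' @export
fold.fixture_backend <- function(backend, sequences, pf = TRUE) {
  rows <- lapply(sequences, function(s) {
    if (!exists(s, envir = backend$cache$folds)) {
      abort(paste0("fixture backend has no recorded fold for sequence: ", s))
    }
    get(s, envir = backend$cache$folds)
  })
  bind_rows(rows)
}

rnafold_run <- function(backend, sequences, pf = TRUE) {
  ids <- paste0("s", seq_along(sequences))
  input <- paste0(">", ids, "\n", sequences, collapse = "\n")
  args <- if (pf) c("--noPS", "--noDP", "-p", "--MEA") else "--noPS"
  out <- run_vienna(backend$rnafold, args, input)
  per <- if (pf) 6L else 2L
  starts <- grep("^>", out)
  if (length(starts) != length(sequences)) {
    abort("folding backend failure: unexpected RNAfold output")
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  first_tok <- function(line) sub("\\s.*$", "", line)
  res <- lapply(seq_along(starts), function(i) {
    block <- out[(starts[i] + 1):(starts[i] + per)]
    mfe_structure <- first_tok(block[2])
    mfe_energy <- num(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", block[2]))
    if (!pf) {
      return(tibble(
        sequence = sequences[i], mfe_structure = mfe_structure,
        mfe_energy = mfe_energy,
        centroid_structure = NA_character_, centroid_energy = NA_real_,
        centroid_distance = NA_real_, mea_structure = NA_character_,
        mea_energy = NA_real_, ensemble_free_energy = NA_real_,
        ensemble_diversity = NA_real_
      ))
    }
    efe <- num(sub(".*\\[\\s*(-?[0-9.]+)\\]\\s*$", "\\1", block[3]))
    centroid_structure <- first_tok(block[4])
    centroid_energy <- num(sub(".*\\{\\s*(-?[0-9.]+)\\s+d=.*$", "\\1", block[4]))
    centroid_distance <- num(sub(".*d=([0-9.]+).*$", "\\1", block[4]))
    mea_structure <- first_tok(block[5])
    mea_energy <- num(sub(".*\\{\\s*(-?[0-9.]+)\\s+MEA=.*$", "\\1", block[5]))
    diversity <- num(sub(".*ensemble diversity\\s+([0-9.]+).*$", "\\1", block[6]))
    tibble(
      sequence = sequences[i], mfe_structure = mfe_structure,
      mfe_energy = mfe_energy, centroid_structure = centroid_structure,
      centroid_energy = centroid_energy, centroid_distance = centroid_distance,
      mea_structure = mea_structure, mea_energy = mea_energy,
      ensemble_free_energy = efe, ensemble_diversity = diversity
    )
  })
  res <- bind_rows(res)
  if (anyNA(res$mfe_energy)) {
    abort("folding backend failure: could not parse RNAfold energies")
  }
  res
}

#' Distance between the base-pair-probability ensembles of two sequences
#'
#' Computes the pair-probability-profile distance (RNApdist semantics)
#' between two equal-length sequences. Symmetric, and zero for identical
#' sequences.
#'
#' @param backend A folding backend.
#' @param seq_a,seq_b Character vectors of equal-length sequence pairs.
#' @return Numeric vector of non-negative distances.
#' @export
ensemble_distance <- function(backend, seq_a, seq_b) {
  UseMethod("ensemble_distance")
}

#' @export
ensemble_distance.vienna_backend <- function(backend, seq_a, seq_b) {
  stopifnot(length(seq_a) == length(seq_b))
  if (any(nchar(seq_a) != nchar(seq_b))) {
    abort("ensemble_distance: sequences in a pair must have equal length")
  }
  out <- rep(NA_real_, length(seq_a))
  out[seq_a == seq_b] <- 0
  keys <- pdist_key(seq_a, seq_b)
  cached <- vapply(keys, exists, logical(1), envir = backend$cache$pdist)
  out[cached] <- vapply(keys[cached], get, numeric(1),
                        envir = backend$cache$pdist)
  todo <- which(is.na(out))
  todo <- todo[!duplicated(keys[todo])]
  if (length(todo) > 0) {
    input <- paste0(">a\n", seq_a[todo], "\n>b\n", seq_b[todo], collapse = "\n")
    raw <- run_vienna(backend$rnapdist, character(0), input)
    vals <- suppressWarnings(as.numeric(raw[!grepl("^>", raw) & nzchar(raw)]))
    vals <- vals[!is.na(vals)]
    if (length(vals) != length(todo)) {
      abort("folding backend failure: unexpected RNApdist output")
    }
    for (i in seq_along(todo)) {
      assign(keys[todo[i]], vals[i], envir = backend$cache$pdist)
    }
  }
  still <- is.na(out)
  out[still] <- vapply(keys[still], get, numeric(1),
                       envir = backend$cache$pdist)
  out
}

#' @export
ensemble_distance.fixture_backend <- function(backend, seq_a, seq_b) {
  stopifnot(length(seq_a) == length(seq_b))
  keys <- pdist_key(seq_a, seq_b)
  vapply(seq_along(keys), function(i) {
    if (seq_a[i] == seq_b[i]) return(0)
    if (!exists(keys[i], envir = backend$cache$pdist)) {
      abort("fixture backend has no recorded ensemble distance for this pair")
    }
    get(keys[i], envir = backend$cache$pdist)
  }, numeric(1))
}

#' Record fold fixtures for later replay
#'
#' @param backend A live backend.
#' @param sequences Sequences to fold and record.
#' @param file Output TSV path.
#' @param pf Record partition-function quantities too.
#' @return The recorded tibble, invisibly.
#' @export
write_fold_fixtures <- function(backend, sequences, file, pf = TRUE) {
  res <- fold(backend, unique(sequences), pf = pf)
  readr::write_tsv(res, file)
  invisible(res)
}

#' Record ensemble-distance fixtures for later replay
#'
#' @param backend A live backend.
#' @param seq_a,seq_b Sequence pairs.
#' @param file Output TSV path.
#' @return The recorded tibble, invisibly.
#' @export
write_pdist_fixtures <- function(backend, seq_a, seq_b, file) {
  d <- ensemble_distance(backend, seq_a, seq_b)
  out <- tibble(seq_a = seq_a, seq_b = seq_b, dist = d)
  readr::write_tsv(out, file)
  invisible(out)
}
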