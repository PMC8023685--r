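#' Partner map of a dot-bracket structure
#'
#' @param structure A balanced dot-bracket string.
#' @return Integer vector, one element per position: the 1-based index of the
#'   pairing partner, or `0` for unpaired positions. Satisfies the involution
#'   `partner[partner[i]] == i` for every paired `i`.
#' @examples
#' pair_table("((..))")
#' @export
pair_table <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  pt <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    c <- chars[i]
    if (c == "(") {
      stack <- c(stack, i)
    } else if (c == ")") {
      if (length(stack) == 0) {
        abort(paste0("unbalanced structure: unmatched ')' at position ", i))
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    } else if (c != ".") {
      abort(paste0("invalid structure character '", c, "' at position ", i))
    }
  }
  if (length(stack) > 0) {
    abort(paste0("unbalanced structure: unmatched '(' at position ",
                 stack[length(stack)]))
  }
  pt
}

#' Edit distance between two secondary structures
#'
#' The default `"string"` mode is a character-level alignment of the two
#' dot-bracket strings with indel cost 1, bracket-vs-dot substitution cost 1
#' and `'('`-vs-`')'` substitution cost 2, so that destroying or creating a
#' base pair always costs exactly 2 edits. On structures with realistic
#' hairpin loops (>= 3 nt, as every thermodynamic folding engine emits) this
#' reproduces ViennaRNA's full-structure string alignment exactly. The
#' `"bpset"` mode instead counts base pairs present in one structure but not
#' the other (symmetric difference of the pair sets).
#'
#' @param s1,s2 Character vectors of equal-length dot-bracket strings
#'   (element-wise pairs).
#' @param mode `"string"` (default) or `"bpset"`.
#' @return Numeric vector of non-negative distances; zero iff the two
#'   structures are identical, and symmetric in its arguments.
#' @examples
#' structure_distance("((..))", "(....)") # one pair removed: 2 edits
#' @export
structure_distance <- function(s1, s2, mode = c("string", "bpset")) {
  mode <- match.arg(mode)
  stopifnot(length(s1) == length(s2))
  if (any(nchar(s1) != nchar(s2))) {
    abort("structure_distance: structures in a pair must have equal length")
  }
  lapply(c(s1, s2), pair_table) # validates balance
  if (mode == "string") {
    return(.db_edit_distance(s1, s2))
  }
  vapply(seq_along(s1), function(i) {
    p1 <- pair_table(s1[i])
    p2 <- pair_table(s2[i])
    pairs1 <- which(p1 > seq_along(p1))
    pairs2 <- which(p2 > seq_along(p2))
    k1 <- paste(pairs1, p1[pairs1])
    k2 <- paste(pairs2, p2[pairs2])
    length(setdiff(k1, k2)) + length(setdiff(k2, k1))
  }, numeric(1))
}

metric_names <- c("dMFE", "dCFE", "dEFE", "dMEAFE",
                  "MFEED", "CED", "EED", "MEAED", "dCD", "dEND")

#' The ten per-SNV structural-disruption metrics for one window pair
#'
#' All delta metrics follow the sign convention `mutant - wild-type`: a
#' positive `dMFE` means the variant weakens (destabilises) the local
#' structure.
#'
#' @param wt,mut One-row fold results (from [fold()]) for the wild-type and
#'   mutant windows, which must be equal-length sequences differing at
#'   exactly one position.
#' @param backend Folding backend, used for the ensemble distance `EED`.
#' @param mode Structure-comparison mode passed to [structure_distance()].
#' @return One-row tibble with columns `dMFE`, `dCFE`, `dEFE`, `dMEAFE`
#'   (kcal/mol energy differences), `MFEED`, `CED`, `MEAED` (structure edit
#'   distances), `EED` (ensemble distance), `dCD` (centroid-distance change)
#'   and `dEND` (ensemble-diversity change).
#' @export
compute_metrics <- function(wt, mut, backend, mode = "string") {
  if (nchar(wt$sequence) != nchar(mut$sequence)) {
    abort("compute_metrics: wild-type and mutant sequences differ in length")
  }
  ndiff <- sum(strsplit(wt$sequence, "")[[1]] != strsplit(mut$sequence, "")[[1]])
  if (ndiff > 1) {
    abort("compute_metrics: sequences differ at more than one position")
  }
  tibble(
    dMFE = mut$mfe_energy - wt$mfe_energy,
    dCFE = mut$centroid_energy - wt$centroid_energy,
    dEFE = mut$ensemble_free_energy - wt$ensemble_free_energy,
    dMEAFE = mut$mea_energy - wt$mea_energy,
    MFEED = structure_distance(wt$mfe_structure, mut$mfe_structure, mode),
    CED = structure_distance(wt$centroid_structure, mut$centroid_structure, mode),
    EED = ensemble_distance(backend, wt$sequence, mut$sequence),
    MEAED = structure_distance(wt$mea_structure, mut$mea_structure, mode),
    dCD = mut$centroid_distance - wt$centroid_distance,
    dEND = mut$ensemble_diversity - wt$ensemble_diversity
  )
}

#' Compute structural-disruption metrics for an enumerated SNV table
#'
#' Folds every distinct wild-type and mutant window (memoised by sequence)
#' and appends the ten disruption metrics plus the binding status of the
#' variant base in the wild-type and mutant MFE structures.
#'
#' @param variants SNV tibble from [enumerate_snvs()].
#' @param backend Folding backend.
#' @param pf Compute partition-function metrics. With `pf = FALSE` only
#'   `dMFE`, `MFEED` and the binding statuses are computed (fast screening
#'   mode); the other metric columns are `NA`.
#' @param eed Compute the ensemble distance `EED` (one partition-function
#'   pair evaluation per SNV; the most expensive metric).
#' @param mode Structure-comparison mode, see [structure_distance()].
#' @return `variants` with metric columns appended, plus `wt_paired` and
#'   `mut_paired` (is the variant base paired in the wild-type / mutant MFE
#'   structure).
#' @export
structure_metrics <- function(variants, backend, pf = TRUE, eed = pf,
                              mode = "string") {
  wt <- fold(backend, variants$wt_window, pf = pf)
  mut <- fold(backend, variants$mut_window, pf = pf)
  paired_at <- function(structs, offsets) {
    vapply(seq_along(structs), function(i) {
      substr(structs[i], offsets[i], offsets[i]) != "."
    }, logical(1))
  }
  out <- variants
  out$dMFE <- mut$mfe_energy - wt$mfe_energy
  out$MFEED <- structure_distance(wt$mfe_structure, mut$mfe_structure, mode)
  if (pf) {
    out$dCFE <- mut$centroid_energy - wt$centroid_energy
    out$dEFE <- mut$ensemble_free_energy - wt$ensemble_free_energy
    out$dMEAFE <- mut$mea_energy - wt$mea_energy
    out$CED <- structure_distance(wt$centroid_structure, mut$centroid_structure, mode)
    out$MEAED <- structure_distance(wt$mea_structure, mut$mea_structure, mode)
    out$dCD <- mut$centroid_distance - wt$centroid_distance
    out$dEND <- mut$ensemble_diversity - wt$ensemble_diversity
  } else {
    out$dCFE <- out$dEFE <- out$dMEAFE <- NA_real_
    out$CED <- out$MEAED <- out$dCD <- out$dEND <- NA_real_
  }
  out$EED <- if (eed) {
    ensemble_distance(backend, variants$wt_window, variants$mut_window)
  } else {
    NA_real_
  }
  out$wt_paired <- paired_at(wt$mfe_structure, variants$window_offset)
  out$mut_paired <- paired_at(mut$mfe_structure, variants$window_offset)
  out[, c(names(variants), metric_names, "wt_paired", "mut_paired")]
}
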