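# Independent oracles used to cross-check the implementation.

# Brute-force dynamic-programming edit distance between dot-bracket strings:
# indel 1, bracket<->dot substitution 1, '('<->')' substitution 2.
# Written as a plain two-dimensional table fill, independent of the
# package's vectorised C++ kernel.
oracle_edit_distance <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(av)
  lb <- length(bv)
  d <- matrix(0, la + 1, lb + 1)
  d[, 1] <- 0:la
  d[1, ] <- 0:lb
  subcost <- function(x, y) {
    if (x == y) return(0)
    if (x %in% c("(", ")") && y %in% c("(", ")")) return(2)
    1
  }
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      d[i + 1, j + 1] <- min(
        d[i, j + 1] + 1,
        d[i + 1, j] + 1,
        d[i, j] + subcost(av[i], bv[j])
      )
    }
  }
  d[la + 1, lb + 1]
}

# Random nested structure with hairpin loops of at least 3 nt, the only kind
# a thermodynamic folding engine can emit.
random_structure <- function(n) {
  s <- rep(".", n)
  pick <- function(lo, hi) if (lo == hi) lo else sample(lo:hi, 1)
  fill <- function(i, j) {
    if (j - i + 1 < 5) return(invisible())
    if (runif(1) < 0.6) {
      a <- pick(i, j - 4)
      b <- pick(a + 4, j)
      s[a] <<- "("
      s[b] <<- ")"
      fill(a + 1, b - 1)
      if (b + 1 <= j) fill(b + 1, j)
    } else {
      m <- floor((i + j) / 2)
      fill(i, m)
      fill(m + 1, j)
    }
  }
  fill(1, n)
  paste(s, collapse = "")
}

# Innermost-loop-elimination parser: repeatedly locate a '(' ... ')' pair
# enclosing only dots and blank it out. Independent of the package's
# stack-based parser.
oracle_pair_table <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  pt <- integer(length(chars))
  work <- chars
  repeat {
    str <- paste(work, collapse = "")
    m <- regexpr("\\([.]*\\)", str)
    if (m == -1) break
    open <- as.integer(m)
    close <- open + attr(m, "match.length") - 1L
    pt[open] <- close
    pt[close] <- open
    work[c(open, close)] <- "."
  }
  if (any(work != ".")) stop("oracle: unbalanced structure")
  pt
}

# Whole-CDS translation oracle for coding-effect classification: translate
# the complete reference and mutated CDS with Biostrings::translate and
# compare the protein strings, rather than classifying codon-by-codon.
oracle_effect <- function(tx, position, ref, alt) {
  s <- tx$sequence
  if (position < tx$cds_start) {
    mut <- s
    substr(mut, position, position) <- alt
    starts <- max(1, position - 2):position
    starts <- starts[starts + 2 <= nchar(s)]
    gain <- any(vapply(starts, function(st) {
      substr(mut, st, st + 2) == "ATG" && substr(s, st, st + 2) != "ATG"
    }, logical(1)))
    return(if (gain) "start_gain" else "utr5")
  }
  if (position > tx$cds_end) return("utr3")
  cds <- substr(s, tx$cds_start, tx$cds_end)
  mut_cds <- cds
  substr(mut_cds, position - tx$cds_start + 1, position - tx$cds_start + 1) <- alt
  tr <- function(x) {
    # no.init.codon: keep literal codon translation (no initiator special case)
    suppressWarnings(as.character(
      Biostrings::translate(Biostrings::DNAString(x), no.init.codon = TRUE,
                            if.fuzzy.codon = "X")
    ))
  }
  p_ref <- tr(cds)
  p_mut <- tr(mut_cds)
  codon_idx <- (position - tx$cds_start) %/% 3 + 1
  aa_ref <- substr(p_ref, codon_idx, codon_idx)
  aa_mut <- substr(p_mut, codon_idx, codon_idx)
  if (codon_idx == 1 && aa_ref == "M" && aa_mut != "M") return("start_loss")
  if (aa_ref != "*" && aa_mut == "*") return("stop_gain")
  if (aa_ref == "*" && aa_mut != "*") return("stop_loss")
  if (p_ref == p_mut) "synonymous" else "missense"
}

# Explicit-summation oracle for the mediator variance decomposition.
oracle_mediator_r2 <- function(y, p_est, x_binned) {
  p_global <- mean(y)
  v_feat <- 0
  v_null <- 0
  for (x in unique(x_binned)) {
    idx <- x_binned == x
    n_x <- sum(idx)
    p_x <- mean(y[idx])
    e_est <- mean(p_est[idx])
    v_feat <- v_feat + n_x * (e_est - p_x)^2
    v_null <- v_null + n_x * (p_global - p_x)^2
  }
  1 - v_feat / v_null
}
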