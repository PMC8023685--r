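pipeline_stages <- c("simulate", "fold-metrics", "annotate", "constraint",
                     "spi", "surf", "all")

default_config <- function() {
  list(
    fasta = NULL, annotation = NULL, wgs = NULL, wes = NULL, tai = NULL,
    exclusion_mask = NULL,
    pf = TRUE, eed = TRUE, mode = "string",
    scheme = "intersect_pass_union_positive",
    inbreeding_threshold = -0.3, min_coverage = 0.70,
    min_positive_per_bin = 1, constraint_metrics = c("dMFE", "CED", "dCD"),
    min_context_size = 200, n_folds = 5, lambda = 1e-3,
    phred_cutoff = 5,
    n_transcripts = 20, mean_length = 600, gc = 0.5, cpg_factor = 1,
    beta = c("(Intercept)" = qlogis(0.138))
  )
}

stage_file <- function(out_dir, name) file.path(out_dir, name)

digest_file <- function(path) {
  if (is.null(path) || !file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}

# nucleotide columns must never be guessed as logicals ("T" columns)
read_variant_tsv <- function(path) {
  base_cols <- c("ref", "alt", "ref_codon", "alt_codon", "upstream_base",
                 "downstream_base", "context", paste0("nt", 1:9))
  spec <- do.call(readr::cols,
                  setNames(rep(list(readr::col_character()), length(base_cols)),
                           base_cols))
  suppressWarnings(readr::read_tsv(path, col_types = spec, guess_max = 10000,
                                   show_col_types = FALSE))
}

#' Run the scoring pipeline
#'
#' Orchestrates the stages — simulate, fold-metrics, annotate, constraint,
#' spi, surf — over TSV outputs in `out_dir`, writing a JSON run manifest
#' (config snapshot, input digests, backend provenance, seed, per-stage row
#' counts and timestamps) whose stage ledger reconciles exactly
#' (output rows = input rows - drops). Any stage can be rerun in isolation
#' from its predecessor's serialized output; outputs are sorted on the
#' variant key, so results are independent of evaluation order, and a rerun
#' with the same config, inputs and seed is byte-identical.
#'
#' @param stage One of `"simulate"`, `"fold-metrics"`, `"annotate"`,
#'   `"constraint"`, `"spi"`, `"surf"`, or `"all"`.
#' @param out_dir Output directory (created if needed).
#' @param config Named list overriding the defaults: input paths (`fasta`,
#'   `annotation`, `wgs`, `wes`, `tai`, `exclusion_mask`), folding options
#'   (`pf`, `eed`, `mode`), constraint options (`scheme`,
#'   `inbreeding_threshold`, `min_coverage`, `min_positive_per_bin`,
#'   `constraint_metrics`), SPI options (`min_context_size`, `n_folds`,
#'   `lambda`, `phred_cutoff`) and simulation parameters (`n_transcripts`,
#'   `mean_length`, `gc`, `cpg_factor`, `beta`).
#' @param backend Folding backend (default [vienna_backend()]).
#' @param seed Seed for every stochastic step.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(stage = "all", out_dir, config = list(),
                         backend = vienna_backend(), seed = 1) {
  stage <- match.arg(stage, pipeline_stages)
  cfg <- utils::modifyList(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- stage_file(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else {
    list(stages = list())
  }
  manifest$backend <- list(name = backend$name, version = backend$version)
  manifest$seed <- seed
  cfg_snapshot <- cfg
  cfg_snapshot$beta <- as.list(cfg$beta)
  manifest$config <- cfg_snapshot

  log_stage <- function(name, rows_in, rows_out, outputs) {
    manifest$stages[[name]] <<- list(
      rows_in = rows_in, rows_out = rows_out,
      dropped = rows_in - rows_out,
      outputs = outputs, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    )
    inform(paste0("[", name, "] ", rows_in, " -> ", rows_out, " rows"))
  }
  need <- function(path, what) {
    if (is.null(path) || !file.exists(path)) {
      abort(paste0("missing input for this stage: ", what,
                   if (!is.null(path)) paste0(" (", path, ")")))
    }
    path
  }
  run_all <- stage == "all"

  if (run_all || stage == "simulate") {
    tx <- simulate_transcripts(n_transcripts = cfg$n_transcripts,
                               mean_length = cfg$mean_length, gc = cfg$gc,
                               cpg_factor = cfg$cpg_factor, seed = seed)
    cfg$fasta <- stage_file(out_dir, "transcripts.fa")
    cfg$annotation <- stage_file(out_dir, "transcripts.tsv")
    write_transcripts(tx, cfg$fasta, cfg$annotation)
    readr::write_tsv(simulate_tai(seed), stage_file(out_dir, "tai.tsv"))
    cfg$tai <- stage_file(out_dir, "tai.tsv")
    log_stage("simulate", nrow(tx), nrow(tx),
              c("transcripts.fa", "transcripts.tsv", "tai.tsv"))
  }

  if (run_all || stage == "fold-metrics") {
    tx <- read_transcripts(need(cfg$fasta, "transcript FASTA"),
                           need(cfg$annotation, "annotation TSV"))
    snvs <- enumerate_snvs(tx)
    met <- structure_metrics(snvs, backend, pf = cfg$pf, eed = cfg$eed,
                             mode = cfg$mode)
    met <- arrange(met, .data$transcript_id, .data$position, .data$alt)
    readr::write_tsv(met, stage_file(out_dir, "metrics.tsv"))
    log_stage("fold-metrics", nrow(snvs), nrow(met), "metrics.tsv")
  }

  if (run_all || stage == "annotate") {
    tx <- read_transcripts(need(cfg$fasta, "transcript FASTA"),
                           need(cfg$annotation, "annotation TSV"))
    met <- read_variant_tsv(need(stage_file(out_dir, "metrics.tsv"),
                                 "metrics table (run fold-metrics first)"))
    mask <- if (!is.null(cfg$exclusion_mask)) {
      readr::read_tsv(cfg$exclusion_mask, show_col_types = FALSE)
    }
    ann <- annotate_variants(met, tx, exclusion_mask = mask)
    ann <- arrange(ann, .data$transcript_id, .data$position, .data$alt)
    readr::write_tsv(ann, stage_file(out_dir, "annotated.tsv"))
    log_stage("annotate", nrow(met), nrow(ann), "annotated.tsv")
  }

  if (run_all || stage %in% c("constraint", "spi", "surf")) {
    ann <- read_variant_tsv(need(stage_file(out_dir, "annotated.tsv"),
                                 "annotated table (run annotate first)"))
    if (run_all) {
      # desk-scale runs simulate their own frequency tables when none given
      if (is.null(cfg$wgs) || is.null(cfg$wes)) {
        freqs <- simulate_frequencies(ann, beta = cfg$beta, seed = seed + 1L)
        cfg$wgs <- stage_file(out_dir, "wgs.tsv")
        cfg$wes <- stage_file(out_dir, "wes.tsv")
        readr::write_tsv(freqs$wgs, cfg$wgs)
        readr::write_tsv(freqs$wes, cfg$wes)
      }
    }
    wgs <- read_variant_tsv(need(cfg$wgs, "WGS frequency table"))
    wes <- read_variant_tsv(need(cfg$wes, "WES frequency table"))
    joint <- combine_frequencies(wgs, wes, scheme = cfg$scheme,
                                 universe = ann,
                                 inbreeding_threshold = cfg$inbreeding_threshold,
                                 min_coverage = cfg$min_coverage)
    labelled <- ann |>
      inner_join(joint, by = c("transcript_id", "position", "ref", "alt")) |>
      filter(.data$analyzed, !.data$excluded)
    syn <- filter(labelled, .data$effect == "synonymous")

    if (run_all || stage == "constraint") {
      curves <- list()
      for (m in cfg$constraint_metrics) {
        for (ctx in unique(syn$context)) {
          d <- syn[syn$context == ctx, ]
          if (nrow(d) < 50) next
          cc <- suppressWarnings(
            fit_constraint_curve(d, m, cfg$min_positive_per_bin, context = ctx)
          )
          if (!is.null(cc)) curves[[paste(m, ctx)]] <- cc
        }
      }
      if (length(curves) > 0) {
        summaries <- bind_rows(lapply(curves, glance))
        bins <- bind_rows(lapply(curves, tidy))
        readr::write_tsv(arrange(summaries, .data$metric, .data$context),
                         stage_file(out_dir, "constraint_summary.tsv"))
        readr::write_tsv(arrange(bins, .data$metric, .data$context, .data$x),
                         stage_file(out_dir, "constraint_bins.tsv"))
      }
      tallies <- bind_rows(
        mutate(attr(joint, "tally_wgs"), dataset = "WGS"),
        mutate(attr(joint, "tally_wes"), dataset = "WES")
      )
      readr::write_tsv(tallies, stage_file(out_dir, "filter_tally.tsv"))
      log_stage("constraint", nrow(ann), nrow(syn),
                c("constraint_summary.tsv", "constraint_bins.tsv",
                  "filter_tally.tsv"))
    }

    if (run_all || stage == "spi") {
      tai <- readr::read_tsv(need(cfg$tai, "tAI table"), show_col_types = FALSE)
      spi <- suppressWarnings(
        train_spi(syn, tai, n_folds = cfg$n_folds, seed = seed,
                  min_context_size = cfg$min_context_size,
                  lambda = cfg$lambda)
      )
      sc <- arrange(tidy(spi), .data$transcript_id, .data$position, .data$alt)
      readr::write_tsv(sc, stage_file(out_dir, "spi_scores.tsv"))
      log_stage("spi", nrow(syn), nrow(sc), "spi_scores.tsv")
    }

    if (run_all || stage == "surf") {
      spi_scores <- if (file.exists(stage_file(out_dir, "spi_scores.tsv"))) {
        readr::read_tsv(stage_file(out_dir, "spi_scores.tsv"),
                        show_col_types = FALSE)
      }
      scored <- score_surf(labelled, spi = spi_scores)
      scored <- arrange(scored, .data$transcript_id, .data$position, .data$alt)
      readr::write_tsv(scored, stage_file(out_dir, "scores.tsv"))
      log_stage("surf", nrow(labelled), nrow(scored), "scores.tsv")
    }
  }

  manifest$inputs <- list(
    fasta = digest_file(cfg$fasta), annotation = digest_file(cfg$annotation),
    wgs = digest_file(cfg$wgs), wes = digest_file(cfg$wes),
    tai = digest_file(cfg$tai)
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
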