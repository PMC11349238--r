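write_tsv_with_header <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_csv_with_header <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(x, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read SNV count tables
#'
#' Reads one or more TSV count tables (columns `cds_pos`, `ref`, `alt`,
#' `count`, `coverage`, `sample_id`; `#` lines ignored) into one long table.
#'
#' @param paths Character vector of file paths.
#' @return Data.frame concatenating all samples.
#' @export
read_counts <- function(paths) {
  tabs <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("count table not found: ", p, call. = FALSE)
    x <- utils::read.delim(p, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("cds_pos", "ref", "alt", "count", "coverage", "sample_id")
    miss <- setdiff(need, names(x))
    if (length(miss) > 0L) {
      stop("count table ", p, " lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    x
  })
  do.call(rbind, tabs)
}

#' Write count tables, one file per sample
#'
#' @param counts Long count table (as from [simulate_screen()]).
#' @param dir Output directory.
#' @param header Optional `#` header lines.
#' @return Paths written, invisibly.
#' @export
write_counts <- function(counts, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(split(counts, counts$sample_id), function(tab) {
    p <- file.path(dir, paste0("counts_", tab$sample_id[1], ".tsv"))
    write_tsv_with_header(tab, p, header)
    p
  }, character(1))
  invisible(paths)
}

#' Write a MaveDB-style scoreset CSV
#'
#' Three-column CSV (`hgvs_nt`, `hgvs_pro`, `score`) of outcome-level
#' scores, the deposition format for multiplexed-assay score sets.
#'
#' @param outcome_scores Outcome-level scores with `hgvs_c` available via
#'   `groups`, or a `screen_scores` object.
#' @param groups Outcome table from [group_outcomes()] (for member c.-names).
#' @param path Output CSV path.
#' @param header Optional `#` header lines.
#' @export
write_scoreset <- function(outcome_scores, groups, path, header = NULL) {
  if (inherits(outcome_scores, "screen_scores")) outcome_scores <- outcome_scores$outcome
  hgvs_nt <- groups$hgvs_c[match(outcome_scores$outcome_id, groups$outcome_id)]
  out <- data.frame(hgvs_nt = hgvs_nt, hgvs_pro = outcome_scores$hgvs_p,
                    score = outcome_scores$rcs)
  write_csv_with_header(out[outcome_scores$scorable, ], path, header)
  invisible(path)
}

#' Build a pipeline configuration
#'
#' Validated configuration for [run_pipeline()], assembled from arguments or
#' a YAML file. Two modes: `"simulate"` generates a synthetic screen;
#' `"ingest"` reads user count tables.
#'
#' @param mode `"simulate"` or `"ingest"`.
#' @param orf_fasta Path to the ORF FASTA (`NULL` in simulate mode uses a
#'   synthetic 543-codon ORF).
#' @param count_tables Character vector of count TSVs (ingest mode).
#' @param before_ids,after_ids Sample ids of unselected/selected replicates.
#' @param annotations Optional annotation CSV/TSV path.
#' @param out_dir Output directory.
#' @param seed Integer seed (mandatory).
#' @param pseudocount,member_stat Scoring options (see [score_screen()]).
#' @param boundary,ridge Classifier options (see [rcs_fit()]).
#' @param sim Named list of [sim_config()] overrides (simulate mode).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "ingest"), orf_fasta = NULL,
                            count_tables = NULL, before_ids = NULL,
                            after_ids = NULL, annotations = NULL,
                            out_dir = "rcscreen_out", seed,
                            pseudocount = 0.5,
                            member_stat = "frequency",
                            boundary = 500L, ridge = 1e-6, sim = list()) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed)) stop("pipeline requires a seed", call. = FALSE)
  if (mode == "ingest") {
    if (is.null(count_tables) || length(count_tables) == 0L) {
      stop("ingest mode requires count_tables", call. = FALSE)
    }
    missing_files <- count_tables[!file.exists(count_tables)]
    if (length(missing_files) > 0L) {
      stop("count table(s) not found: ", paste(missing_files, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(orf_fasta)) stop("ingest mode requires orf_fasta", call. = FALSE)
    if (is.null(before_ids) || is.null(after_ids)) {
      stop("ingest mode requires before_ids and after_ids", call. = FALSE)
    }
  }
  if (!is.null(orf_fasta) && !file.exists(orf_fasta)) {
    stop("ORF FASTA not found: ", orf_fasta, call. = FALSE)
  }
  if (!is.null(annotations) && !file.exists(annotations)) {
    stop("annotation table not found: ", annotations, call. = FALSE)
  }
  structure(list(mode = mode, orf_fasta = orf_fasta,
                 count_tables = count_tables, before_ids = before_ids,
                 after_ids = after_ids, annotations = annotations,
                 out_dir = out_dir, seed = as.integer(seed),
                 pseudocount = pseudocount, member_stat = member_stat,
                 boundary = as.integer(boundary), ridge = ridge, sim = sim),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full screen-analysis pipeline
#'
#' Orchestrates enumerate, simulate-or-ingest, score, classify, summarize
#' and (optionally) compare, writing all artifacts to the output directory:
#' enumeration TSV, per-sample count TSVs (simulate mode), SNV and outcome
#' score TSVs, MaveDB-style scoreset CSV, effect-call TSV, residue-summary
#' TSV, effect-map CSV, ground-truth CSV (simulate mode), concordance
#' reports (when annotations are given), and a JSON manifest with the
#' config, seed and per-file checksums. Every output carries a `#` header
#' with the package version, config hash and seed, and rerunning with an
#' identical config reproduces identical outputs.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the fitted objects and output paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[rcscreen] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  hdr <- c(paste0("rcscreen ", utils::packageVersion("rcscreen")),
           paste0("config_hash: ", hash),
           paste0("seed: ", config$seed))
  paths <- list()

  if (config$mode == "simulate") {
    orf <- if (is.null(config$orf_fasta)) {
      synthetic_orf(543L, seed = config$seed, id = "synthetic_orf_543")
    } else read_orf(config$orf_fasta)
    sim_args <- config$sim
    sim_args$seed <- sim_args$seed %||% config$seed
    cfg <- do.call(sim_config, sim_args)
    say("simulating screen on ", orf$id, " (", cfg$n_clones, " clones)")
    scr <- simulate_screen(orf, cfg)
    enum <- scr$enum; groups <- scr$groups; counts <- scr$counts
    before_ids <- scr$before_ids; after_ids <- scr$after_ids
    paths$counts <- write_counts(counts, config$out_dir, hdr)
    truth_path <- file.path(config$out_dir, "ground_truth.csv")
    write_csv_with_header(as.data.frame(scr$truth), truth_path, hdr)
    paths$ground_truth <- truth_path
    truth <- scr$truth
  } else {
    orf <- read_orf(config$orf_fasta)
    say("ingesting ", length(config$count_tables), " count table(s)")
    counts <- read_counts(config$count_tables)
    enum <- enumerate_snvs(orf)
    groups <- group_outcomes(enum)
    before_ids <- config$before_ids
    after_ids <- config$after_ids
    truth <- NULL
  }

  say("enumerated ", nrow(enum), " SNVs / ", nrow(groups), " coding outcomes")
  paths$enumeration <- file.path(config$out_dir, "enumeration.tsv")
  write_enumeration(enum, paths$enumeration,
                    regions = if (orf$n_codons == 543L) region_map() else NULL,
                    header = hdr)

  say("scoring")
  scores <- score_screen(counts, enum, before_ids, after_ids,
                         pseudocount = config$pseudocount, groups = groups,
                         member_stat = config$member_stat)
  say(sum(scores$snv$scorable), " SNVs scored; ",
      sum(!scores$snv$scorable), " unscorable")
  paths$snv_scores <- file.path(config$out_dir, "snv_scores.tsv")
  write_tsv_with_header(scores$snv, paths$snv_scores, hdr)
  paths$outcome_scores <- file.path(config$out_dir, "outcome_scores.tsv")
  write_tsv_with_header(scores$outcome, paths$outcome_scores, hdr)
  paths$scoreset <- file.path(config$out_dir, "scoreset.csv")
  write_scoreset(scores$outcome, groups, paths$scoreset, hdr)

  say("classifying")
  fit <- rcs_fit(scores$outcome, boundary = config$boundary,
                 ridge = config$ridge)
  say(sprintf("threshold t* = %.3f; %d damaging / %d tolerated calls",
              fit$threshold, sum(fit$calls$label == "damaging"),
              sum(fit$calls$label == "tolerated")))
  paths$calls <- file.path(config$out_dir, "effect_calls.tsv")
  write_tsv_with_header(fit$calls, paths$calls, hdr)
  em <- effect_map(fit, scores$outcome)
  paths$effect_map <- file.path(config$out_dir, "effect_map.csv")
  write_csv_with_header(data.frame(alt_aa = rownames(em), em,
                                   check.names = FALSE),
                        paths$effect_map, hdr)

  say("summarizing")
  regions <- if (orf$n_codons == 543L) region_map() else NULL
  summ <- residue_summaries(scores$outcome, fit$calls, regions)
  paths$residue_summary <- file.path(config$out_dir, "residue_summary.tsv")
  write_tsv_with_header(summ$residue, paths$residue_summary, hdr)
  if (!is.null(summ$region)) {
    paths$region_summary <- file.path(config$out_dir, "region_summary.tsv")
    write_tsv_with_header(summ$region, paths$region_summary, hdr)
  }

  concord <- NULL
  if (!is.null(config$annotations)) {
    say("comparing against annotations")
    ann <- read_annotations(config$annotations)
    concord <- list()
    calls_vec <- setNames(fit$calls$label, fit$calls$hgvs_p)
    if ("clinvar_class" %in% names(ann)) {
      merged <- merge(fit$calls, ann[, c("hgvs_p", "clinvar_class")], by = "hgvs_p")
      if (nrow(merged) > 0L) {
        concord$clinvar <- group_statistics(merged$rcs, merged$clinvar_class)
      }
    }
    assay_cols <- grep("^assay_", names(ann), value = TRUE)
    for (ac in assay_cols) {
      other <- setNames(ann[[ac]], ann$hgvs_p)
      concord[[ac]] <- tryCatch(pairwise_agreement(calls_vec, other),
                                error = function(e) NULL)
    }
    vep_cols <- grep("^vep_", names(ann), value = TRUE)
    for (vc in vep_cols) {
      vep <- setNames(as.numeric(ann[[vc]]), ann$hgvs_p)
      concord[[vc]] <- tryCatch(vep_concordance(calls_vec, vep),
                                error = function(e) NULL)
    }
    summary_rows <- do.call(rbind, lapply(names(concord), function(nm) {
      x <- concord[[nm]]
      if (inherits(x, "agreement")) {
        data.frame(comparison = nm, n = x$n_compared,
                   value = x$fraction, metric = "agreement")
      } else if (inherits(x, "vep_concordance")) {
        data.frame(comparison = nm, n = x$n_compared,
                   value = x$accuracy, metric = "accuracy")
      } else NULL
    }))
    if (!is.null(summary_rows)) {
      paths$concordance <- file.path(config$out_dir, "concordance_summary.csv")
      write_csv_with_header(summary_rows, paths$concordance, hdr)
    }
  }

  manifest <- list(
    package = "rcscreen",
    version = as.character(utils::packageVersion("rcscreen")),
    seed = config$seed,
    config_hash = hash,
    config = unclass(config),
    files = lapply(unlist(paths), function(p)
      list(path = p, md5 = unname(tools::md5sum(p))))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  paths$manifest <- manifest_path
  say("done: ", length(unlist(paths)), " artifact(s) in ", config$out_dir)

  invisible(list(orf = orf, enum = enum, groups = groups, scores = scores,
                 fit = fit, summaries = summ, truth = truth,
                 concordance = concord, paths = paths, config = config))
}
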