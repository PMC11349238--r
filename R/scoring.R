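#' Per-SNV frequencies from a count table
#'
#' Frequency of an SNV in one sample is its read count divided by the
#' sequencing coverage at its nucleotide position. A Haldane-style
#' continuity pseudocount (default 0.5 reads) is added to every SNV in every
#' sample so that library-present SNVs with zero post-selection reads remain
#' scorable; raw detection (count > 0) is tracked separately.
#'
#' @param counts Count-table data.frame with columns `cds_pos`, `ref`,
#'   `alt`, `count`, `coverage` and (for multi-sample tables) `sample_id`.
#' @param pseudocount Reads added to every count before division (0 disables).
#' @return The input with columns `frequency` and `detected` added.
#' @export
compute_frequencies <- function(counts, pseudocount = 0.5) {
  need <- c("cds_pos", "ref", "alt", "count", "coverage")
  stopifnot(all(need %in% names(counts)))
  if (any(counts$coverage <= 0 & counts$count > 0)) {
    stop("zero coverage at a position with nonzero count", call. = FALSE)
  }
  counts$detected <- counts$count > 0
  counts$frequency <- ifelse(counts$coverage > 0,
                             (counts$count + pseudocount) / counts$coverage, 0)
  counts
}

#' Mean frequency across replicates
#'
#' Unweighted arithmetic mean of per-replicate frequencies, as used for the
#' unselected library aliquots and for the selected screen replicates.
#'
#' @param freqs Numeric vector (or matrix with one column per replicate) of
#'   frequencies.
#' @return For a vector, its mean; for a matrix, row means. The number of
#'   replicates is attached as attribute `n_replicates`.
#' @export
average_replicates <- function(freqs) {
  if (is.matrix(freqs)) {
    if (ncol(freqs) == 0L) stop("empty replicate set", call. = FALSE)
    structure(rowMeans(freqs), n_replicates = ncol(freqs))
  } else {
    if (length(freqs) == 0L) stop("empty replicate set", call. = FALSE)
    structure(mean(freqs), n_replicates = length(freqs))
  }
}

#' Complementation score (log2 depletion ratio)
#'
#' The complementation score is log2 of the mean post-selection frequency
#' over the mean pre-selection frequency. Negative scores mean the variant
#' was depleted by selection, i.e. impaired function.
#'
#' @param f_before,f_after Mean pseudocounted frequencies before and after
#'   selection (vectorized).
#' @return Numeric vector of scores; `NA` where `f_before` is not positive
#'   (unscorable).
#' @export
compute_rcs <- function(f_before, f_after) {
  ifelse(f_before > 0, log2(f_after / f_before), NA_real_)
}

#' Score a screen from replicate count tables
#'
#' Computes per-SNV mean before/after frequencies and complementation
#' scores. An SNV with zero raw reads in every before-selection replicate is
#' flagged `missing_in_library` and left unscored (mirroring the exclusion
#' of library-absent variants); zero reads after selection are handled by
#' the pseudocount.
#'
#' @param counts Long count table covering all samples (e.g.
#'   `screen_sim$counts` or [read_counts()] output).
#' @param enum SNV enumeration from [enumerate_snvs()].
#' @param before_ids,after_ids Sample identifiers of the unselected and
#'   selected replicates.
#' @param pseudocount Passed to [compute_frequencies()].
#' @return Data.frame with one row per possible SNV: enumeration columns
#'   plus `f_before`, `f_after`, `rcs`, `n_before`, `n_after`,
#'   `detected_before`, `detected_after`, `missing_in_library`, `scorable`.
#' @export
score_snvs <- function(counts, enum, before_ids, after_ids, pseudocount = 0.5) {
  stopifnot("sample_id" %in% names(counts))
  samples <- unique(counts$sample_id)
  missing_samples <- setdiff(c(before_ids, after_ids), samples)
  if (length(missing_samples) > 0L) {
    stop("count table lacks sample(s): ", paste(missing_samples, collapse = ", "),
         call. = FALSE)
  }
  fr <- compute_frequencies(counts, pseudocount)
  key <- paste0(enum$cds_pos, ":", enum$alt)

  freq_mat <- function(ids) {
    m <- matrix(0, nrow = nrow(enum), ncol = length(ids),
                dimnames = list(NULL, ids))
    d <- matrix(FALSE, nrow = nrow(enum), ncol = length(ids))
    for (j in seq_along(ids)) {
      sub <- fr[fr$sample_id == ids[j], ]
      idx <- match(key, paste0(sub$cds_pos, ":", sub$alt))
      if (anyNA(idx)) {
        stop("sample ", ids[j], " does not cover the full SNV grid", call. = FALSE)
      }
      m[, j] <- sub$frequency[idx]
      d[, j] <- sub$detected[idx]
    }
    list(f = m, d = d)
  }
  bef <- freq_mat(before_ids)
  aft <- freq_mat(after_ids)

  out <- enum
  out$f_before <- as.numeric(average_replicates(bef$f))
  out$f_after <- as.numeric(average_replicates(aft$f))
  out$n_before <- length(before_ids)
  out$n_after <- length(after_ids)
  out$detected_before <- rowSums(bef$d) > 0
  out$detected_after <- rowSums(aft$d) > 0
  out$missing_in_library <- !out$detected_before
  out$scorable <- !out$missing_in_library & out$f_before > 0
  out$rcs <- ifelse(out$scorable, compute_rcs(out$f_before, out$f_after), NA_real_)
  out
}

#' Aggregate SNV scores into unique coding outcomes
#'
#' For outcomes reachable by several SNVs, before/after frequencies are
#' averaged across the scored member SNVs first and a single log2 ratio is
#' then taken (not a mean of member scores). Singleton groups reproduce the
#' member's record exactly.
#'
#' @param snv_scores Output of [score_snvs()].
#' @param groups Outcome table from [group_outcomes()].
#' @param member_stat `"frequency"` (default; average member frequencies,
#'   then one log2) or `"rcs"` (average member scores).
#' @return Data.frame with one row per outcome: `outcome_id`, `codon_index`,
#'   `ref_aa`, `alt_aa`, `kind`, `hgvs_p`, `n_members`, `n_scored`,
#'   `f_before`, `f_after`, `rcs`, `scorable`.
#' @export
aggregate_outcomes <- function(snv_scores, groups,
                               member_stat = c("frequency", "rcs")) {
  member_stat <- match.arg(member_stat)
  stopifnot("outcome_id" %in% names(snv_scores))
  sc <- snv_scores[snv_scores$scorable, ]
  f <- factor(sc$outcome_id, levels = groups$outcome_id)

  out <- groups[, c("outcome_id", "codon_index", "ref_aa", "alt_aa", "kind",
                    "hgvs_p", "n_members")]
  out$n_scored <- as.integer(tapply(sc$scorable, f, sum, default = 0L))
  out$f_before <- as.numeric(tapply(sc$f_before, f, mean, default = NA_real_))
  out$f_after <- as.numeric(tapply(sc$f_after, f, mean, default = NA_real_))
  out$scorable <- out$n_scored > 0L
  if (member_stat == "frequency") {
    out$rcs <- ifelse(out$scorable, compute_rcs(out$f_before, out$f_after),
                      NA_real_)
  } else {
    out$rcs <- as.numeric(tapply(sc$rcs, f, mean, default = NA_real_))
  }
  rownames(out) <- NULL
  out
}

#' Score a screen at SNV and outcome level
#'
#' Convenience wrapper running [score_snvs()] and [aggregate_outcomes()].
#'
#' @inheritParams score_snvs
#' @inheritParams aggregate_outcomes
#' @param groups Outcome table from [group_outcomes()]; computed from `enum`
#'   when `NULL`.
#' @return List of class `screen_scores`: `snv` and `outcome` data.frames,
#'   plus the scoring options used.
#' @export
score_screen <- function(counts, enum, before_ids, after_ids,
                         pseudocount = 0.5, groups = NULL,
                         member_stat = c("frequency", "rcs")) {
  member_stat <- match.arg(member_stat)
  if (is.null(groups)) groups <- group_outcomes(enum)
  snv <- score_snvs(counts, enum, before_ids, after_ids, pseudocount)
  outcome <- aggregate_outcomes(snv, groups, member_stat)
  structure(list(snv = snv, outcome = outcome,
                 pseudocount = pseudocount, member_stat = member_stat,
                 before_ids = before_ids, after_ids = after_ids),
            class = "screen_scores")
}

#' @export
print.screen_scores <- function(x, ...) {
  cat("Screen scores:", nrow(x$snv), "SNVs (", sum(x$snv$scorable), "scorable ),",
      nrow(x$outcome), "coding outcomes\n")
  invisible(x)
}

#' Per-residue and per-region summaries
#'
#' For each residue: the number of scored outcomes, their mean
#' complementation score, and (over classified missense outcomes) counts and
#' fraction of damaging calls. When a region map is given, the same
#' aggregates are reported per named region (missense calls pooled over the
#' region's residues).
#'
#' @param outcome_scores Outcome-level scores ([aggregate_outcomes()]).
#' @param calls Effect calls from [predict_effects()] / [predict.rcs_fit()]
#'   (may be `NULL`: damaging counts are then omitted).
#' @param regions Optional [region_map()].
#' @return List with `residue` (one row per codon) and, if `regions` is
#'   supplied, `region` data.frames.
#' @export
residue_summaries <- function(outcome_scores, calls = NULL, regions = NULL) {
  sc <- outcome_scores[outcome_scores$scorable, ]
  codons <- sort(unique(outcome_scores$codon_index))
  f <- factor(sc$codon_index, levels = codons)
  res <- data.frame(
    codon_index = codons,
    n_outcomes = as.integer(table(f)),
    mean_rcs = as.numeric(tapply(sc$rcs, f, mean, default = NA_real_))
  )
  if (!is.null(calls)) {
    cl <- merge(calls[, c("outcome_id", "label")],
                outcome_scores[, c("outcome_id", "codon_index")],
                by = "outcome_id")
    g <- factor(cl$codon_index, levels = codons)
    res$n_missense <- as.integer(table(g))
    res$n_damaging <- as.integer(tapply(cl$label == "damaging", g, sum, default = 0L))
    res$n_tolerated <- res$n_missense - res$n_damaging
    res$fraction_damaging <- ifelse(res$n_missense > 0,
                                    res$n_damaging / res$n_missense, NA_real_)
  }
  out <- list(residue = res)
  if (!is.null(regions)) {
    nm <- setdiff(names(regions), c("atp_pocket", "stop_boundary"))
    reg <- do.call(rbind, lapply(nm, function(r) {
      iv <- regions[[r]]
      sub <- res[res$codon_index >= iv[1] & res$codon_index <= iv[2], ]
      row <- data.frame(region = r, start = iv[1], end = iv[2],
                        mean_rcs = mean(sub$mean_rcs, na.rm = TRUE))
      if (!is.null(calls)) {
        row$n_missense <- sum(sub$n_missense)
        row$n_damaging <- sum(sub$n_damaging)
        row$fraction_damaging <- ifelse(row$n_missense > 0,
                                        row$n_damaging / row$n_missense, NA_real_)
      }
      row
    }))
    if (length(regions$atp_pocket) > 0L) {
      sub <- res[res$codon_index %in% regions$atp_pocket, ]
      row <- data.frame(region = "atp_pocket", start = NA_integer_,
                        end = NA_integer_,
                        mean_rcs = mean(sub$mean_rcs, na.rm = TRUE))
      if (!is.null(calls)) {
        row$n_missense <- sum(sub$n_missense)
        row$n_damaging <- sum(sub$n_damaging)
        row$fraction_damaging <- ifelse(row$n_missense > 0,
                                        row$n_damaging / row$n_missense, NA_real_)
      }
      reg <- rbind(reg, row)
    }
    rownames(reg) <- NULL
    out$region <- reg
  }
  out
}
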