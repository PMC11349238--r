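#' Normalize protein-level variant keys
#'
#' External annotation tables mix one-letter (`R117G`), three-letter
#' (`Arg117Gly`) and prefixed (`p.Arg117Gly`) conventions. All joins in the
#' concordance functions go through this canonical form:
#' `p.<Ref3><pos><Alt3>` with `Ter` for stop and `p.(<Ref3><pos>=)` for
#' synonymous.
#'
#' @param keys Character vector of protein variant names.
#' @return Canonical HGVS p. keys; `NA` where a key cannot be parsed.
#' @examples
#' normalize_hgvs_p(c("R117G", "p.Arg117Gly", "I157T"))
#' @export
normalize_hgvs_p <- function(keys) {
  keys <- trimws(as.character(keys))
  out <- rep(NA_character_, length(keys))

  syn <- grepl("^p\\.\\(?([A-Za-z]{3})([0-9]+)=\\)?$", keys)
  out[syn] <- sub("^p\\.\\(?([A-Za-z]{3})([0-9]+)=\\)?$", "p.(\\1\\2=)", keys[syn])

  pat3 <- "^(p\\.)?([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2}|Ter|\\*|stop)$"
  three <- grepl(pat3, keys)
  m3 <- regmatches(keys[three], regexec(pat3, keys[three]))
  out[three] <- vapply(m3, function(g) {
    alt <- if (g[5] %in% c("*", "stop")) "Ter" else g[5]
    if (!(g[3] %in% AA3) || !(alt %in% AA3)) return(NA_character_)
    paste0("p.", g[3], g[4], alt)
  }, character(1))

  one <- is.na(out) & grepl("^(p\\.)?([A-Z])([0-9]+)([A-Z]|\\*|X|stop)$", keys)
  m1 <- regmatches(keys[one],
                   regexec("^(p\\.)?([A-Z])([0-9]+)([A-Z]|\\*|X|stop)$", keys[one]))
  out[one] <- vapply(m1, function(g) {
    ref <- AA3[g[3]]
    alt <- if (g[5] %in% c("*", "X", "stop")) "Ter" else unname(AA3[g[5]])
    if (is.na(ref) || is.na(alt)) return(NA_character_)
    paste0("p.", ref, g[4], alt)
  }, character(1))
  out
}

#' Read an external annotation table
#'
#' Reads a CSV/TSV of per-variant external annotations (clinical classes,
#' other-assay calls, predictor scores) and normalizes the variant key.
#'
#' @param path CSV or TSV file (delimiter inferred from the extension).
#' @param key_col Name of the protein-variant column.
#' @return The table with a canonical `hgvs_p` column prepended.
#' @export
read_annotations <- function(path, key_col = "hgvs_p") {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  x <- utils::read.table(path, sep = sep, header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!key_col %in% names(x)) {
    stop("annotation table lacks key column '", key_col, "'", call. = FALSE)
  }
  keys <- normalize_hgvs_p(x[[key_col]])
  if (anyNA(keys)) {
    warning(sum(is.na(keys)), " annotation key(s) could not be parsed")
  }
  cbind(data.frame(hgvs_p = keys, stringsAsFactors = FALSE),
        x[setdiff(names(x), "hgvs_p")])
}

#' Group statistics with pairwise Welch tests
#'
#' Per-group size, mean and standard deviation of the score, plus Welch's
#' unequal-variance two-sample t statistic and p-value for every pair of
#' groups (sizes and variances differ widely across annotation classes, so
#' the pooled-variance test is not appropriate).
#'
#' @param score Numeric score vector.
#' @param group Factor (or coercible) of the same length.
#' @return List of class `group_stats`: `groups` (data.frame `group`, `n`,
#'   `mean`, `sd`) and `pairwise` (data.frame `group1`, `group2`,
#'   `statistic`, `df`, `p_value`, `mean_diff`).
#' @export
group_statistics <- function(score, group) {
  keep <- is.finite(score) & !is.na(group)
  score <- score[keep]
  group <- droplevels(factor(group[keep]))
  if (nlevels(group) < 1L) stop("no groups with finite scores", call. = FALSE)
  gs <- data.frame(
    group = levels(group),
    n = as.integer(table(group)),
    mean = as.numeric(tapply(score, group, mean)),
    sd = as.numeric(tapply(score, group, stats::sd)),
    stringsAsFactors = FALSE
  )
  pairs <- if (nlevels(group) >= 2L) utils::combn(levels(group), 2) else
    matrix(character(0), nrow = 2)
  pw <- do.call(rbind, apply(pairs, 2, function(p) {
    a <- score[group == p[1]]
    b <- score[group == p[2]]
    if (length(a) < 2L || length(b) < 2L) {
      stop("group with n < 2 for a variance-requiring test: ",
           p[which(c(length(a), length(b)) < 2L)][1], call. = FALSE)
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    data.frame(group1 = p[1], group2 = p[2],
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, mean_diff = mean(a) - mean(b),
               stringsAsFactors = FALSE)
  }, simplify = FALSE))
  structure(list(groups = gs, pairwise = pw), class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  print(x$groups, row.names = FALSE)
  if (!is.null(x$pairwise) && nrow(x$pairwise) > 0) {
    cat("\nPairwise Welch tests:\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Positional contrast of premature-stop scores
#'
#' Splits scored stop-gain outcomes at a codon boundary (default 500) and
#' reports both groups' statistics with the Welch test; used to show that
#' truncation late in the protein does not impair complementation.
#'
#' @param outcome_scores Outcome-level scores.
#' @param boundary Codon boundary; stops at codons `<= boundary` form the
#'   early group.
#' @return A [group_statistics()] result with groups `early` and `late`.
#' @export
stop_position_contrast <- function(outcome_scores, boundary = 500L) {
  st <- outcome_scores[outcome_scores$kind == "stop_gain" &
                         outcome_scores$scorable, ]
  side <- factor(ifelse(st$codon_index <= boundary, "early", "late"),
                 levels = c("early", "late"))
  if (any(table(side) == 0L)) {
    stop("no scored stop-gain outcomes on one side of codon ", boundary,
         call. = FALSE)
  }
  group_statistics(st$rcs, side)
}

#' Agreement between two call sets
#'
#' Fraction of shared variants on which two assays' functional calls agree.
#' By default an `intermediate` call counts as a disagreement against a
#' binary call (the arithmetic used when comparing binary screen calls to
#' three-class assays); alternatively such pairs can be excluded.
#'
#' @param calls_a,calls_b Named character vectors (names = variant keys,
#'   values in `damaging`/`tolerated`/`intermediate`).
#' @param intermediate `"disagree"` (default) or `"exclude"`.
#' @return List of class `agreement`: `n_compared`, `n_agree`, `fraction`,
#'   `n_disagree_intermediate` (disagreements where either call is
#'   intermediate), `disagreements` (data.frame).
#' @export
pairwise_agreement <- function(calls_a, calls_b,
                               intermediate = c("disagree", "exclude")) {
  intermediate <- match.arg(intermediate)
  shared <- intersect(names(calls_a), names(calls_b))
  if (length(shared) == 0L) stop("no shared variant keys", call. = FALSE)
  a <- as.character(calls_a[shared])
  b <- as.character(calls_b[shared])
  keep <- !is.na(a) & !is.na(b) & a != "absent" & b != "absent"
  if (intermediate == "exclude") {
    keep <- keep & a != "intermediate" & b != "intermediate"
  }
  a <- a[keep]; b <- b[keep]; shared <- shared[keep]
  if (length(a) == 0L) stop("no comparable variant pairs", call. = FALSE)
  agree <- a == b
  dis <- data.frame(hgvs_p = shared[!agree], call_a = a[!agree],
                    call_b = b[!agree], stringsAsFactors = FALSE)
  structure(list(
    n_compared = length(a), n_agree = sum(agree),
    fraction = mean(agree),
    n_disagree_intermediate = sum(!agree &
                                    (a == "intermediate" | b == "intermediate")),
    disagreements = dis
  ), class = "agreement")
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf("Agreement: %d/%d (%.1f%%); %d disagreement(s) involve an intermediate call\n",
              x$n_agree, x$n_compared, 100 * x$fraction,
              x$n_disagree_intermediate))
  invisible(x)
}

#' Consensus call across assays
#'
#' Majority vote over `damaging`/`intermediate`/`tolerated` calls from two
#' or more assays for one variant; an exact tie is unresolved (`NA` with the
#' tally retained).
#'
#' @param calls Character vector of calls from different assays for one
#'   variant (`absent`/`NA` entries dropped).
#' @return Length-1 character (`NA` if tied) with attribute `tally`.
#' @export
consensus_call <- function(calls) {
  calls <- calls[!is.na(calls) & calls != "absent"]
  if (length(calls) < 2L) {
    stop("consensus requires at least 2 non-absent calls", call. = FALSE)
  }
  tab <- table(factor(calls, levels = c("damaging", "intermediate", "tolerated")))
  top <- names(tab)[tab == max(tab)]
  out <- if (length(top) == 1L) top else NA_character_
  structure(out, tally = tab)
}

#' Consensus calls for a table of assay results
#'
#' @param call_matrix Data.frame or matrix, rows = variants (rownames =
#'   keys), columns = assays, cells in
#'   `damaging`/`intermediate`/`tolerated`/`absent`/`NA`.
#' @return Data.frame `hgvs_p`, `n_calls`, `consensus` (`NA` = unresolved);
#'   rows with fewer than 2 usable calls are dropped.
#' @export
consensus_calls <- function(call_matrix) {
  m <- as.matrix(call_matrix)
  usable <- rowSums(!is.na(m) & m != "absent") >= 2L
  m <- m[usable, , drop = FALSE]
  res <- apply(m, 1, function(r) as.character(consensus_call(r)))
  data.frame(hgvs_p = rownames(m),
             n_calls = rowSums(!is.na(m) & m != "absent"),
             consensus = res, stringsAsFactors = FALSE, row.names = NULL)
}

#' Concordance with a variant effect predictor
#'
#' Binarizes a 0-1 predictor score at a cutoff (>= cutoff predicts
#' damaging) and reports accuracy against the screen's binary calls, plus
#' the mean predictor score per call class. Intermediate calls are excluded:
#' only damaging/tolerated variants are compared.
#'
#' @param calls Named character vector of screen calls
#'   (`damaging`/`tolerated`, names = variant keys).
#' @param scores Named numeric vector of predictor scores in \[0, 1\].
#' @param cutoff Binarization cutoff (default 0.5).
#' @return List of class `vep_concordance`: `n_compared`, `n_correct`,
#'   `accuracy`, `mean_score_damaging`, `mean_score_tolerated`,
#'   `accuracy_damaging`, `accuracy_tolerated`.
#' @export
vep_concordance <- function(calls, scores, cutoff = 0.5) {
  scores <- scores[!is.na(scores)]
  if (any(scores < 0 | scores > 1)) {
    stop("predictor scores must lie in [0, 1]", call. = FALSE)
  }
  shared <- intersect(names(calls), names(scores))
  shared <- shared[calls[shared] %in% c("damaging", "tolerated")]
  if (length(shared) == 0L) stop("no comparable variants", call. = FALSE)
  cl <- as.character(calls[shared])
  sc <- as.numeric(scores[shared])
  pred <- ifelse(sc >= cutoff, "damaging", "tolerated")
  correct <- pred == cl
  acc_by <- function(lab) if (any(cl == lab)) mean(correct[cl == lab]) else NA_real_
  structure(list(
    n_compared = length(shared), n_correct = sum(correct),
    accuracy = mean(correct),
    mean_score_damaging = if (any(cl == "damaging")) mean(sc[cl == "damaging"]) else NA_real_,
    mean_score_tolerated = if (any(cl == "tolerated")) mean(sc[cl == "tolerated"]) else NA_real_,
    accuracy_damaging = acc_by("damaging"),
    accuracy_tolerated = acc_by("tolerated")
  ), class = "vep_concordance")
}

#' @export
print.vep_concordance <- function(x, ...) {
  cat(sprintf("Predictor concordance: %d/%d (%.1f%%) correct; mean score %.3f (damaging) vs %.3f (tolerated)\n",
              x$n_correct, x$n_compared, 100 * x$accuracy,
              x$mean_score_damaging, x$mean_score_tolerated))
  invisible(x)
}
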