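#' Substitution-spectrum model for error-prone PCR
#'
#' Weights for the 12 nucleotide substitution classes (`"G>A"`, `"T>C"`, ...),
#' normalized to sum to 1. Error-prone PCR produces a biased spectrum in
#' which every transition and transversion occurs but G>A dominates while
#' T>G and G>C are rarest; the default encodes exactly that ordinal shape
#' (G>A weighted 3, T>G and G>C weighted 1/3, the other nine classes 1,
#' before normalization) since no numeric spectrum table is available.
#'
#' @param weights Optional named numeric vector over all 12 classes, all
#'   strictly positive (any normalization).
#' @return Named numeric vector of class `spectrum_model`, summing to 1.
#' @export
spectrum_model <- function(weights = NULL) {
  classes <- as.vector(outer(BASES, BASES, function(r, a) paste0(r, ">", a)))
  classes <- classes[substr(classes, 1, 1) != substr(classes, 3, 3)]
  if (is.null(weights)) {
    weights <- setNames(rep(1, 12L), classes)
    weights["G>A"] <- 3
    weights[c("T>G", "G>C")] <- 1 / 3
  }
  if (!all(sort(names(weights)) == sort(classes))) {
    stop("weights must be named by all 12 substitution classes (e.g. 'G>A')",
         call. = FALSE)
  }
  if (any(weights <= 0)) stop("all substitution classes need weight > 0", call. = FALSE)
  w <- weights[classes] / sum(weights)
  structure(w, class = "spectrum_model")
}

#' Simulation configuration for a synthetic complementation screen
#'
#' Default parameters reproduce the screen's measured scale: a mutagenesis
#' rate of 0.86 SNVs per 1,000 nt (about 1.4 SNVs per 1,629-nt clone),
#' background sequencing/PCR error of 0.097 per 1,000 nt, a pool of 62,000
#' yeast transformant clones, 2 unselected library replicates and 4 selected
#' screen replicates, 2.5 million read-equivalents per sample, and a
#' post-selection pool of 28,000 colonies per screen replicate.
#'
#' @param mu Per-nucleotide SNV rate of the mutagenized library.
#' @param epsilon Per-nucleotide background error rate of sequencing.
#' @param n_clones Number of clones in the unselected pool.
#' @param n_before,n_after Number of before-/after-selection replicates.
#' @param read_equivalents Full-length read-equivalents sequenced per sample.
#' @param selection_model `"hard"` (a clone survives iff it carries no
#'   damaging variant) or `"soft"` (survival probability is the product of
#'   per-variant fitness).
#' @param damaging_fraction Probability a missense outcome is damaging in
#'   the simulated ground truth (default 0.242, the fraction observed in the
#'   screen).
#' @param damaging_fitness Relative fitness of a damaging variant under the
#'   soft model (0 reduces soft to hard).
#' @param selected_pool Number of colonies resampled after each selection.
#' @param stop_boundary Last codon at which a premature stop is damaging in
#'   the ground truth; later stops are tolerated.
#' @param seed Integer master seed (mandatory); all stochastic stages draw
#'   from substreams derived from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mu = 0.86 / 1000, epsilon = 0.097 / 1000,
                       n_clones = 62000L, n_before = 2L, n_after = 4L,
                       read_equivalents = 2.5e6,
                       selection_model = c("hard", "soft"),
                       damaging_fraction = 0.242, damaging_fitness = 0,
                       selected_pool = 28000L, stop_boundary = 500L,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("sim_config requires a seed", call. = FALSE)
  selection_model <- match.arg(selection_model)
  stopifnot(mu >= 0, mu <= 1, epsilon >= 0, epsilon <= 1,
            n_clones >= 1, n_before >= 1, n_after >= 1,
            read_equivalents > 0, damaging_fraction >= 0, damaging_fraction <= 1,
            damaging_fitness >= 0, damaging_fitness <= 1, selected_pool >= 1)
  structure(list(
    mu = mu, epsilon = epsilon, n_clones = as.integer(n_clones),
    n_before = as.integer(n_before), n_after = as.integer(n_after),
    read_equivalents = read_equivalents, selection_model = selection_model,
    damaging_fraction = damaging_fraction, damaging_fitness = damaging_fitness,
    selected_pool = as.integer(selected_pool),
    stop_boundary = as.integer(stop_boundary), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate an error-prone-PCR clone library
#'
#' Each clone carries a Poisson(mu * L) number of SNVs at distinct uniform
#' positions; the substituted base is drawn from the spectrum conditioned on
#' the reference base at the position.
#'
#' @param orf An [orf_sequence()].
#' @param config A [sim_config()].
#' @param spectrum A [spectrum_model()].
#' @param enum Optional precomputed [enumerate_snvs()] table for the ORF.
#' @return A list of class `clone_library`: `variants` (data.frame
#'   `clone`, `cds_pos`, `ref`, `alt`, `outcome_id`), `n_clones`, `orf_id`,
#'   `length`.
#' @export
simulate_clone_library <- function(orf, config, spectrum = spectrum_model(),
                                   enum = NULL) {
  stopifnot(inherits(orf, "orf_sequence"), inherits(config, "sim_config"))
  if (is.null(enum)) enum <- enumerate_snvs(orf)
  L <- orf$length
  if (config$mu * L > 0.5 * L) {
    stop("mutation burden mu*L too large for distinct-position sampling", call. = FALSE)
  }
  ref_all <- strsplit(orf$sequence, "")[[1]]

  variants <- with_substream(config$seed, "clone_library", {
    n_var <- rpois(config$n_clones, config$mu * L)
    total <- sum(n_var)
    clone <- rep.int(seq_len(config$n_clones), n_var)
    pos <- sample.int(L, total, replace = TRUE)
    # re-draw positions duplicated within a clone until all are distinct
    for (iter in seq_len(100L)) {
      dup <- duplicated(paste(clone, pos))
      if (!any(dup)) break
      pos[dup] <- sample.int(L, sum(dup), replace = TRUE)
    }
    if (any(duplicated(paste(clone, pos)))) {
      stop("failed to sample distinct positions per clone; mu*L too large",
           call. = FALSE)
    }
    ref <- ref_all[pos]
    alt <- character(total)
    for (b in BASES) {
      idx <- which(ref == b)
      if (length(idx) == 0L) next
      alts <- BASES[BASES != b]
      w <- as.numeric(spectrum[paste0(b, ">", alts)])
      alt[idx] <- sample(alts, length(idx), replace = TRUE, prob = w)
    }
    data.frame(clone = clone, cds_pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  })
  key <- paste0(enum$cds_pos, enum$alt)
  variants$outcome_id <- enum$outcome_id[match(paste0(variants$cds_pos, variants$alt), key)]
  structure(list(variants = variants, n_clones = config$n_clones,
                 orf_id = orf$id, length = L),
            class = "clone_library")
}

#' @export
print.clone_library <- function(x, ...) {
  cat("Clone library:", x$n_clones, "clones,", nrow(x$variants),
      "variant events on", x$orf_id, "\n")
  invisible(x)
}

#' Assign ground-truth effect labels to coding outcomes
#'
#' Mirrors the structure of the screen's internal controls: every premature
#' stop at or before `stop_boundary` is damaging, stops beyond it are
#' tolerated (late truncation does not impair complementation), every
#' synonymous outcome is tolerated, and each missense outcome is damaging
#' independently with probability `damaging_fraction`.
#'
#' @param groups Outcome table from [group_outcomes()].
#' @param config A [sim_config()].
#' @return Data.frame of class `ground_truth`: `outcome_id`, `codon_index`,
#'   `kind`, `label` (`damaging`/`tolerated`), `fitness`.
#' @export
assign_effects <- function(groups, config) {
  stopifnot(inherits(config, "sim_config"))
  label <- rep("tolerated", nrow(groups))
  stops <- groups$kind == "stop_gain" & groups$codon_index <= config$stop_boundary
  label[stops] <- "damaging"
  mis <- which(groups$kind == "missense")
  if (length(mis) > 0L && config$damaging_fraction > 0) {
    hit <- with_substream(config$seed, "ground_truth",
                          runif(length(mis)) < config$damaging_fraction)
    label[mis[hit]] <- "damaging"
  }
  out <- data.frame(outcome_id = groups$outcome_id,
                    codon_index = groups$codon_index,
                    kind = groups$kind, label = label,
                    stringsAsFactors = FALSE)
  out$fitness <- ifelse(out$label == "damaging", config$damaging_fitness, 1)
  class(out) <- c("ground_truth", "data.frame")
  out
}

#' Apply complementation selection to a clone library
#'
#' Under the hard model a clone survives iff it carries no damaging variant;
#' under the soft model it survives with probability equal to the product of
#' its variants' fitness values. Survivors are resampled with replacement to
#' the configured post-selection pool size, which models the colony
#' bottleneck and makes hitchhiking emerge naturally: a tolerated variant
#' that shares a clone with a damaging one is lost with that clone.
#'
#' @param library A [simulate_clone_library()] result.
#' @param truth A [assign_effects()] table covering every variant outcome.
#' @param config A [sim_config()].
#' @param replicate_id Label used to give each screen replicate its own
#'   random substream.
#' @return A `clone_library` of the selected pool.
#' @export
simulate_selection <- function(library, truth, config, replicate_id = "S1") {
  stopifnot(inherits(library, "clone_library"), inherits(config, "sim_config"))
  v <- library$variants
  lab <- truth$label[match(v$outcome_id, truth$outcome_id)]
  if (anyNA(lab)) stop("ground truth missing for some clone variants", call. = FALSE)

  with_substream(config$seed, paste0("selection:", replicate_id), {
    if (config$selection_model == "hard") {
      dead <- unique(v$clone[lab == "damaging"])
      survivors <- setdiff(seq_len(library$n_clones), dead)
    } else {
      fit <- truth$fitness[match(v$outcome_id, truth$outcome_id)]
      logp <- rep(0, library$n_clones)
      agg <- rowsum(log(pmax(fit, 1e-12)), v$clone)
      logp[as.integer(rownames(agg))] <- agg[, 1]
      survivors <- which(runif(library$n_clones) < exp(logp))
    }
    if (length(survivors) == 0L) {
      stop("selection eliminated every clone", call. = FALSE)
    }
    picked <- sample(survivors, config$selected_pool, replace = TRUE)
    # rebuild the variant table for the resampled pool
    idx <- split(seq_len(nrow(v)), factor(v$clone, levels = seq_len(library$n_clones)))
    take <- idx[picked]
    new_clone <- rep.int(seq_along(take), lengths(take))
    nv <- v[unlist(take, use.names = FALSE), , drop = FALSE]
    nv$clone <- new_clone
    rownames(nv) <- NULL
    structure(list(variants = nv, n_clones = config$selected_pool,
                   orf_id = library$orf_id, length = library$length),
              class = "clone_library")
  })
}

#' Tabulate sequencing counts for a clone pool
#'
#' Sequencing is modeled as `read_equivalents` full-length reads multinomially
#' assigned to clones (so coverage equals `read_equivalents` at every
#' position), plus independent background errors at rate `epsilon` per read
#' base, split uniformly over the three alternate bases.
#'
#' @param library A `clone_library`.
#' @param config A [sim_config()].
#' @param sample_id Sample label (also selects the random substream).
#' @param enum SNV enumeration of the same ORF ([enumerate_snvs()]); the
#'   output covers this complete SNV grid (zero counts included).
#' @return A count-table data.frame: `cds_pos`, `ref`, `alt`, `count`,
#'   `coverage`, `sample_id`, one row per possible SNV.
#' @export
tabulate_counts <- function(library, config, sample_id, enum = NULL) {
  stopifnot(inherits(library, "clone_library"), inherits(config, "sim_config"))
  if (config$read_equivalents <= 0) stop("read_equivalents must be > 0", call. = FALSE)
  if (library$n_clones == 0L) stop("empty clone pool", call. = FALSE)
  v <- library$variants
  R <- config$read_equivalents

  with_substream(config$seed, paste0("counts:", sample_id), {
    reads_per_clone <- as.vector(rmultinom(1, R, rep(1, library$n_clones)))
    if (nrow(v) > 0L) {
      agg <- rowsum(reads_per_clone[v$clone], paste0(v$cds_pos, ":", v$alt))
      snv_counts <- setNames(agg[, 1], rownames(agg))
    } else {
      snv_counts <- numeric(0)
    }
    if (is.null(enum)) {
      stop("tabulate_counts needs the SNV enumeration of the ORF", call. = FALSE)
    }
    out <- enum[, c("cds_pos", "ref", "alt")]
    out$count <- 0
    key <- paste0(out$cds_pos, ":", out$alt)
    hit <- match(names(snv_counts), key)
    out$count[hit] <- snv_counts
    if (config$epsilon > 0) {
      out$count <- out$count + rbinom(nrow(out), size = round(R),
                                      prob = config$epsilon / 3)
    }
    out$coverage <- round(R)
    out$count <- pmin(out$count, out$coverage)
    out$sample_id <- sample_id
    out
  })
}

#' Simulate a complete deep-mutational-scanning screen
#'
#' End-to-end generator: error-prone-PCR clone library, ground-truth effect
#' assignment, independent selection per screen replicate, and replicate
#' count tables for the unselected library and the selected pools.
#'
#' @param orf An [orf_sequence()].
#' @param config A [sim_config()].
#' @param spectrum A [spectrum_model()].
#' @return A list of class `screen_sim`: `orf`, `enum`, `groups`, `truth`,
#'   `counts` (single long data.frame over all samples), `before_ids`,
#'   `after_ids`, `config`.
#' @examples
#' \donttest{
#' scr <- simulate_screen(synthetic_orf(50), sim_config(n_clones = 2000,
#'   read_equivalents = 1e5, selected_pool = 1000, seed = 7))
#' table(scr$truth$label)
#' }
#' @export
simulate_screen <- function(orf, config, spectrum = spectrum_model()) {
  enum <- enumerate_snvs(orf)
  groups <- group_outcomes(enum)
  lib <- simulate_clone_library(orf, config, spectrum, enum = enum)
  truth <- assign_effects(groups, config)

  before_ids <- paste0("Lib", LETTERS[seq_len(config$n_before)])
  after_ids <- paste0("S", seq_len(config$n_after))

  tabs <- vector("list", config$n_before + config$n_after)
  for (i in seq_along(before_ids)) {
    tabs[[i]] <- tabulate_counts(lib, config, before_ids[i], enum = enum)
  }
  for (j in seq_along(after_ids)) {
    sel <- simulate_selection(lib, truth, config, replicate_id = after_ids[j])
    tabs[[config$n_before + j]] <- tabulate_counts(sel, config, after_ids[j],
                                                   enum = enum)
  }
  structure(list(orf = orf, enum = enum, groups = groups, truth = truth,
                 counts = do.call(rbind, tabs),
                 before_ids = before_ids, after_ids = after_ids,
                 config = config),
            class = "screen_sim")
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("Simulated screen on", x$orf$id, ":", x$config$n_clones, "clones,",
      length(x$before_ids), "before +", length(x$after_ids),
      "after replicates\n")
  invisible(x)
}
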