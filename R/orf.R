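#' ORF sequence constructor
#'
#' Builds a validated open-reading-frame object from a nucleotide string.
#' The ORF is the mutagenized coding sequence *without* its terminal stop
#' codon (in the screen design the stop is supplied by the vector primer), so
#' a valid ORF contains no stop codon anywhere and stop-loss is not a
#' possible SNV consequence.
#'
#' @param sequence Nucleotide string over A/C/G/T; length must be a positive
#'   multiple of 3 and translation must contain no stop codon.
#' @param id Text label for the ORF.
#' @return An object of class `orf_sequence` with elements `id`, `sequence`,
#'   `length` (nt) and `n_codons`.
#' @examples
#' orf <- orf_sequence("ATGGCT", id = "toy")
#' orf$n_codons
#' @export
orf_sequence <- function(sequence, id = "orf") {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || nchar(sequence) < 3L) {
    stop("ORF sequence must be a single string of at least one codon", call. = FALSE)
  }
  if (grepl("[^ACGT]", sequence)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", sequence), "")[[1]])
    stop("ORF contains non-ACGT symbols: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nchar(sequence) %% 3L != 0L) {
    stop("ORF length (", nchar(sequence), " nt) is not divisible by 3", call. = FALSE)
  }
  aa <- translate_codons(codon_split(sequence))
  if (any(aa == "*")) {
    stop("ORF contains internal stop codon(s) at codon position(s): ",
         paste(which(aa == "*"), collapse = ", "), call. = FALSE)
  }
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence),
         n_codons = nchar(sequence) %/% 3L),
    class = "orf_sequence"
  )
}

#' @export
print.orf_sequence <- function(x, ...) {
  cat("ORF", x$id, ":", x$length, "nt,", x$n_codons, "codons\n")
  invisible(x)
}

#' Read an ORF from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param id Record to use: an identifier present in the file, or `NULL` to
#'   take the first record.
#' @return An [orf_sequence()] object.
#' @export
read_orf <- function(path, id = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  recs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("malformed FASTA: ", conditionMessage(e),
                                            call. = FALSE))
  if (length(recs) == 0L) stop("no records in FASTA: ", path, call. = FALSE)
  if (is.null(id)) {
    idx <- 1L
    id <- sub("\\s.*$", "", names(recs)[1])
  } else {
    idx <- which(sub("\\s.*$", "", names(recs)) == id)
    if (length(idx) == 0L) stop("record '", id, "' not present in ", path, call. = FALSE)
    idx <- idx[1]
  }
  orf_sequence(as.character(recs[[idx]]), id = id)
}

codon_split <- function(sequence) {
  n <- nchar(sequence) %/% 3L
  substring(sequence, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

translate_codons <- function(codons) {
  unname(Biostrings::GENETIC_CODE[codons])
}

#' Generate a random stop-free ORF
#'
#' Draws codons uniformly from the 61 sense codons of the standard genetic
#' code, prefixed with ATG. Used as a synthetic stand-in ORF for tests and
#' simulations when no real coding sequence is supplied.
#'
#' @param n_codons Number of codons (>= 1).
#' @param seed Integer seed.
#' @param id Label for the ORF.
#' @return An [orf_sequence()] object.
#' @export
synthetic_orf <- function(n_codons = 543L, seed = 1L, id = "synthetic_orf") {
  stopifnot(n_codons >= 1L)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  codons <- with_substream(seed, "synthetic_orf", {
    c("ATG", sample(sense, n_codons - 1L, replace = TRUE))[seq_len(n_codons)]
  })
  orf_sequence(paste(codons, collapse = ""), id = id)
}

#' Enumerate every possible SNV of an ORF
#'
#' Lists all 3L single-nucleotide substitutions of an L-nt ORF with their
#' protein-level consequence under the standard genetic code, HGVS c./p.
#' names, and the identifier of the unique coding outcome each SNV produces
#' (one outcome per codon and alternate amino acid; all synonymous changes at
#' a codon share one outcome).
#'
#' @param orf An [orf_sequence()].
#' @return A data.frame with one row per SNV, ordered by CDS position then
#'   alternate base (A < C < G < T): columns `cds_pos`, `ref`, `alt`,
#'   `codon_index`, `ref_aa`, `alt_aa` (single-letter; `*` = stop), `kind`
#'   (`synonymous`/`missense`/`stop_gain`), `hgvs_c`, `hgvs_p`, `outcome_id`.
#' @examples
#' enum <- enumerate_snvs(orf_sequence("ATGGCT"))
#' nrow(enum)  # 18
#' table(enum$kind)
#' @export
enumerate_snvs <- function(orf) {
  stopifnot(inherits(orf, "orf_sequence"))
  L <- orf$length
  ref_all <- strsplit(orf$sequence, "")[[1]]
  cds_pos <- rep(seq_len(L), each = 3L)
  ref <- ref_all[cds_pos]
  # the 3 alternates per position, in A<C<G<T order
  alt <- unlist(lapply(ref_all, function(b) BASES[BASES != b]), use.names = FALSE)

  codon_index <- (cds_pos - 1L) %/% 3L + 1L
  pos_in_codon <- (cds_pos - 1L) %% 3L + 1L
  ref_codons <- codon_split(orf$sequence)
  ref_codon <- ref_codons[codon_index]
  alt_codon <- ref_codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- alt

  ref_aa <- translate_codons(ref_codon)
  alt_aa <- translate_codons(alt_codon)
  kind <- ifelse(alt_aa == "*", "stop_gain",
                 ifelse(alt_aa == ref_aa, "synonymous", "missense"))

  out <- data.frame(
    cds_pos = cds_pos, ref = ref, alt = alt,
    codon_index = codon_index, ref_aa = ref_aa, alt_aa = alt_aa,
    kind = kind, stringsAsFactors = FALSE
  )
  out$hgvs_c <- paste0("c.", out$cds_pos, out$ref, ">", out$alt)
  out$hgvs_p <- hgvs_p_name(out$codon_index, out$ref_aa, out$alt_aa, out$kind)
  out$outcome_id <- outcome_key(out$codon_index, out$alt_aa, out$kind)
  rownames(out) <- NULL
  out
}

# unique-coding-outcome key: codon plus alternate amino acid; all synonymous
# SNVs at one codon collapse onto the "=" marker
outcome_key <- function(codon_index, alt_aa, kind) {
  paste0("c", codon_index, ":", ifelse(kind == "synonymous", "=", alt_aa))
}

hgvs_p_name <- function(codon_index, ref_aa, alt_aa, kind) {
  ref3 <- AA3[ref_aa]
  alt3 <- AA3[alt_aa]
  ifelse(kind == "synonymous",
         paste0("p.(", ref3, codon_index, "=)"),
         paste0("p.", ref3, codon_index, alt3))
}

#' HGVS-style names for an SNV or enumeration rows
#'
#' @param x A data.frame with columns `cds_pos`, `ref`, `alt`, `codon_index`,
#'   `ref_aa`, `alt_aa`, `kind` (e.g. rows of [enumerate_snvs()]).
#' @return A data.frame with columns `hgvs_c` and `hgvs_p`. Synonymous
#'   changes are named `p.(Xaa<pos>=)`; stop gains use the `Ter` symbol
#'   (e.g. `p.Gln510Ter`).
#' @export
name_variant <- function(x) {
  data.frame(
    hgvs_c = paste0("c.", x$cds_pos, x$ref, ">", x$alt),
    hgvs_p = hgvs_p_name(x$codon_index, x$ref_aa, x$alt_aa, x$kind),
    stringsAsFactors = FALSE
  )
}

#' Group SNVs into unique coding outcomes
#'
#' Partitions an SNV enumeration by (codon, protein outcome): a specific
#' alternate amino acid, a stop, or "synonymous". Several distinct SNVs can
#' produce the same outcome (at most 4 under standard-code degeneracy).
#'
#' @param enum A data.frame from [enumerate_snvs()] (complete or subset).
#' @return A data.frame with one row per outcome: `outcome_id`,
#'   `codon_index`, `ref_aa`, `alt_aa`, `kind`, `hgvs_p`, `n_members`,
#'   `hgvs_c` (member c.-names collapsed with `;`).
#' @examples
#' groups <- group_outcomes(enumerate_snvs(orf_sequence("ATGGCT")))
#' nrow(groups)  # 13
#' @export
group_outcomes <- function(enum) {
  need <- c("cds_pos", "ref", "alt", "codon_index", "ref_aa", "alt_aa", "kind")
  stopifnot(all(need %in% names(enum)))
  if (anyDuplicated(paste(enum$cds_pos, enum$alt))) {
    stop("duplicate SNV entries in enumeration", call. = FALSE)
  }
  if (is.null(enum$outcome_id)) {
    enum$outcome_id <- outcome_key(enum$codon_index, enum$alt_aa, enum$kind)
  }
  if (is.null(enum$hgvs_c)) enum$hgvs_c <- name_variant(enum)$hgvs_c

  ord <- order(enum$codon_index, enum$alt_aa)
  enum <- enum[ord, ]
  first <- !duplicated(enum$outcome_id)
  groups <- enum[first, c("outcome_id", "codon_index", "ref_aa", "alt_aa", "kind")]
  groups$hgvs_p <- hgvs_p_name(groups$codon_index, groups$ref_aa,
                               groups$alt_aa, groups$kind)
  tab <- table(enum$outcome_id)
  groups$n_members <- as.integer(tab[groups$outcome_id])
  groups$hgvs_c <- vapply(split(enum$hgvs_c, enum$outcome_id)[groups$outcome_id],
                          paste, character(1), collapse = ";")
  groups <- groups[order(groups$codon_index, groups$alt_aa), ]
  rownames(groups) <- NULL
  groups
}

#' Functional-region map of the protein
#'
#' Named residue intervals of the 543-residue checkpoint kinase: the SQ/TQ
#' cluster domain (SCD), the forkhead-associated (FHA) domain in its
#' structural and alignment delimitations, the kinase domain, the activation
#' (T) loop, the C-terminal nuclear localization signal, and the terminal
#' disordered regions. Two presets for the disordered-region bounds are
#' shipped (`"default"`: N 1-69 / C 506-543; `"predicted"`: N 1-66 /
#' C 506-538, the disorder-prediction delimitation). `atp_pocket` is a residue
#' set (empty by default; supply your own annotation). `stop_boundary` is the
#' last codon at which a premature stop is treated as damaging when building
#' classifier training controls.
#'
#' @param preset `"default"` or `"predicted"` disorder bounds.
#' @param n_codons Protein length used for bound checking.
#' @param atp_pocket Optional integer vector of ATP-binding-pocket residues.
#' @return A list of class `region_map`: named intervals `c(start, end)`,
#'   a residue set `atp_pocket`, and scalar `stop_boundary`.
#' @export
region_map <- function(preset = c("default", "predicted"), n_codons = 543L,
                       atp_pocket = integer()) {
  preset <- match.arg(preset)
  dis <- if (preset == "default") list(n = c(1L, 69L), c = c(506L, 543L))
         else list(n = c(1L, 66L), c = c(506L, 538L))
  rm <- list(
    scd = c(19L, 69L),
    fha = c(92L, 205L),
    fha_alignment = c(113L, 175L),
    kinase = c(220L, 486L),
    activation_loop = c(368L, 394L),
    nls = c(515L, 523L),
    n_disorder = dis$n,
    c_disorder = pmin(dis$c, n_codons),
    atp_pocket = as.integer(atp_pocket),
    stop_boundary = 500L
  )
  for (nm in setdiff(names(rm), c("atp_pocket", "stop_boundary"))) {
    iv <- rm[[nm]]
    if (iv[1] > iv[2] || iv[1] < 1L || iv[2] > n_codons) {
      stop("region ", nm, " out of bounds for ", n_codons, " codons", call. = FALSE)
    }
  }
  structure(rm, n_codons = n_codons, class = "region_map")
}

#' Regions enclosing a residue
#'
#' @param codon_index Integer residue position(s), 1-based.
#' @param regions A [region_map()].
#' @return For a single position, a character vector of enclosing region
#'   names (possibly empty); for several positions, a list of such vectors.
#' @examples
#' annotate_regions(68, region_map())   # scd, n_disorder
#' annotate_regions(347, region_map())  # kinase
#' @export
annotate_regions <- function(codon_index, regions = region_map()) {
  stopifnot(inherits(regions, "region_map"))
  n_codons <- attr(regions, "n_codons")
  if (any(codon_index < 1L | codon_index > n_codons)) {
    stop("codon index out of range 1..", n_codons, call. = FALSE)
  }
  intervals <- regions[setdiff(names(regions), c("atp_pocket", "stop_boundary"))]
  one <- function(i) {
    hits <- names(intervals)[vapply(intervals, function(iv) i >= iv[1] && i <= iv[2],
                                    logical(1))]
    if (i %in% regions$atp_pocket) hits <- c(hits, "atp_pocket")
    hits
  }
  if (length(codon_index) == 1L) one(codon_index) else lapply(codon_index, one)
}

#' Write an SNV enumeration to TSV
#'
#' @param enum Data.frame from [enumerate_snvs()].
#' @param path Output path.
#' @param regions Optional [region_map()]; adds a `regions` column
#'   (comma-separated region names per codon).
#' @param header Optional character vector of `#`-prefixed header lines.
#' @export
write_enumeration <- function(enum, path, regions = NULL, header = NULL) {
  out <- enum
  if (!is.null(regions)) {
    per_codon <- vapply(seq_len(attr(regions, "n_codons")),
                        function(i) paste(annotate_regions(i, regions), collapse = ","),
                        character(1))
    out$regions <- per_codon[out$codon_index]
  }
  write_tsv_with_header(out, path, header)
  invisible(path)
}
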