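# Independent brute-force oracle for SNV enumeration and consequence
# annotation. Deliberately avoids the package's own code path: it mutates
# the full sequence string and translates with seqinr's codon table.

oracle_translate <- function(seq) {
  paste(seqinr::translate(strsplit(seq, "")[[1]]), collapse = "")
}

# all SNVs of an ORF by exhaustive substitution of the whole sequence
oracle_enumerate <- function(seq) {
  bases <- c("A", "C", "G", "T")
  L <- nchar(seq)
  ref_aa_full <- oracle_translate(seq)
  rows <- list()
  k <- 0L
  for (pos in seq_len(L)) {
    ref <- substr(seq, pos, pos)
    for (alt in setdiff(bases, ref)) {
      mutated <- seq
      substr(mutated, pos, pos) <- alt
      alt_aa_full <- oracle_translate(mutated)
      diff <- which(strsplit(ref_aa_full, "")[[1]] != strsplit(alt_aa_full, "")[[1]])
      codon <- (pos - 1L) %/% 3L + 1L
      if (length(diff) == 0L) {
        kind <- "synonymous"
        alt_aa <- substr(ref_aa_full, codon, codon)
      } else {
        stopifnot(length(diff) == 1L, diff == codon)
        alt_aa <- substr(alt_aa_full, codon, codon)
        kind <- if (alt_aa == "*") "stop_gain" else "missense"
      }
      k <- k + 1L
      rows[[k]] <- data.frame(cds_pos = pos, ref = ref, alt = alt,
                              codon_index = codon, alt_aa = alt_aa,
                              kind = kind, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# outcome-group census from the oracle enumeration
oracle_group_census <- function(oracle_enum) {
  key <- paste0(oracle_enum$codon_index, ":",
                ifelse(oracle_enum$kind == "synonymous", "=", oracle_enum$alt_aa))
  groups <- !duplicated(key)
  list(n_groups = sum(groups),
       kind_counts = table(oracle_enum$kind[groups]),
       max_members = max(table(key)))
}

# random stop-free ORF, generated independently of synthetic_orf()
random_sense_orf <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
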