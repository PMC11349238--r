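# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# full-scale default screen: the study conditions the simulator emulates
# (62,000 clones, 2 before / 4 after replicates, 2.5e6 read-equivalents)
default_screen <- function() {
  memo("default_screen", {
    orf <- synthetic_orf(543L, seed = 7, id = "synthetic_orf_543")
    cfg <- sim_config(seed = 20240815)
    scr <- simulate_screen(orf, cfg)
    scores <- score_screen(scr$counts, scr$enum, scr$before_ids, scr$after_ids)
    fit <- rcs_fit(scores)
    list(orf = orf, cfg = cfg, scr = scr, scores = scores, fit = fit)
  })
}

# small screen for cheap structural tests
small_screen <- function() {
  memo("small_screen", {
    orf <- synthetic_orf(60L, seed = 2)
    cfg <- sim_config(n_clones = 3000L, read_equivalents = 2e5,
                      selected_pool = 1500L, seed = 11)
    scr <- simulate_screen(orf, cfg)
    scores <- score_screen(scr$counts, scr$enum, scr$before_ids, scr$after_ids)
    fit <- rcs_fit(scores, boundary = 50L)
    list(orf = orf, cfg = cfg, scr = scr, scores = scores, fit = fit)
  })
}

# hand-built clone library: n1 clones {tolA}, n2 clones {tolA, damB},
# n3 empty clones, on a 2-codon ORF
toy_library <- function(n1, n2, n3, enum) {
  mis <- enum[enum$kind == "missense", ]
  tolA <- mis[1, ]
  damB <- mis[mis$cds_pos != tolA$cds_pos, ][1, ]
  v1 <- data.frame(clone = seq_len(n1), cds_pos = tolA$cds_pos, ref = tolA$ref,
                   alt = tolA$alt, outcome_id = tolA$outcome_id)
  v2a <- data.frame(clone = n1 + seq_len(n2), cds_pos = tolA$cds_pos,
                    ref = tolA$ref, alt = tolA$alt, outcome_id = tolA$outcome_id)
  v2b <- data.frame(clone = n1 + seq_len(n2), cds_pos = damB$cds_pos,
                    ref = damB$ref, alt = damB$alt, outcome_id = damB$outcome_id)
  structure(list(variants = rbind(v1, v2a, v2b), n_clones = n1 + n2 + n3,
                 orf_id = "toy", length = max(enum$cds_pos)),
            class = "clone_library")
}

write_temp_fasta <- function(seq, id = "toy") {
  path <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">", id), seq), path)
  path
}
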