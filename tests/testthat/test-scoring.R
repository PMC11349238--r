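make_counts <- function(count, coverage, sample_id = "LibA",
                        cds_pos = 1L, ref = "A", alt = "C") {
  data.frame(cds_pos = cds_pos, ref = ref, alt = alt, count = count,
             coverage = coverage, sample_id = sample_id,
             stringsAsFactors = FALSE)
}

test_that("frequency is count over coverage, with detection tracked", {
  tab <- make_counts(count = c(5, 0, 1000), coverage = 1000,
                     cds_pos = 1:3, ref = "A", alt = "C")
  fr <- compute_frequencies(tab, pseudocount = 0)
  expect_equal(fr$frequency, c(0.005, 0, 1))
  expect_equal(fr$detected, c(TRUE, FALSE, TRUE))

  frp <- compute_frequencies(tab, pseudocount = 0.5)
  expect_equal(frp$frequency, (c(5, 0, 1000) + 0.5) / 1000)

  bad <- make_counts(count = 3, coverage = 0)
  expect_error(compute_frequencies(bad), "zero coverage")
})

test_that("replicate averaging is the unweighted mean", {
  expect_equal(as.numeric(average_replicates(c(0.004, 0.002))), 0.003)
  expect_equal(as.numeric(average_replicates(0.7)), 0.7)
  expect_equal(as.numeric(average_replicates(rep(0.25, 4))), 0.25)
  expect_equal(attr(average_replicates(c(1, 2, 3)), "n_replicates"), 3L)
  m <- matrix(c(0.1, 0.3, 0.2, 0.4), nrow = 2)
  expect_equal(as.numeric(average_replicates(m)), c(0.15, 0.35))
  expect_error(average_replicates(numeric(0)), "empty replicate")
})

test_that("the complementation score is the log2 frequency ratio", {
  expect_equal(compute_rcs(0.004, 0.004), 0)
  expect_equal(compute_rcs(0.004, 0.001), -2)
  expect_equal(compute_rcs(0.001, 0.008), 3)
  expect_true(is.na(compute_rcs(0, 0.01)))
  # zero-after with pseudocount c and coverage D: rcs = log2((c/D)/f_before)
  D <- 1e4; c0 <- 0.5; f_before <- 0.02
  f_after <- (0 + c0) / D
  expect_equal(compute_rcs(f_before, f_after), log2((c0 / D) / f_before))
})

test_that("score monotonicity: increasing in f_after, decreasing in f_before", {
  set.seed(7)
  f <- runif(200, 1e-6, 1)
  delta <- runif(200, 1e-6, 0.5)
  expect_true(all(compute_rcs(f, f + delta) > compute_rcs(f, f)))
  expect_true(all(compute_rcs(f + delta, f) < compute_rcs(f, f)))
})

test_that("library-absent SNVs are flagged unscorable, never dropped", {
  sm <- small_screen()
  enum <- sm$scr$enum
  counts <- sm$scr$counts
  # erase one SNV from every sample to emulate a library-absent variant
  victim <- enum[17, ]
  hit <- counts$cds_pos == victim$cds_pos & counts$alt == victim$alt
  counts$count[hit] <- 0
  sc <- score_snvs(counts, enum, sm$scr$before_ids, sm$scr$after_ids)
  expect_equal(nrow(sc), nrow(enum))  # every possible SNV has a record
  row <- sc[sc$cds_pos == victim$cds_pos & sc$alt == victim$alt, ]
  expect_true(row$missing_in_library)
  expect_false(row$scorable)
  expect_true(is.na(row$rcs))
})

test_that("scale invariance: rescaling counts and coverage leaves scores unchanged", {
  sm <- small_screen()
  counts <- sm$scr$counts
  # exact with pseudocount disabled
  sc1 <- score_snvs(counts, sm$scr$enum, sm$scr$before_ids, sm$scr$after_ids,
                    pseudocount = 0)
  counts10 <- counts
  counts10$count <- counts10$count * 10
  counts10$coverage <- counts10$coverage * 10
  sc10 <- score_snvs(counts10, sm$scr$enum, sm$scr$before_ids, sm$scr$after_ids,
                     pseudocount = 0)
  expect_equal(sc1$rcs, sc10$rcs)
  # with the pseudocount the perturbation vanishes as counts grow
  scp1 <- score_snvs(counts, sm$scr$enum, sm$scr$before_ids, sm$scr$after_ids)
  scp100 <- local({
    c100 <- counts
    c100$count <- c100$count * 100
    c100$coverage <- c100$coverage * 100
    score_snvs(c100, sm$scr$enum, sm$scr$before_ids, sm$scr$after_ids)
  })
  keep <- scp1$scorable & sc1$scorable & is.finite(sc1$rcs)
  expect_lt(max(abs(scp1$rcs[keep] - sc1$rcs[keep])), 0.5)
  expect_lt(max(abs(scp100$rcs[keep] - sc1$rcs[keep])),
            max(abs(scp1$rcs[keep] - sc1$rcs[keep])) + 1e-9)
})

test_that("outcome aggregation averages frequencies first, then takes one log2", {
  sm <- small_screen()
  snv <- sm$scores$snv
  groups <- group_outcomes(sm$scr$enum)
  out <- aggregate_outcomes(snv, groups)

  # singleton groups reproduce the member record exactly
  singles <- groups$outcome_id[groups$n_members == 1L]
  s_out <- out[match(singles, out$outcome_id), ]
  s_snv <- snv[match(singles, snv$outcome_id), ]
  keep <- s_out$scorable
  expect_equal(s_out$rcs[keep], s_snv$rcs[keep])
  expect_equal(s_out$f_before[keep], s_snv$f_before[keep])

  # multi-member groups: recomputed from mean member frequencies
  multi <- groups$outcome_id[groups$n_members > 1L][1:5]
  for (g in multi) {
    members <- snv[snv$outcome_id == g & snv$scorable, ]
    expect_equal(out$rcs[out$outcome_id == g],
                 log2(mean(members$f_after) / mean(members$f_before)))
  }

  # two members with identical frequencies keep the member score
  fake <- snv[snv$outcome_id == multi[1], ]
  fake$f_before <- 0.004; fake$f_after <- 0.001
  fake$scorable <- TRUE
  g1 <- groups[groups$outcome_id == multi[1], ]
  agg <- aggregate_outcomes(fake, g1)
  expect_equal(agg$rcs, -2)

  # aggregation-consistency: outcome score between member extremes
  for (g in multi) {
    members <- snv[snv$outcome_id == g & snv$scorable, ]
    if (nrow(members) < 2) next
    expect_gte(out$rcs[out$outcome_id == g], min(members$rcs) - 1e-9)
    expect_lte(out$rcs[out$outcome_id == g], max(members$rcs) + 1e-9)
  }

  # the alternative mean-of-member-scores mode
  out_rcs <- aggregate_outcomes(snv, groups, member_stat = "rcs")
  g <- multi[1]
  members <- snv[snv$outcome_id == g & snv$scorable, ]
  expect_equal(out_rcs$rcs[out_rcs$outcome_id == g], mean(members$rcs))
})

test_that("damaging outcomes score stochastically lower than tolerated ones", {
  sm <- small_screen()
  merged <- merge(sm$scores$outcome, sm$scr$truth[, c("outcome_id", "label")],
                  by = "outcome_id")
  merged <- merged[merged$scorable, ]
  wt <- wilcox.test(rcs ~ label, data = merged, alternative = "less")
  expect_lt(wt$p.value, 1e-10)
})

test_that("residue and region summaries count calls per codon", {
  sm <- small_screen()
  fit <- sm$fit
  summ <- residue_summaries(sm$scores$outcome, fit$calls)
  res <- summ$residue
  expect_equal(nrow(res), sm$orf$n_codons)
  expect_equal(res$n_tolerated + res$n_damaging, res$n_missense)
  expect_true(all(res$fraction_damaging >= 0 & res$fraction_damaging <= 1,
                  na.rm = TRUE))
  # cross-check one codon by hand
  i <- res$codon_index[which(res$n_missense > 0)[1]]
  calls_i <- fit$calls[fit$calls$codon_index == i, ]
  expect_equal(res$n_damaging[res$codon_index == i],
               sum(calls_i$label == "damaging"))

  # an all-tolerated residue has damaging fraction zero
  all_tol <- res$codon_index[res$n_missense > 0 & res$n_damaging == 0][1]
  expect_equal(res$fraction_damaging[res$codon_index == all_tol], 0)

  # region aggregation pools missense calls over the interval
  rm60 <- structure(list(front = c(1L, 30L), back = c(31L, 60L),
                         atp_pocket = integer(), stop_boundary = 50L),
                    n_codons = 60L, class = "region_map")
  summ2 <- residue_summaries(sm$scores$outcome, fit$calls, rm60)
  expect_equal(sum(summ2$region$n_missense), sum(res$n_missense))
  front <- summ2$region[summ2$region$region == "front", ]
  expect_equal(front$n_damaging, sum(res$n_damaging[res$codon_index <= 30]))
})
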