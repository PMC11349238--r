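test_that("spectrum model validates and encodes the EP-PCR bias ordinally", {
  sp <- spectrum_model()
  expect_equal(sum(sp), 1)
  expect_equal(names(which.max(sp)), "G>A")
  expect_setequal(names(sp)[sp == min(sp)], c("T>G", "G>C"))
  expect_error(spectrum_model(c(`G>A` = 1)), "12 substitution classes")
  w <- setNames(rep(1, 12), names(sp))
  w["A>C"] <- 0
  expect_error(spectrum_model(w), "weight > 0")
})

test_that("sim_config enforces rates, replicate counts and a mandatory seed", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(mu = 2, seed = 1))
  expect_error(sim_config(n_before = 0, seed = 1))
  cfg <- sim_config(seed = 5)
  expect_equal(cfg$mu, 0.86e-3)
  expect_equal(cfg$epsilon, 0.097e-3)
  expect_equal(cfg$n_clones, 62000L)
  expect_equal(c(cfg$n_before, cfg$n_after), c(2L, 4L))
  expect_equal(cfg$read_equivalents, 2.5e6)
})

test_that("clone library burden is Poisson at the configured rate", {
  orf <- synthetic_orf(543L, seed = 3)  # 1629 nt, the screen's ORF length
  cfg <- sim_config(n_clones = 10000L, seed = 9)
  lib <- simulate_clone_library(orf, cfg)
  per_clone <- tabulate(lib$variants$clone, nbins = cfg$n_clones)
  m <- mean(per_clone)
  expected <- cfg$mu * orf$length  # 1.40 variants per clone
  se <- sd(per_clone) / sqrt(cfg$n_clones)
  expect_lt(abs(m - expected), 3 * se)
  # distinct positions within each clone
  expect_false(anyDuplicated(paste(lib$variants$clone, lib$variants$cds_pos)) > 0)
})

test_that("rate zero produces an empty library and excessive burden errors", {
  orf <- synthetic_orf(20L, seed = 3)
  lib0 <- simulate_clone_library(orf, sim_config(mu = 0, n_clones = 50L, seed = 2))
  expect_equal(nrow(lib0$variants), 0L)
  expect_error(
    simulate_clone_library(orf, sim_config(mu = 0.9, n_clones = 10L, seed = 2)),
    "too large")
})

test_that("simulated substitutions recover the spectrum within sampling error", {
  orf <- synthetic_orf(200L, seed = 4)
  cfg <- sim_config(mu = 5 / 1000, n_clones = 40000L, seed = 13)
  lib <- simulate_clone_library(orf, cfg)
  v <- lib$variants
  expect_gt(nrow(v), 1e5)
  cls <- paste0(v$ref, ">", v$alt)
  expect_equal(names(sort(table(cls), decreasing = TRUE))[1], "G>A")

  # per-class frequency conditioned on ref base matches the spectrum weights
  sp <- spectrum_model()
  for (b in c("A", "C", "G", "T")) {
    sub <- cls[v$ref == b]
    w <- sp[paste0(b, ">", setdiff(c("A", "C", "G", "T"), b))]
    w <- w / sum(w)
    obs <- table(factor(sub, levels = names(w))) / length(sub)
    se <- sqrt(w * (1 - w) / length(sub))
    expect_true(all(abs(obs - w) < 3 * se + 1e-12))
  }
})

test_that("ground-truth assignment follows the control structure", {
  enum <- enumerate_snvs(synthetic_orf(543L, seed = 5))
  groups <- group_outcomes(enum)
  cfg <- sim_config(seed = 21)
  truth <- assign_effects(groups, cfg)
  expect_equal(nrow(truth), nrow(groups))

  stops <- merge(truth, groups[, c("outcome_id", "kind", "codon_index")],
                 by = "outcome_id")
  early_stops <- truth$label[truth$kind == "stop_gain" & truth$codon_index <= 500]
  late_stops <- truth$label[truth$kind == "stop_gain" & truth$codon_index > 500]
  expect_true(all(early_stops == "damaging"))
  expect_true(all(late_stops == "tolerated"))
  expect_true(all(truth$label[truth$kind == "synonymous"] == "tolerated"))

  # missense damaging fraction close to the configured probability
  mis <- truth$label[truth$kind == "missense"] == "damaging"
  p <- cfg$damaging_fraction
  expect_lt(abs(mean(mis) - p), 3 * sqrt(p * (1 - p) / length(mis)))

  # degenerate fractions
  truth0 <- assign_effects(groups, sim_config(damaging_fraction = 0, seed = 21))
  expect_true(all(truth0$label[truth0$kind == "missense"] == "tolerated"))
})

test_that("hard selection removes damaging clones; survivors are a resample", {
  enum <- enumerate_snvs(orf_sequence("ATGGCTGAATTG"))
  lib <- toy_library(n1 = 200, n2 = 100, n3 = 700, enum)
  groups <- group_outcomes(enum)
  cfg <- sim_config(damaging_fraction = 0, selected_pool = 5000L, seed = 3)
  truth <- assign_effects(groups, cfg)

  # all tolerated: every input clone may appear among survivors
  sel <- simulate_selection(lib, truth, cfg)
  expect_equal(sel$n_clones, 5000L)
  a_id <- lib$variants$outcome_id[1]
  freq_in <- (200 + 100) / 1000
  freq_out <- length(unique(sel$variants$clone[sel$variants$outcome_id == a_id])) /
    sel$n_clones
  expect_lt(abs(freq_out - freq_in), 0.05)

  # make B damaging: clones carrying it must vanish
  truth$label[truth$outcome_id == lib$variants$outcome_id[nrow(lib$variants)]] <- "damaging"
  truth$fitness[truth$label == "damaging"] <- 0
  sel2 <- simulate_selection(lib, truth, cfg)
  b_id <- lib$variants$outcome_id[nrow(lib$variants)]
  expect_equal(sum(sel2$variants$outcome_id == b_id), 0L)
})

test_that("hitchhiking matches the analytic marginal survival expectation", {
  # clones: n1 {tolA}, n2 {tolA, damB}, n3 {}; hard selection kills type 2,
  # so E[post frequency of A] = n1 / (n1 + n3) while pre = (n1+n2)/N
  enum <- enumerate_snvs(orf_sequence("ATGGCTGAATTG"))
  groups <- group_outcomes(enum)
  n1 <- 300; n2 <- 200; n3 <- 500
  lib <- toy_library(n1, n2, n3, enum)
  cfg <- sim_config(damaging_fraction = 0, selected_pool = 50000L, seed = 17)
  truth <- assign_effects(groups, cfg)
  b_id <- lib$variants$outcome_id[nrow(lib$variants)]
  truth$label[truth$outcome_id == b_id] <- "damaging"

  sel <- simulate_selection(lib, truth, cfg)
  a_id <- lib$variants$outcome_id[1]
  carriers <- unique(sel$variants$clone[sel$variants$outcome_id == a_id])
  post <- length(carriers) / sel$n_clones
  expected <- n1 / (n1 + n3)
  se <- sqrt(expected * (1 - expected) / cfg$selected_pool)
  expect_lt(abs(post - expected), 4 * se)
  expect_lt(expected, (n1 + n2) / (n1 + n2 + n3))  # depletion by hitchhiking
})

test_that("soft selection with zero damaging fitness reproduces hard selection", {
  enum <- enumerate_snvs(orf_sequence("ATGGCTGAATTG"))
  groups <- group_outcomes(enum)
  lib <- toy_library(100, 100, 100, enum)
  truth <- assign_effects(groups, sim_config(damaging_fraction = 0, seed = 5))
  b_id <- lib$variants$outcome_id[nrow(lib$variants)]
  truth$label[truth$outcome_id == b_id] <- "damaging"
  truth$fitness[truth$outcome_id == b_id] <- 0
  cfg_soft <- sim_config(selection_model = "soft", damaging_fraction = 0,
                         selected_pool = 2000L, seed = 8)
  sel <- simulate_selection(lib, truth, cfg_soft)
  expect_equal(sum(sel$variants$outcome_id == b_id), 0L)

  # all-damaging pool is reported, not silently retried
  truth_all <- truth
  truth_all$label[] <- "damaging"
  lib1 <- toy_library(5, 5, 0, enum)
  expect_error(simulate_selection(lib1, truth_all,
                                  sim_config(damaging_fraction = 0, seed = 2)),
               "eliminated")
})

test_that("count tables conserve coverage and respect count <= coverage", {
  orf <- synthetic_orf(30L, seed = 6)
  enum <- enumerate_snvs(orf)
  cfg <- sim_config(n_clones = 500L, read_equivalents = 5e4,
                    selected_pool = 300L, seed = 19)
  lib <- simulate_clone_library(orf, cfg, enum = enum)
  tab <- tabulate_counts(lib, cfg, "LibA", enum = enum)
  expect_equal(nrow(tab), 3L * orf$length)
  expect_true(all(tab$count <= tab$coverage))
  expect_true(all(tab$coverage == 5e4))

  # epsilon = 0, wild-type-only pool: all counts zero
  wt <- structure(list(variants = lib$variants[0, ], n_clones = 100L,
                       orf_id = orf$id, length = orf$length),
                  class = "clone_library")
  cfg0 <- sim_config(epsilon = 0, n_clones = 100L, read_equivalents = 1e4, seed = 19)
  tab0 <- tabulate_counts(wt, cfg0, "LibA", enum = enum)
  expect_true(all(tab0$count == 0))
  expect_true(all(tab0$coverage == 1e4))
})

test_that("background error calls accumulate at the configured rate", {
  orf <- synthetic_orf(543L, seed = 6)  # 1629 positions
  enum <- enumerate_snvs(orf)
  wt <- structure(list(variants = enum[0, c("cds_pos", "ref", "alt", "outcome_id")],
                       n_clones = 100L, orf_id = orf$id, length = orf$length),
                  class = "clone_library")
  wt$variants$clone <- integer(0)
  cfg <- sim_config(n_clones = 100L, read_equivalents = 1e6, seed = 23)
  tab <- tabulate_counts(wt, cfg, "LibA", enum = enum)
  total_errors <- sum(tab$count)
  lambda <- cfg$epsilon * 1e6 * orf$length  # expected error calls overall
  expect_lt(abs(total_errors - lambda), 3 * sqrt(lambda))
})

test_that("count tables are bit-identical under a fixed seed", {
  sm <- small_screen()
  cfg <- sm$cfg
  enum <- sm$scr$enum
  lib <- simulate_clone_library(sm$orf, cfg, enum = enum)
  t1 <- tabulate_counts(lib, cfg, "LibA", enum = enum)
  t2 <- tabulate_counts(lib, cfg, "LibA", enum = enum)
  expect_identical(t1, t2)
  # replicates use distinct substreams
  t3 <- tabulate_counts(lib, cfg, "LibB", enum = enum)
  expect_false(identical(t1$count, t3$count))
  # the full generator is reproducible end to end
  scr2 <- simulate_screen(sm$orf, cfg)
  expect_identical(sm$scr$counts, scr2$counts)
})
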