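test_that("fold change folds to >= 1 with direction, guarded by pseudocount", {
  fc <- fold_change(30, 15, 0.5)
  expect_equal(fc$fc, 30.5 / 15.5)
  expect_equal(fc$direction, "hyper")

  expect_equal(fold_change(10, 10, 0.5)$fc, 1)
  expect_equal(fold_change(10, 10, 0.5)$direction, "tie")
  expect_equal(fold_change(0, 0, 0.5)$fc, 1)      # pseudocount guards 0/0

  # symmetric under group swap: fc preserved, direction flips
  a <- fold_change(24, 6); b <- fold_change(6, 24)
  expect_equal(a$fc, b$fc)
  expect_equal(c(a$direction, b$direction), c("hyper", "hypo"))
  expect_error(fold_change(-1, 2), ">= 0")
})

test_that("exact permutation test enumerates all label reassignments", {
  cfg <- dmr_config(test = "permutation")
  # identical groups: every reassignment ties or beats the observed stat
  expect_equal(dmr_test(c(5, 7, 9, 11), c(5, 7, 9, 11), cfg), 1.0)
  # fully separated 3 vs 3: only the true split and its mirror are extreme
  expect_equal(dmr_test(c(1, 2, 3), c(101, 102, 103), cfg), 2 / 20)

  # independent enumeration oracle on random 3 + 3 scores
  set.seed(5)
  for (k in 1:5) {
    a <- runif(3, 0, 50); b <- runif(3, 0, 50)
    pooled <- log2(c(a, b) + 0.5)
    obs <- abs(mean(pooled[1:3]) - mean(pooled[4:6]))
    splits <- utils::combn(6, 3)
    stats <- apply(splits, 2, function(ix) {
      abs(mean(pooled[ix]) - mean(pooled[-ix]))
    })
    expect_equal(dmr_test(a, b, cfg), mean(stats >= obs - 1e-12))
  }
})

test_that("Monte-Carlo permutation kicks in beyond 12,870 arrangements and is seeded", {
  cfg <- dmr_config(test = "permutation", n_perm = 2000)
  set.seed(1)
  a <- rnorm(9, 30, 3); b <- rnorm(9, 10, 3)   # choose(18, 9) >> 12,870
  p1 <- dmr_test(a, b, cfg, seed = 42)
  p2 <- dmr_test(a, b, cfg, seed = 42)
  expect_identical(p1, p2)
  expect_lt(p1, 0.01)
  # +1 correction keeps Monte-Carlo p strictly positive
  expect_gte(p1, 1 / 2001)
})

test_that("welch test rejects degenerate one-sample groups, handles zero variance", {
  expect_error(dmr_test(5, c(1, 2, 3)), "permutation")
  expect_equal(dmr_test(c(4, 4, 4), c(4, 4, 4)), 1)
  expect_equal(dmr_test(c(8, 8, 8), c(2, 2, 2)), 0)
})

test_that("welch-on-log type-I error is near nominal on null scores", {
  # scores built so that log2(score + pseudocount) is exactly normal,
  # making the t-test calibration exact up to simulation error
  set.seed(77)
  reps <- 1000
  p <- replicate(reps, dmr_test(2^rnorm(4, 5, 0.5) - 0.5,
                                2^rnorm(4, 5, 0.5) - 0.5))
  # Welch at n = 4 + 4 is mildly conservative (true rate ~0.037)
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.07)
})

test_that("call_dmrs flags planted promoters and respects group symmetry", {
  cfg <- sim_config(genome_length = 100000, n_genes = 20, seed = 31,
                    planted_dmr_fraction = 0.2, dmr_effect = 3)
  sim <- simulate_genome(cfg)
  prom <- promoter_intervals(sim$genes)
  S4Vectors::mcols(prom)$region_id <- S4Vectors::mcols(prom)$gene_id
  reads <- c(simulate_medip_reads(sim, "sedentary"),
             simulate_medip_reads(sim, "trained"))
  groups <- setNames(ifelse(grepl("^sed", names(reads)),
                            "sedentary", "trained"), names(reads))
  sm <- score_matrix(reads, prom, groups = groups)
  dmrs <- call_dmrs(sm, groups)
  expect_equal(nrow(dmrs), 20)
  expect_true(!is.unsorted(dmrs$p_value))

  ev <- evaluate_dmrs(dmrs, sim$truth)
  expect_gte(ev$sensitivity, 0.75)
  if (ev$true_positives > 0) expect_equal(ev$direction_accuracy, 1)

  # swapping condition labels flips directions, preserves p-values
  groups_sw <- setNames(ifelse(groups == "sedentary", "trained", "sedentary"),
                        names(groups))
  dmrs_sw <- call_dmrs(sm, groups_sw)
  m <- merge(dmrs, dmrs_sw, by = "gene_id")
  expect_equal(m$p_value.x, m$p_value.y)
  expect_equal(m$fc.x, m$fc.y)
  flip <- c(hyper = "hypo", hypo = "hyper", tie = "tie")
  expect_equal(unname(flip[m$direction.x]), m$direction.y)

  # an unreachable fold-change threshold passes nothing
  none <- call_dmrs(sm, groups, dmr_config(fc_threshold = 1e9))
  expect_equal(sum(none$passes_filters), 0)

  # cascade nesting: candidates are a subset of passing calls
  cand <- filter_candidates(dmrs)
  expect_lte(nrow(cand), sum(dmrs$passes_filters))
  expect_true(all(cand$gene_id %in% dmrs$gene_id[dmrs$passes_filters]))
})

test_that("score filter keeps records whose larger group mean exceeds the cut", {
  d <- data.frame(gene_id = c("a", "b", "c"),
                  chrom = "chrS", start = 0, end = 900, strand = "+",
                  mean_sedentary = c(4, 4, 30), mean_trained = c(6, 12, 60),
                  fc = c(1.4, 2.6, 1.97), log2fc = log2(c(1.4, 2.6, 1.97)),
                  direction = "hyper", p_value = 0.01, q_value = 0.03,
                  passes_filters = TRUE)
  kept <- filter_candidates(d, dmr_config(min_medip_score = 10))
  expect_setequal(kept$gene_id, c("b", "c"))   # (4,6) dropped, (4,12) kept
  # min score 0 is the identity filter on passing records
  expect_equal(nrow(filter_candidates(d, dmr_config(min_medip_score = 0))), 3)
})

test_that("call_dmrs demands complete group labels", {
  sm <- data.frame(region_id = "r", chrom = "chrS", start = 0, end = 900,
                   strand = "+", sample = c("s1", "s2"), n_reads = 1,
                   score = c(1, 2), status = "unmethylated")
  class(sm) <- c("medip_scores", "data.frame")
  expect_error(call_dmrs(sm, c(s1 = "sedentary")), "missing")
})
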