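test_that("percent methylation is 100 * C / (C + T)", {
  expect_equal(percent_methylation(30, 70), 30)
  expect_equal(percent_methylation(0, 50), 0)
  expect_equal(percent_methylation(50, 0), 100)
  expect_equal(percent_methylation(c(1, 3), c(3, 1)), c(25, 75))
  expect_error(percent_methylation(0, 0), "coverage")
  expect_error(percent_methylation(-1, 5), ">= 0")
})

test_that("conversion QC pools control cytosines against the cut-off", {
  r <- conversion_qc(data.frame(converted = 98, unconverted = 2))
  expect_true(r$pass)
  expect_equal(r$efficiency, 0.98)
  r2 <- conversion_qc(data.frame(converted = 90, unconverted = 10))
  expect_false(r2$pass)
  r3 <- conversion_qc(data.frame(converted = c(50, 50),
                                 unconverted = c(0, 0)))
  expect_true(r3$pass)
  expect_equal(r3$efficiency, 1)
})

# hand-worked balanced 2 (conditions) x 2 (sites) x 2 (replicates) fixture
pyro_fixture <- data.frame(
  condition = rep(c("sedentary", "trained"), each = 4),
  site = rep(rep(c("cpg1", "cpg2"), each = 2), 2),
  percent = c(60, 64, 50, 54, 40, 44, 46, 50))

test_that("two-way ANOVA reproduces hand-computed sums of squares", {
  an <- two_way_anova(pyro_fixture)
  want <- oracle_anova_ss(pyro_fixture$percent, pyro_fixture$condition,
                          pyro_fixture$site)
  expect_equal(an$ss[an$term == "condition"], unname(want["a"]))
  expect_equal(an$ss[an$term == "site"], unname(want["b"]))
  expect_equal(an$ss[an$term == "condition:site"], unname(want["ab"]))
  expect_equal(an$ss[an$term == "residual"], unname(want["resid"]))
  expect_equal(attr(an, "ss_total"), unname(want["total"]))
  # frozen values computed from the cell means of the fixture
  expect_equal(an$ss[an$term == "condition"], 288)
  expect_equal(an$ss[an$term == "site"], 8)
  expect_equal(an$ss[an$term == "condition:site"], 128)
  expect_equal(an$ss[an$term == "residual"], 32)
  expect_equal(an$df, c(1, 1, 1, 4))
  expect_equal(an$f[1], (288 / 1) / (32 / 4))
})

test_that("ANOVA decomposition is exact on random balanced designs", {
  set.seed(30)
  for (k in 1:5) {
    d <- expand.grid(condition = c("sedentary", "trained"),
                     site = paste0("cpg", 1:4), rep = 1:3)
    d$percent <- runif(nrow(d), 0, 100)
    an <- two_way_anova(d[, c("condition", "site", "percent")])
    want <- oracle_anova_ss(d$percent, d$condition, d$site)
    expect_equal(attr(an, "ss_total"), unname(want["total"]),
                 tolerance = 1e-9)
    expect_equal(sum(an$ss), unname(want["total"]), tolerance = 1e-9)
  }
})

test_that("ANOVA rejects unbalanced input and degenerates gracefully", {
  unb <- pyro_fixture[-1, ]
  expect_error(two_way_anova(unb), "unbalanced")
  const <- pyro_fixture; const$percent <- 50
  an <- two_way_anova(const)
  expect_true(all(an$p[1:3] == 1))

  # strong planted condition effect is detected
  set.seed(31)
  d <- expand.grid(condition = c("sedentary", "trained"),
                   site = paste0("cpg", 1:3), rep = 1:4)
  d$percent <- 50 + ifelse(d$condition == "trained", 30, 0) + rnorm(nrow(d), 0, 2)
  an2 <- two_way_anova(d[, c("condition", "site", "percent")])
  expect_lt(an2$p[an2$term == "condition"], 0.001)
})

test_that("per-CpG tests flag only the shifted site", {
  set.seed(32)
  mk <- function(delta_site) {
    d <- expand.grid(condition = c("sedentary", "trained"),
                     site = paste0("cpg", 1:5), rep = 1:6)
    d$percent <- 60 + rnorm(nrow(d), 0, 3)
    sel <- d$site == delta_site & d$condition == "trained"
    d$percent[sel] <- d$percent[sel] - 20
    d[, c("condition", "site", "percent")]
  }
  hits <- replicate(20, {
    res <- per_cpg_tests(mk("cpg3"))
    c(flagged3 = res$p_value[res$site == "cpg3"] < 0.05,
      others = sum(res$p_value[res$site != "cpg3"] < 0.05))
  })
  expect_gte(mean(hits["flagged3", ]), 0.95)
  expect_lt(mean(hits["others", ]), 1)      # few false per-site stars

  # identical groups give p = 1; single replicates are refused
  d <- data.frame(condition = rep(c("sedentary", "trained"), each = 2),
                  site = "cpg1", percent = c(50, 50, 50, 50))
  expect_equal(per_cpg_tests(d)$p_value, 1)
  d1 <- data.frame(condition = c("sedentary", "trained"), site = "cpg1",
                   percent = c(50, 60))
  expect_error(per_cpg_tests(d1), "replicates")

  # bonferroni inflates p by the number of sites
  d5 <- mk("cpg3")
  raw <- per_cpg_tests(d5)
  adj <- per_cpg_tests(d5, adjust = "bonferroni")
  expect_equal(adj$p_value, pmin(1, raw$p_value * 5))
})

test_that("percent methylation of simulated counts recovers planted levels", {
  cfg <- sim_config(genome_length = 50000, n_genes = 10, seed = 41,
                    pyro_depth = 10000)
  sim <- simulate_genome(cfg)
  gid <- sim$truth$gene_id[3]
  i <- match(gid, S4Vectors::mcols(sim$methylome)$region_id)
  for (cond in c("sedentary", "trained")) {
    lev <- S4Vectors::mcols(sim$methylome)[[paste0("level_", cond)]][i]
    pc <- simulate_pyro_counts(sim, gid, cond)
    est <- mean(percent_methylation(pc$sites$nC, pc$sites$nT))
    expect_lt(abs(est - 100 * lev), 1)
  }
})

test_that("pyro summary reports per-condition per-site mean and SEM", {
  s <- pyro_summary(pyro_fixture)
  expect_equal(nrow(s), 4)
  expect_equal(s$mean[s$condition == "sedentary" & s$site == "cpg1"], 62)
  expect_equal(s$sem[s$condition == "sedentary" & s$site == "cpg1"],
               sd(c(60, 64)) / sqrt(2))
})
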