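test_that("simulate_genome echoes the configuration and is deterministic", {
  cfg <- sim_config(genome_length = 50000, n_genes = 10, seed = 7,
                    island_density = 4)
  sim <- simulate_genome(cfg)
  expect_equal(Biostrings::width(sim$genome), 50000)
  expect_length(sim$genes, 10)
  expect_setequal(as.character(BiocGenerics::strand(sim$genes)), c("+", "-"))
  expect_equal(sum(sim$truth$is_planted_dmr),
               round(cfg$planted_dmr_fraction * cfg$n_genes))

  sim2 <- simulate_genome(cfg)
  expect_identical(as.character(sim$genome), as.character(sim2$genome))
  expect_identical(sim$truth, sim2$truth)
  expect_equal(sim$methylome, sim2$methylome)
})

test_that("island_density = 0 plants no islands; genes never overlap", {
  sim <- simulate_genome(sim_config(genome_length = 50000, n_genes = 10,
                                    island_density = 0, seed = 2))
  expect_length(sim$islands, 0)
  ov <- GenomicRanges::findOverlaps(sim$genes, sim$genes,
                                    ignore.strand = TRUE)
  expect_equal(length(ov), length(sim$genes))  # only self-hits
})

test_that("planted islands satisfy the composition criteria by construction", {
  sim <- simulate_genome(sim_config(genome_length = 80000, n_genes = 16,
                                    island_density = 10, seed = 5))
  expect_gt(length(sim$islands), 0)
  seqs <- Biostrings::extractAt(sim$genome[[1]],
                                GenomicRanges::ranges(sim$islands))
  for (i in seq_along(seqs)) {
    s <- as.character(seqs[[i]])
    expect_gte(nchar(s), 200)
    expect_gte(gc_content(s), 0.5)
    expect_gte(cpg_obs_exp(s), 0.6)
  }
})

test_that("a genome too short for the requested genes raises a sizing error", {
  expect_error(simulate_genome(sim_config(genome_length = 20000,
                                          n_genes = 50)),
               "too short to host")
})

test_that("methylome regions are disjoint within each partition and levels are valid", {
  sim <- simulate_genome(sim_config(genome_length = 60000, n_genes = 12,
                                    seed = 9))
  m <- sim$methylome
  lv <- S4Vectors::mcols(m)
  expect_true(all(lv$level_sedentary >= 0 & lv$level_sedentary <= 1))
  expect_true(all(lv$level_trained >= 0 & lv$level_trained <= 1))
  for (cl in unique(lv$region_class)) {
    sub <- m[lv$region_class == cl]
    ov <- GenomicRanges::findOverlaps(sub, sub, ignore.strand = TRUE)
    expect_equal(length(ov), length(sub))
  }
  planted <- sim$truth$gene_id[sim$truth$is_planted_dmr]
  pl <- m[lv$region_class == "promoter" &
            S4Vectors::mcols(m)$gene_id %in% planted]
  lfc <- log2(S4Vectors::mcols(pl)$level_trained /
                S4Vectors::mcols(pl)$level_sedentary)
  expect_true(all(abs(lfc) > 0))
})

test_that("read placement follows methylated-CpG mass (4:1 at levels 0.8 vs 0.2)", {
  # minimal hand-built simulation: two equal-CpG regions, no background
  genome <- Biostrings::DNAStringSet(c(chrS = strrep("A", 4000)))
  meth <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(c(1, 2001), c(1000, 3000)),
    seqinfo = GenomeInfoDb::Seqinfo("chrS", 4000))
  S4Vectors::mcols(meth) <- S4Vectors::DataFrame(
    region_id = c("r1", "r2"), region_class = "promoter",
    gene_id = c("r1", "r2"), level_sedentary = c(0.8, 0.2),
    level_trained = c(0.8, 0.2), cpg_count = c(50L, 50L))
  cfg <- sim_config(genome_length = 50000, n_genes = 10, mean_depth = 10000,
                    background_rate = 0, n_samples_per_group = 1, seed = 11)
  sim <- structure(list(genome = genome, methylome = meth, config = cfg),
                   class = "medip_simulation")
  reads <- simulate_medip_reads(sim, "sedentary")[[1]]
  st <- BiocGenerics::start(reads)
  n1 <- sum(st >= 1 & st <= 1000); n2 <- sum(st >= 2001 & st <= 3000)
  # exact multinomial expectation p1 = 0.8; 3 binomial SEs at n = 10,000
  p1 <- n1 / (n1 + n2)
  expect_lt(abs(p1 - 0.8), 3 * sqrt(0.8 * 0.2 / 10000) + 0.005)

  # conservation: every emitted read is signal or background
  expect_equal(length(reads),
               attr(reads, "n_signal") + attr(reads, "n_background"))
})

test_that("all-zero methylome with zero background yields zero reads", {
  genome <- Biostrings::DNAStringSet(c(chrS = strrep("A", 2000)))
  meth <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(1, 1000),
    seqinfo = GenomeInfoDb::Seqinfo("chrS", 2000))
  S4Vectors::mcols(meth) <- S4Vectors::DataFrame(
    region_id = "r1", region_class = "promoter", gene_id = "r1",
    level_sedentary = 0, level_trained = 0, cpg_count = 50L)
  cfg <- sim_config(genome_length = 50000, n_genes = 10,
                    background_rate = 0, n_samples_per_group = 1, seed = 3)
  sim <- structure(list(genome = genome, methylome = meth, config = cfg),
                   class = "medip_simulation")
  expect_length(simulate_medip_reads(sim, "trained")[[1]], 0)
})

test_that("read simulation is deterministic and stable under added samples", {
  cfg1 <- sim_config(genome_length = 50000, n_genes = 10, seed = 13,
                     n_samples_per_group = 2, mean_depth = 2000)
  sim <- simulate_genome(cfg1)
  r1 <- simulate_medip_reads(sim, "sedentary")
  r1b <- simulate_medip_reads(sim, "sedentary")
  expect_equal(r1, r1b)
  # widening the design must not reshuffle existing per-sample streams
  cfg2 <- cfg1; cfg2$n_samples_per_group <- 4L
  r2 <- simulate_medip_reads(sim, "sedentary", config = cfg2)
  expect_equal(r2[["sed_1"]], r1[["sed_1"]])
  expect_equal(r2[["sed_2"]], r1[["sed_2"]])
})

test_that("stronger planted effects raise the observed promoter fold change", {
  mean_planted_lfc <- function(effect, seed) {
    cfg <- sim_config(genome_length = 60000, n_genes = 12, seed = seed,
                      dmr_effect = effect, planted_dmr_fraction = 0.25,
                      n_samples_per_group = 1, mean_depth = 10000)
    sim <- simulate_genome(cfg)
    prom <- promoter_intervals(sim$genes)
    S4Vectors::mcols(prom)$region_id <- S4Vectors::mcols(prom)$gene_id
    reads <- c(simulate_medip_reads(sim, "sedentary"),
               simulate_medip_reads(sim, "trained"))
    sm <- score_wide(score_matrix(reads, prom))
    planted <- sim$truth$gene_id[sim$truth$is_planted_dmr]
    mean(abs(log2((sm[planted, "trn_1"] + 0.5) /
                    (sm[planted, "sed_1"] + 0.5))))
  }
  seeds <- 1:5
  l1 <- mean(vapply(seeds, function(s) mean_planted_lfc(1.5, s), numeric(1)))
  l2 <- mean(vapply(seeds, function(s) mean_planted_lfc(3, s), numeric(1)))
  l3 <- mean(vapply(seeds, function(s) mean_planted_lfc(6, s), numeric(1)))
  expect_lt(l1, l2)
  expect_lt(l2, l3)
})

test_that("pyro counts honour boundary levels, depth and determinism", {
  cfg <- sim_config(genome_length = 50000, n_genes = 10, seed = 21,
                    pyro_depth = 100, conversion_efficiency = 1)
  sim <- simulate_genome(cfg)
  gid <- sim$truth$gene_id[1]
  # force boundary levels on that promoter
  i <- match(gid, S4Vectors::mcols(sim$methylome)$region_id)
  S4Vectors::mcols(sim$methylome)$level_sedentary[i] <- 1
  S4Vectors::mcols(sim$methylome)$level_trained[i] <- 0
  pc1 <- simulate_pyro_counts(sim, gid, "sedentary")
  expect_true(all(pc1$sites$nC == 100) && all(pc1$sites$nT == 0))
  expect_true(all(pc1$controls$unconverted == 0))
  pc0 <- simulate_pyro_counts(sim, gid, "trained")
  expect_true(all(pc0$sites$nC == 0))
  expect_equal(simulate_pyro_counts(sim, gid, "sedentary"), pc1)

  # intermediate level at depth 10,000: within 3 binomial SEs of truth
  S4Vectors::mcols(sim$methylome)$level_sedentary[i] <- 0.5
  cfg2 <- cfg; cfg2$pyro_depth <- 10000L
  pc <- simulate_pyro_counts(sim, gid, "sedentary", config = cfg2)
  frac <- pc$sites$nC / (pc$sites$nC + pc$sites$nT)
  expect_true(all(abs(frac - 0.5) < 3 * sqrt(0.25 / 10000)))
})

test_that("pyro simulation refuses a region without CpGs", {
  genome <- Biostrings::DNAStringSet(c(chrS = strrep("AT", 1000)))
  meth <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(1, 500),
    seqinfo = GenomeInfoDb::Seqinfo("chrS", 2000))
  S4Vectors::mcols(meth) <- S4Vectors::DataFrame(
    region_id = "r1", region_class = "promoter", gene_id = "r1",
    level_sedentary = 0.5, level_trained = 0.5, cpg_count = 0L)
  sim <- structure(list(genome = genome, methylome = meth,
                        config = sim_config(genome_length = 50000,
                                            n_genes = 10)),
                   class = "medip_simulation")
  expect_error(simulate_pyro_counts(sim, "r1"), "no CpG")
})
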