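test_that("simulation is deterministic: same config gives byte-identical PED/MAP", {
  cfg <- small_sim_config(seed = 3)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  dir.create(d1, showWarnings = FALSE); dir.create(d2, showWarnings = FALSE)
  for (d in c(d1, d2)) {
    sim <- simulate_population(cfg)
    write_ped_map(sim$genotypes, sim$map,
                  file.path(d, "g.ped"), file.path(d, "g.map"))
  }
  expect_identical(readLines(file.path(d1, "g.ped")),
                   readLines(file.path(d2, "g.ped")))
  expect_identical(readLines(file.path(d1, "g.map")),
                   readLines(file.path(d2, "g.map")))
})

test_that("a fixed-difference planted SNP is homozygous opposite by group", {
  cfg <- small_sim_config(seed = 5)
  cfg$planted_diff_snps <- data.frame(chrom = 1L, snp_index = 10L,
                                      freq_high = 1.0, freq_low = 0.0)
  cfg$missing_rate <- 0
  sim <- simulate_population(cfg)
  j <- which(sim$map$id == sim$truth$planted_diff_snp_ids[1])
  g <- sim$genotypes[, j]
  grp <- sim$truth$group[rownames(sim$genotypes)]
  expect_true(all(g[grp == "high"] == 2L))
  expect_true(all(g[grp == "low"] == 0L))
})

test_that("missing_rate = 0 with no planted low-call markers gives a complete PED", {
  cfg <- small_sim_config(seed = 7, missing_rate = 0, n_low_call_snps = 0)
  sim <- simulate_population(cfg)
  expect_false(anyNA(sim$genotypes))
  f <- tempfile()
  write_ped_map(sim$genotypes, sim$map, f, paste0(f, ".map"))
  toks <- strsplit(readLines(f), " ", fixed = TRUE)
  # columns 3-5 (parents, sex) are structural zeros; genotype fields from 7 on
  expect_false(any(vapply(toks, function(x) any(x[-(1:6)] == "0"), TRUE)))
})

test_that("planted ROH carriers have zero heterozygous calls in the span", {
  cfg <- small_sim_config(seed = 9, missing_rate = 0)
  sim <- simulate_population(cfg)
  tr <- sim$truth$planted_roh_regions
  for (i in seq_len(nrow(tr))) {
    span <- which(sim$map$chrom == as.character(tr$chrom[i]) &
                    sim$map$bp >= tr$start_bp[i] & sim$map$bp <= tr$end_bp[i])
    members <- names(sim$truth$group)[sim$truth$group == tr$group[i]]
    het_per_ind <- rowSums(sim$genotypes[members, span, drop = FALSE] == 1L)
    n_carriers <- sum(het_per_ind == 0)
    # at least carrier_fraction of the group must be fully homozygous there
    expect_gte(n_carriers, round(tr$carrier_fraction[i] * length(members)))
  }
})

test_that("overlapping planted ROH and diff SNP is rejected naming the locus", {
  expect_error(
    sim_config(n_chrom = 2, snps_per_chrom = 100,
               planted_roh = data.frame(group = "high", chrom = 1L,
                                        start_snp = 10L, n_snps = 20L,
                                        carrier_fraction = 0.9),
               planted_diff_snps = data.frame(chrom = 1L, snp_index = 15L,
                                              freq_high = 0.9, freq_low = 0.1)),
    "chromosome 1 index 15")
})

test_that("group fecundity means converge to the configured targets", {
  # large-sample check: tolerance ~ 3 / sqrt(n) per group
  cfg <- sim_config(n_high = 800, n_low = 800, n_chrom = 1, snps_per_chrom = 30,
                    n_low_maf_snps = 0, n_hwe_violating_snps = 0,
                    n_low_call_snps = 0,
                    planted_roh = data.frame(group = character(), chrom = integer(),
                                             start_snp = integer(), n_snps = integer(),
                                             carrier_fraction = numeric()),
                    planted_diff_snps = data.frame(chrom = integer(),
                                                   snp_index = integer(),
                                                   freq_high = numeric(),
                                                   freq_low = numeric()),
                    seed = 21)
  ph <- simulate_population(cfg)$phenotypes
  m_high <- mean(ph$fecundity[ph$group == "high"])
  m_low <- mean(ph$fecundity[ph$group == "low"])
  expect_lt(abs(m_high - 1.3), 3 * 0.5 / sqrt(800))
  expect_lt(abs(m_low - 1.1), 3 * 0.4 / sqrt(800))
})

test_that("realized allele frequencies sit within binomial error of the draw", {
  cfg <- small_sim_config(seed = 13, missing_rate = 0)
  sim <- simulate_population(cfg)
  special <- c(sim$truth$planted_diff_snp_ids, sim$truth$qc_fail_snps$id)
  tr <- sim$truth$planted_roh_regions
  in_roh <- rep(FALSE, nrow(sim$map))
  for (i in seq_len(nrow(tr)))
    in_roh <- in_roh | (sim$map$chrom == as.character(tr$chrom[i]) &
                          sim$map$bp >= tr$start_bp[i] & sim$map$bp <= tr$end_bp[i])
  neutral <- !(sim$map$id %in% special) & !in_roh
  p_hat <- colMeans(sim$genotypes[, neutral, drop = FALSE]) / 2
  # every realized frequency must be a plausible binomial draw from some
  # frequency in the configured base range (5 sigma slack at 2n = 96 alleles)
  n2 <- 2 * nrow(sim$genotypes)
  sigma <- sqrt(0.5 * 0.5 / n2)
  expect_true(all(p_hat > 0.05 - 5 * sigma & p_hat < 0.95 + 1e-9))
  # and the MAF distribution must fill the configured band
  expect_gt(mean(pmin(p_hat, 1 - p_hat) > 0.10), 0.5)
})

test_that("gene annotation simulation is deterministic and validates inputs", {
  map <- tiny_map(100, n_chrom = 2, spacing = 1e5)
  expect_error(simulate_gene_annotation(map, n_genes = -1), "n_genes")
  expect_identical(nrow(simulate_gene_annotation(map, 0)), 0L)
  g1 <- simulate_gene_annotation(map, 20, seed = 4)
  g2 <- simulate_gene_annotation(map, 20, seed = 4)
  expect_identical(g1, g2)
  # requested overlaps are honoured
  reg <- data.frame(chrom = "1", start_bp = 2e5, end_bp = 8e5)
  g3 <- simulate_gene_annotation(map, 5, seed = 4, ensure_overlap = reg)
  planted <- g3[g3$gene == "PLANTED_01", ]
  expect_identical(nrow(planted), 1L)
  expect_true(planted$start <= 8e5 && planted$end >= 2e5)
})
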