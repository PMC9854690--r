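test_that("all-homozygous chromosome yields one run covering every SNP", {
  g <- geno_matrix(rep(0L, 100))
  map <- tiny_map(100)
  runs <- detect_runs(g, map)
  expect_identical(nrow(runs), 1L)
  expect_identical(runs$start_index, 1L)
  expect_identical(runs$end_index, 100L)
  expect_identical(runs$n_snp, 100L)
  expect_identical(runs$length_bp, runs$end_bp - runs$start_bp + 1)
})

test_that("alternating heterozygous calls yield zero runs", {
  g <- geno_matrix(rep(c(0L, 1L), 50))
  runs <- detect_runs(g, tiny_map(100))
  expect_identical(nrow(runs), 0L)
})

test_that("a planted homozygous tract flanked by heterozygosity matches the oracle", {
  set.seed(16)
  g <- c(sample(c(0L, 1L, 2L), 60, TRUE, prob = c(0.25, 0.5, 0.25)),
         rep(2L, 30),
         sample(c(0L, 1L, 2L), 60, TRUE, prob = c(0.25, 0.5, 0.25)))
  gm <- geno_matrix(g)
  map <- tiny_map(150)
  params <- roh_params()
  runs <- detect_runs(gm, map, params)
  oracle <- oracle_roh_runs(g, params)
  expect_identical(nrow(runs), length(oracle))
  for (k in seq_along(oracle)) {
    expect_identical(runs$start_index[k], unname(oracle[[k]]["from"]))
    expect_identical(runs$end_index[k], unname(oracle[[k]]["to"]))
  }
  # the planted tract (SNPs 61-90) must be inside a detected run
  expect_true(any(runs$start_index <= 61 & runs$end_index >= 90))
})

test_that("detection equals the brute-force window oracle on random instances", {
  # randomized multi-individual instances with missingness
  for (s in 1:20) {
    set.seed(300 + s)
    n <- sample(3:10, 1)
    L <- sample(60:200, 1)
    params <- roh_params(window_size = sample(3:15, 1),
                         threshold = runif(1, 0.02, 0.6),
                         min_snp = sample(3:20, 1),
                         max_opp_window = sample(0:2, 1),
                         max_miss_window = sample(0:2, 1))
    g <- matrix(sample(c(0L, 1L, 2L, NA), n * L, TRUE,
                       prob = c(0.35, 0.25, 0.35, 0.05)), n, L)
    rownames(g) <- sprintf("I%02d", 1:n)
    colnames(g) <- sprintf("M%03d", 1:L)
    runs <- detect_runs(g, tiny_map(L), params)
    for (i in 1:n) {
      want <- oracle_roh_runs(g[i, ], params)
      got <- runs[runs$individual == rownames(g)[i], , drop = FALSE]
      expect_identical(nrow(got), length(want))
      if (length(want))
        expect_identical(cbind(got$start_index, got$end_index),
                         cbind(vapply(want, `[[`, 0L, "from"),
                               vapply(want, `[[`, 0L, "to")))
    }
  }
})

test_that("runs never span chromosomes and output is invariant to individual order", {
  set.seed(17)
  g <- rand_geno(8, 120, maf = c(0.02, 0.2), seed = 17)
  map <- tiny_map(120, n_chrom = 3)
  params <- roh_params(window_size = 5, min_snp = 6)
  runs <- detect_runs(g, map, params)
  per_chrom <- nrow(map) / 3
  expect_true(all(runs$end_index <= per_chrom))
  for (k in seq_len(nrow(runs))) {
    ch <- runs$chrom[k]
    expect_true(all(map$chrom[map$id == runs$start_snp[k]] == ch))
  }
  perm <- sample(nrow(g))
  runs2 <- detect_runs(g[perm, ], map, params)
  key <- function(r) r[order(r$individual, r$chrom, r$start_index), ]
  expect_equal(key(runs)[, -1], key(runs2)[, -1], ignore_attr = TRUE)
  expect_identical(key(runs)$individual, key(runs2)$individual)
})

test_that("degenerate window parameters reduce runs to maximal homozygous stretches", {
  set.seed(18)
  g <- sample(c(0L, 1L, 2L), 80, TRUE)
  gm <- geno_matrix(g)
  params <- roh_params(window_size = 1, threshold = 0.99, min_snp = 1,
                       max_opp_window = 0, max_miss_window = 0)
  runs <- detect_runs(gm, tiny_map(80), params)
  r <- rle(g != 1L)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  expect_identical(runs$start_index, starts[r$values])
  expect_identical(runs$end_index, ends[r$values])
})

test_that("chromosomes shorter than the window are skipped with a warning", {
  g <- geno_matrix(rep(0L, 10))
  expect_warning(runs <- detect_runs(g, tiny_map(10), roh_params(window_size = 15)),
                 "skipped")
  expect_identical(nrow(runs), 0L)
})

test_that("per-SNP in-run frequency counts covered group members", {
  map <- tiny_map(60)
  # 4 ewes: 3 with a long homozygous tract over SNPs 11-40, 1 heterozygous
  tract <- function() c(rep(1L, 5), rep(0L, 5), rep(0L, 30), rep(1L, 10), rep(0L, 10))
  g <- geno_matrix(tract(), tract(), tract(), rep(c(0L, 1L), 30))
  params <- roh_params(window_size = 5, min_snp = 10, max_opp_window = 0,
                       max_miss_window = 0, threshold = 0.5)
  runs <- detect_runs(g, map, params)
  groups <- setNames(rep("high", 4), rownames(g))
  freq <- snp_run_frequency(runs, groups, map)
  covered <- freq$frequency[freq$id == "M020"]
  expect_equal(covered, 0.75)  # 3 of 4 -> meets the inclusive 0.75 cutoff
  expect_true(all(freq$frequency >= 0 & freq$frequency <= 1))
  expect_error(snp_run_frequency(runs, setNames(character(0), character(0)), map))
})

test_that("no runs means all frequencies zero and no haplotypes", {
  g <- geno_matrix(rep(c(0L, 1L), 30), rep(c(1L, 2L), 30))
  map <- tiny_map(60)
  runs <- detect_runs(g, map)
  freq <- snp_run_frequency(runs, setNames(c("high", "low"), rownames(g)), map)
  expect_true(all(freq$frequency == 0))
  expect_identical(nrow(call_candidate_haplotypes(freq, map)), 0L)
})

test_that("candidate haplotypes obey the frequency and length thresholds", {
  map <- tiny_map(10)
  mk <- function(f) data.frame(group = "high", id = map$id, chrom = map$chrom,
                               bp = map$bp, frequency = f,
                               stringsAsFactors = FALSE)
  # (0.8, 0.8, 0.8) stretch -> one 3-SNP candidate
  f1 <- mk(c(0, 0, 0.8, 0.8, 0.8, 0, 0, 0, 0, 0))
  h1 <- call_candidate_haplotypes(f1, map)
  expect_identical(nrow(h1), 1L)
  expect_identical(h1$n_snp, 3L)
  expect_identical(h1$start_bp, map$bp[3])
  expect_identical(h1$end_bp, map$bp[5])
  expect_equal(h1$snp_freqs[[1]], rep(0.8, 3))
  # (0.8, 0.8) -> below min_snps
  f2 <- mk(c(0, 0, 0.8, 0.8, 0, 0, 0, 0, 0, 0))
  expect_identical(nrow(call_candidate_haplotypes(f2, map)), 0L)
  # boundary: exactly 0.75 is included
  f3 <- mk(c(0.75, 0.75, 0.75, 0, 0, 0, 0, 0, 0, 0))
  expect_identical(nrow(call_candidate_haplotypes(f3, map)), 1L)
})

test_that("planted shared ROH surface as consensus haplotypes over the planted span", {
  sim <- simulate_population(small_sim_config(seed = 29))
  qc <- apply_qc(sim$genotypes)
  map_qc <- sim$map[sim$map$id %in% colnames(qc$genotypes), ]
  runs <- detect_runs(qc$genotypes, map_qc)
  freq <- snp_run_frequency(runs, sim$truth$group, map_qc)
  haps <- call_candidate_haplotypes(freq, map_qc)
  tr <- sim$truth$planted_roh_regions
  for (i in seq_len(nrow(tr))) {
    hit <- haps$group == tr$group[i] &
      haps$chrom == as.character(tr$chrom[i]) &
      haps$start_bp <= tr$end_bp[i] & haps$end_bp >= tr$start_bp[i]
    expect_true(any(hit))
  }
})
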