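# Small programmatic fixtures shared across test files.

# genotype matrix with ids and marker names attached
geno_matrix <- function(..., ids = NULL, byrow = TRUE) {
  rows <- list(...)
  g <- do.call(rbind, rows)
  storage.mode(g) <- "integer"
  rownames(g) <- if (is.null(ids)) sprintf("I%02d", seq_len(nrow(g))) else ids
  colnames(g) <- sprintf("M%03d", seq_len(ncol(g)))
  g
}

# random genotype matrix under HW with per-marker maf drawn uniformly
rand_geno <- function(n, m, maf = c(0.05, 0.5), missing_rate = 0, seed = 1) {
  set.seed(seed)
  p <- runif(m, maf[1], maf[2])
  g <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  if (missing_rate > 0) g[runif(n * m) < missing_rate] <- NA_integer_
  storage.mode(g) <- "integer"
  rownames(g) <- sprintf("I%02d", seq_len(n))
  colnames(g) <- sprintf("M%03d", seq_len(m))
  g
}

# marker map for a matrix: evenly spaced positions on one or more chromosomes
tiny_map <- function(m, n_chrom = 1, spacing = 1000, start = 1000) {
  per <- m / n_chrom
  stopifnot(per == round(per))
  data.frame(chrom = as.character(rep(seq_len(n_chrom), each = per)),
             id = sprintf("M%03d", seq_len(m)),
             bp = rep(start + spacing * (seq_len(per) - 1), n_chrom),
             ref = "A", alt = "B", stringsAsFactors = FALSE)
}

# a group label vector over a genotype matrix's rows
half_groups <- function(g, n_high = NULL) {
  n <- nrow(g)
  if (is.null(n_high)) n_high <- n %/% 2
  stats::setNames(rep(c("high", "low"), c(n_high, n - n_high)), rownames(g))
}

# a small, fast simulation configuration used where full chip scale is not
# the point
small_sim_config <- function(seed = 11, ...) {
  sim_config(n_chrom = 5, snps_per_chrom = 400,
             planted_roh = data.frame(group = c("high", "low"),
                                      chrom = c(5L, 2L),
                                      start_snp = c(150L, 100L),
                                      n_snps = c(40L, 35L),
                                      carrier_fraction = c(0.85, 0.85)),
             planted_diff_snps = data.frame(chrom = c(1L, 3L, 4L, 4L),
                                            snp_index = c(50L, 200L, 120L, 300L),
                                            freq_high = 0.9, freq_low = 0.1),
             seed = seed, ...)
}

# phenotype table with explicit body condition and fecundity
pheno_table <- function(bc, fec, id = sprintf("E%02d", seq_along(bc))) {
  data.frame(id = id, year = 2020L, age = 4, body_condition = bc,
             hours_estrus = 30, n_births = 3, fecundity = fec,
             stringsAsFactors = FALSE)
}
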