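#' Simulation configuration for the synthetic SNP-chip population
#'
#' Builds and validates the configuration for [simulate_population()]. The
#' defaults emulate the study conditions the scan is designed for: 23
#' high-fecundity and 25 low-fecundity ewes with group fecundity means of
#' about 1.3 and 1.1 lambs per mating, 25 autosomes of 2000 biallelic SNPs
#' each (~50k markers total), a small fraction of markers planted to fail
#' each QC filter in roughly the proportions seen on a real 50k ovine chip,
#' shared homozygous tracts planted in one group, and a set of
#' allele-frequency-differentiated loci (0.9 vs 0.1 by default).
#'
#' Body condition is the only covariate with a true effect on fecundity
#' (coefficient `beta1`), and its distribution differs between the groups
#' (high-fecundity ewes have body condition 4-5, low 1-2 by default): the
#' adjustment model predicts fecundity from body condition alone, so the
#' clustering of adjusted phenotypes can only recover the groups if body
#' condition carries the group signal. The default supports leave a
#' two-score gap between the groups, which makes the k = 2 complete-linkage
#' cut of the fitted values deterministic (the between-group fitted gap,
#' 2*beta1, strictly exceeds the within-group spacing beta1); adjacent
#' supports would leave the cut to linkage tie-breaking. The per-group
#' liability offset needed to hit `pheno_means` exactly is calibrated
#' numerically (see [calibrate_group_offset()]).
#'
#' @param n_high,n_low number of ewes per fecundity group (each >= 2).
#' @param n_chrom number of autosomes.
#' @param snps_per_chrom markers per autosome.
#' @param chrom_length_bp autosome length in bp.
#' @param base_maf_range range of baseline alt-allele frequencies, in (0, 0.5].
#' @param missing_rate per-genotype missingness probability.
#' @param n_low_maf_snps markers planted with MAF < 0.05 (default ~7.4% of
#'   markers, the proportion such markers make up on the real chip).
#' @param n_hwe_violating_snps markers planted with strong excess
#'   homozygosity (default ~1%).
#' @param n_low_call_snps markers planted with call rate < 90% (default ~0.5%).
#' @param planted_roh data frame of shared homozygous tracts:
#'   columns `group` ("high"/"low"), `chrom`, `start_snp` (1-based index on
#'   the chromosome), `n_snps`, `carrier_fraction` in (0, 1].
#' @param planted_diff_snps data frame of differentiated loci: columns
#'   `chrom`, `snp_index`, `freq_high`, `freq_low` (alt-allele frequencies).
#' @param pheno_means target discretized fecundity means, `c(high=, low=)`.
#' @param beta0,beta1 intercept and body-condition coefficient of the
#'   phenotype liability model `y = beta0 + beta1 * bc + offset + noise`.
#' @param noise_sd liability noise standard deviation.
#' @param bc_support_high,bc_support_low body-condition score supports per group.
#' @param bc_probs_high,bc_probs_low sampling probabilities over the supports.
#' @param seed integer seed fixing all randomness.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_high = 23, n_low = 25,
                       n_chrom = 25, snps_per_chrom = 2000,
                       chrom_length_bp = 1.11e8,
                       base_maf_range = c(0.05, 0.5),
                       missing_rate = 0.01,
                       n_low_maf_snps = NULL,
                       n_hwe_violating_snps = NULL,
                       n_low_call_snps = NULL,
                       planted_roh = NULL,
                       planted_diff_snps = NULL,
                       pheno_means = c(high = 1.3, low = 1.1),
                       beta0 = 0.8, beta1 = 0.1, noise_sd = 0.25,
                       bc_support_high = 4:5, bc_probs_high = c(0.6, 0.4),
                       bc_support_low = 1:2, bc_probs_low = c(0.4, 0.6),
                       seed = 17L) {
  m_total <- n_chrom * snps_per_chrom
  # QC-failure counts default to the real-chip removal proportions
  # (3838, 516 and 261 of 51,867 markers).
  if (is.null(n_low_maf_snps)) n_low_maf_snps <- round(m_total * 3838 / 51867)
  if (is.null(n_hwe_violating_snps)) n_hwe_violating_snps <- round(m_total * 516 / 51867)
  if (is.null(n_low_call_snps)) n_low_call_snps <- round(m_total * 261 / 51867)

  if (is.null(planted_roh)) {
    planted_roh <- data.frame(
      group = c("high", "low", "low"),
      chrom = c(25L, 16L, 6L),
      start_snp = c(600L, 500L, 300L),
      n_snps = c(40L, 35L, 30L),
      carrier_fraction = c(0.85, 0.85, 0.80))
  }
  if (is.null(planted_diff_snps)) {
    k <- 20L
    planted_diff_snps <- data.frame(
      chrom = (seq_len(k) - 1L) %% 10L + 1L,
      snp_index = 100L + 80L * (seq_len(k) - 1L),
      freq_high = rep(0.9, k),
      freq_low = rep(0.1, k))
  }

  cfg <- list(n_high = n_high, n_low = n_low, n_chrom = n_chrom,
              snps_per_chrom = snps_per_chrom, chrom_length_bp = chrom_length_bp,
              base_maf_range = base_maf_range, missing_rate = missing_rate,
              n_low_maf_snps = n_low_maf_snps,
              n_hwe_violating_snps = n_hwe_violating_snps,
              n_low_call_snps = n_low_call_snps,
              planted_roh = planted_roh, planted_diff_snps = planted_diff_snps,
              pheno_means = pheno_means, beta0 = beta0, beta1 = beta1,
              noise_sd = noise_sd,
              bc_support_high = bc_support_high, bc_probs_high = bc_probs_high,
              bc_support_low = bc_support_low, bc_probs_low = bc_probs_low,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @param config a `sim_config` candidate list.
#' @export
validate_sim_config <- function(config) {
  with(config, {
    if (n_high < 2 || n_low < 2) .stopf("n_high and n_low must be >= 2")
    if (n_chrom < 1 || snps_per_chrom < 1) .stopf("need at least one chromosome and SNP")
    if (length(base_maf_range) != 2 || any(base_maf_range <= 0) ||
        any(base_maf_range > 0.5) || base_maf_range[1] > base_maf_range[2])
      .stopf("base_maf_range must be an increasing pair in (0, 0.5]")
    if (missing_rate < 0 || missing_rate >= 1) .stopf("missing_rate must be in [0, 1)")
    if (n_low_maf_snps < 0 || n_hwe_violating_snps < 0 || n_low_call_snps < 0)
      .stopf("planted QC-failure counts must be nonnegative")
    pr <- planted_roh
    if (nrow(pr)) {
      if (!all(pr$group %in% c("high", "low"))) .stopf("planted_roh group must be high/low")
      if (any(pr$carrier_fraction <= 0 | pr$carrier_fraction > 1))
        .stopf("carrier_fraction must be in (0, 1]")
      if (any(pr$chrom < 1 | pr$chrom > n_chrom)) .stopf("planted_roh chromosome out of range")
      if (any(pr$start_snp < 1 | pr$start_snp + pr$n_snps - 1 > snps_per_chrom))
        .stopf("planted_roh span exceeds chromosome bounds")
    }
    pd <- planted_diff_snps
    if (nrow(pd)) {
      if (any(pd$chrom < 1 | pd$chrom > n_chrom)) .stopf("planted diff SNP chromosome out of range")
      if (any(pd$snp_index < 1 | pd$snp_index > snps_per_chrom))
        .stopf("planted diff SNP index out of range")
      if (any(pd$freq_high < 0 | pd$freq_high > 1 | pd$freq_low < 0 | pd$freq_low > 1))
        .stopf("planted diff SNP frequencies must be in [0, 1]")
    }
    # a locus cannot be both a planted diff SNP and inside a planted ROH span
    if (nrow(pr) && nrow(pd)) {
      for (i in seq_len(nrow(pd))) {
        hit <- pr$chrom == pd$chrom[i] &
          pd$snp_index[i] >= pr$start_snp &
          pd$snp_index[i] <= pr$start_snp + pr$n_snps - 1
        if (any(hit))
          .stopf("planted diff SNP at chromosome %d index %d lies inside a planted ROH span",
                 pd$chrom[i], pd$snp_index[i])
      }
    }
    if (noise_sd <= 0) .stopf("noise_sd must be positive")
    if (abs(sum(bc_probs_high) - 1) > 1e-8 || abs(sum(bc_probs_low) - 1) > 1e-8)
      .stopf("body-condition probabilities must sum to 1")
  })
  invisible(config)
}

#' Calibrate the per-group liability offset
#'
#' Solves for the group offset `delta` such that the expected discretized
#' fecundity `E[clamp(round(beta0 + beta1*bc + delta + noise), 0, 2)]`,
#' averaged over the group's body-condition distribution, equals the target
#' mean. This is a calibration constant of the generator: it guarantees the
#' configured group means are the means the simulated population converges
#' to, rather than hoping a hand-picked offset lands near them.
#'
#' @param target target mean in (0, 2).
#' @param bc_support,bc_probs body-condition distribution of the group.
#' @param beta0,beta1,noise_sd liability-model parameters.
#' @return the offset (numeric scalar).
#' @export
calibrate_group_offset <- function(target, bc_support, bc_probs,
                                   beta0, beta1, noise_sd) {
  expected_mean <- function(delta) {
    mu <- beta0 + beta1 * bc_support + delta
    # P(round to 2) = P(y > 1.5), P(round to 0) = P(y < 0.5); middle is 1
    p2 <- stats::pnorm(1.5, mean = mu, sd = noise_sd, lower.tail = FALSE)
    p0 <- stats::pnorm(0.5, mean = mu, sd = noise_sd)
    sum(bc_probs * (2 * p2 + 1 * (1 - p2 - p0)))
  }
  stats::uniroot(function(d) expected_mean(d) - target,
                 interval = c(-4, 4), tol = 1e-10)$root
}

#' Simulate phenotypes for the two fecundity groups
#'
#' Internal engine shared by [simulate_population()] and exported for fast
#' phenotype-only simulation studies. Body condition is drawn from the
#' group-specific distribution; the continuous liability
#' `y = beta0 + beta1*bc + offset_g + noise` is rounded to the nearest of
#' {0, 1, 2} (clamped) to give the fecundity outcome. Remaining covariates
#' (record year, age, hours to estrus, number of births) are drawn with no
#' effect on fecundity.
#'
#' @param config a [sim_config()] object.
#' @return data frame with one row per ewe: `id`, `group`, `year`, `age`,
#'   `body_condition`, `hours_estrus`, `n_births`, `fecundity`.
#' @export
simulate_phenotypes <- function(config) {
  ids <- c(sprintf("H%03d", seq_len(config$n_high)),
           sprintf("L%03d", seq_len(config$n_low)))
  group <- c(rep("high", config$n_high), rep("low", config$n_low))
  n <- length(ids)

  off_high <- calibrate_group_offset(config$pheno_means[["high"]],
                                     config$bc_support_high, config$bc_probs_high,
                                     config$beta0, config$beta1, config$noise_sd)
  off_low <- calibrate_group_offset(config$pheno_means[["low"]],
                                    config$bc_support_low, config$bc_probs_low,
                                    config$beta0, config$beta1, config$noise_sd)

  bc <- integer(n)
  bc[group == "high"] <- sample(config$bc_support_high, config$n_high,
                                replace = TRUE, prob = config$bc_probs_high)
  bc[group == "low"] <- sample(config$bc_support_low, config$n_low,
                               replace = TRUE, prob = config$bc_probs_low)
  offset <- ifelse(group == "high", off_high, off_low)
  y <- config$beta0 + config$beta1 * bc + offset + stats::rnorm(n, 0, config$noise_sd)
  fec <- pmin(2L, pmax(0L, as.integer(round(y))))

  data.frame(
    id = ids, group = group,
    year = sample(2019:2021, n, replace = TRUE),
    age = pmax(2, pmin(8, round(stats::rnorm(n, 4.5, 1.3)))),
    body_condition = bc,
    hours_estrus = round(stats::rnorm(n, 30, 6), 1),
    n_births = pmax(1, round(stats::rnorm(n, 3.2, 1.3))),
    fecundity = fec,
    stringsAsFactors = FALSE)
}

#' Simulate a genotyped population with planted selection signals
#'
#' Generates a biallelic SNP-array-like dataset for two fecundity groups:
#'
#' * Baseline markers are drawn per SNP under Hardy-Weinberg proportions from
#'   a shared allele frequency in `base_maf_range`.
#' * Planted differentiated loci use group-specific frequencies
#'   (`freq_high` / `freq_low`).
#' * Planted ROH are realised by overwriting the designated SNP span with a
#'   single shared homozygous haplotype in a `carrier_fraction` subset of the
#'   designated group, before missingness is applied.
#' * Designated QC-failure markers are planted to fail exactly one filter:
#'   MAF < 0.05 (any excess alt alleles after sampling are demoted so the
#'   failure is guaranteed, not probabilistic), Hardy-Weinberg
#'   disequilibrium (genotypes drawn with inbreeding-like homozygote excess
#'   F = 0.95 at moderate frequency), or call rate < 90% (a minimum missing
#'   count is enforced on top of random missingness).
#'
#' All randomness is fixed by `config$seed`: the same configuration produces
#' bit-identical outputs.
#'
#' @param config a [sim_config()] object.
#' @return list of class `fecund_sim` with elements `genotypes` (integer
#'   matrix), `map` (marker map data frame), `phenotypes` (data frame), and
#'   `truth` (list: `planted_roh_regions`, `planted_diff_snp_ids`,
#'   `qc_fail_snps`, `group` per individual).
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  .with_seed(config$seed, {
    n_high <- config$n_high; n_low <- config$n_low
    n <- n_high + n_low
    nc <- config$n_chrom; mpc <- config$snps_per_chrom
    m <- nc * mpc

    # ---- marker map ----
    pos <- unlist(lapply(seq_len(nc), function(ch)
      sort(sample.int(config$chrom_length_bp, mpc))))
    chrom <- rep(seq_len(nc), each = mpc)
    ids <- sprintf("SNP_c%02d_%05d", chrom, rep(seq_len(mpc), nc))
    map <- data.frame(chrom = as.character(chrom), id = ids, bp = as.numeric(pos),
                      ref = "A", alt = "B", stringsAsFactors = FALSE)
    gidx <- function(ch, i) (ch - 1L) * mpc + i  # global marker index

    # ---- designate special marker sets (mutually exclusive) ----
    pd <- config$planted_diff_snps
    diff_idx <- if (nrow(pd)) gidx(pd$chrom, pd$snp_index) else integer(0)
    roh_idx <- integer(0)
    pr <- config$planted_roh
    if (nrow(pr)) {
      for (i in seq_len(nrow(pr)))
        roh_idx <- c(roh_idx, gidx(pr$chrom[i], pr$start_snp[i] + seq_len(pr$n_snps[i]) - 1L))
    }
    reserved <- c(diff_idx, roh_idx)
    free <- setdiff(seq_len(m), reserved)
    n_special <- config$n_low_maf_snps + config$n_hwe_violating_snps + config$n_low_call_snps
    if (n_special > length(free))
      .stopf("not enough unreserved markers for the planted QC failures")
    special <- sample(free, n_special)
    low_maf_idx <- special[seq_len(config$n_low_maf_snps)]
    hwe_idx <- special[config$n_low_maf_snps + seq_len(config$n_hwe_violating_snps)]
    low_call_idx <- special[config$n_low_maf_snps + config$n_hwe_violating_snps +
                              seq_len(config$n_low_call_snps)]

    # ---- allele frequencies ----
    p_alt <- stats::runif(m, config$base_maf_range[1], config$base_maf_range[2])
    p_alt[low_maf_idx] <- stats::runif(length(low_maf_idx), 0.002, 0.020)
    p_alt[hwe_idx] <- stats::runif(length(hwe_idx), 0.30, 0.50)
    p_high <- p_low <- p_alt
    if (nrow(pd)) {
      p_high[diff_idx] <- pd$freq_high
      p_low[diff_idx] <- pd$freq_low
    }

    # ---- genotypes under HW proportions, per group ----
    draw_group <- function(ng, p) {
      matrix(stats::rbinom(ng * m, 2L, rep(p, each = ng)), nrow = ng, ncol = m)
    }
    geno <- rbind(draw_group(n_high, p_high), draw_group(n_low, p_low))
    ind_ids <- c(sprintf("H%03d", seq_len(n_high)), sprintf("L%03d", seq_len(n_low)))
    group <- c(rep("high", n_high), rep("low", n_low))
    dimnames(geno) <- list(ind_ids, map$id)

    # HWE-violating markers: inbreeding-like excess homozygosity, F = 0.95
    if (length(hwe_idx)) {
      Fin <- 0.95
      for (j in hwe_idx) {
        p <- p_alt[j]; q <- 1 - p
        pr_g <- c(q^2 + Fin * p * q, 2 * p * q * (1 - Fin), p^2 + Fin * p * q)
        geno[, j] <- sample(0:2, n, replace = TRUE, prob = pr_g)
      }
    }

    # ---- planted ROH: overwrite span with one shared homozygous haplotype ----
    roh_regions <- NULL
    if (nrow(pr)) {
      roh_regions <- pr
      roh_regions$start_bp <- NA_real_; roh_regions$end_bp <- NA_real_
      for (i in seq_len(nrow(pr))) {
        span <- gidx(pr$chrom[i], pr$start_snp[i] + seq_len(pr$n_snps[i]) - 1L)
        g_idx <- which(group == pr$group[i])
        k <- max(1L, round(pr$carrier_fraction[i] * length(g_idx)))
        carriers <- sample(g_idx, k)
        hap <- stats::rbinom(length(span), 1L, p_alt[span])
        geno[carriers, span] <- matrix(2L * hap, nrow = k, ncol = length(span),
                                       byrow = TRUE)
        roh_regions$start_bp[i] <- map$bp[span[1]]
        roh_regions$end_bp[i] <- map$bp[span[length(span)]]
      }
    }

    # ---- guarantee the planted low-MAF failures ----
    # demote excess alt alleles (2 -> 1 -> 0) so realized MAF stays < 0.05
    # even after missingness shrinks the denominator a little
    if (length(low_maf_idx)) {
      cmax <- floor(0.045 * 2 * n)
      for (j in low_maf_idx) {
        excess <- sum(geno[, j]) - cmax
        while (excess > 0) {
          i <- which(geno[, j] > 0L)[1]
          geno[i, j] <- geno[i, j] - 1L
          excess <- excess - 1
        }
      }
    }

    # ---- missingness (after all planting) ----
    if (config$missing_rate > 0) {
      miss <- stats::runif(n * m) < config$missing_rate
      geno[miss] <- NA_integer_
    }
    if (length(low_call_idx)) {
      need <- floor(0.1 * n) + 1L  # enough to push call rate below 90%
      for (j in low_call_idx) {
        already <- which(is.na(geno[, j]))
        extra <- max(0L, need - length(already))
        add <- sample(setdiff(seq_len(n), already),
                      min(extra + 3L, n - length(already)))
        geno[add, j] <- NA_integer_
      }
    }

    # ---- phenotypes ----
    phenos <- simulate_phenotypes(config)

    truth <- list(
      planted_roh_regions = if (is.null(roh_regions)) data.frame() else
        roh_regions[, c("group", "chrom", "start_bp", "end_bp",
                        "start_snp", "n_snps", "carrier_fraction")],
      planted_diff_snp_ids = map$id[diff_idx],
      qc_fail_snps = data.frame(
        id = map$id[c(low_maf_idx, hwe_idx, low_call_idx)],
        reason = rep(c("maf", "hwe", "call_rate"),
                     c(length(low_maf_idx), length(hwe_idx), length(low_call_idx))),
        stringsAsFactors = FALSE),
      group = stats::setNames(group, ind_ids))

    structure(list(genotypes = geno, map = map, phenotypes = phenos,
                   truth = truth, config = config),
              class = "fecund_sim")
  })
}

#' @export
print.fecund_sim <- function(x, ...) {
  cat(sprintf("Synthetic SNP-chip population: %d individuals x %d markers on %d chromosomes\n",
              nrow(x$genotypes), ncol(x$genotypes), x$config$n_chrom))
  cat(sprintf("  groups: %d high / %d low fecundity\n", x$config$n_high, x$config$n_low))
  cat(sprintf("  planted: %d ROH tract(s), %d differentiated SNP(s), %d QC-failing marker(s)\n",
              nrow(x$truth$planted_roh_regions), length(x$truth$planted_diff_snp_ids),
              nrow(x$truth$qc_fail_snps)))
  invisible(x)
}

#' Simulate a gene annotation over a marker map
#'
#' Places genes uniformly on the map's chromosomes with lengths drawn from
#' 20-200 kb, clipped to chromosome bounds (1-based inclusive coordinates).
#' If `ensure_overlap` regions are supplied, one extra gene is placed inside
#' each region so downstream annotation is guaranteed a hit to find.
#'
#' @param map marker map data frame (`chrom`, `bp`).
#' @param n_genes number of background genes (>= 0).
#' @param seed integer seed.
#' @param ensure_overlap optional data frame with `chrom`, `start_bp`,
#'   `end_bp`; one gene is planted overlapping each row.
#' @return data frame of gene records (`gene`, `chrom`, `start`, `end`,
#'   `strand`); planted genes are named `PLANTED_*`.
#' @export
simulate_gene_annotation <- function(map, n_genes, seed = 1L, ensure_overlap = NULL) {
  if (nrow(map) == 0) .stopf("marker map is empty")
  if (n_genes < 0) .stopf("n_genes must be >= 0")
  .with_seed(seed, {
    chroms <- unique(map$chrom)
    chrom_max <- vapply(chroms, function(ch) max(map$bp[map$chrom == ch]), 0)
    out <- data.frame(gene = character(), chrom = character(), start = numeric(),
                      end = numeric(), strand = character(), stringsAsFactors = FALSE)
    if (n_genes > 0) {
      ch <- sample(chroms, n_genes, replace = TRUE)
      len <- round(stats::runif(n_genes, 2e4, 2e5))
      start <- pmax(1, round(stats::runif(n_genes) * (chrom_max[ch] - len)))
      out <- data.frame(gene = sprintf("GENE%04d", seq_len(n_genes)),
                        chrom = ch, start = start, end = start + len - 1,
                        strand = sample(c("+", "-"), n_genes, replace = TRUE),
                        stringsAsFactors = FALSE)
    }
    if (!is.null(ensure_overlap) && nrow(ensure_overlap) > 0) {
      for (i in seq_len(nrow(ensure_overlap))) {
        s <- ensure_overlap$start_bp[i]; e <- ensure_overlap$end_bp[i]
        gs <- max(1, round(s + 0.25 * (e - s)))
        ge <- min(e, gs + max(2e4, round(0.5 * (e - s))))
        out <- rbind(out, data.frame(
          gene = sprintf("PLANTED_%02d", i),
          chrom = as.character(ensure_overlap$chrom[i]),
          start = gs, end = ge, strand = "+", stringsAsFactors = FALSE))
      }
    }
    rownames(out) <- NULL
    out
  })
}
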