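#' Within-group fixation index per SNP
#'
#' For each group and marker: `Ho` is the observed heterozygote fraction
#' among non-missing calls, `He = 2p(1-p)` the expected heterozygosity from
#' the group allele frequency, and `F = 1 - Ho/He`. Monomorphic-in-group
#' markers (He = 0) carry F = 0 by convention. Markers where a group has
#' fewer than two non-missing calls are skipped (NA) and counted in a
#' message.
#'
#' @param genotypes integer matrix of alt-allele counts (`NA` missing).
#' @param groups a [assign_groups()] result or named character vector of
#'   `"high"`/`"low"` labels over the matrix rows.
#' @param markers optional marker ids (or column indices) to restrict to.
#' @return data frame: `id`, `F_high`, `F_low`, `delta`
#'   (`|F_high - F_low|`).
#' @export
per_group_fixation <- function(genotypes, groups, markers = NULL) {
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- sprintf("M%05d", seq_len(ncol(genotypes)))
  labels <- .group_labels(genotypes, groups)
  if (!is.null(markers)) genotypes <- genotypes[, markers, drop = FALSE]
  fix_one <- function(rows) {
    G <- genotypes[rows, , drop = FALSE]
    nn <- colSums(!is.na(G))
    p <- colSums(G, na.rm = TRUE) / (2 * nn)
    ho <- colSums(G == 1L, na.rm = TRUE) / nn
    he <- 2 * p * (1 - p)
    f <- ifelse(he > 0, 1 - ho / he, 0)
    f[nn < 2] <- NA_real_
    f
  }
  f_high <- fix_one(labels == "high")
  f_low <- fix_one(labels == "low")
  skipped <- sum(is.na(f_high) | is.na(f_low))
  if (skipped > 0)
    message(sprintf("%d marker(s) skipped: fewer than 2 non-missing calls in a group",
                    skipped))
  data.frame(id = colnames(genotypes), F_high = f_high, F_low = f_low,
             delta = abs(f_high - f_low), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Per-locus Weir-Cockerham F_ST between two groups
#'
#' Two-population Weir-Cockerham theta from the variance components a
#' (among populations), b (among individuals within populations) and c
#' (within individuals), computed per marker from the group sample sizes,
#' allele frequencies and heterozygote frequencies:
#' `theta = a / (a + b + c)`. Markers monomorphic over both groups have an
#' undefined theta and are reported as `NA`.
#'
#' @inheritParams per_group_fixation
#' @return named numeric vector of per-marker theta values.
#' @export
weir_cockerham_fst <- function(genotypes, groups, markers = NULL) {
  labels <- .group_labels(genotypes, groups)
  if (!is.null(markers)) genotypes <- genotypes[, markers, drop = FALSE]
  r <- 2  # number of populations
  stats_one <- function(rows) {
    G <- genotypes[rows, , drop = FALSE]
    nn <- colSums(!is.na(G))
    list(n = nn,
         p = colSums(G, na.rm = TRUE) / (2 * nn),
         h = colSums(G == 1L, na.rm = TRUE) / nn)
  }
  s1 <- stats_one(labels == "high")
  s2 <- stats_one(labels == "low")

  n1 <- s1$n; n2 <- s2$n; p1 <- s1$p; p2 <- s2$p; h1 <- s1$h; h2 <- s2$h
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2v <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2v - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2v * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2v * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2

  theta <- a / (a + b + cc)
  theta[pbar == 0 | pbar == 1] <- NA_real_  # monomorphic overall: undefined
  theta[n1 == 0 | n2 == 0] <- NA_real_
  stats::setNames(theta, colnames(genotypes))
}

.group_labels <- function(genotypes, groups) {
  labels <- if (inherits(groups, "group_assignment"))
    stats::setNames(groups$assignments$label, groups$assignments$id)
  else groups
  if (!is.null(rownames(genotypes)) && !is.null(names(labels)))
    labels <- labels[rownames(genotypes)]
  if (length(labels) != nrow(genotypes))
    .stopf("group labels do not cover the genotype matrix rows")
  if (anyNA(labels)) .stopf("some individuals lack a group label")
  labels
}

#' Per-SNP fixation-index scan
#'
#' Combines [per_group_fixation()] and [weir_cockerham_fst()] into one
#' per-marker table: within-group F for the high and low subpopulations,
#' their absolute difference `delta` (the primary differential statistic),
#' and the Weir-Cockerham `theta`.
#'
#' @inheritParams per_group_fixation
#' @param map optional marker map; adds `chrom` and `bp` columns.
#' @return data frame of class `fst_scan`: `id`, (`chrom`, `bp`,) `F_high`,
#'   `F_low`, `delta`, `theta`.
#' @export
fst_scan <- function(genotypes, groups, map = NULL) {
  fx <- per_group_fixation(genotypes, groups)
  fx$theta <- unname(weir_cockerham_fst(genotypes, groups))
  if (!is.null(map)) {
    i <- match(fx$id, map$id)
    fx <- data.frame(id = fx$id, chrom = map$chrom[i], bp = map$bp[i],
                     fx[, c("F_high", "F_low", "delta", "theta")],
                     stringsAsFactors = FALSE)
  }
  class(fx) <- c("fst_scan", "data.frame")
  fx
}

#' Select candidate SNPs from the top quantile of a statistic
#'
#' Markers whose statistic is at or above the empirical `(1 - fraction)`
#' quantile are selected; ties at the threshold are all included. The
#' default ranking statistic is the Weir-Cockerham `theta`: it measures
#' between-group differentiation directly, whereas `delta` (the absolute
#' difference of within-group fixation indices, the published wording) is
#' blind to symmetric frequency differences — two groups at alt frequencies
#' 0.9 and 0.1 are each in internal Hardy-Weinberg proportions, so their
#' within-group F values coincide in expectation and delta reduces to
#' sampling noise. `stat = "delta"` remains available.
#'
#' Each selected SNP is tagged with the fecundity group in which it is more
#' strongly fixed (`F_high >= F_low` gives `"high"`).
#'
#' @param scan a [fst_scan()] result (or any data frame with `id` and the
#'   statistic column; `chrom`/`bp` used for ordering when present).
#' @param fraction upper fraction to select, in (0, 1) (default 0.20).
#' @param stat `"theta"` (default) or `"delta"`.
#' @return data frame of class `candidate_snps`: `id`, (`chrom`, `bp`,)
#'   `statistic`, `method = "FST"`, (`group`,) ordered by chromosome and
#'   position.
#' @export
select_candidates <- function(scan, fraction = 0.20, stat = c("theta", "delta")) {
  stat <- match.arg(stat)
  if (fraction <= 0 || fraction >= 1) .stopf("fraction must be in (0, 1)")
  x <- scan[[stat]]
  defined <- !is.na(x)
  if (sum(defined) < 5) .stopf("need at least 5 markers with a defined statistic")
  thr <- stats::quantile(x[defined], probs = 1 - fraction, type = 7, names = FALSE)
  sel <- defined & x >= thr
  out <- data.frame(id = scan$id[sel], stringsAsFactors = FALSE)
  if (!is.null(scan$chrom)) {
    out$chrom <- scan$chrom[sel]
    out$bp <- scan$bp[sel]
  }
  out$statistic <- x[sel]
  out$method <- "FST"
  if (!is.null(scan$F_high) && !is.null(scan$F_low))
    out$group <- ifelse(scan$F_high[sel] >= scan$F_low[sel], "high", "low")
  if (!is.null(out$chrom)) {
    num <- suppressWarnings(as.numeric(out$chrom))
    key <- if (anyNA(num)) order(out$chrom, out$bp) else order(num, out$bp)
    out <- out[key, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "fraction") <- fraction
  attr(out, "stat") <- stat
  class(out) <- c("candidate_snps", "data.frame")
  out
}

#' @export
print.fst_scan <- function(x, ...) {
  cat(sprintf("Fixation-index scan over %d markers\n", nrow(x)))
  cat(sprintf("  delta: median %.4f, max %.4f; theta: median %.4f, max %.4f\n",
              stats::median(x$delta, na.rm = TRUE), max(x$delta, na.rm = TRUE),
              stats::median(x$theta, na.rm = TRUE), max(x$theta, na.rm = TRUE)))
  invisible(x)
}
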