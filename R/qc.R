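#' Minor allele frequency
#'
#' `min(p, 1 - p)` where `p` is the alt-allele frequency over non-missing
#' calls. Invariant to which allele is labelled reference.
#'
#' @param genotypes integer vector (one marker) or matrix (individuals x
#'   markers) of 0/1/2 alt-allele counts with `NA` missing.
#' @return numeric scalar or per-marker vector; `NA` for all-missing markers.
#' @export
minor_allele_frequency <- function(genotypes) {
  if (is.matrix(genotypes)) {
    nn <- colSums(!is.na(genotypes))
    p <- colSums(genotypes, na.rm = TRUE) / (2 * nn)
    p[nn == 0] <- NA_real_
  } else {
    nn <- sum(!is.na(genotypes))
    p <- if (nn == 0) NA_real_ else sum(genotypes, na.rm = TRUE) / (2 * nn)
  }
  pmin(p, 1 - p)
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided test for departure from Hardy-Weinberg genotype
#' proportions, conditional on the observed allele counts: the p-value is
#' the sum of the probabilities of all heterozygote configurations no more
#' probable than the observed one. The conditional probability of observing
#' `nAa` heterozygotes given `n` individuals and `nA` copies of allele A is
#' proportional to `2^nAa * n! / (nAA! nAa! naa!)`. Monomorphic markers give
#' p = 1.
#'
#' @param nAA,nAa,naa genotype counts (nonnegative, `nAA + nAa + naa >= 1`).
#' @return the exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0)) .stopf("genotype counts must be nonnegative")
  n <- nAA + nAa + naa
  if (n < 1) .stopf("need at least one genotyped individual")
  nA <- 2L * nAA + nAa
  rare <- min(nA, 2L * n - nA)
  if (rare == 0L) return(1)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  n_rare_hom <- (rare - hets) %/% 2L
  n_common_hom <- n - hets - n_rare_hom
  logw <- hets * log(2) + lfactorial(n) -
    lfactorial(n_rare_hom) - lfactorial(hets) - lfactorial(n_common_hom)
  w <- exp(logw - max(logw))
  probs <- w / sum(w)
  obs <- probs[match(nAa, hets)]
  # tolerance guards ties against floating-point jitter
  min(1, sum(probs[probs <= obs * (1 + 1e-9)]))
}

# Vectorised HWE p-values for the columns of a genotype matrix.
.hwe_pvals <- function(genotypes) {
  vapply(seq_len(ncol(genotypes)), function(j) {
    g <- genotypes[, j]
    g <- g[!is.na(g)]
    if (length(g) == 0) return(NA_real_)
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, 0)
}

#' Apply marker quality control
#'
#' Applies the three marker filters — minor allele frequency, Hardy-Weinberg
#' exact test, call rate — each evaluated on the full input matrix (not
#' sequentially re-estimated), and removes the union of failing markers. A
#' marker can fail more than one filter; the report records every reason.
#'
#' @param genotypes integer matrix of alt-allele counts, `NA` missing.
#' @param maf_min markers with MAF strictly below this are removed
#'   (default 0.05).
#' @param hwe_p_min Hardy-Weinberg exact p threshold (default 1e-6).
#' @param call_rate_min markers with call rate strictly below this are
#'   removed (default 0.90). All-missing markers fall to this filter.
#' @param hwe_exclude `"below"` (standard: remove p < `hwe_p_min`) or
#'   `"above"` (remove p > `hwe_p_min`), exposed because published QC
#'   descriptions sometimes print the inequality the other way round.
#' @return list with `genotypes` (filtered matrix) and `report`
#'   (a `qc_report`: per-marker stats, per-filter counts, surviving ids).
#' @export
apply_qc <- function(genotypes, maf_min = 0.05, hwe_p_min = 1e-6,
                     call_rate_min = 0.90, hwe_exclude = c("below", "above")) {
  hwe_exclude <- match.arg(hwe_exclude)
  stopifnot(is.matrix(genotypes), ncol(genotypes) >= 1)
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- sprintf("M%05d", seq_len(ncol(genotypes)))

  maf <- minor_allele_frequency(genotypes)
  call_rate <- colMeans(!is.na(genotypes))
  hwe_p <- .hwe_pvals(genotypes)

  fail_maf <- !is.na(maf) & maf < maf_min
  fail_hwe <- !is.na(hwe_p) &
    if (hwe_exclude == "below") hwe_p < hwe_p_min else hwe_p > hwe_p_min
  fail_cr <- call_rate < call_rate_min
  removed <- fail_maf | fail_hwe | fail_cr

  reasons <- vapply(seq_along(removed), function(j)
    paste(c("maf", "hwe", "call_rate")[c(fail_maf[j], fail_hwe[j], fail_cr[j])],
          collapse = "+"), "")

  stats_df <- data.frame(
    id = colnames(genotypes), maf = maf, hwe_p = hwe_p, call_rate = call_rate,
    removed = removed, reason = reasons, stringsAsFactors = FALSE,
    row.names = NULL)

  report <- structure(list(
    stats = stats_df,
    n_input = ncol(genotypes),
    n_removed = sum(removed),
    counts = c(maf = sum(fail_maf), hwe = sum(fail_hwe),
               call_rate = sum(fail_cr),
               multiple = sum(fail_maf + fail_hwe + fail_cr > 1)),
    surviving = colnames(genotypes)[!removed],
    thresholds = c(maf_min = maf_min, hwe_p_min = hwe_p_min,
                   call_rate_min = call_rate_min),
    hwe_exclude = hwe_exclude), class = "qc_report")

  if (all(removed)) {
    cond <- structure(
      class = c("fecundscan_qc_error", "error", "condition"),
      list(message = "quality control removed every marker; report attached as cond$report",
           call = sys.call(-1), report = report))
    stop(cond)
  }

  list(genotypes = genotypes[, !removed, drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("Marker QC: %d of %d markers removed (%d survive)\n",
              x$n_removed, x$n_input, x$n_input - x$n_removed))
  cat(sprintf("  MAF < %g:        %d\n", x$thresholds["maf_min"], x$counts["maf"]))
  cat(sprintf("  HWE p %s %g:  %d\n", if (x$hwe_exclude == "below") "<" else ">",
              x$thresholds["hwe_p_min"], x$counts["hwe"]))
  cat(sprintf("  call rate < %g: %d\n", x$thresholds["call_rate_min"],
              x$counts["call_rate"]))
  if (x$counts["multiple"] > 0)
    cat(sprintf("  (%d markers failed more than one filter)\n", x$counts["multiple"]))
  invisible(x)
}
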