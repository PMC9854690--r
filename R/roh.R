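#' Parameters for sliding-window ROH detection
#'
#' The defaults are the standard values for a ~50k ovine array:
#' `window_size = 15` SNPs, SNP score threshold 0.05, minimum run length 20
#' SNPs, at most 1 heterozygous and 1 missing call per window. Optional gap,
#' length and density constraints exist in some implementations of the
#' method but are disabled by default.
#'
#' @param window_size SNPs per sliding window (>= 1).
#' @param threshold minimum fraction of homozygous windows covering a SNP;
#'   a SNP is "in state" when its score is strictly greater than this.
#' @param min_snp minimum number of SNPs per run.
#' @param max_opp_window maximum heterozygous calls per homozygous window.
#' @param max_miss_window maximum missing calls per homozygous window.
#' @param max_gap_bp optional: split runs at inter-SNP gaps larger than
#'   this (default `Inf`, disabled).
#' @param min_length_bp optional: drop runs shorter than this many bp
#'   (default 0, disabled).
#' @param min_density_snp_per_kb optional: drop runs with fewer SNPs per kb
#'   than this (default 0, disabled).
#' @return object of class `roh_params`.
#' @export
roh_params <- function(window_size = 15, threshold = 0.05, min_snp = 20,
                       max_opp_window = 1, max_miss_window = 1,
                       max_gap_bp = Inf, min_length_bp = 0,
                       min_density_snp_per_kb = 0) {
  if (window_size < 1) .stopf("window_size must be >= 1")
  if (threshold <= 0 || threshold > 1) .stopf("threshold must be in (0, 1]")
  if (min_snp < 1) .stopf("min_snp must be >= 1")
  if (max_opp_window < 0 || max_miss_window < 0)
    .stopf("max_opp_window and max_miss_window must be >= 0")
  structure(list(window_size = as.integer(window_size), threshold = threshold,
                 min_snp = as.integer(min_snp),
                 max_opp_window = as.integer(max_opp_window),
                 max_miss_window = as.integer(max_miss_window),
                 max_gap_bp = max_gap_bp, min_length_bp = min_length_bp,
                 min_density_snp_per_kb = min_density_snp_per_kb),
            class = "roh_params")
}

# windowed counts of a logical vector: out[i] = sum(x[i..i+w-1])
.win_counts <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

# in-state flags for one individual's genotypes on one chromosome
.roh_state <- function(g, params) {
  L <- length(g)
  w <- params$window_size
  het <- !is.na(g) & g == 1L
  mis <- is.na(g)
  ok <- .win_counts(het, w) <= params$max_opp_window &
    .win_counts(mis, w) <= params$max_miss_window
  n_win <- L - w + 1L
  # windows covering SNP j are max(1, j-w+1) .. min(n_win, j)
  cs_ok <- c(0, cumsum(ok))
  j <- seq_len(L)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(n_win, j)
  score <- (cs_ok[hi + 1L] - cs_ok[lo]) / (hi - lo + 1L)
  score > params$threshold
}

#' Detect runs of homozygosity by sliding windows
#'
#' For each individual and chromosome, every contiguous window of
#' `window_size` SNPs is classified homozygous iff it contains at most
#' `max_opp_window` heterozygous and `max_miss_window` missing calls. Each
#' SNP's score is the fraction of windows containing it that are
#' homozygous; SNPs whose score strictly exceeds `threshold` are in state,
#' and maximal consecutive in-state stretches of at least `min_snp` SNPs
#' become runs, with bp bounds taken from the map. Runs never span
#' chromosome boundaries; chromosomes with fewer SNPs than `window_size`
#' are skipped with a warning.
#'
#' @param genotypes integer matrix of alt-allele counts (`NA` missing).
#' @param map marker map (`chrom`, `id`, `bp`), same marker order as the
#'   matrix columns, positions sorted within chromosome.
#' @param params a [roh_params()] object.
#' @return data frame of class `roh_runs`: `individual`, `chrom`,
#'   `start_snp`, `end_snp` (marker ids), `start_index`, `end_index`
#'   (1-based per-chromosome), `start_bp`, `end_bp`, `n_snp`, `length_bp`
#'   (inclusive: `end_bp - start_bp + 1`).
#' @export
detect_runs <- function(genotypes, map, params = roh_params()) {
  stopifnot(is.matrix(genotypes), ncol(genotypes) == nrow(map))
  out <- list()
  chroms <- unique(map$chrom)
  skipped <- character(0)
  for (ch in chroms) {
    cols <- which(map$chrom == ch)
    if (length(cols) < params$window_size) {
      skipped <- c(skipped, ch)
      next
    }
    bp <- map$bp[cols]
    ids <- map$id[cols]
    for (i in seq_len(nrow(genotypes))) {
      state <- .roh_state(genotypes[i, cols], params)
      breaks <- if (is.finite(params$max_gap_bp) && length(bp) > 1)
        which(diff(bp) > params$max_gap_bp) else integer(0)
      segs <- .state_segments(state, breaks)
      if (nrow(segs) == 0) next
      segs <- segs[segs$len >= params$min_snp, , drop = FALSE]
      if (nrow(segs) == 0) next
      runs <- data.frame(
        individual = rownames(genotypes)[i], chrom = ch,
        start_snp = ids[segs$from], end_snp = ids[segs$to],
        start_index = segs$from, end_index = segs$to,
        start_bp = bp[segs$from], end_bp = bp[segs$to],
        n_snp = segs$len, length_bp = bp[segs$to] - bp[segs$from] + 1,
        stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- runs
    }
  }
  if (length(skipped))
    .warnf("chromosome(s) with fewer SNPs than window_size skipped: %s",
           paste(skipped, collapse = ", "))
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(individual = character(), chrom = character(),
               start_snp = character(), end_snp = character(),
               start_index = integer(), end_index = integer(),
               start_bp = numeric(), end_bp = numeric(),
               n_snp = integer(), length_bp = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(res) && (params$min_length_bp > 0 || params$min_density_snp_per_kb > 0)) {
    keep <- res$length_bp >= params$min_length_bp &
      res$n_snp / (res$length_bp / 1000) >= params$min_density_snp_per_kb
    res <- res[keep, , drop = FALSE]
  }
  rownames(res) <- NULL
  class(res) <- c("roh_runs", "data.frame")
  res
}

# maximal TRUE segments of a logical vector; `breaks` are positions b where
# a segment must not continue from b to b+1 (large inter-SNP gaps)
.state_segments <- function(state, breaks = integer(0)) {
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  segs <- data.frame(from = starts[keep], to = ends[keep])
  if (length(breaks) && nrow(segs)) {
    pieces <- list()
    for (k in seq_len(nrow(segs))) {
      cut_at <- sort(breaks[breaks >= segs$from[k] & breaks < segs$to[k]])
      from <- c(segs$from[k], cut_at + 1L)
      to <- c(cut_at, segs$to[k])
      pieces[[k]] <- data.frame(from = from, to = to)
    }
    segs <- do.call(rbind, pieces)
  }
  segs$len <- if (nrow(segs)) segs$to - segs$from + 1L else integer(0)
  segs
}

#' Per-group, per-SNP in-run frequency
#'
#' For each group and SNP, the fraction of the group's individuals having at
#' least one run whose bp span covers the SNP. This is the statistic plotted
#' in the Manhattan-style ROH frequency figure and the input to consensus
#' haplotype calling.
#'
#' @param runs a [detect_runs()] result.
#' @param groups a [assign_groups()] result, or a named character vector of
#'   labels.
#' @param map marker map used for the run detection.
#' @return long data frame: `group`, `id` (marker), `chrom`, `bp`,
#'   `frequency`.
#' @export
snp_run_frequency <- function(runs, groups, map) {
  labels <- if (inherits(groups, "group_assignment"))
    stats::setNames(groups$assignments$label, groups$assignments$id)
  else groups
  if (length(labels) == 0) .stopf("no group labels supplied")
  glevels <- unique(labels)
  out <- list()
  chrom_offset <- stats::setNames(
    cumsum(c(0, head(as.numeric(table(factor(map$chrom, levels = unique(map$chrom)))), -1))),
    unique(map$chrom))
  for (g in glevels) {
    members <- names(labels)[labels == g]
    if (length(members) == 0) .stopf("group '%s' is empty", g)
    cov <- numeric(nrow(map))
    rr <- runs[runs$individual %in% members, , drop = FALSE]
    if (nrow(rr)) {
      for (k in seq_len(nrow(rr))) {
        off <- chrom_offset[[as.character(rr$chrom[k])]]
        cov[(off + rr$start_index[k]):(off + rr$end_index[k])] <-
          cov[(off + rr$start_index[k]):(off + rr$end_index[k])] + 1
      }
    }
    out[[g]] <- data.frame(group = g, id = map$id, chrom = map$chrom,
                           bp = map$bp, frequency = cov / length(members),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call consensus candidate haplotypes from ROH frequencies
#'
#' Maximal stretches of consecutive SNPs whose in-run frequency is at least
#' `min_freq` (inclusive boundary) in one group, retained if they contain at
#' least `min_snps` markers.
#'
#' @param freqs output of [snp_run_frequency()].
#' @param map marker map (defines SNP adjacency).
#' @param min_freq frequency threshold (default 0.75, inclusive).
#' @param min_snps minimum markers per haplotype (default 3).
#' @return data frame of class `candidate_haplotypes`: `group`, `chrom`,
#'   `start_snp`, `end_snp`, `start_bp`, `end_bp`, `n_snp`, plus list
#'   columns `snp_ids` and `snp_freqs`.
#' @export
call_candidate_haplotypes <- function(freqs, map, min_freq = 0.75, min_snps = 3) {
  out <- list()
  for (g in unique(freqs$group)) {
    fg <- freqs[freqs$group == g, , drop = FALSE]
    fg <- fg[match(map$id, fg$id), , drop = FALSE]  # map order
    for (ch in unique(map$chrom)) {
      sel <- which(map$chrom == ch)
      fv <- fg$frequency[sel]
      r <- rle(fv >= min_freq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (s in which(r$values & r$lengths >= min_snps)) {
        idx <- sel[starts[s]:ends[s]]
        out[[length(out) + 1L]] <- data.frame(
          group = g, chrom = ch,
          start_snp = map$id[idx[1]], end_snp = map$id[idx[length(idx)]],
          start_bp = map$bp[idx[1]], end_bp = map$bp[idx[length(idx)]],
          n_snp = length(idx), stringsAsFactors = FALSE)
        out[[length(out)]]$snp_ids <- list(map$id[idx])
        out[[length(out)]]$snp_freqs <- list(fv[starts[s]:ends[s]])
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(group = character(), chrom = character(),
               start_snp = character(), end_snp = character(),
               start_bp = numeric(), end_bp = numeric(), n_snp = integer(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("candidate_haplotypes", "data.frame")
  res
}

#' Manhattan-style plot of per-SNP ROH frequencies
#'
#' One panel per group, SNPs in genome order coloured by chromosome, with a
#' dashed line at the consensus-haplotype frequency cutoff.
#'
#' @param freqs output of [snp_run_frequency()].
#' @param min_freq cutoff line position (default 0.75).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `freqs`.
#' @export
plot_roh_frequency <- function(freqs, min_freq = 0.75, ...) {
  groups <- unique(freqs$group)
  op <- graphics::par(mfrow = c(length(groups), 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  for (g in groups) {
    fg <- freqs[freqs$group == g, ]
    chrom_f <- factor(fg$chrom, levels = unique(fg$chrom))
    graphics::plot(seq_len(nrow(fg)), fg$frequency, pch = 16, cex = 0.4,
                   col = c("grey40", "steelblue")[(as.integer(chrom_f) %% 2) + 1],
                   xlab = "SNP (genome order)", ylab = "ROH frequency",
                   main = paste(g, "fecundity"), ylim = c(0, 1), ...)
    graphics::abline(h = min_freq, lty = 2, col = "goldenrod")
  }
  invisible(freqs)
}
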