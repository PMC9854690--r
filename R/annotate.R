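#' Build candidate regions around candidate SNPs and haplotypes
#'
#' Candidate SNPs are flanked symmetrically by `flank` bp; candidate
#' haplotypes are flanked outward from their bp span. Regions are clipped at
#' position 1 and, by default, overlapping regions sharing the same
#' (method, group) are merged so one gene is not reported once per adjacent
#' candidate SNP.
#'
#' @param candidates a `candidate_snps` data frame (columns `id`, `chrom`,
#'   `bp`, `method`), a `candidate_haplotypes` data frame (columns `group`,
#'   `chrom`, `start_bp`, `end_bp`), or a list of several such objects.
#' @param flank flanking distance in bp (default 50000).
#' @param group group label attached to SNP candidates (haplotype
#'   candidates carry their own); default `"high"`.
#' @param merge merge overlapping same-(method, group) regions
#'   (default `TRUE`; set `FALSE` for per-source auditing).
#' @return data frame of class `candidate_regions`: `chrom`, `start`, `end`
#'   (1-based inclusive), `source`, `group`, `method`.
#' @export
build_regions <- function(candidates, flank = 50000, group = "high", merge = TRUE) {
  if (flank < 0) .stopf("flank must be >= 0")
  if (!is.data.frame(candidates) && is.list(candidates)) {
    parts <- lapply(candidates, build_regions, flank = flank, group = group,
                    merge = merge)
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    class(out) <- c("candidate_regions", "data.frame")
    return(out)
  }

  if (!is.null(candidates$bp) && is.null(candidates$start_bp)) {
    # SNP candidates
    raw <- data.frame(
      chrom = as.character(candidates$chrom),
      start = pmax(1, candidates$bp - flank),
      end = candidates$bp + flank,
      source = candidates$id,
      group = if (!is.null(candidates$group)) candidates$group else group,
      method = if (!is.null(candidates$method)) candidates$method else "FST",
      stringsAsFactors = FALSE)
  } else if (!is.null(candidates$start_bp)) {
    # haplotype candidates
    raw <- data.frame(
      chrom = as.character(candidates$chrom),
      start = pmax(1, candidates$start_bp - flank),
      end = candidates$end_bp + flank,
      source = paste0(candidates$start_snp, "..", candidates$end_snp),
      group = candidates$group,
      method = "ROH",
      stringsAsFactors = FALSE)
  } else {
    .stopf("candidates must carry bp coordinates (bp or start_bp/end_bp)")
  }

  if (merge && nrow(raw) > 1) {
    key <- paste(raw$method, raw$group, sep = "/")
    merged <- lapply(split(raw, key), function(d) {
      gr <- GenomicRanges::GRanges(d$chrom,
                                   IRanges::IRanges(d$start, d$end))
      red <- GenomicRanges::reduce(gr)
      hits <- GenomicRanges::findOverlaps(red, gr)
      src <- vapply(seq_along(red), function(i)
        paste(d$source[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]],
              collapse = ","), "")
      data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                 start = GenomicRanges::start(red), end = GenomicRanges::end(red),
                 source = src, group = d$group[1], method = d$method[1],
                 stringsAsFactors = FALSE)
    })
    raw <- do.call(rbind, merged)
  }
  rownames(raw) <- NULL
  class(raw) <- c("candidate_regions", "data.frame")
  raw
}

#' Intersect candidate regions with a gene annotation
#'
#' A gene is reported for every candidate region its 1-based inclusive
#' interval overlaps by at least `min_overlap` bp (closed-interval overlap,
#' default 1 bp). Each hit is annotated with the region's method and
#' fecundity group; duplicate (gene, method, group) rows are collapsed.
#'
#' @param regions a [build_regions()] result.
#' @param genes gene records (data frame `gene`, `chrom`, `start`, `end`),
#'   e.g. from [read_gene_annotation()].
#' @param min_overlap minimum overlap in bp (default 1 = any overlap).
#' @return data frame of class `candidate_gene_table`: `gene`, `method`,
#'   `group`, `chrom`, `position` (gene start bp).
#' @export
intersect_genes <- function(regions, genes, min_overlap = 1) {
  empty <- data.frame(gene = character(), method = character(),
                      group = character(), chrom = character(),
                      position = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("candidate_gene_table", "data.frame")
  if (nrow(regions) == 0 || nrow(genes) == 0) return(empty)

  rch <- unique(as.character(regions$chrom))
  gch <- unique(as.character(genes$chrom))
  if (length(intersect(rch, gch)) == 0)
    .stopf(paste0("no shared chromosome labels between regions and genes; ",
                  "regions use {%s}, genes use {%s}"),
           paste(sort(rch), collapse = ","), paste(sort(gch), collapse = ","))

  rgr <- GenomicRanges::GRanges(as.character(regions$chrom),
                                IRanges::IRanges(regions$start, regions$end))
  ggr <- GenomicRanges::GRanges(as.character(genes$chrom),
                                IRanges::IRanges(genes$start, genes$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(ggr, rgr, minoverlap = min_overlap))
  if (length(hits) == 0) return(empty)

  gi <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)
  out <- data.frame(gene = genes$gene[gi],
                    method = regions$method[ri],
                    group = regions$group[ri],
                    chrom = as.character(genes$chrom[gi]),
                    position = genes$start[gi],
                    stringsAsFactors = FALSE)
  out <- unique(out)
  num <- suppressWarnings(as.numeric(out$chrom))
  key <- if (anyNA(num)) order(out$method, out$group, out$chrom, out$position)
  else order(out$method, out$group, num, out$position)
  out <- out[key, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_gene_table", "data.frame")
  out
}

#' Summarise the candidate-gene table
#'
#' Row counts of the candidate-gene table by (method, fecundity group) and
#' totals per group across methods.
#'
#' @param table a [intersect_genes()] result (or any data frame with
#'   `gene`, `method`, `group` columns).
#' @return list with `by_method_group` (data frame `method`, `group`, `n`)
#'   and `group_totals` (named vector).
#' @export
summarize_counts <- function(table) {
  if (nrow(table) == 0) {
    return(list(by_method_group = data.frame(method = character(),
                                             group = character(), n = integer()),
                group_totals = integer(0)))
  }
  tab <- as.data.frame(base::table(method = table$method, group = table$group),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tab <- tab[tab$n > 0, , drop = FALSE]
  tab <- tab[order(tab$group, tab$method), , drop = FALSE]
  rownames(tab) <- NULL
  totals <- vapply(split(table, table$group), nrow, 0L)
  list(by_method_group = tab, group_totals = totals)
}

#' Example candidate-gene table for Katahdin ewes
#'
#' The candidate-gene set for fecundity in Katahdin ewes bundled with the
#' package (`inst/extdata/katahdin_candidate_genes.tsv`): 22 genes on sheep
#' chromosomes 3, 5, 6, 16, 21 and 25, each tagged with the detection method
#' (FST or ROH) and the fecundity group it was associated with, plus a free
#' text function summary. Useful as a worked input for
#' [summarize_counts()] and as a template for the table this pipeline emits.
#'
#' @return a `candidate_gene_table` data frame.
#' @export
katahdin_candidate_genes <- function() {
  path <- system.file("extdata", "katahdin_candidate_genes.tsv",
                      package = "fecundscan")
  tab <- read_result_tsv(path)
  tab$chrom <- as.character(tab$chrom)
  class(tab) <- c("candidate_gene_table", "data.frame")
  tab
}
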