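#' Read genotypes from PED/MAP text files
#'
#' Parses the classic whitespace-delimited PED/MAP pair (one PED row per
#' individual: family id, individual id, father, mother, sex, phenotype,
#' then two allele columns per marker) into an individuals x markers matrix
#' of alt-allele counts.
#'
#' For every marker an allele dictionary is built from the data itself: the
#' first non-missing allele encountered (scanning individuals in file order,
#' first allele column before the second) becomes the reference allele, the
#' next distinct allele the alternate. Genotypes are coded 0/1/2 as the count
#' of alternate alleles; `0 0` becomes `NA`. All downstream statistics
#' (homozygosity, MAF, fixation indices) are invariant to which allele is
#' called reference.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file (columns: chromosome, marker id,
#'   genetic distance, bp position).
#' @return list with elements `genotypes` (integer matrix, individual ids as
#'   rownames, marker ids as colnames, `NA` = missing) and `map` (data frame
#'   with columns `chrom`, `id`, `bp`, `ref`, `alt`; 1-based positions).
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) .stopf("PED file not found: %s", ped_path)
  if (!file.exists(map_path)) .stopf("MAP file not found: %s", map_path)

  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "bp"))
  map <- data.frame(chrom = as.character(map$chrom), id = as.character(map$id),
                    bp = as.numeric(map$bp), stringsAsFactors = FALSE)
  if (anyDuplicated(map$id)) .stopf("duplicate marker ids in MAP: %s",
                                    map$id[duplicated(map$id)][1])
  if (any(map$bp < 1)) .stopf("MAP positions must be >= 1")
  for (ch in unique(map$chrom)) {
    p <- map$bp[map$chrom == ch]
    if (any(diff(p) <= 0))
      .stopf("MAP positions not strictly increasing on chromosome %s", ch)
  }
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0) .stopf("PED file is empty: %s", ped_path)

  toks <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(toks)
  bad <- which(len != 6L + 2L * m)
  if (length(bad))
    .stopf("PED line %d has %d fields, expected %d (6 + 2 x %d markers)",
           bad[1], len[bad[1]], 6L + 2L * m, m)

  tokm <- matrix(unlist(toks), nrow = n, byrow = TRUE)
  ids <- tokm[, 2]
  a1 <- tokm[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- tokm[, 6L + 2L * seq_len(m), drop = FALSE]

  geno <- matrix(NA_integer_, n, m, dimnames = list(ids, map$id))
  ref <- alt <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    # interleave so "first seen" follows file order within an individual
    v <- as.vector(rbind(a1[, j], a2[, j]))
    seen <- unique(v[v != "0"])
    if (length(seen) > 2L)
      .stopf("marker %s has more than two alleles (%s)", map$id[j],
             paste(seen, collapse = ", "))
    ref[j] <- if (length(seen) >= 1L) seen[1] else NA_character_
    alt[j] <- if (length(seen) == 2L) seen[2] else NA_character_
    miss <- a1[, j] == "0" | a2[, j] == "0"
    code <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
    code[is.na(code)] <- 0L  # monomorphic marker: everything is ref
    code[miss] <- NA_integer_
    geno[, j] <- as.integer(code)
  }
  map$ref <- ref
  map$alt <- alt
  list(genotypes = geno, map = map)
}

#' Write genotypes to PED/MAP text files
#'
#' Inverse of [read_ped_map()]. Codes 0/1/2 become ref/ref, ref/alt and
#' alt/alt allele pairs using the `ref`/`alt` letters in `map`; missing
#' genotypes are written as `0 0`. PED/MAP carry no comment header (the
#' format does not allow one); provenance headers are written on the TSV
#' outputs instead.
#'
#' @param genotypes integer matrix of alt-allele counts (`NA` = missing).
#' @param map marker map data frame (`chrom`, `id`, `bp`, and optionally
#'   `ref`/`alt`; defaults A/B).
#' @param ped_path,map_path output file paths.
#' @return invisibly, a list of the two paths.
#' @export
write_ped_map <- function(genotypes, map, ped_path, map_path) {
  stopifnot(ncol(genotypes) == nrow(map))
  ref <- if (!is.null(map$ref)) map$ref else rep("A", nrow(map))
  alt <- if (!is.null(map$alt)) map$alt else rep("B", nrow(map))
  ref[is.na(ref)] <- "A"
  alt[is.na(alt)] <- "B"

  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- sprintf("IND%04d", seq_len(nrow(genotypes)))
  lines <- character(nrow(genotypes))
  for (i in seq_len(nrow(genotypes))) {
    g <- genotypes[i, ]
    x1 <- ifelse(is.na(g), "0", ifelse(g == 2L, alt, ref))
    x2 <- ifelse(is.na(g), "0", ifelse(g >= 1L, alt, ref))
    lines[i] <- paste(c(ids[i], ids[i], "0", "0", "0", "-9",
                        as.vector(rbind(x1, x2))), collapse = " ")
  }
  writeLines(lines, ped_path)
  utils::write.table(data.frame(map$chrom, map$id, 0L, map$bp),
                     map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(list(ped = ped_path, map = map_path))
}

#' Read a gene annotation (GFF3 or BED)
#'
#' Returns gene records with 1-based inclusive coordinates. BED input
#' (0-based half-open) is converted at this boundary; GFF3 input is filtered
#' to features of type `gene`.
#'
#' @param path annotation file path.
#' @param format `"gff3"` or `"bed"`.
#' @return data frame with columns `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("annotation file not found: %s", path)
  lines <- readLines(path)
  content <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  empty <- data.frame(gene = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE)
  if (length(content) == 0) return(empty)

  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  if (length(gr) == 0) return(empty)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (format == "gff3") {
    if (!is.null(df$type)) df <- df[as.character(df$type) == "gene", , drop = FALSE]
    if (nrow(df) == 0) return(empty)
    nm <- df$Name
    if (is.null(nm)) nm <- rep(NA_character_, nrow(df))
    nm <- ifelse(is.na(nm) | !nzchar(nm),
                 if (!is.null(df$ID)) df$ID else NA_character_, nm)
  } else {
    nm <- if (!is.null(df$name)) df$name else sprintf("gene%04d", seq_len(nrow(df)))
  }
  data.frame(gene = as.character(nm), chrom = as.character(df$seqnames),
             start = as.numeric(df$start), end = as.numeric(df$end),
             strand = as.character(df$strand), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write gene records as a BED annotation
#'
#' Converts the internal 1-based inclusive records back to BED's 0-based
#' half-open convention on write.
#'
#' @param genes data frame with `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `strand`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  if (nrow(genes) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = if (!is.null(genes$strand) && all(genes$strand %in% c("+", "-", "*")))
      genes$strand else "*")
  gr$name <- genes$gene
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read or write the phenotype table
#'
#' Tab-separated, one row per ewe (or ewe-year), columns `id`, `year`, `age`,
#' `body_condition`, `hours_estrus`, `n_births`, `fecundity`. Lines beginning
#' with `#` are provenance comments.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_phenotypes <- function(path) {
  ph <- read_result_tsv(path)
  need <- c("id", "year", "age", "body_condition", "hours_estrus",
            "n_births", "fecundity")
  missing_cols <- setdiff(need, names(ph))
  if (length(missing_cols))
    .stopf("phenotype table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  ph$id <- as.character(ph$id)
  ph
}
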