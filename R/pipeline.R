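#' Pipeline configuration
#'
#' Collects every stage parameter of the scan with the standard defaults:
#' QC thresholds MAF 0.05 / HWE p 1e-6 / call rate 0.90; ROH sliding-window
#' parameters windowSize 15, threshold 0.05, minSNP 20, maxOppWindow 1,
#' maxMissWindow 1; consensus-haplotype rules min_freq 0.75 and min_snps 3;
#' candidate flank 50 kb; top fraction 0.20; k = 2 groups, complete linkage.
#'
#' @param sim a [sim_config()] object for simulated input, or `NULL` when
#'   `ped`/`map_file`/`phenotype_file`/`annotation_file` point at real data.
#' @param ped,map_file,phenotype_file,annotation_file input file paths
#'   (ignored when `sim` is given).
#' @param annotation_format `"bed"` or `"gff3"`.
#' @param maf_min,hwe_p_min,call_rate_min,hwe_exclude QC thresholds, see
#'   [apply_qc()].
#' @param roh a [roh_params()] object.
#' @param hap_min_freq,hap_min_snps consensus haplotype rules, see
#'   [call_candidate_haplotypes()].
#' @param fst_stat,top_fraction candidate-SNP selection, see
#'   [select_candidates()].
#' @param flank candidate-region flank in bp.
#' @param k,linkage group clustering, see [assign_groups()].
#' @param n_components PCA components.
#' @param n_genes background genes for the simulated annotation.
#' @param seed integer seed for the simulated stages.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            ped = NULL, map_file = NULL,
                            phenotype_file = NULL, annotation_file = NULL,
                            annotation_format = "bed",
                            maf_min = 0.05, hwe_p_min = 1e-6,
                            call_rate_min = 0.90, hwe_exclude = "below",
                            roh = roh_params(),
                            hap_min_freq = 0.75, hap_min_snps = 3,
                            fst_stat = "theta", top_fraction = 0.20,
                            flank = 50000, k = 2, linkage = "complete",
                            n_components = 2, n_genes = 300,
                            seed = if (!is.null(sim)) sim$seed else 1L) {
  cfg <- list(sim = sim, ped = ped, map_file = map_file,
              phenotype_file = phenotype_file,
              annotation_file = annotation_file,
              annotation_format = annotation_format,
              maf_min = maf_min, hwe_p_min = hwe_p_min,
              call_rate_min = call_rate_min, hwe_exclude = hwe_exclude,
              roh = roh, hap_min_freq = hap_min_freq,
              hap_min_snps = hap_min_snps, fst_stat = fst_stat,
              top_fraction = top_fraction, flank = flank, k = k,
              linkage = linkage, n_components = n_components,
              n_genes = n_genes, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

# stable short hash of the configuration (md5 of its deparsed form)
.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "sim")]), tmp)
  substr(unname(tools::md5sum(tmp)), 1, 8)
}

#' Run the full selection-signature scan
#'
#' Executes the stages in order — simulate (when `config$sim` is set) or
#' read inputs; marker QC; phenotype adjustment and group assignment; PCA;
#' ROH detection, per-SNP frequencies and consensus haplotypes; per-SNP
#' fixation-index scan and top-quantile candidates; candidate regions and
#' gene intersection — and writes every result table to `outdir` as TSV
#' stamped with the package version, seed and configuration hash. Reruns
#' with the same configuration are bit-identical.
#'
#' @param config a [pipeline_config()] object.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with all intermediate and final objects:
#'   `sim`, `genotypes`, `map`, `qc`, `fit`, `groups`, `pca`, `runs`,
#'   `roh_freq`, `haplotypes`, `fst`, `fst_candidates`, `regions`,
#'   `candidate_genes`, `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("fecundscan_")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  seed <- config$seed
  emit <- function(x, name) write_result_tsv(x, file.path(outdir, name),
                                             seed = seed, config_hash = hash)

  # ---- inputs ----
  if (!is.null(config$sim)) {
    sim <- simulate_population(config$sim)
    write_ped_map(sim$genotypes, sim$map,
                  file.path(outdir, "genotypes.ped"),
                  file.path(outdir, "genotypes.map"))
    io <- read_ped_map(file.path(outdir, "genotypes.ped"),
                       file.path(outdir, "genotypes.map"))
    genotypes <- io$genotypes; map <- io$map
    phenotypes <- sim$phenotypes
    genes <- simulate_gene_annotation(
      map, n_genes = config$n_genes, seed = seed + 1L,
      ensure_overlap = if (nrow(sim$truth$planted_roh_regions)) data.frame(
        chrom = as.character(sim$truth$planted_roh_regions$chrom),
        start_bp = sim$truth$planted_roh_regions$start_bp,
        end_bp = sim$truth$planted_roh_regions$end_bp) else NULL)
    # also guarantee a gene at each planted differentiated locus
    if (length(sim$truth$planted_diff_snp_ids)) {
      i <- match(sim$truth$planted_diff_snp_ids, map$id)
      dg <- data.frame(gene = sprintf("PLANTED_DIFF_%02d", seq_along(i)),
                       chrom = map$chrom[i],
                       start = pmax(1, map$bp[i] - 5000),
                       end = map$bp[i] + 5000, strand = "+",
                       stringsAsFactors = FALSE)
      genes <- rbind(genes, dg)
    }
    write_gene_annotation(genes, file.path(outdir, "genes.bed"))
    emit(phenotypes, "phenotypes.tsv")
    emit(sim$truth$planted_roh_regions, "truth_planted_roh.tsv")
    emit(data.frame(id = sim$truth$planted_diff_snp_ids), "truth_planted_diff_snps.tsv")
    emit(sim$truth$qc_fail_snps, "truth_qc_fail.tsv")
  } else {
    sim <- NULL
    for (f in c(config$ped, config$map_file, config$phenotype_file,
                config$annotation_file))
      if (!file.exists(f)) .stopf("input file not found: %s", f)
    io <- read_ped_map(config$ped, config$map_file)
    genotypes <- io$genotypes; map <- io$map
    phenotypes <- read_phenotypes(config$phenotype_file)
    genes <- read_gene_annotation(config$annotation_file,
                                  format = config$annotation_format)
  }

  # ---- marker QC ----
  qc <- apply_qc(genotypes, maf_min = config$maf_min,
                 hwe_p_min = config$hwe_p_min,
                 call_rate_min = config$call_rate_min,
                 hwe_exclude = config$hwe_exclude)
  genotypes <- qc$genotypes
  map_qc <- map[map$id %in% colnames(genotypes), , drop = FALSE]
  emit(qc$report$stats, "qc_report.tsv")

  # ---- phenotype adjustment and groups ----
  pheno1 <- aggregate_phenotypes(phenotypes)
  screen <- screen_covariates(pheno1)
  fit <- fit_final_model(pheno1)
  groups <- assign_groups(fit$fitted, k = config$k, linkage = config$linkage)
  emit(data.frame(id = pheno1$id, adjusted = unname(fit$fitted)),
       "adjusted_phenotypes.tsv")
  emit(groups$assignments, "groups.tsv")
  writeLines(groups$newick, file.path(outdir, "dendrogram.nwk"))

  # ---- PCA ----
  pca <- run_pca(genotypes, n_components = config$n_components)
  overlay <- group_overlay(pca, groups)
  emit(overlay, "pca_scores.tsv")

  # ---- ROH scan ----
  runs <- detect_runs(genotypes, map_qc, config$roh)
  roh_freq <- snp_run_frequency(runs, groups, map_qc)
  haplotypes <- call_candidate_haplotypes(roh_freq, map_qc,
                                          min_freq = config$hap_min_freq,
                                          min_snps = config$hap_min_snps)
  emit(runs, "roh_runs.tsv")
  emit(roh_freq, "roh_snp_frequency.tsv")
  emit(haplotypes, "candidate_haplotypes.tsv")

  # ---- FST scan ----
  fst <- fst_scan(genotypes, groups, map_qc)
  fst_candidates <- select_candidates(fst, fraction = config$top_fraction,
                                      stat = config$fst_stat)
  emit(fst, "fst_scan.tsv")
  emit(fst_candidates, "fst_candidates.tsv")

  # ---- candidate regions and genes ----
  regions <- build_regions(list(fst_candidates, haplotypes), flank = config$flank)
  candidate_genes <- intersect_genes(regions, genes)
  summary <- summarize_counts(candidate_genes)
  emit(regions, "candidate_regions.tsv")
  write_gene_annotation(
    data.frame(gene = paste0(regions$method, "/", regions$group),
               chrom = regions$chrom, start = regions$start,
               end = regions$end, strand = "*"),
    file.path(outdir, "candidate_regions.bed"))
  emit(candidate_genes, "candidate_genes.tsv")

  invisible(list(sim = sim, genotypes = genotypes, map = map_qc, qc = qc$report,
                 screen = screen, fit = fit, groups = groups, pca = pca,
                 runs = runs, roh_freq = roh_freq, haplotypes = haplotypes,
                 fst = fst, fst_candidates = fst_candidates, regions = regions,
                 candidate_genes = candidate_genes, summary = summary,
                 genes = genes, outdir = outdir, config_hash = hash))
}
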