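#' Run the full inference chain on synthetic data
#'
#' End-to-end demonstration and integration check of the pipeline on a
#' synthetic two-haplotype line (an I2-like and an I8-like haplotype
#' segregating 50/50): simulate serotyped birds, pool them in the 5 x 3
#' design and scan pool intensities, confirm the peak with an individual
#' case/control scan, reduce peak variants to candidate genes with the
#' impact + membrane + frequency-contrast rules, genotype the panel and score
#' serology concordance, and call the deletion from a short-haplotype
#' carrier's depth track.  Every stage is reproducible from the config seed;
#' rerunning with the same config yields identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param dir Output directory for stage TSVs and the run manifest
#'   (default: a fresh temporary directory).
#' @param quiet Suppress stage messages.
#' @return A list with the per-stage results: `pool_gwas`, `region`,
#'   `case_control`, `candidates`, `concordance`, `deletion`, `exon_overlap`,
#'   `manifest`.
#' @export
run_demo_pipeline <- function(config = pipeline_config(), dir = tempfile("serohap_run_"),
                              quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  panel <- rhce_panel()
  allele_map <- list(I2 = "H02", I8 = "H01")

  # -- simulate the line ------------------------------------------------
  cfg <- line_config("SYN1", c(H01 = 0.5, H02 = 0.5), config$n_samples,
                     serology_error_model(), seed = config$seed)
  sim <- simulate_line(cfg, panel, allele_map)
  say("simulate: %d samples, %d serological classes", nrow(sim$truth),
      length(unique(sim$truth$serology_recorded)))

  # -- pooled-DNA scan --------------------------------------------------
  causal <- cbind(sim$truth$hapA == "H02", sim$truth$hapB == "H02") * 1L
  gc <- genome_config(n_background_snps = config$n_background_snps)
  geno <- simulate_array_genotypes(causal, gc, sample_ids = sim$truth$sample_id,
                                   seed = config$seed + 1L)
  pools <- simulate_pools(geno$geno, sim$truth$serology_recorded,
                          class_counts = c(`I8/I8` = 0, `I2/I8` = 1, `I2/I2` = 2),
                          seed = config$seed + 2L)
  pg <- run_pool_gwas(pools$pools, pools$theta, geno$snps,
                      qc = do.call(qc_config, config$pool_qc))
  region <- top_region(pg, window_bp = 2e5)
  say("pool scan: top SNP %s (r2 = %.3f)", pg$snp_id[1], pg$r2[1])

  # -- individual case/control scan ------------------------------------
  cases <- sim$truth$sample_id[sim$truth$serology_recorded == "I2/I2"]
  controls <- sim$truth$sample_id[sim$truth$serology_recorded != "I2/I2"]
  cc <- run_case_control(geno, cases, controls, qc = do.call(assoc_qc, config$assoc))
  say("case/control: %d significant SNP(s) at -log10 threshold %.3f",
      sum(cc$significant), attr(cc, "threshold"))

  # -- candidate-gene filter -------------------------------------------
  genes <- demo_gene_set(gc)
  variants <- demo_variants(geno, sim$truth, genes)
  cand <- candidate_genes(variants, genes, region, hi = config$contrast_hi)
  say("candidates: %s", if (nrow(cand)) paste(cand$gene_id, collapse = ", ") else "none")

  # -- panel genotyping and concordance --------------------------------
  dip <- apply(sim$panel_calls, 1, function(cv) {
    dc <- call_diplotype(cv, panel, haplotypes = c("H01", "H02"))
    if (dc$unique) dc$compatible_pairs[[1]] else c(NA_character_, NA_character_)
  })
  samples <- data.frame(line_id = "SYN1", serology = sim$truth$serology_recorded,
                        hapA = dip[1, ], hapB = dip[2, ],
                        ambiguous = is.na(dip[1, ]), stringsAsFactors = FALSE)
  conc <- concordance(samples, allele_map)
  say("concordance: %d%% overall", conc$aggregate_overall$overall_pct)

  # -- deletion scan ----------------------------------------------------
  cc_cov <- coverage_config()
  track <- simulate_coverage(2, cc_cov, sample_id = "SYN1_del_hom",
                             seed = config$seed + 3L)
  rt <- normalize_depth(track, flank = c(cc_cov$region[1], cc_cov$deletion_span[1] - 1000))
  del <- do.call(call_deletion, c(list(rt), config$deletion))
  ov <- exon_overlap(del, rhce_exon_model())
  say("deletion: %s %d bp, %d exon(s) fully deleted", del$copy_class, del$length,
      ov$n_fully_deleted)

  # -- artifacts ---------------------------------------------------------
  utils::write.table(pg, file.path(dir, "pool_gwas.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(cc), file.path(dir, "case_control.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cand, file.path(dir, "candidate_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(conc$line_overall, file.path(dir, "concordance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(seed = config$seed, n_samples = config$n_samples,
                   n_snps = ncol(geno$geno), n_pools = nrow(pools$pools),
                   top_snp = pg$snp_id[1], top_gene = if (nrow(cand)) cand$gene_id[1] else NA,
                   concordance_pct = conc$aggregate_overall$overall_pct,
                   deletion = del[c("copy_class", "start", "end", "length")],
                   elapsed_s = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  list(pool_gwas = pg, region = region, case_control = cc, candidates = cand,
       concordance = conc, deletion = del, exon_overlap = ov, manifest = manifest,
       dir = dir)
}

# four synthetic genes tiling the causal interval; the causal one is
# membrane-annotated, one decoy is membrane-annotated too
demo_gene_set <- function(gc) {
  mid <- round(mean(gc$causal_interval))
  data.frame(
    gene_id = c("GENE_A", "CAUSAL_MEM", "GENE_C", "DECOY_MEM"),
    chrom = gc$causal_chrom,
    start = c(gc$causal_interval[1], mid - 25000, mid + 30000, gc$causal_interval[2] - 20000),
    end = c(gc$causal_interval[1] + 20000, mid + 25000, mid + 50000, gc$causal_interval[2]),
    go_terms = c("GO:0008150", "GO:0005886,GO:0008150", "GO:0008150", "GO:0005886"),
    stringsAsFactors = FALSE
  )
}

# impact-annotated variants for the causal-region SNPs, with group frequencies
# measured between the opposing recorded homozygote classes
demo_variants <- function(geno, truth, genes) {
  region <- geno$snps[geno$snps$chrom == "23", ]
  g1 <- truth$sample_id[truth$serology_recorded == "I2/I2"]
  g2 <- truth$sample_id[truth$serology_recorded == "I8/I8"]
  fa1 <- group_allele_freq(geno, g1)[region$snp_id]
  fa2 <- group_allele_freq(geno, g2)[region$snp_id]
  gene_of <- vapply(region$pos, function(p) {
    hit <- which(genes$start <= p & genes$end >= p)
    if (length(hit)) genes$gene_id[hit[1]] else NA_character_
  }, "")
  data.frame(chrom = region$chrom, pos = region$pos, ref = region$ref,
             alt = region$alt, gene_id = gene_of,
             impact = ifelse(is.na(gene_of), "MODIFIER", "MODERATE"),
             fa_group1 = unname(fa1), fa_group2 = unname(fa2),
             stringsAsFactors = FALSE)
}
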