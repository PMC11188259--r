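#' Write genotypes to VCF
#'
#' Serialises a `snp_genotypes` object as VCFv4.2 with a GT field (positions
#' 1-based, alt-allele dosage 0/1/2 encoded as `0/0`, `0/1`, `1/1`, missing
#' as `./.`).
#'
#' @param geno A `snp_genotypes` object.
#' @param file Output path (vcfR writes gzip-compressed; use a `.vcf.gz`
#'   name).
#' @return `file`, invisibly.
#' @importClassesFrom vcfR vcfR
#' @export
write_genotypes_vcf <- function(geno, file) {
  snps <- geno$snps
  g <- geno$geno
  fix <- cbind(CHROM = as.character(snps$chrom), POS = as.character(snps$pos),
               ID = snps$snp_id, REF = snps$ref, ALT = snps$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt_body <- apply(g, 1, function(col) {
    out <- code[as.character(col)]
    out[is.na(col)] <- "./."
    out
  })
  if (is.null(dim(gt_body))) gt_body <- matrix(gt_body, nrow = ncol(g))
  colnames(gt_body) <- rownames(g)
  gt <- cbind(FORMAT = "GT", gt_body)
  vcf <- methods::new("vcfR",
                      meta = c("##fileformat=VCFv4.2",
                               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
                      fix = fix, gt = gt)
  vcfR::write.vcf(vcf, file)
  invisible(file)
}

#' Read genotypes from VCF
#'
#' @param file VCF path (plain or gzipped).
#' @return A `snp_genotypes` object with dosages recovered from the GT field.
#' @export
read_genotypes_vcf <- function(file) {
  vcf <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dose <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                 dimnames = list(colnames(gt), vcfR::getID(vcf)))
  code <- c(`0/0` = 0L, `0/1` = 1L, `1/0` = 1L, `1/1` = 2L,
            `0|0` = 0L, `0|1` = 1L, `1|0` = 1L, `1|1` = 2L)
  for (j in seq_len(nrow(gt))) {
    dose[, j] <- unname(code[gt[j, ]])
  }
  snps <- data.frame(snp_id = vcfR::getID(vcf), chrom = vcfR::getCHROM(vcf),
                     pos = vcfR::getPOS(vcf), ref = vcfR::getREF(vcf),
                     alt = vcfR::getALT(vcf), stringsAsFactors = FALSE)
  structure(list(snps = snps, geno = dose), class = "snp_genotypes")
}

#' Read a per-base depth track from bedGraph
#'
#' bedGraph intervals are 0-based half-open; the conversion to the internal
#' 1-based inclusive convention happens here, exactly once, via rtracklayer.
#' Positions not covered by any interval get depth 0.
#'
#' @param file bedGraph path.
#' @param sample_id Label attached to the track.
#' @param build Genome build tag carried on the track (default `"galGal6"`).
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(file, sample_id = NA_character_, build = "galGal6") {
  gr <- rtracklayer::import(file, format = "bedGraph")
  if (length(unique(as.character(GenomicRanges::seqnames(gr)))) != 1) {
    stop("depth track must cover a single chromosome")
  }
  s <- min(GenomicRanges::start(gr))
  e <- max(GenomicRanges::end(gr))
  depth <- numeric(e - s + 1)
  for (i in seq_along(gr)) {
    idx <- (GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]) - s + 1
    depth[idx] <- gr$score[i]
  }
  structure(list(sample_id = sample_id,
                 chrom = as.character(GenomicRanges::seqnames(gr))[1],
                 start = s, depth = depth, build = build),
            class = "coverage_track")
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal depth are collapsed; rtracklayer handles the 1-based
#' inclusive to 0-based half-open conversion on export.
#'
#' @param track A `coverage_track`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_bedgraph <- function(track, file) {
  r <- rle(track$depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(start = track$start + starts - 1,
                                                end = track$start + ends - 1),
                               score = r$values)
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' Write a deletion call as BED plus a 1-based TSV
#'
#' @param calls List of `deletion_call` objects.
#' @param bed_file BED output (0-based half-open, via rtracklayer).
#' @param tsv_file Optional TSV with 1-based inclusive columns.
#' @return `bed_file`, invisibly.
#' @export
write_deletion_bed <- function(calls, bed_file, tsv_file = NULL) {
  d <- do.call(rbind, lapply(calls, function(x) {
    data.frame(chrom = x$chrom, start = x$start, end = x$end, length = x$length,
               copy_class = x$copy_class, sample_id = x$sample_id,
               mean_ratio = x$mean_ratio, stringsAsFactors = FALSE)
  }))
  d <- d[d$copy_class != "NO_DEL", , drop = FALSE]
  gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(start = d$start, end = d$end),
                               name = sprintf("%s_%s", d$sample_id, d$copy_class))
  rtracklayer::export(gr, bed_file, format = "BED")
  if (!is.null(tsv_file)) {
    utils::write.table(d, tsv_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(bed_file)
}

#' Write / read the long-format pool intensity TSV
#'
#' Columns `pool_id`, `snp_id`, `theta`.
#'
#' @param theta Pool x SNP intensity matrix.
#' @param file Path.
#' @return For the writer, `file` invisibly; for the reader, the matrix.
#' @export
write_pool_intensities <- function(theta, file) {
  long <- data.frame(pool_id = rep(rownames(theta), ncol(theta)),
                     snp_id = rep(colnames(theta), each = nrow(theta)),
                     theta = as.vector(theta), stringsAsFactors = FALSE)
  utils::write.table(long, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_pool_intensities
#' @export
read_pool_intensities <- function(file) {
  long <- utils::read.delim(file, stringsAsFactors = FALSE)
  pools <- unique(long$pool_id)
  snps <- unique(long$snp_id)
  theta <- matrix(NA_real_, length(pools), length(snps), dimnames = list(pools, snps))
  theta[cbind(match(long$pool_id, pools), match(long$snp_id, snps))] <- long$theta
  theta
}

#' Pipeline configuration
#'
#' A schema-versioned configuration covering every stage; unknown keys are
#' rejected so that typos cannot silently fall back to defaults, and every
#' stochastic stage takes its seed from here.
#'
#' @param seed Integer master seed.
#' @param pool_qc,assoc Named lists overriding [qc_config()] / [assoc_qc()]
#'   fields.
#' @param contrast_hi Contrast-rule threshold (default 0.9).
#' @param deletion Named list overriding [call_deletion()] thresholds.
#' @param n_samples,n_background_snps Synthetic-cohort dimensions for the
#'   demo pipeline.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, pool_qc = list(), assoc = list(),
                            contrast_hi = 0.9, deletion = list(),
                            n_samples = 240L, n_background_snps = 300L) {
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) stop(sprintf("unknown %s key(s): %s", where, paste(bad, collapse = ", ")))
  }
  check_keys(pool_qc, c("maf_min", "max_missing", "alpha"), "pool_qc")
  check_keys(assoc, c("maf_min", "call_rate_min", "alpha", "m_independent"), "assoc")
  check_keys(deletion, c("tau_hom", "tau_het_low", "tau_het_high", "min_len",
                         "merge_gap", "edge_min", "het_window"), "deletion")
  structure(list(schema_version = 1L, seed = as.integer(seed), pool_qc = pool_qc,
                 assoc = assoc, contrast_hi = contrast_hi, deletion = deletion,
                 n_samples = as.integer(n_samples),
                 n_background_snps = as.integer(n_background_snps)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param file JSON path.
#' @export
read_pipeline_config <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  allowed <- c("schema_version", "seed", "pool_qc", "assoc", "contrast_hi",
               "deletion", "n_samples", "n_background_snps")
  bad <- setdiff(names(x), allowed)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, x[setdiff(names(x), "schema_version")])
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, file) {
  jsonlite::write_json(unclass(config), file, auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}
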