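#' QC configuration for the individual case/control scan
#'
#' Individual genotyping supports a lower MAF threshold and a stricter call
#' rate than pooled intensities.
#'
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param call_rate_min Minimum per-SNP call rate (default 0.99).
#' @param alpha Significance level (default 0.05).
#' @param m_independent Number of independently segregating markers for the
#'   Bonferroni correction; `NULL` (default) uses the post-QC SNP count.
#' @return A list of class `assoc_qc`.
#' @export
assoc_qc <- function(maf_min = 0.05, call_rate_min = 0.99, alpha = 0.05,
                     m_independent = NULL) {
  stopifnot(maf_min >= 0, maf_min <= 1, call_rate_min >= 0, call_rate_min <= 1,
            alpha > 0, alpha < 1)
  structure(list(maf_min = maf_min, call_rate_min = call_rate_min, alpha = alpha,
                 m_independent = m_independent), class = "assoc_qc")
}

#' Allelic chi-square test at one SNP
#'
#' A 1-df chi-square without continuity correction on the 2x2 allele-count
#' table (case/control x B/A allele).  When any expected cell is below 5 the
#' reported p-value falls back to Fisher's exact test (the chi-square
#' statistic is still returned).  A table with a zero margin carries no
#' association information: `chi2 = 0`, `p = 1`.
#'
#' @param case,control Numeric dosage vectors (0/1/2, `NA` = missing).
#' @return A list with `chi2`, `p`, and `table` (the 2x2 allele-count matrix).
#' @export
allelic_test <- function(case, control) {
  case <- case[!is.na(case)]
  control <- control[!is.na(control)]
  if (!length(case) || !length(control)) stop("empty case or control group")
  tab <- rbind(case = c(B = sum(case), A = 2 * length(case) - sum(case)),
               control = c(B = sum(control), A = 2 * length(control) - sum(control)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(chi2 = 0, p = 1, table = tab))
  }
  cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  p <- unname(cs$p.value)
  if (any(cs$expected < 5)) p <- stats::fisher.test(tab)$p.value
  list(chi2 = unname(cs$statistic), p = p, table = tab)
}

#' Bonferroni genome-wide significance threshold
#'
#' @param m Number of independently segregating markers (>= 1).
#' @param alpha Significance level in (0, 1).
#' @return `-log10(alpha / m)`, the threshold on the -log10 p scale.
#' @examples
#' bonferroni_threshold(1)       # 1.30103
#' bonferroni_threshold(50059)   # 6.000512
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (m < 1) stop("m must be a positive integer")
  stopifnot(alpha > 0, alpha < 1)
  -log10(alpha / m)
}

#' Case/control association scan
#'
#' Applies the individual-genotyping QC (MAF and call rate over all tested
#' samples), runs [allelic_test()] per retained SNP and flags SNPs whose
#' `-log10(p)` reaches the Bonferroni threshold.  Output rows are ordered by
#' (chrom, pos).
#'
#' @param geno A `snp_genotypes` object (or a sample x SNP dosage matrix plus
#'   `snps` metadata).
#' @param case_ids,control_ids Disjoint sample-id vectors present in `geno`.
#' @param qc An [assoc_qc()].
#' @param snps SNP metadata when `geno` is a bare matrix.
#' @return Data.frame of class `assoc_result`: `snp_id`, `chrom`, `pos`,
#'   `case_B`, `case_A`, `control_B`, `control_A`, `chi2`, `p`,
#'   `neg_log10_p`, `significant`; the threshold and `m` are attached as
#'   attributes `threshold` and `m_independent`.
#' @export
run_case_control <- function(geno, case_ids, control_ids, qc = assoc_qc(), snps = NULL) {
  if (inherits(geno, "snp_genotypes")) {
    snps <- geno$snps
    geno <- geno$geno
  }
  if (length(intersect(case_ids, control_ids))) stop("case and control groups overlap")
  missing_ids <- setdiff(c(case_ids, control_ids), rownames(geno))
  if (length(missing_ids)) stop("ids not in genotype matrix: ", paste(missing_ids, collapse = ", "))
  g <- geno[c(case_ids, control_ids), , drop = FALSE]
  keep <- qc_filter(g, qc_config(maf_min = qc$maf_min,
                                 max_missing = 1 - qc$call_rate_min,
                                 alpha = qc$alpha), type = "dosage")
  g <- g[, keep, drop = FALSE]
  m <- if (is.null(qc$m_independent)) length(keep) else qc$m_independent
  thr <- bonferroni_threshold(m, qc$alpha)

  res <- lapply(keep, function(s) {
    at <- allelic_test(g[case_ids, s], g[control_ids, s])
    data.frame(snp_id = s, case_B = at$table["case", "B"], case_A = at$table["case", "A"],
               control_B = at$table["control", "B"], control_A = at$table["control", "A"],
               chi2 = at$chi2, p = at$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  meta <- snps[match(out$snp_id, snps$snp_id), ]
  out$chrom <- meta$chrom
  out$pos <- meta$pos
  out$neg_log10_p <- -log10(out$p)
  out$significant <- out$neg_log10_p >= thr
  out <- out[order(out$chrom, out$pos),
             c("snp_id", "chrom", "pos", "case_B", "case_A", "control_B", "control_A",
               "chi2", "p", "neg_log10_p", "significant")]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "m_independent") <- m
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Manhattan-plot coordinates
#'
#' Cumulative genome coordinates in chromosome order for plotting an
#' association scan.
#'
#' @param results Data.frame with `chrom`, `pos` and either `neg_log10_p` or
#'   `p` columns.
#' @return Data.frame with `chrom`, `pos`, `cum_pos` and `neg_log10_p`.
#' @export
manhattan_data <- function(results) {
  if (is.null(results$neg_log10_p)) results$neg_log10_p <- -log10(results$p)
  chroms <- unique(results$chrom[order(suppressWarnings(as.numeric(results$chrom)),
                                       results$chrom)])
  offset <- 0
  out <- list()
  for (ch in chroms) {
    d <- results[results$chrom == ch, ]
    d <- d[order(d$pos), ]
    d$cum_pos <- d$pos + offset
    offset <- max(d$cum_pos)
    out[[ch]] <- d
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("chrom", "pos", "cum_pos", "neg_log10_p")]
}

#' Manhattan plot of an association scan
#'
#' @param results An `assoc_result` or `snp_summary` table.
#' @param threshold Optional horizontal `-log10(p)` line (defaults to the
#'   table's Bonferroni attribute, if any).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, threshold = attr(results, "threshold")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  d <- manhattan_data(results)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$cum_pos, y = .data$neg_log10_p,
                                       colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::labs(x = "cumulative position (bp)", y = expression(-log[10](p)))
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}
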