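#' Recode a diploid genotype as a B-allele count
#'
#' `AA` -> 0, `AB` -> 1, `BB` -> 2; missing calls (`NA`, `""`, `"./."`,
#' `"NN"`, `"--"`) propagate as `NA`.
#'
#' @param call Character vector of genotype calls.
#' @return Integer vector of B-allele dosages with `NA` for missing.
#' @export
recode_genotype <- function(call) {
  out <- rep(NA_integer_, length(call))
  known <- c(AA = 0L, AB = 1L, BA = 1L, BB = 2L)
  is_missing <- is.na(call) | call %in% c("", "./.", "NN", "--")
  idx <- match(call[!is_missing], names(known))
  if (anyNA(idx)) {
    stop("malformed genotype call: ", call[!is_missing][which(is.na(idx))[1]])
  }
  out[!is_missing] <- known[idx]
  out
}

#' QC configuration for the pooled scan
#'
#' @param maf_min Minimum minor allele frequency (default 0.1, inclusive).
#' @param max_missing Maximum missing fraction (default 0.1, inclusive).
#' @param alpha Significance level carried through to reporting (default 0.05).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(maf_min = 0.1, max_missing = 0.1, alpha = 0.05) {
  stopifnot(maf_min >= 0, maf_min <= 1, max_missing >= 0, max_missing <= 1,
            alpha > 0, alpha < 1)
  structure(list(maf_min = maf_min, max_missing = max_missing, alpha = alpha),
            class = "qc_config")
}

#' MAF / missingness filter
#'
#' Retains SNPs with minor allele frequency at or above `maf_min` and missing
#' fraction at or below `max_missing` (both boundaries inclusive).  For a
#' dosage matrix the allele frequency is the mean dosage / 2; for pool
#' intensities, where individual genotypes are unavailable, it is the mean
#' theta across pools; either estimate is folded to <= 0.5.
#'
#' @param x Numeric matrix, samples/pools in rows, SNPs in columns.
#' @param qc A [qc_config()].
#' @param type `"dosage"` (0/1/2 entries) or `"theta"` (pool intensities).
#' @return Character vector of retained SNP (column) names, with a warning
#'   when nothing survives.
#' @export
qc_filter <- function(x, qc = qc_config(), type = c("dosage", "theta")) {
  type <- match.arg(type)
  if (!is.matrix(x) || ncol(x) == 0) stop("empty SNP matrix")
  p <- if (type == "dosage") colMeans(x, na.rm = TRUE) / 2 else colMeans(x, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  miss <- colMeans(is.na(x))
  keep <- maf >= qc$maf_min & miss <= qc$max_missing
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warning("no SNPs pass QC")
  colnames(x)[keep]
}

#' Least-squares score of one SNP in the pooled scan
#'
#' Ordinary least squares of the expected pool allele count (0/1/2, from
#' serology) on the pool intensity, exactly as the scan is defined: the
#' response/explanatory orientation is unusual but harmless, since r-squared
#' and the slope t-test p-value of a simple linear regression are symmetric
#' in the two variables.  Zero-variance input yields `r2 = 0`, `p = 1`.
#'
#' @param expected Numeric vector of expected allele counts per pool.
#' @param theta Numeric vector of pool intensities.
#' @return A list with `r2` (squared Pearson correlation), `p` (two-sided
#'   t-test on the slope, n - 2 df), `slope`, and `n_pools`.
#' @export
fit_snp_regression <- function(expected, theta) {
  n <- length(expected)
  if (length(theta) != n) stop("expected and theta differ in length")
  if (n < 3) stop("need at least 3 pools")
  if (any(!is.finite(theta))) stop("theta must be finite")
  sxx <- sum((theta - mean(theta))^2)
  syy <- sum((expected - mean(expected))^2)
  if (sxx == 0 || syy == 0) {
    return(list(r2 = 0, p = 1, slope = 0, n_pools = n))
  }
  sxy <- sum((theta - mean(theta)) * (expected - mean(expected)))
  slope <- sxy / sxx
  r2 <- sxy^2 / (sxx * syy)
  # slope t-test with n - 2 df via the r <-> t identity
  r2c <- min(r2, 1 - 1e-15)
  tstat <- sqrt(r2c * (n - 2) / (1 - r2c))
  p <- 2 * stats::pt(-tstat, df = n - 2)
  list(r2 = r2, p = p, slope = slope, n_pools = n)
}

#' Pooled-DNA intensity-regression genome scan
#'
#' Scores every retained SNP by regressing the expected pool allele counts on
#' the pool intensities and returns one summary row per SNP, ordered by
#' p-value ascending with ties broken by (chrom, pos).
#'
#' @param pools Pool data.frame with columns `pool_id` and `expected_count`
#'   (as from [simulate_pools()]).
#' @param theta Pool x SNP intensity matrix (rownames matching `pool_id`).
#' @param snps SNP metadata data.frame (`snp_id`, `chrom`, `pos`) covering the
#'   theta columns.
#' @param qc A [qc_config()] applied to theta-based MAF and missingness.
#' @return Data.frame of class `snp_summary`: `snp_id`, `chrom`, `pos`, `r2`,
#'   `p`, `slope`, `n_pools`.
#' @export
run_pool_gwas <- function(pools, theta, snps, qc = qc_config()) {
  if (nrow(pools) < 3) stop("need at least 3 pools")
  if (length(unique(pools$expected_count)) < 2) {
    stop("all pools are in one expected-count class; the regression is undefined")
  }
  theta <- theta[pools$pool_id, , drop = FALSE]
  keep <- qc_filter(theta, qc, type = "theta")
  theta <- theta[, keep, drop = FALSE]

  y <- pools$expected_count
  n <- length(y)
  yc <- y - mean(y)
  xc <- sweep(theta, 2, colMeans(theta))
  sxx <- colSums(xc^2)
  syy <- sum(yc^2)
  sxy <- as.vector(crossprod(xc, yc))
  slope <- ifelse(sxx > 0, sxy / sxx, 0)
  r2 <- ifelse(sxx > 0 & syy > 0, sxy^2 / (sxx * syy), 0)
  r2c <- pmin(r2, 1 - 1e-15)
  tstat <- sqrt(r2c * (n - 2) / (1 - r2c))
  p <- ifelse(sxx > 0 & syy > 0, 2 * stats::pt(-tstat, df = n - 2), 1)

  m <- snps[match(keep, snps$snp_id), ]
  out <- data.frame(snp_id = keep, chrom = m$chrom, pos = m$pos,
                    r2 = unname(r2), p = unname(p), slope = unname(slope),
                    n_pools = n, stringsAsFactors = FALSE)
  out <- out[order(out$p, out$chrom, out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("snp_summary", "data.frame")
  out
}

#' Candidate region around the top-scoring SNP
#'
#' An interval of width `window_bp` centred on the best SNP (minimum p; ties
#' broken by ascending chrom then pos), clipped to chromosome bounds.
#'
#' @param summaries A `snp_summary` data.frame from [run_pool_gwas()].
#' @param window_bp Window width in bp.
#' @param chrom_length Optional upper bound for clipping; when `NULL` only the
#'   lower bound (position 1) is enforced.
#' @return A list with `chrom`, `start`, `end` (1-based inclusive) and
#'   `best_snp`.
#' @export
top_region <- function(summaries, window_bp, chrom_length = NULL) {
  if (!nrow(summaries)) stop("empty summary table")
  ord <- order(summaries$p, summaries$chrom, summaries$pos)
  best <- summaries[ord[1], ]
  start <- best$pos - floor(window_bp / 2)
  end <- start + window_bp - 1
  if (!is.null(chrom_length)) end <- min(end, chrom_length)
  list(chrom = best$chrom, start = max(1, start), end = end, best_snp = best$snp_id)
}
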