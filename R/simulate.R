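#' Serology error model
#'
#' All discrepancy classes seen in real typing data are het/hom confusions:
#' weak antisera fail to distinguish a homozygote from a heterozygote at
#' dilute titres.  The model therefore has two parameters: a true heterozygote
#' is recorded as homozygous for `dominant_allele` with probability
#' `p_het_as_hom`, and a true homozygote is recorded as heterozygous (with the
#' dominant allele as the spurious partner) with probability `p_hom_miscall`.
#'
#' @param p_het_as_hom Probability a true heterozygote is miscalled homozygous.
#' @param dominant_allele Serological allele label receiving the miscall
#'   (e.g. `"I8"`).
#' @param p_hom_miscall Probability a true homozygote is miscalled heterozygous.
#' @return A list of class `serology_error_model`.
#' @export
serology_error_model <- function(p_het_as_hom = 0, dominant_allele = NA_character_,
                                 p_hom_miscall = 0) {
  stopifnot(p_het_as_hom >= 0, p_het_as_hom <= 1, p_hom_miscall >= 0, p_hom_miscall <= 1)
  if ((p_het_as_hom > 0 || p_hom_miscall > 0) && is.na(dominant_allele)) {
    stop("a nonzero error rate requires a dominant_allele label")
  }
  structure(list(p_het_as_hom = p_het_as_hom, dominant_allele = dominant_allele,
                 p_hom_miscall = p_hom_miscall), class = "serology_error_model")
}

#' Configuration of a simulated line
#'
#' @param line_id Line label.
#' @param haplotype_freqs Named numeric vector of haplotype frequencies
#'   (must sum to 1 within 1e-9).
#' @param n_samples Number of birds to draw (>= 1).
#' @param serology_error A [serology_error_model()].
#' @param seed Integer seed; every simulated quantity is reproducible from it.
#' @return A list of class `line_config`.
#' @export
line_config <- function(line_id, haplotype_freqs, n_samples,
                        serology_error = serology_error_model(), seed = 1L) {
  stopifnot(n_samples >= 1)
  if (abs(sum(haplotype_freqs) - 1) > 1e-9) {
    stop("haplotype frequencies must sum to 1 (got ", sum(haplotype_freqs), ")")
  }
  structure(list(line_id = line_id, haplotype_freqs = haplotype_freqs,
                 n_samples = as.integer(n_samples), serology_error = serology_error,
                 seed = as.integer(seed)), class = "line_config")
}

#' Simulate a serotyped, panel-genotyped line
#'
#' Diplotypes are drawn under Hardy--Weinberg from the configured haplotype
#' frequencies (real lines are selected and pedigreed, but HW suffices for
#' testing the inference machinery).  Panel genotype calls are derived with
#' the deletion-masking rules of [expected_genotype()]; true serology comes
#' from the allele map (a haplotype serving several alleles contributes its
#' first mapped allele) and recorded serology applies the error model.
#'
#' @param config A [line_config()].
#' @param panel An [rhce_panel()] (or compatible) haplotype table.
#' @param allele_map Named list: serological allele -> haplotype name vector.
#' @return A list with `truth` (data.frame: `sample_id`, `hapA`, `hapB`,
#'   `serology_true`, `serology_recorded`, `deletion_copies`), `panel_calls`
#'   (n x 15 character matrix) and `serology` (data.frame ready for CSV:
#'   `sample_id`, `line_id`, `allele1`, `allele2`).
#' @export
simulate_line <- function(config, panel, allele_map) {
  stopifnot(inherits(config, "line_config"))
  haps <- names(config$haplotype_freqs)
  unknown <- setdiff(haps, colnames(panel$alleles))
  if (length(unknown)) stop("unknown haplotype name(s): ", paste(unknown, collapse = ", "))
  set.seed(config$seed)
  n <- config$n_samples

  gametes <- matrix(sample(haps, 2 * n, replace = TRUE, prob = config$haplotype_freqs),
                    ncol = 2)
  # canonical unordered pair
  pair <- t(apply(gametes, 1, sort))
  ids <- sprintf("%s_S%04d", config$line_id, seq_len(n))

  calls <- t(vapply(seq_len(n),
                    function(i) expected_genotype(panel, pair[i, 1], pair[i, 2]),
                    character(nrow(panel$snps))))
  rownames(calls) <- ids

  hap2allele <- function(h) {
    a <- names(allele_map)[vapply(allele_map, function(s) h %in% s, TRUE)]
    if (length(a)) a[1] else NA_character_
  }
  al <- matrix(vapply(pair, hap2allele, ""), ncol = 2)
  sero_true <- apply(al, 1, function(x) paste(sort(x), collapse = "/"))

  em <- config$serology_error
  recorded <- t(apply(al, 1, record_serology, em = em, map = allele_map))
  sero_rec <- apply(recorded, 1, function(x) paste(sort(x), collapse = "/"))

  is_short <- apply(panel$alleles == "DEL", 2, any)
  del_copies <- rowSums(matrix(is_short[pair], ncol = 2))

  truth <- data.frame(sample_id = ids, hapA = pair[, 1], hapB = pair[, 2],
                      serology_true = sero_true, serology_recorded = sero_rec,
                      deletion_copies = as.integer(del_copies),
                      stringsAsFactors = FALSE)
  serology <- data.frame(sample_id = ids, line_id = config$line_id,
                         allele1 = recorded[, 1], allele2 = recorded[, 2],
                         stringsAsFactors = FALSE)
  list(truth = truth, panel_calls = calls, serology = serology)
}

record_serology <- function(true_pair, em, map) {
  het <- !is.na(true_pair[1]) && !is.na(true_pair[2]) && true_pair[1] != true_pair[2]
  if (het) {
    if (em$p_het_as_hom > 0 && stats::runif(1) < em$p_het_as_hom) {
      return(c(em$dominant_allele, em$dominant_allele))
    }
  } else if (!anyNA(true_pair)) {
    if (em$p_hom_miscall > 0 && stats::runif(1) < em$p_hom_miscall) {
      partner <- if (true_pair[1] == em$dominant_allele) {
        setdiff(names(map), em$dominant_allele)[1]
      } else {
        em$dominant_allele
      }
      return(sort(c(true_pair[1], partner)))
    }
  }
  sort(true_pair)
}

#' Construct DNA pools and their array intensities
#'
#' Emulates the pooled-DNA design: `n_sets` sets, each of three pools of birds
#' serologically identified as the two opposing homozygote classes and the
#' heterozygote class, with 4--15 birds per pool.  The intensity of a pool at
#' a SNP is modeled as the B-allele signal fraction: the mean over members of
#' (B-allele dosage)/2, plus Gaussian noise clamped to `[0, 1]`.  Members are
#' drawn without replacement within a set and may recur across sets (small
#' synthetic lines could not otherwise fill the design).
#'
#' @param geno Sample x SNP dosage matrix (0/1/2, B-allele copies), rownames =
#'   sample ids.
#' @param serology Character vector of recorded serology per sample (aligned
#'   with `geno` rows).
#' @param class_counts Named vector mapping serology class to expected
#'   B-allele count at the causal locus, e.g. `c(I2I2 = 0, I2I8 = 1, I8I8 = 2)`
#'   (names use the sorted `"a1/a2"` form or plain labels matching `serology`).
#' @param n_sets Number of pool sets (default 5).
#' @param size_range Inclusive range of pool sizes (default `c(4, 15)`).
#' @param sigma Standard deviation of the intensity noise (default 0.03).
#' @param seed Integer seed.
#' @return A list with `pools` (data.frame: `pool_id`, `set_id`, `class`,
#'   `expected_count`, `size`, `member_ids` semicolon-joined) and `theta`
#'   (pool x SNP intensity matrix).
#' @export
simulate_pools <- function(geno, serology, class_counts, n_sets = 5,
                           size_range = c(4, 15), sigma = 0.03, seed = 1L) {
  stopifnot(nrow(geno) == length(serology))
  set.seed(seed)
  classes <- names(class_counts)
  pools <- list()
  theta <- list()
  k <- 0
  for (s in seq_len(n_sets)) {
    used <- character(0)
    for (cl in classes) {
      sizes <- seq(size_range[1], size_range[2])
      size <- sizes[sample.int(length(sizes), 1)]
      avail <- setdiff(rownames(geno)[serology == cl], used)
      if (length(avail) < size) {
        stop(sprintf("insufficient samples of class %s for set %d (need %d, have %d)",
                     cl, s, size, length(avail)))
      }
      members <- sample(avail, size)
      used <- c(used, members)
      k <- k + 1
      pools[[k]] <- data.frame(pool_id = sprintf("set%d_%s", s, cl),
                               set_id = sprintf("set%d", s), class = cl,
                               expected_count = unname(class_counts[cl]),
                               size = size,
                               member_ids = paste(members, collapse = ";"),
                               stringsAsFactors = FALSE)
      base <- colMeans(geno[members, , drop = FALSE] / 2, na.rm = TRUE)
      noise <- if (sigma > 0) stats::rnorm(ncol(geno), 0, sigma) else 0
      theta[[k]] <- pmin(pmax(base + noise, 0), 1)
    }
  }
  pools <- do.call(rbind, pools)
  theta <- do.call(rbind, theta)
  dimnames(theta) <- list(pools$pool_id, colnames(geno))
  list(pools = pools, theta = theta)
}

#' Genome configuration for simulated array genotypes
#'
#' @param n_background_snps Number of unlinked background SNPs (>= 0).
#' @param causal_chrom Chromosome label of the causal locus (default `"23"`).
#' @param causal_interval 1-based inclusive span containing the causal region.
#' @param ld_decay_bp Length scale of the exponential decay of linkage with
#'   the causal locus (`Inf` = perfect LD across the region).
#' @param allele_freq_range Background allele-frequency interval in (0, 1).
#' @param n_region_snps Number of SNPs placed across the causal interval
#'   (default 20, causal SNP at the interval centre).
#' @return A list of class `genome_config`.
#' @export
genome_config <- function(n_background_snps = 300, causal_chrom = "23",
                          causal_interval = c(2.2e6, 2.4e6), ld_decay_bp = 5e4,
                          allele_freq_range = c(0.1, 0.9), n_region_snps = 20) {
  stopifnot(n_background_snps >= 0, causal_interval[1] <= causal_interval[2])
  structure(list(n_background_snps = as.integer(n_background_snps),
                 causal_chrom = causal_chrom, causal_interval = causal_interval,
                 ld_decay_bp = ld_decay_bp, allele_freq_range = allele_freq_range,
                 n_region_snps = as.integer(n_region_snps)),
            class = "genome_config")
}

#' Simulate array genotypes linked to a causal locus
#'
#' Causal-region SNPs are correlated with the causal allele with correlation
#' decaying as `exp(-d / ld_decay_bp)`: each gamete copies the causal allele
#' with that probability and otherwise draws a fresh allele at the causal
#' allele frequency, so marginal frequencies are preserved.  Background SNPs
#' are independent Hardy--Weinberg draws with frequencies uniform on
#' `allele_freq_range`.
#'
#' @param causal_alleles n x 2 0/1 matrix: per-gamete indicator of the
#'   B-associated causal allele (e.g. 1 = I2-bearing haplotype).
#' @param gc A [genome_config()].
#' @param sample_ids Optional row labels.
#' @param seed Integer seed.
#' @return A `snp_genotypes` object: list with `snps` (data.frame `snp_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `causal`) and `geno` (sample x SNP dosage
#'   matrix of B/alt-allele counts).
#' @export
simulate_array_genotypes <- function(causal_alleles, gc, sample_ids = NULL, seed = 1L) {
  stopifnot(inherits(gc, "genome_config"), ncol(causal_alleles) == 2)
  set.seed(seed)
  n <- nrow(causal_alleles)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(n))
  q <- mean(causal_alleles)  # realized causal allele frequency

  causal_pos <- round(mean(gc$causal_interval))
  region_pos <- unique(sort(c(causal_pos,
    round(seq(gc$causal_interval[1], gc$causal_interval[2],
              length.out = max(gc$n_region_snps, 1))))))
  region <- lapply(region_pos, function(p) {
    rho <- if (is.infinite(gc$ld_decay_bp)) 1 else exp(-abs(p - causal_pos) / gc$ld_decay_bp)
    g <- matrix(0L, n, 2)
    for (k in 1:2) {
      copy <- stats::runif(n) < rho
      g[, k] <- ifelse(copy, causal_alleles[, k],
                       as.integer(stats::runif(n) < q))
    }
    rowSums(g)
  })
  region <- do.call(cbind, region)
  colnames(region) <- sprintf("chr%s_%d", gc$causal_chrom, region_pos)

  if (gc$n_background_snps > 0) {
    freqs <- stats::runif(gc$n_background_snps, gc$allele_freq_range[1], gc$allele_freq_range[2])
    bg <- vapply(freqs, function(f) stats::rbinom(n, 2, f), integer(n))
    bg_pos <- seq_len(gc$n_background_snps) * 10000L
    colnames(bg) <- sprintf("chr1_%d", bg_pos)
    geno <- cbind(region, bg)
    snps <- data.frame(snp_id = colnames(geno),
                       chrom = c(rep(gc$causal_chrom, ncol(region)),
                                 rep("1", gc$n_background_snps)),
                       pos = c(region_pos, bg_pos), stringsAsFactors = FALSE)
  } else {
    geno <- region
    snps <- data.frame(snp_id = colnames(geno), chrom = rep(gc$causal_chrom, ncol(region)),
                       pos = region_pos, stringsAsFactors = FALSE)
  }
  snps$ref <- "A"
  snps$alt <- "B"
  snps$causal <- snps$snp_id == sprintf("chr%s_%d", gc$causal_chrom, causal_pos)
  rownames(geno) <- sample_ids
  structure(list(snps = snps, geno = geno), class = "snp_genotypes")
}

#' @export
print.snp_genotypes <- function(x, ...) {
  cat(sprintf("snp_genotypes: %d samples x %d SNPs\n", nrow(x$geno), ncol(x$geno)))
  invisible(x)
}

#' Coverage configuration for depth simulation
#'
#' @param mean_depth_lambda Expected per-base depth of a diploid region
#'   (default 4, i.e. four combined 1x low-pass passes).
#' @param deletion_span 1-based inclusive interval of the deletion.
#' @param region 1-based inclusive simulated window containing the span.
#' @param chrom Chromosome label (default `"23"`).
#' @param build Genome build tag (default `"galGal6"`, the build of the
#'   reported breakpoints).
#' @return A list of class `coverage_config`.
#' @export
coverage_config <- function(mean_depth_lambda = 4,
                            deletion_span = c(2539342, 2545584),
                            region = c(2535000, 2550000),
                            chrom = "23", build = "galGal6") {
  stopifnot(mean_depth_lambda > 0,
            deletion_span[1] >= region[1], deletion_span[2] <= region[2])
  structure(list(mean_depth_lambda = mean_depth_lambda, deletion_span = deletion_span,
                 region = region, chrom = chrom, build = build),
            class = "coverage_config")
}

#' Simulate a per-base depth track over a deletion
#'
#' Depth is Poisson with mean proportional to local copy number:
#' `lambda * copies / 2` inside the deletion span (where `copies = 2 -
#' deletion_copies`) and `lambda` outside.  In noiseless mode the exact
#' expectation is returned instead of a Poisson draw.
#'
#' @param deletion_copies 0, 1 or 2 deleted copies carried by the sample.
#' @param cc A [coverage_config()].
#' @param noiseless If `TRUE`, return expected depth exactly.
#' @param sample_id Sample label.
#' @param seed Integer seed (ignored when noiseless).
#' @return A `coverage_track`: list with `sample_id`, `chrom`, `start`
#'   (1-based position of the first base), `depth` (numeric vector) and
#'   `build`.
#' @export
simulate_coverage <- function(deletion_copies, cc, noiseless = FALSE,
                              sample_id = NA_character_, seed = 1L) {
  stopifnot(inherits(cc, "coverage_config"), deletion_copies %in% 0:2)
  len <- cc$region[2] - cc$region[1] + 1
  lam <- rep(cc$mean_depth_lambda, len)
  idx <- (cc$deletion_span[1]:cc$deletion_span[2]) - cc$region[1] + 1
  lam[idx] <- cc$mean_depth_lambda * (2 - deletion_copies) / 2
  depth <- if (noiseless) {
    lam
  } else {
    set.seed(seed)
    stats::rpois(len, lam)
  }
  structure(list(sample_id = sample_id, chrom = cc$chrom, start = cc$region[1],
                 depth = depth, build = cc$build), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track [%s] %s:%d-%d (%s), mean depth %.2f\n",
              x$sample_id, x$chrom, x$start, x$start + length(x$depth) - 1,
              x$build, mean(x$depth)))
  invisible(x)
}
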