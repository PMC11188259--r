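#' Alternate-allele frequency within a sample group
#'
#' Frequency = alt-allele count / (2 x non-missing samples), per variant.
#' Variants at which every group member is missing get `NA` (and a message),
#' to be skipped downstream.
#'
#' @param geno A `snp_genotypes` object or sample x variant alt-dosage matrix.
#' @param ids Sample ids of the group (non-empty).
#' @return Named numeric vector of alt-allele frequencies.
#' @export
group_allele_freq <- function(geno, ids) {
  if (inherits(geno, "snp_genotypes")) geno <- geno$geno
  if (!length(ids)) stop("empty sample group")
  g <- geno[ids, , drop = FALSE]
  n_obs <- colSums(!is.na(g))
  fa <- ifelse(n_obs > 0, colSums(g, na.rm = TRUE) / (2 * n_obs), NA_real_)
  if (anyNA(fa)) {
    message(sum(is.na(fa)), " variant(s) with all calls missing in the group; frequency undefined")
  }
  fa
}

#' Homozygote-group frequency-contrast rule
#'
#' A variant passes when its alternate-allele frequency is at least `hi` in
#' one serologically opposing homozygote group and exactly zero in the other
#' (zero observed alternate alleles, not merely small: with homozygote groups
#' of modest size an exact zero is attainable and is what the rule demands).
#' The rule is symmetric in the two groups.
#'
#' @param fa1,fa2 Alternate-allele frequencies in the two groups (vectors
#'   recycle).
#' @param hi Lower bound for the high-frequency group (default 0.9,
#'   inclusive).
#' @return Logical vector.
#' @export
contrast_filter <- function(fa1, fa2, hi = 0.9) {
  (fa1 >= hi & fa2 == 0) | (fa2 >= hi & fa1 == 0)
}

#' Candidate genes in a GWAS peak
#'
#' Reduces impact-annotated variants to a ranked candidate-gene list: a gene
#' qualifies when it overlaps the peak interval (any-bp overlap, 1-based
#' inclusive) and owns at least one variant of qualifying impact that passes
#' the frequency-contrast rule.  Genes annotated to the plasma-membrane GO
#' term rank first, then by descending count of passing variants, then by
#' gene id.  Impact labels are consumed as annotated upstream (SnpEff-style),
#' not recomputed.
#'
#' @param variants Data.frame: `chrom`, `pos`, `ref`, `alt`, `gene_id`,
#'   `impact` (`HIGH`/`MODERATE`/`LOW`/`MODIFIER`), `fa_group1`, `fa_group2`.
#' @param genes Data.frame: `gene_id`, `chrom`, `start`, `end`, `go_terms`
#'   (comma-separated GO ids).
#' @param peak List with `chrom`, `start`, `end` (one chromosome), as from
#'   [top_region()].
#' @param impacts Qualifying impact classes (default `HIGH` and `MODERATE`).
#' @param membrane_go GO id marking plasma-membrane localisation
#'   (default `"GO:0005886"`).
#' @param hi Contrast-rule threshold passed to [contrast_filter()].
#' @return Data.frame: `gene_id`, `chrom`, `start`, `end`, `membrane`,
#'   `n_passing`, `passing_variants` (comma-joined `chrom:pos` labels),
#'   ranked; empty when nothing qualifies.
#' @export
candidate_genes <- function(variants, genes, peak, impacts = c("HIGH", "MODERATE"),
                            membrane_go = "GO:0005886", hi = 0.9) {
  defined <- !is.na(variants$fa_group1) & !is.na(variants$fa_group2)
  pass <- defined & variants$impact %in% impacts &
    contrast_filter(variants$fa_group1, variants$fa_group2, hi = hi)

  in_peak <- genes$chrom == peak$chrom & genes$start <= peak$end & genes$end >= peak$start
  g <- genes[in_peak, , drop = FALSE]
  if (!nrow(g)) return(empty_candidates())

  rows <- lapply(seq_len(nrow(g)), function(i) {
    v <- variants[pass & variants$gene_id == g$gene_id[i], , drop = FALSE]
    if (!nrow(v)) return(NULL)
    go <- trimws(strsplit(g$go_terms[i], ",", fixed = TRUE)[[1]])
    data.frame(gene_id = g$gene_id[i], chrom = g$chrom[i], start = g$start[i],
               end = g$end[i], membrane = membrane_go %in% go, n_passing = nrow(v),
               passing_variants = paste(sprintf("%s:%d", v$chrom, v$pos), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty_candidates())
  out <- do.call(rbind, rows)
  out <- out[order(-out$membrane, -out$n_passing, out$gene_id), ]
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(gene_id = character(0), chrom = character(0), start = integer(0),
              end = integer(0), membrane = logical(0), n_passing = integer(0),
              passing_variants = character(0), stringsAsFactors = FALSE)
}
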