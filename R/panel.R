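#' The RHCE 15-SNP haplotype panel
#'
#' Loads the packaged transcription of the RHCE gene-specific SNP panel: 15
#' nonsynonymous SNPs on microchromosome 23 (build GRCg7b positions) and the 16
#' known panel haplotypes H01--H08, H10--H17.  Four "short" haplotypes (H07,
#' H12, H13, H16) carry a genomic deletion of the 3' part of the gene and are
#' recorded as `DEL` over panel SNPs 8--15: an allele-specific PCR assay on a
#' deleted template yields no product.
#'
#' H07 and H16 carry identical panel profiles in the packaged table; the assay
#' cannot distinguish them (they were assigned separately from different line
#' sources), so table validation is run with this duplicate pair allowed and
#' diplotype uniqueness is judged modulo profile-equivalent haplotypes.
#'
#' @param file Path to a panel TSV; defaults to the packaged transcription.
#' @return An object of class `rhce_panel`: a list with elements `snps` (a
#'   data.frame of the 15 panel SNPs: `order_index`, `rsid`, `chrom`, `pos`,
#'   `exon`, `codon_change`, `aa_change`, `ref`, `alt`), `alleles` (a 15 x
#'   n-haplotype character matrix over `REF`/`ALT`/`DEL`), `serology` (named
#'   list mapping haplotype name to its serological allele(s), where known)
#'   and `build` (genome build tag of the SNP positions).
#' @examples
#' panel <- rhce_panel()
#' haplotype_string(panel, "H01")  # all reference alleles
#' @export
rhce_panel <- function(file = system.file("extdata", "rhce_panel.tsv", package = "serohap")) {
  panel <- read_panel_tsv(file)
  sero_file <- file.path(dirname(file), "rhce_serology.tsv")
  if (file.exists(sero_file)) {
    sero <- utils::read.delim(sero_file, comment.char = "#", stringsAsFactors = FALSE)
    panel$serology <- stats::setNames(
      strsplit(sero$serological_alleles, ",", fixed = TRUE),
      sero$haplotype
    )
  }
  errs <- validate_panel(panel, allow_duplicates = list(c("H07", "H16")))
  if (length(errs)) {
    stop("packaged panel failed validation: ", paste(errs, collapse = "; "))
  }
  panel
}

#' Read a haplotype-panel TSV
#'
#' One row per panel SNP; columns `order_index`, `rsid`, `chrom`, `pos`,
#' `exon`, `codon_change`, `aa_change`, `ref`, `alt`, then one column per
#' haplotype holding the base carried, with `-` marking a deleted (no
#' amplification) site.
#'
#' @param file Path to the TSV.
#' @param build Genome build tag attached to positions (default `"GRCg7b"`).
#' @return An `rhce_panel` object (without serology annotations).
#' @export
read_panel_tsv <- function(file, build = "GRCg7b") {
  tab <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  meta_cols <- c("order_index", "rsid", "chrom", "pos", "exon",
                 "codon_change", "aa_change", "ref", "alt")
  missing_cols <- setdiff(meta_cols, names(tab))
  if (length(missing_cols)) {
    stop("panel TSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  hap_cols <- setdiff(names(tab), meta_cols)
  if (!length(hap_cols)) stop("panel TSV has no haplotype columns")
  snps <- tab[meta_cols]
  snps$chrom <- as.character(snps$chrom)

  # translate bases to symbolic REF/ALT/DEL against the per-SNP ref/alt columns
  alleles <- matrix(NA_character_, nrow = nrow(tab), ncol = length(hap_cols),
                    dimnames = list(snps$rsid, hap_cols))
  for (j in seq_along(hap_cols)) {
    base <- as.character(tab[[hap_cols[j]]])
    sym <- ifelse(base == "-", "DEL",
           ifelse(base == snps$ref, "REF",
           ifelse(base == snps$alt, "ALT", NA_character_)))
    bad <- which(is.na(sym))
    if (length(bad)) {
      stop(sprintf("haplotype %s carries base '%s' at %s which is neither ref, alt nor '-'",
                   hap_cols[j], base[bad[1]], snps$rsid[bad[1]]))
    }
    alleles[, j] <- sym
  }
  structure(list(snps = snps, alleles = alleles, serology = list(), build = build),
            class = "rhce_panel")
}

#' Write a haplotype-panel TSV
#'
#' Inverse of [read_panel_tsv()]: symbolic alleles are written back as bases,
#' `DEL` as `-`.
#'
#' @param panel An `rhce_panel` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_panel_tsv <- function(panel, file) {
  out <- panel$snps
  for (h in colnames(panel$alleles)) {
    sym <- panel$alleles[, h]
    out[[h]] <- ifelse(sym == "DEL", "-", ifelse(sym == "REF", panel$snps$ref, panel$snps$alt))
  }
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @export
print.rhce_panel <- function(x, ...) {
  cat(sprintf("RHCE panel: %d SNPs (%s), %d haplotypes (%d with serological annotation)\n",
              nrow(x$snps), x$build, ncol(x$alleles), length(x$serology)))
  invisible(x)
}

#' Validate a haplotype table
#'
#' Checks, without partial acceptance: 15 metadata invariants (positions
#' strictly increasing in panel order, ref != alt), haplotype-name uniqueness,
#' allele symbols restricted to `REF`/`ALT`/`DEL`, deleted entries forming a
#' contiguous trailing block, and (optionally) uniqueness of allele vectors.
#'
#' @param panel An `rhce_panel` object.
#' @param allow_duplicates List of character vectors naming haplotype groups
#'   that are permitted to share an allele vector (the packaged table declares
#'   `c("H07", "H16")`); any other duplication is an error.
#' @return A character vector of violations; `character(0)` when the table is
#'   valid.
#' @export
validate_panel <- function(panel, allow_duplicates = list()) {
  errs <- character(0)
  snps <- panel$snps
  al <- panel$alleles
  if (any(diff(snps$pos) <= 0)) {
    i <- which(diff(snps$pos) <= 0)[1]
    errs <- c(errs, sprintf("positions not strictly increasing at row %d (%s)", i + 1, snps$rsid[i + 1]))
  }
  if (any(snps$ref == snps$alt)) {
    errs <- c(errs, sprintf("ref == alt at %s", snps$rsid[snps$ref == snps$alt][1]))
  }
  if (anyDuplicated(colnames(al))) {
    errs <- c(errs, sprintf("duplicated haplotype name %s",
                            colnames(al)[duplicated(colnames(al))][1]))
  }
  bad_sym <- !al %in% c("REF", "ALT", "DEL")
  if (any(bad_sym)) {
    idx <- which(bad_sym, arr.ind = TRUE)[1, ]
    errs <- c(errs, sprintf("invalid allele symbol at %s / %s",
                            rownames(al)[idx[1]], colnames(al)[idx[2]]))
  }
  for (h in colnames(al)) {
    del <- unname(which(al[, h] == "DEL"))
    if (length(del) && !identical(del, seq.int(min(del), nrow(al)))) {
      errs <- c(errs, sprintf("haplotype %s: DEL entries are not a contiguous trailing block", h))
    }
  }
  key <- apply(al, 2, paste, collapse = "|")
  dup_groups <- split(names(key), key)
  dup_groups <- dup_groups[lengths(dup_groups) > 1]
  allowed <- vapply(allow_duplicates, function(g) paste(sort(g), collapse = "+"), "")
  for (g in dup_groups) {
    if (!paste(sort(g), collapse = "+") %in% allowed) {
      errs <- c(errs, sprintf("haplotypes %s share an identical allele vector",
                              paste(g, collapse = ", ")))
    }
  }
  errs
}

#' Allele string of a haplotype
#'
#' @param panel An `rhce_panel` object.
#' @param hap Haplotype name.
#' @return Character vector of the 15 bases carried (`-` at deleted sites).
#' @export
haplotype_string <- function(panel, hap) {
  sym <- panel$alleles[, match_hap(panel, hap)]
  unname(ifelse(sym == "DEL", "-", ifelse(sym == "REF", panel$snps$ref, panel$snps$alt)))
}

match_hap <- function(panel, hap) {
  i <- match(hap, colnames(panel$alleles))
  if (is.na(i)) stop("unknown haplotype: ", hap)
  i
}

#' Panel genotype expected from a haplotype pair
#'
#' Per SNP: REF/REF -> `RR`, ALT/ALT -> `AA`, REF/ALT -> `RA`.  A site deleted
#' on exactly one haplotype amplifies hemizygously and appears homozygous for
#' the retained allele (`RR` or `AA`); a site deleted on both haplotypes gives
#' no PCR product (`FAIL`).  This masking is why short haplotypes are only
#' directly visible in the homozygous state.
#'
#' @param panel An `rhce_panel` object.
#' @param hapA,hapB Haplotype names (order irrelevant).
#' @return Character vector over `RR`/`RA`/`AA`/`FAIL`, one entry per panel SNP.
#' @export
expected_genotype <- function(panel, hapA, hapB) {
  a <- panel$alleles[, match_hap(panel, hapA)]
  b <- panel$alleles[, match_hap(panel, hapB)]
  combine_alleles(a, b)
}

combine_alleles <- function(a, b) {
  out <- character(length(a))
  both_del <- a == "DEL" & b == "DEL"
  one_del <- xor(a == "DEL", b == "DEL")
  kept <- ifelse(a == "DEL", b, a)
  out[both_del] <- "FAIL"
  out[one_del] <- ifelse(kept[one_del] == "REF", "RR", "AA")
  full <- !both_del & !one_del
  out[full] <- ifelse(a[full] == b[full],
                      ifelse(a[full] == "REF", "RR", "AA"),
                      "RA")
  out
}

#' Call a sample diplotype from panel genotypes
#'
#' Enumerates all unordered haplotype pairs (with repetition) of the table and
#' keeps those whose [expected_genotype()] equals the observed call vector
#' exactly; panel assays are discrete calls, so no error tolerance is applied.
#'
#' Flags:
#' * `unique` -- exactly one compatible pair after collapsing haplotypes with
#'   identical panel profiles (H07/H16 in the packaged table);
#' * `short_ambiguous` -- the compatible set mixes pairs with and without a
#'   deletion ("short") haplotype, i.e. a full/short heterozygote that is
#'   indistinguishable from a full/full genotype;
#' * `novel` -- no pair is compatible and the profile is fully
#'   homozygous-appearing (no `RA` call), in which case the implied allele
#'   string of the putative new haplotype is reported in `inferred` (this is
#'   how H06 and the short haplotypes were recognisable).
#'
#' @param calls Character vector over `RR`/`RA`/`AA`/`FAIL`, one per panel SNP.
#' @param panel An `rhce_panel` object.
#' @param sample_id Optional sample label carried through to the result.
#' @param haplotypes Optional character vector restricting the candidate
#'   haplotypes, e.g. to those known to segregate in the sample's line (an
#'   all-reference full homozygote is otherwise indistinguishable from a
#'   full/short heterozygote); default: all table haplotypes.
#' @return A list of class `diplotype_call` with elements `sample_id`,
#'   `compatible_pairs` (list of sorted name pairs), `unique`,
#'   `short_ambiguous`, `novel`, and `inferred` (symbolic allele vector or
#'   `NULL`).
#' @export
call_diplotype <- function(calls, panel, sample_id = NA_character_, haplotypes = NULL) {
  if (!is.null(haplotypes)) {
    missing_h <- setdiff(haplotypes, colnames(panel$alleles))
    if (length(missing_h)) stop("unknown haplotype(s): ", paste(missing_h, collapse = ", "))
    panel$alleles <- panel$alleles[, haplotypes, drop = FALSE]
  }
  n_snp <- nrow(panel$snps)
  if (length(calls) != n_snp) {
    stop(sprintf("call vector has length %d, panel has %d SNPs", length(calls), n_snp))
  }
  if (!all(calls %in% c("RR", "RA", "AA", "FAIL"))) {
    stop("malformed call vector: entries must be RR, RA, AA or FAIL")
  }
  eg <- expected_genotype_table(panel)
  obs <- paste(calls, collapse = "|")
  hit <- which(eg$key == obs)
  pairs <- eg$pairs[hit]

  # uniqueness modulo profile-equivalent haplotypes
  prof <- apply(panel$alleles, 2, paste, collapse = "|")
  canon <- vapply(colnames(panel$alleles), function(h) {
    names(prof)[match(prof[h], prof)]
  }, "")
  canon_pairs <- unique(vapply(pairs, function(p) {
    paste(sort(canon[p]), collapse = "/")
  }, ""))
  uniq <- length(canon_pairs) == 1

  is_short <- apply(panel$alleles == "DEL", 2, any)
  n_short <- vapply(pairs, function(p) sum(is_short[p]), 0L)
  short_amb <- length(pairs) > 1 && any(n_short > 0) && any(n_short == 0)

  novel <- FALSE
  inferred <- NULL
  if (!length(pairs) && !any(calls == "RA")) {
    inferred <- ifelse(calls == "FAIL", "DEL", ifelse(calls == "RR", "REF", "ALT"))
    del <- which(inferred == "DEL")
    # a plausible novel haplotype must keep any deleted block as a trailing suffix
    if (!length(del) || identical(del, seq(min(del), n_snp))) novel <- TRUE else inferred <- NULL
  }
  structure(list(sample_id = sample_id, compatible_pairs = pairs, unique = uniq,
                 short_ambiguous = short_amb, novel = novel, inferred = inferred),
            class = "diplotype_call")
}

#' @export
print.diplotype_call <- function(x, ...) {
  lab <- if (length(x$compatible_pairs)) {
    paste(vapply(x$compatible_pairs, paste, "", collapse = "/"), collapse = ", ")
  } else if (x$novel) "novel profile" else "no compatible pair"
  cat(sprintf("diplotype call [%s]: %s%s%s\n", x$sample_id, lab,
              if (x$unique) " (unique)" else "",
              if (x$short_ambiguous) " (short-haplotype ambiguity)" else ""))
  invisible(x)
}

# cache the 136-pair expected-genotype dictionary per panel
expected_genotype_table <- function(panel) {
  key <- paste(apply(panel$alleles, 2, paste, collapse = ""), collapse = "+")
  cache <- get0(".eg_cache", envir = .serohap_env)
  if (!is.null(cache) && identical(cache$panel_key, key)) return(cache)
  haps <- colnames(panel$alleles)
  pairs <- list()
  keys <- character(0)
  k <- 0
  for (i in seq_along(haps)) {
    for (j in i:length(haps)) {
      k <- k + 1
      pairs[[k]] <- c(haps[i], haps[j])
      keys[k] <- paste(combine_alleles(panel$alleles[, i], panel$alleles[, j]), collapse = "|")
    }
  }
  cache <- list(panel_key = key, pairs = pairs, key = keys)
  assign(".eg_cache", cache, envir = .serohap_env)
  cache
}

.serohap_env <- new.env(parent = emptyenv())

#' Predict the serological genotype implied by a diplotype call
#'
#' @param call A `diplotype_call` (or a length-2 character vector of haplotype
#'   names, taken as a unique call).
#' @param allele_map Named list: serological allele -> character vector of the
#'   haplotypes it detects, e.g. `list(I2 = "H02", I8 = c("H03", "H04"))`.
#' @return A string `"<a1>/<a2>"` with alleles sorted, or `"unknown"` when a
#'   haplotype has no mapping, or `"ambiguous"` when the call is non-unique or
#'   several serological assignments are possible.
#' @export
predict_serology <- function(call, allele_map) {
  if (is.character(call) && length(call) == 2) {
    pair <- call
  } else {
    if (!inherits(call, "diplotype_call")) stop("call must be a diplotype_call or a name pair")
    if (!call$unique || !length(call$compatible_pairs)) return("ambiguous")
    pair <- call$compatible_pairs[[1]]
  }
  opts <- lapply(pair, function(h) {
    names(allele_map)[vapply(allele_map, function(s) h %in% s, TRUE)]
  })
  if (any(lengths(opts) == 0)) return("unknown")
  combos <- unique(apply(expand.grid(opts[[1]], opts[[2]], stringsAsFactors = FALSE), 1,
                         function(x) paste(sort(x), collapse = "/")))
  if (length(combos) == 1) combos else "ambiguous"
}

#' Epitope classification of a haplotype
#'
#' The four I8-associated haplotypes share a cluster of six variants (L43F
#' through Y147H, panel SNPs 4--9, encoded by exons 2 and 3) that all differ
#' from I2; the encoded residues sit together on the predicted protein
#' exterior and are the likely serological epitope.  A haplotype is `I2-like`
#' when it carries the alternate allele at all six sites, `I8-like` when it is
#' reference at all six, `indeterminate` when the deleted span intrudes, and
#' `other` for any mixed pattern.
#'
#' @param panel An `rhce_panel` object.
#' @param hap Haplotype name.
#' @return One of `"I2-like"`, `"I8-like"`, `"indeterminate"`, `"other"`.
#' @export
epitope_class <- function(panel, hap) {
  span <- which(panel$snps$order_index %in% 4:9)
  sym <- panel$alleles[span, match_hap(panel, hap)]
  if (any(sym == "DEL")) return("indeterminate")
  if (all(sym == "ALT")) return("I2-like")
  if (all(sym == "REF")) return("I8-like")
  "other"
}
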