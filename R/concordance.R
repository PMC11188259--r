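#' Packaged per-line serology x diplotype cross-tabulations
#'
#' The five cross-tabs for the lines with I-system segregation (WL1, WL2,
#' WL7 and the two NIU DNA-bank sets), one count per (serology genotype,
#' diplotype) cell, together with the line-specific allele maps (which
#' haplotypes each line's antisera detect).  Cells the source text does not
#' print at this resolution (NIU heterozygote outcomes, identities of
#' discordant diplotypes) are reconstructed to match the published per-line
#' consistency rates and error mode, and are flagged in the `reconstructed`
#' column.
#'
#' @return A list with `crosstabs` (data.frame: `line_id`, `serology`,
#'   `hapA`, `hapB`, `n`, `reconstructed`) and `allele_maps` (named list of
#'   per-line allele maps).
#' @export
line_crosstabs <- function() {
  tab <- utils::read.delim(system.file("extdata", "line_crosstabs.tsv", package = "serohap"),
                           comment.char = "#", stringsAsFactors = FALSE)
  maps <- jsonlite::read_json(system.file("extdata", "line_allele_maps.json", package = "serohap"),
                              simplifyVector = TRUE)
  maps <- lapply(maps, function(m) lapply(m, as.character))
  list(crosstabs = tab, allele_maps = maps)
}

#' Does a diplotype agree with a serology genotype?
#'
#' TRUE iff the two haplotypes can be assigned to the two serological alleles
#' so that each haplotype belongs to the set its assigned allele detects.
#' Symmetric in both pair orders.
#'
#' @param serology Length-2 character vector of serological alleles (or an
#'   `"a1/a2"` string).
#' @param diplotype Length-2 character vector of haplotype names.
#' @param allele_map Named list: serological allele -> haplotype set.
#' @return Logical scalar.
#' @export
serology_match <- function(serology, diplotype, allele_map) {
  if (length(serology) == 1) serology <- strsplit(serology, "/", fixed = TRUE)[[1]]
  stopifnot(length(serology) == 2, length(diplotype) == 2)
  unmapped <- setdiff(serology, names(allele_map))
  if (length(unmapped)) stop("unmapped serological allele: ", paste(unmapped, collapse = ", "))
  in_set <- function(h, a) h %in% allele_map[[a]]
  (in_set(diplotype[1], serology[1]) && in_set(diplotype[2], serology[2])) ||
    (in_set(diplotype[1], serology[2]) && in_set(diplotype[2], serology[1]))
}

# round half away from zero to integer percent: matches every published figure
round_pct <- function(num, den) {
  if (den == 0) return(NA_real_)
  x <- 100 * num / den
  sign(x) * floor(abs(x) + 0.5)
}

#' Serology-versus-haplotype concordance report
#'
#' Cross-tabulates serology genotypes against called diplotypes, per line and
#' aggregated, with per-class accuracies.  Classes are the serology
#' genotypes; the heterozygote class counts a sample concordant only on an
#' exact genotype match.  Percentages are rounded half away from zero to
#' whole percent.
#'
#' @param samples Data.frame with one row per sample (or per cross-tab cell
#'   when a count column `n` is present): `line_id`, `serology` (`"a1/a2"`
#'   string or two columns `allele1`/`allele2`), `hapA`, `hapB`.  Rows with an
#'   ambiguous diplotype can be marked with `ambiguous = TRUE`.
#' @param allele_maps Either one allele map used for all lines or a named list
#'   of per-line maps.
#' @param drop_ambiguous Exclude ambiguous-diplotype samples from the
#'   denominator (default `TRUE`); they are always reported in `n_ambiguous`.
#' @return A list of class `concordance_report` with `per_line` (data.frame:
#'   `line_id`, `class`, `n`, `n_concordant`, `pct`), `line_overall`
#'   (`line_id`, `n`, `n_concordant`, `overall_pct`, `n_ambiguous`),
#'   `aggregate` (per-class counts pooled across lines) and
#'   `aggregate_overall`.
#' @export
concordance <- function(samples, allele_maps, drop_ambiguous = TRUE) {
  if (!"serology" %in% names(samples)) {
    samples$serology <- paste(pmin(samples$allele1, samples$allele2),
                              pmax(samples$allele1, samples$allele2), sep = "/")
  }
  if (!"n" %in% names(samples)) samples$n <- 1L
  if (!"ambiguous" %in% names(samples)) samples$ambiguous <- FALSE
  per_line_map <- !is.null(names(allele_maps)) && is.list(allele_maps[[1]])

  norm_class <- function(s) {
    a <- strsplit(s, "/", fixed = TRUE)[[1]]
    if (length(a) == 1) a <- c(substr(s, 1, nchar(s) / 2), substr(s, nchar(s) / 2 + 1, nchar(s)))
    paste(sort(a), collapse = "/")
  }
  samples$class <- vapply(samples$serology, norm_class, "")

  lines <- unique(samples$line_id)
  per_line <- list()
  overall <- list()
  for (ln in lines) {
    d <- samples[samples$line_id == ln, ]
    map <- if (per_line_map) allele_maps[[ln]] else allele_maps
    if (is.null(map)) stop("no allele map for line ", ln)
    amb <- sum(d$n[d$ambiguous])
    if (drop_ambiguous) d <- d[!d$ambiguous, , drop = FALSE]
    d$conc <- vapply(seq_len(nrow(d)), function(i) {
      serology_match(d$class[i], c(d$hapA[i], d$hapB[i]), map)
    }, TRUE)
    cls <- sort(unique(d$class))
    per_line[[ln]] <- do.call(rbind, lapply(cls, function(cl) {
      n <- sum(d$n[d$class == cl])
      nc <- sum(d$n[d$class == cl & d$conc])
      data.frame(line_id = ln, class = cl, n = n, n_concordant = nc,
                 pct = round_pct(nc, n), stringsAsFactors = FALSE)
    }))
    n <- sum(d$n)
    nc <- sum(d$n[d$conc])
    overall[[ln]] <- data.frame(line_id = ln, n = n, n_concordant = nc,
                                overall_pct = round_pct(nc, n), n_ambiguous = amb,
                                stringsAsFactors = FALSE)
  }
  per_line <- do.call(rbind, per_line)
  line_overall <- do.call(rbind, overall)
  rownames(per_line) <- rownames(line_overall) <- NULL

  agg_cls <- sort(unique(per_line$class))
  aggregate <- do.call(rbind, lapply(agg_cls, function(cl) {
    n <- sum(per_line$n[per_line$class == cl])
    nc <- sum(per_line$n_concordant[per_line$class == cl])
    data.frame(class = cl, n = n, n_concordant = nc, pct = round_pct(nc, n),
               stringsAsFactors = FALSE)
  }))
  aggregate_overall <- data.frame(n = sum(line_overall$n),
                                  n_concordant = sum(line_overall$n_concordant))
  aggregate_overall$overall_pct <- round_pct(aggregate_overall$n_concordant,
                                             aggregate_overall$n)
  structure(list(per_line = per_line, line_overall = line_overall,
                 aggregate = aggregate, aggregate_overall = aggregate_overall),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Serology vs haplotype concordance\n")
  for (i in seq_len(nrow(x$line_overall))) {
    r <- x$line_overall[i, ]
    cat(sprintf("  %-16s %3d/%3d concordant (%d%%)%s\n", r$line_id, r$n_concordant, r$n,
                r$overall_pct,
                if (r$n_ambiguous > 0) sprintf(" [%d ambiguous excluded]", r$n_ambiguous) else ""))
  }
  a <- x$aggregate_overall
  cat(sprintf("  aggregate        %3d/%3d concordant (%d%%)\n", a$n_concordant, a$n, a$overall_pct))
  invisible(x)
}
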