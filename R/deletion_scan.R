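#' Normalize a depth track against a flanking region
#'
#' Per-base ratio = depth / median(depth over the flank interval).  The flank
#' should be diploid copy-number-neutral territory near the region of
#' interest.
#'
#' @param track A `coverage_track` (see [simulate_coverage()] /
#'   [read_bedgraph()]).
#' @param flank 1-based inclusive interval within the track used as the
#'   diploid reference.
#' @return The track with `depth` replaced by `ratio` (class `ratio_track`).
#' @export
normalize_depth <- function(track, flank) {
  idx <- (flank[1]:flank[2]) - track$start + 1
  if (min(idx) < 1 || max(idx) > length(track$depth)) stop("flank outside track")
  med <- stats::median(track$depth[idx])
  if (med == 0) stop("flank median depth is zero; cannot normalize")
  out <- track
  out$ratio <- track$depth / med
  out$depth <- NULL
  class(out) <- "ratio_track"
  out
}

#' Call a deletion from a normalized depth track
#'
#' Two-state run-length caller operationalizing what a human would do in a
#' genome browser:
#'
#' * Homozygous deletion: bases with ratio at or below `tau_hom` are grouped
#'   into runs; runs separated by at most `merge_gap` bases are merged;
#'   leading/trailing merged components shorter than `edge_min` are trimmed
#'   as isolated low-coverage noise; the longest surviving candidate is
#'   called `HOM_DEL` when it spans at least `min_len` bases and its mean
#'   ratio is at most `tau_hom`.  Breakpoints are the first and last retained
#'   base, so a noiseless track is recovered exactly.
#' * Heterozygous deletion: when no homozygous call is made, the ratio is
#'   smoothed with a centred running mean of `het_window` bases and maximal
#'   runs with smoothed ratio inside `[tau_het_low, tau_het_high]` of length
#'   at least `min_len` are called `HET_DEL` (per-base thresholding cannot
#'   separate one-copy from two-copy coverage at realistic depth).
#'
#' @param rtrack A `ratio_track` from [normalize_depth()].
#' @param tau_hom Homozygous-deletion ratio ceiling (default 0.15).
#' @param tau_het_low,tau_het_high Band of smoothed ratios treated as
#'   one-copy (defaults 0.3 and 0.7).
#' @param min_len Minimum called length in bp (default 500).
#' @param merge_gap Maximum gap merged between low-ratio runs (default 50).
#' @param edge_min Minimum length of a terminal merged component (default 10).
#' @param het_window Smoothing window for the heterozygous pass (default 200).
#' @return A list of class `deletion_call`: `chrom`, `start`, `end` (1-based
#'   inclusive; `NA` for `NO_DEL`), `length`, `copy_class`
#'   (`HOM_DEL`/`HET_DEL`/`NO_DEL`), `mean_ratio`, `build`.
#' @export
call_deletion <- function(rtrack, tau_hom = 0.15, tau_het_low = 0.3, tau_het_high = 0.7,
                          min_len = 500, merge_gap = 50, edge_min = 10, het_window = 200) {
  stopifnot(tau_hom < tau_het_low, tau_het_low < tau_het_high)
  r <- rtrack$ratio
  no_call <- list(chrom = rtrack$chrom, start = NA_integer_, end = NA_integer_,
                  length = 0L, copy_class = "NO_DEL", mean_ratio = NA_real_,
                  build = rtrack$build, sample_id = rtrack$sample_id)
  class(no_call) <- "deletion_call"

  # --- homozygous pass: exact per-base runs
  cand <- hom_candidates(r <= tau_hom, merge_gap, edge_min)
  if (nrow(cand)) {
    cand$len <- cand$end - cand$start + 1
    cand$mean_ratio <- vapply(seq_len(nrow(cand)),
                              function(i) mean(r[cand$start[i]:cand$end[i]]), 0)
    cand <- cand[cand$len >= min_len & cand$mean_ratio <= tau_hom, , drop = FALSE]
    if (nrow(cand)) {
      best <- cand[which.max(cand$len), ]
      out <- no_call
      out$start <- rtrack$start + best$start - 1L
      out$end <- rtrack$start + best$end - 1L
      out$length <- as.integer(best$len)
      out$copy_class <- "HOM_DEL"
      out$mean_ratio <- best$mean_ratio
      return(out)
    }
  }

  # --- heterozygous pass: smoothed band
  sm <- running_mean(r, het_window)
  in_band <- sm >= tau_het_low & sm <= tau_het_high
  runs <- runs_of(in_band)
  if (nrow(runs)) {
    runs$len <- runs$end - runs$start + 1
    runs <- runs[runs$len >= min_len, , drop = FALSE]
    if (nrow(runs)) {
      best <- runs[which.max(runs$len), ]
      out <- no_call
      out$start <- rtrack$start + best$start - 1L
      out$end <- rtrack$start + best$end - 1L
      out$length <- as.integer(best$len)
      out$copy_class <- "HET_DEL"
      out$mean_ratio <- mean(r[best$start:best$end])
      return(out)
    }
  }
  no_call
}

runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

# merge low runs across gaps <= merge_gap, then trim sub-edge_min terminal components
hom_candidates <- function(low, merge_gap, edge_min) {
  comp <- runs_of(low)
  if (!nrow(comp)) return(data.frame(start = integer(0), end = integer(0)))
  gap <- c(Inf, comp$start[-1] - comp$end[-nrow(comp)] - 1)
  cluster <- cumsum(gap > merge_gap)
  out <- lapply(split(comp, cluster), function(cc) {
    len <- cc$end - cc$start + 1
    keep <- which(len >= edge_min)
    if (!length(keep)) return(NULL)
    data.frame(start = cc$start[min(keep)], end = cc$end[max(keep)])
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  do.call(rbind, out)
}

running_mean <- function(x, w) {
  half <- floor(w / 2)
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' @export
print.deletion_call <- function(x, ...) {
  if (x$copy_class == "NO_DEL") {
    cat(sprintf("deletion_call [%s]: NO_DEL\n", x$sample_id))
  } else {
    cat(sprintf("deletion_call [%s]: %s %s:%d-%d (%d bp, mean ratio %.3f, %s)\n",
                x$sample_id, x$copy_class, x$chrom, x$start, x$end, x$length,
                x$mean_ratio, x$build))
  }
  invisible(x)
}

#' Breakpoint consensus across samples
#'
#' Median start/end over homozygous-deletion calls on one chromosome, with
#' the maximum per-call deviation from the consensus over both ends.
#'
#' @param calls List of `deletion_call` objects (or a data.frame with
#'   `chrom`, `start`, `end`, `copy_class`).
#' @return A list with `chrom`, `start`, `end`, `n`, `max_discrepancy`.
#' @export
breakpoint_consensus <- function(calls) {
  if (is.data.frame(calls)) {
    d <- calls
  } else {
    d <- do.call(rbind, lapply(calls, function(x) {
      data.frame(chrom = x$chrom, start = x$start, end = x$end,
                 copy_class = x$copy_class, stringsAsFactors = FALSE)
    }))
  }
  d <- d[d$copy_class == "HOM_DEL", , drop = FALSE]
  if (nrow(d) < 2) stop("need at least two HOM_DEL calls")
  if (length(unique(d$chrom)) > 1) stop("calls span several chromosomes")
  cs <- stats::median(d$start)
  ce <- stats::median(d$end)
  list(chrom = d$chrom[1], start = cs, end = ce, n = nrow(d),
       max_discrepancy = max(abs(c(d$start - cs, d$end - ce))))
}

#' Synthetic RHCE exon model
#'
#' A packaged synthetic 10-exon model of the RHCE gene in the build of the
#' reported deletion breakpoints: exon boundaries are constructed (the
#' annotated ones are not published at base resolution) so that the deletion
#' removes the last 43 codons of exon 3 and everything downstream, matching
#' the described gene anatomy.
#'
#' @return A list of class `exon_model`: `gene_id`, `chrom`, `strand`,
#'   `exons` (data.frame `exon`, `start`, `end`), `build`.
#' @export
rhce_exon_model <- function() {
  tab <- utils::read.delim(system.file("extdata", "rhce_exons_synthetic.tsv",
                                       package = "serohap"),
                           comment.char = "#", stringsAsFactors = FALSE)
  read_exon_model(tab)
}

#' Build an exon model from a table
#'
#' @param tab Data.frame with `gene_id`, `chrom`, `strand`, `exon`, `start`,
#'   `end` (1-based inclusive), one gene.
#' @param build Genome build tag (default `"galGal6"`).
#' @return An `exon_model` object.
#' @export
read_exon_model <- function(tab, build = "galGal6") {
  tab <- tab[order(tab$start), ]
  if (any(tab$start > tab$end)) stop("exon with start > end")
  if (nrow(tab) > 1 && any(tab$start[-1] <= tab$end[-nrow(tab)])) {
    stop("exons overlap")
  }
  structure(list(gene_id = tab$gene_id[1], chrom = as.character(tab$chrom[1]),
                 strand = tab$strand[1],
                 exons = data.frame(exon = tab$exon, start = tab$start, end = tab$end),
                 build = build), class = "exon_model")
}

#' Exon overlap of a deletion call
#'
#' An exon is fully deleted when its span lies inside the deletion span
#' (boundaries inclusive), partially deleted on any proper overlap.
#'
#' @param del A `deletion_call` (must be on the model's chromosome and carry
#'   the same build tag; cross-build comparison is an error, coordinates are
#'   never converted between builds).
#' @param model An `exon_model`.
#' @return A list with `n_fully_deleted`, `n_partially_deleted` and `exons`
#'   (data.frame `exon`, `start`, `end`, `status` in
#'   `deleted`/`partial`/`intact`).
#' @export
exon_overlap <- function(del, model) {
  if (del$copy_class == "NO_DEL") stop("no deletion called")
  if (!identical(as.character(del$chrom), model$chrom)) {
    stop("deletion and exon model are on different chromosomes")
  }
  if (!is.null(del$build) && !is.null(model$build) && !identical(del$build, model$build)) {
    stop(sprintf("build mismatch: deletion is %s, exon model is %s", del$build, model$build))
  }
  ex <- model$exons
  full <- ex$start >= del$start & ex$end <= del$end
  touch <- ex$start <= del$end & ex$end >= del$start
  ex$status <- ifelse(full, "deleted", ifelse(touch, "partial", "intact"))
  list(n_fully_deleted = sum(full), n_partially_deleted = sum(touch & !full), exons = ex)
}
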