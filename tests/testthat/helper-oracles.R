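# Independent oracles, deliberately written with different code paths than the
# package implementation (scalar if-chains and explicit loops, stats::lm, etc.)

# per-site genotype-call oracle for a haplotype pair
oracle_site_call <- function(a, b) {
  if (a == "DEL" && b == "DEL") return("FAIL")
  if (a == "DEL") return(if (b == "REF") "RR" else "AA")
  if (b == "DEL") return(if (a == "REF") "RR" else "AA")
  if (a == "REF" && b == "REF") return("RR")
  if (a == "ALT" && b == "ALT") return("AA")
  "RA"
}

oracle_expected_genotype <- function(panel, hapA, hapB) {
  a <- panel$alleles[, hapA]
  b <- panel$alleles[, hapB]
  vapply(seq_along(a), function(i) oracle_site_call(a[i], b[i]), "")
}

# exhaustive enumeration over all unordered haplotype pairs
oracle_compatible_pairs <- function(calls, panel) {
  haps <- colnames(panel$alleles)
  out <- list()
  for (i in seq_along(haps)) {
    for (j in i:length(haps)) {
      if (identical(unname(oracle_expected_genotype(panel, haps[i], haps[j])),
                    unname(calls))) {
        out[[length(out) + 1]] <- c(haps[i], haps[j])
      }
    }
  }
  out
}

pair_set <- function(pairs) {
  sort(vapply(pairs, function(p) paste(sort(p), collapse = "/"), ""))
}

# least-squares oracle via stats::lm (the implementation uses closed forms)
oracle_regression <- function(expected, theta) {
  fit <- stats::lm(expected ~ theta)
  s <- summary(fit)
  list(r2 = s$r.squared, p = s$coefficients["theta", "Pr(>|t|)"],
       slope = stats::coef(fit)[["theta"]])
}

demo_panel <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- serohap::rhce_panel()
    p
  }
})
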