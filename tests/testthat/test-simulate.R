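panel <- demo_panel()
wl_map <- list(I2 = "H02", I8 = "H01")

test_that("a monomorphic line is a fixed point of the simulator", {
  cfg <- line_config("MONO", c(H02 = 1), n_samples = 25, seed = 7)
  sim <- simulate_line(cfg, panel, wl_map)
  expect_true(all(sim$truth$hapA == "H02" & sim$truth$hapB == "H02"))
  h02_hom <- expected_genotype(panel, "H02", "H02")
  for (i in seq_len(nrow(sim$panel_calls))) {
    expect_equal(unname(sim$panel_calls[i, ]), unname(h02_hom))
  }
  expect_true(all(sim$truth$serology_true == "I2/I2"))
})

test_that("error-free serology records the truth; unknown haplotypes are rejected", {
  cfg <- line_config("EF", c(H01 = 0.5, H02 = 0.5), n_samples = 200, seed = 11)
  sim <- simulate_line(cfg, panel, wl_map)
  expect_identical(sim$truth$serology_recorded, sim$truth$serology_true)

  expect_error(simulate_line(line_config("X", c(H99 = 1), 5), panel, wl_map),
               "unknown haplotype")
  expect_error(line_config("X", c(H01 = 0.6, H02 = 0.6), 5), "sum to 1")
})

test_that("diplotypes follow Hardy-Weinberg at large n", {
  cfg <- line_config("HW", c(H02 = 0.5, H03 = 0.5), n_samples = 10000, seed = 13)
  sim <- simulate_line(cfg, panel, list(I2 = "H02", I8 = "H03"))
  het <- mean(sim$truth$hapA != sim$truth$hapB)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(het - 0.5), 3 * se)
})

test_that("the serology error model miscalls at the configured rates", {
  em <- serology_error_model(p_het_as_hom = 0.3, dominant_allele = "I8")
  cfg <- line_config("ERR", c(H01 = 0.5, H02 = 0.5), n_samples = 4000,
                     serology_error = em, seed = 17)
  sim <- simulate_line(cfg, panel, wl_map)
  het <- sim$truth$serology_true == "I2/I8"
  miscalled <- sim$truth$serology_recorded[het] == "I8/I8"
  q <- mean(miscalled)
  se <- sqrt(0.3 * 0.7 / sum(het))
  expect_lt(abs(q - 0.3), 3 * se)
  # homozygotes untouched when p_hom_miscall = 0
  expect_identical(sim$truth$serology_recorded[!het], sim$truth$serology_true[!het])
})

test_that("deletion_copies counts short haplotypes in the diplotype", {
  cfg <- line_config("DEL", c(H01 = 0.5, H07 = 0.5), n_samples = 300, seed = 19)
  sim <- simulate_line(cfg, panel, list(I8 = "H01", IX = "H07"))
  n_short <- (sim$truth$hapA == "H07") + (sim$truth$hapB == "H07")
  expect_identical(sim$truth$deletion_copies, as.integer(n_short))
})

test_that("generators are deterministic given config and seed", {
  cfg <- line_config("DET", c(H01 = 0.5, H02 = 0.5), n_samples = 60, seed = 23)
  s1 <- simulate_line(cfg, panel, wl_map)
  s2 <- simulate_line(cfg, panel, wl_map)
  expect_identical(s1, s2)

  geno <- matrix(rep(0:2, each = 20), nrow = 60, ncol = 3,
                 dimnames = list(sprintf("S%02d", 1:60), c("a", "b", "c")))
  cls <- rep(c("c0", "c1", "c2"), each = 20)
  p1 <- simulate_pools(geno, cls, c(c0 = 0, c1 = 1, c2 = 2), n_sets = 2, seed = 5)
  p2 <- simulate_pools(geno, cls, c(c0 = 0, c1 = 1, c2 = 2), n_sets = 2, seed = 5)
  expect_identical(p1, p2)
})

test_that("noise-free pool intensities are exact mean dosage fractions", {
  geno <- rbind(S1 = c(snp = 2), S2 = c(snp = 2), S3 = c(snp = 2), S4 = c(snp = 2),
                S5 = c(snp = 1), S6 = c(snp = 1), S7 = c(snp = 1), S8 = c(snp = 1),
                S9 = c(snp = 0), S10 = c(snp = 2), S11 = c(snp = 0), S12 = c(snp = 2))
  cls <- c(rep("BB", 4), rep("AB", 4), rep("MIX", 4))
  p <- simulate_pools(geno, cls, c(BB = 2, AB = 1, MIX = 1), n_sets = 1,
                      size_range = c(4, 4), sigma = 0, seed = 1)
  theta <- p$theta[, "snp"]
  expect_equal(unname(theta[p$pools$class == "BB"]), 1.0)   # all-BB pool
  expect_equal(unname(theta[p$pools$class == "AB"]), 0.5)   # all-het pool
  expect_equal(unname(theta[p$pools$class == "MIX"]), 0.5)  # {AA,BB} mixture
  expect_error(simulate_pools(geno, cls, c(BB = 2, AB = 1, MIX = 1), n_sets = 1,
                              size_range = c(5, 5), sigma = 0, seed = 1),
               "insufficient")
})

test_that("pool intensities order by expected count at the causal SNP", {
  set.seed(31)
  cfg <- line_config("ORD", c(H01 = 0.5, H02 = 0.5), n_samples = 300, seed = 37)
  sim <- simulate_line(cfg, panel, wl_map)
  causal <- cbind(sim$truth$hapA == "H02", sim$truth$hapB == "H02") * 1L
  geno <- simulate_array_genotypes(causal, genome_config(n_background_snps = 0),
                                   sample_ids = sim$truth$sample_id, seed = 37)
  pools <- simulate_pools(geno$geno, sim$truth$serology_recorded,
                          c(`I8/I8` = 0, `I2/I8` = 1, `I2/I2` = 2), seed = 37)
  csnp <- geno$snps$snp_id[geno$snps$causal]
  means <- tapply(pools$theta[, csnp], pools$pools$expected_count, mean)
  expect_true(means["0"] < means["1"] && means["1"] < means["2"])
})

test_that("array genotypes respect the LD model and Hardy-Weinberg background", {
  set.seed(41)
  n <- 4000
  causal <- cbind(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
  # perfect-LD limit: every region SNP equals the causal dosage
  g_inf <- simulate_array_genotypes(causal, genome_config(n_background_snps = 0,
                                                          ld_decay_bp = Inf,
                                                          n_region_snps = 5),
                                    seed = 43)
  for (s in g_inf$snps$snp_id) {
    expect_identical(unname(g_inf$geno[, s]), unname(rowSums(causal)))
  }
  # background SNPs: genotype frequencies within 3 s.e. of HW expectation
  g_bg <- simulate_array_genotypes(causal, genome_config(n_background_snps = 5,
                                                         allele_freq_range = c(0.3, 0.3)),
                                   seed = 47)
  bg <- g_bg$snps$snp_id[g_bg$snps$chrom == "1"]
  for (s in bg) {
    p_het <- mean(g_bg$geno[, s] == 1)
    exp_het <- 2 * 0.3 * 0.7
    expect_lt(abs(p_het - exp_het), 3 * sqrt(exp_het * (1 - exp_het) / n))
  }
  # zero background SNPs -> only causal-region records
  expect_true(all(g_inf$snps$chrom == "23"))
})

test_that("coverage simulation scales depth with deletion copy number", {
  cc <- coverage_config(mean_depth_lambda = 4, deletion_span = c(1200, 1999),
                        region = c(1000, 2500))
  in_span <- 201:1000

  hom <- simulate_coverage(2, cc, noiseless = TRUE)
  expect_true(all(hom$depth[in_span] == 0))
  expect_true(all(hom$depth[-in_span] == 4))

  het <- simulate_coverage(1, cc, noiseless = TRUE)
  expect_true(all(het$depth[in_span] == 2))

  none <- simulate_coverage(0, cc, seed = 53)
  expect_gt(min(tapply(none$depth[in_span], rep(1:8, each = 100), max)), 0)
  expect_lt(abs(mean(none$depth) - 4), 3 * sqrt(4 / length(none$depth)))
})
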