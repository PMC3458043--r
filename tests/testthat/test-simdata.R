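test_that("simulation is deterministic for a fixed configuration", {
  cfg <- sim_config(seed = 9, genome_length = 30000, ploidies = c(4, 8),
                    site_coverage = 6)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$variants, s2$variants)
  expect_identical(s1$dosage, s2$dosage)
  r1 <- simulate_rrl_reads(s1, 1)
  r2 <- simulate_rrl_reads(s2, 1)
  expect_identical(r1$reads, r2$reads)
})

test_that("planted CCGG sites equal a motif scan of the emitted genome", {
  sim <- simulate_genome(sim_config(seed = 13, genome_length = 50000))
  hits <- gregexpr("CCGG", sim$genome, fixed = TRUE)[[1]]
  expect_equal(as.integer(hits) - 1L, sim$sites$pos)   # 0-based truth
  expect_equal(length(hits), nrow(sim$sites))
})

test_that("theta 0 yields no variants and reads identical to the genome", {
  cfg <- sim_config(seed = 17, genome_length = 30000, theta = 0,
                    ploidies = c(8), site_coverage = 4,
                    err_high = 0, err_low = 0, low_tier_weight = 0)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$variants), 0L)
  lib <- simulate_rrl_reads(sim, 1)
  expect_true(all(startsWith(lib$reads$bases, "CGG")))
  plus <- lib$truth$dir == "+"
  expect_true(all(substring(sim$genome, lib$truth$fstart[plus] + 1L,
                            lib$truth$fend[plus]) ==
                    lib$reads$bases[plus]))
  minus <- which(!plus)
  expect_true(all(revcomp(substring(sim$genome,
                                    lib$truth$fstart[minus] + 1L,
                                    lib$truth$fend[minus])) ==
                    lib$reads$bases[minus]))
})

test_that("methylated sites emit no reads", {
  cfg <- sim_config(seed = 19, genome_length = 40000, methylation_rate = 0.5,
                    ploidies = c(4), site_coverage = 5)
  sim <- simulate_genome(cfg)
  lib <- simulate_rrl_reads(sim, 1)
  meth <- sim$sites[methylated == TRUE]$site
  expect_false(any(lib$truth$site %in% meth))
})

test_that("alternate-read fractions follow the binomial dosage model", {
  set.seed(23)
  cnt <- simulate_site_counts(4000, depth = 40, ploidy = 8, dosage = 2)
  frac <- sum(cnt$alt_n) / sum(cnt$alt_n + cnt$ref_n)
  se <- sqrt(0.25 * 0.75 / (4000 * 40))
  expect_lt(abs(frac - 0.25), 3 * se)
  # balanced sampling reproduces the dosage ratio exactly
  bal <- simulate_site_counts(10, depth = 40, ploidy = 8, dosage = 2,
                              sampling = "balanced")
  expect_true(all(bal$alt_n == 10L))
  expect_error(simulate_site_counts(5, 40, sampling = "balanced",
                                    alt_fraction = 0.1), "binomial")
})

test_that("per-read dosage sampling concentrates near the planted ratio", {
  cfg <- sim_config(seed = 29, genome_length = 60000, ploidies = c(8),
                    theta = 0.004, site_coverage = 25,
                    err_high = 0, err_low = 0, low_tier_weight = 0)
  sim <- simulate_genome(cfg)
  lib <- simulate_rrl_reads(sim, 1)
  rv <- lib$read_variants
  agg <- rv[, .(alt = sum(observed == "alt"), n = .N), by = variant_id]
  agg <- merge(agg, data.table::data.table(
    variant_id = seq_len(nrow(sim$dosage)), dosage = sim$dosage[, 1]),
    by = "variant_id")
  deep <- agg[n >= 20]
  expect_gt(nrow(deep), 10)
  p_hat <- deep$alt / deep$n
  p_true <- deep$dosage / 8
  within <- abs(p_hat - p_true) <= 3 * sqrt(pmax(p_true * (1 - p_true),
                                                 0.02) / deep$n)
  expect_gte(mean(within), 0.95)
})

test_that("EST corruption fractions are recovered by the cleaning stage", {
  sim <- simulate_genome(sim_config(seed = 31, genome_length = 60000))
  est0 <- simulate_ests(sim, n_clones = 30)
  cl0 <- clean_est_set(est0$reads)
  expect_equal(nrow(cl0$reads), nrow(est0$reads))   # no corruption, no loss
  est <- simulate_ests(sim, n_clones = 60, insertless_frac = 0.15)
  cl <- clean_est_set(est$reads)
  ins_clones <- est$truth[insertless == TRUE]$clone_id
  # every insertless clone loses both sisters, nothing else is discarded
  expect_setequal(unique(cl$discarded$clone_id), ins_clones)
  expect_equal(nrow(cl$discarded), 2L * length(ins_clones))
})

test_that("subpopulation genotype simulation produces the declared layout", {
  gm <- simulate_genotypes(n1 = 8, n2 = 5, n_variants = 100, delta = 0.3,
                           seed = 3)
  expect_equal(length(gm$libraries), 13L)
  expect_equal(gm$group, rep(c(1L, 2L), c(8, 5)))
  expect_true(all(gm$geno %in% c("hom_ref", "hom_alt", "het", "missing")))
  expect_identical(gm$geno,
                   simulate_genotypes(n1 = 8, n2 = 5, n_variants = 100,
                                      delta = 0.3, seed = 3)$geno)
})
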