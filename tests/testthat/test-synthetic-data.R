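small_cfg <- function(...) {
  family_sim_config(n_chromosomes = 2, n_variants_per_chrom = 400, ...)
}

test_that("the family simulator is seed-deterministic down to the written file", {
  f1 <- simulate_family(small_cfg(seed = 9))
  f2 <- simulate_family(small_cfg(seed = 9))
  expect_identical(f1$variants, f2$variants)
  expect_identical(f1$truth$ibd, f2$truth$ibd)
  p1 <- withr::local_tempfile(fileext = ".vcf")
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_family_vcf(f1$variants, p1)
  write_family_vcf(f2$variants, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_false(identical(f1$variants,
                         simulate_family(small_cfg(seed = 10))$variants))
})

test_that("error-free transmission is Mendelian under an independent per-site rule", {
  for (seed in c(2, 7, 19)) {
    fam <- simulate_family(small_cfg(seed = seed, genotype_error = 0))
    expect_equal(sum(mendel_inconsistent(fam$variants, fam$pedigree)), 0,
                 info = paste("seed", seed))
  }
  # with genotype error switched on, violations do appear
  fam_err <- simulate_family(small_cfg(seed = 2, genotype_error = 0.02))
  expect_gt(sum(mendel_inconsistent(fam_err$variants, fam_err$pedigree)), 0)
})

test_that("without recombination each chromosome has a constant IBD state and IBD2 implies identical sib genotypes", {
  fam <- simulate_family(small_cfg(seed = 5, recomb_rate_cm_mb = 0,
                                   genotype_error = 0))
  ibd <- fam$truth$ibd
  per_chrom <- tapply(ibd$ibd, ibd$chrom, function(x) length(unique(x)))
  expect_true(all(per_chrom == 1))
  v <- fam$variants
  in_ibd2 <- ibd$ibd == 2
  if (any(in_ibd2)) {
    expect_identical(v$gt_3[in_ibd2], v$gt_5[in_ibd2])
  }
  expect_identical(sort(unique(ibd$ibd)),
                   sort(unique(fam$truth$ibd_segments$ibd)))
})

test_that("crossover counts match the Poisson expectation of the genetic map", {
  # 100 Mb at 1 cM/Mb = 1 Morgan: mean 1 crossover per meiosis per chromosome
  counts <- unlist(lapply(1:200, function(s) {
    fam <- simulate_family(family_sim_config(n_chromosomes = 2,
                                             n_variants_per_chrom = 20,
                                             seed = 1000 + s))
    fam$truth$crossovers$n_crossovers
  }))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 1.0), 3 * se + 1e-12)
})

test_that("the realized sib-pair IBD2 fraction approaches the full-sib expectation of 1/4", {
  fracs <- vapply(1:40, function(s) {
    fam <- simulate_family(family_sim_config(n_chromosomes = 2,
                                             n_variants_per_chrom = 150,
                                             seed = 3000 + s))
    mean(fam$truth$ibd$ibd == 2)
  }, numeric(1))
  se <- stats::sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.25), 3 * se)
})

test_that("planted candidates realize exactly the requested carrier pattern", {
  plants <- plant_spec(c("2", "3", "5"), id = "maternal_shared")
  fam <- simulate_family(small_cfg(seed = 21, genotype_error = 0), plants)
  key <- fam$truth$plants
  expect_equal(nrow(key), 1)
  row <- dplyr::inner_join(fam$variants, key[, c("chrom", "pos", "ref", "alt")],
                           by = c("chrom", "pos", "ref", "alt"))
  expect_equal(nrow(row), 1)
  expect_equal(gt_dosage(c(row$gt_1, row$gt_2, row$gt_3, row$gt_4, row$gt_5)),
               c(0L, 1L, 1L, 0L, 1L))
  expect_equal(row$func_class, "exonic:nonsynonymous")
  expect_false(row$in_segdup)
  expect_true(all(is.na(c(row$freq_dbsnp, row$freq_1000g, row$freq_esp6500))))
  # planted inside a truth IBD2 region
  ibd_at <- fam$truth$ibd$ibd[fam$truth$ibd$chrom == key$chrom &
                                fam$truth$ibd$pos == key$pos]
  expect_equal(ibd_at, 2L)

  # de novo pattern: both affected sibs carry, parents do not
  fam_dn <- simulate_family(small_cfg(seed = 22, genotype_error = 0),
                            plant_spec(c("3", "5"), id = "germline_mosaic"))
  kdn <- fam_dn$truth$plants
  rdn <- dplyr::inner_join(fam_dn$variants,
                           kdn[, c("chrom", "pos", "ref", "alt")],
                           by = c("chrom", "pos", "ref", "alt"))
  expect_equal(gt_dosage(c(rdn$gt_1, rdn$gt_2, rdn$gt_3, rdn$gt_5)),
               c(0L, 0L, 1L, 1L))
})

test_that("impossible carrier patterns are rejected before emission", {
  # sharing the maternal haplotype with sib 3 under IBD2 forces sib 5 to
  # carry too, so {mother, 3} alone is unsatisfiable
  tiny <- family_sim_config(n_chromosomes = 1, n_variants_per_chrom = 60,
                            seed = 4)
  expect_error(
    simulate_family(tiny, plant_spec(c("2", "3"), require_ibd2 = TRUE),
                    max_attempts = 10),
    "inconsistent")
  expect_error(
    simulate_family(tiny, plant_spec(c("1", "2", "3"))),
    "not supported")
  expect_error(
    simulate_family(tiny, plant_spec(c("99"))),
    "Unknown plant carrier")
})

test_that("cohort simulation honours the null, degenerate and error cases", {
  # OR = 1: genotype frequencies agree between arms within 3 SE
  cfg <- cohort_sim_config(n_cases = 2000, n_controls = 2000,
                           p0 = 0.3, or = 1, model = "dominant", seed = 31)
  cohort <- simulate_cohort(cfg)
  p_case <- mean(cohort$snp1[cohort$status == "case"] > 0)
  p_ctrl <- mean(cohort$snp1[cohort$status == "control"] > 0)
  se <- sqrt(p_ctrl * (1 - p_ctrl) * (1 / 2000 + 1 / 2000))
  expect_lt(abs(p_case - p_ctrl), 3 * se)

  # p0 = 0: everyone homozygous reference
  z <- simulate_cohort(cohort_sim_config(p0 = 0, or = 2, seed = 1))
  expect_true(all(z$snp1 == 0))

  expect_error(cohort_sim_config(p0 = 0.1, or = 0), "Odds ratios")
  expect_error(cohort_sim_config(p0 = 0.1, or = -1), "Odds ratios")
  expect_error(cohort_sim_config(p0 = 0.1, or = 1, model = "additive"),
               "model")

  # determinism
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))

  # controls are drawn in HWE at p0 (exact test rarely rejects)
  big <- simulate_cohort(cohort_sim_config(n_cases = 10, n_controls = 3000,
                                           p0 = 0.2, or = 1, seed = 5))
  tab <- table(factor(big$snp1[big$status == "control"], levels = 0:2))
  expect_gt(hwe_exact(tab[1], tab[2], tab[3]), 0.001)
})

test_that("the dominant-model odds ratio is recovered from simulated cohorts", {
  # target parameters mirror the protective low-frequency variant design
  true_or <- 0.21
  pooled <- c(a = 0, b = 0, c = 0, d = 0)
  for (s in 1:500) {
    cohort <- simulate_cohort(cohort_sim_config(
      n_cases = 176, n_controls = 358, p0 = 0.083,
      or = true_or, model = "dominant", seed = 5000 + s))
    cnt <- cohort_counts(cohort)
    tab <- collapse_model(
      c(cnt$case_hom_ref, cnt$case_het, cnt$case_hom_alt),
      c(cnt$ctrl_hom_ref, cnt$ctrl_het, cnt$ctrl_hom_alt), "dominant")
    pooled <- pooled + unlist(tab)
  }
  # pooled counts give a consistent estimate; 3 SE on the log scale
  est <- odds_ratio_ci(pooled["a"], pooled["b"], pooled["c"], pooled["d"])
  se <- sqrt(sum(1 / pooled))
  expect_lt(abs(log(est$or) - log(true_or)), 3 * se)
})
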