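test_that("the exact HWE test matches direct enumeration and handles edge cases", {
  # monomorphic: single configuration
  expect_equal(hwe_exact(25, 0, 0), 1.0)
  expect_equal(hwe_exact(0, 0, 12), 1.0)
  expect_error(hwe_exact(0, 0, 0), "zero")
  expect_error(hwe_exact(-1, 2, 3), "non-negative")

  # published control genotypes show no HWE deviation
  expect_gt(hwe_exact(299, 58, 1), 0.05)

  # exhaustive-enumeration oracle over random tables with n <= 30
  set.seed(123)
  for (rep in 1:200) {
    n <- sample(1:30, 1)
    naa <- sample(0:n, 1)
    nab <- sample(0:(n - naa), 1)
    nbb <- n - naa - nab
    expect_equal(hwe_exact(naa, nab, nbb), oracle_hwe(naa, nab, nbb),
                 tolerance = 1e-10, info = paste(naa, nab, nbb))
  }
})

test_that("HWE p-values under the null are uniform or super-uniform", {
  set.seed(2024)
  n <- 120; q <- 0.3
  p_vals <- vapply(1:5000, function(i) {
    g <- sample(0:2, n, replace = TRUE,
                prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
    tab <- tabulate(g + 1L, 3L)
    hwe_exact(tab[1], tab[2], tab[3])
  }, numeric(1))
  for (a in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(p_vals <= a), a + 3 * sqrt(a * (1 - a) / 5000))
  }
})

test_that("genetic-model collapsing reproduces the published layouts", {
  # control row (GG = 299, GA = 58, AA = 1), dominant: 59 exposed vs 299
  dom <- collapse_model(case = c(169, 7, 0), control = c(299, 58, 1),
                        "dominant")
  expect_equal(dom[c("c", "d")], list(c = 59, d = 299))
  expect_equal(dom[c("a", "b")], list(a = 7, b = 169))
  # case allele counts: A = 7, G = 345
  alle <- collapse_model(case = c(169, 7, 0), control = c(299, 58, 1),
                         "allelic")
  expect_equal(alle$a, 7); expect_equal(alle$b, 345)
  # symmetric toy, dominant: 20 carriers vs 10
  toy <- collapse_model(c(10, 10, 10), c(10, 10, 10), "dominant")
  expect_equal(toy$a, 20); expect_equal(toy$b, 10)
  het <- collapse_model(c(169, 7, 0), c(299, 58, 1), "heterozygote")
  expect_equal(unlist(het), c(a = 7, b = 169, c = 58, d = 299))
  gen <- collapse_model(c(169, 7, 0), c(299, 58, 1), "genotypic")
  expect_equal(dim(gen), c(2L, 3L))
  expect_error(collapse_model(c(1, 1, 1), c(1, 1, 1), "overdominant"))
})

test_that("odds ratios and Woolf intervals reproduce the published values", {
  # dominant: OR 0.21 (0.09-0.47)
  dom <- odds_ratio_ci(7, 169, 59, 299)
  expect_equal(round(dom$or, 2), 0.21)
  expect_equal(round(dom$ci_lo, 2), 0.09)
  expect_equal(round(dom$ci_hi, 2), 0.47)
  # heterozygote: OR 0.21 (0.10-0.48)
  het <- odds_ratio_ci(7, 169, 58, 299)
  expect_equal(round(het$or, 2), 0.21)
  expect_equal(round(het$ci_lo, 2), 0.10)
  expect_equal(round(het$ci_hi, 2), 0.48)
  # allelic from the printed allele rows: OR 0.23 (0.10-0.50)
  alle <- odds_ratio_ci(7, 345, 59, 656)
  expect_equal(round(alle$or, 2), 0.23)
  expect_equal(round(alle$ci_lo, 2), 0.10)
  expect_equal(round(alle$ci_hi, 2), 0.50)
})

test_that("odds-ratio algebra and degenerate tables behave", {
  bal <- odds_ratio_ci(8, 8, 8, 8)
  expect_equal(bal$or, 1)
  expect_equal(log(bal$ci_lo), -log(bal$ci_hi))
  # exposure relabeling inverts the OR
  set.seed(3)
  for (i in 1:20) {
    cells <- sample(1:50, 4, replace = TRUE)
    o1 <- odds_ratio_ci(cells[1], cells[2], cells[3], cells[4])$or
    o2 <- odds_ratio_ci(cells[2], cells[1], cells[4], cells[3])$or
    expect_equal(o1 * o2, 1, tolerance = 1e-12)
  }
  expect_error(odds_ratio_ci(0, 5, 5, 5), "Haldane")
  h <- odds_ratio_ci(0, 5, 5, 5, haldane = TRUE)
  expect_true(is.finite(h$or) && h$or > 0)
})

test_that("contingency tests match their oracles and flag fragile tables", {
  # perfectly proportional margins: chi-square 0, p = 1
  prop <- association_test(list(a = 10, b = 20, c = 30, d = 60))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p, 1)

  # Fisher equals choose()-based enumeration on small tables
  set.seed(9)
  for (i in 1:40) {
    cells <- as.list(sample(0:12, 4, replace = TRUE))
    names(cells) <- c("a", "b", "c", "d")
    if ((cells$a + cells$c) == 0 || (cells$b + cells$d) == 0) next
    got <- association_test(cells, method = "fisher")$p
    want <- oracle_fisher(cells$a, cells$b, cells$c, cells$d)
    expect_equal(got, want, tolerance = 1e-9,
                 info = paste(unlist(cells), collapse = ","))
  }

  # sparse expected counts trigger advice to use Fisher
  expect_warning(association_test(list(a = 1, b = 60, c = 0, d = 70)),
                 "fisher")

  # published dominant table: chi-square p on the 1e-5 scale
  p_dom <- association_test(collapse_model(c(169, 7, 0), c(299, 58, 1),
                                           "dominant"))$p
  expect_gt(p_dom, 3.9e-5 / 2)
  expect_lt(p_dom, 3.9e-5 * 2)

  # genotypic table has 2 df
  gen <- association_test(collapse_model(c(169, 7, 0), c(299, 58, 1),
                                         "genotypic"))
  expect_equal(gen$df, 2)
  expect_error(association_test(collapse_model(c(1, 1, 1), c(1, 1, 1),
                                               "genotypic"),
                                method = "fisher"), "2x2")
})

test_that("permutation p-values agree with exhaustive enumeration on tiny cohorts", {
  set.seed(41)
  cohort <- tibble::tibble(
    subject = paste0("s", 1:9),
    status = rep(c("case", "control"), c(4, 5)),
    snpA = c(2, 1, 1, 0, 0, 0, 1, 0, 0),
    snpB = c(0, 1, 0, 1, 1, 0, 1, 0, 2)
  )
  exact <- permutation_pvalue(cohort, exact = TRUE)

  # independent oracle: enumerate case-index subsets directly
  dos <- as.matrix(cohort[, c("snpA", "snpB")])
  n_case <- 4
  stat <- function(case_ix, col) {
    a <- sum(dos[case_ix, col]); b <- 2 * n_case - a
    cc <- sum(dos[-case_ix, col]); d <- 2 * (nrow(dos) - n_case) - cc
    n <- a + b + cc + d
    den <- (a + b) * (cc + d) * (a + cc) * (b + d)
    if (den == 0) 0 else n * (a * d - b * cc)^2 / den
  }
  subsets <- utils::combn(9, 4)
  for (col in 1:2) {
    obs <- stat(1:4, col)
    all_stats <- apply(subsets, 2, stat, col = col)
    expect_equal(exact$statistic[col], obs, tolerance = 1e-12)
    expect_equal(exact$p_perm[col], mean(all_stats >= obs - 1e-9),
                 tolerance = 1e-12)
    maxes <- pmax(apply(subsets, 2, stat, col = 1),
                  apply(subsets, 2, stat, col = 2))
    expect_equal(exact$p_perm_adj[col], mean(maxes >= obs - 1e-9),
                 tolerance = 1e-12)
  }
})

test_that("permutation adjustment dominates the raw p-value and nulls are flat", {
  # a SNP identical in cases and controls has adjusted p near 1
  flat <- tibble::tibble(status = rep(c("case", "control"), each = 10),
                         snp1 = rep(1, 20))
  res <- permutation_pvalue(flat, n_perm = 300, seed = 2)
  expect_gt(res$p_perm_adj, 0.99)

  cohort <- simulate_cohort(cohort_sim_config(
    n_cases = 60, n_controls = 80, seed = 8,
    snps = tibble::tibble(snp = paste0("s", 1:4), p0 = c(0.1, 0.2, 0.3, 0.4),
                          or = c(3, 1, 0.5, 1), model = "dominant")))
  res2 <- permutation_pvalue(cohort, n_perm = 500, seed = 3)
  expect_true(all(res2$p_perm_adj >= res2$p_perm - 1e-12))
  # determinism
  res3 <- permutation_pvalue(cohort, n_perm = 500, seed = 3)
  expect_identical(res2, res3)
  expect_warning(permutation_pvalue(cohort, n_perm = 50, seed = 1),
                 "permutations")
})

test_that("analytic power reproduces the null, the published figure, and monotonicity", {
  # GRR = 1 collapses power to alpha
  null_power <- cats_power(0.01, 0.1, 1, "dominant", alpha = 0.05,
                           n_cases = 100, n_controls = 100)
  expect_equal(null_power$power, 0.05, tolerance = 1e-10)

  # the published design: 83% at genome-wide alpha
  pw <- cats_power(prevalence = 0.01, daf = 0.08, grr = 4.35,
                   model = "dominant", alpha = 1e-7,
                   n_cases = 176, n_controls = 358)
  expect_equal(100 * pw$power, 83, tolerance = 2)

  # power strictly increases with the number of cases
  powers <- vapply(c(100, 176, 300), function(n)
    cats_power(0.01, 0.08, 4.35, "dominant", 1e-7, n, 358)$power, numeric(1))
  expect_true(all(diff(powers) > 0))

  expect_error(cats_power(0.5, 0.1, 30, "dominant", 0.05, 100, 100),
               "infeasible")
  expect_error(penetrance_model(0.01, 0.08, 0.3, "additive"), "infeasible")
})

test_that("analytic power agrees with Monte-Carlo simulation of the same test", {
  mc <- power_mc(prevalence = 0.01, daf = 0.08, grr = 4.35,
                 model = "dominant", alpha = 1e-7,
                 n_cases = 176, n_controls = 358, n_sims = 600, seed = 5)
  expect_lt(abs(mc$power_mc - mc$power_analytic), 0.02 + 3 * mc$mc_se)
})

test_that("two-sided analytic power matches a chi-square Monte-Carlo at moderate effects", {
  # at modest effect sizes the pooled and unpooled variances agree, so the
  # Pearson chi-square simulation is an independent cross-check
  sets <- list(list(K = 0.05, daf = 0.30, grr = 1.35),
               list(K = 0.10, daf = 0.20, grr = 1.40),
               list(K = 0.05, daf = 0.40, grr = 1.30))
  for (s in sets) {
    analytic <- cats_power(s$K, s$daf, s$grr, "dominant", alpha = 0.05,
                           n_cases = 176, n_controls = 358, sided = 2)
    pm <- penetrance_model(s$K, s$daf, s$grr, "dominant")
    or_allelic <- (pm$p_case / (1 - pm$p_case)) /
      (pm$p_ctrl / (1 - pm$p_ctrl))
    hits <- vapply(1:1500, function(k) {
      cohort <- simulate_cohort(cohort_sim_config(
        n_cases = 176, n_controls = 358, p0 = pm$p_ctrl, or = or_allelic,
        model = "allelic", seed = 60000 + k))
      cnt <- cohort_counts(cohort)
      tab <- collapse_model(
        c(cnt$case_hom_ref, cnt$case_het, cnt$case_hom_alt),
        c(cnt$ctrl_hom_ref, cnt$ctrl_het, cnt$ctrl_hom_alt), "allelic")
      association_test(tab)$p < 0.05
    }, logical(1))
    mc_power <- mean(hits)
    expect_lt(abs(mc_power - analytic$power), 0.02 + 3 * sqrt(0.25 / 1500),
              label = paste("daf", s$daf))
  }
})

test_that("the allelic test holds its nominal type-I error on simulated nulls", {
  hits <- vapply(1:500, function(k) {
    cohort <- simulate_cohort(cohort_sim_config(
      n_cases = 176, n_controls = 358, p0 = 0.2, or = 1,
      model = "allelic", seed = 70000 + k))
    cnt <- cohort_counts(cohort)
    tab <- collapse_model(
      c(cnt$case_hom_ref, cnt$case_het, cnt$case_hom_alt),
      c(cnt$ctrl_hom_ref, cnt$ctrl_het, cnt$ctrl_hom_alt), "allelic")
    association_test(tab)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})
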