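#' Configuration for the case-control cohort simulator
#'
#' Controls are drawn in Hardy-Weinberg equilibrium at the control minor-allele
#' frequency `p0`; case genotype frequencies are tilted by the configured odds
#' ratio under the chosen genetic model. Defaults mirror the follow-up design
#' the package's association tools target: 176 cases and 358 controls.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param snps A tibble with one row per SNP and columns `snp`, `p0`
#'   (control minor-allele frequency), `or` (odds ratio; for
#'   `model = "genotypic"` a list-column of length-2 vectors, heterozygote and
#'   homozygote OR), and `model` (one of `"dominant"`, `"allelic"`,
#'   `"genotypic"`). Alternatively pass `p0`, `or`, `model` scalars for a
#'   single SNP.
#' @param p0,or,model Single-SNP shortcut used when `snps` is `NULL`.
#' @param seed Integer seed; the seed determines the output.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_cases = 176, n_controls = 358,
                              snps = NULL, p0 = 0.1, or = 1, model = "dominant",
                              seed = 1L) {
  if (is.null(snps)) {
    snps <- tibble(snp = "snp1", p0 = p0, or = list(or), model = model)
  } else {
    snps <- as_tibble(snps)
    if (!is.list(snps$or)) snps$or <- as.list(snps$or)
  }
  stopifnot(all(c("snp", "p0", "or", "model") %in% names(snps)))
  if (!all(snps$model %in% c("dominant", "allelic", "genotypic"))) {
    abort("model must be one of dominant, allelic, genotypic.")
  }
  if (any(snps$p0 < 0 | snps$p0 > 1)) abort("p0 must lie in [0, 1].")
  if (any(unlist(snps$or) <= 0)) abort("Odds ratios must be > 0.")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 snps = snps, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

# genotype probabilities (hom-ref, het, hom-alt) in controls and cases
cohort_genotype_probs <- function(p0, or, model) {
  q0 <- 1 - p0
  g_ctrl <- c(q0^2, 2 * p0 * q0, p0^2)
  g_case <- switch(model,
    dominant = {
      carr0 <- g_ctrl[2] + g_ctrl[3]
      if (carr0 %in% c(0, 1)) {
        g_ctrl          # degenerate: no carrier contrast to tilt
      } else {
        odds1 <- carr0 / (1 - carr0) * or[1]
        carr1 <- odds1 / (1 + odds1)
        within <- g_ctrl[2:3] / carr0
        c(1 - carr1, carr1 * within)
      }
    },
    allelic = {
      if (p0 %in% c(0, 1)) g_ctrl else {
        odds1 <- p0 / q0 * or[1]
        p1 <- odds1 / (1 + odds1)
        c((1 - p1)^2, 2 * p1 * (1 - p1), p1^2)
      }
    },
    genotypic = {
      or2 <- if (length(or) >= 2) or[2] else or[1]
      w <- g_ctrl * c(1, or[1], or2)
      w / sum(w)
    }
  )
  list(control = g_ctrl, case = g_case)
}

#' Simulate a case-control genotype cohort
#'
#' @param config A [cohort_sim_config()].
#' @return A tibble with one row per subject: `subject`, `status`
#'   (`"case"`/`"control"`) and one dosage column (0/1/2 alternate alleles) per
#'   SNP. The truth (per-SNP `p0`, odds ratios, model, and the implied case
#'   genotype frequencies) is attached as attribute `"truth"`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_sim_config(p0 = 0.083, or = 0.21, seed = 7))
#' table(cohort$status, cohort$snp1)
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  n_ca <- config$n_cases; n_co <- config$n_controls
  out <- tibble(
    subject = sprintf("S%04d", seq_len(n_ca + n_co)),
    status = rep(c("case", "control"), c(n_ca, n_co))
  )
  truth <- vector("list", nrow(config$snps))
  for (k in seq_len(nrow(config$snps))) {
    s <- config$snps[k, ]
    pr <- cohort_genotype_probs(s$p0, unlist(s$or), s$model)
    g_case <- sample(0:2, n_ca, replace = TRUE, prob = pr$case)
    g_ctrl <- sample(0:2, n_co, replace = TRUE, prob = pr$control)
    out[[s$snp]] <- c(g_case, g_ctrl)
    truth[[k]] <- tibble(snp = s$snp, p0 = s$p0, or = s$or, model = s$model,
                         case_probs = list(pr$case),
                         control_probs = list(pr$control))
  }
  attr(out, "truth") <- dplyr::bind_rows(truth)
  out
}

#' Tabulate a simulated cohort into per-SNP genotype counts
#'
#' Collapses a subject-level cohort (as returned by [simulate_cohort()]) into
#' the per-SNP genotype-count layout consumed by [run_association()].
#'
#' @param cohort Subject-level cohort tibble.
#' @return A tibble with one row per SNP and genotype-count columns.
#' @export
cohort_counts <- function(cohort) {
  snp_cols <- setdiff(names(cohort), c("subject", "status"))
  purrr::map_dfr(snp_cols, function(s) {
    cnt <- function(status, dos) {
      sum(cohort$status == status & cohort[[s]] == dos, na.rm = TRUE)
    }
    tibble(snp = s,
           ctrl_hom_ref = cnt("control", 0), ctrl_het = cnt("control", 1),
           ctrl_hom_alt = cnt("control", 2),
           case_hom_ref = cnt("case", 0), case_het = cnt("case", 1),
           case_hom_alt = cnt("case", 2))
  })
}
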