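#' Run the full family prioritization workflow
#'
#' Orchestrates, for a nuclear pedigree with an affected sib pair: the
#' annotation-reduction funnel for each sibling, IBD2 segment calling and
#' filtering, and both candidate set strategies (linkage-based and
#' de-novo-based, the latter subtracting the parents' raw call sets). The
#' report carries a per-member count ladder mirroring the workflow's boxes so
#' each stage is auditable.
#'
#' @param variants Annotated variant tibble with a `gt_<id>` column per member.
#' @param pedigree Pedigree tibble.
#' @param reduction A [reduction_config()].
#' @param ibd2 An [ibd2_config()].
#' @param use_ibd2 Apply the IBD2 filter to the siblings' reduced sets. The
#'   filter assumes autosomal recessive inheritance; disable it when the model
#'   is in doubt.
#' @param genotype_aware Genotype-aware subtraction in the linkage strategy.
#' @return A `prioritization_report` list: `traces`, `segments`, `linkage`,
#'   `denovo`, `candidates`, `ladder`, `config_hash`. `tidy()` returns the
#'   ladder; `glance()` a one-row summary.
#' @export
#' @examples
#' fam <- simulate_family(family_sim_config(n_chromosomes = 2,
#'                                          n_variants_per_chrom = 500))
#' rep <- run_prioritization(fam$variants, fam$pedigree)
#' rep$ladder
run_prioritization <- function(variants, pedigree = sim_pedigree(),
                               reduction = reduction_config(),
                               ibd2 = ibd2_config(),
                               use_ibd2 = TRUE,
                               genotype_aware = FALSE) {
  roles <- ped_roles(pedigree)
  a1 <- roles$affected_pair[1]; a2 <- roles$affected_pair[2]
  if (!length(roles$unaffected_sibs)) {
    abort("Linkage strategy needs at least one unaffected sibling.")
  }
  u <- roles$unaffected_sibs[1]

  reductions <- lapply(setNames(c(a1, a2, u), c(a1, a2, u)), function(m)
    reduce_variants(variants, m, reduction))

  segments <- NULL
  sib_sets <- lapply(reductions, function(r)
    carrier_keys(r$variants, r$member, keep_genotype = genotype_aware))
  if (use_ibd2) {
    segments <- call_ibd2_segments(variants, sibs = c(a1, a2), config = ibd2)
    sib_sets <- lapply(sib_sets, filter_to_ibd2, segments = segments)
  }

  # log keys whose subtraction is blocked by a missing unaffected genotype
  shared <- dplyr::inner_join(sib_sets[[a1]][, key_cols()],
                              sib_sets[[a2]][, key_cols()], by = key_cols())
  u_gt <- dplyr::left_join(shared, variants[, c(key_cols(), paste0("gt_", u))],
                           by = key_cols())[[paste0("gt_", u)]]
  n_blocked <- sum(is.na(u_gt))
  if (n_blocked > 0) {
    inform(paste0(n_blocked, " shared key(s) have a missing genotype in the ",
                  "unaffected sib and are never subtracted."))
  }

  linkage <- linkage_strategy(sib_sets[[a1]], sib_sets[[a2]], sib_sets[[u]],
                              genotype_aware = genotype_aware)
  denovo <- denovo_strategy(sib_sets[[a1]][, key_cols()],
                            sib_sets[[a2]][, key_cols()],
                            carrier_keys(variants, roles$father),
                            carrier_keys(variants, roles$mother))

  raw_counts <- vapply(pedigree$id, function(m)
    nrow(carrier_keys(variants, m)), integer(1))
  ladder <- dplyr::bind_rows(
    tibble(member = pedigree$id, step = "raw_calls",
           n = unname(raw_counts)),
    purrr::map_dfr(reductions, function(r)
      tibble(member = r$member, step = "annotation_reduced",
             n = tail(r$trace$n_out, 1))),
    purrr::map_dfr(names(sib_sets), function(m)
      tibble(member = m, step = if (use_ibd2) "ibd2_filtered" else
        "strategy_input", n = nrow(sib_sets[[m]]))),
    tibble(member = NA_character_, step = "shared_affected",
           n = linkage$trace$n_shared),
    tibble(member = NA_character_, step = "linkage_candidates",
           n = linkage$trace$n_candidates),
    tibble(member = NA_character_, step = "denovo_candidates",
           n = denovo$trace$n_candidates)
  )

  cfg <- list(reduction = reduction, ibd2 = ibd2, use_ibd2 = use_ibd2,
              genotype_aware = genotype_aware)
  structure(list(
    traces = reductions, segments = segments,
    linkage = linkage, denovo = denovo,
    candidates = linkage$candidates,
    ladder = ladder, roles = roles,
    config = cfg, config_hash = rlang::hash(cfg)
  ), class = "prioritization_report")
}

#' @export
print.prioritization_report <- function(x, ...) {
  cat("Family variant prioritization report (config", x$config_hash, ")\n")
  print(as.data.frame(x$ladder), row.names = FALSE)
  cat(sprintf("linkage candidates: %d; de novo candidates: %d\n",
              nrow(x$linkage$candidates), nrow(x$denovo$candidates)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.prioritization_report <- function(x, ...) x$ladder

#' @exportS3Method generics::glance
glance.prioritization_report <- function(x, ...) {
  tibble(n_linkage = nrow(x$linkage$candidates),
         n_denovo = nrow(x$denovo$candidates),
         n_ibd2_segments = if (is.null(x$segments)) NA_integer_ else
           sum(x$segments$state == "IBD2"),
         config_hash = x$config_hash)
}

#' Run the case-control association workflow
#'
#' For each SNP of a genotype-count panel: an exact Hardy-Weinberg screen on
#' the controls (flagged, not fatal), odds ratios with Woolf intervals and the
#' chosen contingency test under each genetic model, and a max-statistic
#' permutation adjustment of the allelic test across the panel.
#'
#' Inputs are per-SNP genotype counts (columns `ctrl_hom_ref`, `ctrl_het`,
#' `ctrl_hom_alt`, `case_hom_ref`, `case_het`, `case_hom_alt`; see
#' [example_cohort_counts()] or [cohort_counts()]). When allele-count columns
#' (`*_ref_alleles`, `*_alt_alleles`) are also present they take precedence
#' for the allelic model; a warning is raised if they disagree with the
#' genotype-derived counts.
#'
#' @param counts Per-SNP genotype-count tibble.
#' @param models Genetic models to evaluate.
#' @param test Contingency test passed to [association_test()].
#' @param conf_level Confidence level for odds-ratio intervals.
#' @param n_perm Permutations for the allelic familywise adjustment
#'   (0 disables; subjects are reconstructed from the counts, which determines
#'   the permutation distribution exactly since subjects are exchangeable).
#' @param seed Integer seed for the permutation draw.
#' @param hwe_threshold Controls failing the exact HWE test below this level
#'   are flagged.
#' @return A tibble of class `association_scan`: one row per SNP and model
#'   with cell counts, `or`, `ci_lo`, `ci_hi`, `statistic`, `p`, control HWE
#'   results and (on allelic rows) `p_perm` and `p_perm_adj`.
#' @export
#' @examples
#' run_association(example_cohort_counts(), n_perm = 200, seed = 1)
run_association <- function(counts,
                            models = c("dominant", "heterozygote",
                                       "recessive", "allelic", "genotypic"),
                            test = "chi2",
                            conf_level = 0.95,
                            n_perm = 10000, seed = 1L,
                            hwe_threshold = 0.05) {
  counts <- as_tibble(counts)
  models <- match.arg(models, several.ok = TRUE)
  if (!nrow(counts)) {
    out <- tibble(snp = character(), model = character(), a = numeric(),
                  b = numeric(), c = numeric(), d = numeric(), or = numeric(),
                  ci_lo = numeric(), ci_hi = numeric(), statistic = numeric(),
                  p = numeric(), hwe_p_ctrl = numeric(), hwe_ok = logical(),
                  p_perm = numeric(), p_perm_adj = numeric())
    class(out) <- c("association_scan", class(out))
    return(out)
  }
  if (!"snp" %in% names(counts)) counts$snp <- paste0("snp", seq_len(nrow(counts)))
  geno_cols <- c("ctrl_hom_ref", "ctrl_het", "ctrl_hom_alt",
                 "case_hom_ref", "case_het", "case_hom_alt")
  missing_cols <- setdiff(geno_cols, names(counts))
  if (length(missing_cols)) {
    abort("Counts table is missing column(s): ",
          paste(missing_cols, collapse = ", "))
  }
  allele_cols <- c("ctrl_ref_alleles", "ctrl_alt_alleles",
                   "case_ref_alleles", "case_alt_alleles")
  has_alleles <- all(allele_cols %in% names(counts))

  rows <- purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    ctrl <- c(r$ctrl_hom_ref, r$ctrl_het, r$ctrl_hom_alt)
    case <- c(r$case_hom_ref, r$case_het, r$case_hom_alt)
    hwe_p <- hwe_exact(ctrl[1], ctrl[2], ctrl[3])
    purrr::map_dfr(models, function(mod) {
      if (mod == "genotypic") {
        tst <- association_test(collapse_model(case, ctrl, "genotypic"),
                                method = test)
        return(tibble(snp = r$snp, model = mod,
                      a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
                      or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                      haldane = NA,
                      statistic = tst$statistic, p = tst$p,
                      hwe_p_ctrl = hwe_p, hwe_ok = hwe_p >= hwe_threshold))
      }
      tab <- collapse_model(case, ctrl, mod)
      if (mod == "allelic" && has_alleles) {
        supplied <- list(a = r$case_alt_alleles, b = r$case_ref_alleles,
                         c = r$ctrl_alt_alleles, d = r$ctrl_ref_alleles)
        if (!isTRUE(all.equal(as.numeric(unlist(supplied)),
                              as.numeric(unlist(tab))))) {
          warn(paste0("SNP ", r$snp, ": supplied allele counts disagree with ",
                      "genotype-derived counts; using the supplied counts."))
        }
        tab <- supplied
      }
      haldane <- any(unlist(tab) == 0)
      orci <- odds_ratio_ci(tab$a, tab$b, tab$c, tab$d,
                            conf_level = conf_level, haldane = haldane)
      tst <- association_test(tab, method = test)
      tibble(snp = r$snp, model = mod,
             a = tab$a, b = tab$b, c = tab$c, d = tab$d,
             or = orci$or, ci_lo = orci$ci_lo, ci_hi = orci$ci_hi,
             haldane = haldane,
             statistic = tst$statistic, p = tst$p,
             hwe_p_ctrl = hwe_p, hwe_ok = hwe_p >= hwe_threshold)
    })
  })

  if (n_perm > 0) {
    cohort <- counts_to_subjects(counts)
    perm <- permutation_pvalue(cohort, n_perm = n_perm, seed = seed)
    rows <- dplyr::left_join(
      rows,
      dplyr::mutate(perm[, c("snp", "p_perm", "p_perm_adj")],
                    model = "allelic"),
      by = c("snp", "model"))
  } else {
    rows$p_perm <- NA_real_
    rows$p_perm_adj <- NA_real_
  }
  class(rows) <- c("association_scan", class(rows))
  rows
}

#' Expand a genotype-count panel into an exchangeable subject table
#'
#' @param counts Per-SNP genotype-count tibble (equal cohort sizes across
#'   SNPs are required for a joint subject table; SNPs genotyped on fewer
#'   subjects are padded per-SNP with the modal control genotype and a
#'   warning).
#' @return Subject-level tibble usable with [permutation_pvalue()].
#' @keywords internal
counts_to_subjects <- function(counts) {
  n_case <- counts$case_hom_ref + counts$case_het + counts$case_hom_alt
  n_ctrl <- counts$ctrl_hom_ref + counts$ctrl_het + counts$ctrl_hom_alt
  max_case <- max(n_case); max_ctrl <- max(n_ctrl)
  if (any(n_case != max_case) || any(n_ctrl != max_ctrl)) {
    warn("Unequal per-SNP cohort sizes (call-rate differences); smaller ",
         "panels are padded with hom-ref genotypes for the joint permutation.")
  }
  out <- tibble(
    subject = sprintf("S%04d", seq_len(max_case + max_ctrl)),
    status = rep(c("case", "control"), c(max_case, max_ctrl))
  )
  for (i in seq_len(nrow(counts))) {
    r <- counts[i, ]
    case_dos <- c(rep(0, r$case_hom_ref), rep(1, r$case_het),
                  rep(2, r$case_hom_alt), rep(0, max_case - n_case[i]))
    ctrl_dos <- c(rep(0, r$ctrl_hom_ref), rep(1, r$ctrl_het),
                  rep(2, r$ctrl_hom_alt), rep(0, max_ctrl - n_ctrl[i]))
    out[[r$snp]] <- c(case_dos, ctrl_dos)
  }
  out
}

#' Control minor-allele frequency from a counts panel
#'
#' Uses supplied allele-count columns when present (as printed panels do),
#' otherwise derives allele counts from genotypes.
#'
#' @param counts Per-SNP counts tibble.
#' @return Tibble with `snp` and `maf_ctrl` (fraction in `[0, 1]`).
#' @export
control_maf <- function(counts) {
  counts <- as_tibble(counts)
  if (all(c("ctrl_ref_alleles", "ctrl_alt_alleles") %in% names(counts))) {
    alt <- counts$ctrl_alt_alleles
    tot <- counts$ctrl_alt_alleles + counts$ctrl_ref_alleles
  } else {
    alt <- 2 * counts$ctrl_hom_alt + counts$ctrl_het
    tot <- 2 * (counts$ctrl_hom_ref + counts$ctrl_het + counts$ctrl_hom_alt)
  }
  tibble(snp = counts$snp, maf_ctrl = alt / tot)
}
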