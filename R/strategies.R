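#' Linkage-based candidate strategy
#'
#' Candidates are the variants shared by both affected siblings minus those
#' carried by the unaffected sibling: `(A1 ∩ A2) \\ U`. Membership is by
#' variant key; by default subtraction is genotype-blind (a key is removed if
#' the unaffected sib carries any alternate allele at it). With
#' `genotype_aware = TRUE` the inputs must carry a `gt` column (see
#' [carrier_keys()] with `keep_genotype = TRUE`) and subtraction removes a key
#' only when the unaffected sib's genotype matches both affected sibs'
#' (shared) genotype.
#'
#' @param affected1,affected2 Key tibbles for the two affected siblings
#'   (typically reduced and IBD2-filtered).
#' @param unaffected Key tibble for the unaffected sibling (the subtrahend).
#' @param genotype_aware Match genotypes, not just keys, when subtracting.
#' @return A `strategy_result`: list with `strategy`, `candidates` (key
#'   tibble) and `trace` (set sizes). `tidy()` returns the candidates,
#'   `glance()` the trace.
#' @export
linkage_strategy <- function(affected1, affected2, unaffected,
                             genotype_aware = FALSE) {
  a1 <- dedupe_keys(affected1, genotype_aware)
  a2 <- dedupe_keys(affected2, genotype_aware)
  u <- dedupe_keys(unaffected, genotype_aware)
  by <- if (genotype_aware) c(key_cols(), "gt") else key_cols()
  shared <- dplyr::inner_join(a1, a2, by = by)
  candidates <- dplyr::anti_join(shared, u, by = by)
  new_strategy_result("linkage", candidates[, intersect(by, names(candidates))],
                      tibble(n_affected1 = nrow(a1), n_affected2 = nrow(a2),
                             n_shared = nrow(shared),
                             n_subtrahend = nrow(u),
                             n_candidates = nrow(candidates)))
}

#' De-novo-based candidate strategy
#'
#' Candidates are the variants shared by both affected siblings that appear in
#' neither parent's raw (pre-reduction) call set:
#' `(A1 ∩ A2) \\ (P1 ∪ P2)`. Parent sets should be the full caller
#' output — subtracting reduced parental sets would leave inherited variants
#' behind.
#'
#' @param affected1,affected2 Key tibbles for the affected siblings (reduced).
#' @param parent1,parent2 Raw carrier key tibbles for the parents.
#' @return A `strategy_result` (see [linkage_strategy()]).
#' @export
denovo_strategy <- function(affected1, affected2, parent1, parent2) {
  a1 <- dedupe_keys(affected1, FALSE)
  a2 <- dedupe_keys(affected2, FALSE)
  p <- dedupe_keys(dplyr::bind_rows(parent1[, key_cols()],
                                    parent2[, key_cols()]), FALSE)
  shared <- dplyr::inner_join(a1, a2, by = key_cols())
  candidates <- dplyr::anti_join(shared, p, by = key_cols())
  new_strategy_result("denovo", candidates,
                      tibble(n_affected1 = nrow(a1), n_affected2 = nrow(a2),
                             n_shared = nrow(shared),
                             n_subtrahend = nrow(p),
                             n_candidates = nrow(candidates)))
}

dedupe_keys <- function(keys, genotype_aware) {
  keys <- as_tibble(keys)
  cols <- key_cols()
  if (genotype_aware) {
    if (!"gt" %in% names(keys)) {
      abort("genotype_aware set operations need a 'gt' column; ",
            "use carrier_keys(..., keep_genotype = TRUE).")
    }
    cols <- c(cols, "gt")
  }
  missing_cols <- setdiff(setdiff(cols, "gt"), names(keys))
  if (length(missing_cols)) {
    abort("Key tibble is missing column(s): ",
          paste(missing_cols, collapse = ", "))
  }
  dplyr::distinct(keys[, cols])
}

new_strategy_result <- function(strategy, candidates, trace) {
  structure(list(strategy = strategy,
                 candidates = as_tibble(candidates),
                 trace = trace),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("%s strategy: %d candidate variant(s)\n",
              x$strategy, nrow(x$candidates)))
  print(as.data.frame(x$trace), row.names = FALSE)
  if (nrow(x$candidates)) print(x$candidates, n = 10)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.strategy_result <- function(x, ...) x$candidates

#' @exportS3Method generics::glance
glance.strategy_result <- function(x, ...) {
  dplyr::bind_cols(tibble(strategy = x$strategy), x$trace)
}
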