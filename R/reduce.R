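#' Configuration for stepwise annotation-based variant reduction
#'
#' The funnel applies, in order: (1) restriction to variants the focal member
#' actually carries, (2) retention of putatively deleterious functional
#' classes, (3) exclusion of segmental-duplication regions, (4) exclusion of
#' variants common in population databases. The frequency step supports two
#' modes: `"threshold"` drops a variant when any consulted database reports an
#' allele frequency at or above `freq_threshold`; `"presence"` drops it when
#' any consulted database lists it at all (a stricter, frequency-blind rule).
#'
#' @param keep_classes Functional classes retained at the gene-based step.
#' @param drop_segdup Drop variants inside segmental duplications.
#' @param freq_threshold Minor-allele-frequency cutoff for `"threshold"` mode.
#' @param databases Which database columns to consult.
#' @param freq_mode `"threshold"` (default) or `"presence"`.
#' @return A `reduction_config` list.
#' @export
reduction_config <- function(keep_classes = c("exonic:nonsynonymous",
                                              "exonic:stopgain",
                                              "exonic:stoploss",
                                              "exonic:frameshift",
                                              "exonic:nonframeshift",
                                              "splicing"),
                             drop_segdup = TRUE,
                             freq_threshold = 0.01,
                             databases = c("freq_dbsnp", "freq_1000g",
                                           "freq_esp6500"),
                             freq_mode = c("threshold", "presence")) {
  freq_mode <- match.arg(freq_mode)
  if (!length(keep_classes)) abort("keep_classes must be non-empty.")
  unknown <- setdiff(keep_classes, func_classes())
  if (length(unknown)) {
    abort("Unknown functional class label(s): ", paste(unknown, collapse = ", "))
  }
  if (freq_threshold < 0 || freq_threshold > 1) {
    abort("freq_threshold must lie in [0, 1].")
  }
  bad_db <- setdiff(databases, c("freq_dbsnp", "freq_1000g", "freq_esp6500"))
  if (length(bad_db)) abort("Unknown database column(s): ",
                            paste(bad_db, collapse = ", "))
  structure(list(keep_classes = keep_classes, drop_segdup = drop_segdup,
                 freq_threshold = freq_threshold, databases = databases,
                 freq_mode = freq_mode),
            class = "reduction_config")
}

#' Reduce one member's variant calls through the annotation funnel
#'
#' @param variants Annotated variant tibble (see [read_family_vcf()] or
#'   [simulate_family()]).
#' @param member Pedigree member id whose call set enters the funnel.
#' @param config A [reduction_config()].
#' @return A `reduction_result`: list with `variants` (surviving rows),
#'   `trace` (tibble of `step`, `n_in`, `n_out`), `member` and `config`.
#'   `tidy()` returns the surviving keys, `glance()` the trace in wide form.
#' @export
#' @examples
#' fam <- simulate_family(family_sim_config(n_chromosomes = 1,
#'                                          n_variants_per_chrom = 200))
#' reduce_variants(fam$variants, "3")
reduce_variants <- function(variants, member, config = reduction_config()) {
  stopifnot(inherits(config, "reduction_config"))
  variants <- as_tibble(variants)
  col <- paste0("gt_", member)
  if (!col %in% names(variants)) {
    abort("Variants carry no genotype column for member '", member, "'.")
  }
  bad_cls <- setdiff(unique(variants$func_class[!is.na(variants$func_class)]),
                     func_classes())
  if (length(bad_cls)) {
    abort("Unknown func_class label(s) in input: ",
          paste(bad_cls, collapse = ", "))
  }

  trace <- list()
  step <- function(name, data, keep) {
    trace[[length(trace) + 1]] <<- tibble(step = name, n_in = nrow(data),
                                          n_out = sum(keep))
    data[keep, , drop = FALSE]
  }

  dos <- gt_dosage(variants[[col]])
  cur <- step("carrier", variants, !is.na(dos) & dos >= 1L)
  cur <- step("functional_class", cur,
              !is.na(cur$func_class) & cur$func_class %in% config$keep_classes)
  if (config$drop_segdup) {
    cur <- step("segdup", cur, !(cur$in_segdup %in% TRUE))
  }
  fq <- as.matrix(cur[, config$databases, drop = FALSE])
  common <- if (config$freq_mode == "threshold") {
    rowSums(!is.na(fq) & fq >= config$freq_threshold) > 0
  } else {
    rowSums(!is.na(fq)) > 0
  }
  cur <- step("frequency", cur, !common)

  structure(list(variants = cur, trace = dplyr::bind_rows(trace),
                 member = member, config = config),
            class = "reduction_result")
}

#' @export
print.reduction_result <- function(x, ...) {
  cat("Variant reduction funnel for member", x$member,
      sprintf("(frequency mode: %s)\n", x$config$freq_mode))
  print(as.data.frame(x$trace), row.names = FALSE)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.reduction_result <- function(x, ...) {
  as_tibble(x$variants[, key_cols()])
}

#' @exportS3Method generics::glance
glance.reduction_result <- function(x, ...) {
  wide <- setNames(as.list(x$trace$n_out), paste0("n_after_", x$trace$step))
  dplyr::bind_cols(tibble(member = x$member, n_input = x$trace$n_in[1]),
                   as_tibble(wide))
}
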