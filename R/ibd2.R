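#' Configuration for the IBD2 segment caller
#'
#' The caller scans the affected sib pair's genotypes: under IBD=2 the sibs
#' inherited the same haplotype from each parent, so their genotypes can
#' disagree only through genotyping error. A two-state hidden Markov model
#' (IBD2 / not-IBD2) is decoded by Viterbi over per-site incompatibility
#' calls; the incompatibility rate outside IBD2 is estimated from the data.
#'
#' @param eps Emission error rate: probability of an incompatible call inside
#'   a true IBD2 segment (driven by genotyping error).
#' @param tau Per-site state transition probability.
#' @param min_length_bp Minimum IBD2 segment length; shorter calls are demoted.
#' @param min_sites Minimum informative sites per IBD2 segment.
#' @param q_floor Lower bound for the estimated incompatibility rate outside
#'   IBD2 (keeps the model identifiable on unusually concordant data).
#' @param exclude_chroms Chromosome labels skipped entirely (sex chromosomes
#'   by default: sib-pair IBD2 logic is stated for autosomes).
#' @return An `ibd2_config` list.
#' @export
ibd2_config <- function(eps = 0.005, tau = 1e-4,
                        min_length_bp = 1e6, min_sites = 25,
                        q_floor = 0.05,
                        exclude_chroms = c("X", "Y", "chrX", "chrY")) {
  if (eps <= 0 || eps >= 0.5) abort("eps must lie in (0, 0.5).")
  if (tau <= 0 || tau >= 1) abort("tau must lie in (0, 1).")
  structure(list(eps = eps, tau = tau, min_length_bp = min_length_bp,
                 min_sites = min_sites, q_floor = q_floor,
                 exclude_chroms = exclude_chroms),
            class = "ibd2_config")
}

#' Classify a pair of sib genotypes at one site
#'
#' `incompatible` means both genotypes are called and differ (impossible under
#' IBD=2 barring error); `uninformative` means either is missing; `compatible`
#' otherwise.
#'
#' @param g1,g2 Genotype strings (see [gt_normalize()]); vectorized.
#' @return Character vector over
#'   `{"compatible", "incompatible", "uninformative"}`.
#' @export
#' @examples
#' site_compatibility(c("0/1", "0/0", "0/1"), c("0/1", "1/1", NA))
site_compatibility <- function(g1, g2) {
  g1 <- gt_normalize(g1); g2 <- gt_normalize(g2)
  dplyr::case_when(
    is.na(g1) | is.na(g2) ~ "uninformative",
    g1 != g2 ~ "incompatible",
    TRUE ~ "compatible"
  )
}

#' Call IBD2 segments for the affected sib pair
#'
#' @param variants Variant tibble with `chrom`, `pos` and genotype columns for
#'   the two siblings (`gt_<id>`).
#' @param sibs Character vector of the two sibling ids. With the `gt_a`/`gt_b`
#'   layout of [simulate_sib_pair()], use `sibs = c("a", "b")`.
#' @param config An [ibd2_config()].
#' @return A tibble of class `ibd_segments`: `chrom`, `start`, `end` (1-based,
#'   closed, spanning the informative sites of the run), `state` (`"IBD2"` /
#'   `"notIBD2"`), `n_sites`, `n_incompatible`.
#' @export
call_ibd2_segments <- function(variants, sibs, config = ibd2_config()) {
  stopifnot(inherits(config, "ibd2_config"), length(sibs) == 2)
  cols <- paste0("gt_", sibs)
  if (!all(cols %in% names(variants))) {
    abort("Variants lack genotype column(s): ",
          paste(setdiff(cols, names(variants)), collapse = ", "))
  }
  v <- dplyr::arrange(as_tibble(variants), .data$chrom, .data$pos)
  v <- v[!(v$chrom %in% config$exclude_chroms), , drop = FALSE]
  comp <- site_compatibility(v[[cols[1]]], v[[cols[2]]])
  informative <- comp != "uninformative"

  # self-calibrated incompatibility rate outside IBD2
  q_hat <- max(mean(comp[informative] == "incompatible"), config$q_floor)
  if (q_hat <= config$eps) q_hat <- min(2 * config$eps, 0.5)

  out <- list()
  for (cc in unique(v$chrom)) {
    ix <- which(v$chrom == cc & informative)
    if (length(ix) < 2) {
      warn(paste0("Chromosome ", cc, ": fewer than 2 informative sites; ",
                  "called notIBD2 throughout."))
      if (length(ix)) {
        out[[cc]] <- tibble(chrom = cc, start = v$pos[ix[1]],
                            end = v$pos[ix[length(ix)]], state = "notIBD2",
                            n_sites = length(ix),
                            n_incompatible = sum(comp[ix] == "incompatible"))
      }
      next
    }
    incomp <- comp[ix] == "incompatible"
    path <- viterbi_ibd2(incomp, config$eps, q_hat, config$tau)
    segs <- segments_from_path(v$pos[ix], incomp, path)
    segs <- demote_short_segments(segs, config)
    segs$chrom <- cc
    out[[cc]] <- segs[, c("chrom", "start", "end", "state", "n_sites",
                          "n_incompatible")]
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble(chrom = character(), start = integer(), end = integer(),
           state = character(), n_sites = integer(),
           n_incompatible = integer())
  class(res) <- c("ibd_segments", class(res))
  attr(res, "q_hat") <- q_hat
  res
}

# Viterbi decode over informative sites; state 1 = IBD2, 2 = notIBD2
viterbi_ibd2 <- function(incomp, eps, q, tau) {
  n <- length(incomp)
  le1 <- ifelse(incomp, log(eps), log1p(-eps))
  le2 <- ifelse(incomp, log(q), log1p(-q))
  lstay <- log1p(-tau); lswitch <- log(tau)
  d1 <- numeric(n); d2 <- numeric(n)
  p1 <- integer(n); p2 <- integer(n)
  d1[1] <- log(0.5) + le1[1]
  d2[1] <- log(0.5) + le2[1]
  for (i in 2:n) {
    a <- d1[i - 1] + lstay; b <- d2[i - 1] + lswitch
    if (a >= b) { d1[i] <- a + le1[i]; p1[i] <- 1L }
    else        { d1[i] <- b + le1[i]; p1[i] <- 2L }
    a <- d1[i - 1] + lswitch; b <- d2[i - 1] + lstay
    if (a >= b) { d2[i] <- a + le2[i]; p2[i] <- 1L }
    else        { d2[i] <- b + le2[i]; p2[i] <- 2L }
  }
  path <- integer(n)
  path[n] <- if (d1[n] >= d2[n]) 1L else 2L
  for (i in n:2) path[i - 1] <- if (path[i] == 1L) p1[i] else p2[i]
  path
}

segments_from_path <- function(pos, incomp, path) {
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  tibble(
    start = pos[starts], end = pos[ends],
    state = ifelse(r$values == 1L, "IBD2", "notIBD2"),
    n_sites = r$lengths,
    n_incompatible = vapply(seq_along(starts), function(k)
      sum(incomp[starts[k]:ends[k]]), integer(1))
  )
}

demote_short_segments <- function(segs, config) {
  repeat {
    short <- segs$state == "IBD2" &
      (segs$end - segs$start + 1 < config$min_length_bp |
         segs$n_sites < config$min_sites)
    if (!any(short)) break
    segs$state[short] <- "notIBD2"
    # merge adjacent equal-state runs
    r <- rle(segs$state)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1) + 1L)
    segs <- tibble(
      start = segs$start[starts], end = segs$end[ends], state = r$values,
      n_sites = vapply(seq_along(starts), function(k)
        sum(segs$n_sites[starts[k]:ends[k]]), integer(1)),
      n_incompatible = vapply(seq_along(starts), function(k)
        sum(segs$n_incompatible[starts[k]:ends[k]]), integer(1))
    )
  }
  segs
}

#' Restrict variant keys to IBD2 segments
#'
#' Keeps keys whose position lies inside an IBD2 segment on the same
#' chromosome; segment intervals are closed, so a key at a boundary position
#' is kept.
#'
#' @param keys Tibble with at least `chrom` and `pos`.
#' @param segments Segments from [call_ibd2_segments()].
#' @return The subset of `keys` inside IBD2 segments.
#' @export
filter_to_ibd2 <- function(keys, segments) {
  segs <- dplyr::filter(as_tibble(segments), .data$state == "IBD2")
  if (!nrow(segs) || !nrow(keys)) return(keys[0, , drop = FALSE])
  keep <- rep(FALSE, nrow(keys))
  for (k in seq_len(nrow(segs))) {
    keep <- keep | (keys$chrom == segs$chrom[k] &
                      keys$pos >= segs$start[k] & keys$pos <= segs$end[k])
  }
  keys[keep, , drop = FALSE]
}

#' Write IBD segments to disk
#'
#' `write_segments_bed()` uses BED convention (0-based, half-open);
#' `write_segments_tsv()` writes 1-based closed intervals with the full
#' segment annotation.
#'
#' @param segments Segments from [call_ibd2_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start - 1L,
                    end = segments$end,
                    name = segments$state)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_bed
#' @export
write_segments_tsv <- function(segments, path) {
  readr::write_tsv(as_tibble(segments), path)
  invisible(path)
}
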