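# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the code paths of the package implementation.

# Minimal representation by exhaustive trimming: consider every legal
# (suffix, prefix) trim pair, keep representations with >= 1 base per allele,
# choose the shortest; ties broken by the smallest position (left alignment).
oracle_normalize <- function(pos, ref, alt) {
  rn <- nchar(ref); an <- nchar(alt)
  best <- NULL
  for (i in 0:(min(rn, an) - 1)) {        # bases trimmed from the end
    r1 <- substr(ref, 1, rn - i); a1 <- substr(alt, 1, an - i)
    if (i > 0 && substr(ref, rn - i + 1, rn) != substr(alt, an - i + 1, an)) next
    for (j in 0:(min(nchar(r1), nchar(a1)) - 1)) { # bases trimmed at the start
      if (j > 0 && substr(r1, 1, j) != substr(a1, 1, j)) next
      r2 <- substr(r1, j + 1, nchar(r1)); a2 <- substr(a1, j + 1, nchar(a1))
      cand <- list(pos = pos + j, ref = r2, alt = a2,
                   len = nchar(r2) + nchar(a2))
      if (is.null(best) || cand$len < best$len ||
          (cand$len == best$len && cand$pos < best$pos)) {
        best <- cand
      }
    }
  }
  best[c("pos", "ref", "alt")]
}

random_allele <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Exhaustive max-probability state path for the 2-state IBD model.
# Returns the maximum achievable log probability over all 2^n paths.
oracle_viterbi_logprob <- function(incomp, eps, q, tau) {
  n <- length(incomp)
  emis <- function(state, inc) {
    e <- if (state == 1) eps else q
    if (inc) log(e) else log(1 - e)
  }
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  best <- -Inf
  for (k in seq_len(nrow(paths))) {
    s <- paths[k, ]
    lp <- log(0.5) + emis(s[1], incomp[1])
    if (n > 1) for (i in 2:n) {
      lp <- lp + (if (s[i] == s[i - 1]) log(1 - tau) else log(tau)) +
        emis(s[i], incomp[i])
    }
    if (lp > best) best <- lp
  }
  best
}

ibd2_path_logprob <- function(path, incomp, eps, q, tau) {
  n <- length(incomp)
  emis <- function(state, inc) {
    e <- if (state == 1) eps else q
    if (inc) log(e) else log(1 - e)
  }
  lp <- log(0.5) + emis(path[1], incomp[1])
  if (n > 1) for (i in 2:n) {
    lp <- lp + (if (path[i] == path[i - 1]) log(1 - tau) else log(tau)) +
      emis(path[i], incomp[i])
  }
  lp
}

# HWE exact p-value by direct enumeration with choose(); independent of the
# lgamma-based implementation in the package.
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_bb + n_ab
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  prob <- sapply(hets, function(h) {
    nbb <- (na - h) / 2
    naa <- n - h - nbb
    # multinomial genotype configurations / hypergeometric allele pairing
    choose(n, naa) * choose(n - naa, h) * 2^h / choose(2 * n, na) *
      choose(na, na) # explicit 1; allele labels fixed
  })
  prob <- prob / sum(prob)
  obs <- prob[hets == n_ab]
  sum(prob[prob <= obs * (1 + 1e-12)])
}

# Two-sided Fisher p by enumeration over the hypergeometric support using
# choose() directly.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  support <- max(0, k - n2):min(k, m)
  prob <- sapply(support, function(x)
    choose(m, x) * choose(n2, k - x) / choose(m + n2, k))
  obs <- prob[support == a]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

# Independent per-site Mendelian consistency check: every child allele pair
# must be explainable by one allele from each parent (dosage arithmetic).
mendel_inconsistent <- function(variants, pedigree) {
  roles <- ped_roles(pedigree)
  kids <- pedigree$id[!is.na(pedigree$father)]
  dad <- gt_dosage(variants[[paste0("gt_", roles$father)]])
  mom <- gt_dosage(variants[[paste0("gt_", roles$mother)]])
  half <- function(d) {
    # possible transmitted allele counts (0/1) for a parent dosage
    lapply(d, function(x) switch(x + 1L, 0L, 0:1, 1L))
  }
  from_dad <- half(dad); from_mom <- half(mom)
  bad <- rep(FALSE, nrow(variants))
  for (kid in kids) {
    g <- gt_dosage(variants[[paste0("gt_", kid)]])
    for (i in seq_along(g)) {
      if (is.na(g[i]) || is.na(dad[i]) || is.na(mom[i])) next
      ok <- any(outer(from_dad[[i]], from_mom[[i]], `+`) == g[i])
      if (!ok) bad[i] <- TRUE
    }
  }
  bad
}

# bp-level Jaccard between two segment tables (single chromosome assumed
# handled by caller filtering)
segment_jaccard <- function(a, b) {
  if (!nrow(a) && !nrow(b)) return(1)
  if (!nrow(a) || !nrow(b)) return(0)
  cover <- function(segs, grid) {
    hit <- rep(FALSE, length(grid))
    for (k in seq_len(nrow(segs))) {
      hit <- hit | (grid >= segs$start[k] & grid <= segs$end[k])
    }
    hit
  }
  lo <- min(a$start, b$start); hi <- max(a$end, b$end)
  grid <- seq(lo, hi, length.out = 20000)
  ca <- cover(a, grid); cb <- cover(b, grid)
  sum(ca & cb) / sum(ca | cb)
}

table2_counts <- function() example_cohort_counts()
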