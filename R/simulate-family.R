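#' Configuration for the pedigree variant simulator
#'
#' Defaults describe a scaled-down exome: 4 chromosomes of 100 Mb with 5,000
#' variant sites each (20,000 sites total), a Beta(0.8, 0.8) population
#' allele-frequency spectrum, recombination at 1 cM/Mb (Poisson crossovers, no
#' interference), a symmetric per-allele genotype error of 0.005, 5% of sites
#' flagged as segmental duplication, and 90% of sites "common" in the
#' population databases (so they fail the default frequency filter).
#'
#' @param n_chromosomes Number of autosomes to simulate.
#' @param chrom_length_bp Chromosome length in base pairs.
#' @param n_variants_per_chrom Variant sites per chromosome.
#' @param af_shape1,af_shape2 Beta parameters of the allele-frequency spectrum.
#' @param recomb_rate_cm_mb Genetic map density in cM/Mb (uniform).
#' @param genotype_error Per-allele symmetric miscall probability.
#' @param class_props Named numeric vector of `func_class` proportions; must
#'   name a subset of [func_classes()] and sum to 1.
#' @param frac_segdup Fraction of sites inside segmental duplications.
#' @param frac_db_common Fraction of sites assigned database frequencies at or
#'   above common thresholds (decoys removed by the frequency filter).
#' @param indel_frac Fraction of sites emitted as 1-bp deletions rather than
#'   SNVs.
#' @param seed Integer seed; the seed fully determines the output.
#' @return A `family_sim_config` list.
#' @export
family_sim_config <- function(n_chromosomes = 4,
                              chrom_length_bp = 1e8,
                              n_variants_per_chrom = 5000,
                              af_shape1 = 0.8,
                              af_shape2 = 0.8,
                              recomb_rate_cm_mb = 1.0,
                              genotype_error = 0.005,
                              class_props = default_class_props(),
                              frac_segdup = 0.05,
                              frac_db_common = 0.9,
                              indel_frac = 0.05,
                              seed = 1L) {
  probs <- c(genotype_error, frac_segdup, frac_db_common, indel_frac)
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  if (is.null(names(class_props)) ||
      !all(names(class_props) %in% func_classes())) {
    abort("class_props must be named with labels from func_classes().")
  }
  if (abs(sum(class_props) - 1) > 1e-8) abort("class_props must sum to 1.")
  if (recomb_rate_cm_mb < 0) abort("recomb_rate_cm_mb must be >= 0.")
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.integer(chrom_length_bp),
    n_variants_per_chrom = as.integer(n_variants_per_chrom),
    af_shape1 = af_shape1, af_shape2 = af_shape2,
    recomb_rate_cm_mb = recomb_rate_cm_mb,
    genotype_error = genotype_error,
    class_props = class_props,
    frac_segdup = frac_segdup,
    frac_db_common = frac_db_common,
    indel_frac = indel_frac,
    seed = as.integer(seed)
  ), class = "family_sim_config")
}

#' @rdname family_sim_config
#' @export
default_class_props <- function() {
  c("exonic:nonsynonymous" = 0.22, "exonic:synonymous" = 0.25,
    "exonic:stopgain" = 0.005, "exonic:stoploss" = 0.002,
    "exonic:frameshift" = 0.008, "exonic:nonframeshift" = 0.010,
    "splicing" = 0.010, "intronic" = 0.200, "UTR" = 0.150,
    "intergenic" = 0.080, "other" = 0.065)
}

#' Specify candidate variants to plant in a simulated family
#'
#' Each plant requests a carrier set over pedigree members. Supported patterns:
#' one parent plus any subset of children (the alternate allele is placed on a
#' founder haplotype whose realized transmissions match the request — the
#' classic "risk allele transmitted from one parent" pattern), or children
#' only (a de novo / germline-mosaic allele injected directly, absent from both
#' parents). An inconsistent request (no matching site exists) is an error
#' before emission.
#'
#' @param carriers Character vector of member ids that must carry the allele.
#' @param func_class Functional class of the planted variant.
#' @param require_ibd2 Restrict placement to sites where the affected sib pair
#'   is truly IBD=2.
#' @param id Label for the plant in the truth record.
#' @return A one-row `plant_spec` tibble; combine plants with
#'   [dplyr::bind_rows()].
#' @export
plant_spec <- function(carriers,
                       func_class = "exonic:nonsynonymous",
                       require_ibd2 = TRUE,
                       id = paste0("plant_", paste(carriers, collapse = ""))) {
  stopifnot(is.character(carriers), length(carriers) >= 1)
  tibble(id = id, carriers = list(carriers), func_class = func_class,
         require_ibd2 = require_ibd2)
}

#' Simulate whole-exome variant calls for a nuclear pedigree
#'
#' Draws four founder haplotypes per chromosome from the configured
#' allele-frequency spectrum, forms each child's haplotypes by recombining the
#' parental haplotypes (Poisson crossovers at the configured cM/Mb), plants any
#' requested candidate variants, applies the symmetric per-allele genotype
#' error, and annotates every site (functional class, segmental-duplication
#' flag, database frequencies).
#'
#' The truth record contains the realized IBD state (0/1/2) of the affected sib
#' pair along every chromosome, per-meiosis crossover counts, and the planted
#' variant keys, so downstream filters can be scored against ground truth.
#'
#' @param config A [family_sim_config()].
#' @param plants Optional [plant_spec()] tibble.
#' @param pedigree Pedigree tibble; defaults to [sim_pedigree()]. Must contain
#'   two founders and their children.
#' @param max_attempts Planted carrier patterns are realized against the
#'   simulated transmissions; when a drawn transmission offers no eligible
#'   site, the whole family is redrawn (rejection sampling over
#'   transmissions, seeded) up to this many times before the pattern is
#'   declared inconsistent.
#' @return A list of class `family_sim` with elements `variants` (annotated
#'   variant tibble with `gt_*` columns), `pedigree`, and `truth` (list with
#'   `ibd` — per-site sib-pair IBD states, `ibd_segments`, `crossovers`,
#'   `plants`).
#' @export
simulate_family <- function(config = family_sim_config(), plants = NULL,
                            pedigree = sim_pedigree(), max_attempts = 25L) {
  set.seed(config$seed)
  attempt_seeds <- sample.int(2^30, max_attempts)
  attempt_seeds[1] <- config$seed
  for (k in seq_len(max_attempts)) {
    res <- tryCatch(
      simulate_family_once(config, plants, pedigree, attempt_seeds[k]),
      sibexome_plant_error = function(e) e
    )
    if (!inherits(res, "condition")) return(res)
    if (k == max_attempts) {
      abort(conditionMessage(res),
            " (", max_attempts, " transmission draws tried.)")
    }
  }
}

plant_error <- function(...) {
  stop(structure(class = c("sibexome_plant_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

simulate_family_once <- function(config, plants, pedigree, seed) {
  validate_pedigree(pedigree)
  roles <- ped_roles(pedigree)
  founders <- pedigree$id[is.na(pedigree$father) & is.na(pedigree$mother)]
  if (length(founders) != 2) abort("Simulator expects exactly 2 founders.")
  father <- roles$father; mother <- roles$mother
  children <- pedigree$id[!is.na(pedigree$father)]
  set.seed(seed)

  per_chrom <- vector("list", config$n_chromosomes)
  xover_rec <- list()
  morgans <- config$chrom_length_bp / 1e6 * config$recomb_rate_cm_mb / 100

  for (cc in seq_len(config$n_chromosomes)) {
    n <- config$n_variants_per_chrom
    pos <- sort(sample.int(config$chrom_length_bp, n))
    af <- rbeta(n, config$af_shape1, config$af_shape2)
    # founder haplotypes: columns F1,F2 (father), M1,M2 (mother)
    hap <- matrix(rbinom(4L * n, 1L, rep(af, 4)), nrow = n, ncol = 4)
    colnames(hap) <- c("F1", "F2", "M1", "M2")

    # per-child, per-parent origin vectors (1 or 2 = which parental haplotype)
    origin <- list()
    for (kid in children) {
      for (parent in c("pat", "mat")) {
        n_x <- rpois(1, morgans)
        xover_rec[[length(xover_rec) + 1]] <-
          tibble(chrom = as.character(cc), child = kid, meiosis = parent,
                 n_crossovers = n_x)
        breaks <- sort(runif(n_x, 0, config$chrom_length_bp))
        seg_ix <- findInterval(pos, breaks)           # 0..n_x
        start <- sample(1:2, 1)
        origin[[paste(kid, parent)]] <- 1L + (start - 1L + seg_ix) %% 2L
      }
    }

    # true haplotypes (allele on transmitted strand), one matrix per member
    true_hap <- list()
    true_hap[[father]] <- hap[, c("F1", "F2")]
    true_hap[[mother]] <- hap[, c("M1", "M2")]
    for (kid in children) {
      po <- origin[[paste(kid, "pat")]]
      mo <- origin[[paste(kid, "mat")]]
      true_hap[[kid]] <- cbind(
        hap[cbind(seq_len(n), po)],         # F1/F2 columns are 1,2
        hap[cbind(seq_len(n), 2L + mo)]     # M1/M2 columns are 3,4
      )
    }

    sib1 <- roles$affected_pair[1]; sib2 <- roles$affected_pair[2]
    ibd <- as.integer(origin[[paste(sib1, "pat")]] == origin[[paste(sib2, "pat")]]) +
           as.integer(origin[[paste(sib1, "mat")]] == origin[[paste(sib2, "mat")]])

    per_chrom[[cc]] <- list(chrom = as.character(cc), pos = pos, af = af,
                            hap = hap, origin = origin, true_hap = true_hap,
                            ibd = ibd)
  }

  # ---- plants --------------------------------------------------------------
  plant_truth <- list()
  if (!is.null(plants) && nrow(plants)) {
    for (k in seq_len(nrow(plants))) {
      carriers <- plants$carriers[[k]]
      unknown <- setdiff(carriers, pedigree$id)
      if (length(unknown)) abort("Unknown plant carrier(s): ",
                                 paste(unknown, collapse = ", "))
      parents_in <- intersect(carriers, c(father, mother))
      placed <- FALSE
      if (length(parents_in) == 0) {
        # de novo injection: flip one allele in each carrier child at a site
        # where everyone is currently homozygous reference
        for (cc in seq_along(per_chrom)) {
          ch <- per_chrom[[cc]]
          if (plants$require_ibd2[k]) ok_ibd <- ch$ibd == 2L else ok_ibd <- TRUE
          all_ref <- Reduce(`&`, lapply(ch$true_hap, function(m) m[, 1] + m[, 2] == 0))
          cand <- which(all_ref & ok_ibd)
          if (length(cand)) {
            j <- cand[ceiling(length(cand) / 2)]
            for (m in carriers) per_chrom[[cc]]$true_hap[[m]][j, 1] <- 1L
            plant_truth[[length(plant_truth) + 1]] <-
              tibble(id = plants$id[k], chrom = ch$chrom, site = j,
                     func_class = plants$func_class[k])
            placed <- TRUE
            break
          }
        }
      } else if (length(parents_in) == 1) {
        src <- parents_in[1]
        kid_carriers <- setdiff(carriers, src)
        kid_non <- setdiff(children, kid_carriers)
        haps <- if (src == father) c(1L, 2L) else c(1L, 2L)
        side <- if (src == father) "pat" else "mat"
        for (cc in seq_along(per_chrom)) {
          ch <- per_chrom[[cc]]
          for (h in haps) {
            got_h <- vapply(children, function(kid)
              ch$origin[[paste(kid, side)]] == h, logical(length(ch$pos)))
            ok <- rep(TRUE, length(ch$pos))
            for (kid in kid_carriers) ok <- ok & got_h[, kid]
            for (kid in kid_non) ok <- ok & !got_h[, kid]
            if (plants$require_ibd2[k]) ok <- ok & ch$ibd == 2L
            cand <- which(ok)
            if (!length(cand)) next
            # prefer the site deepest inside its run of eligible sites
            runs <- cumsum(c(1, diff(cand) != 1))
            depth <- stats::ave(seq_along(cand), runs, FUN = function(ix) {
              r <- seq_along(ix); pmin(r, rev(r))
            })
            j <- cand[which.max(depth)]
            col <- if (src == father) h else 2L + h
            # place the alternate allele on founder haplotype h only
            per_chrom[[cc]]$hap[j, ] <- 0L
            per_chrom[[cc]]$hap[j, col] <- 1L
            # rebuild true haplotypes at that site
            per_chrom[[cc]]$true_hap[[father]][j, ] <- per_chrom[[cc]]$hap[j, 1:2]
            per_chrom[[cc]]$true_hap[[mother]][j, ] <- per_chrom[[cc]]$hap[j, 3:4]
            for (kid in children) {
              po <- ch$origin[[paste(kid, "pat")]][j]
              mo <- ch$origin[[paste(kid, "mat")]][j]
              per_chrom[[cc]]$true_hap[[kid]][j, ] <-
                c(per_chrom[[cc]]$hap[j, po], per_chrom[[cc]]$hap[j, 2L + mo])
            }
            plant_truth[[length(plant_truth) + 1]] <-
              tibble(id = plants$id[k], chrom = ch$chrom, site = j,
                     func_class = plants$func_class[k])
            placed <- TRUE
            break
          }
          if (placed) break
        }
      } else {
        abort("Plant '", plants$id[k], "': carrier sets containing both ",
              "parents are not supported.")
      }
      if (!placed) {
        plant_error("Plant '", plants$id[k], "' is inconsistent with the ",
                    "generated transmissions: no eligible site found")
      }
    }
  }
  plant_truth <- if (length(plant_truth)) dplyr::bind_rows(plant_truth) else
    tibble(id = character(), chrom = character(), site = integer(),
           func_class = character())

  # ---- emit annotated variant table ---------------------------------------
  members <- pedigree$id
  tabs <- vector("list", length(per_chrom))
  seg_truth <- vector("list", length(per_chrom))
  for (cc in seq_along(per_chrom)) {
    ch <- per_chrom[[cc]]
    n <- length(ch$pos)
    planted_here <- plant_truth$site[plant_truth$chrom == ch$chrom]

    is_indel <- runif(n) < config$indel_frac
    base <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt_snv <- vapply(base, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    next_base <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    ref <- ifelse(is_indel, paste0(base, next_base), base)
    alt <- ifelse(is_indel, base, alt_snv)

    cls <- sample(names(config$class_props), n, replace = TRUE,
                  prob = config$class_props)
    segdup <- runif(n) < config$frac_segdup
    common <- runif(n) < config$frac_db_common
    fq <- matrix(NA_real_, n, 3)
    # common sites: registered everywhere near their population frequency
    fq[common, 1] <- pmax(ch$af[common], 0.02)
    fq[common, 2] <- pmax(ch$af[common], 0.02)
    fq[common, 3] <- pmax(ch$af[common], 0.02)
    # rare sites: half absent everywhere, half registered rare in one database
    rare <- which(!common)
    listed <- rare[runif(length(rare)) < 0.5]
    which_db <- sample.int(3, length(listed), replace = TRUE)
    fq[cbind(listed, which_db)] <- runif(length(listed), 0, 0.009)

    if (length(planted_here)) {
      cls[planted_here] <- plant_truth$func_class[plant_truth$chrom == ch$chrom]
      segdup[planted_here] <- FALSE
      fq[planted_here, ] <- NA_real_
    }

    tab <- tibble(chrom = ch$chrom, pos = ch$pos, ref = ref, alt = alt,
                  func_class = cls, in_segdup = segdup,
                  freq_dbsnp = fq[, 1], freq_1000g = fq[, 2],
                  freq_esp6500 = fq[, 3])
    for (m in members) {
      th <- ch$true_hap[[m]]
      a1 <- th[, 1]; a2 <- th[, 2]
      if (config$genotype_error > 0) {
        flip1 <- runif(n) < config$genotype_error
        flip2 <- runif(n) < config$genotype_error
        a1 <- ifelse(flip1, 1L - a1, a1)
        a2 <- ifelse(flip2, 1L - a2, a2)
      }
      tab[[paste0("gt_", m)]] <- paste0(pmin(a1, a2), "/", pmax(a1, a2))
    }
    tabs[[cc]] <- tab
    seg_truth[[cc]] <- runs_to_segments(ch$chrom, ch$pos, ch$ibd)
  }

  variants <- normalize_keys(dplyr::bind_rows(tabs))
  ibd_sites <- dplyr::bind_rows(lapply(per_chrom, function(ch)
    tibble(chrom = ch$chrom, pos = ch$pos, ibd = ch$ibd)))
  plant_keys <- if (nrow(plant_truth)) {
    dplyr::bind_rows(lapply(seq_len(nrow(plant_truth)), function(k) {
      ch <- per_chrom[[as.integer(plant_truth$chrom[k])]]
      j <- plant_truth$site[k]
      vv <- tabs[[as.integer(plant_truth$chrom[k])]][j, key_cols()]
      normalize_keys(dplyr::mutate(vv, id = plant_truth$id[k]))
    }))
  } else {
    tibble(chrom = character(), pos = integer(), ref = character(),
           alt = character(), id = character())
  }

  structure(list(
    variants = variants,
    pedigree = pedigree,
    truth = list(
      ibd = ibd_sites,
      ibd_segments = dplyr::bind_rows(seg_truth),
      crossovers = dplyr::bind_rows(xover_rec),
      plants = plant_keys
    ),
    config = config
  ), class = "family_sim")
}

# collapse a per-site integer state vector into run segments
runs_to_segments <- function(chrom, pos, state) {
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  tibble(chrom = chrom, start = pos[starts], end = pos[ends],
         ibd = r$values, n_sites = r$lengths)
}

#' Simulate a sib-pair chromosome conditional on a known IBD path
#'
#' Generates genotypes for two full siblings given the true per-site IBD state
#' (0, 1 or 2), by drawing founder haplotypes from the allele-frequency
#' spectrum and sharing 0, 1 or 2 parental haplotypes per site as requested.
#' Used to score the IBD2 segment caller against a controlled truth.
#'
#' @param ibd_states Integer vector of per-site truth IBD states (0/1/2).
#' @param positions Site positions in bp (sorted, same length).
#' @param af Per-site population allele frequencies; a single value recycles.
#' @param genotype_error Per-allele symmetric miscall probability.
#' @param seed Integer seed.
#' @return A tibble with `chrom`, `pos`, `ibd` (truth), `gt_a`, `gt_b`.
#' @export
simulate_sib_pair <- function(ibd_states, positions,
                              af = NULL, genotype_error = 0.005, seed = 1L) {
  n <- length(ibd_states)
  stopifnot(length(positions) == n, all(ibd_states %in% 0:2))
  set.seed(seed)
  if (is.null(af)) af <- rbeta(n, 0.8, 0.8)
  af <- rep_len(af, n)
  # four independent parental haplotype draws per site
  h <- matrix(rbinom(4L * n, 1L, rep(af, 4)), nrow = n)
  a_pat <- h[, 1]; a_mat <- h[, 3]
  # sib b shares the maternal haplotype when IBD >= 1, both when IBD == 2
  b_pat <- ifelse(ibd_states == 2L, h[, 1], h[, 2])
  b_mat <- ifelse(ibd_states >= 1L, h[, 3], h[, 4])
  emit <- function(x1, x2) {
    if (genotype_error > 0) {
      x1 <- ifelse(runif(n) < genotype_error, 1L - x1, x1)
      x2 <- ifelse(runif(n) < genotype_error, 1L - x2, x2)
    }
    paste0(pmin(x1, x2), "/", pmax(x1, x2))
  }
  tibble(chrom = "1", pos = positions, ibd = as.integer(ibd_states),
         gt_a = emit(a_pat, a_mat), gt_b = emit(b_pat, b_mat))
}
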