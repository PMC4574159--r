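#' Functional annotation classes
#'
#' The controlled vocabulary for the `func_class` annotation column. Classes
#' follow the usual exome-annotator breakdown of coding consequence plus
#' coarse genomic context.
#'
#' @return Character vector of the recognized class labels.
#' @export
func_classes <- function() {
  c("exonic:nonsynonymous", "exonic:stopgain", "exonic:stoploss",
    "exonic:synonymous", "exonic:frameshift", "exonic:nonframeshift",
    "splicing", "intronic", "UTR", "intergenic", "other")
}

annotation_cols <- function() {
  c("func_class", "in_segdup", "freq_dbsnp", "freq_1000g", "freq_esp6500")
}

key_cols <- function() c("chrom", "pos", "ref", "alt")

# ---- genotypes -------------------------------------------------------------

#' Genotype helpers
#'
#' Genotypes are stored as unordered strings over allele indices, e.g. `"0/1"`;
#' missing is `NA`. `gt_normalize()` sorts the two alleles so `"1/0"` and
#' `"0/1"` compare equal; `gt_dosage()` counts alternate alleles (0, 1, 2 or
#' `NA`).
#'
#' @param gt Character vector of genotype strings (`"a/b"` or `"a|b"`; `"."`
#'   for a missing allele).
#' @return `gt_normalize()`: normalized genotype strings; `gt_dosage()`:
#'   integer alternate-allele counts.
#' @export
gt_normalize <- function(gt) {
  if (!length(gt)) return(character(0))
  gt <- gsub("|", "/", gt, fixed = TRUE)
  miss <- is.na(gt) | !grepl("^[0-9]+/[0-9]+$", gt)
  parts <- strsplit(ifelse(miss, "0/0", gt), "/", fixed = TRUE)
  out <- vapply(parts, function(p) {
    p <- sort(as.integer(p))
    paste0(p[1], "/", p[2])
  }, character(1))
  out[miss] <- NA_character_
  out
}

#' @rdname gt_normalize
#' @export
gt_dosage <- function(gt) {
  gt <- gt_normalize(gt)
  a1 <- as.integer(substr(gt, 1, 1))
  a2 <- as.integer(substr(gt, 3, 3))
  as.integer((a1 > 0) + (a2 > 0))
}

# ---- key normalization -----------------------------------------------------

#' Normalize variant keys to a minimal left-aligned representation
#'
#' Trims shared trailing bases, then shared leading bases (advancing `pos`),
#' keeping at least one base in each allele. This makes set operations over
#' `(chrom, pos, ref, alt)` keys well-defined for indels; the operation is
#' idempotent.
#'
#' @param variants A data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (additional columns pass through untouched).
#' @return A tibble with normalized `pos`, `ref`, `alt`.
#' @export
#' @examples
#' normalize_keys(tibble::tibble(chrom = "1", pos = 100, ref = "CT", alt = "CA"))
normalize_keys <- function(variants) {
  variants <- as_tibble(variants)
  stopifnot(all(key_cols() %in% names(variants)))
  ref <- toupper(variants$ref)
  alt <- toupper(variants$alt)
  bad <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt)
  if (any(bad)) {
    abort("Non-ACGT allele(s) at row(s): ",
          paste(head(which(bad), 5), collapse = ", "))
  }
  if (any(ref == alt)) {
    abort("ref equals alt at row(s): ",
          paste(head(which(ref == alt), 5), collapse = ", "))
  }
  if (any(variants$pos < 1)) abort("pos must be >= 1.")
  pos <- as.integer(variants$pos)
  needs <- which(nchar(ref) > 1 & nchar(alt) > 1)
  for (i in needs) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    # trim common suffix
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1)
      a <- substr(a, 1, nchar(a) - 1)
    }
    # trim common prefix, advancing pos
    while (nchar(r) > 1 && nchar(a) > 1 && substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r))
      a <- substr(a, 2, nchar(a))
      p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  variants$pos <- pos
  variants$ref <- ref
  variants$alt <- alt
  variants
}

#' @rdname normalize_keys
#' @param chrom,pos,ref,alt Components of a single raw VCF-style key.
#' @export
normalize_key <- function(chrom, pos, ref, alt) {
  normalize_keys(tibble(chrom = chrom, pos = pos, ref = ref, alt = alt))
}

# ---- annotation tables -----------------------------------------------------

#' Read or write a variant annotation table
#'
#' The side annotation table is a TSV keyed by `(chrom, pos, ref, alt)` with
#' columns `func_class`, `in_segdup` and population-database allele
#' frequencies `freq_dbsnp`, `freq_1000g`, `freq_esp6500` (empty = not
#' registered in that database).
#'
#' @param path Path to the TSV.
#' @return A tibble with the key and annotation columns.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chrom = readr::col_character(),
                           pos = readr::col_integer(),
                           ref = readr::col_character(),
                           alt = readr::col_character(),
                           func_class = readr::col_character(),
                           in_segdup = readr::col_logical(),
                           freq_dbsnp = readr::col_double(),
                           freq_1000g = readr::col_double(),
                           freq_esp6500 = readr::col_double()
                         ))
  missing_cols <- setdiff(c(key_cols(), annotation_cols()), names(ann))
  if (length(missing_cols)) {
    abort("Annotation table is missing required columns: ",
          paste(missing_cols, collapse = ", "))
  }
  check_freq_range(ann)
  normalize_keys(ann)
}

#' @rdname read_annotations
#' @param annotations A tibble with key and annotation columns.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(all(c(key_cols(), annotation_cols()) %in% names(annotations)))
  readr::write_tsv(annotations[, c(key_cols(), annotation_cols())], path)
  invisible(path)
}

check_freq_range <- function(df) {
  for (col in c("freq_dbsnp", "freq_1000g", "freq_esp6500")) {
    x <- df[[col]]
    if (any(!is.na(x) & (x < 0 | x > 1))) {
      abort("Column ", col, " has values outside [0, 1].")
    }
  }
  invisible(df)
}

# ---- VCF I/O ---------------------------------------------------------------

#' Read a multi-sample family VCF into an annotated variant table
#'
#' Reads a VCF with one sample column per pedigree member, splits multi-allelic
#' records into one row per alternate allele, normalizes keys, and joins
#' per-variant annotation either from a side table or from the `FUNC`/`SEGDUP`/
#' `FDBSNP`/`F1KG`/`FESP` INFO keys written by [write_family_vcf()].
#'
#' In a split multi-allelic record, alleles other than the focal alternate are
#' coded as reference, so each row's genotypes refer to a biallelic site.
#'
#' @param path Path to a VCF 4.x file (plain text or gzipped).
#' @param pedigree Pedigree tibble; every member id must be a VCF sample.
#' @param annotations Optional annotation tibble (see [read_annotations()]);
#'   if `NULL`, annotation is parsed from INFO when present.
#' @return A tibble with key columns, annotation columns and one genotype
#'   column per member, named `gt_<id>`.
#' @export
read_family_vcf <- function(path, pedigree, annotations = NULL) {
  validate_pedigree(pedigree)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_mat <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt_mat)
  absent <- setdiff(pedigree$id, samples)
  if (length(absent)) {
    abort("VCF is missing sample column(s) for pedigree member(s): ",
          paste(absent, collapse = ", "))
  }
  pos <- as.integer(fix$POS)
  # unsorted input is a hard error: the set algebra assumes one pass per chrom
  unsorted <- tapply(pos, factor(fix$CHROM, levels = unique(fix$CHROM)),
                     function(p) any(diff(p) < 0))
  if (any(unlist(unsorted))) {
    abort("VCF records are not position-sorted within chromosome(s): ",
          paste(names(which(unlist(unsorted))), collapse = ", "))
  }

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  row_id <- rep(seq_along(pos), n_alt)
  alt_ix <- sequence(n_alt)

  out <- tibble(
    chrom = fix$CHROM[row_id],
    pos = pos[row_id],
    ref = fix$REF[row_id],
    alt = unlist(alts),
    .row = row_id,
    .alt_ix = alt_ix
  )

  for (m in pedigree$id) {
    raw <- gt_mat[out$.row, m]
    out[[paste0("gt_", m)]] <- recode_split_gt(raw, out$.alt_ix)
  }

  info <- fix$INFO[out$.row]
  out <- dplyr::select(out, -".row", -".alt_ix")
  out <- normalize_keys(out)

  dup <- duplicated(out[, key_cols()])
  if (any(dup)) {
    d <- out[which(dup)[1], ]
    abort("Duplicated variant key after normalization: ",
          paste(d$chrom, d$pos, d$ref, d$alt, collapse = " "))
  }

  if (!is.null(annotations)) {
    ann <- normalize_keys(as_tibble(annotations))
    check_freq_range(ann)
    out <- dplyr::left_join(out, ann[, c(key_cols(), annotation_cols())],
                            by = key_cols())
  } else {
    out <- dplyr::bind_cols(out, parse_info_annotation(info))
  }
  out[, c(key_cols(), annotation_cols(),
          paste0("gt_", pedigree$id))]
}

# map one alternate allele of a (possibly multi-allelic) genotype onto 0/1
recode_split_gt <- function(gt, alt_ix) {
  if (!length(gt)) return(character(0))
  gt <- gsub("|", "/", gt, fixed = TRUE)
  miss <- is.na(gt) | !grepl("^[0-9]+/[0-9]+$", gt)
  parts <- strsplit(ifelse(miss, "0/0", gt), "/", fixed = TRUE)
  a1 <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  a2 <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  b1 <- as.integer(a1 == alt_ix)
  b2 <- as.integer(a2 == alt_ix)
  out <- paste0(pmin(b1, b2), "/", pmax(b1, b2))
  out[miss] <- NA_character_
  out
}

parse_info_annotation <- function(info) {
  info[is.na(info)] <- "."
  get_tag <- function(tag) {
    hit <- regexpr(paste0("(^|;)", tag, "=[^;]*"), info)
    val <- rep(NA_character_, length(info))
    ok <- !is.na(hit) & hit > 0
    if (any(ok)) {
      val[ok] <- sub(paste0("^;?", tag, "="), "", regmatches(info, hit))
    }
    val
  }
  tibble(
    func_class = get_tag("FUNC"),
    in_segdup = grepl("(^|;)SEGDUP(;|$)", info),
    freq_dbsnp = as.numeric(get_tag("FDBSNP")),
    freq_1000g = as.numeric(get_tag("F1KG")),
    freq_esp6500 = as.numeric(get_tag("FESP"))
  )
}

#' Write an annotated variant table as a multi-sample VCF
#'
#' Emits a biallelic, position-sorted VCF 4.2 with annotation encoded in INFO
#' (`FUNC`, `SEGDUP`, `FDBSNP`, `F1KG`, `FESP`) and one `GT` sample column per
#' genotype column of the table, so that [read_family_vcf()] round-trips keys,
#' genotypes and annotation exactly.
#'
#' @param variants Annotated variant tibble (key + annotation + `gt_*`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family_vcf <- function(variants, path) {
  gt_cols <- grep("^gt_", names(variants), value = TRUE)
  members <- sub("^gt_", "", gt_cols)
  v <- dplyr::arrange(variants, .data$chrom, .data$pos, .data$ref, .data$alt)
  info <- paste0(
    ifelse(is.na(v$func_class), "", paste0("FUNC=", v$func_class, ";")),
    ifelse(!is.na(v$in_segdup) & v$in_segdup, "SEGDUP;", ""),
    ifelse(is.na(v$freq_dbsnp), "", paste0("FDBSNP=", format(v$freq_dbsnp, digits = 15), ";")),
    ifelse(is.na(v$freq_1000g), "", paste0("F1KG=", format(v$freq_1000g, digits = 15), ";")),
    ifelse(is.na(v$freq_esp6500), "", paste0("FESP=", format(v$freq_esp6500, digits = 15), ";"))
  )
  info <- sub(";$", "", info)
  info[info == ""] <- "."
  gts <- do.call(cbind, lapply(gt_cols, function(col) {
    g <- gt_normalize(v[[col]])
    ifelse(is.na(g), "./.", g)
  }))
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=FUNC,Number=1,Type=String,Description=\"Functional class\">",
    "##INFO=<ID=SEGDUP,Number=0,Type=Flag,Description=\"In segmental duplication\">",
    "##INFO=<ID=FDBSNP,Number=1,Type=Float,Description=\"dbSNP allele frequency\">",
    "##INFO=<ID=F1KG,Number=1,Type=Float,Description=\"1000 Genomes allele frequency\">",
    "##INFO=<ID=FESP,Number=1,Type=Float,Description=\"ESP6500 allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", members), collapse = "\t")
  )
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, "GT",
                apply(gts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Variant keys carried by one pedigree member
#'
#' A member "carries" a variant when the genotype holds at least one alternate
#' allele; a missing genotype is never treated as carrying.
#'
#' @param variants Annotated variant tibble.
#' @param member Member id (the `gt_<member>` column is used).
#' @param keep_genotype Keep the member's genotype column (as `gt`) for
#'   genotype-aware set operations.
#' @return Tibble of `(chrom, pos, ref, alt)` keys (plus `gt` if requested).
#' @export
carrier_keys <- function(variants, member, keep_genotype = FALSE) {
  col <- paste0("gt_", member)
  if (!col %in% names(variants)) {
    abort("No genotype column for member '", member, "'.")
  }
  dos <- gt_dosage(variants[[col]])
  out <- variants[!is.na(dos) & dos >= 1, , drop = FALSE]
  keys <- out[, key_cols()]
  if (keep_genotype) keys$gt <- gt_normalize(out[[col]])
  as_tibble(keys)
}
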