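#' Read a pedigree from a PED/FAM file
#'
#' Parses the six leading columns of a PED/FAM file (family id, individual id,
#' father id, mother id, sex, phenotype) into a pedigree tibble. Any trailing
#' genotype columns are ignored. Parent id `0` means founder; phenotype `2`
#' means affected, `1` unaffected, anything else missing.
#'
#' @param path Path to a whitespace-delimited PED or FAM file.
#' @return A tibble with columns `id`, `father`, `mother` (character, `NA` for
#'   founders), `sex` (integer, 1 = male, 2 = female, `NA` unknown) and
#'   `affected` (logical).
#' @export
#' @examples
#' ped_file <- tempfile(fileext = ".ped")
#' write_pedigree(sim_pedigree(), ped_file)
#' read_pedigree(ped_file)
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 6) {
    abort("PED/FAM file must have at least 6 columns (found ", ncol(raw), ").")
  }
  ped <- tibble(
    id       = raw[[2]],
    father   = ifelse(raw[[3]] == "0", NA_character_, raw[[3]]),
    mother   = ifelse(raw[[4]] == "0", NA_character_, raw[[4]]),
    sex      = ifelse(raw[[5]] %in% c("1", "2"), as.integer(raw[[5]]), NA_integer_),
    affected = dplyr::case_when(raw[[6]] == "2" ~ TRUE,
                                raw[[6]] == "1" ~ FALSE,
                                TRUE ~ NA)
  )
  if (anyDuplicated(ped$id)) {
    abort("Duplicated individual ids in pedigree: ",
          paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  # order so that parents precede children, but keep input order otherwise
  validate_pedigree(ped)
  ped
}

#' Write a pedigree to a PED file
#'
#' @param pedigree A pedigree tibble (see [read_pedigree()]).
#' @param path Output path.
#' @param family_id Family identifier written in column 1.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path, family_id = "FAM1") {
  validate_pedigree(pedigree)
  out <- data.frame(
    fam = family_id,
    id = pedigree$id,
    father = ifelse(is.na(pedigree$father), "0", pedigree$father),
    mother = ifelse(is.na(pedigree$mother), "0", pedigree$mother),
    sex = ifelse(is.na(pedigree$sex), "0", as.character(pedigree$sex)),
    phe = ifelse(is.na(pedigree$affected), "0", ifelse(pedigree$affected, "2", "1"))
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_pedigree <- function(pedigree) {
  needed <- c("id", "father", "mother", "sex", "affected")
  missing_cols <- setdiff(needed, names(pedigree))
  if (length(missing_cols)) {
    abort("Pedigree is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("father", "mother")) {
    refs <- pedigree[[col]]
    bad <- !is.na(refs) & !(refs %in% pedigree$id)
    if (any(bad)) {
      abort("Pedigree ", col, " reference(s) do not resolve: ",
            paste(unique(refs[bad]), collapse = ", "))
    }
  }
  invisible(pedigree)
}

#' Default five-member study pedigree
#'
#' Two unaffected founders (father `1`, mother `2`) and three sons: the first
#' (`3`) and third (`5`) affected, the second (`4`) unaffected. This is the
#' nuclear-family structure the prioritization strategies assume: an affected
#' sib pair plus an unaffected sib.
#'
#' @return A pedigree tibble.
#' @export
#' @examples
#' ped_roles(sim_pedigree())
sim_pedigree <- function() {
  tibble(
    id       = c("1", "2", "3", "4", "5"),
    father   = c(NA, NA, "1", "1", "1"),
    mother   = c(NA, NA, "2", "2", "2"),
    sex      = c(1L, 2L, 1L, 1L, 1L),
    affected = c(FALSE, FALSE, TRUE, FALSE, TRUE)
  )
}

#' Derive family roles from a pedigree
#'
#' Identifies the affected sib pair (exactly two affected full siblings), their
#' parents, and any unaffected full siblings. These roles drive the reduction,
#' IBD2, and set-strategy stages.
#'
#' @param pedigree A pedigree tibble.
#' @return A list with elements `father`, `mother`, `affected_pair` (character
#'   vector of length 2) and `unaffected_sibs` (character vector, possibly
#'   empty).
#' @export
ped_roles <- function(pedigree) {
  validate_pedigree(pedigree)
  kids <- dplyr::filter(pedigree, !is.na(.data$father) & !is.na(.data$mother))
  aff <- dplyr::filter(kids, .data$affected %in% TRUE)
  if (nrow(aff) != 2) {
    abort("Affected sib-pair analysis needs exactly 2 affected non-founder ",
          "siblings; found ", nrow(aff), ".")
  }
  if (length(unique(aff$father)) != 1 || length(unique(aff$mother)) != 1) {
    abort("The two affected individuals do not share both parents; ",
          "affected sib-pair analysis is not applicable.")
  }
  sibs <- dplyr::filter(kids, .data$father == aff$father[1],
                        .data$mother == aff$mother[1])
  list(
    father = aff$father[1],
    mother = aff$mother[1],
    affected_pair = sort(aff$id),
    unaffected_sibs = sibs$id[!(sibs$id %in% aff$id) & sibs$affected %in% FALSE]
  )
}
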