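#' The built-in prostaglandin-metabolism enzyme vocabulary
#'
#' Controlled vocabulary of the nine prostaglandin (Pg) metabolism functions
#' recovered from Swiss-Prot annotations of dinoflagellate transcriptomes:
#' the pathway-initiating cyclooxygenase (COX2), the terminal synthases
#' HPGDS, PTGES2, PTGFS1 and PTGFS2, the reductase PGE2-9-OR, and the
#' catabolic (inactivating) enzymes 15-PGDH, PTGR1 and PTGR2. Six entries
#' carry the `synthesis` role and three the `catabolism` role.
#'
#' Synonyms cover the Swiss-Prot protein names and the common abbreviations,
#' and drive [canonicalize()]: a description is assigned to a code when it
#' contains one of that code's synonyms (case-insensitive substring,
#' longest synonym tried first).
#'
#' @param path Optional path to a vocabulary TSV with columns `code`,
#'   `full_name`, `role` (`synthesis` or `catabolism`) and `synonyms`
#'   (pipe-separated). When `NULL` (default) the built-in nine-entry
#'   vocabulary is returned.
#' @return A tibble with columns `code`, `full_name`, `role` and `synonyms`
#'   (a list-column of character vectors).
#' @examples
#' pg_vocabulary()
#' @export
pg_vocabulary <- function(path = NULL) {
  if (!is.null(path)) {
    return(read_vocabulary(path))
  }
  voc <- tibble::tribble(
    ~code, ~full_name, ~role, ~synonyms,
    "COX2", "Prostaglandin G/H synthase 2", "synthesis",
    c("Prostaglandin G/H synthase 2", "PTG/HS2", "COX2", "Cyclooxygenase-2",
      "Cyclooxygenase 2", "PGHS-2"),
    "HPGDS", "Hematopoietic prostaglandin D synthase", "synthesis",
    c("Hematopoietic prostaglandin D synthase", "HPGDS",
      "Glutathione-requiring prostaglandin D synthase"),
    "PTGES2", "Prostaglandin E synthase 2", "synthesis",
    c("Prostaglandin E synthase 2", "PTGES2"),
    "PGE2-9-OR", "Prostaglandin-E(2) 9-reductase", "synthesis",
    c("Prostaglandin-E(2) 9-reductase", "Prostaglandin E2 9-reductase",
      "PGE2-9-OR", "PGE(2)-9-OR", "9OXORED", "PGE 9-ketoreductase"),
    "15-PGDH", "15-hydroxyprostaglandin dehydrogenase [NAD(+)]", "catabolism",
    c("15-hydroxyprostaglandin dehydrogenase [NAD(+)]",
      "15-hydroxyprostaglandin dehydrogenase [NAD+]",
      "15-hydroxyprostaglandin dehydrogenase", "15-PGDH", "15-HPGD"),
    "PTGFS1", "Prostaglandin F synthase 1", "synthesis",
    c("Prostaglandin F synthase 1", "PTGFS1"),
    "PTGFS2", "Prostaglandin F synthase 2", "synthesis",
    c("Prostaglandin F synthase 2", "PTGFS2"),
    "PTGR1", "Prostaglandin reductase 1", "catabolism",
    c("Prostaglandin reductase 1", "PTGR1"),
    "PTGR2", "Prostaglandin reductase 2", "catabolism",
    c("Prostaglandin reductase 2", "PTGR2")
  )
  # presentation order of the occurrence tables
  voc <- voc[match(pg_function_codes(), voc$code), ]
  validate_vocabulary(voc)
}

#' Canonical function-code order
#'
#' Fixed column order used by every presence/occurrence surface.
#'
#' @return Character vector of the nine codes.
#' @export
pg_function_codes <- function() {
  c("COX2", "HPGDS", "PTGES2", "PGE2-9-OR", "15-PGDH",
    "PTGFS1", "PTGFS2", "PTGR1", "PTGR2")
}

#' Read a vocabulary TSV
#'
#' @param path TSV with columns `code`, `full_name`, `role`, `synonyms`
#'   (pipe-separated).
#' @return Vocabulary tibble, as [pg_vocabulary()].
#' @export
read_vocabulary <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("vocabulary file not found: ", path), class = "pgmine_io_error")
  }
  voc <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("code", "full_name", "role", "synonyms")
  missing <- setdiff(required, names(voc))
  if (length(missing) > 0) {
    abort(paste0("vocabulary file lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "pgmine_validation_error")
  }
  voc <- tibble::as_tibble(voc)
  voc$synonyms <- strsplit(voc$synonyms, "|", fixed = TRUE)
  validate_vocabulary(voc)
}

#' Write a vocabulary tibble to TSV
#'
#' @param vocabulary A vocabulary tibble ([pg_vocabulary()] shape).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(vocabulary, path) {
  out <- vocabulary
  out$synonyms <- vapply(out$synonyms, paste, "", collapse = "|")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

validate_vocabulary <- function(voc) {
  if (anyDuplicated(voc$code)) {
    abort("vocabulary codes must be unique", class = "pgmine_validation_error")
  }
  if (!all(voc$role %in% c("synthesis", "catabolism"))) {
    abort("vocabulary role must be 'synthesis' or 'catabolism'",
          class = "pgmine_validation_error")
  }
  syn <- tibble::tibble(
    code = rep(voc$code, lengths(voc$synonyms)),
    synonym = tolower(unlist(voc$synonyms))
  )
  dup <- syn |>
    dplyr::distinct(.data$code, .data$synonym) |>
    dplyr::count(.data$synonym) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("synonym claimed by more than one code: ",
                 paste(dup$synonym, collapse = ", ")),
          class = "pgmine_validation_error")
  }
  voc
}

# long synonym-to-code lookup ordered longest-first for canonicalize()
vocabulary_lookup <- function(vocabulary) {
  lk <- tibble::tibble(
    code = rep(vocabulary$code, lengths(vocabulary$synonyms)),
    synonym = unlist(vocabulary$synonyms)
  )
  lk[order(-nchar(lk$synonym), lk$synonym), ]
}
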