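# shared builder: pairs (label, function_code) -> presence tibble
build_presence_from_pairs <- function(pairs, key) {
  codes <- pg_function_codes()
  labels <- sort(unique(pairs[[key]]))
  m <- matrix(FALSE, nrow = length(labels), ncol = length(codes),
              dimnames = list(labels, codes))
  for (i in seq_len(nrow(pairs))) {
    m[pairs[[key]][i], pairs$function_code[i]] <- TRUE
  }
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  tibble::add_column(out, !!key := labels, .before = 1)
}

#' Presence/absence matrix of pathway functions
#'
#' Builds the species-by-function (or transcriptome-by-function) boolean
#' occurrence table: a cell is `TRUE` iff at least one assignment exists for
#' that (row, function). Columns are always the nine vocabulary codes in
#' fixed order; rows with no `TRUE` cell are dropped unless
#' `drop_empty = FALSE`. Species-level presence is the union over that
#' species' transcriptomes — any strain or condition counts.
#'
#' @param assignments Assignment tibble from [assign_functions()].
#' @param level `"species"` or `"transcriptome"`.
#' @param drop_empty Drop all-`FALSE` rows (default `TRUE`).
#' @return Tibble: label column (`species` or `mmetsp_code`) plus nine
#'   logical columns.
#' @export
build_presence <- function(assignments, level = c("species", "transcriptome"),
                           drop_empty = TRUE) {
  level <- match.arg(level)
  key <- if (level == "species") "species" else "mmetsp_code"
  if (nrow(assignments) == 0) {
    return(build_presence_from_pairs(
      tibble::tibble(!!key := character(0), function_code = character(0)),
      key))
  }
  pairs <- dplyr::distinct(assignments, .data[[key]], .data$function_code)
  out <- build_presence_from_pairs(pairs, key)
  if (drop_empty) {
    any_true <- rowSums(as.matrix(out[, -1, drop = FALSE])) > 0
    out <- out[any_true, ]
  }
  out
}

presence_to_matrix <- function(presence) {
  m <- as.matrix(presence[, -1, drop = FALSE])
  rownames(m) <- presence[[1]]
  m
}

#' Per-function occurrence counts
#'
#' For each of the nine functions, the number of species and of
#' transcriptomes in which it was found annotated — the column sums of the
#' two presence matrices.
#'
#' @param species_presence Species-level presence tibble
#'   ([build_presence()]).
#' @param transcriptome_presence Optional transcriptome-level presence
#'   tibble; when `NULL`, `n_transcriptomes` is `NA`.
#' @return Tibble: `function_code`, `n_species`, `n_transcriptomes`.
#' @export
count_occurrences <- function(species_presence,
                              transcriptome_presence = NULL) {
  codes <- pg_function_codes()
  check_codes <- function(p, what) {
    if (!identical(colnames(p)[-1], codes)) {
      abort(paste0(what, " presence columns must be the nine vocabulary ",
                   "codes in canonical order"),
            class = "pgmine_validation_error")
    }
  }
  check_codes(species_presence, "species")
  n_species <- colSums(presence_to_matrix(species_presence))
  n_tx <- rep(NA_integer_, length(codes))
  if (!is.null(transcriptome_presence)) {
    check_codes(transcriptome_presence, "transcriptome")
    n_tx <- colSums(presence_to_matrix(transcriptome_presence))
  }
  tibble::tibble(
    function_code = codes,
    n_species = as.integer(n_species),
    n_transcriptomes = as.integer(n_tx)
  )
}

#' Rows of a presence matrix with at least one annotated function
#'
#' Under the default drop rule this equals the row count; kept explicit for
#' matrices built with `drop_empty = FALSE`.
#'
#' @param presence Presence tibble ([build_presence()]).
#' @return Integer count.
#' @export
species_with_any <- function(presence) {
  if (nrow(presence) == 0) return(0L)
  sum(rowSums(as.matrix(presence[, -1, drop = FALSE])) > 0)
}

#' Census of a transcriptome metadata table
#'
#' @param metadata Tibble with columns `mmetsp_code`, `genus`, `species`
#'   (e.g. [mmetsp_growth_conditions()] or bundle metadata). Species are
#'   counted as distinct (genus, species) pairs; basionyms under different
#'   genera therefore count separately.
#' @return One-row tibble: `n_transcriptomes`, `n_genera`, `n_species`.
#' @export
metadata_census <- function(metadata) {
  if (anyDuplicated(metadata$mmetsp_code)) {
    abort("duplicate mmetsp_code in metadata", class = "pgmine_validation_error")
  }
  tibble::tibble(
    n_transcriptomes = dplyr::n_distinct(metadata$mmetsp_code),
    n_genera = dplyr::n_distinct(metadata$genus),
    n_species = nrow(dplyr::distinct(metadata, .data$genus, .data$species))
  )
}

#' Assembly-statistics table of a bundle set
#'
#' @param bundles List of [transcriptome_bundle()] objects.
#' @return Tibble keyed by `mmetsp_code` with `species`, `n_sequences`,
#'   `min_length`, `max_length`, `n50`.
#' @export
stats_table <- function(bundles) {
  dplyr::bind_rows(lapply(bundles, function(b) {
    tibble::tibble(
      mmetsp_code = b$mmetsp_code,
      species = b$species,
      compute_assembly_stats(b$transcripts$nucleotide_length)
    )
  }))
}

#' Assembly-size difference between two transcriptomes
#'
#' Absolute difference in `n_sequences` between two accessions of a
#' statistics table ([stats_table()] or [mmetsp_assembly_stats()]).
#'
#' @param stats Statistics tibble with `mmetsp_code` and `n_sequences`.
#' @param code_a,code_b Accessions to compare.
#' @return Integer difference.
#' @export
size_difference <- function(stats, code_a, code_b) {
  pick <- function(code) {
    n <- stats$n_sequences[stats$mmetsp_code == code]
    if (length(n) != 1 || is.na(n)) {
      abort(paste0("unknown or stats-less mmetsp_code: ", code),
            class = "pgmine_validation_error")
    }
    n
  }
  as.integer(abs(pick(code_a) - pick(code_b)))
}
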