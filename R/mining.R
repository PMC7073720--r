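#' Keyword query of a bundle's annotation table
#'
#' Returns the annotation rows whose Swiss-Prot description contains the
#' search term (case-insensitive substring), in input order. Only the
#' description field is searched.
#'
#' @param bundle A [transcriptome_bundle()].
#' @param term Non-empty search term (the canonical query is
#'   `"prostaglandin"`).
#' @return Tibble of matching annotation rows.
#' @export
query_annotations <- function(bundle, term = "prostaglandin") {
  if (!nzchar(term)) {
    abort("search term must be non-empty", class = "pgmine_validation_error")
  }
  ann <- bundle$annotations
  ann[stringr::str_detect(stringr::str_to_lower(ann$description),
                          stringr::fixed(stringr::str_to_lower(term))), ]
}

#' Canonicalize descriptions against the enzyme vocabulary
#'
#' Case-insensitive substring match of each description against every
#' vocabulary synonym, longest synonym first; the first matching synonym's
#' code wins. Descriptions matching no synonym map to `NA` ("unmapped") and
#' should be reported, not dropped.
#'
#' @param description Character vector of annotation descriptions.
#' @param vocabulary Vocabulary tibble ([pg_vocabulary()]).
#' @return Character vector of function codes, `NA` where unmapped.
#' @examples
#' canonicalize(c("Prostaglandin G/H synthase 2", "Prostaglandin transporter"))
#' @export
canonicalize <- function(description, vocabulary = pg_vocabulary()) {
  if (any(!nzchar(description))) {
    abort("descriptions must be non-empty", class = "pgmine_validation_error")
  }
  lk <- vocabulary_lookup(vocabulary)
  lower <- stringr::str_to_lower(description)
  out <- rep(NA_character_, length(description))
  for (i in seq_len(nrow(lk))) {
    todo <- is.na(out)
    if (!any(todo)) break
    hit <- stringr::str_detect(lower[todo],
                               stringr::fixed(stringr::str_to_lower(lk$synonym[i])))
    out[todo][hit] <- lk$code[i]
  }
  out
}

#' Assign pathway functions to a bundle's transcripts
#'
#' Composes [query_annotations()] and [canonicalize()]: every term-matching
#' annotation whose description canonicalizes to a vocabulary code yields a
#' (transcript, function) assignment. Duplicate (transcript, function) pairs
#' collapse to one; a transcript annotated with two *different* functions
#' keeps both. Term-matching descriptions that map to no code are retained
#' in the unmapped report (see [unmapped_hits()]), never silently dropped.
#'
#' @param bundle A [transcriptome_bundle()], or a list of bundles.
#' @param vocabulary Vocabulary tibble.
#' @param term Search term.
#' @return Tibble with columns `transcript_id`, `mmetsp_code`, `species`,
#'   `function_code`, `matched_description`, carrying the unmapped report as
#'   attribute `"unmapped"`.
#' @export
assign_functions <- function(bundle, vocabulary = pg_vocabulary(),
                             term = "prostaglandin") {
  if (!inherits(bundle, "transcriptome_bundle")) {
    # list of bundles: map and combine, pooling the unmapped reports
    parts <- lapply(bundle, assign_functions, vocabulary = vocabulary,
                    term = term)
    out <- dplyr::bind_rows(lapply(parts, as.data.frame))
    attr(out, "unmapped") <- dplyr::bind_rows(lapply(parts, unmapped_hits))
    return(tibble::as_tibble(out))
  }
  hits <- query_annotations(bundle, term)
  codes <- if (nrow(hits) > 0) canonicalize(hits$description, vocabulary)
           else character(0)
  mapped <- tibble::tibble(
    transcript_id = hits$transcript_id,
    mmetsp_code = bundle$mmetsp_code,
    species = bundle$species,
    function_code = codes,
    matched_description = hits$description
  )
  unmapped <- mapped[is.na(mapped$function_code),
                     c("transcript_id", "mmetsp_code", "species",
                       "matched_description")]
  mapped <- mapped[!is.na(mapped$function_code), ] |>
    dplyr::distinct(.data$transcript_id, .data$function_code,
                    .keep_all = TRUE)
  attr(mapped, "unmapped") <- unmapped
  mapped
}

#' Unmapped-hit report of an assignment table
#'
#' Term-matching annotation rows whose description canonicalized to no
#' vocabulary code (e.g. "Prostaglandin transporter").
#'
#' @param assignments Output of [assign_functions()].
#' @return Tibble of unmapped hits (possibly empty).
#' @export
unmapped_hits <- function(assignments) {
  um <- attr(assignments, "unmapped")
  if (is.null(um)) {
    um <- tibble::tibble(transcript_id = character(0),
                         mmetsp_code = character(0),
                         species = character(0),
                         matched_description = character(0))
  }
  tibble::as_tibble(um)
}
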