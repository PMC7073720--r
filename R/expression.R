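#' FPKM of a transcript
#'
#' Fragments per kilobase of transcript per million mapped read pairs:
#' `mapped_read_pairs / (transcript_length / 1000) / (total_read_pairs / 1e6)`.
#' Vectorized; invariant under joint scaling of the mapped and total counts.
#'
#' @param mapped_read_pairs Read pairs mapped to the transcript (>= 0).
#' @param transcript_length Transcript length in bp (>= 1).
#' @param total_read_pairs Library size in read pairs (>= 1).
#' @return Numeric FPKM values.
#' @examples
#' compute_fpkm(1000, 1000, 1e6) # 1000
#' compute_fpkm(250, 500, 2e6)   # 250
#' @export
compute_fpkm <- function(mapped_read_pairs, transcript_length,
                         total_read_pairs) {
  if (any(transcript_length < 1)) {
    abort("transcript_length must be >= 1 (division by zero)",
          class = "pgmine_validation_error")
  }
  if (any(total_read_pairs < 1)) {
    abort("total_read_pairs must be >= 1 (division by zero)",
          class = "pgmine_validation_error")
  }
  if (any(mapped_read_pairs < 0)) {
    abort("mapped_read_pairs must be >= 0", class = "pgmine_validation_error")
  }
  mapped_read_pairs / (transcript_length / 1000) / (total_read_pairs / 1e6)
}

#' Per-transcript FPKM table of a bundle
#'
#' @param bundle A [transcriptome_bundle()], or a list of bundles.
#' @return Tibble with `transcript_id`, `mmetsp_code`, `fpkm`.
#' @export
transcript_fpkm <- function(bundle) {
  if (!inherits(bundle, "transcriptome_bundle")) {
    return(dplyr::bind_rows(lapply(bundle, transcript_fpkm)))
  }
  tibble::tibble(
    transcript_id = bundle$transcripts$transcript_id,
    mmetsp_code = bundle$mmetsp_code,
    fpkm = compute_fpkm(bundle$transcripts$mapped_read_pairs,
                        bundle$transcripts$nucleotide_length,
                        bundle$total_read_pairs)
  )
}

#' Per-function summed FPKM
#'
#' For each (transcriptome, function), sums the FPKM values of the
#' contributing transcripts — by default only the cluster representatives
#' ("heads"), since downstream analysis works on heads; `mode = "all"` sums
#' every assigned transcript instead. A function with no contributing
#' transcript in a transcriptome yields *no* record (absence, distinct from
#' an FPKM sum of zero).
#'
#' @param assignments Assignment tibble from [assign_functions()].
#' @param fpkm Per-transcript FPKM tibble from [transcript_fpkm()]; every
#'   assigned transcript must appear in it.
#' @param clusters Member-level cluster tibble (`clusters` element of
#'   [cluster_by_function()]); required for `mode = "heads"`. Heads are
#'   matched per transcript id, so clusters computed per transcriptome keep
#'   one head per replicate.
#' @param mode `"heads"` (default) or `"all"`.
#' @return Tibble: `mmetsp_code`, `species`, `function_code`, `fpkm_sum`,
#'   `n_transcripts`.
#' @export
function_expression <- function(assignments, fpkm, clusters = NULL,
                                mode = c("heads", "all")) {
  mode <- match.arg(mode)
  contributing <- assignments
  if (mode == "heads") {
    if (is.null(clusters)) {
      abort("mode = 'heads' requires the clusters table",
            class = "pgmine_validation_error")
    }
    heads <- unique(clusters$representative_id)
    contributing <- contributing[contributing$transcript_id %in% heads, ]
  }
  joined <- dplyr::left_join(contributing, fpkm,
                             by = c("transcript_id", "mmetsp_code"))
  if (any(is.na(joined$fpkm))) {
    bad <- unique(joined$transcript_id[is.na(joined$fpkm)])
    abort(paste0("assigned transcript(s) without an expression record: ",
                 paste(bad, collapse = ", ")),
          class = "pgmine_validation_error")
  }
  joined |>
    dplyr::group_by(.data$mmetsp_code, .data$species, .data$function_code) |>
    dplyr::summarise(fpkm_sum = sum(.data$fpkm),
                     n_transcripts = dplyr::n(), .groups = "drop")
}

#' Function-by-transcriptome expression matrix
#'
#' Rows are the nine vocabulary codes in fixed order, columns are
#' transcriptomes; a function absent from a transcriptome is a missing cell
#' (`NA`), never zero. With `grouping = "species"` columns are ordered by
#' species (species-grouped blocks) and the species of each column is kept
#' in attribute `"column_species"`.
#'
#' @param function_expression Output of [function_expression()].
#' @param grouping `"transcriptome"` (default) or `"species"`.
#' @return Numeric matrix with dimnames, suitable for [write_matrix()] and
#'   [render_heatmap()].
#' @export
expression_matrix <- function(function_expression,
                              grouping = c("transcriptome", "species")) {
  grouping <- match.arg(grouping)
  fe <- function_expression
  cols <- fe |>
    dplyr::distinct(.data$mmetsp_code, .data$species)
  cols <- if (grouping == "species") {
    dplyr::arrange(cols, .data$species, .data$mmetsp_code)
  } else {
    dplyr::arrange(cols, .data$mmetsp_code)
  }
  codes <- pg_function_codes()
  m <- matrix(NA_real_, nrow = length(codes), ncol = nrow(cols),
              dimnames = list(codes, cols$mmetsp_code))
  for (i in seq_len(nrow(fe))) {
    m[fe$function_code[i], fe$mmetsp_code[i]] <- fe$fpkm_sum[i]
  }
  attr(m, "column_species") <- cols$species
  m
}
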