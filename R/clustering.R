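#' Pairwise amino-acid identity
#'
#' Fraction of identical residues under an optimal global alignment scored
#' match = 1, mismatch = 0, zero linear gap penalty (gapped positions count
#' as non-identity), divided by the length of the *shorter* sequence — the
#' CD-Hit convention. With that scoring the optimal number of identities is
#' the longest common subsequence, computed by a dynamic-programming core in
#' C++. Symmetric in its arguments.
#'
#' @param a,b Non-empty amino-acid strings.
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("AAAA", "AAAT")   # 0.75
#' pairwise_identity("AAAA", "AAAAAA") # 1: 4 identities / shorter length 4
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) {
    abort("sequences must be non-empty", class = "pgmine_validation_error")
  }
  .align_matches(a, b) / min(nchar(a), nchar(b))
}

# normalize sequence input: named character vector or a data frame with an
# id column (id / transcript_id) and a peptide/sequence column
as_seq_tbl <- function(sequences) {
  if (is.data.frame(sequences)) {
    id_col <- intersect(c("id", "transcript_id"), names(sequences))[1]
    seq_col <- intersect(c("peptide", "sequence"), names(sequences))[1]
    if (is.na(id_col) || is.na(seq_col)) {
      abort("sequence table needs an id/transcript_id and a peptide/sequence column",
            class = "pgmine_validation_error")
    }
    tb <- tibble::tibble(id = as.character(sequences[[id_col]]),
                         sequence = as.character(sequences[[seq_col]]))
  } else {
    if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
      abort("sequences must be named", class = "pgmine_validation_error")
    }
    tb <- tibble::tibble(id = names(sequences),
                         sequence = as.character(sequences))
  }
  if (anyDuplicated(tb$id)) {
    abort("sequence ids must be unique", class = "pgmine_validation_error")
  }
  if (any(is.na(tb$sequence)) || any(!nzchar(tb$sequence))) {
    abort("sequences must be non-empty", class = "pgmine_validation_error")
  }
  tb
}

# deterministic greedy processing order: length descending, id ascending
greedy_order <- function(tb) {
  tb[order(-nchar(tb$sequence), tb$id), ]
}

new_pg_clusters <- function(members, threshold) {
  out <- tibble::new_tibble(members, class = "pg_clusters")
  attr(out, "threshold") <- threshold
  out
}

#' Greedy incremental identity clustering
#'
#' The CD-Hit-style algorithm: process sequences by decreasing length
#' (ties broken by ascending id); each sequence joins the first existing
#' cluster whose *representative* it matches at or above the identity
#' threshold, else it founds a new cluster and becomes its representative.
#' Representatives are therefore always a longest member of their cluster,
#' and the clusters partition the input.
#'
#' @param sequences Named character vector of amino-acid sequences, or a
#'   data frame with `id`/`transcript_id` and `peptide`/`sequence` columns.
#' @param threshold Identity threshold in `(0, 1]`; default 0.90.
#' @return A `pg_clusters` tibble, one row per member: `cluster_id`,
#'   `member_id`, `representative_id`, `identity_to_representative`,
#'   `member_length`; threshold stored as attribute `"threshold"`.
#' @examples
#' greedy_cluster(c(a = "MKLVMKLV", b = "MKLVMKLV", c = "WWWWYYYY"), 0.9)
#' @export
greedy_cluster <- function(sequences, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1) {
    abort("threshold must be in (0, 1]", class = "pgmine_validation_error")
  }
  tb <- greedy_order(as_seq_tbl(sequences))
  n <- nrow(tb)
  if (n == 0) {
    abort("at least one sequence is required", class = "pgmine_validation_error")
  }
  rep_idx <- integer(0)           # row index of each cluster's representative
  cluster_of <- integer(n)
  identity_of <- numeric(n)
  for (i in seq_len(n)) {
    assigned <- FALSE
    for (k in seq_along(rep_idx)) {
      id <- pairwise_identity(tb$sequence[i], tb$sequence[rep_idx[k]])
      if (id >= threshold) {
        cluster_of[i] <- k
        identity_of[i] <- id
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_idx <- c(rep_idx, i)
      cluster_of[i] <- length(rep_idx)
      identity_of[i] <- 1
    }
  }
  new_pg_clusters(
    tibble::tibble(
      cluster_id = cluster_of,
      member_id = tb$id,
      representative_id = tb$id[rep_idx[cluster_of]],
      identity_to_representative = identity_of,
      member_length = nchar(tb$sequence)
    ),
    threshold
  )
}

#' Brute-force clustering oracle
#'
#' Same greedy contract as [greedy_cluster()], but executed by first
#' computing the exhaustive all-pairs identity matrix and then replaying the
#' assignment rule from it — an independent code path used to validate the
#' incremental implementation on small inputs.
#'
#' @inheritParams greedy_cluster
#' @return A `pg_clusters` tibble, as [greedy_cluster()].
#' @export
brute_force_cluster <- function(sequences, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1) {
    abort("threshold must be in (0, 1]", class = "pgmine_validation_error")
  }
  tb <- greedy_order(as_seq_tbl(sequences))
  n <- nrow(tb)
  if (n == 0) {
    abort("at least one sequence is required", class = "pgmine_validation_error")
  }
  if (n > 50) {
    abort("brute-force oracle is limited to 50 sequences",
          class = "pgmine_validation_error")
  }
  idm <- .identity_matrix(tb$sequence)
  rep_idx <- integer(0)
  cluster_of <- integer(n)
  identity_of <- numeric(n)
  for (i in seq_len(n)) {
    hits <- which(idm[i, rep_idx] >= threshold)
    if (length(hits) > 0) {
      k <- hits[1]
      cluster_of[i] <- k
      identity_of[i] <- idm[i, rep_idx[k]]
    } else {
      rep_idx <- c(rep_idx, i)
      cluster_of[i] <- length(rep_idx)
      identity_of[i] <- 1
    }
  }
  new_pg_clusters(
    tibble::tibble(
      cluster_id = cluster_of,
      member_id = tb$id,
      representative_id = tb$id[rep_idx[cluster_of]],
      identity_to_representative = identity_of,
      member_length = nchar(tb$sequence)
    ),
    threshold
  )
}

#' @export
tidy.pg_clusters <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

#' @export
glance.pg_clusters <- function(x, ...) {
  tibble::tibble(
    n_sequences = nrow(x),
    n_clusters = dplyr::n_distinct(x$cluster_id),
    threshold = attr(x, "threshold"),
    largest_cluster = max(table(x$cluster_id))
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.pg_clusters <- function(object, ...) {
  sizes <- dplyr::count(tibble::as_tibble(unclass_tbl(object)),
                        .data$cluster_id, name = "size")
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "cluster size (members)", y = "clusters",
                  title = "Cluster size distribution") +
    ggplot2::theme_minimal()
}

unclass_tbl <- function(x) {
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' Cluster assigned transcripts per group and function
#'
#' Runs [greedy_cluster()] independently for every (group, function) cell,
#' where the group is the species (default, pooling a species' replicate
#' transcriptomes) or the single transcriptome. The companion report
#' tabulates, per cell, the transcript count before clustering (`sp_count`)
#' and the cluster count after (`cdhit_count`).
#'
#' @param assignments Assignment tibble from [assign_functions()].
#' @param peptides Named character vector `transcript_id -> peptide`, or a
#'   data frame with `transcript_id` and `peptide` columns (e.g. bound
#'   bundle transcript tables).
#' @param threshold Identity threshold.
#' @param by `"species"` or `"transcriptome"`.
#' @return List with `clusters` (member-level tibble: group column,
#'   `function_code`, `cluster_id`, `member_id`, `representative_id`,
#'   `identity_to_representative`) and `report` (per-cell tibble with
#'   `sp_count` and `cdhit_count`).
#' @export
cluster_by_function <- function(assignments, peptides, threshold = 0.9,
                                by = c("species", "transcriptome")) {
  by <- match.arg(by)
  key <- if (by == "species") "species" else "mmetsp_code"
  pep <- as_seq_tbl(if (is.data.frame(peptides)) {
    peptides[!is.na(peptides$peptide), ]
  } else {
    peptides
  })
  missing <- setdiff(unique(assignments$transcript_id), pep$id)
  if (length(missing) > 0) {
    abort(paste0("no peptide sequence for assigned transcript(s): ",
                 paste(missing, collapse = ", ")),
          class = "pgmine_validation_error")
  }
  pep_lookup <- setNames(pep$sequence, pep$id)

  groups <- assignments |>
    dplyr::distinct(.data[[key]], .data$function_code, .data$transcript_id) |>
    dplyr::group_by(.data[[key]], .data$function_code)
  keys <- dplyr::group_keys(groups)
  splits <- dplyr::group_split(groups)

  cluster_parts <- vector("list", length(splits))
  report_parts <- vector("list", length(splits))
  for (g in seq_along(splits)) {
    ids <- splits[[g]]$transcript_id
    cl <- greedy_cluster(setNames(pep_lookup[ids], ids), threshold)
    cluster_parts[[g]] <- tibble::tibble(
      !!key := keys[[key]][g],
      function_code = keys$function_code[g],
      tibble::as_tibble(unclass_tbl(cl))
    )
    report_parts[[g]] <- tibble::tibble(
      !!key := keys[[key]][g],
      function_code = keys$function_code[g],
      sp_count = length(ids),
      cdhit_count = dplyr::n_distinct(cl$cluster_id)
    )
  }
  list(clusters = dplyr::bind_rows(cluster_parts),
       report = dplyr::bind_rows(report_parts))
}

#' Species/function purity of a pooled clustering
#'
#' For a clustering of all assigned transcripts pooled across species and
#' functions, reports per cluster whether its members share a single species
#' and a single function, and the overall fraction of pure clusters. On real
#' transcriptomes this fraction being 1 reflects the species specificity of
#' each gene sequence.
#'
#' @param clusters A `pg_clusters` tibble from a pooled [greedy_cluster()]
#'   run (or the member-level tibble of [cluster_by_function()]).
#' @param assignments Assignment tibble mapping `transcript_id` to `species`
#'   and `function_code`.
#' @return List of class `pg_purity`: `per_cluster` tibble (`cluster_id`,
#'   `n_members`, `n_species`, `n_functions`, `pure`) and `purity`, the
#'   fraction of pure clusters (`NA` with a note when there are no clusters).
#' @export
cross_species_purity <- function(clusters, assignments) {
  tb <- tibble::as_tibble(unclass_tbl(clusters))
  if (nrow(tb) == 0) {
    out <- list(per_cluster = tibble::tibble(
      cluster_id = integer(0), n_members = integer(0),
      n_species = integer(0), n_functions = integer(0), pure = logical(0)),
      purity = NA_real_, note = "no clusters")
    class(out) <- "pg_purity"
    return(out)
  }
  labels <- assignments |>
    dplyr::distinct(.data$transcript_id, .data$species, .data$function_code)
  per <- tb |>
    dplyr::left_join(labels, by = c(member_id = "transcript_id"),
                     relationship = "many-to-many") |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      n_members = dplyr::n_distinct(.data$member_id),
      n_species = dplyr::n_distinct(.data$species),
      n_functions = dplyr::n_distinct(.data$function_code),
      .groups = "drop"
    ) |>
    dplyr::mutate(pure = .data$n_species == 1 & .data$n_functions == 1)
  out <- list(per_cluster = per, purity = mean(per$pure), note = NULL)
  class(out) <- "pg_purity"
  out
}

#' @export
print.pg_purity <- function(x, ...) {
  if (!is.null(x$note)) {
    cat("<pg_purity> ", x$note, "\n", sep = "")
  } else {
    cat("<pg_purity> ", nrow(x$per_cluster), " clusters, purity ",
        format(x$purity, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Write clusters in CD-Hit .clstr style
#'
#' @param clusters A `pg_clusters` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clstr <- function(clusters, path) {
  tb <- tibble::as_tibble(unclass_tbl(clusters))
  lines <- character(0)
  for (cid in sort(unique(tb$cluster_id))) {
    lines <- c(lines, paste0(">Cluster ", cid - 1))
    mem <- tb[tb$cluster_id == cid, ]
    is_rep <- mem$member_id == mem$representative_id
    lines <- c(lines, paste0(
      seq_len(nrow(mem)) - 1, "\t", mem$member_length, "aa, >",
      mem$member_id, "... ",
      ifelse(is_rep, "*",
             paste0("at ", sprintf("%.2f", 100 * mem$identity_to_representative),
                    "%"))
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write cluster-representative peptides as FASTA
#'
#' @param clusters A `pg_clusters` tibble (or `cluster_by_function()`
#'   member table).
#' @param peptides Named vector or data frame of peptides, as
#'   [cluster_by_function()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_representatives <- function(clusters, peptides, path) {
  tb <- tibble::as_tibble(unclass_tbl(clusters))
  pep <- as_seq_tbl(if (is.data.frame(peptides)) {
    peptides[!is.na(peptides$peptide), ]
  } else {
    peptides
  })
  reps <- unique(tb$representative_id)
  seqs <- setNames(pep$sequence[match(reps, pep$id)], reps)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
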