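#' Run the full mining pipeline
#'
#' End-to-end composition of the pipeline stages on a set of bundles:
#' keyword mining and vocabulary canonicalization, greedy identity
#' clustering (per species for the cluster report, per transcriptome for
#' head selection, pooled for the purity check), FPKM quantification and
#' per-function summation, presence/occurrence summarization, assembly
#' statistics, figures and a run log. The mining path is deterministic:
#' re-running on the same inputs reproduces every table byte for byte.
#'
#' @param bundles Character vector of bundle directories, or a list of
#'   [transcriptome_bundle()] objects.
#' @param vocabulary Vocabulary tibble ([pg_vocabulary()]).
#' @param term Annotation search term.
#' @param threshold Clustering identity threshold.
#' @param sum_mode `"heads"` (sum FPKM over cluster representatives,
#'   default) or `"all"` (over all assigned transcripts).
#' @param out_dir Output directory; created if needed. When `NULL`, nothing
#'   is written and only the result object is returned.
#' @return Invisibly, a list of class `pg_run` with every intermediate and
#'   summary table.
#' @export
run_pipeline <- function(bundles, vocabulary = pg_vocabulary(),
                         term = "prostaglandin", threshold = 0.9,
                         sum_mode = c("heads", "all"), out_dir = NULL) {
  sum_mode <- match.arg(sum_mode)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "pgmine_pipeline_error")
    })
  }

  bundles <- stage("read", {
    if (is.character(bundles)) {
      bl <- lapply(bundles, read_bundle)
      names(bl) <- vapply(bl, function(b) b$mmetsp_code, "")
      bl
    } else if (inherits(bundles, "transcriptome_bundle")) {
      setNames(list(bundles), bundles$mmetsp_code)
    } else {
      bundles
    }
  })
  if (length(bundles) == 0) {
    abort("pipeline stage 'read' failed: at least one bundle is required",
          class = "pgmine_pipeline_error")
  }

  assignments <- stage("mine",
                       assign_functions(bundles, vocabulary, term))
  unmapped <- unmapped_hits(assignments)

  peptides <- dplyr::bind_rows(lapply(bundles, function(b) {
    b$transcripts[, c("transcript_id", "peptide")]
  }))

  empty_members <- tibble::tibble(
    species = character(0), mmetsp_code = character(0),
    function_code = character(0), cluster_id = integer(0),
    member_id = character(0), representative_id = character(0),
    identity_to_representative = numeric(0), member_length = integer(0)
  )
  has_hits <- nrow(assignments) > 0

  clusters_species <- stage("cluster", {
    if (has_hits) {
      cluster_by_function(assignments, peptides, threshold, by = "species")
    } else {
      list(clusters = empty_members[, -2],
           report = tibble::tibble(species = character(0),
                                   function_code = character(0),
                                   sp_count = integer(0),
                                   cdhit_count = integer(0)))
    }
  })
  clusters_tx <- stage("cluster", {
    if (has_hits) {
      cluster_by_function(assignments, peptides, threshold,
                          by = "transcriptome")
    } else {
      list(clusters = empty_members[, -1],
           report = tibble::tibble(mmetsp_code = character(0),
                                   function_code = character(0),
                                   sp_count = integer(0),
                                   cdhit_count = integer(0)))
    }
  })
  purity <- stage("cluster", {
    if (has_hits) {
      pep_assigned <- peptides[peptides$transcript_id %in%
                                 assignments$transcript_id, ]
      pooled <- greedy_cluster(pep_assigned, threshold)
      cross_species_purity(pooled, assignments)
    } else {
      cross_species_purity(empty_members, assignments)
    }
  })

  fpkm <- stage("expression", transcript_fpkm(bundles))
  fn_expr <- stage("expression", {
    if (has_hits) {
      function_expression(assignments, fpkm,
                          clusters = clusters_tx$clusters, mode = sum_mode)
    } else {
      tibble::tibble(mmetsp_code = character(0), species = character(0),
                     function_code = character(0), fpkm_sum = numeric(0),
                     n_transcripts = integer(0))
    }
  })
  expr_matrix <- stage("expression", expression_matrix(fn_expr))

  presence_species <- stage("summarize",
                            build_presence(assignments, "species"))
  presence_tx <- stage("summarize",
                       build_presence(assignments, "transcriptome"))
  occurrence <- stage("summarize",
                      count_occurrences(presence_species, presence_tx))
  census <- stage("summarize", metadata_census(dplyr::bind_rows(
    lapply(bundles, function(b) tibble::tibble(
      mmetsp_code = b$mmetsp_code, genus = b$genus, species = b$species)))))
  stats <- stage("summarize", stats_table(bundles))

  result <- structure(
    list(
      bundles = bundles,
      assignments = assignments,
      unmapped = unmapped,
      cluster_report = clusters_species$report,
      clusters_species = clusters_species$clusters,
      clusters_transcriptome = clusters_tx$clusters,
      purity = purity,
      fpkm = fpkm,
      function_expression = fn_expr,
      expression_matrix = expr_matrix,
      presence_species = presence_species,
      presence_transcriptome = presence_tx,
      occurrence = occurrence,
      census = census,
      stats = stats,
      params = list(term = term, threshold = threshold, sum_mode = sum_mode,
                    n_bundles = length(bundles))
    ),
    class = "pg_run"
  )

  if (!is.null(out_dir)) {
    stage("write", write_run(result, out_dir))
  }
  invisible(result)
}

write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(out_dir, name)
  wt <- function(tb, name) readr::write_tsv(tb, out(name), na = "NA",
                                            progress = FALSE)
  wt(as.data.frame(result$assignments), "assignments.tsv")
  wt(result$unmapped, "unmapped_hits.tsv")
  wt(result$cluster_report, "cluster_report.tsv")
  wt(result$clusters_species, "cluster_members.tsv")
  wt(result$function_expression, "function_expression.tsv")
  wt(result$presence_species, "presence_species.tsv")
  wt(result$presence_transcriptome, "presence_transcriptome.tsv")
  wt(result$occurrence, "occurrence_counts.tsv")
  wt(result$stats, "assembly_stats.tsv")
  write_matrix(result$expression_matrix, out("expression_matrix.tsv"),
               row_label = "function_code")
  if (nrow(result$clusters_species) > 0) {
    peptides <- dplyr::bind_rows(lapply(result$bundles, function(b) {
      b$transcripts[, c("transcript_id", "peptide")]
    }))
    cl <- new_pg_clusters(result$clusters_species,
                          result$params$threshold)
    write_clstr(cl, out("clusters.clstr"))
    write_representatives(cl, peptides, out("representatives.fa"))
  }
  occurrence_chart(result$occurrence, out("occurrence_chart.png"))
  if (ncol(result$expression_matrix) > 0) {
    render_heatmap(result$expression_matrix, out("expression_heatmap.png"))
  }
  log_lines <- c(
    "pgmine run log",
    paste0("bundles: ", result$params$n_bundles),
    paste0("term: ", result$params$term),
    paste0("identity threshold: ", result$params$threshold),
    paste0("fpkm sum mode: ", result$params$sum_mode),
    paste0("assignments: ", nrow(result$assignments)),
    paste0("unmapped term-matching hits: ", nrow(result$unmapped)),
    paste0("species with >=1 function: ",
           species_with_any(result$presence_species)),
    "mining path is deterministic (no random number draws)"
  )
  writeLines(log_lines, out("run_log.txt"))
  invisible(out_dir)
}

#' @export
print.pg_run <- function(x, ...) {
  cat("<pg_run> ", x$params$n_bundles, " bundles, ",
      nrow(x$assignments), " assignments, ",
      species_with_any(x$presence_species), " species with >=1 function\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.pg_run <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$assignments))
}

#' @export
glance.pg_run <- function(x, ...) {
  tibble::tibble(
    n_bundles = x$params$n_bundles,
    n_assignments = nrow(x$assignments),
    n_unmapped = nrow(x$unmapped),
    n_clusters = if (nrow(x$clusters_species) == 0) 0L else dplyr::n_distinct(
      paste(x$clusters_species$species, x$clusters_species$function_code,
            x$clusters_species$cluster_id)),
    n_species_with_function = species_with_any(x$presence_species),
    threshold = x$params$threshold
  )
}
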