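#' Occurrence bar chart
#'
#' Per-function counts of species and transcriptomes carrying at least one
#' annotated transcript, as a grouped bar chart in canonical code order.
#'
#' @param counts Occurrence tibble ([count_occurrences()]).
#' @return A ggplot object.
#' @export
plot_occurrence <- function(counts) {
  codes <- pg_function_codes()
  long <- counts |>
    tidyr::pivot_longer(c("n_species", "n_transcriptomes"),
                        names_to = "level", values_to = "n") |>
    dplyr::filter(!is.na(.data$n)) |>
    dplyr::mutate(
      function_code = factor(.data$function_code, levels = codes),
      level = dplyr::recode(.data$level, n_species = "species",
                            n_transcriptomes = "transcriptomes")
    )
  if (nrow(long) == 0 || all(long$n == 0)) {
    return(
      ggplot2::ggplot() +
        ggplot2::annotate("text", x = 0, y = 0, label = "no functions found") +
        ggplot2::theme_void()
    )
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$function_code, y = .data$n,
                                     fill = .data$level)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(species = "#1B7837",
                                          transcriptomes = "#762A83")) +
    ggplot2::labs(x = NULL, y = "count",
                  title = "Occurrence of prostaglandin-pathway functions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write the occurrence chart to file
#'
#' @param counts Occurrence tibble ([count_occurrences()]).
#' @param path Output image path (`.png` or `.svg`).
#' @param width,height,dpi Device geometry.
#' @return `path`, invisibly.
#' @export
occurrence_chart <- function(counts, path, width = 7, height = 4.5, dpi = 96) {
  save_plot(plot_occurrence(counts), path, width, height, dpi)
}

# reserved color for missing cells of expression heatmaps: absence of an
# annotated transcript, distinct from an FPKM of zero
HEATMAP_NA_COLOR <- "#BFBFBF"

#' Expression heatmap
#'
#' Functions on the rows, transcriptomes on the columns; missing cells
#' (function not annotated in that transcriptome) are drawn in a reserved
#' grey, distinct from the low end of the expression scale.
#'
#' @param matrix Numeric matrix from [expression_matrix()] (may contain
#'   `NA`).
#' @param transform `"raw"` (default) or `"log10p1"`
#'   (`log10(FPKM + 1)`, finite at zero).
#' @return A ggplot object.
#' @export
plot_expression_heatmap <- function(matrix, transform = c("raw", "log10p1")) {
  transform <- match.arg(transform)
  m <- matrix
  if (transform == "log10p1") {
    m <- log10(m + 1)
  }
  long <- tibble::tibble(
    function_code = factor(rep(rownames(m), ncol(m)), levels = rev(rownames(m))),
    mmetsp_code = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    value = as.vector(m)
  )
  lab <- if (transform == "log10p1") "log10(FPKM + 1)" else "FPKM"
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mmetsp_code,
                                     y = .data$function_code,
                                     fill = .data$value)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_gradient(low = "#FFF7BC", high = "#D7301F",
                                 na.value = HEATMAP_NA_COLOR, name = lab) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write an expression heatmap to file
#'
#' @inheritParams plot_expression_heatmap
#' @param path Output image path.
#' @param width,height,dpi Device geometry.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(matrix, path, transform = c("raw", "log10p1"),
                           width = 7, height = 4.5, dpi = 96) {
  save_plot(plot_expression_heatmap(matrix, transform), path,
            width, height, dpi)
}

save_plot <- function(plot, path, width, height, dpi) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ggplot2::ggsave(path, plot = plot, width = width, height = height,
                  dpi = dpi, units = "in")
  invisible(path)
}
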