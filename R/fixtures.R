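fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "pgmine")
  if (!nzchar(p)) {
    abort(paste0("bundled reference table not found: ", name),
          class = "pgmine_io_error")
  }
  p
}

#' Reference table: the 42 dinoflagellate MMETSP transcriptomes
#'
#' Survey of the dinoflagellate transcriptomes in the MMETSP/iMicrobe
#' collection: 42 transcriptomes covering 15 genera and 19 species, with the
#' culture conditions (light, photoperiod, phosphate, nitrate, salinity) and
#' geographic origin reported for each accession. Shipped as a plain-TSV
#' reference table so the census and summary logic can run without any
#' download. *G. foliaceum* and its basionym *K. foliaceum* are separate
#' species rows (distinct genera).
#'
#' @return Tibble, one row per transcriptome accession.
#' @export
mmetsp_growth_conditions <- function() {
  readr::read_tsv(
    fixture_path("dinoflagellate_transcriptomes.tsv"),
    col_types = readr::cols(
      genus = "c", species = "c", mmetsp_code = "c", strain = "c",
      light = "d", day_portion = "c", phosphate_umol_kg = "d",
      nitrate_umol = "d", salinity_pct = "d", note = "c", geo_area = "c"
    ),
    progress = FALSE
  )
}

#' Reference table: assembly statistics of the 42 transcriptomes
#'
#' Reported per-assembly sequencing statistics (number of sequences,
#' minimum/maximum contig length, N50) for the dinoflagellate MMETSP
#' transcriptomes. One accession (MMETSP0380) has no reported statistics
#' and carries `NA`s.
#'
#' @return Tibble keyed by `mmetsp_code`.
#' @export
mmetsp_assembly_stats <- function() {
  readr::read_tsv(
    fixture_path("dinoflagellate_assembly_stats.tsv"),
    col_types = readr::cols(
      genus = "c", species = "c", mmetsp_code = "c",
      n_sequences = "i", min_length = "i", max_length = "i", n50 = "i"
    ),
    progress = FALSE
  )
}

#' Reference table: species-level enzyme presence
#'
#' Reported occurrence of the nine prostaglandin-metabolism functions in the
#' fourteen dinoflagellate species where at least one function was found
#' annotated, in the canonical presence-matrix shape of [build_presence()].
#'
#' @return Presence tibble: `species` plus nine logical columns.
#' @export
mmetsp_presence <- function() {
  readr::read_tsv(
    fixture_path("dinoflagellate_presence.tsv"),
    col_types = readr::cols(species = "c", .default = "l"),
    progress = FALSE
  )
}
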