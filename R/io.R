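#' Construct a transcriptome bundle
#'
#' A bundle is one transcriptome's worth of the MMETSP-style file set:
#' assembled transcripts with their read counts, Swiss-Prot annotation hits,
#' library size and growth metadata. [read_bundle()] and the synthetic
#' generator both return this structure.
#'
#' @param mmetsp_code Transcriptome accession, e.g. `"MMETSP0201"`.
#' @param species,genus Organism names. `species` is the full binomial-style
#'   label used for grouping; `genus` its genus part.
#' @param transcripts Tibble with columns `transcript_id`,
#'   `nucleotide_length` (bp, >= 1), `peptide` (amino-acid string or `NA`) and
#'   `mapped_read_pairs` (>= 0). Optionally `nucleotide_sequence`.
#' @param annotations Tibble with columns `transcript_id`,
#'   `subject_accession`, `description` (non-empty), `start`, `end`
#'   (1-based inclusive, `start <= end`) and `score` (may be `NA`).
#'   Rows referencing unknown transcript ids are dropped with a warning.
#' @param total_read_pairs Library size (total mapped read pairs) used as the
#'   FPKM denominator; the per-transcript mapped pairs may sum to less.
#' @param strain Optional strain label.
#' @param growth_metadata Named list of culture-condition fields (light,
#'   photoperiod, phosphate, nitrate, salinity, note, geographic area).
#' @return An object of class `transcriptome_bundle`.
#' @export
transcriptome_bundle <- function(mmetsp_code, species, genus, transcripts,
                                 annotations, total_read_pairs,
                                 strain = NA_character_,
                                 growth_metadata = list()) {
  transcripts <- tibble::as_tibble(transcripts)
  annotations <- tibble::as_tibble(annotations)
  stopifnot(is.character(mmetsp_code), length(mmetsp_code) == 1)
  req <- c("transcript_id", "nucleotide_length", "peptide", "mapped_read_pairs")
  missing <- setdiff(req, names(transcripts))
  if (length(missing) > 0) {
    abort(paste0("transcripts lacks column(s): ", paste(missing, collapse = ", ")),
          class = "pgmine_validation_error")
  }
  transcripts$nucleotide_length <- as.integer(transcripts$nucleotide_length)
  transcripts$mapped_read_pairs <- as.double(transcripts$mapped_read_pairs)
  if (anyDuplicated(transcripts$transcript_id)) {
    abort("transcript ids must be unique within a bundle",
          class = "pgmine_validation_error")
  }
  if (any(transcripts$nucleotide_length < 1)) {
    abort("nucleotide_length must be >= 1", class = "pgmine_validation_error")
  }
  if (any(transcripts$mapped_read_pairs < 0)) {
    abort("mapped_read_pairs must be >= 0", class = "pgmine_validation_error")
  }
  if (nrow(annotations) > 0) {
    if (any(!nzchar(annotations$description))) {
      abort("annotation descriptions must be non-empty",
            class = "pgmine_validation_error")
    }
    if (any(annotations$start < 1 | annotations$start > annotations$end)) {
      abort("annotation coordinates must satisfy 1 <= start <= end",
            class = "pgmine_validation_error")
    }
    orphan <- !(annotations$transcript_id %in% transcripts$transcript_id)
    if (any(orphan)) {
      warn(paste0(sum(orphan), " annotation row(s) reference unknown ",
                  "transcript ids and were dropped"),
           class = "pgmine_orphan_annotation")
      annotations <- annotations[!orphan, ]
    }
  }
  if (total_read_pairs < 0) {
    abort("total_read_pairs must be >= 0", class = "pgmine_validation_error")
  }
  structure(
    list(
      mmetsp_code = mmetsp_code,
      species = species,
      genus = genus,
      strain = strain,
      transcripts = transcripts,
      annotations = annotations,
      total_read_pairs = as.double(total_read_pairs),
      growth_metadata = growth_metadata
    ),
    class = "transcriptome_bundle"
  )
}

#' @export
print.transcriptome_bundle <- function(x, ...) {
  cat("<transcriptome_bundle> ", x$mmetsp_code, " (", x$species, ")\n", sep = "")
  cat("  transcripts: ", nrow(x$transcripts),
      "; annotations: ", nrow(x$annotations),
      "; total read pairs: ", format(x$total_read_pairs, big.mark = ","),
      "\n", sep = "")
  invisible(x)
}

#' Read an MMETSP-style bundle directory
#'
#' Expects at minimum a peptide FASTA (`pep.fa`), an annotation table
#' (`swissprot.gff3` or `annotations.tsv`; dialect auto-detected by
#' extension) and a read-count table (`contig.dat`: tab-separated
#' `transcript_id`, `length_bp`, `mapped_read_pairs` with a
#' `#total_read_pairs<TAB>N` sidecar line), plus a `metadata.yaml` sidecar
#' naming the accession and organism. A nucleotide FASTA (`Nt.fa`) is read
#' when present; `cds.dat` and `stats.txt` are accepted but not consumed.
#'
#' @param dir Bundle directory.
#' @return A [transcriptome_bundle()]. Annotation rows for unknown transcript
#'   ids are dropped with a warning carrying the dropped-row count.
#' @export
read_bundle <- function(dir) {
  if (!dir.exists(dir)) {
    abort(paste0("bundle directory not found: ", dir), class = "pgmine_io_error")
  }
  need <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) {
      abort(paste0("mandatory bundle file missing: ", name, " (in ", dir, ")"),
            class = "pgmine_io_error")
    }
    p
  }
  pep_path <- need("pep.fa")
  counts_path <- need("contig.dat")
  meta_path <- need("metadata.yaml")
  gff_path <- file.path(dir, "swissprot.gff3")
  tsv_path <- file.path(dir, "annotations.tsv")
  if (!file.exists(gff_path) && !file.exists(tsv_path)) {
    abort(paste0("mandatory annotation table missing: expected swissprot.gff3 ",
                 "or annotations.tsv in ", dir),
          class = "pgmine_io_error")
  }

  meta <- yaml::read_yaml(meta_path)
  for (field in c("mmetsp_code", "species", "genus")) {
    if (is.null(meta[[field]])) {
      abort(paste0("metadata.yaml lacks field: ", field),
            class = "pgmine_validation_error")
    }
  }

  counts <- read_contig_counts(counts_path)
  peptides <- read_fasta_checked(pep_path, Biostrings::readAAStringSet)
  pep_tbl <- tibble::tibble(
    transcript_id = names(peptides),
    peptide = unname(as.character(peptides))
  )

  transcripts <- counts$table |>
    dplyr::left_join(pep_tbl, by = "transcript_id") |>
    dplyr::transmute(
      transcript_id = .data$transcript_id,
      nucleotide_length = .data$length_bp,
      peptide = .data$peptide,
      mapped_read_pairs = .data$mapped_read_pairs
    )

  nt_path <- file.path(dir, "Nt.fa")
  if (file.exists(nt_path)) {
    nt <- read_fasta_checked(nt_path, Biostrings::readDNAStringSet)
    nt_tbl <- tibble::tibble(transcript_id = names(nt),
                             nucleotide_sequence = unname(as.character(nt)))
    transcripts <- dplyr::left_join(transcripts, nt_tbl, by = "transcript_id")
  }

  annotations <- if (file.exists(gff_path)) {
    read_annotation_gff3(gff_path)
  } else {
    read_annotation_tsv(tsv_path)
  }

  transcriptome_bundle(
    mmetsp_code = meta$mmetsp_code,
    species = meta$species,
    genus = meta$genus,
    strain = meta$strain %||% NA_character_,
    transcripts = transcripts,
    annotations = annotations,
    total_read_pairs = counts$total_read_pairs,
    growth_metadata = meta$growth_metadata %||% list()
  )
}

read_contig_counts <- function(path) {
  lines <- readLines(path)
  total <- NA_real_
  header_idx <- integer(0)
  for (i in seq_along(lines)) {
    if (startsWith(lines[i], "#total_read_pairs")) {
      total <- suppressWarnings(as.numeric(strsplit(lines[i], "\t")[[1]][2]))
    }
  }
  body_idx <- which(!startsWith(lines, "#") & nzchar(lines))
  if (length(body_idx) > 0 &&
      identical(strsplit(lines[body_idx[1]], "\t")[[1]][1], "transcript_id")) {
    body_idx <- body_idx[-1]
  }
  rows <- vector("list", length(body_idx))
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    parts <- strsplit(lines[i], "\t")[[1]]
    if (length(parts) < 3) {
      abort(paste0(path, " line ", i, ": expected 3 tab-separated fields"),
            class = "pgmine_io_error")
    }
    len <- suppressWarnings(as.integer(parts[2]))
    cnt <- suppressWarnings(as.numeric(parts[3]))
    if (is.na(len) || is.na(cnt) || cnt != floor(cnt)) {
      abort(paste0(path, " line ", i, ": non-integer length or read count"),
            class = "pgmine_io_error")
    }
    if (cnt < 0) {
      abort(paste0(path, " line ", i, ": negative read count"),
            class = "pgmine_io_error")
    }
    rows[[k]] <- tibble::tibble(transcript_id = parts[1], length_bp = len,
                                mapped_read_pairs = cnt)
  }
  tbl <- dplyr::bind_rows(rows)
  if (is.na(total)) {
    abort(paste0(path, ": missing '#total_read_pairs' sidecar line"),
          class = "pgmine_io_error")
  }
  list(table = tbl, total_read_pairs = total)
}

read_fasta_checked <- function(path, reader) {
  lines <- readLines(path, n = 50L)
  first <- which(nzchar(lines))[1]
  if (!is.na(first) && !startsWith(lines[first], ">")) {
    abort(paste0(path, " line ", first, ": malformed FASTA (expected '>')"),
          class = "pgmine_io_error")
  }
  x <- reader(path)
  # keep only the id token, as MMETSP headers carry trailing description
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

read_annotation_gff3 <- function(path) {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g)
  tibble::tibble(
    transcript_id = as.character(g$seqid),
    subject_accession = as.character(g$Name %||% NA_character_),
    description = as.character(g$description),
    start = as.integer(g$start),
    end = as.integer(g$end),
    score = as.numeric(g$score)
  )
}

read_annotation_tsv <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    transcript_id = "c", subject_accession = "c", description = "c",
    start = "i", end = "i", score = "d"
  ), progress = FALSE)
  tibble::as_tibble(tb)
}

#' Write a bundle to an MMETSP-style directory
#'
#' Inverse of [read_bundle()]: writes `pep.fa`, `swissprot.gff3`,
#' `contig.dat`, `metadata.yaml`, `stats.txt` and, when nucleotide sequences
#' are carried, `Nt.fa`.
#'
#' @param bundle A [transcriptome_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- bundle$transcripts

  pep <- tr[!is.na(tr$peptide), ]
  pp <- Biostrings::AAStringSet(setNames(pep$peptide, pep$transcript_id))
  Biostrings::writeXStringSet(pp, file.path(dir, "pep.fa"))

  if ("nucleotide_sequence" %in% names(tr) &&
      any(!is.na(tr$nucleotide_sequence))) {
    nt <- tr[!is.na(tr$nucleotide_sequence), ]
    ns <- Biostrings::DNAStringSet(setNames(nt$nucleotide_sequence,
                                            nt$transcript_id))
    Biostrings::writeXStringSet(ns, file.path(dir, "Nt.fa"))
  }

  counts_lines <- c(
    paste0("#total_read_pairs\t", format(bundle$total_read_pairs,
                                         scientific = FALSE, trim = TRUE)),
    "transcript_id\tlength_bp\tmapped_read_pairs",
    paste(tr$transcript_id, tr$nucleotide_length,
          format(tr$mapped_read_pairs, scientific = FALSE, trim = TRUE),
          sep = "\t")
  )
  writeLines(counts_lines, file.path(dir, "contig.dat"))

  write_annotation_gff3(bundle$annotations, file.path(dir, "swissprot.gff3"))

  yaml::write_yaml(
    list(mmetsp_code = bundle$mmetsp_code, species = bundle$species,
         genus = bundle$genus,
         strain = if (is.na(bundle$strain)) NULL else bundle$strain,
         growth_metadata = bundle$growth_metadata),
    file.path(dir, "metadata.yaml")
  )

  st <- compute_assembly_stats(tr$nucleotide_length)
  readr::write_tsv(st, file.path(dir, "stats.txt"), progress = FALSE)
  invisible(dir)
}

# GFF3 attribute values: percent-encode the reserved characters only
gff3_encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x
}

write_annotation_gff3 <- function(annotations, path) {
  header <- "##gff-version 3"
  if (nrow(annotations) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  attrs <- paste0(
    "ID=hit", seq_len(nrow(annotations)),
    ";Name=", gff3_encode(annotations$subject_accession),
    ";description=", gff3_encode(annotations$description)
  )
  body <- paste(
    annotations$transcript_id, "swissprot", "protein_match",
    annotations$start, annotations$end,
    ifelse(is.na(annotations$score), ".",
           format(annotations$score, scientific = FALSE, trim = TRUE)),
    ".", ".", attrs,
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Assembly statistics (N50 and friends)
#'
#' Classical N50: sort contig lengths in descending order and take the length
#' at which the cumulative sum first reaches half the total assembly length.
#'
#' @param lengths Integer vector of contig lengths (bp, all >= 1).
#' @return One-row tibble: `n_sequences`, `min_length`, `max_length`, `n50`.
#' @examples
#' compute_assembly_stats(c(1, 2, 3, 4, 5)) # n50 = 4
#' @export
compute_assembly_stats <- function(lengths) {
  if (length(lengths) == 0) {
    abort("empty assembly", class = "pgmine_validation_error")
  }
  if (any(lengths < 1)) {
    abort("contig lengths must be >= 1", class = "pgmine_validation_error")
  }
  sorted <- sort(as.double(lengths), decreasing = TRUE)
  crossing <- which(cumsum(sorted) >= sum(sorted) / 2)[1]
  tibble::tibble(
    n_sequences = length(lengths),
    min_length = as.integer(min(lengths)),
    max_length = as.integer(max(lengths)),
    n50 = as.integer(sorted[crossing])
  )
}

#' Write / read a labelled matrix as TSV
#'
#' Tab-separated with a header row; the first column carries the row labels.
#' `read_matrix(write_matrix(m, path))` reproduces `m` exactly, including
#' missing cells (written as `NA`).
#'
#' @param matrix A matrix with unique row and column names (logical, numeric
#'   or character cells).
#' @param path Output file.
#' @param row_label Header for the row-label column.
#' @return `path` invisibly for `write_matrix`; the matrix for `read_matrix`.
#' @export
write_matrix <- function(matrix, path, row_label = "id") {
  if (anyDuplicated(rownames(matrix)) || anyDuplicated(colnames(matrix))) {
    abort("row and column labels must be unique",
          class = "pgmine_validation_error")
  }
  df <- tibble::as_tibble(as.data.frame(matrix, check.names = FALSE,
                                        stringsAsFactors = FALSE))
  df <- tibble::add_column(df, !!row_label := rownames(matrix) %||% character(0),
                           .before = 1)
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        na = "NA")
  if (ncol(tb) == 0) {
    return(matrix(nrow = 0, ncol = 0))
  }
  rn <- as.character(tb[[1]])
  body <- tb[, -1, drop = FALSE]
  m <- as.matrix(body)
  rownames(m) <- rn
  m
}
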