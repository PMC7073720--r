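AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Swiss-Prot-style background descriptions for decoy transcripts: never
# contain the query term.
DECOY_DESCRIPTIONS <- c(
  "60S ribosomal protein L7",
  "40S ribosomal protein S3",
  "Photosystem II protein D1",
  "Photosystem I P700 chlorophyll a apoprotein A1",
  "Heat shock protein 70",
  "ATP synthase subunit beta",
  "Tubulin alpha chain",
  "Actin-1",
  "Elongation factor 1-alpha",
  "Ribulose bisphosphate carboxylase large chain",
  "Histone H3",
  "Peridinin-chlorophyll a-binding protein",
  "Glyceraldehyde-3-phosphate dehydrogenase",
  "Calmodulin",
  "Ubiquitin-60S ribosomal protein L40"
)

# Near-miss decoys: contain the query term but no vocabulary synonym, so
# they exercise the canonicalization gate (term matching alone must not
# produce an assignment).
NEAR_MISS_DESCRIPTIONS <- c(
  "Prostaglandin transporter",
  "Solute carrier organic anion transporter (prostaglandin transporter)",
  "Prostaglandin D2 receptor",
  "Prostaglandin E2 receptor EP4 subtype",
  "Prostaglandin F2-alpha receptor"
)

#' Configuration for the synthetic-bundle generator
#'
#' Describes a simulated study: a set of species, each sequenced as one or
#' more replicate transcriptomes, with pathway genes planted from the
#' nine-enzyme vocabulary, redundant transcript copies at controlled
#' amino-acid identity, decoy transcripts with non-pathway (and optionally
#' near-miss) annotations, and per-transcript read counts drawn from an
#' overdispersed (gamma-mixed Poisson) count model.
#'
#' The defaults emulate a small multi-species survey: 3 species with 2
#' replicate transcriptomes each, 4 planted functions per species, 3
#' transcript copies per gene at 0.95 identity to the original, and 50
#' decoy transcripts per transcriptome of which 10% carry near-miss
#' prostaglandin-containing descriptions.
#'
#' @param n_species Number of simulated species.
#' @param transcriptomes_per_species Replicate transcriptomes per species.
#' @param planted_functions Named list `species -> character vector of
#'   vocabulary codes`. Default: 4 codes per species, rotating through the
#'   nine-code vocabulary so different species carry different enzyme sets.
#' @param copies_per_gene Redundant transcript copies per planted gene
#'   (>= 1); copy 1 is the unmutated original.
#' @param copy_identity Target amino-acid identity of redundant copies to
#'   the original, in `[0, 1]`.
#' @param n_decoy_transcripts Decoy (non-pathway) transcripts per
#'   transcriptome.
#' @param decoy_annotation_rate Fraction of decoys annotated with near-miss
#'   descriptions (contain the query term, match no vocabulary synonym).
#' @param expression_mean Mean mapped read pairs per planted transcript:
#'   a single number, or a tibble with columns `species`, `function_code`,
#'   `mean` for per-(species, function) means.
#' @param decoy_expression_mean Mean mapped read pairs per decoy transcript.
#' @param dispersion Overdispersion of the count model: counts have variance
#'   `mean + dispersion * mean^2`. `dispersion = 0` switches to a fully
#'   deterministic model (`count = round(mean)`), which makes replicate
#'   columns of the expression matrix identical.
#' @param total_read_pairs_mean Library size; held fixed (not resampled) so
#'   expected FPKM is exactly analytic.
#' @param peptide_length Length (aa) of planted peptides.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_species = 3,
                              transcriptomes_per_species = 2,
                              planted_functions = NULL,
                              copies_per_gene = 3,
                              copy_identity = 0.95,
                              n_decoy_transcripts = 50,
                              decoy_annotation_rate = 0.1,
                              expression_mean = 200,
                              decoy_expression_mean = 50,
                              dispersion = 0.3,
                              total_read_pairs_mean = 1e6,
                              peptide_length = 300,
                              seed = 1) {
  if (copy_identity < 0 || copy_identity > 1) {
    abort("copy_identity must be in [0, 1]", class = "pgmine_validation_error")
  }
  if (copies_per_gene < 1) {
    abort("copies_per_gene must be >= 1", class = "pgmine_validation_error")
  }
  species <- sprintf("Synthodinium sp%02d", seq_len(n_species))
  if (is.null(planted_functions)) {
    codes <- pg_function_codes()
    planted_functions <- lapply(seq_len(n_species), function(i) {
      codes[(((i - 1) * 4 + 0:3) %% length(codes)) + 1]
    })
    names(planted_functions) <- species
  } else {
    species <- names(planted_functions)
    n_species <- length(species)
  }
  structure(
    list(
      n_species = n_species,
      species = species,
      transcriptomes_per_species = transcriptomes_per_species,
      planted_functions = planted_functions,
      copies_per_gene = copies_per_gene,
      copy_identity = copy_identity,
      n_decoy_transcripts = n_decoy_transcripts,
      decoy_annotation_rate = decoy_annotation_rate,
      expression_mean = expression_mean,
      decoy_expression_mean = decoy_expression_mean,
      dispersion = dispersion,
      total_read_pairs_mean = total_read_pairs_mean,
      peptide_length = peptide_length,
      seed = seed
    ),
    class = "simulation_config"
  )
}

#' Substitute residues to reach a target identity
#'
#' Replaces `round((1 - target_identity) * nchar(sequence))` positions,
#' chosen uniformly at random, with a different residue each (no indels),
#' so the Hamming identity of the result to the input is exactly the target
#' up to rounding.
#'
#' @param sequence Amino-acid string (length >= 1).
#' @param target_identity Fraction in `[0, 1]`.
#' @return Mutated amino-acid string of the same length.
#' @examples
#' set.seed(1)
#' mutate_copy("MKLVMKLVMKLV", 0.75)
#' @export
mutate_copy <- function(sequence, target_identity) {
  if (target_identity < 0 || target_identity > 1) {
    abort("target_identity must be in [0, 1]", class = "pgmine_validation_error")
  }
  chars <- strsplit(sequence, "")[[1]]
  len <- length(chars)
  if (len < 1) {
    abort("sequence must have length >= 1", class = "pgmine_validation_error")
  }
  n_sub <- round((1 - target_identity) * len)
  if (n_sub == 0) {
    return(sequence)
  }
  pos <- sample.int(len, n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

random_peptide <- function(length) {
  paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = "")
}

random_dna <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

# gamma-mixed Poisson counts: mean m, variance m + dispersion * m^2.
# dispersion 0 degenerates to deterministic round(m).
draw_counts <- function(n, mean, dispersion) {
  if (dispersion == 0) {
    return(rep(round(mean), n))
  }
  lambda <- rgamma(n, shape = 1 / dispersion, scale = mean * dispersion)
  as.double(rpois(n, lambda))
}

expression_mean_for <- function(config, species, code) {
  em <- config$expression_mean
  if (is.numeric(em)) {
    return(em)
  }
  hit <- em$mean[em$species == species & em$function_code == code]
  if (length(hit) != 1) {
    abort(paste0("no expression mean configured for (", species, ", ", code, ")"),
          class = "pgmine_validation_error")
  }
  hit
}

#' Generate synthetic transcriptome bundles with known truth
#'
#' Builds one bundle per (species, replicate) according to `config`:
#' planted pathway transcripts annotated with vocabulary synonyms, redundant
#' copies of each planted gene at the configured identity, decoys with
#' background or near-miss annotations, and read counts from the
#' overdispersed count model. The original peptide of each gene is drawn
#' once per species so replicate transcriptomes carry near-identical copies
#' of the same gene, as strains of one species would.
#'
#' @param config A [simulation_config()].
#' @param vocabulary Vocabulary tibble; planted codes must be present in it.
#' @return A list of class `pg_simulation`:
#'   * `bundles` — named list of [transcriptome_bundle()] objects;
#'   * `truth` — tibble with one row per planted transcript
#'     (`mmetsp_code`, `species`, `transcript_id`, `function_code`,
#'     `gene_id`, `copy_index`, `true_mean`);
#'   * `config` — the configuration used.
#' @export
generate_bundles <- function(config, vocabulary = pg_vocabulary()) {
  bad <- setdiff(unique(unlist(config$planted_functions)), vocabulary$code)
  if (length(bad) > 0) {
    abort(paste0("planted function(s) not in vocabulary: ",
                 paste(bad, collapse = ", ")),
          class = "pgmine_validation_error")
  }
  set.seed(config$seed)
  # planted annotations emulate Swiss-Prot protein names, so draw only from
  # the synonyms that contain the query term (abbreviations like "COX2"
  # would not be retrieved by a term query of a real annotation table)
  syn_by_code <- setNames(
    lapply(seq_len(nrow(vocabulary)), function(i) {
      s <- vocabulary$synonyms[[i]]
      s <- s[grepl("prostaglandin", s, ignore.case = TRUE)]
      if (length(s) == 0) vocabulary$full_name[i] else s
    }),
    vocabulary$code
  )

  # one original peptide per (species, function) gene, shared by replicates
  originals <- list()
  for (sp in config$species) {
    for (code in config$planted_functions[[sp]]) {
      originals[[paste(sp, code, sep = "\r")]] <-
        random_peptide(config$peptide_length)
    }
  }

  bundles <- list()
  truth_rows <- list()
  bundle_no <- 0
  for (si in seq_along(config$species)) {
    sp <- config$species[si]
    genus <- strsplit(sp, " ")[[1]][1]
    for (rep_i in seq_len(config$transcriptomes_per_species)) {
      bundle_no <- bundle_no + 1
      code_mmetsp <- sprintf("MMETSP9%03d", bundle_no)
      t_counter <- 0
      tr_rows <- list()
      ann_rows <- list()

      for (fn in config$planted_functions[[sp]]) {
        origin <- originals[[paste(sp, fn, sep = "\r")]]
        gene_id <- paste(sp, fn, "g1", sep = "|")
        mu <- expression_mean_for(config, sp, fn)
        for (ci in seq_len(config$copies_per_gene)) {
          t_counter <- t_counter + 1
          tid <- sprintf("%s_t%04d", code_mmetsp, t_counter)
          pep <- if (ci == 1) origin else mutate_copy(origin, config$copy_identity)
          nt_len <- 3L * nchar(pep) + 3L
          tr_rows[[length(tr_rows) + 1]] <- tibble::tibble(
            transcript_id = tid,
            nucleotide_length = nt_len,
            peptide = pep,
            mapped_read_pairs = draw_counts(1, mu, config$dispersion),
            nucleotide_sequence = random_dna(nt_len)
          )
          syns <- syn_by_code[[fn]]
          ann_rows[[length(ann_rows) + 1]] <- tibble::tibble(
            transcript_id = tid,
            subject_accession = sprintf("SP%05d", sample.int(99999, 1)),
            description = syns[sample.int(length(syns), 1)],
            start = 1L,
            end = nt_len,
            score = round(stats::runif(1, 50, 400), 1)
          )
          truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
            mmetsp_code = code_mmetsp, species = sp, transcript_id = tid,
            function_code = fn, gene_id = gene_id, copy_index = ci,
            true_mean = mu
          )
        }
      }

      if (config$n_decoy_transcripts > 0) {
        n_near <- round(config$decoy_annotation_rate * config$n_decoy_transcripts)
        is_near <- seq_len(config$n_decoy_transcripts) <= n_near
        for (di in seq_len(config$n_decoy_transcripts)) {
          t_counter <- t_counter + 1
          tid <- sprintf("%s_t%04d", code_mmetsp, t_counter)
          pep <- random_peptide(sample(100:400, 1))
          nt_len <- 3L * nchar(pep) + 3L
          tr_rows[[length(tr_rows) + 1]] <- tibble::tibble(
            transcript_id = tid,
            nucleotide_length = nt_len,
            peptide = pep,
            mapped_read_pairs = draw_counts(1, config$decoy_expression_mean,
                                            config$dispersion),
            nucleotide_sequence = random_dna(nt_len)
          )
          desc <- if (is_near[di]) {
            NEAR_MISS_DESCRIPTIONS[sample.int(length(NEAR_MISS_DESCRIPTIONS), 1)]
          } else {
            DECOY_DESCRIPTIONS[sample.int(length(DECOY_DESCRIPTIONS), 1)]
          }
          ann_rows[[length(ann_rows) + 1]] <- tibble::tibble(
            transcript_id = tid,
            subject_accession = sprintf("SP%05d", sample.int(99999, 1)),
            description = desc,
            start = 1L,
            end = nt_len,
            score = round(stats::runif(1, 50, 400), 1)
          )
        }
      }

      bundles[[code_mmetsp]] <- transcriptome_bundle(
        mmetsp_code = code_mmetsp,
        species = sp,
        genus = genus,
        strain = sprintf("rep%d", rep_i),
        transcripts = dplyr::bind_rows(tr_rows),
        annotations = dplyr::bind_rows(ann_rows),
        total_read_pairs = config$total_read_pairs_mean,
        growth_metadata = list(replicate = rep_i)
      )
    }
  }

  structure(
    list(bundles = bundles,
         truth = dplyr::bind_rows(truth_rows),
         config = config),
    class = "pg_simulation"
  )
}

#' @export
print.pg_simulation <- function(x, ...) {
  cat("<pg_simulation> ", length(x$bundles), " bundles, ",
      nrow(x$truth), " planted transcripts\n", sep = "")
  invisible(x)
}

#' Planted species-by-function presence truth
#'
#' The boolean presence matrix implied by a simulation's planted functions,
#' in the same shape as [build_presence()] output, for exact comparison.
#'
#' @param sim A `pg_simulation` from [generate_bundles()].
#' @param level `"species"` or `"transcriptome"`.
#' @return Presence tibble (label column plus the nine code columns).
#' @export
truth_presence <- function(sim, level = c("species", "transcriptome")) {
  level <- match.arg(level)
  key <- if (level == "species") "species" else "mmetsp_code"
  build_presence_from_pairs(
    dplyr::distinct(sim$truth, .data[[key]], .data$function_code),
    key
  )
}

#' Write a simulation to bundle directories
#'
#' One subdirectory per bundle (standard MMETSP-style file set) plus a
#' `truth.json` sidecar with the planted-transcript table and a
#' `simulation_config.yaml` copy of the scalar configuration fields.
#'
#' @param sim A `pg_simulation`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in sim$bundles) {
    write_bundle(b, file.path(dir, b$mmetsp_code))
  }
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  cfg <- sim$config
  scalar <- cfg[vapply(cfg, function(v) is.atomic(v) && length(v) == 1, TRUE)]
  yaml::write_yaml(scalar, file.path(dir, "simulation_config.yaml"))
  invisible(dir)
}
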