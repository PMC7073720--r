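# hand-built three-transcript bundle used across the io/mining tests
make_test_bundle <- function() {
  transcriptome_bundle(
    mmetsp_code = "MMETSP0001",
    species = "Testodinium testii",
    genus = "Testodinium",
    strain = "T1",
    transcripts = tibble::tibble(
      transcript_id = c("t1", "t2", "t3"),
      nucleotide_length = c(900L, 1200L, 600L),
      peptide = c("MKLVWAAALKLV", "MKLVWAAALKLVMKLVWAAA", NA),
      mapped_read_pairs = c(100, 0, 25)
    ),
    annotations = tibble::tibble(
      transcript_id = c("t1", "t2"),
      subject_accession = c("P12345", "Q99999"),
      description = c("Prostaglandin E synthase 2",
                      "60S ribosomal protein L7"),
      start = c(1L, 10L),
      end = c(300L, 500L),
      score = c(180.5, NA)
    ),
    total_read_pairs = 1e6,
    growth_metadata = list(light = 150, salinity = 30)
  )
}

# small, fast simulation for unit tests
tiny_config <- function(...) {
  args <- list(n_species = 1, transcriptomes_per_species = 1,
               copies_per_gene = 1, n_decoy_transcripts = 0,
               peptide_length = 60, seed = 11)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_config, args)
}

# random amino-acid string helper for property tests
rand_aa <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

# random clustering instance: a few base sequences plus noisy copies, so
# clusters actually form at high thresholds
rand_cluster_instance <- function(n_max = 30) {
  n_base <- sample(2:5, 1)
  seqs <- character(0)
  for (b in seq_len(n_base)) {
    base <- rand_aa(sample(20:60, 1))
    n_copies <- sample(1:4, 1)
    seqs <- c(seqs, base,
              vapply(seq_len(max(0, n_copies - 1)),
                     function(i) mutate_copy(base, stats::runif(1, 0.6, 1)),
                     ""))
  }
  extra <- sample(0:5, 1)
  if (extra > 0) {
    seqs <- c(seqs, vapply(seq_len(extra),
                           function(i) rand_aa(sample(10:60, 1)), ""))
  }
  seqs <- head(seqs, n_max)
  setNames(seqs, sprintf("s%02d", seq_along(seqs)))
}
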