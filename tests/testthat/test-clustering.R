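test_that("pairwise identity follows the shorter-length convention", {
  expect_equal(pairwise_identity("MKLV", "MKLV"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_equal(pairwise_identity("AAAA", "AAAAAA"), 1.0)
  expect_error(pairwise_identity("", "AAA"), "non-empty",
               class = "pgmine_validation_error")
})

test_that("identity core agrees with an optimal-alignment reference", {
  # reference: Biostrings global alignment, match = 1, mismatch = 0,
  # zero gap penalties; the score is the maximal number of identities
  sm <- matrix(0, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(sm) <- 1
  ref_identity <- function(a, b) {
    s <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = sm,
                                       gapOpening = 0, gapExtension = 0,
                                       type = "global", scoreOnly = TRUE)
    s / min(nchar(a), nchar(b))
  }
  set.seed(17)
  for (i in 1:40) {
    a <- rand_aa(sample(5:60, 1))
    b <- if (i %% 2 == 0) mutate_copy(a, stats::runif(1, 0.5, 1)) else
      rand_aa(sample(5:60, 1))
    expect_equal(pairwise_identity(a, b), ref_identity(a, b))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("greedy clustering honours its contract on small cases", {
  cl <- greedy_cluster(c(a = "MKLVWYAA", b = "MKLVWYAA"), 0.9)
  expect_equal(dplyr::n_distinct(cl$cluster_id), 1)
  expect_equal(nrow(cl), 2)

  single <- greedy_cluster(c(only = "MKLV"), 0.9)
  expect_equal(single$representative_id, "only")

  base <- rand_aa(40)
  seqs <- c(x1 = base, x2 = mutate_copy(base, 0.95),
            y = "WWWWYYYYHHHHPPPPGGGGCCCCDDDDEEEEFFFFAAAA")
  set.seed(2)
  cl3 <- greedy_cluster(seqs, 0.9)
  expect_equal(dplyr::n_distinct(cl3$cluster_id), 2)
  expect_equal(tidy(brute_force_cluster(seqs, 0.9)), tidy(cl3))

  expect_error(greedy_cluster(seqs, 0), "threshold",
               class = "pgmine_validation_error")
})

test_that("clusters partition the input and satisfy threshold soundness", {
  set.seed(31)
  for (i in 1:25) {
    seqs <- rand_cluster_instance()
    thr <- sample(c(0.7, 0.8, 0.9, 0.95), 1)
    cl <- greedy_cluster(seqs, thr)
    expect_setequal(cl$member_id, names(seqs))
    expect_equal(anyDuplicated(cl$member_id), 0)
    expect_true(all(cl$identity_to_representative >= thr))
    # representatives are longest members of their cluster
    rep_len <- nchar(seqs[cl$representative_id])
    expect_true(all(rep_len >= cl$member_length))
    # recompute identities independently of the clustering loop
    for (j in seq_len(nrow(cl))) {
      expect_equal(
        pairwise_identity(seqs[[cl$member_id[j]]],
                          seqs[[cl$representative_id[j]]]),
        cl$identity_to_representative[j]
      )
    }
  }
})

test_that("raising the threshold never decreases the cluster count", {
  set.seed(57)
  for (i in 1:10) {
    seqs <- rand_cluster_instance()
    counts <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.95, 1),
                     function(t) dplyr::n_distinct(
                       greedy_cluster(seqs, t)$cluster_id), 0L)
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("per-group clustering reports transcript and gene counts", {
  sim <- generate_bundles(simulation_config(
    n_species = 2, transcriptomes_per_species = 1, copies_per_gene = 3,
    n_decoy_transcripts = 0, seed = 9))
  a <- assign_functions(sim$bundles)
  peptides <- dplyr::bind_rows(lapply(sim$bundles, function(b)
    b$transcripts[c("transcript_id", "peptide")]))
  out <- cluster_by_function(a, peptides, 0.9, by = "species")
  # three redundant copies of one gene collapse: sp_count 3 -> cdhit_count 1
  expect_true(all(out$report$sp_count == 3))
  expect_true(all(out$report$cdhit_count == 1))
  expect_true(all(out$report$cdhit_count <= out$report$sp_count))

  # missing peptide is fatal and lists the ids
  expect_error(
    cluster_by_function(a, peptides[-1, ], 0.9),
    a$transcript_id[a$transcript_id == peptides$transcript_id[1]][1],
    class = "pgmine_validation_error"
  )
})

test_that("two species with identical sequences stay in separate groups", {
  pep <- c(s1_t1 = "MKLVWYAAHHPPGG", s2_t1 = "MKLVWYAAHHPPGG")
  a <- tibble::tibble(
    transcript_id = names(pep),
    mmetsp_code = c("M1", "M2"),
    species = c("sp one", "sp two"),
    function_code = "PTGR1",
    matched_description = "Prostaglandin reductase 1"
  )
  out <- cluster_by_function(a, pep, 0.9, by = "species")
  expect_equal(nrow(out$report), 2)
  expect_equal(sum(out$report$cdhit_count), 2)
  # pooled run without grouping flags the shared sequence as impure
  pooled <- greedy_cluster(pep, 0.9)
  pur <- cross_species_purity(pooled, a)
  expect_lt(pur$purity, 1)
  expect_false(pur$per_cluster$pure[1])
})

test_that("pooled clusters of species-distinct genes are pure", {
  sim <- generate_bundles(simulation_config(
    n_species = 3, transcriptomes_per_species = 2,
    n_decoy_transcripts = 0, seed = 13))
  a <- assign_functions(sim$bundles)
  peptides <- dplyr::bind_rows(lapply(sim$bundles, function(b)
    b$transcripts[c("transcript_id", "peptide")]))
  pooled <- greedy_cluster(peptides, 0.9)
  pur <- cross_species_purity(pooled, a)
  expect_equal(pur$purity, 1)

  empty <- cross_species_purity(pooled[0, ], a)
  expect_true(is.na(empty$purity))
  expect_equal(empty$note, "no clusters")
})

test_that("clstr output lists every member and marks representatives", {
  seqs <- c(a = "MKLVWYAAHH", b = "MKLVWYAAHH", c = "WWYYHHPPGG")
  cl <- greedy_cluster(seqs, 0.9)
  p <- withr::local_tempfile(fileext = ".clstr")
  write_clstr(cl, p)
  lines <- readLines(p)
  expect_equal(sum(grepl("^>Cluster", lines)),
               dplyr::n_distinct(cl$cluster_id))
  expect_equal(sum(grepl("\\*$", lines)), dplyr::n_distinct(cl$cluster_id))
  expect_equal(sum(!grepl("^>", lines)), length(seqs))
})
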