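test_that("FPKM evaluates the formula and rejects zero denominators", {
  expect_equal(compute_fpkm(0, 1000, 1e6), 0)
  expect_equal(compute_fpkm(1000, 1000, 1e6), 1000)
  expect_equal(compute_fpkm(250, 500, 2e6), 250)
  expect_error(compute_fpkm(1, 0, 1e6), "division",
               class = "pgmine_validation_error")
  expect_error(compute_fpkm(1, 100, 0), "division",
               class = "pgmine_validation_error")
  expect_error(compute_fpkm(-1, 100, 1e6), class = "pgmine_validation_error")
})

test_that("FPKM matches direct arithmetic and is scale invariant", {
  set.seed(101)
  for (i in 1:100) {
    m <- sample(0:1e5, 1); L <- sample(1:2e4, 1); total <- sample(1e5:1e8, 1)
    expect_equal(compute_fpkm(m, L, total),
                 m / (L / 1000) / (total / 1e6))
    k <- stats::runif(1, 0.1, 50)
    expect_equal(compute_fpkm(k * m, L, k * total),
                 compute_fpkm(m, L, total))
  }
})

test_that("per-function sums follow the stated summation rule", {
  fpkm <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3"),
    mmetsp_code = "M1",
    fpkm = c(1.5, 2.5, 7.5)
  )
  a <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3"),
    mmetsp_code = "M1",
    species = "sp",
    function_code = c("PTGR1", "PTGR1", "HPGDS"),
    matched_description = "x"
  )
  fe <- function_expression(a, fpkm, mode = "all")
  expect_equal(fe$fpkm_sum[fe$function_code == "PTGR1"], 4.0)
  expect_equal(fe$n_transcripts[fe$function_code == "PTGR1"], 2L)
  expect_equal(fe$fpkm_sum[fe$function_code == "HPGDS"], 7.5)

  # absent function -> no record, not a zero
  expect_false("COX2" %in% fe$function_code)

  # assignment without an expression record is fatal and lists the id
  expect_error(function_expression(a, fpkm[-1, ], mode = "all"), "t1",
               class = "pgmine_validation_error")
})

test_that("heads mode sums representatives only; all mode sums everything", {
  sim <- generate_bundles(simulation_config(
    n_species = 1, transcriptomes_per_species = 1, copies_per_gene = 3,
    n_decoy_transcripts = 0, dispersion = 0, seed = 5))
  a <- assign_functions(sim$bundles)
  pep <- dplyr::bind_rows(lapply(sim$bundles, function(b)
    b$transcripts[c("transcript_id", "peptide")]))
  cl <- cluster_by_function(a, pep, 0.9, by = "transcriptome")
  fpkm <- transcript_fpkm(sim$bundles)
  heads <- function_expression(a, fpkm, cl$clusters, mode = "heads")
  all_tx <- function_expression(a, fpkm, mode = "all")
  expect_true(all(heads$n_transcripts == 1))
  expect_true(all(all_tx$n_transcripts == 3))
  # deterministic counts: each copy carries the same FPKM
  expect_equal(all_tx$fpkm_sum, 3 * heads$fpkm_sum)
  # linearity: group sums equal independent summation
  manual <- dplyr::summarise(
    dplyr::group_by(dplyr::left_join(as.data.frame(a), fpkm,
                                     by = c("transcript_id", "mmetsp_code")),
                    function_code),
    s = sum(fpkm), .groups = "drop")
  expect_equal(sort(all_tx$fpkm_sum),
               sort(manual$s))
})

test_that("expression matrix encodes absence as missing, not zero", {
  fe <- tibble::tibble(
    mmetsp_code = c("M1", "M1", "M2"),
    species = c("sp a", "sp a", "sp b"),
    function_code = c("COX2", "PTGR1", "PTGR1"),
    fpkm_sum = c(3, 1, 2),
    n_transcripts = 1L
  )
  m <- expression_matrix(fe)
  expect_equal(dim(m), c(9, 2))
  expect_equal(m["COX2", "M1"], 3)
  expect_true(is.na(m["COX2", "M2"]))
  expect_true(is.na(m["HPGDS", "M1"]))

  p <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, p, row_label = "function_code")
  m2 <- read_matrix(p)
  expect_true(is.na(m2["COX2", "M2"]))
  expect_equal(m2, m, ignore_attr = TRUE)
})

test_that("replicate columns are identical when dispersion is zero", {
  sim <- generate_bundles(simulation_config(
    n_species = 1, transcriptomes_per_species = 2, copies_per_gene = 2,
    n_decoy_transcripts = 0, dispersion = 0, seed = 2))
  res <- run_pipeline(sim$bundles)
  m <- res$expression_matrix
  expect_equal(ncol(m), 2)
  expect_equal(m[, 1], m[, 2], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("mean summed FPKM matches the analytic expectation", {
  # 200 replicate transcriptomes of one species; head = unmutated original
  n_rep <- 200
  mu <- 200; pep_len <- 150; total <- 1e6
  sim <- generate_bundles(simulation_config(
    n_species = 1, transcriptomes_per_species = n_rep, copies_per_gene = 2,
    n_decoy_transcripts = 0, peptide_length = pep_len,
    expression_mean = mu, total_read_pairs_mean = total, seed = 41))
  a <- assign_functions(sim$bundles)
  pep <- dplyr::bind_rows(lapply(sim$bundles, function(b)
    b$transcripts[c("transcript_id", "peptide")]))
  cl <- cluster_by_function(a, pep, 0.9, by = "transcriptome")
  fe <- function_expression(a, transcript_fpkm(sim$bundles),
                            cl$clusters, mode = "heads")
  nt_len <- 3 * pep_len + 3
  expected <- mu / (nt_len / 1000) / (total / 1e6)
  per_fn <- dplyr::group_by(fe, function_code)
  stats_tbl <- dplyr::summarise(per_fn, m = mean(fpkm_sum),
                                se = stats::sd(fpkm_sum) / sqrt(dplyr::n()),
                                .groups = "drop")
  expect_true(all(abs(stats_tbl$m - expected) <= 3 * stats_tbl$se))
})
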