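test_that("presence matrices mark annotated functions and drop empty rows", {
  a <- tibble::tibble(
    transcript_id = c("t1", "t2"),
    mmetsp_code = c("M1", "M2"),
    species = c("sp a", "sp b"),
    function_code = "PTGR1",
    matched_description = "Prostaglandin reductase 1"
  )
  p <- build_presence(a, "species")
  expect_equal(names(p), c("species", pg_function_codes()))
  expect_equal(nrow(p), 2)
  expect_true(all(p$PTGR1))
  expect_true(all(!p$COX2))

  expect_equal(nrow(build_presence(a[0, ], "species")), 0)
  expect_equal(species_with_any(build_presence(a[0, ], "species")), 0)
})

test_that("occurrence counts equal direct assignment grouping", {
  sim <- generate_bundles(simulation_config(seed = 29))
  a <- assign_functions(sim$bundles)
  counts <- count_occurrences(build_presence(a, "species"),
                              build_presence(a, "transcriptome"))
  # independent path: group the assignments directly
  direct <- dplyr::summarise(
    dplyr::group_by(as.data.frame(a), function_code),
    n_species = dplyr::n_distinct(species),
    n_transcriptomes = dplyr::n_distinct(mmetsp_code),
    .groups = "drop")
  for (code in direct$function_code) {
    expect_equal(counts$n_species[counts$function_code == code],
                 direct$n_species[direct$function_code == code])
    expect_equal(counts$n_transcriptomes[counts$function_code == code],
                 direct$n_transcriptomes[direct$function_code == code])
  }
  # functions never assigned count zero
  expect_true(all(counts$n_species[!counts$function_code %in%
                                     direct$function_code] == 0))
  # n_species <= n_transcriptomes when every species has >= 1 transcriptome
  expect_true(all(counts$n_species <= counts$n_transcriptomes))
})

test_that("the bundled species survey reproduces the reported counts", {
  p <- mmetsp_presence()
  expect_equal(nrow(p), 14)
  expect_equal(species_with_any(p), 14)
  counts <- count_occurrences(p)
  expect_equal(counts$n_species[counts$function_code == "COX2"], 2L)
  expect_equal(counts$n_species[counts$function_code == "HPGDS"], 9L)
  expect_equal(counts$n_species[counts$function_code == "PTGES2"], 12L)
  expect_equal(counts$n_species[counts$function_code == "PTGR1"], 14L)
})

test_that("metadata census counts transcriptomes, genera and species", {
  expect_equal(metadata_census(mmetsp_growth_conditions()),
               tibble::tibble(n_transcriptomes = 42L, n_genera = 15L,
                              n_species = 19L))
  one <- tibble::tibble(mmetsp_code = "M1", genus = "G", species = "s")
  expect_equal(unlist(metadata_census(one)),
               c(n_transcriptomes = 1L, n_genera = 1L, n_species = 1L))
  two_strains <- tibble::tibble(mmetsp_code = c("M1", "M2"),
                                genus = "G", species = "s")
  expect_equal(metadata_census(two_strains)$n_species, 1L)
  dup <- tibble::tibble(mmetsp_code = c("M1", "M1"), genus = "G",
                        species = c("s", "t"))
  expect_error(metadata_census(dup), "duplicate",
               class = "pgmine_validation_error")
})

test_that("assembly-size differences are computed between accessions", {
  st <- mmetsp_assembly_stats()
  expect_equal(size_difference(st, "MMETSP0201", "MMETSP0202"), 11600L)
  expect_equal(size_difference(st, "MMETSP0201", "MMETSP0201"), 0L)
  expect_error(size_difference(st, "MMETSP0201", "MMETSP9999"), "unknown",
               class = "pgmine_validation_error")
  # MMETSP0380 has no reported statistics
  expect_error(size_difference(st, "MMETSP0380", "MMETSP0201"),
               class = "pgmine_validation_error")

  sim <- generate_bundles(tiny_config(n_decoy_transcripts = 4))
  own <- stats_table(sim$bundles)
  expect_equal(own$n_sequences, nrow(sim$bundles[[1]]$transcripts))
})

test_that("figures are written and missing cells use the reserved color", {
  skip_if_not_installed("png")
  d <- withr::local_tempdir()
  counts <- tibble::tibble(function_code = pg_function_codes(),
                           n_species = c(2L, 9L, 12L, 4L, 1L, 3L, 1L, 14L, 4L),
                           n_transcriptomes = c(2L, 18L, 20L, 6L, 2L, 4L,
                                                1L, 24L, 7L))
  f1 <- file.path(d, "occ.png")
  occurrence_chart(counts, f1)
  expect_gt(file.size(f1), 0)
  # determinism at the pixel level
  f2 <- file.path(d, "occ2.png")
  occurrence_chart(counts, f2)
  expect_identical(png::readPNG(f1), png::readPNG(f2))

  m <- matrix(c(1, NA, 3, 4), 2, 2,
              dimnames = list(c("COX2", "PTGR1"), c("M1", "M2")))
  fh <- file.path(d, "heat.png")
  render_heatmap(m, fh)
  img <- png::readPNG(fh)
  reserved <- grDevices::col2rgb("#BFBFBF")[, 1] / 255
  hit <- abs(img[, , 1] - reserved[1]) < 1e-3 &
    abs(img[, , 2] - reserved[2]) < 1e-3 &
    abs(img[, , 3] - reserved[3]) < 1e-3
  expect_gt(sum(hit), 100)

  # log10(x + 1) stays finite on zeros
  m0 <- matrix(0, 1, 1, dimnames = list("COX2", "M1"))
  render_heatmap(m0, file.path(d, "zero.png"), transform = "log10p1")
  expect_gt(file.size(file.path(d, "zero.png")), 0)

  # empty counts still render with a notice
  empty <- tibble::tibble(function_code = character(0),
                          n_species = integer(0),
                          n_transcriptomes = integer(0))
  occurrence_chart(empty, file.path(d, "empty.png"))
  expect_gt(file.size(file.path(d, "empty.png")), 0)
})

test_that("pipeline recovers planted truth and reruns byte-identically", {
  sim <- generate_bundles(simulation_config(seed = 77))
  dirs <- withr::local_tempdir()
  write_simulation(sim, dirs)
  bundle_dirs <- list.dirs(dirs, recursive = FALSE)
  out1 <- file.path(dirs, "run1"); out2 <- file.path(dirs, "run2")
  res <- run_pipeline(bundle_dirs, out_dir = out1)
  expect_equal(res$presence_species, truth_presence(sim))
  expect_equal(res$presence_transcriptome,
               truth_presence(sim, "transcriptome"))
  run_pipeline(bundle_dirs, out_dir = out2)
  for (f in grep("\\.tsv$", list.files(out1), value = TRUE)) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), info = f)
  }
})

test_that("a bundle with zero pathway hits yields empty outputs, no error", {
  b <- make_test_bundle()
  b$annotations <- b$annotations[2, ]   # ribosomal protein only
  d <- withr::local_tempdir()
  res <- run_pipeline(list(b), out_dir = d)
  expect_equal(nrow(res$assignments), 0)
  expect_equal(nrow(res$presence_species), 0)
  expect_equal(sum(res$occurrence$n_species), 0)
  expect_true(file.exists(file.path(d, "presence_species.tsv")))
})
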