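make_fixture <- function(seed = 3) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  write_fixture_dir(dir, seed = seed, n_proteins = 6, n_sites = 2,
                    n_secretome = 40, n_intact = 2, n_cleaved = 2)
  dir
}

test_that("run_scan reproduces generator truth and reruns byte-identically", {
  dir <- make_fixture()
  out1 <- file.path(dir, "out1")
  out2 <- file.path(dir, "out2")
  cfg <- list(fasta = file.path(dir, "proteome.fasta"),
              signal_tsv = file.path(dir, "signal.tsv"),
              topology_tsv = file.path(dir, "topology.tsv"),
              out_dir = out1, seed = 1L)
  sm <- run_scan(cfg)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  counts <- setNames(tidy(sm)$value, tidy(sm)$metric)
  n_amid_truth <- sum(truth$precursor_products$amidated)
  expect_equal(counts[["n_amidated_peptides"]], n_amid_truth)
  expect_true(file.exists(file.path(out1, "sites_pc.tsv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))

  cfg$out_dir <- out2
  run_scan(cfg)
  for (f in c("sites_pc.tsv", "peptides.tsv", "summary.tsv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  # manifests differ only in config hash (out_dir differs), inputs match
  m1 <- jsonlite::read_json(file.path(out1, "manifest.json"))
  m2 <- jsonlite::read_json(file.path(out2, "manifest.json"))
  expect_identical(m1$input_md5, m2$input_md5)
})

test_that("run_scan rejects empty or missing inputs", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "empty.fasta")
  writeLines(character(), f)
  expect_error(run_scan(list(fasta = f, signal_tsv = f, topology_tsv = f,
                             out_dir = dir)),
               "No FASTA entries")
  expect_error(run_scan(list(fasta = f)), "missing config key")
})

test_that("run_secretome retains exactly the truth set and writes a census", {
  dir <- make_fixture()
  samples <- setNames(file.path(dir, paste0("sample_", LETTERS[1:6],
                                            ".tsv")), LETTERS[1:6])
  out <- file.path(dir, "sec_out")
  merged <- run_secretome(list(
    samples = as.list(samples),
    dataset_ids = c(1, 1, 1, 2, 2, 2),
    localization_tsv = file.path(dir, "localization.tsv"),
    signal_tsv = file.path(dir, "signal.tsv"),
    out_dir = out))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(merged$protein_id, truth$secretome_retained)
  census <- jsonlite::read_json(file.path(out, "census.json"),
                                simplifyVector = TRUE)
  expect_equal(census$n_merged, nrow(merged))
  expect_true(census$top_n_share <= 1)
  # one sample with min_presence 1 is an identity merge
  one <- run_secretome(list(samples = list(A = samples[["A"]]),
                            min_presence = 1,
                            out_dir = file.path(dir, "one_out")))
  a <- readr::read_tsv(samples[["A"]], col_names = c("protein_id", "count"),
                       col_types = "ci")
  expect_setequal(one$protein_id, a$protein_id)
  # min_presence exceeding the sample count errors
  expect_error(run_secretome(list(samples = list(A = samples[["A"]]),
                                  min_presence = 7,
                                  out_dir = file.path(dir, "bad"))),
               "exceeds")
})

test_that("run_slices recovers gel truth, handles empty evidence and bad slices", {
  dir <- make_fixture()
  out <- file.path(dir, "gel_out")
  calls <- run_slices(list(slices_tsv = file.path(dir, "slices.tsv"),
                           evidence_tsv = file.path(dir, "evidence.tsv"),
                           proteins_tsv = file.path(dir, "gel_proteins.tsv"),
                           out_dir = out))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  j <- dplyr::left_join(calls, tibble::as_tibble(truth$gel_truth),
                        by = "protein_id", suffix = c("", "_truth"))
  expect_equal(as.character(j$status), j$status_truth)
  expect_true(file.exists(file.path(out, "calls.tsv")))

  # empty evidence: no calls, clean exit
  empty_ev <- file.path(dir, "empty_ev.tsv")
  file.create(empty_ev)
  calls0 <- run_slices(list(slices_tsv = file.path(dir, "slices.tsv"),
                            evidence_tsv = empty_ev,
                            proteins_tsv = file.path(dir,
                                                     "gel_proteins.tsv"),
                            out_dir = file.path(dir, "gel_empty")))
  expect_equal(nrow(calls0), 0L)

  # corrupt slice reference errors
  bad_ev <- file.path(dir, "bad_ev.tsv")
  writeLines("GEL001\t99\t1\t20\t5", bad_ev)
  expect_error(run_slices(list(slices_tsv = file.path(dir, "slices.tsv"),
                               evidence_tsv = bad_ev,
                               proteins_tsv = file.path(dir,
                                                        "gel_proteins.tsv"),
                               out_dir = file.path(dir, "gel_bad"))),
               "unknown slice")
})

test_that("configs load from YAML files too", {
  dir <- make_fixture()
  cfg_file <- file.path(dir, "scan.yaml")
  yaml::write_yaml(list(fasta = file.path(dir, "proteome.fasta"),
                        signal_tsv = file.path(dir, "signal.tsv"),
                        topology_tsv = file.path(dir, "topology.tsv"),
                        out_dir = file.path(dir, "yaml_out"),
                        preset = "results-spacings"), cfg_file)
  sm <- run_scan(cfg_file)
  expect_s3_class(sm, "proteome_summary")
  expect_equal(sm$config$pc_spacings, c(0L, 2L))
})
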