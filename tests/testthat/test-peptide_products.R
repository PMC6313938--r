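test_that("cleave cuts the mature chain and tiles it exactly", {
  prot <- tibble::tibble(protein_id = "p1", sequence = "MKWVSAEGKRSFLD",
                         signal_end = 4L)
  pep <- cleave(prot, tibble::tibble(protein_id = "p1",
                                     cleavage_after = 10L))
  expect_equal(pep$sequence, c("SAEGKR", "SFLD"))
  expect_equal(pep$start, c(5L, 11L))
  expect_equal(pep$start_mature, c(1L, 7L))

  # no sites: one peptide covering the whole mature chain
  pep0 <- cleave(prot, tibble::tibble(protein_id = character(),
                                      cleavage_after = integer()))
  expect_equal(pep0$sequence, "SAEGKRSFLD")

  # two cuts -> three peptides whose lengths sum to the mature length
  pep2 <- cleave(prot, tibble::tibble(protein_id = "p1",
                                      cleavage_after = c(7L, 10L)))
  expect_equal(nrow(pep2), 3L)
  expect_equal(sum(nchar(pep2$sequence)), 10L)

  # duplicate and out-of-range cut points collapse / are skipped
  expect_message(
    pep3 <- cleave(prot, tibble::tibble(protein_id = "p1",
                                        cleavage_after = c(10L, 10L, 2L,
                                                           99L))),
    "skipped")
  expect_equal(pep3$sequence, c("SAEGKR", "SFLD"))
})

test_that("tiling conservation holds on random precursors", {
  set.seed(11)
  cfg <- motif_config()
  for (i in 1:25) {
    seq <- paste0("M", random_aa_sequence(sample(50:200, 1), p_basic = 0.15))
    prot <- tibble::tibble(protein_id = "p", sequence = seq,
                           signal_end = sample(0:10, 1))
    sites <- dplyr::bind_rows(find_pc_sites(prot, cfg),
                              find_furin_sites(prot))
    pep <- suppressMessages(cleave(prot, sites))
    expect_equal(sum(nchar(pep$sequence)), nchar(seq) - prot$signal_end)
    expect_equal(pep$start[1], prot$signal_end + 1L)
    expect_equal(pep$end[nrow(pep)], nchar(seq))
  }
})

test_that("trimming and amidation follow the CPB/PAM rules", {
  out <- trim_and_amidate(tibble::tibble(
    sequence = c("SAEGKR", "SFLD", "GKR", "KRKR", "AG")))
  expect_equal(out$trimmed_basics, c(2L, 0L, 2L, 4L, 0L))
  expect_equal(out$amidated, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$amide_residue, c("E", NA, NA, NA, "A"))
  expect_equal(out$length_final, c(3L, 4L, 1L, 0L, 1L))
  # GKR leaves a lone Gly; KRKR trims away entirely: both degenerate
  expect_equal(out$degenerate, c(FALSE, FALSE, TRUE, TRUE, FALSE))
})

test_that("amide histogram counts amidated peptides only and sums right", {
  pep <- trim_and_amidate(tibble::tibble(
    sequence = c("SAEGKR", "QGK", "SFLD", "TTGRR")))
  h <- amide_histogram(pep)
  expect_equal(sum(h$n), sum(pep$amidated))
  expect_setequal(h$amide_residue, c("E", "Q", "T"))
  empty <- amide_histogram(trim_and_amidate(tibble::tibble(
    sequence = "SFLD")))
  expect_equal(nrow(empty), 0L)
})

test_that("proteome summary recovers planted ground truth", {
  gen <- generate_precursor_set(6, n_sites = 2L, seed = 31)
  sm <- summarize_proteome(gen$proteins)
  counts <- setNames(tidy(sm)$value, tidy(sm)$metric)
  # every planted amidatable site yields exactly one amidated peptide
  expect_equal(counts[["n_amidated_peptides"]], 2L * 6L)
  expect_equal(counts[["n_proteins_amidated"]], 6L)
  got <- dplyr::filter(sm$peptides, amidated)
  want <- dplyr::filter(gen$truth$products, amidated)
  expect_equal(
    dplyr::arrange(got[, c("precursor_id", "start", "end",
                           "amide_residue")],
                   precursor_id, start),
    dplyr::arrange(want[, c("precursor_id", "start", "end",
                            "amide_residue")],
                   precursor_id, start))
  # spacers are motif-free: no false products beyond the planted ones
  expect_equal(nrow(got), nrow(want))
})

test_that("terminal-Gly proteins are counted and amidated", {
  g <- generate_precursor(0, end_with = "G", seed = 5)
  sm <- summarize_proteome(g$protein)
  counts <- setNames(tidy(sm)$value, tidy(sm)$metric)
  expect_equal(counts[["n_terminal_G"]], 1L)
  expect_equal(counts[["n_terminal_G_tail"]], 0L)
  expect_gte(counts[["n_amidated_peptides"]], 1L)

  g2 <- generate_precursor(0, end_with = "G_tail", seed = 5)
  sm2 <- summarize_proteome(g2$protein)
  counts2 <- setNames(tidy(sm2)$value, tidy(sm2)$metric)
  expect_equal(counts2[["n_terminal_G_tail"]], 1L)
})

test_that("furin-amidatable counting singles out RG(K/R)R", {
  prot <- tibble::tibble(
    protein_id = c("fa", "fn"),
    sequence = c("MAAAARGKRAAAA", "MAAAARQKRAAAA"))
  sm <- summarize_proteome(prot)
  counts <- setNames(tidy(sm)$value, tidy(sm)$metric)
  expect_equal(counts[["n_with_furin"]], 2L)
  expect_equal(counts[["n_furin_amidatable"]], 1L)
})

test_that("summaries are deterministic and export byte-identical TSVs", {
  gen <- generate_precursor_set(4, n_sites = 2L, seed = 8)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_summary_tsvs(summarize_proteome(gen$proteins), d1)
  write_summary_tsvs(summarize_proteome(gen$proteins), d2)
  for (f in c("peptides.tsv", "summary.tsv", "amide_histogram.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("known-motifs mode counts proteins yielding amidated products", {
  gen <- generate_precursor_set(5, n_sites = 1L, seed = 12)
  sm <- summarize_proteome(gen$proteins, mode = "known_motifs")
  counts <- setNames(tidy(sm)$value, tidy(sm)$metric)
  # planted GKR blocks carry a KR known motif; products end in G after trim
  expect_equal(counts[["n_proteins_amidated"]], 5L)
  expect_equal(counts[["n_amidated_peptides"]], 5L)
})
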