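test_that("PC finder matches the worked dibasic examples", {
  cfg0 <- motif_config(pc_spacings = 0)
  s <- find_pc_sites("AKRSA", cfg0)
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 2L)
  expect_equal(s$end, 3L)
  expect_equal(s$cleavage_after, 3L)
  expect_equal(s$motif, "KR")

  # an R-K-R run holds two spacing-0 pairs but no spacing-1 pair
  seq <- paste0(strrep("A", 135), "RKR", strrep("A", 10))
  s <- find_pc_sites(seq)
  expect_equal(s[, c("start", "end")],
               tibble::tibble(start = c(136L, 137L), end = c(137L, 138L)))

  expect_equal(nrow(find_pc_sites("ACDEFG")), 0L)
  expect_equal(nrow(find_pc_sites("")), 0L)
})

test_that("furin finder requires R-X-(K/R)-R", {
  s <- find_furin_sites("ARQKRA")
  expect_equal(s$start, 2L)
  expect_equal(s$end, 5L)
  expect_equal(s$cleavage_after, 5L)
  expect_equal(nrow(find_furin_sites("KQKR")), 0L)
  # RGRR doubles as furin site and RG(K/R)R amidation motif
  expect_equal(nrow(find_furin_sites("RGRR")), 1L)
  am <- find_amidation_sites("RGRR")
  expect_true("RG_KR_R" %in% am$site_class)
})

test_that("amidation motif classes land on the right glycine", {
  a <- find_amidation_sites("AGKRA")
  expect_equal(a$site_class, "G_KR_KR")
  expect_equal(a$gly_position, 2L)

  a <- find_amidation_sites("KAGRD")
  expect_equal(a$site_class, "KR_XnG_KR")
  expect_equal(a$gly_position, 3L)

  a <- find_amidation_sites("ARGKRD")
  expect_true(all(c("RG_KR_R", "G_KR_KR") %in% a$site_class))
  expect_equal(a$gly_position[a$site_class == "RG_KR_R"], 3L)
})

test_that("terminal amidation distinguishes -G, -G(K/R)n and neither", {
  t1 <- find_terminal_amidation(c(a = "QADG", b = "QADGKR", c = "QADK"))
  expect_equal(t1$site_class[t1$protein_id == "a"], "terminal_G")
  expect_equal(t1$site_class[t1$protein_id == "b"], "terminal_G_basic_tail")
  expect_false("c" %in% t1$protein_id)
  # tail longer than max_basic_tail does not qualify
  t2 <- find_terminal_amidation("QAGKRKR", motif_config(max_basic_tail = 3))
  expect_equal(nrow(t2), 0L)
})

test_that("known-motif matching applies exclusions after matching", {
  ex0 <- character()
  s <- find_known_motif_sites("AKKA", motif_config(known_motifs = "KK",
                                                   excluded_motifs = ex0))
  expect_equal(s$cleavage_after, 3L)

  s <- find_known_motif_sites("ARKA",
                              motif_config(known_motifs = c("RK", "KR"),
                                           excluded_motifs = "RK"))
  expect_equal(nrow(s), 0L)

  s <- find_known_motif_sites("AKAAK",
                              motif_config(known_motifs = "KXXK",
                                           excluded_motifs = "KXXK"))
  expect_equal(nrow(s), 0L)

  expect_error(motif_config(known_motifs = "KQR"), "K, R, X")
})

test_that("finders agree with brute-force oracles on random sequences", {
  set.seed(101)
  cfg <- motif_config()
  for (i in 1:60) {
    seq <- random_aa_sequence(sample(10:300, 1), p_basic = 0.15)
    got <- find_pc_sites(seq, cfg)
    want <- oracle_pc_sites(seq, cfg$pc_spacings)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
    fu <- find_furin_sites(seq)
    expect_equal(if (nrow(fu)) fu$start else integer(),
                 oracle_furin_sites(seq))
    am <- find_amidation_sites(seq, cfg)
    am_want <- oracle_amidation_sites(seq, cfg$amidation_spacings)
    expect_equal(nrow(am), nrow(am_want))
    if (nrow(am_want)) {
      am <- am[order(am$end, am$start, am$site_class), ]
      expect_equal(am$gly_position, am_want$gly_position)
      expect_equal(am$site_class, am_want$site_class)
    }
    km <- find_known_motif_sites(seq, cfg)
    km_want <- oracle_known_motifs(seq, cfg$known_motifs,
                                   cfg$excluded_motifs)
    km_want <- km_want[order(km_want$end, km_want$start), ]
    if (nrow(km)) km <- km[order(km$end, km$start), ]
    expect_equal(nrow(km), nrow(km_want))
    if (nrow(km_want)) {
      expect_equal(km$start, km_want$start)
      expect_equal(km$end, km_want$end)
    }
  }
})

test_that("enlarging pc_spacings never removes a site; K/R-free means none", {
  set.seed(7)
  for (i in 1:20) {
    seq <- random_aa_sequence(150, p_basic = 0.2)
    small <- find_pc_sites(seq, motif_config(pc_spacings = c(0, 2)))
    big <- find_pc_sites(seq, motif_config(pc_spacings = c(0, 2, 4, 6)))
    if (nrow(small)) {
      key <- function(x) paste(x$start, x$end)
      expect_true(all(key(small) %in% key(big)))
    }
    nb <- random_aa_sequence(150, p_basic = 0)
    expect_equal(nrow(find_pc_sites(nb)), 0L)
    expect_equal(nrow(find_furin_sites(nb)), 0L)
    expect_equal(nrow(find_known_motif_sites(nb, motif_config())), 0L)
  }
})

test_that("sites overlapping the signal peptide are flagged", {
  prot <- tibble::tibble(protein_id = "p", sequence = "MKRAAAAKRA",
                         signal_end = 4L)
  s <- find_pc_sites(prot, motif_config(pc_spacings = 0))
  expect_equal(s$in_signal, c(TRUE, FALSE))
})

test_that("motif configuration round-trips through YAML and has presets", {
  expect_equal(motif_config(preset = "results-spacings")$pc_spacings,
               c(0L, 2L))
  expect_equal(motif_config()$pc_spacings, c(0L, 2L, 4L, 6L))
  cfg <- motif_config(pc_spacings = c(0, 2), known_motifs = c("KR", "RR"))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_motif_config(cfg, f)
  expect_equal(read_motif_config(f), cfg)
})
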