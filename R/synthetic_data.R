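# Ground-truthed synthetic inputs for every stage. Spacer regions exclude
# K, R and G by construction, so the only grammar matches are the planted
# ones and false-positive expectations are exactly zero. Every generator is
# a pure function of (parameters, seed).

SPACER_ALPHABET <- c("A", "S", "T", "V", "L", "E", "D", "Q", "N", "P", "F")

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_spacer <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

#' Generate one synthetic precursor with planted processing sites
#'
#' Builds a signal peptide followed by alternating motif-free spacers and
#' planted motif blocks, recording every planted site and the peptide
#' products (with their amidation state) that the processing model should
#' recover. Spacer lengths must exceed the largest PC spacing so blocks
#' cannot combine into unplanned motifs.
#'
#' Supported site classes:
#' * `"G_KR_KR"` — plants `GKR`: a dibasic cleavage whose product is
#'   amidatable (trim K, R; Gly consumed; the preceding spacer residue ends
#'   up amidated).
#' * `"KR"` — plants a plain dibasic cleavage (product not amidatable).
#' * `"furin"` — plants `R<x>KR` (x a spacer residue): furin-consensus
#'   cleavage, not amidatable.
#'
#' @param n_sites number of planted internal sites (0 allowed).
#' @param site_classes character vector recycled over sites.
#' @param spacer_length residues between blocks (default 8; must be >= 7 so
#'   the default spacing sets cannot bridge blocks).
#' @param signal_length planted signal-peptide length (default 20).
#' @param end_with `"none"`, `"G"` (C-terminal Gly) or `"G_tail"`
#'   (Gly + `KR` tail), planting direct C-terminal amidation.
#' @param spacer_alphabet residues used for spacers; must exclude K, R, G.
#' @param protein_id id for the record.
#' @param seed integer seed.
#' @return List with `protein` (one-row protein tibble incl. `signal_end`)
#'   and `truth` (list: `sites` tibble with planted class and
#'   `cleavage_after`; `products` tibble with spans, sequences, amidation
#'   state and amide residue).
#' @export
generate_precursor <- function(n_sites, site_classes = "G_KR_KR",
                               spacer_length = 8L, signal_length = 20L,
                               end_with = c("none", "G", "G_tail"),
                               spacer_alphabet = SPACER_ALPHABET,
                               protein_id = "SYN1", seed = 1L) {
  n_sites <- assert_count_scalar(n_sites, "n_sites")
  end_with <- match.arg(end_with)
  if (any(c("K", "R", "G") %in% spacer_alphabet)) {
    abort("spacer_alphabet must exclude K, R and G.")
  }
  if (spacer_length < 7L) abort("spacer_length must be >= 7.")
  classes <- if (n_sites > 0) rep_len(site_classes, n_sites) else character()
  bad <- setdiff(classes, c("G_KR_KR", "KR", "furin"))
  if (length(bad)) abort(paste0("Unknown site class: ", bad[1]))

  with_seed(seed, {
    signal <- paste0("M", random_spacer(signal_length - 1L, spacer_alphabet))
    pieces <- character()
    sites <- list()
    products <- list()
    pos <- signal_length          # last residue written so far
    prev_cut <- signal_length     # product start bookkeeping
    for (i in seq_len(n_sites)) {
      sp <- random_spacer(spacer_length, spacer_alphabet)
      block <- switch(classes[i],
        G_KR_KR = "GKR",
        KR = "KR",
        furin = paste0("R", sample(spacer_alphabet, 1), "KR"))
      pieces <- c(pieces, sp, block)
      block_end <- pos + spacer_length + str_length(block)
      sites[[i]] <- tibble(
        protein_id = protein_id, site_class = classes[i],
        start = pos + spacer_length + 1L, end = block_end,
        cleavage_after = block_end)
      pep_seq <- paste0(sp, block)
      amid <- classes[i] == "G_KR_KR"
      products[[i]] <- tibble(
        precursor_id = protein_id, start = prev_cut + 1L, end = block_end,
        sequence = pep_seq, amidated = amid,
        amide_residue = if (amid) str_sub(sp, spacer_length, spacer_length)
                        else NA_character_)
      pos <- block_end
      prev_cut <- block_end
    }
    tail_sp <- random_spacer(spacer_length, spacer_alphabet)
    tail_seq <- switch(end_with,
      none = tail_sp,
      G = paste0(tail_sp, "G"),
      G_tail = paste0(tail_sp, "GKR"))
    pieces <- c(pieces, tail_seq)
    seq <- paste0(signal, paste(pieces, collapse = ""))
    len <- str_length(seq)
    tail_amid <- end_with %in% c("G", "G_tail")
    products[[n_sites + 1L]] <- tibble(
      precursor_id = protein_id, start = prev_cut + 1L, end = len,
      sequence = tail_seq, amidated = tail_amid,
      amide_residue = if (tail_amid)
        str_sub(tail_sp, spacer_length, spacer_length) else NA_character_)
    list(
      protein = tibble(protein_id = protein_id, description = "synthetic",
                       sequence = seq, length = len,
                       signal_end = signal_length),
      truth = list(sites = if (length(sites)) bind_rows(sites)
                           else empty_sites(),
                   products = bind_rows(products)))
  })
}

#' Generate a set of synthetic precursors
#'
#' Convenience wrapper around [generate_precursor()]; per-protein seeds are
#' derived deterministically from `seed`.
#'
#' @param n_proteins number of precursors.
#' @param n_sites sites per precursor (recycled).
#' @param ... passed to [generate_precursor()].
#' @param seed integer seed.
#' @return List with `proteins` (tibble) and `truth` (combined `sites` and
#'   `products` tibbles).
#' @export
generate_precursor_set <- function(n_proteins, n_sites = 3L, ...,
                                   seed = 1L) {
  n_proteins <- assert_count_scalar(n_proteins, "n_proteins", min = 1L)
  n_sites <- rep_len(n_sites, n_proteins)
  res <- map(seq_len(n_proteins), function(i) {
    generate_precursor(n_sites[i], ...,
                       protein_id = sprintf("SYN%04d", i),
                       seed = seed * 10000L + i)
  })
  list(proteins = bind_rows(map(res, "protein")),
       truth = list(sites = bind_rows(map(res, ~ .x$truth$sites)),
                    products = bind_rows(map(res, ~ .x$truth$products))))
}

#' Generate a six-sample synthetic secretome with controlled presence
#'
#' Each protein draws a presence level from `presence_probs` (over 1..6
#' samples), the samples it appears in, and strictly positive
#' negative-binomial spectral counts (overdispersed, as label-free counts
#' are). Samples A-C form dataset 1, D-F dataset 2.
#'
#' @param n_proteins number of proteins.
#' @param presence_probs probabilities over presence levels 1..6.
#' @param count_mean negative-binomial mean (default 20).
#' @param count_dispersion negative-binomial size parameter (default 2;
#'   smaller = more overdispersed).
#' @param seed integer seed.
#' @return List: `counts` (long tibble `sample_id`, `dataset_id`,
#'   `protein_id`, `count`) and `truth` (`presence` tibble and `retained`,
#'   the ids expected to survive the >= 4-of-6 filter).
#' @export
generate_secretome <- function(n_proteins = 200L,
                               presence_probs = c(0.10, 0.10, 0.15, 0.20,
                                                  0.20, 0.25),
                               count_mean = 20, count_dispersion = 2,
                               seed = 1L) {
  n_proteins <- assert_count_scalar(n_proteins, "n_proteins", min = 1L)
  if (length(presence_probs) != 6L || any(presence_probs < 0) ||
      sum(presence_probs) <= 0) {
    abort("presence_probs must be 6 non-negative values with positive sum.")
  }
  samples <- LETTERS[1:6]
  with_seed(seed, {
    ids <- sprintf("PROT%04d", seq_len(n_proteins))
    presence <- sample(1:6, n_proteins, replace = TRUE,
                       prob = presence_probs)
    rows <- map(seq_len(n_proteins), function(i) {
      in_samples <- sort(sample(samples, presence[i]))
      counts <- rnbinom(presence[i], mu = count_mean,
                        size = count_dispersion) + 1L
      tibble(sample_id = in_samples,
             dataset_id = if_else(in_samples %in% c("A", "B", "C"), 1L, 2L),
             protein_id = ids[i], count = as.integer(counts))
    })
    list(counts = bind_rows(rows),
         truth = list(presence = tibble(protein_id = ids,
                                        presence = presence),
                      retained = ids[presence >= 4L]))
  })
}

#' Default gel-slice layout for synthetic gels
#'
#' Nine contiguous slices spanning 10-250 kDa, indexed from the lightest.
#'
#' @return Slice tibble (`slice_index`, `mass_low`, `mass_high`).
#' @export
default_gel_slices <- function() {
  bounds <- c(10, 15, 20, 30, 40, 60, 80, 120, 180, 250)
  tibble(slice_index = seq_len(length(bounds) - 1L),
         mass_low = bounds[-length(bounds)],
         mass_high = bounds[-1])
}

#' Generate gel-slice evidence for intact and cleaved proteins
#'
#' Intact proteins receive tryptic-peptide evidence only in or above the
#' slice holding their intact mass; cleaved proteins receive evidence
#' restricted to a planted N- or C-terminal fragment, placed in a slice well
#' below the intact mass (mass_high < 0.7 x intact mass), with at least two
#' summed spectral counts. Noiseless by construction: no stray peptides.
#'
#' @param n_intact number of intact proteins.
#' @param n_cleaved number of cleaved proteins.
#' @param slices slice tibble (default [default_gel_slices()]).
#' @param cleaved_regions `"N_terminal"`, `"C_terminal"` or both (recycled
#'   over cleaved proteins).
#' @param seed integer seed.
#' @return List: `proteins` (`protein_id`, `length`, `intact_mass_kda`),
#'   `evidence`, `slices`, and `truth` (`protein_id`, `status`, `region`,
#'   `frag_start`, `frag_end`).
#' @export
generate_gel_dataset <- function(n_intact = 5L, n_cleaved = 5L,
                                 slices = default_gel_slices(),
                                 cleaved_regions = c("N_terminal",
                                                     "C_terminal"),
                                 seed = 1L) {
  n_intact <- assert_count_scalar(n_intact, "n_intact")
  n_cleaved <- assert_count_scalar(n_cleaved, "n_cleaved")
  slices <- validate_slices(slices)
  stopifnot(all(cleaved_regions %in% c("N_terminal", "C_terminal")))
  n <- n_intact + n_cleaved
  if (n == 0L) abort("Need at least one protein.")
  regions <- if (n_cleaved > 0) rep_len(cleaved_regions, n_cleaved)
             else character()
  with_seed(seed, {
    ids <- sprintf("GEL%03d", seq_len(n))
    # masses placed mid-gel so sub-intact slices exist below every protein
    mass <- stats::runif(n, 60, 200)
    len <- as.integer(round(mass * 1000 / 110))  # ~110 Da per residue
    status <- c(rep("intact", n_intact), rep("cleaved", n_cleaved))
    intact_idx <- locate_intact_slice(mass, slices)$slice_index
    rank_of <- setNames(seq_len(nrow(slices)), slices$slice_index)
    ev <- list(); tr <- list()
    for (i in seq_len(n)) {
      if (status[i] == "intact") {
        ok_slices <- slices$slice_index[
          rank_of[as.character(slices$slice_index)] >=
            rank_of[as.character(intact_idx[i])]]
        k <- sample(2:4, 1)
        ps <- sort(sample(seq_len(len[i] - 30L), k))
        ev[[i]] <- tibble(
          protein_id = ids[i],
          slice_index = ok_slices[sample.int(length(ok_slices), k,
                                             replace = TRUE)],
          peptide_start = ps, peptide_end = ps + sample(8:25, k,
                                                        replace = TRUE),
          spectral_count = sample(2:8, k, replace = TRUE))
        tr[[i]] <- tibble(protein_id = ids[i], status = "intact",
                          region = NA_character_, frag_start = NA_integer_,
                          frag_end = NA_integer_)
      } else {
        reg <- regions[i - n_intact]
        frag <- if (reg == "N_terminal") {
          c(1L, as.integer(floor(0.35 * len[i])))
        } else {
          c(as.integer(ceiling(0.65 * len[i])), len[i])
        }
        sub_slices <- slices$slice_index[slices$mass_high < 0.7 * mass[i]]
        k <- sample(2:4, 1)
        ps <- sort(sample(frag[1]:(frag[2] - 20L), k))
        pe <- pmin(ps + sample(8:18, k, replace = TRUE), frag[2])
        ev[[i]] <- tibble(
          protein_id = ids[i],
          slice_index = sub_slices[sample.int(length(sub_slices), 1)],
          peptide_start = ps, peptide_end = pe,
          spectral_count = sample(2:6, k, replace = TRUE))
        tr[[i]] <- tibble(protein_id = ids[i], status = "cleaved",
                          region = reg, frag_start = min(ps),
                          frag_end = max(pe))
      }
    }
    list(proteins = tibble(protein_id = ids, length = len,
                           intact_mass_kda = mass),
         evidence = bind_rows(ev), slices = slices,
         truth = bind_rows(tr))
  })
}

#' Write a complete synthetic fixture directory
#'
#' Generates a precursor set, a six-sample secretome and a gel dataset, and
#' writes every input format the pipeline readers consume: `proteome.fasta`,
#' `signal.tsv`, `topology.tsv`, `localization.tsv`, per-sample count TSVs
#' (`sample_A.tsv` ... `sample_F.tsv`), `slices.tsv`, `evidence.tsv`,
#' `gel_proteins.tsv`, plus a `truth.json` manifest of all planted ground
#' truth.
#'
#' @param dir output directory (created).
#' @param seed integer seed controlling all randomness.
#' @param n_proteins precursors in the FASTA.
#' @param n_sites planted sites per precursor.
#' @param n_secretome proteins in the count tables.
#' @param n_intact,n_cleaved gel dataset composition.
#' @return `dir`, invisibly. Side effect: files written.
#' @export
write_fixture_dir <- function(dir, seed = 1L, n_proteins = 20L,
                              n_sites = 3L, n_secretome = 100L,
                              n_intact = 4L, n_cleaved = 4L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pre <- generate_precursor_set(n_proteins, n_sites = n_sites, seed = seed)
  sec <- generate_secretome(n_secretome, seed = seed + 1L)
  gel <- generate_gel_dataset(n_intact, n_cleaved, seed = seed + 2L)

  write_fasta(pre$proteins, file.path(dir, "proteome.fasta"))
  write_annotation_table(
    tibble(protein_id = pre$proteins$protein_id, has_signal = TRUE,
           signal_end = pre$proteins$signal_end),
    file.path(dir, "signal.tsv"))
  write_annotation_table(
    tibble(protein_id = pre$proteins$protein_id,
           tm_helices = map(seq_len(nrow(pre$proteins)),
                            ~ tibble(start = integer(), end = integer()))),
    file.path(dir, "topology.tsv"))
  sec_ids <- unique(sec$counts$protein_id)
  write_annotation_table(
    tibble(protein_id = sec_ids, category = "SP"),
    file.path(dir, "localization.tsv"))
  for (s in LETTERS[1:6]) {
    sub <- filter(sec$counts, .data$sample_id == s)
    readr::write_tsv(select(sub, "protein_id", "count"),
                     file.path(dir, paste0("sample_", s, ".tsv")),
                     col_names = FALSE, progress = FALSE)
  }
  readr::write_tsv(gel$slices, file.path(dir, "slices.tsv"),
                   col_names = FALSE, progress = FALSE)
  readr::write_tsv(gel$evidence, file.path(dir, "evidence.tsv"),
                   col_names = FALSE, progress = FALSE)
  readr::write_tsv(gel$proteins, file.path(dir, "gel_proteins.tsv"),
                   col_names = FALSE, progress = FALSE)
  truth <- list(seed = seed,
                precursor_sites = pre$truth$sites,
                precursor_products = pre$truth$products,
                secretome_presence = sec$truth$presence,
                secretome_retained = sec$truth$retained,
                gel_truth = gel$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
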