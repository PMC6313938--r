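# From cleavage sites to predicted peptide products: simultaneous cleavage at
# all predicted sites, carboxypeptidase-B-like trimming of C-terminal K/R,
# amidation of peptides whose trimmed core ends in Gly, and the per-proteome
# product statistics.

#' Cleave mature chains at predicted sites
#'
#' The mature chain (residues `signal_end + 1 .. length`; `signal_end` 0 or
#' `NA` means no signal peptide) is cut after every distinct `cleavage_after`
#' position. Cleavage is treated as simultaneous at all sites ("ordered"
#' kinetics are not modeled — only the product set matters). Sites sharing a
#' cut point collapse to one cut; sites inside the signal peptide or beyond
#' the chain are skipped with a message. The returned peptides tile the
#' mature chain exactly.
#'
#' @param proteins data frame with `protein_id`, `sequence` and optionally
#'   `signal_end`.
#' @param sites site tibble with `protein_id` and `cleavage_after` (any
#'   finder output; classes may be mixed).
#' @return Tibble of pre-trim peptides: `precursor_id`, `start`, `end`
#'   (precursor coordinates), `start_mature`, `end_mature` (1-based in the
#'   mature chain), `sequence`.
#' @export
cleave <- function(proteins, sites) {
  proteins <- as_protein_tbl(proteins)
  sig <- if ("signal_end" %in% names(proteins)) {
    if_else(is.na(proteins$signal_end), 0L, as.integer(proteins$signal_end))
  } else rep(0L, nrow(proteins))
  n_skipped <- 0L
  rows <- pmap(list(proteins$protein_id, proteins$sequence,
                    proteins$length, sig),
               function(id, seq, len, s0) {
    cuts <- sort(unique(as.integer(sites$cleavage_after[
      sites$protein_id == id])))
    out_of_range <- cuts[cuts <= s0 | cuts > len]
    n_skipped <<- n_skipped + length(out_of_range)
    cuts <- cuts[cuts > s0 & cuts < len]   # a cut at `len` is a no-op
    bounds <- c(s0, cuts, len)
    starts <- bounds[-length(bounds)] + 1L
    ends <- bounds[-1]
    tibble(precursor_id = id, start = starts, end = ends,
           start_mature = starts - s0, end_mature = ends - s0,
           sequence = str_sub(seq, starts, ends))
  })
  if (n_skipped > 0L) {
    inform(paste0(n_skipped, " site(s) outside the mature chain ",
                  "(signal-peptide overlap or past the C-terminus) skipped."))
  }
  bind_rows(rows)
}

#' Apply CPB-like trimming and PAM amidation to predicted peptides
#'
#' C-terminal Lys/Arg exposed by endoproteolysis are removed iteratively
#' (carboxypeptidase-B-like step). If the trimmed core ends in Gly and
#' retains at least one further residue, the Gly is consumed by the
#' amidating enzyme, leaving the preceding residue alpha-amidated. A peptide
#' whose trimming removes everything is flagged degenerate and never
#' amidated.
#'
#' @param peptides tibble from [cleave()] (needs a `sequence` column).
#' @return Input with added columns: `trimmed_basics`, `amidated`,
#'   `amide_residue` (`NA` unless amidated), `mature_sequence` (post-trim,
#'   post-Gly-removal), `length_final`, `degenerate`.
#' @export
trim_and_amidate <- function(peptides) {
  stopifnot(is.data.frame(peptides), "sequence" %in% names(peptides))
  seq <- peptides$sequence
  core <- sub("[KR]+$", "", seq)
  trimmed <- str_length(seq) - str_length(core)
  nc <- str_length(core)
  # degenerate: trimming empties the peptide, or only a lone Gly remains so
  # that amidation would leave nothing to amidate
  degenerate <- nc == 0L | (nc == 1L & core == "G")
  amidated <- !degenerate & nc >= 2L & str_sub(core, nc, nc) == "G"
  mature <- if_else(amidated, str_sub(core, 1L, nc - 1L), core)
  nm <- str_length(mature)
  as_tibble(peptides) %>%
    mutate(trimmed_basics = trimmed,
           amidated = amidated,
           amide_residue = if_else(amidated, str_sub(mature, nm, nm),
                                   NA_character_),
           mature_sequence = if_else(nc == 0L, NA_character_, mature),
           length_final = nm,
           degenerate = degenerate)
}

#' Histogram of amidated C-terminal residues
#'
#' @param peptides tibble from [trim_and_amidate()].
#' @return Tibble (`amide_residue`, `n`) over amidated peptides only; `n`
#'   sums to the number of amidated peptides.
#' @export
amide_histogram <- function(peptides) {
  peptides %>%
    filter(.data$amidated) %>%
    count(.data$amide_residue, name = "n") %>%
    arrange(desc(.data$n), .data$amide_residue)
}

#' Proteome-wide precursor-processing summary
#'
#' Runs the site finders on every protein, enumerates peptide products, and
#' tabulates the precursor statistics: how many proteins carry PC sites,
#' amidation signatures of each class, furin sites (and amidatable ones,
#' i.e. RG(K/R)R), C-terminal Gly (with or without a basic tail), and — for
#' the product enumeration — how many amidated peptides arise, their length
#' distribution and amidated-residue histogram.
#'
#' In `"grammar"` mode products come from cleavage at PC plus furin sites; in
#' `"known_motifs"` mode from the known-motif table, mirroring motif-table
#' predictor usage. Sites overlapping the signal peptide are excluded
#' throughout. Amidated peptides are counted per (precursor, span); identical
#' sequences from different precursors count separately.
#'
#' @param proteins protein tibble, ideally from [select_secreted_soluble()]
#'   so that `signal_end` is available.
#' @param config a [motif_config()].
#' @param mode `"grammar"` or `"known_motifs"`.
#' @return A `proteome_summary` object; see [tidy.proteome_summary()],
#'   [glance.proteome_summary()], [autoplot.proteome_summary()].
#' @export
summarize_proteome <- function(proteins, config = motif_config(),
                               mode = c("grammar", "known_motifs")) {
  mode <- match.arg(mode)
  proteins <- as_protein_tbl(proteins)
  drop_signal <- function(x) {
    if (nrow(x) && "in_signal" %in% names(x)) filter(x, !.data$in_signal)
    else x
  }
  pc <- drop_signal(find_pc_sites(proteins, config))
  fu <- drop_signal(find_furin_sites(proteins))
  am <- drop_signal(find_amidation_sites(proteins, config))
  term <- find_terminal_amidation(proteins, config)

  n_class <- function(x, cls) {
    if (nrow(x) == 0) return(0L)
    n_distinct(x$protein_id[x$site_class %in% cls])
  }
  cut_sites <- switch(mode,
    grammar = bind_rows(pc, fu),
    known_motifs = drop_signal(find_known_motif_sites(proteins, config)))
  peptides <- trim_and_amidate(cleave(proteins, cut_sites))
  amidated <- filter(peptides, .data$amidated)

  counts <- tibble(
    metric = c("n_proteins", "n_proteins_with_pc_sites", "n_with_G_KR_KR",
               "n_with_KR_XnG_KR", "n_with_furin", "n_furin_amidatable",
               "n_terminal_G", "n_terminal_G_tail", "n_proteins_amidated",
               "n_amidated_peptides"),
    value = c(nrow(proteins),
              n_class(pc, "PC"),
              n_class(am, "G_KR_KR"),
              n_class(am, "KR_XnG_KR"),
              n_class(fu, "furin"),
              if (nrow(fu)) n_distinct(fu$protein_id[
                str_sub(fu$motif, 2L, 2L) == "G"]) else 0L,
              n_class(term, "terminal_G"),
              n_class(term, "terminal_G_basic_tail"),
              if (nrow(amidated)) n_distinct(amidated$precursor_id) else 0L,
              nrow(amidated)))

  structure(list(
    counts = counts,
    peptides = peptides,
    histogram = amide_histogram(peptides),
    length_distribution = count(amidated, .data$length_final, name = "n"),
    per_protein = count(amidated, .data$precursor_id,
                        name = "n_amidated_peptides"),
    mode = mode, config = config),
    class = "proteome_summary")
}

#' @export
print.proteome_summary <- function(x, ...) {
  cat("<proteome_summary> mode =", x$mode, "\n")
  v <- setNames(x$counts$value, x$counts$metric)
  cat(sprintf("  %d proteins scanned; %d with PC sites; %d with furin sites\n",
              v["n_proteins"], v["n_proteins_with_pc_sites"],
              v["n_with_furin"]))
  cat(sprintf("  %d amidated peptides from %d proteins\n",
              v["n_amidated_peptides"], v["n_proteins_amidated"]))
  invisible(x)
}

#' Tidy a proteome summary into a metric/value tibble
#'
#' @param x a `proteome_summary`.
#' @param ... unused.
#' @return Tibble (`metric`, `value`) of the precursor statistics.
#' @export
tidy.proteome_summary <- function(x, ...) x$counts

#' One-row overview of a proteome summary
#'
#' @param x a `proteome_summary`.
#' @param ... unused.
#' @return One-row tibble of the headline counts plus amidated-peptide length
#'   range.
#' @export
glance.proteome_summary <- function(x, ...) {
  v <- setNames(as.integer(x$counts$value), x$counts$metric)
  len <- x$length_distribution$length_final
  tibble(mode = x$mode,
         n_proteins = v[["n_proteins"]],
         n_proteins_with_pc_sites = v[["n_proteins_with_pc_sites"]],
         n_with_furin = v[["n_with_furin"]],
         n_proteins_amidated = v[["n_proteins_amidated"]],
         n_amidated_peptides = v[["n_amidated_peptides"]],
         min_peptide_length = if (length(len)) min(len) else NA_integer_,
         max_peptide_length = if (length(len)) max(len) else NA_integer_)
}

#' Plot the amidated-residue histogram of a proteome summary
#'
#' @param object a `proteome_summary`.
#' @param ... unused.
#' @return A ggplot: predicted amidated C-terminal residue vs peptide count.
#' @export
autoplot.proteome_summary <- function(object, ...) {
  ggplot(object$histogram, aes(x = .data$amide_residue, y = .data$n)) +
    geom_col(fill = "grey30") +
    labs(x = "amidated C-terminal residue", y = "predicted peptides",
         title = paste0("Predicted amidated peptides (", object$mode,
                        " mode)")) +
    theme_minimal()
}

#' Export predicted peptides and summary tables to TSV
#'
#' Writes `peptides.tsv`, `summary.tsv` and `amide_histogram.tsv` under
#' `dir`.
#'
#' @param summary a `proteome_summary`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_summary_tsvs <- function(summary, dir) {
  stopifnot(inherits(summary, "proteome_summary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(summary$peptides, file.path(dir, "peptides.tsv"),
                   progress = FALSE)
  readr::write_tsv(summary$counts, file.path(dir, "summary.tsv"),
                   progress = FALSE)
  readr::write_tsv(summary$histogram, file.path(dir, "amide_histogram.tsv"),
                   progress = FALSE)
  invisible(dir)
}
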