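# Motif grammar for precursor processing: prohormone convertase (PC) paired
# basic sites (K/R)Xn(K/R), furin RX(K/R)R, amidation signatures, and a
# NeuroPred-style "known motifs" table. All matching is overlap-aware (every
# match is reported, including nested ones); positions are 1-based inclusive
# and cleavage points are "after residue i".

#' Motif-scan configuration
#'
#' Bundles the tunable pieces of the processing grammar:
#' * `pc_spacings` — allowed numbers of intervening residues in
#'   (K/R)Xn(K/R); the default follows the full spacing set `{0, 2, 4, 6}`,
#'   the `"results-spacings"` preset restricts to `{0, 2}`.
#' * `amidation_spacings` — `n` in (K/R)XnG(K/R) (default `{1, 3}`).
#' * `known_motifs` — cleavage patterns over the alphabet `{K, R, X}` (X =
#'   any residue) used in known-motif mode. The shipped default is the
#'   mono-/dibasic plus spaced-tetrabasic set; the table is user-replaceable
#'   because published known-motif tables vary.
#' * `excluded_motifs` — patterns removed *after* matching (default
#'   `RK`, `KXXK`, `KXXR`, reflecting cleavages not observed in
#'   *Aplysia*-trained motif sets).
#' * `max_basic_tail` — longest Lys/Arg tail accepted after a C-terminal Gly
#'   for direct amidation (default 3).
#'
#' @param pc_spacings non-negative integers.
#' @param amidation_spacings non-negative integers.
#' @param known_motifs character patterns over `{K, R, X}`.
#' @param excluded_motifs character patterns over `{K, R, X}`.
#' @param max_basic_tail single non-negative integer.
#' @param preset `"methods-spacings"` (default, `pc_spacings = {0,2,4,6}`) or
#'   `"results-spacings"` (`{0,2}`); explicit arguments win over the preset.
#' @return A `motif_config` list.
#' @export
motif_config <- function(pc_spacings = NULL,
                         amidation_spacings = c(1L, 3L),
                         known_motifs = c("KR", "RR", "KK", "RK",
                                          "KXXK", "KXXR", "RXXR", "RXXK"),
                         excluded_motifs = c("RK", "KXXK", "KXXR"),
                         max_basic_tail = 3L,
                         preset = c("methods-spacings", "results-spacings")) {
  preset <- match.arg(preset)
  if (is.null(pc_spacings)) {
    pc_spacings <- if (preset == "methods-spacings") c(0L, 2L, 4L, 6L)
                   else c(0L, 2L)
  }
  cfg <- list(
    pc_spacings = sort(unique(vapply(pc_spacings, assert_count_scalar,
                                     integer(1), name = "pc_spacings"))),
    amidation_spacings = sort(unique(vapply(amidation_spacings,
                                            assert_count_scalar, integer(1),
                                            name = "amidation_spacings"))),
    known_motifs = unique(as.character(known_motifs)),
    excluded_motifs = unique(as.character(excluded_motifs)),
    max_basic_tail = assert_count_scalar(max_basic_tail, "max_basic_tail"))
  bad <- grepl("[^KRX]", c(cfg$known_motifs, cfg$excluded_motifs))
  if (any(bad)) {
    abort(paste0("Motif patterns may only use K, R, X; offending: ",
                 paste(c(cfg$known_motifs, cfg$excluded_motifs)[bad],
                       collapse = ", ")))
  }
  structure(cfg, class = "motif_config")
}

#' @export
print.motif_config <- function(x, ...) {
  cat("<motif_config>\n")
  cat("  PC spacings:       ", paste(x$pc_spacings, collapse = ", "), "\n")
  cat("  amidation spacings:", paste(x$amidation_spacings, collapse = ", "), "\n")
  cat("  known motifs:      ", paste(x$known_motifs, collapse = ", "), "\n")
  cat("  excluded motifs:   ", paste(x$excluded_motifs, collapse = ", "), "\n")
  cat("  max basic tail:    ", x$max_basic_tail, "\n")
  invisible(x)
}

#' Read/write a motif configuration as YAML
#'
#' @param path YAML file.
#' @return [read_motif_config()] returns a `motif_config`;
#'   [write_motif_config()] returns `path` invisibly.
#' @export
read_motif_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- c("pc_spacings", "amidation_spacings", "known_motifs",
               "excluded_motifs", "max_basic_tail")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown)) {
    abort(paste0("Unknown motif_config key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(motif_config, vals)
}

#' @rdname read_motif_config
#' @param config a `motif_config`.
#' @export
write_motif_config <- function(config, path) {
  stopifnot(inherits(config, "motif_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# overlap-aware fixed-width regex scan of one sequence; returns integer starts
scan_starts <- function(sequence, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

# run a per-sequence site finder over the canonical protein tibble and flag
# matches overlapping the annotated signal peptide (when `signal_end` known);
# `empty` is the typed zero-row prototype returned when nothing matches
scan_proteins <- function(proteins, fun, empty) {
  proteins <- as_protein_tbl(proteins, allow_empty = TRUE)
  sig <- if ("signal_end" %in% names(proteins)) proteins$signal_end
         else rep(NA_integer_, nrow(proteins))
  res <- map2(proteins$sequence, proteins$protein_id, fun)
  out <- bind_rows(res)
  if (nrow(out) == 0) return(mutate(empty, in_signal = logical()))
  sig_map <- setNames(sig, proteins$protein_id)
  out$in_signal <- unname(!is.na(sig_map[out$protein_id]) &
                            out$start <= sig_map[out$protein_id])
  out
}

#' Find prohormone-convertase (paired/spaced basic) cleavage sites
#'
#' Matches (K/R)Xn(K/R) for every `n` in `config$pc_spacings`; X is any
#' residue (including K, R or G). All matches are reported, overlapping and
#' nested ones included; the cleavage point lies after the C-terminal basic
#' residue of the pair. When the input carries a `signal_end` column, matches
#' overlapping the signal peptide are flagged `in_signal`.
#'
#' @param proteins data frame with `protein_id` and `sequence` (optionally
#'   `signal_end`), or a character vector of sequences.
#' @param config a [motif_config()].
#' @return Tibble: `protein_id`, `site_class` (`"PC"`), `motif`, `start`,
#'   `end`, `cleavage_after`, `spacing`, and `in_signal` flag; sorted by
#'   (`end`, `start`) within protein.
#' @export
find_pc_sites <- function(proteins, config = motif_config()) {
  stopifnot(inherits(config, "motif_config"))
  scan_proteins(proteins, empty = mutate(empty_sites(), spacing = integer()),
                function(seq, id) {
    hits <- map(config$pc_spacings, function(n) {
      s <- scan_starts(seq, sprintf("[KR].{%d}[KR]", n))
      if (!length(s)) return(NULL)
      tibble(start = s, end = s + n + 1L, spacing = n)
    })
    out <- bind_rows(hits)
    if (nrow(out) == 0) return(NULL)
    out %>%
      arrange(.data$end, .data$start) %>%
      mutate(protein_id = id, site_class = "PC",
             motif = str_sub(seq, .data$start, .data$end),
             cleavage_after = .data$end) %>%
      select("protein_id", "site_class", "motif", "start", "end",
             "cleavage_after", "spacing")
  })
}

#' Find furin cleavage sites (RX(K/R)R)
#'
#' Furin operates at near-neutral pH (trans-Golgi/endocytic pathway), so its
#' consensus is screened separately from the PC grammar. Cleavage lies after
#' the final Arg of the motif.
#'
#' @inheritParams find_pc_sites
#' @return Site tibble as in [find_pc_sites()] with `site_class = "furin"`.
#' @export
find_furin_sites <- function(proteins) {
  scan_proteins(proteins, empty = empty_sites(), function(seq, id) {
    s <- scan_starts(seq, "R.[KR]R")
    if (!length(s)) return(NULL)
    tibble(protein_id = id, site_class = "furin",
           motif = str_sub(seq, s, s + 3L),
           start = s, end = s + 3L, cleavage_after = s + 3L)
  })
}

#' Find internal amidation-site motifs
#'
#' Three classes mark a Gly that can be exposed by cleavage plus
#' carboxypeptidase-B trimming and then consumed by the amidating enzyme:
#' * `G_KR_KR` — G(K/R)(K/R); the Gly opens the motif.
#' * `KR_XnG_KR` — (K/R)XnG(K/R) for `n` in `config$amidation_spacings`.
#' * `RG_KR_R` — RG(K/R)R, the amidatable furin special case.
#'
#' @inheritParams find_pc_sites
#' @return Tibble: `protein_id`, `site_class`, `gly_position`, `start`,
#'   `end`, plus `in_signal` when `signal_end` is available.
#' @export
find_amidation_sites <- function(proteins, config = motif_config()) {
  stopifnot(inherits(config, "motif_config"))
  scan_proteins(proteins, empty = empty_amidation(), function(seq, id) {
    g1 <- scan_starts(seq, "G[KR][KR]")
    out <- list(
      if (length(g1)) tibble(site_class = "G_KR_KR", gly_position = g1,
                             start = g1, end = g1 + 2L))
    out <- c(out, map(config$amidation_spacings, function(n) {
      s <- scan_starts(seq, sprintf("[KR].{%d}G[KR]", n))
      if (!length(s)) return(NULL)
      tibble(site_class = "KR_XnG_KR", gly_position = s + n + 1L,
             start = s, end = s + n + 2L)
    }))
    g3 <- scan_starts(seq, "RG[KR]R")
    out <- c(out, list(
      if (length(g3)) tibble(site_class = "RG_KR_R", gly_position = g3 + 1L,
                             start = g3, end = g3 + 3L)))
    res <- bind_rows(out)
    if (nrow(res) == 0) return(NULL)
    res %>%
      mutate(protein_id = id) %>%
      arrange(.data$end, .data$start) %>%
      select("protein_id", "site_class", "gly_position", "start", "end")
  })
}

#' Detect C-terminal amidation without prior endoproteolysis
#'
#' A protein ending in -Gly (`terminal_G`) or -Gly-(Lys/Arg)n with
#' `1 <= n <= config$max_basic_tail` (`terminal_G_basic_tail`) can be
#' amidated directly (the tail case after CPB-like trimming).
#'
#' @inheritParams find_pc_sites
#' @return Tibble with one row per protein that qualifies: `protein_id`,
#'   `site_class`, `gly_position`, `start`, `end` (the Gly plus any tail).
#' @export
find_terminal_amidation <- function(proteins, config = motif_config()) {
  stopifnot(inherits(config, "motif_config"))
  proteins <- as_protein_tbl(proteins)
  rows <- pmap(list(proteins$sequence, proteins$protein_id, proteins$length),
               function(seq, id, len) {
    if (str_sub(seq, len, len) == "G") {
      return(tibble(protein_id = id, site_class = "terminal_G",
                    gly_position = len, start = len, end = len))
    }
    tail <- sub("^.*?([KR]*)$", "\\1", seq)
    nt <- str_length(tail)
    if (nt >= 1L && nt <= config$max_basic_tail &&
        str_sub(seq, len - nt, len - nt) == "G") {
      return(tibble(protein_id = id, site_class = "terminal_G_basic_tail",
                    gly_position = len - nt, start = len - nt, end = len))
    }
    NULL
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(empty_amidation())
  out
}

# pattern over {K,R,X} -> regex with X as any residue
motif_to_regex <- function(pattern) gsub("X", ".", pattern, fixed = TRUE)

# does matched text fit an excluded pattern (same length, fixed chars equal)?
fits_excluded <- function(text, excluded) {
  if (!length(excluded)) return(rep(FALSE, length(text)))
  hits <- map(excluded, function(p)
    str_length(text) == str_length(p) &
      grepl(paste0("^", motif_to_regex(p), "$"), text))
  Reduce(`|`, hits)
}

#' Find cleavage sites from a user-supplied known-motif table
#'
#' Matches every pattern in `config$known_motifs` (strings over `{K, R, X}`,
#' X = any residue), then removes matches whose matched text fits a pattern
#' in `config$excluded_motifs`. Cleavage lies after the final residue of the
#' motif. This reproduces the "known motifs" mode of motif-table cleavage
#' predictors; no trained scoring model is involved.
#'
#' @inheritParams find_pc_sites
#' @return Site tibble with `site_class = "known_motif"` and a `pattern`
#'   column naming the motif that matched.
#' @export
find_known_motif_sites <- function(proteins, config = motif_config()) {
  stopifnot(inherits(config, "motif_config"))
  if (!length(config$known_motifs)) abort("known_motifs must be non-empty.")
  scan_proteins(proteins, empty = mutate(empty_sites(),
                                         pattern = character()),
                function(seq, id) {
    hits <- map(config$known_motifs, function(p) {
      s <- scan_starts(seq, motif_to_regex(p))
      if (!length(s)) return(NULL)
      tibble(start = s, end = s + str_length(p) - 1L, pattern = p)
    })
    out <- bind_rows(hits)
    if (nrow(out) == 0) return(NULL)
    out <- out %>%
      mutate(protein_id = id, site_class = "known_motif",
             motif = str_sub(seq, .data$start, .data$end),
             cleavage_after = .data$end) %>%
      filter(!fits_excluded(.data$motif, config$excluded_motifs))
    if (nrow(out) == 0) return(NULL)
    out %>%
      distinct(.data$protein_id, .data$start, .data$end, .keep_all = TRUE) %>%
      arrange(.data$end, .data$start) %>%
      select("protein_id", "site_class", "motif", "pattern", "start", "end",
             "cleavage_after")
  })
}

#' Export a site tibble to TSV
#'
#' @param sites site tibble from any finder.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  keep <- intersect(c("protein_id", "site_class", "motif", "pattern", "start",
                      "end", "cleavage_after", "gly_position", "in_signal"),
                    names(sites))
  readr::write_tsv(sites[keep], path, progress = FALSE)
  invisible(path)
}
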