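# Membrane-topology assignment from signal-peptide and TM-helix annotations.
# Helix *position* is deliberately ignored: a protein with its only helix
# near the C-terminus but no cleavable signal peptide is still Type II under
# this rule set, which reproduces published groupings of the S8 subtilisin
# family.

#' Classify membrane topology from signal and TM annotations
#'
#' Four mutually exclusive, exhaustive rules:
#' * signal peptide and no TM helix -> `secreted`
#' * signal peptide and >= 1 TM helix -> `type_I`
#' * no signal peptide and >= 1 TM helix -> `type_II`
#' * neither -> `other` (possibly cytosolic)
#'
#' @param signal_ann signal annotation tibble (`protein_id`, `has_signal`).
#' @param topology_ann topology annotation tibble (`protein_id`, `n_tm` or
#'   `tm_helices`).
#' @return Tibble: `protein_id`, `call` (factor with the four levels),
#'   `rationale`.
#' @export
classify_topology <- function(signal_ann, topology_ann) {
  if (!"n_tm" %in% names(topology_ann)) {
    topology_ann$n_tm <- map_int(topology_ann$tm_helices, nrow)
  }
  ids <- union(signal_ann$protein_id, topology_ann$protein_id)
  tibble(protein_id = ids) %>%
    left_join(select(signal_ann, "protein_id", "has_signal"),
              by = "protein_id") %>%
    left_join(select(topology_ann, "protein_id", "n_tm"),
              by = "protein_id") %>%
    mutate(has_signal = dplyr::coalesce(.data$has_signal, FALSE),
           n_tm = dplyr::coalesce(.data$n_tm, 0L),
           call = factor(case_when(
             .data$has_signal & .data$n_tm == 0L ~ "secreted",
             .data$has_signal & .data$n_tm >= 1L ~ "type_I",
             !.data$has_signal & .data$n_tm >= 1L ~ "type_II",
             TRUE ~ "other"),
             levels = c("secreted", "type_I", "type_II", "other")),
           rationale = case_when(
             .data$call == "secreted" ~ "signal peptide, no TM helix",
             .data$call == "type_I" ~ "signal peptide + TM helix",
             .data$call == "type_II" ~ "TM helix, no signal peptide",
             TRUE ~ "no signal peptide, no TM helix")) %>%
    select("protein_id", "call", "rationale")
}

#' Count topology calls
#'
#' @param calls tibble from [classify_topology()].
#' @return Tibble (`call`, `n`) covering all four classes (zero-filled);
#'   counts sum to the number of inputs.
#' @export
topology_census <- function(calls) {
  calls %>% count(.data$call, .drop = FALSE, name = "n")
}

#' Annotations for the 21 S8-peptidase-domain proteins of *C. reinhardtii*
#'
#' Packaged transcription of the published SMART-derived signal-peptide and
#' TM-helix annotations for the 21 S8 (subtilisin) domain proteins of the
#' *Chlamydomonas reinhardtii* genome — the worked example for the topology
#' classifier (7 secreted, 1 Type I, 6 Type II, 7 other).
#'
#' @return List with `signal` and `topology` annotation tibbles (21 rows
#'   each).
#' @export
s8_subtilisin_annotations <- function() {
  dir <- system.file("extdata", package = "secretopep")
  list(
    signal = read_annotation_table(
      file.path(dir, "s8_subtilisin_signal.tsv"), "signal"),
    topology = read_annotation_table(
      file.path(dir, "s8_subtilisin_topology.tsv"), "topology"))
}
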