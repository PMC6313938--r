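# End-to-end pipeline wrappers chaining the stages, each writing TSV outputs
# and a deterministic run manifest (config hash, input checksums, package
# version, seed) so reruns are bit-identical and traceable.

# accept a config as a list or a YAML file path
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  config
}

require_keys <- function(config, keys, stage) {
  miss <- setdiff(keys, names(config))
  if (length(miss)) {
    abort(paste0(stage, ": missing config key(s): ",
                 paste(miss, collapse = ", ")))
  }
}

motif_config_from <- function(config) {
  if (!is.null(config$motif_config_yaml)) {
    read_motif_config(config$motif_config_yaml)
  } else if (!is.null(config$motif)) {
    do.call(motif_config, config$motif)
  } else if (!is.null(config$preset)) {
    motif_config(preset = config$preset)
  } else {
    motif_config()
  }
}

write_manifest <- function(out_dir, stage, config, input_paths) {
  input_paths <- input_paths[!vapply(input_paths, is.null, logical(1))]
  checks <- map(input_paths, ~ unname(tools::md5sum(.x)))
  manifest <- list(stage = stage,
                   package = "secretopep",
                   version = as.character(utils::packageVersion("secretopep")),
                   seed = config$seed %||% NA,
                   config_hash = rlang::hash(config),
                   input_md5 = checks)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run the precursor-scan pipeline
#'
#' Chains FASTA + annotation input, soluble-secretory selection, motif
#' scanning and product enumeration. Config keys: `fasta`, `signal_tsv`,
#' `topology_tsv`, `out_dir`; optional `mode` (`"grammar"` default or
#' `"known_motifs"`), `preset`, `motif` (list of [motif_config()] args) or
#' `motif_config_yaml`, `seed`.
#'
#' Writes `sites_pc.tsv`, `sites_furin.tsv`, `sites_amidation.tsv`,
#' `peptides.tsv`, `summary.tsv`, `amide_histogram.tsv`, `manifest.json`.
#'
#' @param config list or YAML path.
#' @return The `proteome_summary`, invisibly.
#' @export
run_scan <- function(config) {
  config <- load_run_config(config)
  require_keys(config, c("fasta", "signal_tsv", "topology_tsv", "out_dir"),
               "run_scan")
  cfg <- motif_config_from(config)
  mode <- config$mode %||% "grammar"
  proteins <- read_fasta(config$fasta)
  sig <- read_annotation_table(config$signal_tsv, "signal")
  top <- read_annotation_table(config$topology_tsv, "topology")
  input_set <- select_secreted_soluble(proteins, sig, top)
  if (nrow(input_set) == 0L) {
    abort("run_scan: no signal(+)/TM(-) proteins in the input set.")
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_sites_tsv(find_pc_sites(input_set, cfg),
                  file.path(out, "sites_pc.tsv"))
  write_sites_tsv(find_furin_sites(input_set),
                  file.path(out, "sites_furin.tsv"))
  write_sites_tsv(find_amidation_sites(input_set, cfg),
                  file.path(out, "sites_amidation.tsv"))
  summary <- summarize_proteome(input_set, cfg, mode = mode)
  write_summary_tsvs(summary, out)
  write_manifest(out, "scan", config,
                 list(fasta = config$fasta, signal = config$signal_tsv,
                      topology = config$topology_tsv))
  invisible(summary)
}

#' Run the secretome merge pipeline
#'
#' Merges per-sample spectral-count tables, applies the presence filter and
#' normalization, and (when localization/signal tables are supplied) the
#' signal-peptide triage. Config keys: `samples` (named list/vector of
#' per-sample TSV paths), `out_dir`; optional `dataset_ids`, `min_presence`
#' (default 4), `normalize` (`"total"`/`"none"`), `localization_tsv`,
#' `signal_tsv`, `top_n` (default 30).
#'
#' Writes `merged.tsv`, `census.json`, `manifest.json`.
#'
#' @param config list or YAML path.
#' @return The merged tibble, invisibly.
#' @export
run_secretome <- function(config) {
  config <- load_run_config(config)
  require_keys(config, c("samples", "out_dir"), "run_secretome")
  paths <- unlist(config$samples)
  counts <- read_sample_counts(paths,
                               dataset_ids = config$dataset_ids %||% NA)
  merged <- merge_and_filter(counts,
                             min_presence = config$min_presence %||% 4L,
                             normalize = config$normalize %||% "total")
  if (!is.null(config$localization_tsv) && !is.null(config$signal_tsv)) {
    loc <- read_annotation_table(config$localization_tsv, "localization")
    sig <- read_annotation_table(config$signal_tsv, "signal")
    merged <- triage_signal_peptide(merged, loc, sig)
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  flat <- merged %>%
    mutate(norm_counts = map_chr(.data$norm_counts,
                                 ~ paste(signif(.x, 8), collapse = ";")))
  readr::write_tsv(flat, file.path(out, "merged.tsv"), progress = FALSE)
  census <- dataset_census(counts)
  top_n <- min(config$top_n %||% 30L, nrow(merged))
  share <- rank_and_share(merged, top_n)$share
  jsonlite::write_json(
    list(per_dataset = census$per_dataset, n_union = census$n_union,
         n_intersection = census$n_intersection,
         n_merged = nrow(merged),
         n_signal_peptide = if ("is_signal_peptide" %in% names(merged))
           sum(merged$is_signal_peptide) else NA,
         top_n = top_n, top_n_share = share),
    file.path(out, "census.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA)
  write_manifest(out, "secretome", config, as.list(paths))
  invisible(merged)
}

#' Run the gel-slice cleavage pipeline
#'
#' Config keys: `slices_tsv`, `evidence_tsv`, `proteins_tsv` (headerless
#' `protein_id  length  intact_mass_kda`), `out_dir`; optional
#' `domains_tsv`, `tolerance_fraction` (default 0.2), `min_counts`
#' (default 2), `terminal_fraction` (default 0.4).
#'
#' Writes `calls.tsv`, `manifest.json`.
#'
#' @param config list or YAML path.
#' @return The calls tibble, invisibly.
#' @export
run_slices <- function(config) {
  config <- load_run_config(config)
  require_keys(config, c("slices_tsv", "evidence_tsv", "proteins_tsv",
                         "out_dir"), "run_slices")
  slices <- read_slices_tsv(config$slices_tsv)
  evidence <- read_evidence_tsv(config$evidence_tsv)
  proteins <- readr::read_tsv(config$proteins_tsv,
                              col_names = c("protein_id", "length",
                                            "intact_mass_kda"),
                              col_types = "cid", progress = FALSE)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (nrow(evidence) == 0L) {
    calls <- tibble(protein_id = character(),
                    status = factor(character(),
                                    levels = c("intact", "cleaved",
                                               "ambiguous")))
    readr::write_tsv(calls, file.path(out, "calls.tsv"), progress = FALSE)
  } else {
    calls <- call_cleavage(
      evidence, slices, proteins,
      tolerance_fraction = config$tolerance_fraction %||% 0.2,
      min_counts = config$min_counts %||% 2L,
      terminal_fraction = config$terminal_fraction %||% 0.4)
    if (!is.null(config$domains_tsv)) {
      calls <- annotate_fragments_with_domains(
        calls, read_domains_tsv(config$domains_tsv))
    }
    write_calls_tsv(calls, file.path(out, "calls.tsv"))
  }
  write_manifest(out, "slices", config,
                 list(slices = config$slices_tsv,
                      evidence = config$evidence_tsv,
                      proteins = config$proteins_tsv,
                      domains = config$domains_tsv))
  invisible(calls)
}
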