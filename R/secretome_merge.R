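# Replicate merge for label-free spectral-count runs: equal-total
# normalization, the >= 4-of-6 presence filter, per-protein mean/SEM,
# ranking, and the localization/signal-peptide triage.

#' Read per-sample spectral-count tables
#'
#' Each file is a headerless TSV `protein_id <TAB> spectral_count` holding
#' one sample; absence of a protein is encoded by omission, so counts must be
#' strictly positive.
#'
#' @param paths named character vector of file paths; names are sample ids
#'   (e.g. `A`..`F`).
#' @param dataset_ids optional vector (recycled against `paths`) assigning
#'   each sample to a dataset (e.g. 1 or 2).
#' @return Long tibble: `sample_id`, `dataset_id`, `protein_id`, `count`.
#' @export
read_sample_counts <- function(paths, dataset_ids = NA) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    abort("`paths` must be a named vector; names are sample ids.")
  }
  dataset_ids <- rep_len(dataset_ids, length(paths))
  out <- imap(setNames(seq_along(paths), names(paths)), function(i, sid) {
    tab <- readr::read_tsv(paths[[i]], col_names = c("protein_id", "count"),
                           col_types = "ci", progress = FALSE)
    mutate(tab, sample_id = sid, dataset_id = dataset_ids[[i]],
           .before = 1)
  }) %>% bind_rows()
  validate_sample_counts(out)
}

validate_sample_counts <- function(counts) {
  need <- setdiff(c("sample_id", "protein_id", "count"), names(counts))
  if (length(need)) {
    abort(paste0("Count table missing column(s): ",
                 paste(need, collapse = ", ")))
  }
  if (any(is.na(counts$count)) || any(counts$count <= 0)) {
    abort("Spectral counts must be strictly positive (absence = omission).")
  }
  dup <- counts %>% count(.data$sample_id, .data$protein_id) %>%
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("Duplicate (sample, protein) rows, e.g. ",
                 dup$sample_id[1], "/", dup$protein_id[1]))
  }
  as_tibble(counts)
}

#' Scale samples to a common spectral-count total
#'
#' Each sample's counts are multiplied by (mean of per-sample totals) /
#' (that sample's total), so all samples end with the same total — the usual
#' equal-total ("normalized spectral count") scaling for label-free runs.
#' With `method = "none"` counts pass through unchanged.
#'
#' @param counts long tibble with `sample_id`, `protein_id`, `count`.
#' @param method `"total"` (default) or `"none"`.
#' @return Input with an added `norm_count` column.
#' @export
normalize_counts <- function(counts, method = c("total", "none")) {
  method <- match.arg(method)
  counts <- validate_sample_counts(counts)
  if (method == "none") return(mutate(counts, norm_count = as.numeric(.data$count)))
  totals <- counts %>% group_by(.data$sample_id) %>%
    summarise(total = sum(.data$count), .groups = "drop")
  if (any(totals$total <= 0)) abort("Sample with zero total count.")
  target <- mean(totals$total)
  counts %>%
    left_join(totals, by = "sample_id") %>%
    mutate(norm_count = .data$count * target / .data$total) %>%
    select(-"total")
}

#' Merge replicate samples and apply the presence filter
#'
#' Takes the union of protein ids over all samples, counts in how many
#' samples each protein appears (`presence`), and drops proteins seen in
#' fewer than `min_presence` samples. Per-protein statistics are computed
#' over *all* samples with absences contributing zero: `avg_total` is the
#' mean normalized count and `sem` the sample standard deviation (n - 1
#' denominator) divided by sqrt(n), n being the number of samples. Proteins
#' are ranked by descending `avg_total`, ties broken lexicographically by
#' id.
#'
#' @param counts long tibble (`sample_id`, `protein_id`, `count`).
#' @param min_presence minimum number of samples a protein must appear in
#'   (default 4, matching a six-sample design).
#' @param normalize `"total"` or `"none"`, passed to [normalize_counts()].
#' @return Tibble: `rank`, `protein_id`, `presence`, `avg_total`, `sem`,
#'   plus a `norm_counts` list column of per-sample values (named, absent
#'   samples as 0).
#' @export
merge_and_filter <- function(counts, min_presence = 4L,
                             normalize = c("total", "none")) {
  counts <- validate_sample_counts(counts)
  min_presence <- assert_count_scalar(min_presence, "min_presence", min = 0L)
  samples <- sort(unique(counts$sample_id))
  if (min_presence > length(samples)) {
    abort(paste0("min_presence (", min_presence, ") exceeds the number of ",
                 "samples (", length(samples), ")."))
  }
  normed <- normalize_counts(counts, match.arg(normalize))
  wide <- normed %>%
    select("sample_id", "protein_id", "norm_count") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "norm_count",
                       values_fill = 0)
  mat <- as.matrix(wide[samples])
  n <- length(samples)
  out <- tibble(
    protein_id = wide$protein_id,
    presence = as.integer(rowSums(mat > 0)),
    avg_total = rowMeans(mat),
    sem = apply(mat, 1, sd) / sqrt(n),
    norm_counts = map(seq_len(nrow(mat)), ~ setNames(mat[.x, ], samples))) %>%
    filter(.data$presence >= min_presence) %>%
    arrange(desc(.data$avg_total), .data$protein_id) %>%
    mutate(rank = row_number(), .before = 1)
  out
}

#' Flag signal-peptide-containing proteins in a merged dataset
#'
#' The triage rule: a protein counts as signal-peptide-containing when its
#' predicted localization is `SP` (secretory pathway), or when it is
#' localized `O` (other) or `NA` (not assigned) but carries a predicted
#' signal peptide. Organelle-localized proteins (`C`, `M`) are excluded even
#' if a signal peptide is predicted. Ids missing from either map default to
#' category `NA` / no signal and are reported.
#'
#' @param merged tibble from [merge_and_filter()].
#' @param localization_ann localization annotation tibble (`protein_id`,
#'   `category`).
#' @param signal_ann signal annotation tibble (`protein_id`, `has_signal`).
#' @return `merged` with added `category`, `has_signal`,
#'   `is_signal_peptide`.
#' @export
triage_signal_peptide <- function(merged, localization_ann, signal_ann) {
  missing_ids <- setdiff(merged$protein_id,
                         union(localization_ann$protein_id,
                               signal_ann$protein_id))
  if (length(missing_ids)) {
    inform(paste0(length(missing_ids), " merged protein(s) lacked ",
                  "localization/signal annotation; treated as NA / no ",
                  "signal."))
  }
  merged %>%
    left_join(select(localization_ann, "protein_id", "category"),
              by = "protein_id") %>%
    left_join(select(signal_ann, "protein_id", "has_signal"),
              by = "protein_id") %>%
    mutate(category = dplyr::coalesce(.data$category, "NA"),
           has_signal = dplyr::coalesce(.data$has_signal, FALSE),
           is_signal_peptide = .data$category == "SP" |
             (.data$category %in% c("O", "NA") & .data$has_signal))
}

#' Top-n proteins and their share of total spectral counts
#'
#' @param merged tibble from [merge_and_filter()] (must carry `avg_total`).
#' @param n how many top proteins to take (by descending `avg_total`, ties
#'   by id).
#' @return List with `top` (the n highest-ranked rows) and `share` (their
#'   summed `avg_total` over the grand total, in `[0, 1]`).
#' @export
rank_and_share <- function(merged, n) {
  n <- assert_count_scalar(n, "n", min = 1L)
  if (n > nrow(merged)) abort("`n` exceeds the number of proteins.")
  ranked <- arrange(merged, desc(.data$avg_total), .data$protein_id)
  top <- slice_head(ranked, n = n)
  list(top = top,
       share = sum(top$avg_total) / sum(ranked$avg_total))
}

#' Per-dataset identification census
#'
#' Reports how many distinct proteins each dataset identified, plus the
#' union and intersection across datasets — published per-dataset and
#' combined totals are not always mutually consistent, so all three views
#' are returned rather than a single "combined" number.
#'
#' @param counts long tibble with `dataset_id`, `protein_id`.
#' @return List: `per_dataset` tibble (`dataset_id`, `n_proteins`),
#'   `n_union`, `n_intersection`.
#' @export
dataset_census <- function(counts) {
  stopifnot(all(c("dataset_id", "protein_id") %in% names(counts)))
  per <- counts %>% group_by(.data$dataset_id) %>%
    summarise(n_proteins = n_distinct(.data$protein_id), .groups = "drop")
  sets <- split(counts$protein_id, counts$dataset_id) %>% map(unique)
  list(per_dataset = per,
       n_union = length(Reduce(union, sets)),
       n_intersection = length(Reduce(intersect, sets)))
}

#' Plot the merged-secretome abundance ranking
#'
#' @param merged tibble from [merge_and_filter()].
#' @param n how many top proteins to show (default 30).
#' @return A ggplot of mean normalized total spectral counts with SEM bars.
#' @export
plot_secretome_ranks <- function(merged, n = 30L) {
  top <- rank_and_share(merged, min(n, nrow(merged)))$top
  ggplot(top, aes(x = stats::reorder(.data$protein_id, .data$avg_total),
                  y = .data$avg_total)) +
    geom_col(fill = "grey40") +
    geom_segment(aes(xend = stats::reorder(.data$protein_id, .data$avg_total),
                     y = .data$avg_total - .data$sem,
                     yend = .data$avg_total + .data$sem)) +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "mean normalized total spectral counts") +
    theme_minimal()
}
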