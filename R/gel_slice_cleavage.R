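# Intact-vs-cleaved inference from SDS-PAGE gel-slice-resolved tryptic
# peptides: a protein whose peptides show up in gel slices well below its
# intact mass has been endoproteolytically processed into stable fragments;
# one seen only at or above its intact mass migrated whole.

#' Read gel-slice definitions, slice evidence, or a domain table
#'
#' Headerless TSV layouts:
#' * slices: `slice_index <TAB> mass_low_kda <TAB> mass_high_kda`
#' * evidence: `protein_id <TAB> slice_index <TAB> peptide_start <TAB>
#'   peptide_end <TAB> spectral_count`
#' * domains: `protein_id <TAB> domain_name <TAB> start <TAB> end`
#'
#' @param path file path.
#' @return A validated tibble of the corresponding layout.
#' @export
read_slices_tsv <- function(path) {
  tab <- readr::read_tsv(path, col_names = c("slice_index", "mass_low",
                                             "mass_high"),
                         col_types = "idd", progress = FALSE)
  validate_slices(tab)
}

#' @rdname read_slices_tsv
#' @export
read_evidence_tsv <- function(path) {
  readr::read_tsv(path, col_names = c("protein_id", "slice_index",
                                      "peptide_start", "peptide_end",
                                      "spectral_count"),
                  col_types = "ciiii", progress = FALSE)
}

#' @rdname read_slices_tsv
#' @export
read_domains_tsv <- function(path) {
  readr::read_tsv(path, col_names = c("protein_id", "domain_name",
                                      "start", "end"),
                  col_types = "ccii", progress = FALSE)
}

validate_slices <- function(slices) {
  stopifnot(all(c("slice_index", "mass_low", "mass_high") %in% names(slices)))
  if (nrow(slices) == 0) abort("Empty gel-slice table.")
  if (any(slices$mass_low <= 0) || any(slices$mass_high <= slices$mass_low)) {
    abort("Slices require 0 < mass_low < mass_high.")
  }
  slices <- arrange(slices, .data$mass_low)
  if (nrow(slices) > 1 &&
      any(slices$mass_low[-1] < slices$mass_high[-nrow(slices)])) {
    abort("Gel slices overlap.")
  }
  as_tibble(slices)
}

#' Locate the gel slice containing a protein's intact mass
#'
#' Slices are half-open `[mass_low, mass_high)`, so a mass exactly on a
#' boundary lands in the higher slice. A mass outside the union of ranges is
#' assigned the nearest boundary slice and flagged.
#'
#' @param intact_mass_kda numeric vector of intact masses (kDa).
#' @param slices slice tibble (see [read_slices_tsv()]).
#' @return Tibble: `intact_mass_kda`, `slice_index`, `flagged` (out of
#'   range).
#' @export
locate_intact_slice <- function(intact_mass_kda, slices) {
  slices <- validate_slices(slices)
  rows <- map(intact_mass_kda, function(m) {
    hit <- which(m >= slices$mass_low & m < slices$mass_high)
    if (length(hit) == 1L) {
      return(tibble(intact_mass_kda = m,
                    slice_index = slices$slice_index[hit], flagged = FALSE))
    }
    idx <- if (m >= slices$mass_high[nrow(slices)]) nrow(slices)
           else if (m < slices$mass_low[1]) 1L
           else which.max(slices$mass_low > m)  # gap between slices
    tibble(intact_mass_kda = m, slice_index = slices$slice_index[idx],
           flagged = TRUE)
  })
  out <- bind_rows(rows)
  if (any(out$flagged)) {
    inform(paste0(sum(out$flagged), " intact mass(es) outside the slice ",
                  "ranges assigned to a boundary slice."))
  }
  out
}

# merge overlapping/adjacent residue spans into maximal runs
merge_spans <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1L) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  tibble(start = c(out_s, ms), end = c(out_e, me))
}

#' Call intact vs cleaved from gel-slice peptide evidence
#'
#' Evidence slices whose upper mass bound falls below
#' `(1 - tolerance_fraction) * intact_mass` are "sub-intact". A protein is
#' called:
#' * `cleaved` when sub-intact slices carry at least `min_counts` summed
#'   spectral counts; fragment regions are the merged peptide-span runs in
#'   those slices, labeled `N_terminal` if the run lies within the first
#'   `terminal_fraction` of the protein, `C_terminal` if within the last
#'   `terminal_fraction`, else `internal`.
#' * `intact` when every evidence slice sits at or above the slice holding
#'   the intact mass.
#' * `ambiguous` otherwise (e.g. evidence just below the intact slice but
#'   within the migration tolerance, or too few sub-intact counts).
#'
#' The mass tolerance absorbs the imprecision of gel migration; raising it
#' never converts an intact call into a cleaved one.
#'
#' @param evidence evidence tibble (`protein_id`, `slice_index`,
#'   `peptide_start`, `peptide_end`, `spectral_count`).
#' @param slices slice tibble.
#' @param proteins tibble with `protein_id`, `length` and `intact_mass_kda`
#'   (use [mass_from_sequence()] for an approximate mass when no annotated
#'   mass is available).
#' @param tolerance_fraction fraction of intact mass below which a slice
#'   counts as sub-intact (default 0.2).
#' @param min_counts minimum summed spectral counts in sub-intact slices to
#'   call cleavage (default 2; guards against single stray PSMs).
#' @param terminal_fraction protein-length fraction defining the N-/C-
#'   terminal zones (default 0.4).
#' @return Tibble: `protein_id`, `status` (factor intact/cleaved/ambiguous),
#'   `intact_slice`, `evidence_slices` (list), `sub_intact_counts`,
#'   `fragments` (list column of `region`/`start`/`end` tibbles).
#' @export
call_cleavage <- function(evidence, slices, proteins,
                          tolerance_fraction = 0.2, min_counts = 2L,
                          terminal_fraction = 0.4) {
  slices <- validate_slices(slices)
  stopifnot(all(c("protein_id", "length", "intact_mass_kda") %in%
                  names(proteins)))
  bad_slice <- setdiff(evidence$slice_index, slices$slice_index)
  if (length(bad_slice)) {
    abort(paste0("Evidence references unknown slice index: ",
                 paste(bad_slice, collapse = ", ")))
  }
  no_ev <- setdiff(proteins$protein_id, evidence$protein_id)
  if (length(no_ev)) {
    abort(paste0("No slice evidence for: ",
                 paste(head(no_ev, 5), collapse = ", ")))
  }
  # slice order by mass; intact slice per protein
  slices <- mutate(slices, .mass_rank = row_number())
  intact <- locate_intact_slice(proteins$intact_mass_kda, slices)
  prot <- proteins %>%
    mutate(intact_slice = intact$slice_index,
           intact_rank = slices$.mass_rank[match(intact$slice_index,
                                                 slices$slice_index)])
  rows <- pmap(list(prot$protein_id, prot$length, prot$intact_mass_kda,
                    prot$intact_slice, prot$intact_rank),
               function(id, len, mass, intact_slice, intact_rank) {
    ev <- evidence[evidence$protein_id == id, ]
    ev_rank <- slices$.mass_rank[match(ev$slice_index, slices$slice_index)]
    ev_high <- slices$mass_high[match(ev$slice_index, slices$slice_index)]
    sub <- ev_high < (1 - tolerance_fraction) * mass
    sub_counts <- sum(ev$spectral_count[sub])
    if (sub_counts >= min_counts) {
      # one candidate region per sub-intact slice: the hull of its peptide
      # spans (the region the tryptic peptides came from); overlapping
      # hulls from neighbouring slices merge
      hulls <- ev[sub, ] %>%
        group_by(.data$slice_index) %>%
        summarise(start = min(.data$peptide_start),
                  end = max(.data$peptide_end), .groups = "drop")
      spans <- merge_spans(hulls$start, hulls$end)
      frags <- spans %>%
        mutate(region = case_when(
          .data$end <= terminal_fraction * len ~ "N_terminal",
          .data$start >= (1 - terminal_fraction) * len ~ "C_terminal",
          TRUE ~ "internal")) %>%
        select("region", "start", "end")
      status <- "cleaved"
    } else if (all(ev_rank >= intact_rank)) {
      frags <- tibble(region = character(), start = integer(),
                      end = integer())
      status <- "intact"
    } else {
      frags <- tibble(region = character(), start = integer(),
                      end = integer())
      status <- "ambiguous"
    }
    tibble(protein_id = id, status = status, intact_slice = intact_slice,
           evidence_slices = list(sort(unique(ev$slice_index))),
           sub_intact_counts = sub_counts, fragments = list(frags))
  })
  bind_rows(rows) %>%
    mutate(status = factor(.data$status,
                           levels = c("intact", "cleaved", "ambiguous")))
}

#' Label fragment regions with overlapping domains
#'
#' A fragment is labeled with every domain whose span it overlaps by at
#' least `min_overlap` of the domain's length.
#'
#' @param calls tibble from [call_cleavage()].
#' @param domain_table tibble (`protein_id`, `domain_name`, `start`, `end`).
#' @param min_overlap minimum fraction of the domain covered (default 0.5).
#' @return `calls` with each `fragments` tibble gaining a `domains` column
#'   (semicolon-separated names, `""` when none).
#' @export
annotate_fragments_with_domains <- function(calls, domain_table,
                                            min_overlap = 0.5) {
  stopifnot(all(c("protein_id", "domain_name", "start", "end") %in%
                  names(domain_table)))
  calls %>%
    mutate(fragments = map2(.data$fragments, .data$protein_id,
                            function(fr, id) {
      if (nrow(fr) == 0) {
        fr$domains <- character(0)
        return(fr)
      }
      doms <- domain_table[domain_table$protein_id == id, ]
      fr$domains <- map_chr(seq_len(nrow(fr)), function(i) {
        if (nrow(doms) == 0) return("")
        ov <- pmin(fr$end[i], doms$end) - pmax(fr$start[i], doms$start) + 1L
        hit <- ov >= min_overlap * (doms$end - doms$start + 1L)
        paste(doms$domain_name[hit], collapse = ";")
      })
      fr
    }))
}

#' Approximate protein mass from sequence (kDa)
#'
#' Sum of average residue masses plus one water; `X` contributes the mean
#' residue mass. This is an approximation (no PTMs, no glycosylation) and is
#' offered only as a fallback when no annotated intact mass is available —
#' heavily glycosylated secretome proteins migrate far from this value.
#'
#' @param sequence character vector of amino-acid sequences.
#' @return Numeric vector of masses in kDa.
#' @export
mass_from_sequence <- function(sequence) {
  avg <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
           C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
           H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
           M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
           T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  avg <- c(avg, X = mean(avg))
  map_dbl(normalize_sequence(sequence), function(s) {
    res <- str_split(s, "")[[1]]
    (sum(avg[res], na.rm = TRUE) + 18.0153) / 1000
  })
}

#' Write cleavage calls to TSV (fragments flattened)
#'
#' @param calls tibble from [call_cleavage()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  flat <- calls %>%
    mutate(evidence_slices = map_chr(.data$evidence_slices,
                                     paste, collapse = ";"),
           fragments = map_chr(.data$fragments, function(fr) {
             if (nrow(fr) == 0) return("-")
             paste(paste0(fr$region, ":", fr$start, "-", fr$end,
                          if ("domains" %in% names(fr))
                            ifelse(fr$domains == "", "",
                                   paste0("[", fr$domains, "]")) else ""),
                   collapse = ";")
           }))
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}

#' Plot gel-slice evidence against intact mass
#'
#' One panel per protein: spectral counts per slice (by slice mass
#' midpoint), with the intact-mass slice marked.
#'
#' @param evidence evidence tibble.
#' @param slices slice tibble.
#' @param proteins tibble with `protein_id`, `intact_mass_kda`.
#' @return A ggplot.
#' @export
plot_slice_evidence <- function(evidence, slices, proteins) {
  slices <- validate_slices(slices)
  dat <- evidence %>%
    group_by(.data$protein_id, .data$slice_index) %>%
    summarise(counts = sum(.data$spectral_count), .groups = "drop") %>%
    left_join(slices, by = "slice_index") %>%
    mutate(mid = (.data$mass_low + .data$mass_high) / 2)
  ggplot(dat, aes(x = .data$mid, y = .data$counts)) +
    geom_col(width = 2, fill = "grey35") +
    ggplot2::geom_vline(data = proteins,
                        aes(xintercept = .data$intact_mass_kda),
                        linetype = "dashed") +
    facet_wrap(~protein_id, scales = "free_y") +
    labs(x = "slice mass (kDa)", y = "spectral counts") +
    theme_minimal()
}
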