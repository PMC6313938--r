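# Proteome input: FASTA plus per-protein annotation tables (signal peptide,
# TM helices, predicted localization), and the signal(+)/TM(-) input-set
# selection used throughout the scan stage.

#' Read a protein FASTA file
#'
#' Headers are split on whitespace: the first token is the `protein_id`, the
#' remainder the `description`. Sequences are upper-cased and trailing stop
#' symbols (`*`) stripped. Entry order is preserved.
#'
#' @param path path to a protein FASTA file.
#' @return Tibble with columns `protein_id`, `description`, `sequence`,
#'   `length`.
#' @export
read_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) abort(paste0("No FASTA entries in ", path))
  headers <- names(aas)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- normalize_sequence(as.character(aas))
  if (any(seqs == "")) {
    abort(paste0("Empty sequence for FASTA entr",
                 if (sum(seqs == "") > 1) "ies: " else "y: ",
                 paste(ids[seqs == ""], collapse = ", ")))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(paste0("Duplicate protein_id in FASTA: ",
                 paste(dup, collapse = ", ")))
  }
  tibble(protein_id = ids, description = desc, sequence = seqs,
         length = str_length(seqs))
}

#' Write protein records to FASTA
#'
#' Round-trips with [read_fasta()]: ids and sequences are reproduced exactly.
#'
#' @param proteins tibble with `protein_id`, `sequence` and optionally
#'   `description`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  proteins <- as_protein_tbl(proteins)
  hdr <- proteins$protein_id
  if (!is.null(proteins$description)) {
    has_desc <- !is.na(proteins$description) & proteins$description != ""
    hdr[has_desc] <- paste(hdr[has_desc], proteins$description[has_desc])
  }
  aas <- Biostrings::AAStringSet(setNames(proteins$sequence, hdr))
  Biostrings::writeXStringSet(aas, path, width = 70L)
  invisible(path)
}

#' Read a per-protein annotation table
#'
#' Headerless tab-separated files, one row per protein:
#' \describe{
#'   \item{signal}{`protein_id <TAB> Y/N <TAB> signal_end` (`-` when absent).
#'     `signal_end` is the 1-based index of the last signal-peptide residue.}
#'   \item{topology}{`protein_id <TAB> spans`, spans being
#'     semicolon-separated `start-end` pairs (1-based inclusive) or `-` for
#'     none.}
#'   \item{localization}{`protein_id <TAB> category`, category one of
#'     `C`, `M`, `SP`, `O`, `NA`.}
#' }
#' Unparseable rows are dropped with a warning naming their row numbers;
#' annotations for proteins absent from a proteome are allowed (tables may be
#' supersets).
#'
#' @param path path to the TSV.
#' @param kind one of `"signal"`, `"topology"`, `"localization"`.
#' @return Tibble keyed by `protein_id`; see Details per kind. Topology rows
#'   carry `tm_helices` (list column of `start`/`end` tibbles) and `n_tm`.
#' @export
read_annotation_table <- function(path,
                                  kind = c("signal", "topology",
                                           "localization")) {
  kind <- match.arg(kind)
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()), na = character(), progress = FALSE)
  n_need <- if (kind == "signal") 3L else 2L
  if (ncol(raw) < n_need) {
    abort(paste0("Annotation table ", path, " (kind=", kind, ") needs ",
                 n_need, " columns, found ", ncol(raw), "."))
  }
  parse_annotation_rows(raw, kind, source = path)
}

# shared row-level parser so generated tables can bypass disk
parse_annotation_rows <- function(raw, kind, source = "<data>") {
  bad <- integer()
  out <- switch(kind,
    signal = {
      yn <- str_to_upper(raw[[2]])
      end <- suppressWarnings(as.integer(raw[[3]]))
      ok_yes <- yn == "Y" & !is.na(end) & end >= 1L
      ok_no <- yn == "N"
      bad <- which(!(ok_yes | ok_no))
      tibble(protein_id = raw[[1]],
             has_signal = yn == "Y",
             signal_end = if_else(yn == "Y", end, NA_integer_))[
               ok_yes | ok_no, ]
    },
    topology = {
      spans <- map(raw[[2]], parse_spans)
      bad <- which(map_lgl(spans, is.null))
      keep <- !map_lgl(spans, is.null)
      tibble(protein_id = raw[[1]][keep],
             tm_helices = spans[keep],
             n_tm = map_int(spans[keep], nrow))
    },
    localization = {
      cat <- str_to_upper(raw[[2]])
      ok <- cat %in% c("C", "M", "SP", "O", "NA")
      bad <- which(!ok)
      tibble(protein_id = raw[[1]][ok], category = cat[ok])
    })
  if (length(bad)) {
    warn(paste0("Dropped ", length(bad), " unparseable ", kind,
                " row(s) in ", source, ": ",
                paste(head(bad, 10), collapse = ", ")))
  }
  dup <- unique(out$protein_id[duplicated(out$protein_id)])
  if (length(dup)) {
    abort(paste0("Duplicate protein_id in ", kind, " table: ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  out
}

# "37-59;100-122" -> tibble(start, end); "-" or "" -> zero-row tibble;
# malformed -> NULL (row rejected)
parse_spans <- function(txt) {
  if (is.na(txt)) return(NULL)
  txt <- gsub("–", "-", trimws(txt))  # en dash tolerated
  if (txt %in% c("-", "", "no", "NO", "No")) {
    return(tibble(start = integer(), end = integer()))
  }
  parts <- str_split(txt, ";")[[1]]
  m <- regmatches(parts, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", parts))
  if (any(lengths(m) != 3L)) return(NULL)
  start <- as.integer(map_chr(m, 2))
  end <- as.integer(map_chr(m, 3))
  if (any(start > end)) return(NULL)
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (any(start[-1] <= end[-length(end)])) return(NULL)  # overlap
  tibble(start = start, end = end)
}

#' Convert SignalP 4.1 short-format output to the signal annotation tibble
#'
#' Parses the whitespace-delimited short output (comment lines starting `#`
#' ignored): column 10 is the Y/N decision and the Ymax position (column 5)
#' marks the first mature residue, so `signal_end = ymax_pos - 1`.
#'
#' @param path SignalP 4.1 short-format file.
#' @return Signal annotation tibble as from
#'   `read_annotation_table(kind = "signal")`.
#' @export
read_signalp_short <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) {
    return(tibble(protein_id = character(), has_signal = logical(),
                  signal_end = integer()))
  }
  fields <- str_split(trimws(lines), "\\s+")
  if (any(lengths(fields) < 10L)) {
    abort("SignalP short format requires >= 10 whitespace-separated columns.")
  }
  tibble(
    protein_id = map_chr(fields, 1),
    has_signal = map_chr(fields, 10) == "Y",
    signal_end = if_else(map_chr(fields, 10) == "Y",
                         as.integer(map_chr(fields, 5)) - 1L, NA_integer_))
}

#' Convert TMHMM 2.0 long-format output to the topology annotation tibble
#'
#' Keeps the `TMhelix` rows (`id  TMHMM2.0  TMhelix  start  end`); proteins
#' appearing only in comment/inside/outside rows get zero helices.
#'
#' @param path TMHMM 2.0 long-format file.
#' @return Topology annotation tibble with `tm_helices` list column and
#'   `n_tm`.
#' @export
read_tmhmm_long <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  ids <- unique(c(
    sub("^#\\s*(\\S+).*$", "\\1", lines[grepl("^#\\s*\\S+\\s+Length", lines)]),
    map_chr(str_split(lines[!grepl("^\\s*(#|$)", lines)], "\\s+"), 1)))
  hel <- lines[grepl("\\bTMhelix\\b", lines)]
  hel_f <- str_split(trimws(hel), "\\s+")
  hel_tbl <- tibble(protein_id = map_chr(hel_f, 1),
                    start = as.integer(map_chr(hel_f, 4)),
                    end = as.integer(map_chr(hel_f, 5)))
  tibble(protein_id = ids) %>%
    mutate(tm_helices = map(.data$protein_id, function(id) {
      h <- hel_tbl[hel_tbl$protein_id == id, c("start", "end")]
      arrange(h, .data$start)
    }),
    n_tm = map_int(.data$tm_helices, nrow))
}

#' Write an annotation tibble back to its TSV form
#'
#' Inverse of [read_annotation_table()]; useful for exporting converted
#' SignalP/TMHMM annotations.
#'
#' @param ann annotation tibble (signal, topology or localization layout).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(ann, path) {
  out <- if ("has_signal" %in% names(ann)) {
    tibble(ann$protein_id,
           if_else(ann$has_signal, "Y", "N"),
           if_else(ann$has_signal, as.character(ann$signal_end), "-"))
  } else if ("tm_helices" %in% names(ann)) {
    tibble(ann$protein_id,
           map_chr(ann$tm_helices, function(h) {
             if (nrow(h) == 0) "-" else
               paste(paste0(h$start, "-", h$end), collapse = ";")
           }))
  } else if ("category" %in% names(ann)) {
    tibble(ann$protein_id, ann$category)
  } else {
    abort("Unrecognized annotation tibble layout.")
  }
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Select signal-peptide-positive, membrane-helix-free proteins
#'
#' The soluble-secretory input set for motif scanning: proteins with a
#' predicted signal peptide and no transmembrane helices. Proteins lacking a
#' row in either annotation table default to "no signal" / "no helices"
#' (prediction tools routinely omit negatives); defaulted ids are reported
#' via a message.
#'
#' @param proteins protein tibble from [read_fasta()] (or any data frame with
#'   `protein_id`, `sequence`).
#' @param signal_ann signal annotation tibble.
#' @param topology_ann topology annotation tibble.
#' @return The subset of `proteins` that is signal(+) and TM-helix-free, with
#'   `signal_end` joined on.
#' @export
select_secreted_soluble <- function(proteins, signal_ann, topology_ann) {
  proteins <- as_protein_tbl(proteins)
  miss_sig <- setdiff(proteins$protein_id, signal_ann$protein_id)
  miss_top <- setdiff(proteins$protein_id, topology_ann$protein_id)
  n_default <- length(union(miss_sig, miss_top))
  if (n_default) {
    inform(paste0(n_default, " protein(s) lacked an annotation row and were ",
                  "treated as not secreted / helix-free, e.g. ",
                  paste(head(union(miss_sig, miss_top), 5), collapse = ", ")))
  }
  out <- proteins %>%
    select(-dplyr::any_of(c("has_signal", "signal_end", "n_tm"))) %>%
    left_join(select(signal_ann, "protein_id", "has_signal", "signal_end"),
              by = "protein_id") %>%
    left_join(select(topology_ann, "protein_id", "n_tm"), by = "protein_id") %>%
    mutate(has_signal = dplyr::coalesce(.data$has_signal, FALSE),
           n_tm = dplyr::coalesce(.data$n_tm, 0L)) %>%
    filter(.data$has_signal, .data$n_tm == 0L) %>%
    select(-"has_signal", -"n_tm")
  bad <- !is.na(out$signal_end) & out$signal_end >= out$length
  if (any(bad)) {
    abort(paste0("signal_end >= sequence length for: ",
                 paste(out$protein_id[bad], collapse = ", ")))
  }
  out
}
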