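# shared input coercion and small validators

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Coerce protein input to the canonical protein tibble
#'
#' Accepts either a data frame with at least `protein_id` and `sequence`
#' columns, or a character vector of sequences (names become ids; unnamed
#' vectors get `seq1`, `seq2`, ...). Sequences are upper-cased and trailing
#' stop symbols (`*`) stripped, matching [read_fasta()].
#'
#' @param x data frame or character vector of amino-acid sequences.
#' @param allow_empty keep zero-length sequences instead of erroring
#'   (scanners treat them as having no sites).
#' @return A tibble with columns `protein_id`, `sequence`, `length` (other
#'   columns of a data-frame input are preserved).
#' @export
as_protein_tbl <- function(x, allow_empty = FALSE) {
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    ids[ids == ""] <- paste0("seq", which(ids == ""))
    x <- tibble(protein_id = ids, sequence = unname(x))
  }
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame or a character vector of sequences.")
  }
  need <- setdiff(c("protein_id", "sequence"), names(x))
  if (length(need)) {
    abort(paste0("Missing required column(s): ", paste(need, collapse = ", ")))
  }
  out <- as_tibble(x)
  out$sequence <- normalize_sequence(out$sequence)
  if (!allow_empty && any(out$sequence == "")) {
    abort(paste0("Empty sequence for: ",
                 paste(out$protein_id[out$sequence == ""], collapse = ", ")))
  }
  dup <- unique(out$protein_id[duplicated(out$protein_id)])
  if (length(dup)) {
    abort(paste0("Duplicate protein_id: ", paste(dup, collapse = ", ")))
  }
  out$length <- str_length(out$sequence)
  out
}

# uppercase and strip trailing stop symbols; internal "*" is rejected later by
# motif scans simply never matching it
normalize_sequence <- function(x) {
  str_remove(str_to_upper(x), "\\*+$")
}

# positive scalar integer check
assert_count_scalar <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != trunc(x)) {
    abort(paste0("`", name, "` must be a single integer >= ", min, "."))
  }
  as.integer(x)
}

# empty site tibble with canonical columns
empty_sites <- function() {
  tibble(protein_id = character(), site_class = character(),
         motif = character(), start = integer(), end = integer(),
         cleavage_after = integer())
}

empty_amidation <- function() {
  tibble(protein_id = character(), site_class = character(),
         gly_position = integer(), start = integer(), end = integer())
}
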