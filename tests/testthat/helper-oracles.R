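# Independent brute-force matchers used as oracles for the motif finders.
# They enumerate candidate positions directly (double loop over index pairs
# for PC sites; position-by-position substring checks otherwise) and share
# no code with the package's regex-based scanners.

oracle_pc_sites <- function(sequence, spacings) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  if (L < 2) return(data.frame(start = integer(), end = integer()))
  pairs <- expand.grid(i = seq_len(L), j = seq_len(L))
  pairs <- pairs[pairs$j > pairs$i, ]
  keep <- chars[pairs$i] %in% c("K", "R") &
    chars[pairs$j] %in% c("K", "R") &
    (pairs$j - pairs$i - 1L) %in% spacings
  hit <- pairs[keep, ]
  hit <- hit[order(hit$j, hit$i), ]
  data.frame(start = hit$i, end = hit$j)
}

oracle_furin_sites <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  starts <- integer()
  for (i in seq_len(max(L - 3L, 0L))) {
    if (chars[i] == "R" && chars[i + 2L] %in% c("K", "R") &&
        chars[i + 3L] == "R") {
      starts <- c(starts, i)
    }
  }
  starts
}

oracle_amidation_sites <- function(sequence, spacings) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  basic <- function(x) x %in% c("K", "R")
  out <- list()
  for (i in seq_len(L)) {
    if (i + 2L <= L && chars[i] == "G" && basic(chars[i + 1L]) &&
        basic(chars[i + 2L])) {
      out[[length(out) + 1L]] <- data.frame(
        site_class = "G_KR_KR", gly_position = i, start = i, end = i + 2L)
    }
    for (n in spacings) {
      if (i + n + 2L <= L && basic(chars[i]) && chars[i + n + 1L] == "G" &&
          basic(chars[i + n + 2L])) {
        out[[length(out) + 1L]] <- data.frame(
          site_class = "KR_XnG_KR", gly_position = i + n + 1L,
          start = i, end = i + n + 2L)
      }
    }
    if (i + 3L <= L && chars[i] == "R" && chars[i + 1L] == "G" &&
        basic(chars[i + 2L]) && chars[i + 3L] == "R") {
      out[[length(out) + 1L]] <- data.frame(
        site_class = "RG_KR_R", gly_position = i + 1L, start = i,
        end = i + 3L)
    }
  }
  if (!length(out)) {
    return(data.frame(site_class = character(), gly_position = integer(),
                      start = integer(), end = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$end, res$start, res$site_class), ]
}

oracle_known_motifs <- function(sequence, motifs, excluded) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  # position-by-position character comparison; X matches anything
  starts_matching <- function(pattern) {
    pc <- strsplit(pattern, "")[[1]]
    w <- length(pc)
    if (L < w) return(integer())
    ok <- rep(TRUE, L - w + 1L)
    for (k in seq_len(w)) {
      if (pc[k] != "X") ok <- ok & chars[seq_len(L - w + 1L) + k - 1L] == pc[k]
    }
    which(ok)
  }
  out <- list()
  for (p in motifs) {
    w <- nchar(p)
    for (i in starts_matching(p)) {
      excluded_hit <- FALSE
      for (e in excluded) {
        if (nchar(e) != w) next
        ec <- strsplit(e, "")[[1]]
        if (all(ec == "X" | ec == chars[i:(i + w - 1L)])) {
          excluded_hit <- TRUE
          break
        }
      }
      if (!excluded_hit) {
        out[[length(out) + 1L]] <- data.frame(start = i, end = i + w - 1L)
      }
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  unique(do.call(rbind, out))
}

random_aa_sequence <- function(len, p_basic = 0.1,
                               alphabet = setdiff(LETTERS[LETTERS %in%
                                 strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]],
                                 c("K", "R"))) {
  basic <- runif(len) < p_basic
  chars <- ifelse(basic, sample(c("K", "R"), len, replace = TRUE),
                  sample(alphabet, len, replace = TRUE))
  paste(chars, collapse = "")
}
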