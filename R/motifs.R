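#' Scan protein sequences for CXXC motifs
#'
#' Finds every tetrapeptide `C-X-X-C` (cysteines three residues apart), the
#' redox-active / metal-binding unit of thioredoxin-fold oxidoreductases
#' and zinc fingers.  By default `X` may be any residue including cysteine
#' (so `CCCC` yields overlapping hits); `strict_x = TRUE` excludes cysteine
#' from the two middle positions.  With `overlapping = FALSE` hits are
#' selected greedily left to right so that no two selected motifs share a
#' residue.
#'
#' @param x Protein sequences: a named character vector, a data frame with
#'   columns `id` and `seq`, or a `Biostrings::AAStringSet`.  Sequences
#'   must be ungapped.
#' @param overlapping Report all hits (`TRUE`, default) or a greedy
#'   non-overlapping subset.
#' @param strict_x Exclude cysteine from the middle positions (default
#'   `FALSE`).
#' @return A tibble with columns `sequence_id`, `position` (1-based index
#'   of the first cysteine) and `tetrapeptide`.
#' @examples
#' scan_cxxc(c(p = "MCTTCGGCAAC"))
#' scan_cxxc(c(p = "MCTTCGGCAAC"), overlapping = FALSE)
#' @export
scan_cxxc <- function(x, overlapping = TRUE, strict_x = FALSE) {
  seqs <- as_protein_tbl(x)
  if (any(grepl("-", seqs$seq, fixed = TRUE))) {
    abort("sequences contain gap characters; remove gaps before scanning",
          class = "csidetect_input_error")
  }
  hits <- purrr::map_dfr(seq_len(nrow(seqs)), function(i) {
    s <- str_to_upper(seqs$seq[i])
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    n <- length(ch)
    if (n < 4L) return(NULL)
    pos <- which(ch[seq_len(n - 3L)] == "C" & ch[4:n] == "C")
    if (strict_x) {
      pos <- pos[ch[pos + 1L] != "C" & ch[pos + 2L] != "C"]
    }
    if (!overlapping && length(pos) > 1L) {
      keep <- pos[1L]
      for (p in pos[-1L]) {
        if (p >= keep[length(keep)] + 4L) keep <- c(keep, p)
      }
      pos <- keep
    }
    if (length(pos) == 0L) return(NULL)
    tibble(sequence_id = seqs$id[i], position = pos,
           tetrapeptide = substring(s, pos, pos + 3L))
  })
  if (nrow(hits) == 0L) {
    hits <- tibble(sequence_id = character(), position = integer(),
                   tetrapeptide = character())
  }
  hits
}

#' Count CXXC motifs per protein
#'
#' @inheritParams scan_cxxc
#' @return A tibble of class `motif_counts` with columns `sequence_id`,
#'   `length` and `n_motifs`, sorted by descending count then id; proteins
#'   with zero motifs are retained.
#' @export
count_motifs <- function(x, overlapping = TRUE, strict_x = FALSE) {
  seqs <- as_protein_tbl(x)
  hits <- scan_cxxc(seqs, overlapping = overlapping, strict_x = strict_x)
  counts <- if (nrow(hits) == 0L) {
    tibble(sequence_id = character(), n = integer())
  } else {
    dplyr::count(hits, .data$sequence_id)
  }
  out <- tibble(sequence_id = seqs$id, length = nchar(seqs$seq)) |>
    left_join(counts, by = "sequence_id") |>
    mutate(n_motifs = dplyr::coalesce(.data$n, 0L)) |>
    select("sequence_id", "length", "n_motifs") |>
    arrange(desc(.data$n_motifs), .data$sequence_id)
  class(out) <- c("motif_counts", class(out))
  attr(out, "overlapping") <- overlapping
  attr(out, "strict_x") <- strict_x
  out
}

as_protein_tbl <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "seq") %in% names(x)))
    return(tibble(id = as.character(x$id), seq = as.character(x$seq)))
  }
  if (methods::is(x, "AAStringSet")) {
    return(tibble(id = names(x) %||% as.character(seq_along(x)),
                  seq = as.character(x)))
  }
  if (is.character(x)) {
    ids <- names(x) %||% as.character(seq_along(x))
    return(tibble(id = ids, seq = unname(x)))
  }
  abort("cannot interpret input as protein sequences",
        class = "csidetect_input_error")
}

#' Read protein sequences from FASTA
#' @param path FASTA file path.
#' @return A tibble with columns `id` and `seq` (ids are the first header
#'   token).
#' @export
read_proteins <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  tibble(id = sub("\\s.*$", "", names(set)),
         seq = as.character(set))
}

#' Write protein sequences to FASTA
#' @param proteins Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins$seq)
  names(set) <- proteins$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
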