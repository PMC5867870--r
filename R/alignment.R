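#' Build an alignment tibble from sequences
#'
#' An alignment is an ordinary tibble with one row per sequence and columns
#' `id` (unique, no whitespace), `taxon` (free-text organism label) and `seq`
#' (gapped residue string).  All sequences must have identical length; the
#' gap character is `-`.  Lower case is upper-cased and the Clustal-dialect
#' gap `.` is normalised to `-` on construction.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param seq Character vector of gapped residue strings, same length as `id`.
#' @param taxon Optional organism labels; defaults to `id`.
#' @return A tibble with columns `id`, `taxon`, `seq`.
#' @examples
#' alignment(c("a", "b"), c("AC-GT", "ACAGT"))
#' @export
alignment <- function(id, seq, taxon = id) {
  seq <- normalise_residues(seq)
  aln <- tibble(id = as.character(id), taxon = as.character(taxon), seq = seq)
  validate_alignment(aln)
  aln
}

normalise_residues <- function(seq) {
  gsub(".", "-", str_to_upper(seq), fixed = TRUE)
}

validate_alignment <- function(aln, min_records = 2L) {
  stopifnot(is.data.frame(aln), all(c("id", "taxon", "seq") %in% names(aln)))
  if (nrow(aln) < min_records) {
    abort(sprintf("alignment needs at least %d sequences, got %d",
                  min_records, nrow(aln)), class = "csidetect_shape_error")
  }
  if (anyDuplicated(aln$id) || any(!nzchar(aln$id)) || any(grepl("\\s", aln$id))) {
    abort("sequence ids must be non-empty, whitespace-free and unique",
          class = "csidetect_input_error")
  }
  len <- nchar(aln$seq)
  if (any(len == 0L)) {
    abort("empty sequence present", class = "csidetect_input_error")
  }
  if (length(unique(len)) != 1L) {
    bad <- aln$id[len != len[1L]]
    abort(sprintf("unequal sequence lengths (e.g. '%s'): not an alignment",
                  bad[1L]), class = "csidetect_shape_error")
  }
  bad <- !str_detect(aln$seq, sprintf("^[%s-]*$", paste(c(AA_LETTERS, "X"), collapse = "")))
  if (any(bad)) {
    i <- which(bad)[1L]
    col <- regexpr(sprintf("[^%sX-]", paste(AA_LETTERS, collapse = "")), aln$seq[i])
    abort(sprintf("illegal character in sequence '%s' at column %d",
                  aln$id[i], as.integer(col)), class = "csidetect_character_error")
  }
  invisible(aln)
}

#' Number of columns in an alignment
#' @param aln Alignment tibble (see [alignment()]).
#' @return Integer column count.
#' @export
aln_length <- function(aln) nchar(aln$seq[1L])

#' Alignment as a character matrix
#'
#' Rows are sequences (named by `id`), columns are alignment columns.
#' @inheritParams aln_length
#' @return A character matrix.
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(m) <- aln$id
  m
}

#' Read a protein multiple sequence alignment
#'
#' FASTA is read with `Biostrings::readAAStringSet()`; Clustal with
#' `Biostrings::readAAMultipleAlignment()`.  Record order is preserved.
#' For FASTA, the id is the first whitespace-delimited token of the header
#' and any remainder becomes the `taxon` label.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @return An alignment tibble.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "csidetect_input_error")
  }
  if (format == "fasta") {
    set <- tryCatch(Biostrings::readAAStringSet(path),
                    error = function(e) abort(conditionMessage(e),
                                              class = "csidetect_input_error"))
    if (length(set) == 0L) {
      abort(sprintf("empty alignment file: %s", path),
            class = "csidetect_input_error")
    }
    hdr <- names(set)
    id <- sub("\\s.*$", "", hdr)
    taxon <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), id)
    aln <- tibble(id = id, taxon = taxon,
                  seq = normalise_residues(as.character(set)))
  } else {
    ma <- tryCatch(Biostrings::readAAMultipleAlignment(path, format = "clustal"),
                   error = function(e) abort(conditionMessage(e),
                                             class = "csidetect_input_error"))
    s <- as.character(Biostrings::unmasked(ma))
    aln <- tibble(id = names(s), taxon = names(s), seq = normalise_residues(s))
  }
  validate_alignment(aln)
  aln
}

#' Write an alignment to FASTA or Clustal
#'
#' The inverse of [read_alignment()]: reading the written file reproduces
#' ids and residue strings exactly.  FASTA headers carry the taxon label
#' after the id when it differs.
#'
#' @param aln Alignment tibble.
#' @param path Output path.
#' @param format `"fasta"` or `"clustal"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  validate_alignment(aln)
  if (format == "fasta") {
    set <- Biostrings::AAStringSet(aln$seq)
    names(set) <- ifelse(aln$taxon == aln$id, aln$id,
                         paste(aln$id, aln$taxon))
    Biostrings::writeXStringSet(set, path)
  } else {
    width <- 60L
    L <- aln_length(aln)
    idw <- max(nchar(aln$id)) + 3L
    lines <- c("CLUSTAL W multiple sequence alignment", "", "")
    for (s in seq(1L, L, by = width)) {
      e <- min(s + width - 1L, L)
      block <- paste0(str_pad(aln$id, idw, side = "right"),
                      substr(aln$seq, s, e))
      lines <- c(lines, block, strrep(" ", idw + e - s + 1L), "")
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Define an in-group / out-group taxon partition
#'
#' The partition names the clade whose specific signature is sought
#' (in-group), the comparison taxa that must lack it (out-group), and the
#' reference sequence used for coordinate reporting (an in-group member,
#' typically the best-annotated genome of the clade).
#'
#' @param ingroup Character vector of in-group sequence ids.
#' @param outgroup Character vector of out-group sequence ids.
#' @param reference Reference sequence id; defaults to the first in-group id.
#' @return A tibble with columns `id`, `group` (`"ingroup"`/`"outgroup"`) and
#'   `is_reference`.
#' @export
taxon_partition <- function(ingroup, outgroup, reference = ingroup[1L]) {
  ingroup <- as.character(ingroup); outgroup <- as.character(outgroup)
  if (length(ingroup) == 0L || length(outgroup) == 0L) {
    abort("both in-group and out-group must be non-empty",
          class = "csidetect_partition_error")
  }
  if (length(intersect(ingroup, outgroup)) > 0L) {
    abort("in-group and out-group overlap", class = "csidetect_partition_error")
  }
  if (!reference %in% ingroup) {
    abort("reference sequence must belong to the in-group",
          class = "csidetect_partition_error")
  }
  tibble(id = c(ingroup, outgroup),
         group = rep(c("ingroup", "outgroup"),
                     c(length(ingroup), length(outgroup))),
         is_reference = c(ingroup, outgroup) == reference)
}

#' Read a taxon partition from a three-column TSV
#'
#' Columns: `id`, `group` (`ingroup`/`outgroup`), `is_reference` (logical or
#' 0/1).  Exactly one in-group row must be flagged as reference.
#'
#' @param path Path to the TSV file.
#' @return A partition tibble (see [taxon_partition()]).
#' @export
read_partition <- function(path) {
  p <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(),
    group = readr::col_character(),
    is_reference = readr::col_logical()
  ))
  if (!all(p$group %in% c("ingroup", "outgroup"))) {
    abort("partition group must be 'ingroup' or 'outgroup'",
          class = "csidetect_partition_error")
  }
  ref <- p$id[p$is_reference]
  if (length(ref) != 1L) {
    abort("exactly one row must be flagged is_reference",
          class = "csidetect_partition_error")
  }
  taxon_partition(p$id[p$group == "ingroup"], p$id[p$group == "outgroup"], ref)
}

partition_ids <- function(part, group) part$id[part$group == group]
reference_id <- function(part) part$id[part$is_reference][1L]

check_partition <- function(aln, part) {
  miss <- setdiff(part$id, aln$id)
  if (length(miss) > 0L) {
    abort(sprintf("partition ids absent from alignment: %s",
                  paste(miss, collapse = ", ")),
          class = "csidetect_partition_error")
  }
  invisible(part)
}

#' Per-column conservation profile of an alignment
#'
#' A column is conserved when a single non-gap residue occurs in at least
#' `threshold` of all records; gaps and `X` count in the denominator (they
#' are mismatches against any residue), so a column cannot be conserved by
#' virtue of being mostly gap.  The majority residue is the most frequent
#' amino-acid letter in the column (ties broken alphabetically); it is `NA`
#' for an all-gap/all-X column.
#'
#' @param aln Alignment tibble.
#' @param threshold Required majority fraction, in (0, 1]. Default 0.8.
#' @param ids Optional subset of sequence ids over which to profile
#'   (e.g. in-group only); defaults to all records.
#' @return A tibble of class `conservation_profile` with columns `column`,
#'   `majority_residue`, `majority_fraction`, `is_conserved`.
#' @examples
#' aln <- alignment(c("a", "b", "c"), c("AAG", "AAG", "A-C"))
#' conservation_profile(aln, threshold = 0.6)
#' @export
conservation_profile <- function(aln, threshold = 0.8, ids = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    abort("threshold must be a single number in (0, 1]",
          class = "csidetect_parameter_error")
  }
  validate_alignment(aln)
  m <- aln_matrix(aln)
  if (!is.null(ids)) {
    if (!all(ids %in% rownames(m))) {
      abort("unknown ids in conservation_profile()",
            class = "csidetect_lookup_error")
    }
    m <- m[ids, , drop = FALSE]
  }
  nrec <- nrow(m)
  code <- matrix(match(m, AA_LETTERS), nrow = nrow(m))  # NA for gaps and X
  counts <- vapply(seq_len(ncol(code)), function(j) {
    tab <- tabulate(code[, j], nbins = 20L)
    top <- which.max(tab)  # which.max takes the first (alphabetical) tie
    c(tab[top], top)
  }, numeric(2L))
  maj_count <- counts[1L, ]
  res <- AA_LETTERS[counts[2L, ]]
  res[maj_count == 0L] <- NA_character_
  frac <- maj_count / nrec
  frac[maj_count == 0L] <- NA_real_
  out <- tibble(
    column = seq_len(ncol(m)),
    majority_residue = res,
    majority_fraction = frac,
    is_conserved = !is.na(frac) & frac >= threshold
  )
  class(out) <- c("conservation_profile", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Map alignment columns to ungapped reference coordinates
#'
#' Converts 1-based alignment column indices into 1-based residue positions
#' of the (ungapped) reference sequence — the numbering convention used when
#' reporting signature regions.  A column where the reference holds a gap
#' maps to the nearest preceding reference residue (0 if none precedes).
#'
#' @param aln Alignment tibble.
#' @param ref Reference sequence id.
#' @param column Integer vector of 1-based column indices.
#' @return Integer vector of reference positions (0 when no reference
#'   residue at or before the column).
#' @examples
#' aln <- alignment(c("r", "b"), c("AC-GT", "ACAGT"))
#' map_column_to_reference(aln, "r", 1:5)  # 1 2 2 3 4
#' @export
map_column_to_reference <- function(aln, ref, column) {
  validate_alignment(aln)
  i <- match(ref, aln$id)
  if (is.na(i)) {
    abort(sprintf("unknown reference id '%s'", ref),
          class = "csidetect_lookup_error")
  }
  L <- aln_length(aln)
  if (any(column < 1L | column > L)) {
    abort("column index out of range", class = "csidetect_parameter_error")
  }
  chars <- strsplit(aln$seq[i], "", fixed = TRUE)[[1L]]
  cumsum(chars != GAP)[column]
}

#' Ungapped reference sequence of an alignment
#' @param aln Alignment tibble.
#' @param ref Reference sequence id.
#' @return Single ungapped residue string.
#' @export
reference_sequence <- function(aln, ref) {
  i <- match(ref, aln$id)
  if (is.na(i)) {
    abort(sprintf("unknown reference id '%s'", ref),
          class = "csidetect_lookup_error")
  }
  gsub(GAP, "", aln$seq[i], fixed = TRUE)
}
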