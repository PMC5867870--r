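#' Format a signature alignment block for a CSI
#'
#' Renders the classical signature display: a header carrying the
#' reference region, the reference sequence printed in full on the top
#' line, then every other row with `-` wherever it is identical to the top
#' line, the residue letter where it differs, and `.` where the row holds
#' a gap against a reference residue.  In-group rows come first, then an
#' `#OUTGROUP` separator, then out-group rows.  The encoding is lossless:
#' [parse_signature()] reconstructs the aligned residues exactly.
#'
#' @param aln Alignment tibble.
#' @param csi One row of a [detect_csis()] result (uses its
#'   `region_col_start`/`region_col_end` window and reference coordinates).
#' @param part Taxon partition.
#' @return A single string (the text block).
#' @export
format_signature <- function(aln, csi, part) {
  validate_alignment(aln)
  check_partition(aln, part)
  ref <- reference_id(part)
  cols <- csi$region_col_start:csi$region_col_end
  m <- aln_matrix(aln)[, cols, drop = FALSE]
  topline <- m[ref, ]

  encode <- function(row) {
    out <- ifelse(row == topline, "-",
                  ifelse(row == GAP, ".", row))
    paste(out, collapse = "")
  }
  ord <- c(ref,
           setdiff(intersect(aln$id, partition_ids(part, "ingroup")), ref),
           intersect(aln$id, partition_ids(part, "outgroup")))
  idw <- max(nchar(ord)) + 2L
  body <- vapply(ord, function(id) {
    s <- if (id == ref) paste(m[id, ], collapse = "") else encode(m[id, ])
    paste0(str_pad(id, idw, side = "right"), s)
  }, character(1L))
  n_in <- sum(ord %in% partition_ids(part, "ingroup"))
  header <- sprintf("#SIGNATURE %s %s %d-%d ref=%s region=%d-%d",
                    csi$protein %||% "protein", csi$indel_type,
                    csi$size_min, csi$size_max, ref,
                    csi$region_start, csi$region_end)
  paste(c(header, body[seq_len(n_in)], "#OUTGROUP",
          body[seq2(n_in + 1L, length(body))]), collapse = "\n")
}

#' Decode a signature block back to aligned residues
#'
#' The inverse of [format_signature()]: dashes are replaced by the top-line
#' residue, `.` by the gap character, letters kept as-is.
#'
#' @param text A signature block produced by [format_signature()].
#' @return A tibble with columns `id`, `seq` (decoded aligned residues) and
#'   `group`.
#' @export
parse_signature <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  if (!startsWith(lines[1L], "#SIGNATURE")) {
    abort("not a signature block", class = "csidetect_input_error")
  }
  lines <- lines[-1L]
  sep <- which(lines == "#OUTGROUP")
  group <- rep("ingroup", length(lines))
  group[seq2(sep + 1L, length(lines))] <- "outgroup"
  keep <- lines != "#OUTGROUP"
  lines <- lines[keep]; group <- group[keep]
  id <- sub("\\s.*$", "", lines)
  body <- sub("^\\S+\\s+", "", lines)
  top <- strsplit(body[1L], "", fixed = TRUE)[[1L]]
  seqs <- vapply(body, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    paste(ifelse(ch == "-", top, ifelse(ch == ".", GAP, ch)), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
  seqs[1L] <- body[1L]  # reference row is printed verbatim
  tibble(id = id, seq = seqs, group = group)
}

#' Write signature blocks to text files
#' @param csis A [detect_csis()] result.
#' @param dir Output directory (created if absent).
#' @return Paths written, invisibly.
#' @export
write_signatures <- function(csis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_len(nrow(csis)), function(i) {
    p <- file.path(dir, sprintf("%s_%03d_%s.sig.txt", csis$protein[i], i,
                                csis$indel_type[i]))
    writeLines(csis$signature[i], p)
    p
  }, character(1L))
  invisible(paths)
}
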