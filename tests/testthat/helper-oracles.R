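# Independent oracles and tiny fixture builders, deliberately written
# against the definitions rather than the package's code paths.

# build an alignment tibble straight from residue strings
make_aln <- function(...) {
  seqs <- c(...)
  alignment(names(seqs), seqs)
}

# exhaustive per-column conservation oracle: direct counting with table()
oracle_profile <- function(aln, threshold) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  purrr::map_dfr(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[!col %in% c("-", "X")]
    if (length(col) == 0L) {
      return(tibble::tibble(column = j, majority_residue = NA_character_,
                            majority_fraction = NA_real_,
                            is_conserved = FALSE))
    }
    tab <- sort(table(col), decreasing = TRUE)
    best <- names(tab)[tab == max(tab)]
    res <- sort(best)[1L]
    frac <- max(tab) / n
    tibble::tibble(column = j, majority_residue = res,
                   majority_fraction = frac,
                   is_conserved = frac >= threshold)
  })
}

# brute-force indel-candidate oracle: every interval is tested column by
# column against the tolerance definitions; only maximal intervals kept
oracle_gap_blocks <- function(aln, part, params) {
  m <- aln_matrix(aln)
  ig <- part$id[part$group == "ingroup"]
  og <- part$id[part$group == "outgroup"]
  L <- ncol(m)
  col_ok <- function(j, type) {
    fi <- mean(m[ig, j] != "-")
    fo <- mean(m[og, j] != "-")
    if (type == "insertion") {
      fi >= 1 - params$max_ingroup_missing && fo <= params$max_outgroup_sharing
    } else {
      fi <= params$max_ingroup_missing && fo >= 1 - params$max_outgroup_sharing
    }
  }
  out <- list()
  for (type in c("insertion", "deletion")) {
    ok <- vapply(seq_len(L), col_ok, logical(1L), type = type)
    for (s in seq_len(L)) {
      for (e in s:L) {
        all_ok <- all(ok[s:e])
        left_max <- s == 1L || !ok[s - 1L]
        right_max <- e == L || !ok[e + 1L]
        if (all_ok && left_max && right_max) {
          carrier <- if (type == "insertion") ig else og
          sz <- rowSums(m[carrier, s:e, drop = FALSE] != "-")
          sz <- sz[sz > 0L]
          smin <- if (length(sz)) min(sz) else 0L
          smax <- if (length(sz)) max(sz) else 0L
          if (smin >= params$min_indel_size && smax <= params$max_indel_size) {
            out[[length(out) + 1L]] <- tibble::tibble(
              indel_type = type, col_start = s, col_end = e,
              size_min = as.integer(smin), size_max = as.integer(smax))
          }
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(indel_type = character(), col_start = integer(),
                          col_end = integer(), size_min = integer(),
                          size_max = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), col_start, indel_type)
}

# all-positions CXXC oracle (loop over every start index)
oracle_scan_cxxc <- function(seq, strict_x = FALSE) {
  ch <- strsplit(toupper(seq), "")[[1L]]
  hits <- integer(0)
  for (i in seq_len(max(0L, length(ch) - 3L))) {
    ok <- ch[i] == "C" && ch[i + 3L] == "C"
    if (ok && strict_x) ok <- ch[i + 1L] != "C" && ch[i + 2L] != "C"
    if (ok) hits <- c(hits, i)
  }
  hits
}

# random gapped alignment + partition for property tests
random_alignment <- function(n_seq = NULL, len = NULL, gap_prob = 0.25,
                             alphabet = c("A", "G", "L", "S")) {
  n_seq <- n_seq %||% sample(4:8, 1L)
  len <- len %||% sample(10:40, 1L)
  seqs <- replicate(n_seq, {
    ch <- sample(alphabet, len, replace = TRUE)
    ch[runif(len) < gap_prob] <- "-"
    paste(ch, collapse = "")
  })
  # avoid all-gap sequences (invalid as proteins, uninteresting here)
  seqs <- vapply(seqs, function(s) {
    if (grepl("^-+$", s)) sub("-", "A", s) else s
  }, character(1L), USE.NAMES = FALSE)
  ids <- sprintf("s%02d", seq_len(n_seq))
  n_in <- sample(2:(n_seq - 2L), 1L)
  list(aln = alignment(ids, seqs),
       part = taxon_partition(ids[seq_len(n_in)], ids[(n_in + 1L):n_seq]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
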