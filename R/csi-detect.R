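#' Detection parameters for conserved signature indels
#'
#' Bundles the tunable criteria of the CSI screen.  Defaults encode the
#' classical working definition of a conserved signature indel: a
#' group-differential gap block of any size, flanked on both sides by at
#' least 5 conserved residues within a 35-column window, strictly specific
#' for the in-group (all in-group members carry it, no out-group member
#' does), with an 80-residue validation segment exported around each hit.
#'
#' @param min_indel_size,max_indel_size Indel size bounds in residues.
#' @param flank_window Columns examined on each side of a candidate
#'   (default 35).
#' @param min_conserved_flank Conserved columns required within each flank
#'   window (default 5).
#' @param conservation_threshold Majority fraction that makes a column
#'   conserved (default 0.8); see [conservation_profile()].
#' @param conservation_scope `"all"` scores flank conservation across both
#'   groups (default); `"ingroup"` across the in-group only.
#' @param max_ingroup_missing Tolerated fraction of in-group records not
#'   carrying the indel (default 0, i.e. all must carry it).
#' @param max_outgroup_sharing Tolerated fraction of out-group records
#'   sharing the indel (default 0).
#' @param allow_isolated_exception When `TRUE`, a single out-group record
#'   sharing the indel does not reject the candidate; it is listed as an
#'   exception and the verdict downgraded to `"tolerant"`.
#' @param validation_segment_length Length, in reference residues, of the
#'   exported segment spanning the indel and its conserved flanks; clamped
#'   to 60--100 (default 80).
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(min_indel_size = 1L,
                             max_indel_size = Inf,
                             flank_window = 35L,
                             min_conserved_flank = 5L,
                             conservation_threshold = 0.8,
                             conservation_scope = c("all", "ingroup"),
                             max_ingroup_missing = 0,
                             max_outgroup_sharing = 0,
                             allow_isolated_exception = FALSE,
                             validation_segment_length = 80L) {
  conservation_scope <- match.arg(conservation_scope)
  p <- list(
    min_indel_size = as.integer(min_indel_size),
    max_indel_size = max_indel_size,
    flank_window = as.integer(flank_window),
    min_conserved_flank = as.integer(min_conserved_flank),
    conservation_threshold = conservation_threshold,
    conservation_scope = conservation_scope,
    max_ingroup_missing = max_ingroup_missing,
    max_outgroup_sharing = max_outgroup_sharing,
    allow_isolated_exception = isTRUE(allow_isolated_exception),
    validation_segment_length = as.integer(validation_segment_length)
  )
  if (p$min_indel_size < 1L) {
    abort("min_indel_size must be >= 1", class = "csidetect_parameter_error")
  }
  if (p$max_indel_size < p$min_indel_size) {
    abort("max_indel_size < min_indel_size", class = "csidetect_parameter_error")
  }
  if (p$flank_window < p$min_conserved_flank) {
    abort("flank_window must be >= min_conserved_flank",
          class = "csidetect_parameter_error")
  }
  for (f in c("max_ingroup_missing", "max_outgroup_sharing")) {
    if (p[[f]] < 0 || p[[f]] > 1) {
      abort(sprintf("%s must lie in [0, 1]", f),
            class = "csidetect_parameter_error")
    }
  }
  if (p$conservation_threshold <= 0 || p$conservation_threshold > 1) {
    abort("conservation_threshold must lie in (0, 1]",
          class = "csidetect_parameter_error")
  }
  if (p$validation_segment_length < 60L || p$validation_segment_length > 100L) {
    p$validation_segment_length <-
      max(60L, min(100L, p$validation_segment_length))
    warn(sprintf("validation_segment_length clamped to %d (allowed 60-100)",
                 p$validation_segment_length))
  }
  structure(p, class = "detection_params")
}

as_detection_params <- function(params) {
  if (inherits(params, "detection_params")) params else
    do.call(detection_params, params)
}

# per-column fraction of records (rows of `m`) holding a residue (non-gap)
.nongap_fraction <- function(m) colMeans(m != GAP)

#' Locate group-differential gap blocks (indel candidates)
#'
#' Scans the alignment for maximal runs of contiguous columns in which the
#' in-group holds residues while the out-group holds gaps (an insertion,
#' relative to the in-group) or the converse (a deletion), up to the
#' tolerance fractions in `params`.  Indel sizes are the non-gap residue
#' counts of the carrier group within the run: the in-group for insertions,
#' the out-group for deletions (the material the in-group lacks).  Runs
#' whose size range falls outside `[min_indel_size, max_indel_size]` are
#' discarded.
#'
#' @param aln Alignment tibble.
#' @param part Taxon partition (see [taxon_partition()]).
#' @param params Detection parameters (see [detection_params()]).
#' @return A tibble with one row per candidate: `indel_type`, `col_start`,
#'   `col_end` (1-based inclusive alignment columns), `size_min`,
#'   `size_max`, and a `lengths` list-column of per-record non-gap counts
#'   within the run.
#' @export
find_gap_blocks <- function(aln, part, params = detection_params()) {
  params <- as_detection_params(params)
  validate_alignment(aln)
  check_partition(aln, part)
  m <- aln_matrix(aln)
  ig <- partition_ids(part, "ingroup")
  og <- partition_ids(part, "outgroup")
  fi <- .nongap_fraction(m[ig, , drop = FALSE])
  fo <- .nongap_fraction(m[og, , drop = FALSE])

  ins_col <- fi >= 1 - params$max_ingroup_missing &
    fo <= params$max_outgroup_sharing
  del_col <- fi <= params$max_ingroup_missing &
    fo >= 1 - params$max_outgroup_sharing

  cand <- bind_rows(
    .column_runs(ins_col, "insertion"),
    .column_runs(del_col, "deletion")
  )
  if (nrow(cand) == 0L) return(.empty_candidates())

  cand <- cand |>
    mutate(
      lengths = map2_runs(m, .data$col_start, .data$col_end),
      sizes = purrr::map2(.data$lengths, .data$indel_type, function(len, ty) {
        carrier <- if (ty == "insertion") ig else og
        s <- len[carrier]
        s[s > 0L]
      }),
      size_min = map_int(.data$sizes, ~ if (length(.x)) min(.x) else 0L),
      size_max = map_int(.data$sizes, ~ if (length(.x)) max(.x) else 0L)
    ) |>
    filter(.data$size_min >= params$min_indel_size,
           .data$size_max <= params$max_indel_size) |>
    select("indel_type", "col_start", "col_end",
           "size_min", "size_max", "lengths") |>
    arrange(.data$col_start, .data$indel_type)
  cand
}

.empty_candidates <- function() {
  tibble(indel_type = character(), col_start = integer(),
         col_end = integer(), size_min = integer(), size_max = integer(),
         lengths = list())
}

# maximal runs of TRUE in a logical vector, as a candidate skeleton
.column_runs <- function(flag, type) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(NULL)
  tibble(indel_type = type, col_start = starts[keep], col_end = ends[keep])
}

# per-record non-gap residue counts within [s, e], as a named-int list col
map2_runs <- function(m, s, e) {
  purrr::map2(s, e, function(a, b) {
    rowSums(m[, a:b, drop = FALSE] != GAP)
  })
}

#' Score flank conservation around an indel candidate
#'
#' Counts conserved columns (per [conservation_profile()] at the parameter
#' threshold, over all records or the in-group depending on
#' `conservation_scope`) within `flank_window` columns on each side of the
#' candidate, excluding the candidate interval itself; windows are
#' truncated at the alignment edges.  The candidate passes when both counts
#' reach `min_conserved_flank`.
#'
#' @inheritParams find_gap_blocks
#' @param candidate One row of the [find_gap_blocks()] output (or any list
#'   with `col_start` and `col_end`).
#' @return A one-row tibble: `left_count`, `right_count`, `pass`, and the
#'   leftmost/rightmost conserved flank columns `left_col`/`right_col`
#'   (`NA` when a flank holds no conserved column).
#' @export
evaluate_flanks <- function(aln, candidate, part, params = detection_params()) {
  params <- as_detection_params(params)
  ids <- if (params$conservation_scope == "ingroup")
    partition_ids(part, "ingroup") else NULL
  prof <- conservation_profile(aln, params$conservation_threshold, ids = ids)
  .flanks_from_profile(prof, candidate, params)
}

.flanks_from_profile <- function(prof, candidate, params) {
  L <- nrow(prof)
  s <- candidate$col_start
  e <- candidate$col_end
  left <- seq2(max(1L, s - params$flank_window), s - 1L)
  right <- seq2(e + 1L, min(L, e + params$flank_window))
  lc <- left[prof$is_conserved[left]]
  rc <- right[prof$is_conserved[right]]
  tibble(
    left_count = length(lc), right_count = length(rc),
    pass = length(lc) >= params$min_conserved_flank &&
      length(rc) >= params$min_conserved_flank,
    left_col = if (length(lc)) min(lc) else NA_integer_,
    right_col = if (length(rc)) max(rc) else NA_integer_
  )
}

seq2 <- function(from, to) if (from > to) integer(0) else from:to

#' Judge clade specificity of an indel candidate
#'
#' A record *carries* an insertion when it holds at least one residue in
#' the candidate interval, and carries a deletion when the interval is all
#' gap.  The verdict is `"strict"` when every in-group record carries the
#' indel and no out-group record does; `"tolerant"` when violations stay
#' within `max_ingroup_missing` / `max_outgroup_sharing` (or a single
#' out-group sharer under `allow_isolated_exception`), with the violating
#' ids listed; otherwise `"rejected"`.
#'
#' @inheritParams evaluate_flanks
#' @return A one-row tibble: `verdict`, `n_ingroup_missing`,
#'   `n_outgroup_sharing`, and an `exceptions` list-column of violating ids.
#' @export
evaluate_specificity <- function(aln, candidate, part,
                                 params = detection_params()) {
  params <- as_detection_params(params)
  validate_alignment(aln)
  check_partition(aln, part)
  m <- aln_matrix(aln)[, candidate$col_start:candidate$col_end, drop = FALSE]
  nongap <- rowSums(m != GAP)
  carries <- if (candidate$indel_type == "insertion") nongap > 0L else
    nongap == 0L
  ig <- partition_ids(part, "ingroup")
  og <- partition_ids(part, "outgroup")
  miss <- ig[!carries[ig]]
  share <- og[carries[og]]
  verdict <- if (length(miss) == 0L && length(share) == 0L) {
    "strict"
  } else if ((length(miss) / length(ig) <= params$max_ingroup_missing) &&
             (length(share) / length(og) <= params$max_outgroup_sharing ||
              (params$allow_isolated_exception && length(share) <= 1L))) {
    "tolerant"
  } else {
    "rejected"
  }
  tibble(verdict = verdict,
         n_ingroup_missing = length(miss),
         n_outgroup_sharing = length(share),
         exceptions = list(c(miss, share)))
}

#' Detect conserved signature indels in an alignment
#'
#' The full screen: group-differential gap blocks are located
#' ([find_gap_blocks()]), each is required to sit within conserved flanking
#' sequence ([evaluate_flanks()]) and to be specific for the in-group
#' ([evaluate_specificity()]); survivors are mapped to ungapped
#' reference-protein coordinates and reported as catalogue rows, each with
#' a publication-style signature block ([format_signature()]) and an
#' ungapped validation segment ([export_validation_segment()]).
#'
#' The reported region (`region_start`--`region_end`) spans from the
#' leftmost conserved column of the passing left flank to the rightmost of
#' the right flank, in reference coordinates; `indel_start`--`indel_end`
#' is the indel itself (for a deletion, the reference residues bracketing
#' the missing block).
#'
#' @inheritParams find_gap_blocks
#' @param protein Protein/family name recorded in the output (default
#'   `"protein"`).
#' @return A tibble of class `csi_tbl`, one row per emitted CSI, sorted by
#'   `region_start`: `protein`, `indel_type`, `size_min`, `size_max`,
#'   `region_start`, `region_end`, `indel_start`, `indel_end`,
#'   `flank_left`, `flank_right`, `specificity`, `exceptions` (comma
#'   string), `signature` (text block), `segment`, `segment_start`,
#'   `segment_end`, plus alignment-column bookkeeping (`col_start`,
#'   `col_end`, `region_col_start`, `region_col_end`).
#' @examples
#' sim <- sim_family_alignment(family_sim_config(
#'   seed = 7, protein_length = 200, indel_length = 16, indel_position = 90))
#' detect_csis(sim$alignment, sim$partition, protein = "UvrC-like")
#' @export
detect_csis <- function(aln, part, params = detection_params(),
                        protein = "protein") {
  params <- as_detection_params(params)
  validate_alignment(aln)
  check_partition(aln, part)
  cand <- find_gap_blocks(aln, part, params)
  ids <- if (params$conservation_scope == "ingroup")
    partition_ids(part, "ingroup") else NULL
  prof <- conservation_profile(aln, params$conservation_threshold, ids = ids)
  ref <- reference_id(part)

  rows <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
    cd <- cand[i, ]
    fl <- .flanks_from_profile(prof, cd, params)
    if (!fl$pass) return(NULL)
    sp <- evaluate_specificity(aln, cd, part, params)
    if (sp$verdict == "rejected") return(NULL)
    ref_map <- function(col) map_column_to_reference(aln, ref, col)
    rec <- tibble(
      protein = protein,
      indel_type = cd$indel_type,
      size_min = cd$size_min, size_max = cd$size_max,
      region_start = ref_map(fl$left_col),
      region_end = ref_map(fl$right_col),
      indel_start = ref_map(cd$col_start),
      indel_end = ref_map(cd$col_end),
      flank_left = fl$left_count, flank_right = fl$right_count,
      specificity = sp$verdict,
      exceptions = paste(sp$exceptions[[1L]], collapse = ","),
      col_start = cd$col_start, col_end = cd$col_end,
      region_col_start = fl$left_col, region_col_end = fl$right_col
    )
    seg <- export_validation_segment(aln, rec, part, params)
    rec$segment <- seg$seq
    rec$segment_start <- seg$start
    rec$segment_end <- seg$end
    rec$signature <- format_signature(aln, rec, part)
    rec
  })
  if (nrow(rows) == 0L) rows <- .empty_csi_tbl()
  rows <- arrange(rows, .data$region_start, .data$col_start)
  class(rows) <- c("csi_tbl", class(rows))
  attr(rows, "params") <- params
  attr(rows, "n_candidates") <- nrow(cand)
  attr(rows, "reference") <- ref
  attr(rows, "n_ingroup") <- length(partition_ids(part, "ingroup"))
  attr(rows, "n_outgroup") <- length(partition_ids(part, "outgroup"))
  rows
}

.empty_csi_tbl <- function() {
  tibble(protein = character(), indel_type = character(),
         size_min = integer(), size_max = integer(),
         region_start = integer(), region_end = integer(),
         indel_start = integer(), indel_end = integer(),
         flank_left = integer(), flank_right = integer(),
         specificity = character(), exceptions = character(),
         col_start = integer(), col_end = integer(),
         region_col_start = integer(), region_col_end = integer(),
         segment = character(), segment_start = integer(),
         segment_end = integer(), signature = character())
}

#' Extract the ungapped validation segment around a CSI
#'
#' Returns the reference-protein subsequence (of `validation_segment_length`
#' residues, truncated only by the protein ends) centred on the indel — the
#' piece one would submit to a homology search to screen the indel's
#' specificity against a wider sequence panel.
#'
#' @inheritParams evaluate_flanks
#' @param csi One row of a [detect_csis()] result.
#' @return A one-row tibble: `protein`, `start`, `end` (1-based reference
#'   positions), `seq`, `header` (FASTA-ready provenance header).
#' @export
export_validation_segment <- function(aln, csi, part,
                                      params = detection_params()) {
  params <- as_detection_params(params)
  ref <- reference_id(part)
  refseq <- reference_sequence(aln, ref)
  n <- nchar(refseq)
  a <- max(1L, csi$indel_start)
  b <- max(a, csi$indel_end)
  span <- b - a + 1L
  if (span > n) {
    abort("reference shorter than indel span",
          class = "csidetect_internal_error")
  }
  len <- min(params$validation_segment_length, n)
  len <- max(len, span)
  pad <- len - span
  start <- a - pad %/% 2L
  if (start < 1L) start <- 1L
  end <- start + len - 1L
  if (end > n) {
    end <- n
    start <- max(1L, end - len + 1L)
  }
  tibble(
    protein = csi$protein %||% "protein",
    start = start, end = end,
    seq = substr(refseq, start, end),
    header = sprintf("%s|%s|%d-%d|indel:%s:%d-%d",
                     csi$protein %||% "protein", ref, start, end,
                     csi$indel_type, csi$indel_start, csi$indel_end)
  )
}

#' Write validation segments as FASTA
#' @param csis A [detect_csis()] result.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_validation_fasta <- function(csis, path) {
  set <- Biostrings::AAStringSet(csis$segment)
  names(set) <- sprintf("%s|%d-%d|%s", csis$protein,
                        csis$segment_start, csis$segment_end,
                        csis$indel_type)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
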