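#' Tidy a CSI catalogue
#'
#' Drops the bulky text columns (signature block, validation segment) and
#' the internal alignment-column bookkeeping, leaving the Table-style
#' catalogue rows.
#'
#' @param x A `csi_tbl` from [detect_csis()] or [run_csi()].
#' @param ... Unused.
#' @return A plain tibble.
#' @method tidy csi_tbl
#' @export
tidy.csi_tbl <- function(x, ...) {
  as_tibble(x)[c("protein", "indel_type", "size_min", "size_max",
                 "region_start", "region_end", "indel_start", "indel_end",
                 "flank_left", "flank_right", "specificity", "exceptions")]
}

#' One-row summary of a CSI screen
#'
#' @param x A `csi_tbl`.
#' @param ... Unused.
#' @return A one-row tibble: number of gap-block candidates examined,
#'   number of CSIs emitted, strict/tolerant counts and the thresholds
#'   used.
#' @method glance csi_tbl
#' @export
glance.csi_tbl <- function(x, ...) {
  p <- attr(x, "params")
  tibble(
    n_candidates = attr(x, "n_candidates") %||% NA_integer_,
    n_csi = nrow(x),
    n_strict = sum(x$specificity == "strict"),
    n_tolerant = sum(x$specificity == "tolerant"),
    conservation_threshold = p$conservation_threshold,
    min_conserved_flank = p$min_conserved_flank,
    flank_window = p$flank_window
  )
}

#' One-row summary of an arrangement comparison
#'
#' @param x An `arrangement_summary` from [compare_arrangements()].
#' @param ... Unused.
#' @return A one-row tibble with `n_match`, `n_total` and the match
#'   fraction.
#' @method glance arrangement_summary
#' @export
glance.arrangement_summary <- function(x, ...) {
  tibble(n_match = attr(x, "n_match"),
         n_total = attr(x, "n_total"),
         fraction = attr(x, "n_match") / attr(x, "n_total"))
}

#' @export
print.detection_params <- function(x, ...) {
  cat("CSI detection parameters:\n")
  for (f in names(x)) cat(sprintf("  %-26s %s\n", f, format(x[[f]])))
  invisible(x)
}
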