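#' Run the CSI catalogue analysis over one or more protein families
#'
#' For each input family the alignment and partition are read, the CSI
#' screen ([detect_csis()]) is run, and the results are pooled into one
#' catalogue.  When `out_dir` is given, writes `csi_table.tsv` (one row
#' per CSI), per-CSI signature blocks under `signatures/`, and all
#' validation segments to `validation_segments.fasta`.  Output ordering is
#' deterministic: by protein name, then region start.
#'
#' @param inputs A data frame with columns `protein`, `alignment`
#'   (alignment file path), `partition` (partition TSV path) and optional
#'   `format` (`"fasta"` default, or `"clustal"`).
#' @param params Detection parameters ([detection_params()]).
#' @param out_dir Optional output directory (created if needed).
#' @return The pooled `csi_tbl` (invisibly when writing).  Families whose
#'   files fail to parse are skipped with a warning; if no family parses,
#'   an error of class `csidetect_no_input_error` is raised.
#' @export
run_csi <- function(inputs, params = detection_params(), out_dir = NULL) {
  stopifnot(is.data.frame(inputs),
            all(c("protein", "alignment", "partition") %in% names(inputs)))
  if (nrow(inputs) == 0L) {
    abort("no input families given", class = "csidetect_usage_error")
  }
  fmt <- if ("format" %in% names(inputs)) inputs$format else
    rep("fasta", nrow(inputs))
  ok <- 0L
  res <- purrr::map_dfr(seq_len(nrow(inputs)), function(i) {
    out <- tryCatch({
      aln <- read_alignment(inputs$alignment[i], format = fmt[i])
      part <- read_partition(inputs$partition[i])
      r <- detect_csis(aln, part, params, protein = inputs$protein[i])
      ok <<- ok + 1L
      r
    }, error = function(e) {
      warn(sprintf("family '%s' skipped: %s", inputs$protein[i],
                   conditionMessage(e)))
      NULL
    })
    out
  })
  if (ok == 0L) {
    abort("no input family could be parsed",
          class = "csidetect_no_input_error")
  }
  if (nrow(res) == 0L) res <- .empty_csi_tbl()
  res <- arrange(res, .data$protein, .data$region_start)
  class(res) <- c("csi_tbl", class(res))
  attr(res, "params") <- as_detection_params(params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_csi_table(res, file.path(out_dir, "csi_table.tsv"))
    write_signatures(res, file.path(out_dir, "signatures"))
    if (nrow(res) > 0L) {
      write_validation_fasta(res, file.path(out_dir,
                                            "validation_segments.fasta"))
    }
    return(invisible(res))
  }
  res
}

#' Write a CSI catalogue as TSV
#'
#' Columns: protein, indel_type, size_min, size_max, region_start,
#' region_end, flank_left, flank_right, specificity, exceptions.
#'
#' @param csis A `csi_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csi_table <- function(csis, path) {
  cols <- c("protein", "indel_type", "size_min", "size_max",
            "region_start", "region_end", "flank_left", "flank_right",
            "specificity", "exceptions")
  readr::write_tsv(as_tibble(csis)[cols], path)
  invisible(path)
}

#' Run the gene-neighborhood / operon analysis
#'
#' Reads the annotations, predicts operons ([predict_operons()]), extracts
#' the neighborhood of `anchor_family` and compares every genome's
#' arrangement against `reference` ([compare_arrangements()]).  When
#' `out_dir` is given, writes `operons.tsv` and `arrangements.tsv`.
#'
#' @param annotations Either a genome annotation tibble or a character
#'   vector of annotation file paths (read as `format`).
#' @param anchor_family Family label anchoring the neighborhood.
#' @param reference Reference arrangement (data frame `family`, `strand`).
#' @param format,family_map Passed to [read_annotation()] when
#'   `annotations` is a path vector.
#' @param k Neighborhood radius in genes (default 3).
#' @param linkage_bp Operon linkage threshold (default 200).
#' @param out_dir Optional output directory.
#' @return A list with `operons` (operon-call tibble), `arrangements`
#'   (the [compare_arrangements()] summary) and `neighborhoods`.
#' @export
run_neighborhood <- function(annotations, anchor_family, reference,
                             format = "tsv", family_map = NULL, k = 3L,
                             linkage_bp = 200L, out_dir = NULL) {
  ann <- if (is.character(annotations)) {
    bind_rows(purrr::map(annotations, read_annotation, format = format,
                         family_map = family_map))
  } else {
    validate_annotation(annotations)
  }
  operons <- predict_operons(ann, linkage_bp = linkage_bp)
  nb <- extract_neighborhood(ann, anchor_family, k = k)
  arr <- compare_arrangements(nb, reference)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    flat <- operons |>
      mutate(loci = map_chr(.data$loci, paste, collapse = ","),
             families = map_chr(.data$families, paste, collapse = ","),
             gaps = map_chr(.data$gaps, paste, collapse = ","))
    readr::write_tsv(flat, file.path(out_dir, "operons.tsv"))
    readr::write_tsv(as_tibble(arr), file.path(out_dir, "arrangements.tsv"))
  }
  list(operons = operons, arrangements = arr, neighborhoods = nb)
}

#' Run the CXXC motif census
#'
#' Scans every input proteome and writes/returns per-hit and per-protein
#' tables.
#'
#' @param proteins A tibble (`id`, `seq`), named character vector, or a
#'   character vector of FASTA paths (detected by file existence).
#' @param overlapping,strict_x Scanning policy; see [scan_cxxc()].
#' @param out_dir Optional output directory (`motif_hits.tsv`,
#'   `motif_counts.tsv`).
#' @return A list with `hits` and `counts`.
#' @export
run_motifs <- function(proteins, overlapping = TRUE, strict_x = FALSE,
                       out_dir = NULL) {
  if (is.character(proteins) && length(proteins) > 0L &&
      all(file.exists(proteins))) {
    proteins <- bind_rows(purrr::map(proteins, read_proteins))
  }
  seqs <- as_protein_tbl(proteins)
  if (nrow(seqs) == 0L) {
    warn("no protein sequences given; emitting empty tables")
  }
  hits <- scan_cxxc(seqs, overlapping = overlapping, strict_x = strict_x)
  counts <- count_motifs(seqs, overlapping = overlapping,
                         strict_x = strict_x)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(hits, file.path(out_dir, "motif_hits.tsv"))
    readr::write_tsv(as_tibble(counts), file.path(out_dir, "motif_counts.tsv"))
  }
  list(hits = hits, counts = counts)
}

#' Write a genome annotation as the package's TSV exchange format
#' @param ann Genome annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(ann, path) {
  readr::write_tsv(tibble(genome = ann$genome_id, contig = ann$contig,
                          locus = ann$locus_id, family = ann$family,
                          strand = ann$strand, start = ann$start,
                          end = ann$end), path)
  invisible(path)
}
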