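#' Read a genome annotation into a gene table
#'
#' A genome annotation is a tibble with one row per protein-coding gene and
#' columns `genome_id`, `contig`, `locus_id`, `family`, `strand` (`+`/`-`),
#' `start`, `end` (1-based inclusive bp, `start <= end`), sorted by
#' (`contig`, `start`).  Three input formats are supported:
#'
#' * `"tsv"` — columns `genome`, `contig`, `locus`, `family`, `strand`,
#'   `start`, `end` (the package's minimal exchange format);
#' * `"gff3"` — canonical GFF3, read with `rtracklayer::import()`; `gene`
#'   features are used (falling back to `CDS` when no `gene` rows exist),
#'   `locus_tag`/`ID` gives the locus and a `family` attribute or `Name`
#'   the family label;
#' * `"feature_table"` — an NCBI assembly `*_feature_table.txt` TSV
#'   (columns include `feature`, `genomic_accession`, `start`, `end`,
#'   `strand`, `locus_tag`); `CDS` rows are used.
#'
#' Family labels absent from the file are filled from `family_map`; loci
#' still unlabelled keep their locus id as family.
#'
#' @param path Annotation file path.
#' @param format One of `"tsv"`, `"gff3"`, `"feature_table"`.
#' @param family_map Optional named character vector or two-column data
#'   frame (`locus_id`, `family`) mapping loci to ortholog-family labels.
#' @param genome_id Genome identifier; defaults to the file name (for
#'   formats that do not carry one).
#' @return A genome annotation tibble.
#' @export
read_annotation <- function(path, format = c("tsv", "gff3", "feature_table"),
                            family_map = NULL, genome_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "csidetect_input_error")
  }
  gid <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
  ann <- switch(format,
    tsv = {
      x <- readr::read_tsv(path, col_types = readr::cols(
        genome = readr::col_character(), contig = readr::col_character(),
        locus = readr::col_character(), family = readr::col_character(),
        strand = readr::col_character(),
        start = readr::col_integer(), end = readr::col_integer()))
      tibble(genome_id = x$genome, contig = x$contig, locus_id = x$locus,
             family = x$family, strand = x$strand,
             start = x$start, end = x$end)
    },
    gff3 = {
      g <- rtracklayer::import(path, format = "gff3")
      g <- g[g$type %in% c("gene", "CDS")]
      if (any(g$type == "gene")) g <- g[g$type == "gene"]
      locus <- if (!is.null(g$locus_tag)) g$locus_tag else g$ID
      fam <- if (!is.null(g$family)) g$family else
        if (!is.null(g$Name)) g$Name else NA_character_
      tibble(genome_id = gid,
             contig = as.character(GenomicRanges::seqnames(g)),
             locus_id = as.character(locus),
             family = as.character(fam),
             strand = as.character(GenomicRanges::strand(g)),
             start = GenomicRanges::start(g), end = GenomicRanges::end(g))
    },
    feature_table = {
      x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
      names(x)[1L] <- sub("^#\\s*", "", names(x)[1L])
      x <- x[x$feature == "CDS", ]
      tibble(genome_id = gid, contig = x$genomic_accession,
             locus_id = x$locus_tag,
             family = if ("symbol" %in% names(x)) x$symbol else NA_character_,
             strand = x$strand,
             start = as.integer(x$start), end = as.integer(x$end))
    })
  validate_annotation(apply_family_map(ann, family_map))
}

apply_family_map <- function(ann, family_map) {
  if (is.null(family_map)) {
    ann$family <- ifelse(is.na(ann$family), ann$locus_id, ann$family)
    return(ann)
  }
  if (is.data.frame(family_map)) {
    fm <- stats::setNames(as.character(family_map[[2L]]),
                          as.character(family_map[[1L]]))
  } else {
    fm <- family_map
  }
  mapped <- unname(fm[ann$locus_id])
  ann$family <- dplyr::coalesce(mapped, ann$family, ann$locus_id)
  ann
}

validate_annotation <- function(ann) {
  need <- c("genome_id", "contig", "locus_id", "family", "strand",
            "start", "end")
  stopifnot(is.data.frame(ann), all(need %in% names(ann)))
  if (any(is.na(ann$strand)) || !all(ann$strand %in% c("+", "-"))) {
    bad <- ann$locus_id[is.na(ann$strand) | !ann$strand %in% c("+", "-")]
    abort(sprintf("missing/invalid strand for locus '%s'", bad[1L]),
          class = "csidetect_record_error")
  }
  if (any(is.na(ann$start) | is.na(ann$end))) {
    bad <- ann$locus_id[is.na(ann$start) | is.na(ann$end)]
    abort(sprintf("missing coordinates for locus '%s'", bad[1L]),
          class = "csidetect_record_error")
  }
  if (any(ann$end < ann$start) || any(ann$start < 1L)) {
    bad <- ann$locus_id[ann$end < ann$start | ann$start < 1L]
    abort(sprintf("invalid coordinates (end < start or start < 1) for locus '%s'",
                  bad[1L]), class = "csidetect_record_error")
  }
  dup <- ann |> group_by(.data$genome_id) |>
    filter(duplicated(.data$locus_id)) |> ungroup()
  if (nrow(dup) > 0L) {
    abort(sprintf("duplicate locus id '%s' in genome '%s'",
                  dup$locus_id[1L], dup$genome_id[1L]),
          class = "csidetect_record_error")
  }
  arrange(as_tibble(ann), .data$genome_id, .data$contig, .data$start)
}

#' Intergenic distance between two genes
#'
#' `start(b) - end(a) - 1` on 1-based inclusive coordinates: abutting genes
#' give 0 and overlapping coding regions give a negative distance (itself
#' evidence of co-transcription).
#'
#' @param a,b One-row gene records (b downstream of a, same contig).
#' @return Integer distance in bp (possibly negative).
#' @export
intergenic_distance <- function(a, b) {
  if (!identical(a$contig, b$contig) ||
      !identical(a$genome_id, b$genome_id)) {
    abort("genes on different contigs/genomes are not comparable",
          class = "csidetect_comparability_error")
  }
  as.integer(b$start - a$end - 1L)
}

#' Predict operons from strand, direction and intergenic distance
#'
#' Genes are grouped into maximal runs of consecutive same-contig,
#' same-strand genes (hence transcribed in the same direction) in which
#' every consecutive intergenic distance is strictly below `linkage_bp`;
#' overlapping genes (negative distance) are always linked.  Every gene
#' belongs to exactly one call (isolated genes form singletons).
#'
#' @param ann Genome annotation tibble (possibly several genomes).
#' @param linkage_bp Linkage threshold in bp, strict (`< linkage_bp`);
#'   default 200, the distance below which neighbouring same-strand genes
#'   are likely co-transcribed.
#' @return A tibble of operon calls, one row per call: `genome_id`,
#'   `contig`, `operon_id`, `strand`, `n_genes`, `span_start`, `span_end`,
#'   `merged` (always `FALSE` here; see [merge_operons()]), plus
#'   list-columns `loci`, `families` and `gaps` (the `n_genes - 1`
#'   within-call intergenic distances).
#' @export
predict_operons <- function(ann, linkage_bp = 200L) {
  ann <- validate_annotation(ann)
  ann |>
    group_by(.data$genome_id, .data$contig) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(
      gap_prev = .data$start - dplyr::lag(.data$end) - 1L,
      new_run = is.na(.data$gap_prev) |
        .data$strand != dplyr::lag(.data$strand) |
        .data$gap_prev >= linkage_bp,
      run = cumsum(.data$new_run)
    ) |>
    group_by(.data$genome_id, .data$contig, .data$run) |>
    summarise(
      strand = .data$strand[1L],
      n_genes = n(),
      span_start = min(.data$start), span_end = max(.data$end),
      loci = list(.data$locus_id),
      families = list(.data$family),
      gaps = list(.data$gap_prev[-1L]),
      .groups = "drop"
    ) |>
    group_by(.data$genome_id) |>
    mutate(operon_id = sprintf("%s_op%03d", .data$genome_id, row_number()),
           merged = FALSE) |>
    ungroup() |>
    select("genome_id", "contig", "operon_id", "strand", "n_genes",
           "span_start", "span_end", "merged", "loci", "families", "gaps")
}

#' Merge adjacent operon calls separated by very short gaps
#'
#' Applies the secondary rule used when reconciling externally predicted
#' operons (e.g. a database's calls that split a cluster in two): two
#' adjacent calls on the same contig and strand whose boundary gap is
#' strictly below `merge_bp` are joined into one call flagged `merged`.
#'
#' @param calls An operon-call tibble ([predict_operons()] output or an
#'   external table of the same shape).
#' @param merge_bp Merge threshold in bp, strict; default 100.
#' @return An operon-call tibble of the same shape.
#' @export
merge_operons <- function(calls, merge_bp = 100L) {
  calls |>
    group_by(.data$genome_id, .data$contig) |>
    arrange(.data$span_start, .by_group = TRUE) |>
    mutate(
      boundary_gap = .data$span_start - dplyr::lag(.data$span_end) - 1L,
      join = !is.na(.data$boundary_gap) & .data$boundary_gap < merge_bp &
        .data$strand == dplyr::lag(.data$strand),
      grp = cumsum(!.data$join)
    ) |>
    group_by(.data$genome_id, .data$contig, .data$grp) |>
    summarise(
      operon_id = .data$operon_id[1L],
      strand = .data$strand[1L],
      n_genes = sum(.data$n_genes),
      span_start = min(.data$span_start), span_end = max(.data$span_end),
      merged = n() > 1L | any(.data$merged),
      loci = list(unlist(.data$loci)),
      families = list(unlist(.data$families)),
      gaps = list(.interleave_gaps(.data$gaps, .data$boundary_gap)),
      .groups = "drop"
    ) |>
    select("genome_id", "contig", "operon_id", "strand", "n_genes",
           "span_start", "span_end", "merged", "loci", "families", "gaps")
}

# within-call gaps of merged calls, with boundary gaps interleaved
.interleave_gaps <- function(gaps, boundary) {
  out <- gaps[[1L]]
  for (i in seq2(2L, length(gaps))) {
    out <- c(out, boundary[i], gaps[[i]])
  }
  as.integer(out)
}

#' Extract the gene neighborhood around an anchor family
#'
#' Returns up to `k` genes on each side of every occurrence of
#' `anchor_family`, in genomic order, with orientation normalised so the
#' anchor reads left-to-right on the `+` strand: for a `-`-strand anchor
#' the gene order is reversed and strands flipped, so "downstream" always
#' means 3' of the anchor.
#'
#' @param ann Genome annotation tibble.
#' @param anchor_family Family label of the anchor gene.
#' @param k Genes to report on each side (default 3).
#' @return A tibble with columns `genome_id`, `anchor_locus`, `offset`
#'   (-k..k; 0 is the anchor), `locus_id`, `family`, `strand` (normalised)
#'   and `gap` (intergenic distance to the previous gene in normalised
#'   order; `NA` for the first).  Genomes lacking the anchor contribute no
#'   rows and are recorded in the `missing_genomes` attribute.
#' @export
extract_neighborhood <- function(ann, anchor_family, k = 3L) {
  ann <- validate_annotation(ann)
  genomes <- unique(ann$genome_id)
  out <- purrr::map_dfr(genomes, function(g) {
    sub <- filter(ann, .data$genome_id == g)
    anchors <- which(sub$family == anchor_family)
    purrr::map_dfr(anchors, function(i) {
      ctg <- sub$contig[i]
      rows <- which(sub$contig == ctg)
      pos <- match(i, rows)
      idx <- rows[seq2(max(1L, pos - k), min(length(rows), pos + k))]
      nb <- sub[idx, ]
      off <- seq_along(idx) - match(i, idx)
      gap <- nb$start - dplyr::lag(nb$end) - 1L
      if (sub$strand[i] == "-") {
        nb <- nb[rev(seq_len(nrow(nb))), ]
        off <- rev(-off)
        gap <- rev(c(gap[-1L], NA_integer_))
        nb$strand <- ifelse(nb$strand == "+", "-", "+")
      }
      tibble(genome_id = g, anchor_locus = sub$locus_id[i],
             offset = off, locus_id = nb$locus_id, family = nb$family,
             strand = nb$strand, gap = as.integer(gap))
    })
  })
  if (nrow(out) == 0L) {
    out <- tibble(genome_id = character(), anchor_locus = character(),
                  offset = integer(), locus_id = character(),
                  family = character(), strand = character(),
                  gap = integer())
  }
  missing <- setdiff(genomes, unique(out$genome_id))
  if (length(missing) > 0L) {
    warn(sprintf("anchor family '%s' absent from %d genome(s): %s",
                 anchor_family, length(missing),
                 paste(missing, collapse = ", ")))
  }
  attr(out, "missing_genomes") <- missing
  attr(out, "anchor_family") <- anchor_family
  out
}

#' Compare gene-order arrangements across genomes
#'
#' A genome matches when its ordered (family, strand) tuple over the
#' reference window — by default offsets `0 .. nrow(reference) - 1`, i.e.
#' the anchor and its downstream genes — equals the reference arrangement
#' exactly.  A zero-length reference matches every genome vacuously.
#' Genomes lacking the anchor (the `missing_genomes` attribute of
#' [extract_neighborhood()]) count in the total but never match.
#'
#' @param neighborhoods Output of [extract_neighborhood()].
#' @param reference A data frame with columns `family` and `strand`, in
#'   gene order, defining the arrangement to match.
#' @param offsets Neighborhood offsets compared against the reference rows;
#'   default `0:(nrow(reference) - 1)`.
#' @return A tibble of class `arrangement_summary` with one row per genome
#'   (`genome_id`, `match`); attributes `n_match`, `n_total` and
#'   `reference` carry the counts, also available via [glance()].
#' @export
compare_arrangements <- function(neighborhoods, reference,
                                 offsets = seq_len(nrow(reference)) - 1L) {
  stopifnot(all(c("family", "strand") %in% names(reference)))
  key <- paste(reference$family, reference$strand, sep = "/")
  per <- neighborhoods |>
    group_by(.data$genome_id, .data$anchor_locus) |>
    summarise(match = {
      sel <- match(offsets, .data$offset)
      tup <- paste(.data$family[sel], .data$strand[sel], sep = "/")
      length(key) == 0L ||
        (!anyNA(sel) && length(tup) == length(key) && all(tup == key))
    }, .groups = "drop") |>
    group_by(.data$genome_id) |>
    summarise(match = any(.data$match), .groups = "drop")
  missing <- attr(neighborhoods, "missing_genomes") %||% character(0)
  if (length(missing) > 0L) {
    per <- bind_rows(per, tibble(genome_id = missing,
                                 match = length(key) == 0L))
  }
  per <- arrange(per, .data$genome_id)
  class(per) <- c("arrangement_summary", class(per))
  attr(per, "n_match") <- sum(per$match)
  attr(per, "n_total") <- nrow(per)
  attr(per, "reference") <- as_tibble(reference[c("family", "strand")])
  per
}
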