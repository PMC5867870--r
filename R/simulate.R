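#' Configuration for a simulated protein-family alignment
#'
#' The generator emulates the sequence structure of a protein family in
#' which a clade-restricted indel sits inside conserved flanking sequence:
#' a fraction of columns is held invariant across every sequence (the
#' conserved backbone shared by in- and out-group, including a forced
#' invariant run on each side of the indel), the remaining columns carry
#' i.i.d. per-sequence substitutions, and the planted indel appears as
#' residues in the in-group against gap columns in the out-group
#' (insertion) or the converse (deletion).
#'
#' Defaults describe the study conditions used throughout the package's
#' verification: 24 in-group vs 12 out-group sequences, a 600-residue
#' reference, half of the columns invariant, 30% per-sequence substitution
#' probability at variable columns, and a 30-residue insertion.
#'
#' @param seed Integer seed; the generator is a pure function of the
#'   config including the seed.
#' @param n_ingroup,n_outgroup Sequence counts (each >= 2).
#' @param protein_length Ungapped length of the in-group reference protein.
#' @param conserved_fraction Fraction of columns held invariant.
#' @param substitution_prob Per-sequence replacement probability at each
#'   variable column.
#' @param indel_type `"insertion"`, `"deletion"`, or `"none"` (a null
#'   family with no group-differential indel).
#' @param indel_length Planted indel size in residues.
#' @param indel_position 1-based reference position of the indel (for an
#'   insertion, its first residue; for a deletion, the last reference
#'   residue before the missing block).  Default: centred.
#' @param ragged_range Optional `c(min, max)`: per-in-group-sequence
#'   insertion lengths drawn uniformly from the range (gap-padded right),
#'   producing a size range as seen in ragged clade indels.
#' @param flank_conserved_run Columns forced invariant on each side of the
#'   indel (default 6).
#' @param shared_gap_length When > 0 (used for null families), a gap block
#'   of this length is planted at a random location in a random subset of
#'   sequences from *both* groups — alignment noise that must not be
#'   called as a signature.
#' @return A list of class `family_sim_config`.
#' @export
family_sim_config <- function(seed = 1L,
                              n_ingroup = 24L, n_outgroup = 12L,
                              protein_length = 600L,
                              conserved_fraction = 0.5,
                              substitution_prob = 0.3,
                              indel_type = c("insertion", "deletion", "none"),
                              indel_length = 30L,
                              indel_position = NULL,
                              ragged_range = NULL,
                              flank_conserved_run = 6L,
                              shared_gap_length = 0L) {
  indel_type <- match.arg(indel_type)
  cfg <- list(seed = as.integer(seed),
              n_ingroup = as.integer(n_ingroup),
              n_outgroup = as.integer(n_outgroup),
              protein_length = as.integer(protein_length),
              conserved_fraction = conserved_fraction,
              substitution_prob = substitution_prob,
              indel_type = indel_type,
              indel_length = as.integer(indel_length),
              indel_position = indel_position,
              ragged_range = ragged_range,
              flank_conserved_run = as.integer(flank_conserved_run),
              shared_gap_length = as.integer(shared_gap_length))
  if (cfg$n_ingroup < 2L || cfg$n_outgroup < 2L) {
    abort("need at least 2 sequences per group",
          class = "csidetect_config_error")
  }
  if (indel_type != "none") {
    if (is.null(cfg$indel_position)) {
      cfg$indel_position <- as.integer(cfg$protein_length %/% 2L)
    }
    cfg$indel_position <- as.integer(cfg$indel_position)
    lo <- cfg$flank_conserved_run + 1L
    hi <- if (indel_type == "insertion")
      cfg$protein_length - cfg$indel_length - cfg$flank_conserved_run + 1L
    else cfg$protein_length - cfg$flank_conserved_run
    if (cfg$indel_position < lo || cfg$indel_position > hi) {
      abort("indel does not fit inside the protein with its flanks",
            class = "csidetect_config_error")
    }
    if (!is.null(ragged_range) &&
        (length(ragged_range) != 2L || ragged_range[1L] > ragged_range[2L] ||
         ragged_range[2L] != cfg$indel_length)) {
      abort("ragged_range must be c(min, max) with max == indel_length",
            class = "csidetect_config_error")
    }
  }
  structure(cfg, class = "family_sim_config")
}

#' Simulate a protein-family alignment with a planted indel
#'
#' Deterministic for a given config ([family_sim_config()]).  Returns the
#' alignment, the taxon partition (reference = first in-group sequence),
#' and a ground-truth list sufficient to verify any detection output
#' exactly: the indel's alignment columns, reference span, per-sequence
#' sizes and the invariant-column set.
#'
#' @param cfg A [family_sim_config()].
#' @return A list with elements `alignment`, `partition`, `truth`.
#' @export
sim_family_alignment <- function(cfg) {
  stopifnot(inherits(cfg, "family_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  n <- cfg$n_ingroup + cfg$n_outgroup
  ig_rows <- seq_len(cfg$n_ingroup)
  og_rows <- cfg$n_ingroup + seq_len(cfg$n_outgroup)

  if (cfg$indel_type == "insertion") {
    ncol <- cfg$protein_length
    indel_cols <- seq2(cfg$indel_position,
                       cfg$indel_position + cfg$indel_length - 1L)
  } else if (cfg$indel_type == "deletion") {
    ncol <- cfg$protein_length + cfg$indel_length
    indel_cols <- seq2(cfg$indel_position + 1L,
                       cfg$indel_position + cfg$indel_length)
  } else {
    ncol <- cfg$protein_length
    indel_cols <- integer(0)
  }

  base <- sample(AA_LETTERS, ncol, replace = TRUE)
  m <- matrix(rep(base, each = n), nrow = n)

  # invariant backbone: forced runs flanking the indel, plus random columns
  forced <- if (length(indel_cols) > 0L) {
    c(seq2(min(indel_cols) - cfg$flank_conserved_run, min(indel_cols) - 1L),
      seq2(max(indel_cols) + 1L, max(indel_cols) + cfg$flank_conserved_run))
  } else integer(0)
  forced <- forced[forced >= 1L & forced <= ncol]
  n_conserved <- round(cfg$conserved_fraction * ncol)
  pool <- setdiff(seq_len(ncol), c(indel_cols, forced))
  extra <- sample(pool, max(0L, min(length(pool), n_conserved - length(forced))))
  conserved_cols <- sort(c(forced, extra))
  variable_cols <- setdiff(seq_len(ncol), c(conserved_cols, indel_cols))

  # i.i.d. substitutions at variable columns
  for (j in variable_cols) {
    hit <- stats::runif(n) < cfg$substitution_prob
    if (any(hit)) {
      m[hit, j] <- vapply(m[hit, j, drop = TRUE], function(r)
        sample(setdiff(AA_LETTERS, r), 1L), character(1L))
    }
  }

  sizes <- stats::setNames(integer(n), NULL)
  if (cfg$indel_type == "insertion") {
    m[og_rows, indel_cols] <- GAP
    if (!is.null(cfg$ragged_range)) {
      lens <- resample(seq2(cfg$ragged_range[1L], cfg$ragged_range[2L]),
                       cfg$n_ingroup, replace = TRUE)
      lens[1L] <- cfg$ragged_range[2L]  # reference keeps the full insert
      for (r in ig_rows) {
        drop <- seq2(min(indel_cols) + lens[r], max(indel_cols))
        m[r, drop] <- GAP
      }
    }
  } else if (cfg$indel_type == "deletion") {
    m[ig_rows, indel_cols] <- GAP
  }
  if (cfg$shared_gap_length > 0L) {
    s <- sample(seq_len(ncol - cfg$shared_gap_length + 1L), 1L)
    block <- s:(s + cfg$shared_gap_length - 1L)
    gapped <- stats::runif(n) < 0.5
    m[gapped, block] <- GAP
  }

  ids <- c(sprintf("ing%02d", ig_rows), sprintf("out%02d", seq_len(cfg$n_outgroup)))
  taxa <- c(sprintf("Cladeus ingroupii strain %d", ig_rows),
            sprintf("Extera outgroupii strain %d", seq_len(cfg$n_outgroup)))
  aln <- alignment(ids, apply(m, 1L, paste, collapse = ""), taxa)
  part <- taxon_partition(ids[ig_rows], ids[og_rows], ids[1L])

  truth <- list(
    seed = cfg$seed,
    indel_type = cfg$indel_type,
    col_start = if (length(indel_cols)) min(indel_cols) else NA_integer_,
    col_end = if (length(indel_cols)) max(indel_cols) else NA_integer_,
    ref_start = if (cfg$indel_type == "insertion") cfg$indel_position
      else if (cfg$indel_type == "deletion") cfg$indel_position
      else NA_integer_,
    ref_end = if (cfg$indel_type == "insertion")
      cfg$indel_position + cfg$indel_length - 1L
      else if (cfg$indel_type == "deletion") cfg$indel_position
      else NA_integer_,
    size_min = if (cfg$indel_type == "none") NA_integer_ else
      if (!is.null(cfg$ragged_range)) min(rowSums(m[ig_rows, indel_cols,
                                                    drop = FALSE] != GAP))
      else cfg$indel_length,
    size_max = if (cfg$indel_type == "none") NA_integer_ else cfg$indel_length,
    conserved_cols = conserved_cols
  )
  list(alignment = aln, partition = part, truth = truth)
}

#' Configuration for a simulated genome set
#'
#' Emulates a conserved same-strand gene cluster (anchor plus downstream
#' partners with small intergenic gaps) present in a subset of genomes,
#' against a background of unrelated genes separated by operon-breaking
#' distances.  Genomes without the full cluster keep the anchor but carry
#' a substituted partner gene, so their arrangement tuple differs.
#'
#' @param seed Integer seed.
#' @param n_genomes Number of genomes (default 26).
#' @param n_with_cluster Genomes carrying the intact cluster (default 24).
#' @param cluster_families Data frame with columns `family`, `strand`
#'   giving the cluster in gene order; default the four-gene layout
#'   `uvrA1 (+), dCSP-1 (+), dsbA (+), dsbB (+)`.
#' @param intergenic_gap_range Within-cluster intergenic gaps, bp,
#'   inclusive (default 5--99: comfortably inside operon linkage).
#' @param overlap_gap Optional negative gap planted between the last two
#'   cluster genes of every cluster genome (overlapping coding regions).
#' @param background_genes_per_genome Unrelated genes per genome
#'   (default 6).
#' @param background_gap_range Gaps around/between background genes, bp
#'   (default 200--800: at or above operon linkage, so background never
#'   joins the cluster call).
#' @return A list of class `genome_sim_config`.
#' @export
genome_sim_config <- function(seed = 1L, n_genomes = 26L,
                              n_with_cluster = 24L,
                              cluster_families = NULL,
                              intergenic_gap_range = c(5L, 99L),
                              overlap_gap = NULL,
                              background_genes_per_genome = 6L,
                              background_gap_range = c(200L, 800L)) {
  cluster_families <- cluster_families %||% tibble(
    family = c("uvrA1", "dCSP-1", "dsbA", "dsbB"),
    strand = "+")
  cfg <- list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
              n_with_cluster = as.integer(n_with_cluster),
              cluster_families = as_tibble(cluster_families),
              intergenic_gap_range = as.integer(intergenic_gap_range),
              overlap_gap = if (is.null(overlap_gap)) NULL else
                as.integer(overlap_gap),
              background_genes_per_genome =
                as.integer(background_genes_per_genome),
              background_gap_range = as.integer(background_gap_range))
  if (cfg$n_with_cluster > cfg$n_genomes) {
    abort("n_with_cluster must be <= n_genomes",
          class = "csidetect_config_error")
  }
  if (nrow(cfg$cluster_families) < 2L) {
    abort("cluster needs at least 2 genes", class = "csidetect_config_error")
  }
  structure(cfg, class = "genome_sim_config")
}

#' Simulate a set of annotated genomes with a planted gene cluster
#'
#' Deterministic for a given config ([genome_sim_config()]).  Coordinates
#' are laid out gene by gene left to right, so planted gaps are exact by
#' construction.
#'
#' @param cfg A [genome_sim_config()].
#' @return A list with `annotations` (one tibble over all genomes) and
#'   `truth` (per-genome tibble: `genome_id`, `has_cluster`, plus a `gaps`
#'   list-column of the planted within-cluster gaps).
#' @export
sim_genome_set <- function(cfg) {
  stopifnot(inherits(cfg, "genome_sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  fams <- cfg$cluster_families
  k <- nrow(fams)
  res <- purrr::map(seq_len(cfg$n_genomes), function(g) {
    gid <- sprintf("genome%02d", g)
    has_cluster <- g <= cfg$n_with_cluster
    cl_fams <- fams$family
    cl_strands <- fams$strand
    if (!has_cluster) {
      # substitute one non-anchor partner, breaking the arrangement
      i <- sample(2:k, 1L)
      cl_fams[i] <- sprintf("sub%02d", g)
    }
    nb <- cfg$background_genes_per_genome
    n_before <- nb %/% 2L
    fam_all <- c(sprintf("bg%02d_%02d", g, seq_len(n_before)),
                 cl_fams,
                 sprintf("bg%02d_%02d", g, n_before + seq_len(nb - n_before)))
    strand_all <- c(sample(c("+", "-"), n_before, replace = TRUE),
                    cl_strands,
                    sample(c("+", "-"), nb - n_before, replace = TRUE))
    in_cluster <- seq2(n_before + 1L, n_before + k)
    ngene <- length(fam_all)
    glen <- sample(300:2500, ngene, replace = TRUE)
    cluster_gaps <- resample(
      seq2(cfg$intergenic_gap_range[1L], cfg$intergenic_gap_range[2L]),
      k - 1L, replace = TRUE)
    if (!is.null(cfg$overlap_gap)) cluster_gaps[k - 1L] <- cfg$overlap_gap
    gaps <- integer(ngene)  # gap preceding each gene; gaps[1] unused
    for (j in 2:ngene) {
      gaps[j] <- if (j %in% in_cluster[-1L]) {
        cluster_gaps[match(j, in_cluster) - 1L]
      } else {
        resample(seq2(cfg$background_gap_range[1L],
                      cfg$background_gap_range[2L]), 1L)
      }
    }
    start <- integer(ngene); end <- integer(ngene)
    start[1L] <- sample(1:1000, 1L)
    end[1L] <- start[1L] + glen[1L] - 1L
    for (j in 2:ngene) {
      start[j] <- end[j - 1L] + gaps[j] + 1L
      end[j] <- start[j] + glen[j] - 1L
    }
    list(
      ann = tibble(genome_id = gid, contig = paste0(gid, "_c1"),
                   locus_id = sprintf("%s_g%03d", gid, seq_len(ngene)),
                   family = fam_all, strand = strand_all,
                   start = start, end = end),
      truth = tibble(genome_id = gid, has_cluster = has_cluster,
                     gaps = list(cluster_gaps),
                     cluster_loci = list(sprintf("%s_g%03d", gid, in_cluster)))
    )
  })
  list(annotations = validate_annotation(bind_rows(purrr::map(res, "ann"))),
       truth = bind_rows(purrr::map(res, "truth")))
}

#' Simulate a proteome with planted CXXC motif counts
#'
#' Background residues are drawn with cysteine excluded, and each planted
#' motif contributes exactly two cysteines three residues apart with
#' non-cysteine middle positions; motif starts are spaced at least 8
#' residues apart, so the planted count is the true count under every
#' scanning policy (overlapping or not, strict or not).
#'
#' @param spec Data frame with columns `id`, `length`, `n_motifs`.
#' @param seed Integer seed.
#' @return A list with `proteins` (tibble `id`, `seq`) and `truth` (the
#'   spec with a `positions` list-column of planted motif starts).
#' @export
sim_proteome_with_motifs <- function(spec, seed = 1L) {
  stopifnot(all(c("id", "length", "n_motifs") %in% names(spec)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  bg <- setdiff(AA_LETTERS, "C")
  rows <- purrr::pmap(spec[c("id", "length", "n_motifs")],
                      function(id, length, n_motifs) {
    L <- as.integer(length); nm <- as.integer(n_motifs)
    if (nm > 0L && (L - 3L - (nm - 1L) * 7L) < nm) {
      abort(sprintf("protein '%s' too short for %d disjoint motifs", id, nm),
            class = "csidetect_config_error")
    }
    ch <- sample(bg, L, replace = TRUE)
    pos <- integer(0)
    if (nm > 0L) {
      # sorted draws + spreading guarantee pairwise spacing >= 8
      x <- sort(sample(L - 3L - (nm - 1L) * 7L, nm))
      pos <- x + (seq_len(nm) - 1L) * 7L
      for (p in pos) {
        ch[p] <- "C"; ch[p + 3L] <- "C"
      }
    }
    list(protein = tibble(id = id, seq = paste(ch, collapse = "")),
         truth = tibble(id = id, length = L, n_motifs = nm,
                        positions = list(pos)))
  })
  list(proteins = bind_rows(purrr::map(rows, "protein")),
       truth = bind_rows(purrr::map(rows, "truth")))
}

# sample() from a vector without the scalar-x surprise
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
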