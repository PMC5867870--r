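# hand-built family: identical conserved background with a block that the
# out-group lacks — the minimal CSI-bearing alignment
block_aln <- function(n_in = 4L, n_out = 3L, L = 100L, s = 41L, e = 70L,
                      ragged = NULL) {
  set.seed(7)
  base <- paste(sample(c("A", "D", "E", "K", "L", "R"), L, replace = TRUE),
                collapse = "")
  gap_block <- function(x, a, b) {
    paste0(substr(x, 1L, a - 1L), strrep("-", b - a + 1L),
           substr(x, b + 1L, nchar(x)))
  }
  ins <- vapply(seq_len(n_in), function(i) {
    if (is.null(ragged)) base else {
      keep <- ragged[i]
      gap_block(base, s + keep, e)
    }
  }, character(1L))
  outs <- rep(gap_block(base, s, e), n_out)
  ids <- c(sprintf("in%d", seq_len(n_in)), sprintf("out%d", seq_len(n_out)))
  list(aln = alignment(ids, c(ins, outs)),
       part = taxon_partition(ids[seq_len(n_in)],
                              ids[n_in + seq_len(n_out)]))
}

test_that("find_gap_blocks locates a constructed differential block", {
  fx <- block_aln()
  cand <- find_gap_blocks(fx$aln, fx$part)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$indel_type, "insertion")
  expect_equal(c(cand$col_start, cand$col_end), c(41L, 70L))
  expect_equal(c(cand$size_min, cand$size_max), c(30L, 30L))
})

test_that("ragged in-group inserts report a size range", {
  # in-group sequences keep 5, 7, 6 and 7 residues of a 7-column insert;
  # the ragged tail columns are gapped in part of the in-group, so the
  # "most members" tolerance must be open for them to join the block
  fx <- block_aln(n_in = 4L, s = 41L, e = 47L, ragged = c(5L, 7L, 6L, 7L))
  cand <- find_gap_blocks(fx$aln, fx$part,
                          detection_params(max_ingroup_missing = 0.5))
  expect_equal(nrow(cand), 1L)
  expect_equal(c(cand$col_start, cand$col_end), c(41L, 47L))
  expect_equal(c(cand$size_min, cand$size_max), c(5L, 7L))
  # under the strict all-members rule only the shared 5-column core remains
  strict <- find_gap_blocks(fx$aln, fx$part)
  expect_equal(c(strict$col_start, strict$col_end), c(41L, 45L))
})

test_that("alignments without group-differential columns yield no candidates", {
  aln <- make_aln(a = "MKVLT", b = "MKVLT", c = "MKVLT", d = "MKVLT")
  part <- taxon_partition(c("a", "b"), c("c", "d"))
  expect_equal(nrow(find_gap_blocks(aln, part)), 0L)
  expect_equal(nrow(detect_csis(aln, part)), 0L)
})

test_that("find_gap_blocks equals the brute-force interval oracle", {
  set.seed(11)
  params_pool <- list(
    detection_params(),
    detection_params(max_ingroup_missing = 0.34, max_outgroup_sharing = 0.34),
    detection_params(min_indel_size = 2L, max_indel_size = 10L)
  )
  for (i in 1:40) {
    ra <- random_alignment()
    params <- params_pool[[sample(3L, 1L)]]
    got <- find_gap_blocks(ra$aln, ra$part, params)[
      c("indel_type", "col_start", "col_end", "size_min", "size_max")]
    exp <- oracle_gap_blocks(ra$aln, ra$part, params)
    if (nrow(exp) == 0L) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(as.data.frame(got), as.data.frame(exp))
    }
  }
})

test_that("flank evaluation counts conserved columns within the window", {
  fx <- block_aln()  # fully identical background: every flank column conserved
  cand <- find_gap_blocks(fx$aln, fx$part)
  fl <- evaluate_flanks(fx$aln, cand, fx$part)
  expect_true(fl$pass)
  expect_equal(fl$left_count, 35L)   # window capped at 35
  expect_equal(fl$right_count, 30L)  # truncated by the alignment end
})

test_that("flank pass sits exactly at the min_conserved_flank boundary", {
  # variable left flank with an exact number of invariant columns
  set.seed(13)
  n <- 6L
  left_cons <- 5L
  make <- function(n_cons) {
    L <- 35L
    cols <- matrix("", n, L + 10L)
    cons_at <- sample(L, n_cons)
    for (j in seq_len(L)) {
      cols[, j] <- if (j %in% cons_at) "A" else
        sample(c("D", "E", "K", "L", "R", "S"), n, replace = TRUE)
    }
    # candidate block: columns L+1..L+4, in-group only
    for (j in (L + 1L):(L + 4L)) cols[, j] <- c(rep("G", 3L), rep("-", 3L))
    for (j in (L + 5L):(L + 10L)) cols[, j] <- "W"  # conserved right flank
    ids <- sprintf("s%d", 1:n)
    list(aln = alignment(ids, apply(cols, 1L, paste, collapse = "")),
         part = taxon_partition(ids[1:3], ids[4:6]))
  }
  params <- detection_params(min_conserved_flank = 5L)
  fx5 <- make(5L)
  cand <- find_gap_blocks(fx5$aln, fx5$part, params)
  expect_true(evaluate_flanks(fx5$aln, cand, fx5$part, params)$pass)
  fx4 <- make(4L)
  cand4 <- find_gap_blocks(fx4$aln, fx4$part, params)
  fl4 <- evaluate_flanks(fx4$aln, cand4, fx4$part, params)
  expect_false(fl4$pass)
  expect_equal(fl4$left_count, 4L)
})

test_that("a candidate at the alignment edge fails its truncated flank", {
  aln <- alignment(c("a", "b", "c", "d"),
                   c("GGGAAAAAAA", "GGGAAAAAAA", "---AAAAAAA", "---AAAAAAA"))
  part <- taxon_partition(c("a", "b"), c("c", "d"))
  cand <- find_gap_blocks(aln, part)
  expect_equal(cand$col_start, 1L)
  fl <- evaluate_flanks(aln, cand, part)
  expect_equal(fl$left_count, 0L)
  expect_false(fl$pass)
})

test_that("specificity verdicts: strict, isolated exception, rejected", {
  base <- strrep("A", 20L)
  gap <- paste0(strrep("A", 8L), "----", strrep("A", 8L))
  ids <- sprintf("s%02d", 1:36)
  mk <- function(n_out_sharing) {
    seqs <- c(rep(base, 24L),                       # in-group carries block
              rep(base, n_out_sharing),             # sharing out-group
              rep(gap, 12L - n_out_sharing))
    list(aln = alignment(ids, seqs),
         part = taxon_partition(ids[1:24], ids[25:36]))
  }
  cand <- tibble::tibble(indel_type = "insertion", col_start = 9L,
                         col_end = 12L)
  s0 <- mk(0L)
  expect_equal(evaluate_specificity(s0$aln, cand, s0$part)$verdict, "strict")
  s1 <- mk(1L)
  sp1 <- evaluate_specificity(s1$aln, cand, s1$part,
                              detection_params(allow_isolated_exception = TRUE))
  expect_equal(sp1$verdict, "tolerant")
  expect_equal(sp1$exceptions[[1L]], "s25")
  expect_equal(evaluate_specificity(s1$aln, cand, s1$part)$verdict, "rejected")
  s3 <- mk(3L)
  sp3 <- evaluate_specificity(s3$aln, cand, s3$part,
                              detection_params(allow_isolated_exception = TRUE))
  expect_equal(sp3$verdict, "rejected")
})

test_that("detect_csis recovers a planted insertion with exact size and position", {
  sim <- sim_family_alignment(family_sim_config(
    seed = 101, protein_length = 400L, indel_length = 16L,
    indel_position = 180L))
  r <- detect_csis(sim$alignment, sim$partition, protein = "UvrC-like")
  expect_equal(nrow(r), 1L)
  expect_equal(r$indel_type, "insertion")
  expect_equal(c(r$size_min, r$size_max), c(16L, 16L))
  expect_equal(r$indel_start, sim$truth$ref_start)
  expect_equal(r$indel_end, sim$truth$ref_end)
  expect_equal(r$specificity, "strict")
  # the reported region brackets the indel
  expect_lte(r$region_start, r$indel_start)
  expect_gte(r$region_end, r$indel_end)
})

test_that("deletions are reported with sizes from the residue-bearing out-group", {
  sim <- sim_family_alignment(family_sim_config(
    seed = 55, protein_length = 300L, indel_type = "deletion",
    indel_length = 2L, indel_position = 140L))
  r <- detect_csis(sim$alignment, sim$partition)
  expect_equal(nrow(r), 1L)
  expect_equal(r$indel_type, "deletion")
  expect_equal(c(r$size_min, r$size_max), c(2L, 2L))
  expect_equal(r$indel_start, 140L)
})

test_that("validation segments are centred, bounded and truncated correctly", {
  sim <- sim_family_alignment(family_sim_config(
    seed = 31, protein_length = 500L, indel_length = 30L,
    indel_position = 100L))
  r <- detect_csis(sim$alignment, sim$partition)
  seg <- export_validation_segment(sim$alignment, r[1L, ], sim$partition,
                                   detection_params(validation_segment_length = 80L))
  expect_equal(seg$end - seg$start + 1L, 80L)
  expect_lte(seg$start, r$indel_start)
  expect_gte(seg$end, r$indel_end)
  expect_equal(nchar(seg$seq), 80L)
  expect_equal(seg$seq,
               substr(reference_sequence(sim$alignment, "ing01"),
                      seg$start, seg$end))
  # indel near the protein start: left-truncated but still covers the indel
  sim2 <- sim_family_alignment(family_sim_config(
    seed = 32, protein_length = 500L, indel_length = 30L,
    indel_position = 10L))
  r2 <- detect_csis(sim2$alignment, sim2$partition)
  seg2 <- export_validation_segment(sim2$alignment, r2[1L, ], sim2$partition)
  expect_equal(seg2$start, 1L)
  expect_gte(seg2$end, r2$indel_end)
  # protein shorter than the requested segment: whole protein
  fx <- block_aln(L = 50L, s = 21L, e = 24L)
  cand <- find_gap_blocks(fx$aln, fx$part)
  csi <- tibble::tibble(protein = "p", indel_type = "insertion",
                        indel_start = 21L, indel_end = 24L)
  seg3 <- export_validation_segment(fx$aln, csi, fx$part)
  expect_equal(c(seg3$start, seg3$end), c(1L, 50L))
})

test_that("raising thresholds never increases the number of emitted CSIs", {
  set.seed(77)
  seeds <- sample(1e6, 6L)
  for (sd in seeds) {
    sim <- sim_family_alignment(family_sim_config(
      seed = sd, protein_length = 300L, indel_length = 16L,
      indel_position = 150L, substitution_prob = 0.4))
    n_base <- nrow(detect_csis(sim$alignment, sim$partition,
                               detection_params(conservation_threshold = 0.7)))
    n_hi <- nrow(detect_csis(sim$alignment, sim$partition,
                             detection_params(conservation_threshold = 0.95)))
    expect_lte(n_hi, n_base)
    n_flank <- nrow(detect_csis(sim$alignment, sim$partition,
                                detection_params(min_conserved_flank = 20L)))
    expect_lte(n_flank, n_base)
  }
})

test_that("detection parameter validation catches bad settings", {
  expect_error(detection_params(flank_window = 3L, min_conserved_flank = 5L),
               class = "csidetect_parameter_error")
  expect_error(detection_params(max_ingroup_missing = 1.5),
               class = "csidetect_parameter_error")
  expect_warning(p <- detection_params(validation_segment_length = 120L),
                 "clamped")
  expect_equal(p$validation_segment_length, 100L)
  fx <- block_aln()
  bad_part <- taxon_partition("zz", "yy")
  expect_error(find_gap_blocks(fx$aln, bad_part),
               class = "csidetect_partition_error")
})
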