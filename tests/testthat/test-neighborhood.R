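# minimal four-gene annotation: the classical anchor + three downstream
# partners on one strand with operon-scale gaps (49, 12, 80 bp)
cluster_ann <- function(gaps = c(49L, 12L, 80L), strands = rep("+", 4L),
                        genome = "g1") {
  fams <- c("uvrA1", "dCSP-1", "dsbA", "dsbB")
  len <- c(2900L, 740L, 620L, 530L)
  start <- integer(4L); end <- integer(4L)
  start[1L] <- 1000L; end[1L] <- start[1L] + len[1L] - 1L
  for (j in 2:4) {
    start[j] <- end[j - 1L] + gaps[j - 1L] + 1L
    end[j] <- start[j] + len[j] - 1L
  }
  tibble::tibble(genome_id = genome, contig = "c1",
                 locus_id = paste0(genome, "_", fams), family = fams,
                 strand = strands, start = start, end = end)
}

test_that("TSV annotations read, sort and validate", {
  ann <- cluster_ann()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(ann[c(3, 1, 4, 2), ], f)   # shuffled: sorted on read
  back <- read_annotation(f, format = "tsv")
  expect_equal(back$locus_id, ann$locus_id)
  expect_equal(back$start, ann$start)

  bad <- ann; bad$end[2L] <- bad$start[2L] - 10L
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(bad, f2)
  expect_error(read_annotation(f2, format = "tsv"),
               class = "csidetect_record_error")
})

test_that("GFF3 annotations preserve strand and take families from the map", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\ttest\tgene\t100\t400\t.\t+\t.\tID=gene1;locus_tag=L001",
    "c1\ttest\tgene\t500\t900\t.\t-\t.\tID=gene2;locus_tag=L002"
  ), f)
  ann <- read_annotation(f, format = "gff3",
                         family_map = c(L001 = "uvrA1", L002 = "dsbA"),
                         genome_id = "gX")
  expect_equal(ann$strand, c("+", "-"))
  expect_equal(ann$family, c("uvrA1", "dsbA"))
  expect_equal(ann$locus_id, c("L001", "L002"))
})

test_that("intergenic distance follows the start(b) - end(a) - 1 convention", {
  g <- function(start, end, contig = "c1")
    tibble::tibble(genome_id = "g", contig = contig, locus_id = "x",
                   family = "x", strand = "+", start = start, end = end)
  expect_equal(intergenic_distance(g(1, 100), g(150, 300)), 49L)
  expect_equal(intergenic_distance(g(1, 100), g(101, 300)), 0L)
  expect_equal(intergenic_distance(g(1, 100), g(90, 300)), -11L)
  expect_error(intergenic_distance(g(1, 100), g(150, 300, contig = "c2")),
               class = "csidetect_comparability_error")
  # translation invariance
  shift <- function(x, c) { x$start <- x$start + c; x$end <- x$end + c; x }
  expect_equal(intergenic_distance(shift(g(1, 100), 5000),
                                   shift(g(150, 300), 5000)), 49L)
})

test_that("operon prediction applies the strand and distance rules", {
  # 4 same-strand genes with gaps 49, 12, 80 -> one operon of four
  ops <- predict_operons(cluster_ann())
  expect_equal(nrow(ops), 1L)
  expect_equal(ops$n_genes, 4L)
  expect_equal(ops$gaps[[1L]], c(49L, 12L, 80L))
  expect_false(ops$merged)
  # a 250 bp gap splits
  ops2 <- predict_operons(cluster_ann(gaps = c(49L, 250L, 80L)))
  expect_equal(ops2$n_genes, c(2L, 2L))
  # overlapping coding regions always link
  ops3 <- predict_operons(cluster_ann(gaps = c(49L, -11L, 80L)))
  expect_equal(nrow(ops3), 1L)
  expect_equal(ops3$gaps[[1L]][2L], -11L)
  # a strand flip breaks the run regardless of distance
  ops4 <- predict_operons(cluster_ann(strands = c("+", "+", "-", "+")))
  expect_equal(nrow(ops4), 3L)
  # exactly-at-threshold gap splits (strict inequality)
  ops5 <- predict_operons(cluster_ann(gaps = c(49L, 200L, 80L)),
                          linkage_bp = 200L)
  expect_equal(nrow(ops5), 2L)
})

test_that("merge rule joins adjacent calls across sub-100 bp boundaries", {
  # two predicted runs split by a 120 bp gap: linkage 100 splits them,
  # the DOOR-style merge under 200 joins them back, flagged
  ann <- cluster_ann(gaps = c(49L, 120L, 80L))
  calls <- predict_operons(ann, linkage_bp = 100L)
  expect_equal(nrow(calls), 2L)
  merged <- merge_operons(calls, merge_bp = 200L)
  expect_equal(nrow(merged), 1L)
  expect_true(merged$merged)
  expect_equal(merged$gaps[[1L]], c(49L, 120L, 80L))
  # boundary at or above merge_bp stays split
  expect_equal(nrow(merge_operons(calls, merge_bp = 100L)), 2L)
})

test_that("operon calls partition the genes and grow with linkage_bp", {
  gs <- sim_genome_set(genome_sim_config(seed = 9, n_genomes = 6L,
                                         n_with_cluster = 5L))
  ann <- gs$annotations
  for (lk in c(50L, 200L, 1000L)) {
    ops <- predict_operons(ann, linkage_bp = lk)
    loci <- unlist(ops$loci)
    expect_setequal(loci, ann$locus_id)       # every gene exactly once
    expect_equal(length(loci), nrow(ann))
  }
  # monotone membership: each operon at a smaller linkage is contained in
  # one operon at a larger linkage
  small <- predict_operons(ann, linkage_bp = 100L)
  large <- predict_operons(ann, linkage_bp = 500L)
  assign_large <- stats::setNames(
    rep(large$operon_id, lengths(large$loci)), unlist(large$loci))
  for (i in seq_len(nrow(small))) {
    expect_equal(length(unique(assign_large[small$loci[[i]]])), 1L)
  }
})

test_that("neighborhood extraction returns the planted downstream partners", {
  gs <- sim_genome_set(genome_sim_config(seed = 3, n_genomes = 4L,
                                         n_with_cluster = 4L))
  nb <- extract_neighborhood(gs$annotations, "uvrA1", k = 3L)
  down <- dplyr::filter(nb, offset %in% 1:3, genome_id == "genome01")
  expect_equal(down$family, c("dCSP-1", "dsbA", "dsbB"))
  expect_equal(down$strand, rep("+", 3L))
  # planted gaps are reported as the intergenic distances
  expect_equal(down$gap, gs$truth$gaps[[1L]])
})

test_that("minus-strand anchors are flipped so downstream means 3-prime", {
  ann <- tibble::tibble(
    genome_id = "g", contig = "c1",
    locus_id = c("l1", "l2", "l3"),
    family = c("after", "anchor", "before"),
    strand = c("-", "-", "+"),
    start = c(100L, 600L, 1200L), end = c(400L, 1000L, 1500L))
  nb <- extract_neighborhood(ann, "anchor", k = 1L)
  expect_equal(nb$offset, c(-1L, 0L, 1L))
  # genomic left of a '-' anchor is its downstream side
  expect_equal(nb$family, c("before", "anchor", "after"))
  expect_equal(nb$strand, c("-", "+", "+"))
  expect_equal(nb$gap[3L], 600L - 400L - 1L)
})

test_that("a missing anchor is reported, not fatal", {
  ann <- cluster_ann()
  expect_warning(nb <- extract_neighborhood(ann, "nonesuch"),
                 "absent")
  expect_equal(nrow(nb), 0L)
  expect_equal(attr(nb, "missing_genomes"), "g1")
})

test_that("arrangement comparison counts exact (family, strand) matches", {
  gs <- sim_genome_set(genome_sim_config(seed = 21, n_genomes = 8L,
                                         n_with_cluster = 6L))
  nb <- extract_neighborhood(gs$annotations, "uvrA1", k = 3L)
  ref <- tibble::tibble(family = c("uvrA1", "dCSP-1", "dsbA", "dsbB"),
                        strand = "+")
  arr <- compare_arrangements(nb, ref)
  expect_equal(glance(arr)$n_match, 6L)
  expect_equal(glance(arr)$n_total, 8L)
  expect_equal(arr$match, gs$truth$has_cluster[order(gs$truth$genome_id)])
  # all genomes identical
  gs2 <- sim_genome_set(genome_sim_config(seed = 22, n_genomes = 5L,
                                          n_with_cluster = 5L))
  nb2 <- extract_neighborhood(gs2$annotations, "uvrA1", k = 3L)
  arr2 <- compare_arrangements(nb2, ref)
  expect_equal(glance(arr2)$n_match, glance(arr2)$n_total)
  # zero-length reference matches vacuously
  arr0 <- compare_arrangements(nb2, ref[0, ])
  expect_true(all(arr0$match))
})
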