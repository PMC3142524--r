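# Builds a 3-genome gapless fixture where gene boundaries can be varied per
# genome, then checks the classification decision table.
classify_fixture <- function(coords, strands = NULL, width = 240L) {
  genomes <- names(coords)
  set.seed(7)
  txt <- paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
               collapse = "")
  b <- fix_block("b1", lapply(genomes, fix_row, text = txt,
                              src_size = width + 50L))
  rows <- do.call(rbind, lapply(genomes, function(g) {
    m <- coords[[g]]
    if (is.null(dim(m))) m <- matrix(m, ncol = 2L)
    data.frame(genome_id = g, start = m[, 1], end = m[, 2],
               n = nrow(m), stringsAsFactors = FALSE)
  }))
  rows$gene_id <- sprintf("%s_x%d", rows$genome_id, stats::ave(
    seq_len(nrow(rows)), rows$genome_id, FUN = seq_along))
  genes <- gene_table(gene_id = rows$gene_id, genome_id = rows$genome_id,
                      contig_id = "c1", start = rows$start, end = rows$end,
                      strand = if (is.null(strands)) "+" else
                        strands[rows$genome_id])
  idx <- build_alignment_index(list(b), genes)
  group <- fix_group("OG00001", genes, genes$gene_id)
  list(index = idx, group = group, genes = genes)
}

test_that("gene termini reflect strand: 5' start base and 3' stop base", {
  b <- fix_block("b1", list(fix_row("g1", paste(rep("A", 10), collapse = ""),
                                    fwd_start = 10L, src_size = 40L)))
  plus <- gene_table("p", "g1", "c1", 10L, 16L, "+")
  minus <- gene_table("m", "g1", "c1", 10L, 16L, "-")
  idx <- build_alignment_index(list(b), rbind(plus, minus))
  tp <- locate_gene_termini(idx, plus[1, ])
  expect_equal(c(tp$start$column, tp$stop$column), c(0L, 5L))
  tm <- locate_gene_termini(idx, minus[1, ])
  expect_equal(c(tm$start$column, tm$stop$column), c(5L, 0L))
})

test_that("termini columns follow gap-skipping projection", {
  b <- fix_block("b1", list(fix_row("g1", "A-CGTT", fwd_start = 10L,
                                    src_size = 40L)))
  g <- gene_table("p", "g1", "c1", 11L, 14L, "+")
  idx <- build_alignment_index(list(b), g)
  # per-base oracle table of the fixture block
  sp <- scan_row_positions(b$rows$g1)
  t <- locate_gene_termini(idx, g[1, ])
  expect_equal(t$start$column, sp$cols[match(11L, sp$pos)] - 1L)
  expect_equal(t$stop$column, sp$cols[match(13L, sp$pos)] - 1L)
})

test_that("the classification decision table is exact", {
  # consistent
  fx <- classify_fixture(list(g1 = c(30, 150), g2 = c(30, 150), g3 = c(30, 150)))
  expect_equal(classify_group(fx$group, fx$index)$class, "consistent")

  # inconsistent starts, sole outlier identified
  fx <- classify_fixture(list(g1 = c(30, 150), g2 = c(30, 150), g3 = c(45, 150)))
  r <- classify_group(fx$group, fx$index)
  expect_equal(r$class, "inconsistent_starts")
  expect_equal(r$sole_outlier_genome, "g3")

  # inconsistent stops
  fx <- classify_fixture(list(g1 = c(30, 150), g2 = c(30, 150), g3 = c(30, 120)))
  expect_equal(classify_group(fx$group, fx$index)$class, "inconsistent_stops")

  # both differ in one genome: combination
  fx <- classify_fixture(list(g1 = c(30, 150), g2 = c(30, 150), g3 = c(45, 120)))
  expect_equal(classify_group(fx$group, fx$index)$class, "combination")

  # opposite strand for one member: combination
  fx <- classify_fixture(list(g1 = c(30, 150), g2 = c(30, 150), g3 = c(30, 150)),
                         strands = c(g1 = "+", g2 = "+", g3 = "-"))
  expect_equal(classify_group(fx$group, fx$index)$class, "combination")

  # two genomes disagreeing differently: no sole outlier
  fx <- classify_fixture(list(g1 = c(30, 150), g2 = c(45, 150), g3 = c(60, 150)))
  r <- classify_group(fx$group, fx$index)
  expect_equal(r$class, "inconsistent_starts")
  expect_true(is.na(r$sole_outlier_genome))
})

test_that("fragmentation is primary when a genome contributes two members", {
  fx <- classify_fixture(list(g1 = c(30, 210), g2 = c(30, 210),
                              g3 = rbind(c(30, 90), c(120, 210))))
  r <- classify_group(fx$group, fx$index)
  expect_equal(r$class, "fragmentation")
  expect_false(is.na(r$secondary_classes))  # boundary comparison retained
  expect_equal(r$sole_outlier_genome, "g3")
})

test_that("singleton groups are classified separately, not as anomalies", {
  fx <- classify_fixture(list(g1 = c(30, 150)))
  g <- fix_group("OG1", fx$genes, "g1_x1")
  expect_equal(classify_group(g, fx$index)$class, "singleton")
})

test_that("contig-boundary flagging uses partial flags and the W window", {
  fx <- classify_fixture(list(g1 = c(30, 150), g2 = c(30, 150)))
  an <- classify_groups(list(fx$group), fx$index)
  genomes <- fix_genomes(list(fx$index$blocks$b1))
  # interior genes: not flagged
  an1 <- flag_contig_boundary(an, list(fx$group), fx$genes, genomes, W = 10L)
  expect_false(an1$contig_boundary)
  # partial3 on one member: flagged
  genes2 <- fx$genes
  genes2$partial3[1] <- TRUE
  an2 <- flag_contig_boundary(an, list(fx$group), genes2, genomes, W = 10L)
  expect_true(an2$contig_boundary)
  # terminus within W of the contig end: flagged (contig len 290, end 285)
  fx3 <- classify_fixture(list(g1 = c(30, 150), g2 = c(165, 285)))
  an3 <- classify_groups(list(fx3$group), fx3$index)
  genomes3 <- fix_genomes(list(fx3$index$blocks$b1))
  expect_true(flag_contig_boundary(an3, list(fx3$group), fx3$genes,
                                   genomes3, W = 10L)$contig_boundary)
  expect_false(flag_contig_boundary(an3, list(fx3$group), fx3$genes,
                                    genomes3, W = 2L)$contig_boundary)
})

test_that("missing annotations require alignment without overlapping genes", {
  width <- 240L
  set.seed(7)
  txt <- paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
               collapse = "")
  b3 <- fix_block("b1", lapply(c("g1", "g2", "g3"), fix_row, text = txt,
                               src_size = width + 50L))
  genes2 <- gene_table(gene_id = c("g1_a", "g2_a"), genome_id = c("g1", "g2"),
                       contig_id = "c1", start = 30L, end = 150L, strand = "+")
  idx <- build_alignment_index(list(b3), genes2)
  grp <- fix_group("OG1", genes2, genes2$gene_id)
  miss <- find_missing_annotations(list(grp), idx)
  expect_equal(nrow(miss), 1L)
  expect_equal(miss$genome_id, "g3")
  expect_equal(c(miss$start, miss$end), c(30L, 150L))

  # an overlapping unrelated gene in g3 suppresses the record
  genes3 <- rbind(genes2, gene_table("g3_z", "g3", "c1", 140L, 200L, "+"))
  class(genes3) <- c("gene_table", "data.frame")
  idx3 <- build_alignment_index(list(b3), genes3)
  grp3 <- fix_group("OG1", genes3, c("g1_a", "g2_a"))
  expect_equal(nrow(find_missing_annotations(list(grp3), idx3)), 0L)

  # genome absent from the block: not reported
  b2 <- fix_block("b1", lapply(c("g1", "g2"), fix_row, text = txt,
                               src_size = width + 50L))
  idx2 <- build_alignment_index(list(b2), genes2,
                                genomes = fix_genomes(list(b3)))
  expect_equal(nrow(find_missing_annotations(list(grp), idx2)), 0L)
})

test_that("planted in-frame TIS shifts classify as inconsistent starts with the right outlier", {
  for (seed in c(81L, 82L, 83L)) {
    sim <- tiny_sim(seed, n_genomes = 3L, n_genes = 10L,
                    anomalies = list(tis_shift = 1L))
    idx <- build_alignment_index(sim$blocks, sim$genes, sim$genomes)
    groups <- group_orthologs(sim$genes, idx)
    an <- classify_groups(groups, idx)
    expect_equal(sum(an$class == "inconsistent_starts"), 1L)
    expect_equal(an$sole_outlier_genome[an$class == "inconsistent_starts"],
                 sim$truth$anomalies$genome_id[1])
    expect_equal(sum(an$class == "consistent"), 9L)
  }
})
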