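# A 2-genome fixture whose block text IS the genome sequence, so codon
# content is fully controlled.
orf_fixture <- function(g1_seq, g2_text, genes_spec) {
  t1 <- g1_seq
  b <- fix_block("b1", list(
    fix_row("g1", t1, src_size = nchar(gsub("-", "", t1)) + 10L),
    fix_row("g2", g2_text, src_size = nchar(gsub("-", "", g2_text)) + 10L)
  ))
  genes <- do.call(rbind, lapply(names(genes_spec), function(id) {
    s <- genes_spec[[id]]
    gene_table(id, s$genome, "c1", s$start, s$end, s$strand %||% "+")
  }))
  class(genes) <- c("gene_table", "data.frame")
  genomes <- fix_genomes(list(b))
  idx <- build_alignment_index(list(b), genes, genomes)
  list(index = idx, genes = genes, genomes = genomes, block = b)
}

test_that("codon pairs are the orientation-filtered cross product of distinct termini", {
  fx <- classify_fixture <- NULL
  set.seed(3)
  txt <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  b <- fix_block("b1", lapply(paste0("g", 1:3), fix_row, text = txt,
                              src_size = 350L))
  genes <- gene_table(gene_id = paste0("g", 1:3, "_a"),
                      genome_id = paste0("g", 1:3), contig_id = "c1",
                      start = c(30L, 45L, 30L), end = c(150L, 150L, 150L),
                      strand = "+")
  idx <- build_alignment_index(list(b), genes)
  grp <- fix_group("OG1", genes, genes$gene_id)
  pairs <- enumerate_codon_pairs(grp, idx)
  expect_equal(nrow(pairs), 2L)  # 2 distinct starts x 1 stop

  # fully consistent group: a single pair
  genes2 <- gene_table(gene_id = paste0("g", 1:3, "_a"),
                       genome_id = paste0("g", 1:3), contig_id = "c1",
                       start = 30L, end = 150L, strand = "+")
  idx2 <- build_alignment_index(list(b), genes2)
  expect_equal(nrow(enumerate_codon_pairs(fix_group("OG1", genes2,
                                                    genes2$gene_id), idx2)), 1L)

  # 3 starts x 2 stops with one inverted pairing -> 5 (brute-force oracle)
  genes3 <- gene_table(gene_id = paste0("x", 1:3),
                       genome_id = paste0("g", 1:3), contig_id = "c1",
                       start = c(30L, 60L, 160L), end = c(150L, 150L, 240L),
                       strand = "+")
  idx3 <- build_alignment_index(list(b), genes3)
  pairs3 <- enumerate_codon_pairs(fix_group("OG1", genes3, genes3$gene_id), idx3)
  starts <- c(30L, 60L, 160L)
  stops <- c(149L, 239L)
  oracle <- expand.grid(s = starts, e = stops)
  oracle <- oracle[oracle$s < oracle$e - 1L, ]
  expect_equal(nrow(pairs3), nrow(oracle))
  expect_equal(nrow(pairs3), 5L)
  expect_setequal(paste(pairs3$start_col, pairs3$stop_col),
                  paste(oracle$s, oracle$e))
})

test_that("a canonical ORF validates and an internal in-frame stop invalidates", {
  seqv <- "ATGAAATAA"
  fx <- orf_fixture(seqv, seqv,
                    list(a1 = list(genome = "g1", start = 0L, end = 9L),
                         a2 = list(genome = "g2", start = 0L, end = 9L)))
  pair <- data.frame(start_block = "b1", start_col = 0L, stop_block = "b1",
                     stop_col = 8L, strand = "+", stringsAsFactors = FALSE)
  e <- evaluate_orf(pair[1, ], "g2", fx$index, fx$genomes)
  expect_true(e$orf_valid)
  expect_equal(e$n_frameshifts, 0L)
  expect_equal(c(e$start, e$end), c(0L, 9L))

  # an internal in-frame stop invalidates even with valid boundaries
  expect_false(panann:::check_orf("ATGTAATAA", codon_config()))
  expect_true(panann:::check_orf("ATGAAATAA", codon_config()))
})

test_that("a single planted indel is repaired by one frameshift at the gap column", {
  g1 <- "ATGAAACCCGGGTAA"          # intact 15-bp ORF
  g2 <- "ATGAAAC-CGGGTAA"          # 1-bp deletion at column 7
  fx <- orf_fixture(g1, g2,
                    list(a1 = list(genome = "g1", start = 0L, end = 15L)))
  pair <- data.frame(start_block = "b1", start_col = 0L, stop_block = "b1",
                     stop_col = 14L, strand = "+", stringsAsFactors = FALSE)
  e1 <- evaluate_orf(pair[1, ], "g1", fx$index, fx$genomes)
  expect_true(e1$orf_valid)
  e2 <- evaluate_orf(pair[1, ], "g2", fx$index, fx$genomes)
  expect_true(e2$orf_valid)
  expect_equal(e2$n_frameshifts, 1L)
  expect_equal(e2$shift_cols, 7L)
  # hand-translation oracle of the fixture
  expect_true(indep_check_orf_shift("ATGAAACCGGGTAA", 7L))
  # without gaps the same invalid ORF is not repaired
  e0 <- evaluate_orf(data.frame(start_block = "b1", start_col = 0L,
                                stop_block = "b1", stop_col = 13L,
                                strand = "+", stringsAsFactors = FALSE),
                     "g1", fx$index, fx$genomes)
  expect_false(e0$orf_valid)
})

test_that("alternatives rank by valid ORFs then length, with the length filter", {
  set.seed(5)
  txt <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  b <- fix_block("b1", lapply(paste0("g", 1:3), fix_row, text = txt,
                              src_size = 150L))
  genes <- gene_table(gene_id = paste0("g", 1:3, "_a"),
                      genome_id = paste0("g", 1:3), contig_id = "c1",
                      start = 0L, end = 90L, strand = "+")
  idx <- build_alignment_index(list(b), genes)
  grp <- fix_group("OG1", genes, genes$gene_id)
  mkpair <- function(s, e) data.frame(start_block = "b1", start_col = s,
                                      stop_block = "b1", stop_col = e,
                                      strand = "+", stringsAsFactors = FALSE)
  mkeval <- function(g, s, e, valid) list(
    genome_id = g, absent = FALSE, contig_id = "c1", start = s, end = e,
    strand = "+", orf_valid = valid, n_frameshifts = 0L,
    shift_cols = integer(0), reason = NA_character_)
  cands <- list(
    list(pair = mkpair(0L, 59L),   # valid in 3 genomes, length 60
         evals = lapply(paste0("g", 1:3), mkeval, s = 0L, e = 60L, valid = TRUE)),
    list(pair = mkpair(0L, 89L),   # valid in 2 genomes, length 90
         evals = c(lapply(paste0("g", 1:2), mkeval, s = 0L, e = 90L,
                          valid = TRUE),
                   list(mkeval("g3", 0L, 90L, FALSE)))),
    list(pair = mkpair(30L, 59L),  # 30/90 = 33% of annotated length: dropped
         evals = lapply(paste0("g", 1:3), mkeval, s = 30L, e = 60L,
                        valid = TRUE))
  )
  r <- rank_alternatives(cands, grp, idx)
  expect_equal(nrow(r), 2L)
  expect_equal(r$n_valid_orfs, c(3L, 2L))
  expect_equal(r$rank, 1:2)

  # equal validity: longer first
  cands2 <- list(
    list(pair = mkpair(30L, 89L),
         evals = lapply(paste0("g", 1:3), mkeval, s = 30L, e = 90L, valid = TRUE)),
    list(pair = mkpair(0L, 89L),
         evals = lapply(paste0("g", 1:3), mkeval, s = 0L, e = 90L, valid = TRUE))
  )
  r2 <- rank_alternatives(cands2, grp, idx)
  expect_equal(r2$length, c(90L, 60L))

  # configurable order: length first even when fewer genomes validate
  cands3 <- list(
    list(pair = mkpair(0L, 89L),
         evals = c(lapply(paste0("g", 1:2), mkeval, s = 0L, e = 90L,
                          valid = TRUE), list(mkeval("g3", 0L, 90L, FALSE)))),
    list(pair = mkpair(30L, 89L),
         evals = lapply(paste0("g", 1:3), mkeval, s = 30L, e = 90L, valid = TRUE))
  )
  expect_equal(rank_alternatives(cands3, grp, idx)$length, c(60L, 90L))
  expect_equal(rank_alternatives(cands3, grp, idx,
                                 sort_order = "length,valid_orfs")$length,
               c(90L, 60L))
})

test_that("overlap flags fire only for genes outside the group", {
  set.seed(6)
  txt <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  b <- fix_block("b1", list(fix_row("g1", txt, src_size = 250L)))
  genes <- gene_table(gene_id = c("m", "adj"), genome_id = "g1",
                      contig_id = "c1", start = c(60L, 0L), end = c(150L, 50L),
                      strand = "+")
  idx <- build_alignment_index(list(b), genes)
  ev <- function(s, e) list(list(genome_id = "g1", absent = FALSE,
                                 contig_id = "c1", start = s, end = e,
                                 strand = "+", orf_valid = TRUE,
                                 n_frameshifts = 0L))
  # extends 30 bp upstream into the adjacent gene: flagged
  expect_true(flag_overlaps(ev(30L, 150L), "m", idx))
  # interior to the existing span: not flagged
  expect_false(flag_overlaps(ev(70L, 140L), "m", idx))
  # overlap only with the member being replaced: not flagged
  expect_false(flag_overlaps(ev(60L, 150L), "m", idx))
})

test_that("missing genes are suggested only when the projected ORF is valid", {
  sim <- tiny_sim(541L, n_genomes = 3L, n_genes = 10L,
                  anomalies = list(deleted_annotation = 1L))
  idx <- build_alignment_index(sim$blocks, sim$genes, sim$genomes)
  groups <- group_orthologs(sim$genes, idx)
  miss <- find_missing_annotations(groups, idx)
  expect_equal(nrow(miss), 1L)
  sug <- suggest_missing_genes(miss, groups, idx, sim$genomes)
  expect_equal(nrow(sug), 1L)
  expect_equal(sug$genome_id, sim$truth$anomalies$genome_id[1])
  # the suggested interval has the ancestral gene's length and is a real ORF
  anc <- sim$ancestor$genes[
    sim$ancestor$genes$gene_id == sim$truth$anomalies$anc_gene[1], ]
  expect_equal(sug$end - sug$start, anc$end - anc$start)
  gseq <- sim$genomes[[sug$genome_id]]$contigs[[sug$contig_id]]
  s <- substr(gseq, sug$start + 1L, sug$end)
  if (sug$strand == "-") s <- revcomp(s)
  expect_true(indep_check_orf(s))
})

test_that("adding a genome with a valid ORF never demotes a candidate", {
  set.seed(8)
  core <- "ATGAAACCCGGGAAATTTCCCGGGAAACCCTAA"  # 33 bp ORF
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  seqs <- paste0("ATGAAA", core)  # alternative upstream in-frame start
  rows3 <- lapply(paste0("g", 1:3), fix_row, text = seqs, src_size = 60L)
  rows4 <- lapply(paste0("g", 1:4), fix_row, text = seqs, src_size = 60L)
  mkgenes <- function(gg, starts) {
    do.call(rbind, lapply(seq_along(gg), function(i) {
      gene_table(paste0(gg[i], "_a"), gg[i], "c1", starts[i], 39L, "+")
    }))
  }
  g3 <- mkgenes(paste0("g", 1:3), c(0L, 6L, 6L))
  class(g3) <- c("gene_table", "data.frame")
  g4 <- mkgenes(paste0("g", 1:4), c(0L, 6L, 6L, 6L))
  class(g4) <- c("gene_table", "data.frame")
  b3 <- fix_block("b1", rows3)
  b4 <- fix_block("b1", rows4)
  i3 <- build_alignment_index(list(b3), g3, fix_genomes(list(b3)))
  i4 <- build_alignment_index(list(b4), g4, fix_genomes(list(b4)))
  a3 <- propose_alternatives(fix_group("OG1", g3, g3$gene_id), i3,
                             fix_genomes(list(b3)))
  a4 <- propose_alternatives(fix_group("OG1", g4, g4$gene_id), i4,
                             fix_genomes(list(b4)))
  expect_equal(nrow(a3), nrow(a4))
  key <- function(a) paste(a$start_col, a$stop_col)
  expect_equal(key(a3), key(a4))  # relative order unchanged
  expect_true(all(a4$n_valid_orfs >= a3$n_valid_orfs))
})
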