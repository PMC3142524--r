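test_that("ancestral genes are valid ORFs under independent translation", {
  set.seed(1)
  anc <- generate_ancestor(sim_config(n_genomes = 2L, genome_len = 20000L,
                                      n_genes = 15L,
                                      gene_len_range = c(120L, 600L)))
  expect_equal(nrow(anc$genes), 15L)
  seqv <- anc$genome$contigs[[1]]
  for (i in seq_len(nrow(anc$genes))) {
    g <- anc$genes[i, ]
    s <- substr(seqv, g$start + 1L, g$end)
    if (g$strand == "-") s <- revcomp(s)
    expect_true(indep_check_orf(s))
  }
  # genes do not overlap
  o <- order(anc$genes$start)
  expect_true(all(diff(rbind(anc$genes$start[o], anc$genes$end[o])[1, ]) > 0))
  expect_true(all(anc$genes$end[o][-15] <= anc$genes$start[o][-1]))
})

test_that("degenerate configurations behave: no genes, infeasible packing", {
  set.seed(1)
  anc0 <- generate_ancestor(sim_config(genome_len = 5000L, n_genes = 0L))
  expect_equal(nrow(anc0$genes), 0L)
  expect_equal(nchar(anc0$genome$contigs[[1]]), 5000L)
  expect_error(generate_ancestor(sim_config(genome_len = 2000L,
                                            n_genes = 10L,
                                            gene_len_range = c(300L, 300L))),
               "infeasible")
})

test_that("zero mutation rates reproduce the ancestor exactly (identity limit)", {
  sim <- tiny_sim(11L, n_genomes = 2L, n_genes = 8L, snp_rate = 0,
                  indel_rate = 0)
  anc_seq <- sim$ancestor$genome$contigs[[1]]
  for (iso in sim$isolates) {
    expect_identical(iso$seq, anc_seq)
    expect_equal(iso$genes$start, sim$ancestor$genes$start)
    expect_equal(iso$genes$end, sim$ancestor$genes$end)
  }
  # gapless alignment, width = contig length, one row per genome
  expect_length(sim$blocks, 1L)
  expect_equal(sim$blocks[[1]]$width, nchar(anc_seq))
  expect_length(sim$blocks[[1]]$rows, 2L)
  expect_false(any(grepl("-", vapply(sim$blocks[[1]]$rows, `[[`, "", "text"),
                         fixed = TRUE)))
})

test_that("annotation liftover preserves gene content through indels", {
  sim <- tiny_sim(13L, n_genomes = 3L, n_genes = 10L, snp_rate = 0,
                  indel_rate = 5e-3)
  n_indels <- sum(vapply(sim$isolates,
                         function(i) sum(i$log$type != "snp"), 0L))
  expect_gt(n_indels, 0L)  # the regime actually exercises indels
  anc_seq <- sim$ancestor$genome$contigs[[1]]
  for (iso in sim$isolates) {
    for (i in seq_len(nrow(iso$genes))) {
      g <- iso$genes[i, ]
      anc_g <- sim$ancestor$genes[
        sim$ancestor$genes$gene_id == sub("^[^_]+_", "", g$gene_id), ]
      expect_identical(substr(iso$seq, g$start + 1L, g$end),
                       substr(anc_seq, anc_g$start + 1L, anc_g$end))
    }
  }
})

test_that("a single insertion creates exactly one gap column in other rows", {
  sim <- tiny_sim(17L, n_genomes = 3L, n_genes = 5L, snp_rate = 0,
                  indel_rate = 0)
  # splice one 1-bp insertion into isolate 2 by hand, then rebuild
  iso <- sim$isolates[[2]]
  p <- 1234L  # intergenic for this fixture (first gene starts later)
  stopifnot(p < min(sim$ancestor$genes$start))
  iso$seq <- paste0(substr(iso$seq, 1L, p), "A",
                    substr(iso$seq, p + 1L, nchar(iso$seq)))
  iso$log <- rbind(iso$log, data.frame(type = "ins", anc_pos = p, len = 1L,
                                       payload = "A", stringsAsFactors = FALSE))
  g <- iso$genes
  g$start <- g$start + 1L
  g$end <- g$end + 1L
  iso$genes <- g
  sim$isolates[[2]] <- iso
  sim2 <- build_truth_alignment(sim)
  b <- sim2$blocks[[1]]
  L <- nchar(sim$ancestor$genome$contigs[[1]])
  expect_equal(b$width, L + 1L)
  gaps <- vapply(b$rows, function(r) sum(strsplit(r$text, "")[[1]] == "-"), 0L)
  expect_equal(unname(gaps[c("iso01", "iso02", "iso03")]), c(1L, 0L, 1L))
})

test_that("simulation is deterministic given the seed", {
  s1 <- tiny_sim(19L, anomalies = list(tis_shift = 1L, gene_split_indel = 1L))
  s2 <- tiny_sim(19L, anomalies = list(tis_shift = 1L, gene_split_indel = 1L))
  expect_identical(vapply(s1$isolates, `[[`, "", "seq"),
                   vapply(s2$isolates, `[[`, "", "seq"))
  expect_identical(s1$truth$anomalies, s2$truth$anomalies)
  f1 <- tempfile(fileext = ".maf")
  f2 <- tempfile(fileext = ".maf")
  write_maf(s1$blocks, f1)
  write_maf(s2$blocks, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("emitted files parse cleanly and agree with each other", {
  dir <- tempfile()
  sim <- tiny_sim(23L, n_genomes = 3L, n_genes = 10L,
                  anomalies = list(contig_break = 1L), outdir = dir)
  blocks <- read_maf(sim$paths$maf)
  # contig break splits the alignment into two blocks
  expect_length(blocks, 2L)
  genomes <- stats::setNames(
    lapply(names(sim$paths$fasta), function(id) {
      read_fasta(sim$paths$fasta[[id]], genome_id = id)
    }), names(sim$paths$fasta))
  # the broken isolate has two contigs
  broken <- sim$truth$anomalies$genome_id[1]
  expect_length(genomes[[broken]]$contigs, 2L)
  expect_true(validate_alignment(blocks, genomes))
  genes <- do.call(rbind, lapply(names(sim$paths$gff3), function(id) {
    read_gff3(sim$paths$gff3[[id]], genome_id = id)
  }))
  expect_equal(sort(genes$gene_id), sort(sim$genes$gene_id))
  # both break fragments are flagged partial
  frags <- genes[grepl("_p[12]$", genes$gene_id), ]
  expect_equal(nrow(frags), 2L)
  expect_true(all(frags$partial5 | frags$partial3))
})

test_that("planted anomaly counts are recovered exactly on a small pan-genome", {
  sim <- tiny_sim(29L, n_genomes = 4L, genome_len = 40000L, n_genes = 25L,
                  anomalies = list(tis_shift = 3L, gene_split_indel = 2L,
                                   deleted_annotation = 2L))
  idx <- build_alignment_index(sim$blocks, sim$genes, sim$genomes)
  groups <- group_orthologs(sim$genes, idx)
  expect_length(groups, 25L)
  an <- classify_groups(groups, idx)
  expect_equal(sum(an$class == "inconsistent_starts"), 3L)
  expect_equal(sum(an$class == "fragmentation"), 2L)
  expect_equal(sum(an$class == "consistent"), 20L)
  miss <- find_missing_annotations(groups, idx)
  expect_equal(nrow(miss), 2L)
})
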