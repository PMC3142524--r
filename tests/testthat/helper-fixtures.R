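# Hand-constructed alignment fixtures and cached simulations shared across
# test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

fix_row <- function(genome_id, text, fwd_start = 0L, strand = "+",
                    src_size = NULL, contig_id = "c1") {
  size <- nchar(gsub("-", "", text, fixed = TRUE))
  list(genome_id = genome_id, contig_id = contig_id,
       fwd_start = as.integer(fwd_start), size = size, strand = strand,
       src_size = as.integer(src_size %||% (fwd_start + size + 20L)),
       text = text)
}

fix_block <- function(block_id, rows) {
  width <- unique(nchar(vapply(rows, `[[`, "", "text")))
  stopifnot(length(width) == 1L)
  names(rows) <- vapply(rows, `[[`, "", "genome_id")
  panann:::new_block(block_id, rows, width)
}

# Genomes whose contigs agree with the aligned rows (random elsewhere).
fix_genomes <- function(blocks, seed = 99L) {
  set.seed(seed)
  specs <- list()  # genome -> contig -> len
  for (b in blocks) {
    for (row in b$rows) {
      cur <- specs[[row$genome_id]][[row$contig_id]] %||% 0L
      specs[[row$genome_id]][[row$contig_id]] <- max(cur, row$src_size)
    }
  }
  genomes <- lapply(names(specs), function(g) {
    contigs <- vapply(names(specs[[g]]), function(ct) {
      paste(sample(c("A", "C", "G", "T"), specs[[g]][[ct]], replace = TRUE),
            collapse = "")
    }, "")
    names(contigs) <- names(specs[[g]])
    contigs
  })
  names(genomes) <- names(specs)
  for (b in blocks) {
    for (row in b$rows) {
      seg <- gsub("-", "", row$text, fixed = TRUE)
      if (row$strand == "-") seg <- revcomp(seg)
      ct <- genomes[[row$genome_id]][[row$contig_id]]
      substr(ct, row$fwd_start + 1L, row$fwd_start + row$size) <- seg
      genomes[[row$genome_id]][[row$contig_id]] <- ct
    }
  }
  lapply(stats::setNames(names(genomes), names(genomes)), function(g) {
    genome_sequence(g, genomes[[g]])
  })
}

# Minimal group object as group_orthologs() would emit.
fix_group <- function(group_id, genes, member_ids, query = NULL) {
  m <- genes[genes$gene_id %in% member_ids, , drop = FALSE]
  len <- m$end - m$start
  query <- query %||% m$gene_id[order(-len, m$genome_id, m$gene_id)][1]
  counts <- table(m$genome_id)
  list(group_id = group_id, query_gene = query, members = m$gene_id,
       member_genomes = m$genome_id,
       genomes_present = sort(unique(m$genome_id)),
       n_per_genome = stats::setNames(as.integer(counts), names(counts)))
}

tiny_sim <- function(seed, n_genomes = 3L, genome_len = 20000L, n_genes = 15L,
                     anomalies = list(), snp_rate = 0.005, indel_rate = 1e-4,
                     outdir = NULL) {
  simulate_pangenome(sim_config(
    n_genomes = n_genomes, genome_len = genome_len, n_genes = n_genes,
    gene_len_range = c(300L, 900L), snp_rate = snp_rate,
    indel_rate = indel_rate, seed = seed, anomalies = anomalies
  ), outdir = outdir)
}

# Simulations reused by several acceptance checks.
.sim_cache <- new.env(parent = emptyenv())
cached <- function(name, maker) {
  if (is.null(.sim_cache[[name]])) assign(name, maker(), envir = .sim_cache)
  get(name, envir = .sim_cache)
}

acceptance_clean <- function() {
  cached("clean", function() {
    dir <- file.path(tempdir(), "panann_acc_clean")
    sim <- simulate_pangenome(sim_config(seed = 4001L), outdir = dir)
    res <- run_annotate(fasta = sim$paths$fasta, gff = sim$paths$gff3,
                        maf = sim$paths$maf, quiet = TRUE)
    list(sim = sim, res = res)
  })
}

acceptance_planted <- function() {
  cached("planted", function() {
    dir <- file.path(tempdir(), "panann_acc_planted")
    sim <- simulate_pangenome(sim_config(
      seed = 5001L,
      anomalies = list(tis_shift = 20L, gene_split_indel = 10L,
                       deleted_annotation = 10L)
    ), outdir = dir)
    res <- run_annotate(fasta = sim$paths$fasta, gff = sim$paths$gff3,
                        maf = sim$paths$maf, quiet = TRUE)
    list(sim = sim, res = res)
  })
}
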