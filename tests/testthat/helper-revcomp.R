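# Rewrite a simulated data set (FASTA/GFF3/MAF files) with every genome
# reverse-complemented, keeping the alignment content identical. Used to
# check strand invariance of the whole analysis.
revcomp_dataset <- function(paths, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  new <- list(fasta = character(0), gff3 = character(0))
  clens <- list()
  for (id in names(paths$fasta)) {
    g <- read_fasta(paths$fasta[[id]], genome_id = id)
    g$contigs <- vapply(g$contigs, revcomp, "", USE.NAMES = TRUE)
    clens[[id]] <- nchar(g$contigs)
    fp <- file.path(outdir, paste0(id, ".fasta"))
    write_fasta(g, fp)
    new$fasta[id] <- fp
  }
  for (id in names(paths$gff3)) {
    genes <- read_gff3(paths$gff3[[id]], genome_id = id)
    if (nrow(genes)) {
      L <- clens[[id]][genes$contig_id]
      s <- genes$start
      genes$start <- L - genes$end
      genes$end <- L - s
      genes$strand <- ifelse(genes$strand == "+", "-", "+")
      p5 <- genes$partial5
      genes$partial5 <- genes$partial3
      genes$partial3 <- p5
    }
    gp <- file.path(outdir, paste0(id, ".gff3"))
    write_gff3(genes, gp)
    new$gff3[id] <- gp
  }
  blocks <- read_maf(paths$maf)
  for (i in seq_along(blocks)) {
    for (g in names(blocks[[i]]$rows)) {
      row <- blocks[[i]]$rows[[g]]
      row$fwd_start <- row$src_size - row$fwd_start - row$size
      row$strand <- if (row$strand == "+") "-" else "+"
      blocks[[i]]$rows[[g]] <- row
    }
  }
  new$maf <- file.path(outdir, "alignment.maf")
  write_maf(blocks, new$maf)
  new
}
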