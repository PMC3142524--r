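# End-to-end orchestration: read inputs, cross-validate alignment against
# sequence, group orthologs, classify anomalies, propose alternatives, and
# write reports.

#' Cross-validate alignment rows against genome sequence
#'
#' Every non-gap character of every block row must equal the corresponding
#' FASTA base (after strand normalization). A mismatch is fatal: every
#' downstream codon decision depends on the alignment and sequence agreeing.
#'
#' @param blocks Alignment blocks from [read_maf()].
#' @param genomes Named list of [genome_sequence()] objects.
#' @return `TRUE`, invisibly; errors on the first mismatch, naming the
#'   block, row and offset.
#' @export
validate_alignment <- function(blocks, genomes) {
  for (b in blocks) {
    for (row in b$rows) {
      g <- genomes[[row$genome_id]]
      if (is.null(g)) next
      contig <- g$contigs[[row$contig_id]]
      if (is.null(contig)) {
        stop2("MAF block ", b$block_id, ": contig '", row$contig_id,
              "' not present in genome '", row$genome_id, "'")
      }
      if (row$src_size != nchar(contig)) {
        stop2("MAF block ", b$block_id, ", row ", row$genome_id, ".",
              row$contig_id, ": srcSize ", row$src_size,
              " != contig length ", nchar(contig))
      }
      seg <- substr(contig, row$fwd_start + 1L, row$fwd_start + row$size)
      expected <- if (row$strand == "+") seg else revcomp(seg)
      got <- gsub("-", "", row$text, fixed = TRUE)
      if (got != expected) {
        d <- which(strsplit(got, "")[[1]] != strsplit(expected, "")[[1]])[1]
        stop2("MAF/FASTA sequence mismatch: block ", b$block_id, ", row ",
              row$genome_id, ".", row$contig_id, ", aligned base offset ",
              d - 1L, " ('", substr(got, d, d), "' vs '",
              substr(expected, d, d), "')")
      }
    }
  }
  invisible(TRUE)
}

anomaly_classes <- c("inconsistent_starts", "inconsistent_stops",
                     "combination", "fragmentation")

#' Run the full annotation-consistency analysis
#'
#' The three analysis stages downstream of whole-genome alignment: ortholog
#' grouping from the alignment, anomaly classification, and alternative
#' annotation. Inputs are one FASTA and one GFF3 per genome plus the MAF
#' alignment; outputs are the report files of [write_reports()] and an
#' in-memory result object.
#'
#' @param fasta,gff Character vectors of file paths, named by genome id
#'   (unnamed paths are named by file basename without extension). Every
#'   genome present in the MAF must have one of each.
#' @param maf Path to the MAF whole-genome multiple alignment.
#' @param outdir Output directory for reports (`NULL` to skip writing).
#' @param cov_query,cov_match Ortholog coverage cutoffs
#'   (see [group_orthologs()]).
#' @param min_len_frac Alternative-length filter (see [rank_alternatives()]).
#' @param start_codons,stop_codons,max_frameshifts Codon configuration
#'   (see [codon_config()]).
#' @param W Contig-boundary window in bp (see [flag_contig_boundary()]).
#' @param min_genome_frac Missing-annotation reporting threshold
#'   (see [find_missing_annotations()]).
#' @param sort_order Alternative sort order (see [rank_alternatives()]).
#' @param dump Alignment-dump policy (see [write_reports()]).
#' @param quiet Suppress progress messages.
#' @return A list of class `panann_run` with `index`, `groups`, `anomalies`,
#'   `missing`, `alternatives` (named by group id), `suggestions`,
#'   `genome_counts` and `summary`.
#' @export
run_annotate <- function(fasta, gff, maf, outdir = NULL,
                         cov_query = 0.5, cov_match = 0.5,
                         min_len_frac = 0.5,
                         start_codons = c("ATG", "GTG", "TTG"),
                         stop_codons = c("TAA", "TAG", "TGA"),
                         max_frameshifts = 1L, W = 10L,
                         min_genome_frac = 0.9,
                         sort_order = "valid_orfs,length",
                         dump = "anomalous", quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  name_paths <- function(p) {
    if (is.null(names(p)) || any(!nzchar(names(p)))) {
      names(p) <- sub("\\.[^.]*$", "", basename(p))
    }
    p
  }
  fasta <- name_paths(fasta)
  gff <- name_paths(gff)

  blocks <- read_maf(maf)
  maf_genomes <- sort(unique(unlist(lapply(blocks, function(b) names(b$rows)))))
  missing_fasta <- setdiff(maf_genomes, names(fasta))
  if (length(missing_fasta)) {
    stop2("no FASTA provided for MAF genome(s): ",
          paste(missing_fasta, collapse = ", "))
  }
  missing_gff <- setdiff(maf_genomes, names(gff))
  if (length(missing_gff)) {
    stop2("no GFF3 provided for MAF genome(s): ",
          paste(missing_gff, collapse = ", "))
  }
  extra <- setdiff(names(gff), maf_genomes)
  if (length(extra) && length(maf_genomes)) {
    warning("genome(s) annotated but absent from the alignment, excluded: ",
            paste(extra, collapse = ", "), call. = FALSE)
    gff <- gff[setdiff(names(gff), extra)]
    fasta <- fasta[intersect(names(fasta), names(gff))]
  }

  genomes <- stats::setNames(
    lapply(names(fasta), function(id) read_fasta(fasta[[id]], genome_id = id)),
    names(fasta))
  validate_alignment(blocks, genomes)

  genes <- do.call(rbind, lapply(names(gff), function(id) {
    read_gff3(gff[[id]], genome_id = id)
  }))
  if (is.null(genes)) genes <- gene_table()
  rownames(genes) <- NULL
  class(genes) <- c("gene_table", "data.frame")
  if (anyDuplicated(genes$gene_id)) {
    warning("gene ids collide across genomes; prefixing with genome id",
            call. = FALSE)
    genes$gene_id <- paste(genes$genome_id, genes$gene_id, sep = ":")
  }
  say("read ", length(genomes), " genomes, ", nrow(genes), " genes, ",
      length(blocks), " alignment blocks")

  cfg <- codon_config(start_codons, stop_codons, max_frameshifts)
  index <- build_alignment_index(blocks, genes, genomes)
  groups <- group_orthologs(genes, index, cov_query, cov_match)
  say("built ", length(groups), " ortholog groups")

  anomalies <- classify_groups(groups, index)
  termini <- attr(anomalies, "termini")
  anomalies <- flag_contig_boundary(anomalies, groups, genes, genomes, W)
  missing <- find_missing_annotations(groups, index, min_genome_frac)
  say("classified groups: ",
      paste(names(table(anomalies$class)), table(anomalies$class),
            sep = "=", collapse = ", "),
      "; ", nrow(missing), " missing-annotation records")

  byid <- stats::setNames(groups, vapply(groups, `[[`, "", "group_id"))
  todo <- anomalies$group_id[anomalies$class %in% anomaly_classes]
  alternatives <- stats::setNames(
    lapply(todo, function(gid) {
      propose_alternatives(byid[[gid]], index, genomes, cfg,
                           termini = termini, min_len_frac = min_len_frac,
                           sort_order = sort_order)
    }), todo)
  suggestions <- suggest_missing_genes(missing, groups, index, genomes, cfg,
                                       alternatives = alternatives,
                                       termini = termini)
  genome_counts <- per_genome_inconsistency_counts(groups, anomalies,
                                                   genomes = names(genomes))

  ns <- anomalies[anomalies$class != "singleton", , drop = FALSE]
  class_counts <- table(factor(ns$class,
                               levels = c("consistent", anomaly_classes)))
  n_resolvable <- sum(vapply(alternatives, function(a) {
    nrow(a) > 0L && a$n_valid_orfs[1] >= 1L
  }, TRUE))
  n_fs_repaired <- sum(vapply(alternatives, function(a) {
    nrow(a) > 0L && a$n_frameshifts[1] > 0L
  }, TRUE))
  summary <- list(
    n_genomes = length(genomes), n_genes = nrow(genes),
    n_blocks = length(blocks), n_groups = length(groups),
    n_singletons = sum(anomalies$class == "singleton"),
    n_nonsingleton = nrow(ns),
    class_counts = class_counts,
    frac_consistent = if (nrow(ns)) unname(class_counts["consistent"]) / nrow(ns)
      else NA_real_,
    n_missing = nrow(missing), n_suggestions = nrow(suggestions),
    n_alternative_sets = n_resolvable,
    n_frameshift_repaired = n_fs_repaired
  )

  res <- structure(list(
    index = index, groups = groups, anomalies = anomalies, termini = termini,
    missing = missing, alternatives = alternatives, suggestions = suggestions,
    genome_counts = genome_counts, summary = summary
  ), class = "panann_run")

  if (!is.null(outdir)) {
    write_reports(groups, anomalies, alternatives, outdir, missing = missing,
                  genome_counts = genome_counts, suggestions = suggestions,
                  index = index, dump = dump)
    say("reports written to ", outdir)
  }
  res
}

#' @export
print.panann_run <- function(x, ...) {
  s <- x$summary
  cat("panann analysis of ", s$n_genomes, " genomes (", s$n_genes,
      " genes, ", s$n_blocks, " alignment blocks)\n", sep = "")
  cat("  ortholog groups:      ", s$n_groups, " (", s$n_singletons,
      " singletons)\n", sep = "")
  for (cl in names(s$class_counts)) {
    cat(sprintf("  %-22s %d\n", paste0(cl, ":"), s$class_counts[[cl]]))
  }
  if (!is.na(s$frac_consistent)) {
    cat(sprintf("  fraction consistent:   %.1f%% of %d non-singleton groups\n",
                100 * s$frac_consistent, s$n_nonsingleton))
  }
  cat("  missing annotations:  ", s$n_missing, " (", s$n_suggestions,
      " with a valid suggested ORF)\n", sep = "")
  cat("  groups with a ranked alternative: ", s$n_alternative_sets,
      " (", s$n_frameshift_repaired, " via single-frameshift repair)\n",
      sep = "")
  invisible(x)
}
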