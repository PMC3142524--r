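# Greedy, length-sorted positional ortholog clustering over the whole-genome
# multiple alignment.
#
# The longest remaining gene seeds each group (the "query"); genes from OTHER
# genomes whose intervals intersect the query's aligned column span join when
# coverage cutoffs are met, and every gene is placed in exactly one group.
# A query may capture several adjacent fragments from a single genome, which
# is how disrupted/fragmented genes surface.

#' Build positional ortholog groups
#'
#' Genes are processed in decreasing length order (ties: genome id, then gene
#' id). The current longest gene becomes the query of a new group. A candidate
#' gene from another genome joins when (a) the aligned (non-gap in both rows)
#' overlap with the query's column span covers at least `cov_match` of the
#' candidate's length, and (b) the alignment covers at least `cov_query` of
#' the query's length (evaluated once per query, over the union of its
#' blocks). Joined genes leave the pool; queries with no joiners become
#' singleton groups.
#'
#' @param genes A [gene_table()]; must be the same table the index was built
#'   from.
#' @param index An [build_alignment_index()] result.
#' @param cov_query,cov_match Coverage cutoffs in `[0, 1]` (default 0.5 each).
#' @return A list of ortholog groups; each is a list with `group_id`,
#'   `query_gene`, `members` (gene ids, query included), `member_genomes`,
#'   `genomes_present`, and `n_per_genome` (named integer).
#' @export
group_orthologs <- function(genes, index, cov_query = 0.5, cov_match = 0.5) {
  stopifnot(cov_query >= 0, cov_query <= 1, cov_match >= 0, cov_match <= 1)
  if (!identical(genes$gene_id, index$genes$gene_id)) {
    stop2("`genes` must be the gene table the index was built from")
  }
  n <- nrow(genes)
  if (n == 0L) return(list())
  len <- gene_length(genes)
  ord <- order(-len, genes$genome_id, genes$gene_id)
  alive <- rep(TRUE, n)
  groups <- list()
  ng <- 0L

  for (i in ord) {
    if (!alive[i]) next
    alive[i] <- FALSE
    q <- genes[i, ]
    spans <- gene_column_span(index, q)
    joined <- integer(0)
    qcov <- if (nrow(spans)) sum(spans$covered_bases) / len[i] else 0
    if (qcov >= cov_query && nrow(spans)) {
      shared <- numeric(0)  # named by gene index
      for (si in seq_len(nrow(spans))) {
        b <- index$blocks[[spans$block_id[si]]]
        qrow <- b$rows[[q$genome_id]]
        cols1 <- (spans$col_start[si] + 1L):spans$col_end[si]
        qng <- qrow$nongap[cols1]
        for (g in names(b$rows)) {
          if (g == q$genome_id) next
          row <- b$rows[[g]]
          cng <- row$nongap[cols1]
          both <- qng & cng
          if (!any(both)) next
          posb <- row$col2pos[cols1[both]]
          gtree <- index$gene_trees[[tkey(g, row$contig_id)]]
          hits <- tree_query(gtree, min(posb), max(posb) + 1L)
          if (length(hits) == 0L) next
          for (j in gtree$payload[hits]) {
            if (!alive[j]) next
            a <- max(genes$start[j], row$fwd_start)
            bb <- min(genes$end[j], row$fwd_start + row$size) - 1L
            if (a > bb) next
            cj1 <- row$pos2col[a - row$fwd_start + 1L]
            cj2 <- row$pos2col[bb - row$fwd_start + 1L]
            lo <- max(min(cj1, cj2), spans$col_start[si] + 1L)
            hi <- min(max(cj1, cj2), spans$col_end[si])
            if (lo > hi) next
            cc <- lo:hi
            nsh <- sum(qrow$nongap[cc] & row$nongap[cc])
            key <- as.character(j)
            shared[key] <- (shared[key] %||% 0) + nsh
            if (is.na(shared[key])) shared[key] <- nsh
          }
        }
      }
      if (length(shared)) {
        js <- as.integer(names(shared))
        ok <- shared >= cov_match * len[js]
        joined <- js[ok]
        joined <- joined[order(genes$genome_id[joined], genes$gene_id[joined])]
        alive[joined] <- FALSE
      }
    }
    ng <- ng + 1L
    members <- c(i, joined)
    counts <- table(genes$genome_id[members])
    groups[[ng]] <- list(
      group_id = sprintf("OG%05d", ng),
      query_gene = genes$gene_id[i],
      members = genes$gene_id[members],
      member_genomes = genes$genome_id[members],
      genomes_present = sort(unique(genes$genome_id[members])),
      n_per_genome = stats::setNames(as.integer(counts), names(counts))
    )
  }
  groups
}

#' Count groups where a single genome is the sole inconsistency
#'
#' For each genome, the number of ortholog groups in which that genome's
#' annotation is the only mismatch: removing its gene(s) would make the
#' remaining annotations fully consistent.
#'
#' @param groups Result of [group_orthologs()].
#' @param anomalies Result of [classify_groups()].
#' @param genomes Optional character vector of all genome ids (to include
#'   zero counts).
#' @return A `data.frame` with columns `genome_id`, `n_sole_outlier`.
#' @export
per_genome_inconsistency_counts <- function(groups, anomalies, genomes = NULL) {
  if (is.null(genomes)) {
    genomes <- sort(unique(unlist(lapply(groups, `[[`, "member_genomes"),
                                  use.names = FALSE)))
  }
  counts <- stats::setNames(integer(length(genomes)), genomes)
  so <- anomalies$sole_outlier_genome
  so <- so[!is.na(so)]
  if (length(so)) {
    tb <- table(so)
    counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
  }
  data.frame(genome_id = genomes, n_sole_outlier = as.integer(counts),
             stringsAsFactors = FALSE)
}
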