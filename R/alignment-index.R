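# Interval-tree indexing of alignment blocks and gene annotations, and
# bidirectional projection between genome coordinates and alignment columns.
#
# Alignment columns are the shared coordinate system in which "same location"
# comparisons happen. Columns are 0-based within a block. A gap column
# projects to the nearest non-gap position on the LEFT of the row text (a
# deterministic anchor needed for ORF extraction across indels).

# Build per-row lookup vectors:
#  * nongap: logical, one per column
#  * col2pos: integer, one per column, 0-based forward-strand position of the
#    base at that column, or of the nearest non-gap character to the left in
#    the row text (-1 if none)
#  * pos2col: integer, one per base (index pos - fwd_start + 1), 1-based
#    internal column index
index_row <- function(row) {
  ch <- strsplit(row$text, "", fixed = TRUE)[[1]]
  ng <- ch != "-"
  if (sum(ng) != row$size) {
    stop2("block row ", row$genome_id, ".", row$contig_id,
          ": non-gap count != size")
  }
  # forward-strand position of each base, in row-text order
  pos_text_order <- if (row$strand == "+") {
    row$fwd_start + seq.int(0L, row$size - 1L)
  } else {
    row$fwd_start + row$size - 1L - seq.int(0L, row$size - 1L)
  }
  idx <- cumsum(ng)
  col2pos <- rep(-1L, length(ng))
  has <- idx > 0L
  col2pos[has] <- pos_text_order[idx[has]]
  pos2col <- integer(row$size)
  pos2col[pos_text_order - row$fwd_start + 1L] <- which(ng)
  row$nongap <- ng
  row$col2pos <- as.integer(col2pos)
  row$pos2col <- pos2col
  row
}

make_tree <- function(starts0, ends0, payload) {
  # 0-based half-open -> IRanges 1-based inclusive
  ir <- IRanges::IRanges(start = starts0 + 1L, end = ends0)
  list(ranges = ir, nclist = IRanges::NCList(ir), payload = payload)
}

tree_query <- function(tree, start0, end0) {
  if (is.null(tree)) return(integer(0))
  q <- IRanges::IRanges(start = start0 + 1L, end = end0)
  hits <- IRanges::findOverlaps(q, tree$nclist)
  S4Vectors::subjectHits(hits)
}

tkey <- function(genome_id, contig_id) paste(genome_id, contig_id, sep = "\r")

#' Build an alignment index over blocks and gene annotations
#'
#' Stores, per (genome, contig), an interval tree of the aligned row segments
#' and a second interval tree of the gene intervals, plus per-row column maps
#' supporting constant-time position/column lookups.
#'
#' @param blocks List of alignment blocks from [read_maf()].
#' @param genes A [gene_table()] with annotations for all genomes.
#' @param genomes Optional named list of [genome_sequence()] objects; stored
#'   for downstream ORF evaluation and contig-length checks.
#' @return An object of class `alignment_index`.
#' @export
build_alignment_index <- function(blocks, genes, genomes = NULL) {
  stopifnot(inherits(genes, "data.frame"))
  names(blocks) <- vapply(blocks, `[[`, "", "block_id")
  blocks <- lapply(blocks, function(b) {
    b$rows <- lapply(b$rows, index_row)
    b
  })

  row_df <- if (length(blocks)) {
    do.call(rbind, lapply(blocks, function(b) {
      data.frame(
        block_id = b$block_id,
        genome_id = vapply(b$rows, `[[`, "", "genome_id"),
        contig_id = vapply(b$rows, `[[`, "", "contig_id"),
        start = vapply(b$rows, `[[`, 0L, "fwd_start"),
        end = vapply(b$rows, function(r) r$fwd_start + r$size, 0L),
        stringsAsFactors = FALSE, row.names = NULL
      )
    }))
  } else {
    data.frame(block_id = character(0), genome_id = character(0),
               contig_id = character(0), start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  }

  row_trees <- list()
  if (nrow(row_df)) {
    for (k in split(seq_len(nrow(row_df)), tkey(row_df$genome_id, row_df$contig_id))) {
      key <- tkey(row_df$genome_id[k[1]], row_df$contig_id[k[1]])
      row_trees[[key]] <- make_tree(row_df$start[k], row_df$end[k],
                                    row_df$block_id[k])
    }
  }

  gene_trees <- list()
  if (nrow(genes)) {
    for (k in split(seq_len(nrow(genes)), tkey(genes$genome_id, genes$contig_id))) {
      key <- tkey(genes$genome_id[k[1]], genes$contig_id[k[1]])
      gene_trees[[key]] <- make_tree(genes$start[k], genes$end[k], k)
    }
  }

  all_genomes <- sort(unique(c(
    genes$genome_id,
    unlist(lapply(blocks, function(b) names(b$rows)), use.names = FALSE),
    names(genomes)
  )))

  idx <- structure(list(
    blocks = blocks, row_trees = row_trees, gene_trees = gene_trees,
    genes = genes, genomes = genomes, all_genomes = all_genomes
  ), class = "alignment_index")

  idx$gene_aligned <- if (nrow(genes)) {
    vapply(seq_len(nrow(genes)), function(i) {
      length(tree_query(row_trees[[tkey(genes$genome_id[i], genes$contig_id[i])]],
                        genes$start[i], genes$end[i])) > 0L
    }, TRUE)
  } else logical(0)
  idx
}

#' @export
print.alignment_index <- function(x, ...) {
  cat("<alignment_index> ", length(x$blocks), " block(s), ",
      nrow(x$genes), " gene(s), ", length(x$all_genomes), " genome(s)\n",
      sep = "")
  invisible(x)
}

known_location <- function(index, genome_id, contig_id) {
  key <- tkey(genome_id, contig_id)
  if (!is.null(index$row_trees[[key]]) || !is.null(index$gene_trees[[key]])) {
    return(TRUE)
  }
  if (!is.null(index$genomes) && !is.null(index$genomes[[genome_id]]) &&
      contig_id %in% names(index$genomes[[genome_id]]$contigs)) {
    return(TRUE)
  }
  FALSE
}

#' Project a genome position to an alignment column
#'
#' @param index An [build_alignment_index()] result.
#' @param genome_id,contig_id Location of the position.
#' @param pos 0-based forward-strand offset.
#' @return A list `(block_id, column)` with a 0-based column, or `NULL` when
#'   the position is unaligned. When multiple blocks cover the position the
#'   lowest block id wins.
#' @export
project_to_column <- function(index, genome_id, contig_id, pos) {
  if (!known_location(index, genome_id, contig_id)) {
    stop2("unknown genome/contig: ", genome_id, ".", contig_id)
  }
  tree <- index$row_trees[[tkey(genome_id, contig_id)]]
  hits <- tree_query(tree, pos, pos + 1L)
  if (length(hits) == 0L) return(NULL)
  bids <- sort(tree$payload[hits])
  bid <- bids[1]
  row <- index$blocks[[bid]]$rows[[genome_id]]
  list(block_id = bid, column = row$pos2col[pos - row$fwd_start + 1L] - 1L)
}

#' Project an alignment column into a genome
#'
#' @param index An [build_alignment_index()] result.
#' @param block_id Block identifier.
#' @param column 0-based column index.
#' @param genome_id Target genome.
#' @return A list with `absent` (`TRUE` when the genome has no row in the
#'   block), `contig_id`, `pos` (0-based forward-strand offset; for a gap
#'   column the offset of the nearest non-gap character to the left in the
#'   row text, -1 if none) and `is_gap`.
#' @export
project_from_column <- function(index, block_id, column, genome_id) {
  b <- index$blocks[[block_id]]
  if (is.null(b)) stop2("unknown block: ", block_id)
  if (column < 0L || column >= b$width) {
    stop2("column ", column, " outside block ", block_id, " width ", b$width)
  }
  row <- b$rows[[genome_id]]
  if (is.null(row)) return(list(absent = TRUE, genome_id = genome_id))
  c1 <- column + 1L
  list(absent = FALSE, genome_id = genome_id, contig_id = row$contig_id,
       pos = row$col2pos[c1], is_gap = !row$nongap[c1])
}

#' Column span of a gene in each overlapping block
#'
#' For each alignment block overlapping the gene, the smallest 0-based
#' half-open column interval containing all the gene's aligned bases there,
#' plus the number of gene bases aligned in that block. The block containing
#' the gene's stop codon is listed first (ties: most covered bases, then
#' lowest block id); downstream consumers use it as the primary anchor for
#' genes split across blocks.
#'
#' @param index An [build_alignment_index()] result.
#' @param gene One row of a [gene_table()].
#' @return A `data.frame` with columns `block_id`, `col_start`, `col_end`,
#'   `covered_bases`; zero rows for an unaligned gene.
#' @export
gene_column_span <- function(index, gene) {
  empty <- data.frame(block_id = character(0), col_start = integer(0),
                      col_end = integer(0), covered_bases = integer(0),
                      stringsAsFactors = FALSE)
  tree <- index$row_trees[[tkey(gene$genome_id, gene$contig_id)]]
  hits <- tree_query(tree, gene$start, gene$end)
  if (length(hits) == 0L) return(empty)
  bids <- tree$payload[hits]
  out <- lapply(bids, function(bid) {
    row <- index$blocks[[bid]]$rows[[gene$genome_id]]
    a <- max(gene$start, row$fwd_start)
    b <- min(gene$end, row$fwd_start + row$size) - 1L
    if (a > b) return(NULL)
    c1 <- row$pos2col[a - row$fwd_start + 1L]
    c2 <- row$pos2col[b - row$fwd_start + 1L]
    data.frame(block_id = bid, col_start = min(c1, c2) - 1L,
               col_end = max(c1, c2), covered_bases = b - a + 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out) || nrow(out) == 0L) return(empty)
  # primary anchor: block containing the stop codon's terminal base
  stop_pos <- terminus_pos(gene, "stop")
  prim <- vapply(out$block_id, function(bid) {
    row <- index$blocks[[bid]]$rows[[gene$genome_id]]
    stop_pos >= row$fwd_start && stop_pos < row$fwd_start + row$size
  }, TRUE)
  ord <- order(!prim, -out$covered_bases, out$block_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# 0-based position of a gene terminus: the biological 5' base for "start",
# the biological 3' terminal base for "stop".
terminus_pos <- function(gene, what = c("start", "stop")) {
  what <- match.arg(what)
  if (gene$strand == "+") {
    if (what == "start") gene$start else gene$end - 1L
  } else {
    if (what == "start") gene$end - 1L else gene$start
  }
}
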