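# Classification of ortholog groups into annotation-consistency classes, and
# detection of missing annotations and contig-boundary artifacts.
#
# All comparisons happen in alignment-column space: two termini agree only if
# they sit in the same block at the same column (genes anchored in different
# blocks are never guessed equal).

#' Locate a gene's start and stop codons in the alignment
#'
#' The start locus is the column of the biological 5' base of the start codon
#' (forward-strand leftmost base for `+` genes, rightmost for `-` genes); the
#' stop locus is the column of the biological 3' terminal base.
#'
#' @param index An [build_alignment_index()] result.
#' @param gene One row of a [gene_table()].
#' @return A list with `start` and `stop`, each either a
#'   `(block_id, column, strand)` list (strand is the gene strand expressed in
#'   block orientation) or `NULL` with a `reason` when that terminus is
#'   unaligned. Errors if the gene is fully unaligned.
#' @export
locate_gene_termini <- function(index, gene) {
  spans <- gene_column_span(index, gene)
  if (nrow(spans) == 0L) {
    stop2("gene '", gene$gene_id, "' is fully unaligned")
  }
  one <- function(what) {
    pos <- terminus_pos(gene, what)
    loc <- project_to_column(index, gene$genome_id, gene$contig_id, pos)
    if (is.null(loc)) return(NULL)
    row <- index$blocks[[loc$block_id]]$rows[[gene$genome_id]]
    loc$strand <- compose_strand(gene$strand, row$strand)
    loc
  }
  res <- list(start = one("start"), stop = one("stop"))
  if (is.null(res$start)) res$start_reason <- "start terminus unaligned"
  if (is.null(res$stop)) res$stop_reason <- "stop terminus unaligned"
  res
}

# Termini table for all members of a group. Fully unaligned members (only
# possible for singletons) get NA loci instead of the error
# locate_gene_termini() raises.
group_termini <- function(group, index) {
  genes <- index$genes
  rows <- lapply(group$members, function(gid) {
    g <- genes[genes$gene_id == gid, , drop = FALSE][1, ]
    t <- tryCatch(locate_gene_termini(index, g),
                  error = function(e) list(start = NULL, stop = NULL))
    data.frame(
      group_id = group$group_id, gene_id = gid, genome_id = g$genome_id,
      s_block = if (is.null(t$start)) NA_character_ else t$start$block_id,
      s_col = if (is.null(t$start)) NA_integer_ else t$start$column,
      e_block = if (is.null(t$stop)) NA_character_ else t$stop$block_id,
      e_col = if (is.null(t$stop)) NA_integer_ else t$stop$column,
      strand_aln = if (!is.null(t$stop)) t$stop$strand else
        if (!is.null(t$start)) t$start$strand else NA_character_,
      gene_strand = g$strand,
      length = g$end - g$start,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

all_same <- function(x) !anyNA(x) && length(unique(x)) == 1L

termini_consistent <- function(tm) {
  if (anyDuplicated(tm$genome_id)) return(FALSE)
  all_same(paste(tm$s_block, tm$s_col)) && all_same(paste(tm$e_block, tm$e_col))
}

#' Classify one ortholog group
#'
#' Decision table over member termini: all start columns equal and all stop
#' columns equal and at most one gene per genome gives `consistent`; stops
#' equal but starts differing gives `inconsistent_starts`; starts equal but
#' stops differing gives `inconsistent_stops`; both differing (which absorbs
#' members on different strands or reading frames) gives `combination`. Any
#' genome contributing two or more members makes the group a `fragmentation`
#' anomaly; the boundary comparison is then kept as a secondary class.
#' Singleton groups are classified `singleton` and excluded from anomaly
#' statistics. `sole_outlier_genome` is set when removing exactly one
#' genome's gene(s) leaves the rest consistent.
#'
#' @param group One group from [group_orthologs()].
#' @param index An [build_alignment_index()] result.
#' @return A one-row `data.frame` (see [classify_groups()] for columns) with
#'   the member termini attached as attribute `"termini"`.
#' @export
classify_group <- function(group, index) {
  tm <- group_termini(group, index)
  n_members <- nrow(tm)
  n_genomes <- length(unique(tm$genome_id))
  res <- data.frame(
    group_id = group$group_id, class = "consistent",
    secondary_classes = NA_character_,
    n_genomes = n_genomes, n_members = n_members,
    sole_outlier_genome = NA_character_,
    contig_boundary = FALSE, block_split = FALSE,
    stringsAsFactors = FALSE
  )
  if (n_members == 1L) {
    res$class <- "singleton"
    attr(res, "termini") <- tm
    return(res)
  }
  skey <- paste(tm$s_block, tm$s_col)
  ekey <- paste(tm$e_block, tm$e_col)
  starts_eq <- all_same(skey) && !anyNA(tm$s_col)
  stops_eq <- all_same(ekey) && !anyNA(tm$e_col)
  mixed_strand <- length(unique(tm$strand_aln[!is.na(tm$strand_aln)])) > 1L
  block_split <- length(unique(c(tm$s_block, tm$e_block))) > 1L

  boundary <- if (mixed_strand) {
    "combination"
  } else if (starts_eq && stops_eq) {
    "consistent"
  } else if (stops_eq) {
    "inconsistent_starts"
  } else if (starts_eq) {
    "inconsistent_stops"
  } else {
    "combination"
  }

  frag <- anyDuplicated(tm$genome_id) > 0L
  if (frag) {
    res$class <- "fragmentation"
    if (boundary != "consistent") res$secondary_classes <- boundary
  } else {
    res$class <- boundary
  }
  res$block_split <- block_split

  if (res$class != "consistent") {
    cand <- character(0)
    for (g in unique(tm$genome_id)) {
      rest <- tm[tm$genome_id != g, , drop = FALSE]
      if (nrow(rest) >= 1L && termini_consistent(rest)) cand <- c(cand, g)
    }
    if (length(cand) == 1L) res$sole_outlier_genome <- cand
  }
  attr(res, "termini") <- tm
  res
}

#' Classify all ortholog groups
#'
#' @param groups Result of [group_orthologs()].
#' @param index An [build_alignment_index()] result.
#' @return A `data.frame` with one row per group: `group_id`, `class` (one of
#'   `consistent`, `inconsistent_starts`, `inconsistent_stops`, `combination`,
#'   `fragmentation`, `singleton`), `secondary_classes`, `n_genomes`,
#'   `n_members`, `sole_outlier_genome`, `contig_boundary`, `block_split`.
#'   The combined member-termini table is attached as attribute `"termini"`.
#' @export
classify_groups <- function(groups, index) {
  if (length(groups) == 0L) {
    res <- data.frame(group_id = character(0), class = character(0),
                      secondary_classes = character(0), n_genomes = integer(0),
                      n_members = integer(0), sole_outlier_genome = character(0),
                      contig_boundary = logical(0), block_split = logical(0),
                      stringsAsFactors = FALSE)
    attr(res, "termini") <- NULL
    return(res)
  }
  parts <- lapply(groups, classify_group, index = index)
  res <- do.call(rbind, parts)
  attr(res, "termini") <- do.call(rbind, lapply(parts, attr, "termini"))
  rownames(res) <- NULL
  res
}

#' Flag anomalies attributable to contig boundaries
#'
#' A group is flagged when any member gene is marked partial (5' or 3') or
#' any member terminus lies within `W` bp of a contig end: draft assemblies
#' truncate genes at contig boundaries, and such anomalies reflect sequencing
#' rather than annotation.
#'
#' @param anomalies Result of [classify_groups()].
#' @param groups Result of [group_orthologs()].
#' @param genes The [gene_table()] used throughout.
#' @param genomes Named list of [genome_sequence()] objects (for contig
#'   lengths); may be `NULL`, in which case only partial flags are used.
#' @param W Window in bp (default 10).
#' @return `anomalies` with the `contig_boundary` column filled in.
#' @export
flag_contig_boundary <- function(anomalies, groups, genes, genomes = NULL,
                                 W = 10L) {
  if (nrow(anomalies) == 0L) return(anomalies)
  byid <- stats::setNames(groups, vapply(groups, `[[`, "", "group_id"))
  flags <- vapply(anomalies$group_id, function(gid) {
    g <- byid[[gid]]
    mm <- genes[genes$gene_id %in% g$members, , drop = FALSE]
    if (any(mm$partial5 | mm$partial3)) return(TRUE)
    if (is.null(genomes)) return(FALSE)
    for (k in seq_len(nrow(mm))) {
      gn <- genomes[[mm$genome_id[k]]]
      if (is.null(gn)) next
      clen <- nchar(gn$contigs[[mm$contig_id[k]]] %||% "")
      if (clen == 0L) next
      if (mm$start[k] < W || (clen - mm$end[k]) < W) return(TRUE)
    }
    FALSE
  }, TRUE, USE.NAMES = FALSE)
  anomalies$contig_boundary <- flags
  attr(anomalies, "termini") <- attr(anomalies, "termini")
  anomalies
}

#' Find putative missing annotations
#'
#' For each group, genomes that are aligned across the group's region but
#' contribute no member gene are reported with the query gene's interval
#' projected into that genome, provided no annotated gene of any kind
#' overlaps the projection. Reporting is restricted to groups whose aligned
#' region covers at least `min_genome_frac` of all genomes in the run, which
#' suppresses noise from accessory regions aligned in only a few isolates.
#'
#' @param groups Result of [group_orthologs()].
#' @param index An [build_alignment_index()] result.
#' @param min_genome_frac Minimum fraction of all genomes that must be
#'   aligned in the group's region (default 0.9).
#' @return A `data.frame` with columns `group_id`, `genome_id`, `contig_id`,
#'   `start`, `end` (projected 0-based half-open interval).
#' @export
find_missing_annotations <- function(groups, index, min_genome_frac = 0.9) {
  empty <- data.frame(group_id = character(0), genome_id = character(0),
                      contig_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (length(groups) == 0L) return(empty)
  n_total <- length(index$all_genomes)
  out <- list()
  for (g in groups) {
    q <- index$genes[index$genes$gene_id == g$query_gene, , drop = FALSE][1, ]
    spans <- gene_column_span(index, q)
    if (nrow(spans) == 0L) next
    # genomes with at least one aligned base inside the span
    proj <- list()  # genome -> (contig, min pos, max pos, n aligned)
    for (si in seq_len(nrow(spans))) {
      b <- index$blocks[[spans$block_id[si]]]
      cols1 <- (spans$col_start[si] + 1L):spans$col_end[si]
      for (gm in names(b$rows)) {
        row <- b$rows[[gm]]
        ng <- row$nongap[cols1]
        if (!any(ng)) next
        posb <- row$col2pos[cols1[ng]]
        cur <- proj[[gm]]
        if (is.null(cur) || cur$contig == row$contig_id) {
          proj[[gm]] <- list(
            contig = row$contig_id,
            lo = min(posb, cur$lo %||% Inf),
            hi = max(posb, cur$hi %||% -Inf),
            n = (cur$n %||% 0L) + length(posb)
          )
        }
      }
    }
    aligned <- names(proj)
    if (length(aligned) / n_total < min_genome_frac) next
    for (gm in setdiff(aligned, g$genomes_present)) {
      p <- proj[[gm]]
      hits <- tree_query(index$gene_trees[[tkey(gm, p$contig)]], p$lo, p$hi + 1L)
      if (length(hits) > 0L) next
      out[[length(out) + 1L]] <- data.frame(
        group_id = g$group_id, genome_id = gm, contig_id = p$contig,
        start = as.integer(p$lo), end = as.integer(p$hi + 1L),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}
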