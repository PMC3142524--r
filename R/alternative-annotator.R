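# Enumeration and ranking of alternative gene structures: start/stop column
# pairs drawn from the annotated termini of a group, evaluated for ORF
# validity (bacterial translation table 11) in every aligned genome, with
# optional single-frameshift repair at alignment gap columns.

#' Codon configuration
#'
#' The genetic-code symbols used for ORF validation. The default start set
#' `{ATG, GTG, TTG}` is the common prokaryotic-annotation subset of the
#' bacterial/archaeal code (which formally admits rarer initiators such as
#' ATT or CTG); widen it here if your annotations use them.
#'
#' @param start_codons,stop_codons Character vectors of length-3 DNA codons;
#'   the two sets must be disjoint.
#' @param max_frameshifts Maximum number of frameshifts allowed when
#'   repairing an invalid ORF across alignment gaps (default 1, maximum 2).
#' @return A list of class `codon_config`.
#' @export
codon_config <- function(start_codons = c("ATG", "GTG", "TTG"),
                         stop_codons = c("TAA", "TAG", "TGA"),
                         max_frameshifts = 1L) {
  start_codons <- toupper(start_codons)
  stop_codons <- toupper(stop_codons)
  stopifnot(all(nchar(start_codons) == 3L), all(nchar(stop_codons) == 3L),
            length(intersect(start_codons, stop_codons)) == 0L,
            max_frameshifts >= 0L, max_frameshifts <= 2L)
  structure(list(start_codons = start_codons, stop_codons = stop_codons,
                 max_frameshifts = as.integer(max_frameshifts)),
            class = "codon_config")
}

# Plain in-frame ORF check.
check_orf <- function(seq, cfg) {
  L <- nchar(seq)
  if (L < 6L || L %% 3L != 0L) return(FALSE)
  cod <- split_codons(seq)
  n <- length(cod)
  cod[1] %in% cfg$start_codons && cod[n] %in% cfg$stop_codons &&
    !any(cod[-c(1L, n)] %in% cfg$stop_codons)
}

# ORF check with a single frame change after `q` bases (the 5' segment is
# read in the start-anchored frame, the 3' segment in the stop-anchored
# frame; up to two bases straddling the junction are left unchecked).
check_orf_shift <- function(seq, q, cfg) {
  L <- nchar(seq)
  if (L %% 3L == 0L) return(FALSE)
  if (q < 3L || q > L - 3L) return(FALSE)
  n1 <- q %/% 3L
  pre_starts <- seq.int(1L, by = 3L, length.out = n1)
  pre <- substring(seq, pre_starts, pre_starts + 2L)
  if (!pre[1] %in% cfg$start_codons) return(FALSE)
  if (n1 > 1L && any(pre[-1L] %in% cfg$stop_codons)) return(FALSE)
  m <- L - q
  n2 <- m %/% 3L
  if (n2 < 1L) return(FALSE)
  suf_starts <- L - 3L * seq.int(n2, 1L) + 1L
  if (suf_starts[1] < q + 1L) suf_starts <- suf_starts[-1L]
  n2 <- length(suf_starts)
  if (n2 < 1L) return(FALSE)
  suf <- substring(seq, suf_starts, suf_starts + 2L)
  if (!suf[n2] %in% cfg$stop_codons) return(FALSE)
  if (n2 > 1L && any(suf[-n2] %in% cfg$stop_codons)) return(FALSE)
  TRUE
}

#' Enumerate candidate start/stop column pairs for a group
#'
#' The Cartesian pairing of all distinct annotated start loci with all
#' distinct annotated stop loci observed among group members, restricted to
#' strand-consistent pairs with the start 5' of the stop, deduplicated.
#'
#' @param group One group from [group_orthologs()].
#' @param index An [build_alignment_index()] result.
#' @param termini Optional precomputed termini table for the group (from the
#'   `"termini"` attribute of [classify_groups()]).
#' @return A `data.frame` with columns `start_block`, `start_col`,
#'   `stop_block`, `stop_col`, `strand`.
#' @export
enumerate_codon_pairs <- function(group, index, termini = NULL) {
  tm <- termini %||% group_termini(group, index)
  tm <- tm[tm$group_id == group$group_id, , drop = FALSE]
  empty <- data.frame(start_block = character(0), start_col = integer(0),
                      stop_block = character(0), stop_col = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  st <- unique(tm[!is.na(tm$s_col), c("s_block", "s_col", "strand_aln")])
  en <- unique(tm[!is.na(tm$e_col), c("e_block", "e_col", "strand_aln")])
  if (nrow(st) == 0L || nrow(en) == 0L) return(empty)
  pairs <- merge(st, en, by = NULL)
  pairs <- pairs[pairs$strand_aln.x == pairs$strand_aln.y, , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty)
  same_block <- pairs$s_block == pairs$e_block
  ok <- !same_block |
    (pairs$strand_aln.x == "+" & pairs$s_col < pairs$e_col) |
    (pairs$strand_aln.x == "-" & pairs$s_col > pairs$e_col)
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty)
  out <- data.frame(start_block = pairs$s_block, start_col = pairs$s_col,
                    stop_block = pairs$e_block, stop_col = pairs$e_col,
                    strand = pairs$strand_aln.x, stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$start_block, out$start_col, out$stop_block, out$stop_col), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

invalid_eval <- function(genome_id, reason) {
  list(genome_id = genome_id, absent = identical(reason, "absent"),
       orf_valid = FALSE, n_frameshifts = 0L, shift_cols = integer(0),
       reason = reason)
}

#' Evaluate a start/stop column pair as an ORF in one genome
#'
#' Projects both loci into the genome (gap columns anchor to the nearest
#' non-gap position on the left of the row text), extracts the genomic
#' subsequence on the gene strand, and checks it for a valid start codon,
#' terminal stop codon and absence of internal in-frame stops. When the
#' direct check fails and the genome's row contains gap columns inside the
#' span, up to `max_frameshifts` frame changes are tried at gap-adjacent
#' positions (within one codon of the gap anchor), keeping the minimal number
#' of shifts that validates.
#'
#' @param pair One row of [enumerate_codon_pairs()] output.
#' @param genome_id Target genome.
#' @param index An [build_alignment_index()] result.
#' @param genomes Named list of [genome_sequence()] objects.
#' @param cfg A [codon_config()].
#' @return A list with `genome_id`, `absent`, `contig_id`, `start`, `end`
#'   (0-based half-open genomic interval), `strand`, `orf_valid`,
#'   `n_frameshifts`, `shift_cols` (0-based gap columns used) and `reason`
#'   for invalid results.
#' @export
evaluate_orf <- function(pair, genome_id, index, genomes, cfg = codon_config()) {
  ps <- project_from_column(index, pair$start_block, pair$start_col, genome_id)
  pe <- project_from_column(index, pair$stop_block, pair$stop_col, genome_id)
  if (isTRUE(ps$absent) || isTRUE(pe$absent)) {
    return(invalid_eval(genome_id, "absent"))
  }
  if (ps$contig_id != pe$contig_id) return(invalid_eval(genome_id, "unprojectable"))
  gseq <- genomes[[genome_id]]
  if (is.null(gseq)) return(invalid_eval(genome_id, "no sequence"))
  contig <- gseq$contigs[[ps$contig_id]]
  if (is.null(contig)) return(invalid_eval(genome_id, "no sequence"))

  row <- index$blocks[[pair$start_block]]$rows[[genome_id]]
  eff <- compose_strand(pair$strand, row$strand)
  a <- if (eff == "+") ps$pos else pe$pos
  b <- if (eff == "+") pe$pos else ps$pos
  if (is.na(a) || is.na(b) || a < 0L || b < 0L || b >= nchar(contig) || b - a + 1L < 6L) {
    return(invalid_eval(genome_id, "unprojectable"))
  }
  seq <- substr(contig, a + 1L, b + 1L)
  if (eff == "-") seq <- revcomp(seq)
  L <- nchar(seq)

  base <- list(genome_id = genome_id, absent = FALSE, contig_id = ps$contig_id,
               start = a, end = b + 1L, strand = eff, orf_valid = FALSE,
               n_frameshifts = 0L, shift_cols = integer(0), reason = NA_character_)
  if (check_orf(seq, cfg)) {
    base$orf_valid <- TRUE
    return(base)
  }

  # single-frameshift repair at alignment gaps (same-block pairs only)
  if (cfg$max_frameshifts >= 1L && pair$start_block == pair$stop_block) {
    clo <- min(pair$start_col, pair$stop_col) + 1L
    chi <- max(pair$start_col, pair$stop_col) + 1L
    gapcols <- which(!row$nongap[clo:chi]) + clo - 1L  # 1-based internal
    if (length(gapcols) && L %% 3L != 0L) {
      runs <- split(gapcols, cumsum(c(1L, diff(gapcols) != 1L)))
      for (run in runs) {
        anchor <- row$col2pos[run[1]]
        if (anchor < 0L) next
        q0 <- if (eff == "+") anchor - a + 1L else b - anchor
        for (dq in c(0L, 1L, -1L, 2L, -2L, 3L, -3L)) {
          q <- q0 + dq
          if (check_orf_shift(seq, q, cfg)) {
            base$orf_valid <- TRUE
            base$n_frameshifts <- 1L
            base$shift_cols <- run[1] - 1L  # 0-based column
            return(base)
          }
        }
      }
    }
  }
  base$reason <- "invalid ORF"
  base
}

#' Flag candidate intervals that overlap genes outside the group
#'
#' @param evals Per-genome evaluations of one candidate (list as returned by
#'   [evaluate_orf()]).
#' @param member_ids Gene ids of the group's members (overlap with the gene
#'   being replaced is not flagged).
#' @param index An [build_alignment_index()] result.
#' @return `TRUE` when, in any genome, the candidate interval overlaps at
#'   least 1 bp of an annotated gene outside the group.
#' @export
flag_overlaps <- function(evals, member_ids, index) {
  for (e in evals) {
    if (isTRUE(e$absent) || is.null(e$start) || is.na(e$start %||% NA)) next
    tree <- index$gene_trees[[tkey(e$genome_id, e$contig_id)]]
    hits <- tree_query(tree, e$start, e$end)
    if (length(hits) == 0L) next
    hit_ids <- index$genes$gene_id[tree$payload[hits]]
    if (any(!hit_ids %in% member_ids)) return(TRUE)
  }
  FALSE
}

#' Rank evaluated alternative annotations
#'
#' Candidates whose projected length in a genome falls below
#' `min_len_frac` of that genome's annotated member length are dropped (the
#' filter is applied only where the genome has an annotated member).
#' Survivors are sorted by the configured order (default: number of valid
#' ORFs, then length, both descending; ties broken by start then stop locus)
#' and assigned ranks from 1.
#'
#' @param cands List of candidates, each a list with `pair` (one row of
#'   [enumerate_codon_pairs()]) and `evals` (per-genome [evaluate_orf()]
#'   results).
#' @param group The group the candidates belong to.
#' @param index An [build_alignment_index()] result.
#' @param min_len_frac Minimum candidate/annotated length ratio (default 0.5).
#' @param sort_order `"valid_orfs,length"` (default) or `"length,valid_orfs"`.
#' @return A `data.frame` with one row per retained candidate: `group_id`,
#'   `rank`, the pair loci, `strand`, `n_valid_orfs`, `length` (ungapped span
#'   in the query genome), `n_frameshifts` (total over genomes),
#'   `overlap_flag`, and a list-column `evals` with the per-genome detail.
#' @export
rank_alternatives <- function(cands, group, index, min_len_frac = 0.5,
                              sort_order = "valid_orfs,length") {
  empty <- data.frame(group_id = character(0), rank = integer(0),
                      start_block = character(0), start_col = integer(0),
                      stop_block = character(0), stop_col = integer(0),
                      strand = character(0), n_valid_orfs = integer(0),
                      length = integer(0), n_frameshifts = integer(0),
                      overlap_flag = logical(0), stringsAsFactors = FALSE)
  empty$evals <- list()
  if (length(cands) == 0L) return(empty)
  genes <- index$genes
  members <- genes[genes$gene_id %in% group$members, , drop = FALSE]
  ann_len <- tapply(gene_length(members), members$genome_id, max)
  qgenome <- members$genome_id[members$gene_id == group$query_gene][1]

  rows <- list()
  for (cand in cands) {
    evals <- cand$evals
    # length filter against the annotated length in the same genome
    drop <- FALSE
    for (e in evals) {
      if (isTRUE(e$absent) || is.null(e$start)) next
      al <- ann_len[e$genome_id]
      if (!is.na(al) && (e$end - e$start) < min_len_frac * al) {
        drop <- TRUE
        break
      }
    }
    if (drop) next
    qlen <- NA_integer_
    for (e in evals) {
      if (identical(e$genome_id, qgenome) && !isTRUE(e$absent) &&
          !is.null(e$start)) {
        qlen <- e$end - e$start
      }
    }
    if (is.na(qlen)) {
      lens <- vapply(evals, function(e) {
        if (isTRUE(e$absent) || is.null(e$start)) NA_integer_ else e$end - e$start
      }, 0L)
      qlen <- if (all(is.na(lens))) 0L else as.integer(max(lens, na.rm = TRUE))
    }
    rows[[length(rows) + 1L]] <- list(
      pair = cand$pair,
      n_valid = sum(vapply(evals, function(e) isTRUE(e$orf_valid), TRUE)),
      length = qlen,
      n_fs = sum(vapply(evals, function(e) e$n_frameshifts %||% 0L, 0L)),
      overlap = flag_overlaps(evals, group$members, index),
      evals = evals
    )
  }
  if (length(rows) == 0L) return(empty)

  nv <- vapply(rows, `[[`, 0L, "n_valid")
  ln <- vapply(rows, `[[`, 0L, "length")
  sb <- vapply(rows, function(r) r$pair$start_block, "")
  sc <- vapply(rows, function(r) r$pair$start_col, 0L)
  eb <- vapply(rows, function(r) r$pair$stop_block, "")
  ec <- vapply(rows, function(r) r$pair$stop_col, 0L)
  ord <- if (identical(sort_order, "length,valid_orfs")) {
    order(-ln, -nv, sb, sc, eb, ec)
  } else {
    order(-nv, -ln, sb, sc, eb, ec)
  }
  rows <- rows[ord]
  out <- data.frame(
    group_id = group$group_id,
    rank = seq_along(rows),
    start_block = vapply(rows, function(r) r$pair$start_block, ""),
    start_col = vapply(rows, function(r) r$pair$start_col, 0L),
    stop_block = vapply(rows, function(r) r$pair$stop_block, ""),
    stop_col = vapply(rows, function(r) r$pair$stop_col, 0L),
    strand = vapply(rows, function(r) r$pair$strand, ""),
    n_valid_orfs = vapply(rows, `[[`, 0L, "n_valid"),
    length = vapply(rows, `[[`, 0L, "length"),
    n_frameshifts = vapply(rows, `[[`, 0L, "n_fs"),
    overlap_flag = vapply(rows, `[[`, TRUE, "overlap"),
    stringsAsFactors = FALSE
  )
  out$evals <- lapply(rows, `[[`, "evals")
  out
}

# Genomes aligned in the blocks a pair touches.
pair_genomes <- function(pair, index) {
  unique(c(names(index$blocks[[pair$start_block]]$rows),
           names(index$blocks[[pair$stop_block]]$rows)))
}

#' Enumerate, evaluate and rank alternatives for one group
#'
#' @param group One group from [group_orthologs()].
#' @param index An [build_alignment_index()] result.
#' @param genomes Named list of [genome_sequence()] objects.
#' @param cfg A [codon_config()].
#' @param termini Optional precomputed termini table.
#' @param min_len_frac,sort_order Passed to [rank_alternatives()].
#' @return The ranked alternatives `data.frame` (see [rank_alternatives()]).
#' @export
propose_alternatives <- function(group, index, genomes, cfg = codon_config(),
                                 termini = NULL, min_len_frac = 0.5,
                                 sort_order = "valid_orfs,length") {
  pairs <- enumerate_codon_pairs(group, index, termini)
  cands <- lapply(seq_len(nrow(pairs)), function(i) {
    pair <- pairs[i, ]
    gms <- pair_genomes(pair, index)
    list(pair = pair,
         evals = lapply(gms, evaluate_orf, pair = pair, index = index,
                        genomes = genomes, cfg = cfg))
  })
  rank_alternatives(cands, group, index, min_len_frac = min_len_frac,
                    sort_order = sort_order)
}

#' Suggest genes for genomes with missing annotations
#'
#' For each missing-annotation record, the group's best-ranked start/stop
#' pair (its own annotated pair for a consistent group) is evaluated in the
#' unannotated genome; a suggestion is emitted only when the projected region
#' is a valid ORF there.
#'
#' @param missing Result of [find_missing_annotations()].
#' @param groups Result of [group_orthologs()].
#' @param index An [build_alignment_index()] result.
#' @param genomes Named list of [genome_sequence()] objects.
#' @param cfg A [codon_config()].
#' @param alternatives Optional named list (by group id) of ranked
#'   alternatives; the rank-1 pair is used when present.
#' @param termini Optional combined termini table (attribute of
#'   [classify_groups()]).
#' @return A `data.frame` with columns `group_id`, `genome_id`, `contig_id`,
#'   `start`, `end`, `strand`, `n_frameshifts`.
#' @export
suggest_missing_genes <- function(missing, groups, index, genomes,
                                  cfg = codon_config(), alternatives = NULL,
                                  termini = NULL) {
  empty <- data.frame(group_id = character(0), genome_id = character(0),
                      contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_frameshifts = integer(0), stringsAsFactors = FALSE)
  if (is.null(missing) || nrow(missing) == 0L) return(empty)
  byid <- stats::setNames(groups, vapply(groups, `[[`, "", "group_id"))
  out <- list()
  for (i in seq_len(nrow(missing))) {
    gid <- missing$group_id[i]
    g <- byid[[gid]]
    if (is.null(g)) next
    pair <- NULL
    alt <- alternatives[[gid]]
    if (!is.null(alt) && nrow(alt) > 0L) {
      pair <- alt[1, c("start_block", "start_col", "stop_block", "stop_col",
                       "strand")]
      names(pair) <- c("start_block", "start_col", "stop_block", "stop_col",
                       "strand")
    } else {
      pairs <- enumerate_codon_pairs(g, index, termini)
      if (nrow(pairs) > 0L) pair <- pairs[1, ]
    }
    if (is.null(pair)) next
    e <- evaluate_orf(pair, missing$genome_id[i], index, genomes, cfg)
    if (isTRUE(e$orf_valid)) {
      out[[length(out) + 1L]] <- data.frame(
        group_id = gid, genome_id = e$genome_id, contig_id = e$contig_id,
        start = e$start, end = e$end, strand = e$strand,
        n_frameshifts = e$n_frameshifts, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}
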