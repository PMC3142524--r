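# I/O for the standard formats consumed and produced by the pipeline:
# FASTA genomes, GFF3 CDS annotations, MAF whole-genome multiple alignments,
# and tab-delimited report files.
#
# Internal coordinates are 0-based half-open on the forward strand everywhere;
# conversion to/from the 1-based conventions of GFF3 and the strand-relative
# offsets of MAF happens only in this file.

#' Construct a genome sequence object
#'
#' @param genome_id Genome identifier.
#' @param contigs Named character vector of contig sequences (names are contig
#'   ids). Sequences are uppercased; characters outside `A,C,G,T,N` become `N`.
#' @return An object of class `genome_sequence`: a list with elements
#'   `genome_id` and `contigs`.
#' @export
genome_sequence <- function(genome_id, contigs) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  if (length(contigs) == 0L) stop2("genome '", genome_id, "': no contigs")
  if (is.null(names(contigs)) || any(!nzchar(names(contigs)))) {
    stop2("genome '", genome_id, "': contigs must be named")
  }
  if (anyDuplicated(names(contigs))) {
    stop2("genome '", genome_id, "': duplicate contig_id '",
          names(contigs)[duplicated(names(contigs))][1], "'")
  }
  if (any(!nzchar(contigs))) stop2("genome '", genome_id, "': empty contig sequence")
  contigs <- vapply(contigs, clean_dna, "", USE.NAMES = TRUE)
  structure(list(genome_id = genome_id, contigs = contigs),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("<genome_sequence> ", x$genome_id, ": ", length(x$contigs),
      " contig(s), ", sum(nchar(x$contigs)), " bp\n", sep = "")
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' The first whitespace-delimited token of each header becomes the contig id.
#'
#' @param path Path to a FASTA file.
#' @param genome_id Genome identifier; defaults to the file name without its
#'   extension.
#' @return A [genome_sequence()] object.
#' @export
read_fasta <- function(path,
                       genome_id = sub("\\.(fa|fasta|fna)$", "",
                                       basename(path), ignore.case = TRUE)) {
  if (!file.exists(path)) stop2("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop2("no FASTA records in ", path)
  ids <- vapply(strsplit(names(ss), "\\s+"), function(x) x[1] %||% "", "")
  if (any(is.na(ids) | !nzchar(ids))) stop2("FASTA record with empty header in ", path)
  if (anyDuplicated(ids)) {
    stop2("duplicate contig_id '", ids[duplicated(ids)][1], "' in ", path)
  }
  if (any(BiocGenerics::width(ss) == 0L)) {
    stop2("empty FASTA record '", ids[BiocGenerics::width(ss) == 0L][1], "' in ", path)
  }
  contigs <- as.character(ss)
  names(contigs) <- ids
  genome_sequence(genome_id, contigs)
}

#' Write a genome to a FASTA file
#'
#' @param genome A [genome_sequence()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Construct a gene annotation table
#'
#' The canonical container for CDS annotations: one row per gene, 0-based
#' half-open forward-strand coordinates.
#'
#' @param gene_id,genome_id,contig_id Identifiers.
#' @param start,end Integer 0-based half-open interval on the forward strand.
#' @param strand `"+"` or `"-"`.
#' @param partial5,partial3 Logical: the 5' (start codon) or 3' (stop codon)
#'   boundary lies outside the contig (draft-assembly partial genes).
#' @return A `data.frame` with class `gene_table`.
#' @export
gene_table <- function(gene_id = character(0), genome_id = character(0),
                       contig_id = character(0),
                       start = integer(0), end = integer(0),
                       strand = character(0),
                       partial5 = logical(length(gene_id)),
                       partial3 = logical(length(gene_id))) {
  df <- data.frame(
    gene_id = as.character(gene_id), genome_id = as.character(genome_id),
    contig_id = as.character(contig_id),
    start = as.integer(start), end = as.integer(end),
    strand = as.character(strand),
    partial5 = as.logical(partial5), partial3 = as.logical(partial3),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    if (any(df$start < 0L) || any(df$end <= df$start)) {
      bad <- df$gene_id[df$start < 0L | df$end <= df$start][1]
      stop2("gene '", bad, "': requires 0 <= start < end")
    }
    if (any(!df$strand %in% c("+", "-"))) {
      bad <- df$gene_id[!df$strand %in% c("+", "-")][1]
      stop2("gene '", bad, "': unknown strand")
    }
    key <- paste(df$genome_id, df$gene_id)
    if (anyDuplicated(key)) {
      stop2("duplicate gene_id within a genome: ", key[duplicated(key)][1])
    }
  }
  class(df) <- c("gene_table", "data.frame")
  df
}

gene_length <- function(genes) genes$end - genes$start

#' Read CDS annotations from a GFF3 file
#'
#' Only rows of type `CDS` are kept. GFF3 1-based inclusive coordinates are
#' converted to 0-based half-open. Partial genes may be marked with a
#' `partial=5`, `partial=3` or `partial=5,3` attribute.
#'
#' @param path Path to a GFF3 file.
#' @param genome_id Genome the annotations belong to.
#' @return A [gene_table()].
#' @export
read_gff3 <- function(path, genome_id) {
  if (!file.exists(path)) stop2("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
  if (length(gr) == 0L) return(gene_table())
  str <- as.character(BiocGenerics::strand(gr))
  if (any(!str %in% c("+", "-"))) {
    stop2("CDS with unknown strand in ", path)
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- rep(NA_character_, length(gr))
  if (anyNA(ids) && !is.null(gr$Parent)) {
    par <- vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
    ids[is.na(ids)] <- par[is.na(ids)]
  }
  if (anyNA(ids)) stop2("CDS without ID or Parent attribute in ", path)
  partial <- rep("", length(gr))
  if (!is.null(gr$partial)) {
    pa <- gr$partial
    if (is.list(pa) || methods::is(pa, "List")) {
      pa <- vapply(pa, function(p) paste(p, collapse = ","), "")
    }
    partial <- ifelse(is.na(pa), "", as.character(pa))
  }
  gene_table(
    gene_id = ids, genome_id = genome_id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L, end = BiocGenerics::end(gr),
    strand = str,
    partial5 = grepl("5", partial, fixed = TRUE),
    partial3 = grepl("3", partial, fixed = TRUE)
  )
}

#' Write CDS annotations to a GFF3 file
#'
#' @param genes A [gene_table()].
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, source = "panann") {
  if (nrow(genes) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$source <- source
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- genes$gene_id
  partial <- ifelse(genes$partial5 & genes$partial3, "5,3",
                    ifelse(genes$partial5, "5", ifelse(genes$partial3, "3", NA)))
  if (any(!is.na(partial))) gr$partial <- partial
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# ---------------------------------------------------------------------------
# MAF

new_block <- function(block_id, rows, width) {
  structure(list(block_id = block_id, width = width, rows = rows),
            class = "alignment_block")
}

#' Read a MAF whole-genome multiple alignment
#'
#' Each `s` line's `src` field is split at the FIRST dot into
#' `genome_id.contig_id`. Minus-strand starts (offsets on the reverse
#' complement) are converted to forward-strand leftmost offsets
#' (`fwd_start = srcSize - start - size`); the row text is stored as read, so
#' minus-strand rows keep their reverse-complement text. A block with more
#' than one row for the same genome is skipped with a warning: the method
#' expects one aligned segment per organism and does not interpret
#' duplications.
#'
#' @param path Path to a MAF file.
#' @return A list of alignment blocks. Each block is a list with `block_id`,
#'   `width`, and `rows`: a named-by-genome list of rows holding `genome_id`,
#'   `contig_id`, `fwd_start` (0-based forward-strand leftmost offset),
#'   `size` (ungapped length), `strand`, `src_size` (contig length) and
#'   `text` (the gapped row).
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop2("MAF file not found: ", path)
  lines <- readLines(path)
  first <- substr(lines, 1L, 2L)
  a_idx <- which(first == "a " | lines == "a")
  s_idx <- which(first == "s ")
  if (length(s_idx) && (length(a_idx) == 0L || s_idx[1] < a_idx[1])) {
    stop2("malformed MAF: 's' line before any 'a' line in ", path)
  }
  blocks <- list()
  nb <- 0L
  for (bi in seq_along(a_idx)) {
    lo <- a_idx[bi]
    hi <- if (bi < length(a_idx)) a_idx[bi + 1L] - 1L else length(lines)
    sl <- s_idx[s_idx >= lo & s_idx <= hi]
    if (length(sl) == 0L) next
    block_id <- paste0("b", bi)
    rows <- list()
    skip <- FALSE
    for (li in sl) {
      f <- strsplit(trimws(lines[li]), "\\s+")[[1]]
      if (length(f) != 7L) stop2("malformed MAF 's' line (block ", block_id, "): ", lines[li])
      src <- f[2]
      if (!grepl(".", src, fixed = TRUE)) {
        stop2("MAF src '", src, "' has no '.' separating genome and contig (block ",
              block_id, ")")
      }
      genome_id <- sub("\\..*$", "", src)
      contig_id <- sub("^[^.]*\\.", "", src)
      start <- as.integer(f[3]); size <- as.integer(f[4])
      strand <- f[5]; src_size <- as.integer(f[6]); text <- toupper(f[7])
      if (!strand %in% c("+", "-")) stop2("unknown strand in MAF block ", block_id)
      ngap <- nchar(gsub("-", "", text, fixed = TRUE))
      if (ngap != size) {
        stop2("MAF block ", block_id, ", row ", src,
              ": non-gap character count (", ngap, ") != size field (", size, ")")
      }
      fwd_start <- if (strand == "+") start else src_size - start - size
      if (!is.null(rows[[genome_id]])) {
        warning("MAF block ", block_id, " has >1 row for genome '", genome_id,
                "'; block skipped (one segment per organism expected)",
                call. = FALSE)
        skip <- TRUE
        break
      }
      rows[[genome_id]] <- list(
        genome_id = genome_id, contig_id = contig_id, fwd_start = fwd_start,
        size = size, strand = strand, src_size = src_size, text = text
      )
    }
    if (skip || length(rows) == 0L) next
    widths <- unique(nchar(vapply(rows, `[[`, "", "text")))
    if (length(widths) != 1L) {
      stop2("MAF block ", block_id, ": rows have unequal widths")
    }
    nb <- nb + 1L
    blocks[[nb]] <- new_block(paste0("b", nb), rows, widths)
  }
  blocks
}

#' Write alignment blocks to a MAF file
#'
#' Inverse of [read_maf()]: forward-strand leftmost offsets are converted back
#' to strand-relative MAF starts for minus-strand rows.
#'
#' @param blocks List of alignment blocks.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("", con)
    writeLines("a score=0", con)
    for (row in b$rows) {
      maf_start <- if (row$strand == "+") row$fwd_start else
        row$src_size - row$fwd_start - row$size
      writeLines(paste("s", paste0(row$genome_id, ".", row$contig_id),
                       maf_start, row$size, row$strand, row$src_size, row$text),
                 con)
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Reports

write_tsv <- function(df, path) {
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (is.character(v)) v[is.na(v) | !nzchar(v)] <- "."
    df[[j]] <- v
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' Write the analysis report files
#'
#' Produces tab-delimited reports under `outdir`: `groups.tsv` (ortholog group
#' membership), `anomalies.tsv` (per-group consistency classes),
#' `alternatives.tsv` (ranked alternative gene structures), and, when
#' supplied, `missing.tsv` (putative missing annotations),
#' `genome_inconsistency.tsv` (per-genome sole-outlier counts) and
#' `suggestions.tsv` (validated missing-gene suggestions). Empty cells are
#' written as `"."`. Plain-text gapped alignment dumps with annotated
#' starts/stops marked are written under `outdir/alignments/` for anomalous
#' groups when an alignment index is supplied.
#'
#' @param groups Ortholog groups (list, from [group_orthologs()]).
#' @param anomalies Classification table (from [classify_groups()]).
#' @param alternatives Alternatives table (rows from [rank_alternatives()]).
#' @param outdir Output directory (created if needed).
#' @param missing Optional missing-annotation table.
#' @param genome_counts Optional per-genome inconsistency table.
#' @param suggestions Optional missing-gene suggestion table.
#' @param index Optional [build_alignment_index()] result enabling alignment
#'   dumps.
#' @param dump Which groups to dump alignments for: `"anomalous"` (default),
#'   `"none"`, or `"all"`.
#' @return `outdir`, invisibly.
#' @export
write_reports <- function(groups, anomalies, alternatives, outdir,
                          missing = NULL, genome_counts = NULL,
                          suggestions = NULL, index = NULL,
                          dump = c("anomalous", "none", "all")) {
  dump <- match.arg(dump)
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop2("cannot create output directory: ", outdir)
  write_tsv(membership_table(groups), file.path(outdir, "groups.tsv"))

  an <- anomalies
  if (is.null(an) || nrow(an) == 0L) {
    an <- data.frame(group_id = character(0), class = character(0),
                     secondary_classes = character(0), n_genomes = integer(0),
                     n_members = integer(0), sole_outlier_genome = character(0),
                     contig_boundary = logical(0), block_split = logical(0),
                     stringsAsFactors = FALSE)
  }
  write_tsv(an, file.path(outdir, "anomalies.tsv"))

  alt <- flatten_alternatives(alternatives)
  write_tsv(alt, file.path(outdir, "alternatives.tsv"))

  if (!is.null(missing)) write_tsv(missing, file.path(outdir, "missing.tsv"))
  if (!is.null(genome_counts)) {
    write_tsv(genome_counts, file.path(outdir, "genome_inconsistency.tsv"))
  }
  if (!is.null(suggestions)) {
    write_tsv(suggestions, file.path(outdir, "suggestions.tsv"))
  }

  if (dump != "none" && !is.null(index) && length(groups)) {
    ddir <- file.path(outdir, "alignments")
    dir.create(ddir, showWarnings = FALSE)
    ids <- if (dump == "all") vapply(groups, `[[`, "", "group_id") else
      an$group_id[an$class != "consistent" & an$class != "singleton"]
    byid <- stats::setNames(groups, vapply(groups, `[[`, "", "group_id"))
    for (gid in ids) {
      g <- byid[[gid]]
      if (!is.null(g)) {
        dump_group_alignment(index, g, file.path(ddir, paste0(gid, ".txt")))
      }
    }
  }
  invisible(outdir)
}

# One row per (group, member) with the query flagged.
membership_table <- function(groups) {
  if (length(groups) == 0L) {
    return(data.frame(group_id = character(0), gene_id = character(0),
                      genome_id = character(0), is_query = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(groups, function(g) {
    data.frame(group_id = g$group_id, gene_id = g$members,
               genome_id = g$member_genomes,
               is_query = g$members == g$query_gene,
               stringsAsFactors = FALSE)
  }))
}

flatten_alternatives <- function(alternatives) {
  empty <- data.frame(group_id = character(0), rank = integer(0),
                      start_block = character(0), start_col = integer(0),
                      stop_block = character(0), stop_col = integer(0),
                      strand = character(0), n_valid_orfs = integer(0),
                      length = integer(0), n_frameshifts = integer(0),
                      overlap_flag = logical(0), per_genome = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(alternatives)) return(empty)
  if (is.data.frame(alternatives)) alternatives <- list(alternatives)
  alternatives <- Filter(function(x) !is.null(x) && nrow(x) > 0L, alternatives)
  if (length(alternatives) == 0L) return(empty)
  do.call(rbind, lapply(alternatives, function(df) {
    pg <- vapply(df$evals, function(ev) {
      paste(vapply(ev, function(e) {
        if (isTRUE(e$absent)) return(paste0(e$genome_id, "=absent"))
        sprintf("%s=%s:%d-%d:%s:%s:%d", e$genome_id,
                e$contig_id %||% ".", e$start %||% -1L, e$end %||% -1L,
                e$strand %||% ".",
                if (isTRUE(e$orf_valid)) "valid" else "invalid",
                e$n_frameshifts %||% 0L)
      }, ""), collapse = ",")
    }, "")
    data.frame(group_id = df$group_id, rank = df$rank,
               start_block = df$start_block, start_col = df$start_col,
               stop_block = df$stop_block, stop_col = df$stop_col,
               strand = df$strand, n_valid_orfs = df$n_valid_orfs,
               length = df$length, n_frameshifts = df$n_frameshifts,
               overlap_flag = df$overlap_flag, per_genome = pg,
               stringsAsFactors = FALSE)
  }))
}

# Plain-text gapped alignment view of one group with start/stop marks.
dump_group_alignment <- function(index, group, path) {
  genes <- index$genes[index$genes$gene_id %in% group$members, , drop = FALSE]
  q <- index$genes[index$genes$gene_id == group$query_gene, , drop = FALSE]
  spans <- gene_column_span(index, q[1, ])
  if (nrow(spans) == 0L) return(invisible(NULL))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# group ", group$group_id, " query ", group$query_gene), con)
  for (si in seq_len(nrow(spans))) {
    b <- index$blocks[[spans$block_id[si]]]
    lo <- spans$col_start[si]; hi <- spans$col_end[si]
    pad <- 30L
    lo <- max(0L, lo - pad); hi <- min(b$width, hi + pad)
    writeLines(paste0("# block ", b$block_id, " columns [", lo, ",", hi, ")"), con)
    for (row in b$rows) {
      marks <- rep(" ", hi - lo)
      gg <- genes[genes$genome_id == row$genome_id &
                    genes$contig_id == row$contig_id, , drop = FALSE]
      for (k in seq_len(nrow(gg))) {
        for (what in c("start", "stop")) {
          pos <- terminus_pos(gg[k, ], what)
          if (pos >= row$fwd_start && pos < row$fwd_start + row$size) {
            col <- row$pos2col[pos - row$fwd_start + 1L] - 1L
            if (col >= lo && col < hi) {
              marks[col - lo + 1L] <- if (what == "start") "S" else "E"
            }
          }
        }
      }
      writeLines(sprintf("%-20s %s", paste0(row$genome_id, ".", row$contig_id),
                         substr(row$text, lo + 1L, hi)), con)
      writeLines(sprintf("%-20s %s", "", paste(marks, collapse = "")), con)
    }
  }
  invisible(path)
}
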