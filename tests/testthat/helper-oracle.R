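# Independent oracles: per-base column-set projection, a naive quadratic
# greedy grouper, an independent ORF re-translator, and a randomized
# instance generator. None of these touch the package's index internals.

ORACLE_STARTS <- c("ATG", "GTG", "TTG")
ORACLE_STOPS <- c("TAA", "TAG", "TGA")

# (column, forward-strand position) pairs of a row, by direct text scanning.
scan_row_positions <- function(row) {
  ch <- strsplit(row$text, "", fixed = TRUE)[[1]]
  cols <- which(ch != "-")
  pos <- if (row$strand == "+") {
    row$fwd_start + seq_along(cols) - 1L
  } else {
    row$fwd_start + row$size - seq_along(cols)
  }
  list(cols = cols, pos = pos)  # text order; cols are 1-based
}

# Set of "block column" labels holding a gene's aligned bases.
gene_colset <- function(gene, blocks) {
  out <- character(0)
  for (b in blocks) {
    row <- b$rows[[gene$genome_id]]
    if (is.null(row) || row$contig_id != gene$contig_id) next
    sp <- scan_row_positions(row)
    sel <- sp$pos >= gene$start & sp$pos < gene$end
    if (any(sel)) out <- c(out, paste(b$block_id, sp$cols[sel]))
  }
  out
}

# Naive O(n^2) greedy grouping: same contract as group_orthologs(), per-base
# column sets and a linear scan over all genes instead of interval trees.
naive_group_orthologs <- function(genes, blocks, cov_query = 0.5,
                                  cov_match = 0.5) {
  n <- nrow(genes)
  len <- genes$end - genes$start
  colsets <- lapply(seq_len(n), function(i) gene_colset(genes[i, ], blocks))
  ord <- order(-len, genes$genome_id, genes$gene_id)
  alive <- rep(TRUE, n)
  groups <- list()
  for (i in ord) {
    if (!alive[i]) next
    alive[i] <- FALSE
    members <- i
    if (length(colsets[[i]]) / len[i] >= cov_query) {
      for (j in seq_len(n)) {
        if (!alive[j] || genes$genome_id[j] == genes$genome_id[i]) next
        shared <- length(intersect(colsets[[i]], colsets[[j]]))
        if (shared > 0 && shared >= cov_match * len[j]) {
          members <- c(members, j)
        }
      }
      alive[members[-1]] <- FALSE
    }
    groups[[length(groups) + 1L]] <- sort(genes$gene_id[members])
  }
  groups
}

membership_sets <- function(groups) {
  sets <- lapply(groups, function(g) sort(g$members))
  sets[order(vapply(sets, `[`, "", 1))]
}

naive_sets <- function(groups) groups[order(vapply(groups, `[`, "", 1))]

# Randomized small instance: 5 genomes, 1-2 blocks with random gaps and
# strands, random (possibly overlapping, partially aligned) genes.
rand_instance <- function(seed) {
  set.seed(seed)
  genomes <- paste0("g", 1:5)
  n_blocks <- sample(1:2, 1)
  width <- sample(800:1500, 1)
  blocks <- list()
  for (bi in seq_len(n_blocks)) {
    rows <- lapply(genomes, function(g) {
      gap <- stats::runif(width) < stats::runif(1, 0.02, 0.12)
      ch <- ifelse(gap, "-", sample(c("A", "C", "G", "T"), width, replace = TRUE))
      fix_row(g, paste(ch, collapse = ""),
              fwd_start = sample(0:500, 1),
              strand = sample(c("+", "-"), 1),
              src_size = 4000L)
    })
    blocks[[bi]] <- fix_block(paste0("b", bi), rows)
  }
  genes <- do.call(rbind, lapply(genomes, function(g) {
    k <- sample(4:10, 1)
    starts <- sample(0:3600, k)
    lens <- sample(30:400, k, replace = TRUE)
    gene_table(gene_id = sprintf("%s_x%02d", g, seq_len(k)), genome_id = g,
               contig_id = "c1", start = starts,
               end = pmin(starts + lens, 4000L), strand = sample(c("+", "-"), k,
                                                                 replace = TRUE))
  }))
  rownames(genes) <- NULL
  class(genes) <- c("gene_table", "data.frame")
  list(blocks = blocks, genes = genes)
}

# --- independent ORF re-translation -------------------------------------

indep_check_orf <- function(seq) {
  L <- nchar(seq)
  if (L < 6L || L %% 3L != 0L) return(FALSE)
  starts <- seq.int(1L, L - 2L, by = 3L)
  cod <- substring(seq, starts, starts + 2L)
  n <- length(cod)
  cod[1] %in% ORACLE_STARTS && cod[n] %in% ORACLE_STOPS &&
    !any(cod[-c(1L, n)] %in% ORACLE_STOPS)
}

indep_check_orf_shift <- function(seq, q) {
  L <- nchar(seq)
  if (L %% 3L == 0L || q < 3L || q > L - 3L) return(FALSE)
  n1 <- q %/% 3L
  ps <- seq.int(1L, by = 3L, length.out = n1)
  pre <- substring(seq, ps, ps + 2L)
  if (!pre[1] %in% ORACLE_STARTS) return(FALSE)
  if (n1 > 1L && any(pre[-1] %in% ORACLE_STOPS)) return(FALSE)
  n2 <- (L - q) %/% 3L
  if (n2 < 1L) return(FALSE)
  ss <- L - 3L * seq.int(n2, 1L) + 1L
  ss <- ss[ss >= q + 1L]
  if (length(ss) < 1L) return(FALSE)
  suf <- substring(seq, ss, ss + 2L)
  k <- length(suf)
  suf[k] %in% ORACLE_STOPS && !(k > 1L && any(suf[-k] %in% ORACLE_STOPS))
}

# Minimal independent MAF scan: rows of block `bid` parsed straight from the
# file text.
maf_rows_from_file <- function(path, bid) {
  lines <- readLines(path)
  ai <- which(grepl("^a( |$)", lines))
  want <- as.integer(sub("^b", "", bid))
  lo <- ai[want]
  hi <- if (want < length(ai)) ai[want + 1L] - 1L else length(lines)
  sl <- lines[lo:hi]
  sl <- sl[startsWith(sl, "s ")]
  rows <- lapply(sl, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    src_size <- as.integer(f[6])
    start <- as.integer(f[3]); size <- as.integer(f[4])
    list(genome_id = sub("\\..*$", "", f[2]),
         contig_id = sub("^[^.]*\\.", "", f[2]),
         fwd_start = if (f[5] == "+") start else src_size - start - size,
         size = size, strand = f[5], src_size = src_size, text = f[7])
  })
  stats::setNames(rows, vapply(rows, `[[`, "", "genome_id"))
}

# Re-check one evaluate_orf() result from the raw FASTA (and, for frameshift
# repairs, the raw MAF text), bypassing the alignment index.
recheck_eval <- function(e, pair, fasta_paths, maf_path) {
  if (!isTRUE(e$orf_valid)) return(NA)
  fa <- Biostrings::readDNAStringSet(fasta_paths[[e$genome_id]])
  names(fa) <- vapply(strsplit(names(fa), "\\s+"), `[`, "", 1)
  contig <- toupper(as.character(fa[[e$contig_id]]))
  seq <- substr(contig, e$start + 1L, e$end)
  if (e$strand == "-") seq <- revcomp(seq)
  if (e$n_frameshifts == 0L) return(indep_check_orf(seq))
  rows <- maf_rows_from_file(maf_path, pair$start_block)
  row <- rows[[e$genome_id]]
  col0 <- e$shift_cols[1]
  n_before <- nchar(gsub("-", "", substr(row$text, 1L, col0), fixed = TRUE))
  anchor <- row$fwd_start + n_before - 1L  # all simulated rows are "+"
  q <- if (e$strand == "+") anchor - e$start + 1L else e$end - 1L - anchor
  any(vapply(-3:3, function(d) indep_check_orf_shift(seq, q + d), TRUE))
}
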