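# Ground-truthed synthetic pan-genome generation: an ancestral genome packed
# with non-overlapping ORFs, descendant isolates carrying substitutions and
# small intergenic indels, a truth multiple alignment star-aligned to the
# ancestor, and planted annotation anomalies (TIS shifts, gene-splitting
# indels, deleted annotations, contig breaks).
#
# A single RNG stream drives everything, consumed in a fixed order (ancestor,
# then isolates in index order, then anomalies in plan order), so a seed
# reproduces the data set byte for byte.

#' Simulation configuration
#'
#' @param n_genomes Number of descendant isolates.
#' @param genome_len Ancestor genome length in bp (single circular-free
#'   contig).
#' @param n_genes Number of non-overlapping ancestral ORFs.
#' @param gene_len_range Gene length range in bp (rounded to codons).
#' @param snp_rate Per-base substitution probability per isolate.
#' @param indel_rate Per-base indel initiation probability per isolate;
#'   indels are restricted to intergenic sequence so that reading frames
#'   break only where the anomaly plan says so.
#' @param indel_len_range Indel length range in bp.
#' @param seed Integer seed for the single RNG stream.
#' @param anomalies Named list of planted anomaly counts: `tis_shift`
#'   (in-frame start moved to a downstream in-frame start codon in one
#'   isolate), `gene_split_indel` (1-bp deletion planted in the sequence and
#'   the gene re-annotated as two fragments), `deleted_annotation` (GFF
#'   record dropped, sequence untouched), `contig_break` (contig split inside
#'   a gene, both fragments marked partial).
#' @param min_intergenic Minimum intergenic spacer length in bp.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 5L, genome_len = 1000000L, n_genes = 800L,
                       gene_len_range = c(300L, 1200L), snp_rate = 0.005,
                       indel_rate = 1e-4, indel_len_range = c(1L, 3L),
                       seed = 1L, anomalies = list(), min_intergenic = 20L) {
  plan <- list(tis_shift = 0L, gene_split_indel = 0L,
               deleted_annotation = 0L, contig_break = 0L)
  for (nm in names(anomalies)) {
    if (!nm %in% names(plan)) stop2("unknown anomaly type: ", nm)
    plan[[nm]] <- as.integer(anomalies[[nm]])
  }
  stopifnot(n_genomes >= 1L, genome_len >= 1000L, n_genes >= 0L,
            snp_rate >= 0, snp_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            gene_len_range[1] >= 9L, gene_len_range[2] >= gene_len_range[1],
            indel_len_range[1] >= 1L, indel_len_range[2] >= indel_len_range[1])
  if (sum(unlist(plan)) > n_genes) {
    stop2("anomaly plan exceeds the number of genes")
  }
  structure(list(
    n_genomes = as.integer(n_genomes), genome_len = as.integer(genome_len),
    n_genes = as.integer(n_genes),
    gene_len_range = as.integer(gene_len_range),
    snp_rate = snp_rate, indel_rate = indel_rate,
    indel_len_range = as.integer(indel_len_range),
    seed = as.integer(seed), anomalies = plan,
    min_intergenic = as.integer(min_intergenic)
  ), class = "sim_config")
}

# sample() treats a scalar first argument as 1:n; always pass the vector
sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n) else
    sample(seq.int(lo, hi), n, replace = TRUE)
}

rand_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

all_codons <- function() {
  g <- expand.grid(DNA_BASES, DNA_BASES, DNA_BASES, stringsAsFactors = FALSE)
  paste0(g[[3]], g[[2]], g[[1]])
}

# Random valid ORF of `len` bp: start codon, non-stop internals, one stop.
random_orf <- function(len, cfg) {
  nc <- len %/% 3L
  pool <- setdiff(all_codons(), cfg$stop_codons)
  paste0(sample(cfg$start_codons, 1L),
         paste(sample(pool, nc - 2L, replace = TRUE), collapse = ""),
         sample(cfg$stop_codons, 1L))
}

#' Generate the ancestral genome and its annotations
#'
#' Packs `n_genes` non-overlapping valid ORFs (both strands) separated by
#' random intergenic spacers into a single contig.
#'
#' @param config A [sim_config()].
#' @param cfg A [codon_config()] supplying the start/stop codon sets.
#' @return A list with `genome` (a [genome_sequence()]) and `genes` (a
#'   [gene_table()]).
#' @export
generate_ancestor <- function(config, cfg = codon_config()) {
  n <- config$n_genes
  if (n == 0L) {
    return(list(genome = genome_sequence("ancestor",
                                         c(c1 = rand_dna(config$genome_len))),
                genes = gene_table()))
  }
  nc_min <- ceiling(config$gene_len_range[1] / 3)
  nc_max <- max(nc_min, floor(config$gene_len_range[2] / 3))
  lens <- 3L * sample_range(nc_min, nc_max, n)
  inter_total <- config$genome_len - sum(lens)
  if (inter_total < (n + 1L) * config$min_intergenic) {
    stop2("infeasible packing: ", n, " genes of total ", sum(lens),
          " bp do not fit in ", config$genome_len, " bp")
  }
  extra <- inter_total - (n + 1L) * config$min_intergenic
  gaps <- config$min_intergenic +
    as.integer(stats::rmultinom(1L, extra, rep(1, n + 1L)))
  strands <- sample(c("+", "-"), n, replace = TRUE)

  pieces <- character(2L * n + 1L)
  starts <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- rand_dna(gaps[i])
    pos <- pos + gaps[i]
    starts[i] <- pos
    orf <- random_orf(lens[i], cfg)
    pieces[2L * i] <- if (strands[i] == "+") orf else revcomp(orf)
    pos <- pos + lens[i]
  }
  pieces[2L * n + 1L] <- rand_dna(gaps[n + 1L])
  seq <- paste(pieces, collapse = "")

  genes <- gene_table(
    gene_id = sprintf("anc%04d", seq_len(n)), genome_id = "ancestor",
    contig_id = "c1", start = starts, end = starts + lens, strand = strands
  )
  list(genome = genome_sequence("ancestor", c(c1 = seq)), genes = genes)
}

# Would a substitution of base `p` (0-based) to `alt` corrupt the gene
# [s, e) on `strand`? Start codons must stay start codons, the terminal stop
# a stop, and no internal codon may become a stop.
snp_ok <- function(ch, p, alt, s, e, strand, cfg) {
  if (strand == "+") {
    off <- p - s
    ci <- off %/% 3L
    idxs <- (s + 3L * ci + 1L):(s + 3L * ci + 3L)
    cod <- ch[idxs]
    cod[idxs == p + 1L] <- alt
    codon <- paste(cod, collapse = "")
  } else {
    off <- (e - 1L) - p
    ci <- off %/% 3L
    idxs <- (e - 3L * ci - 2L):(e - 3L * ci)
    cod <- ch[idxs]
    cod[idxs == p + 1L] <- alt
    codon <- paste(revcomp_chars(cod), collapse = "")
  }
  ncd <- (e - s) %/% 3L
  if (ci == 0L) return(codon %in% cfg$start_codons)
  if (ci == ncd - 1L) return(codon %in% cfg$stop_codons)
  !(codon %in% cfg$stop_codons)
}

# Lift a vector of kept ancestor positions through an indel event table.
make_lift <- function(events) {
  ev <- events[events$type %in% c("ins", "del"), , drop = FALSE]
  if (nrow(ev) == 0L) return(function(p) p)
  th <- ifelse(ev$type == "ins", ev$anc_pos, ev$anc_pos + ev$len)
  d <- ifelse(ev$type == "ins", ev$len, -ev$len)
  o <- order(th)
  th <- th[o]
  cum <- cumsum(d[o])
  function(p) {
    i <- findInterval(p, th)
    p + ifelse(i > 0L, cum[pmax(i, 1L)], 0L)
  }
}

#' Evolve descendant isolates from the ancestor
#'
#' Each isolate receives substitutions at `snp_rate` and small intergenic
#' indels at `indel_rate`. Substitutions inside genes are rejection-sampled
#' so they never create a premature stop or destroy the annotated start/stop
#' codon; indels are kept out of genes entirely. Annotations are lifted
#' through the mutation log, so without planted anomalies every isolate's
#' gene set is a coordinate-shifted copy of the ancestor's.
#'
#' @param ancestor Result of [generate_ancestor()].
#' @param config A [sim_config()].
#' @param cfg A [codon_config()].
#' @return A list of isolates; each holds `genome_id`, `seq` (whole-contig
#'   string), `genes` (a [gene_table()] in whole-contig coordinates), `log`
#'   (mutation event table in ancestor coordinates), `breaks` and
#'   `anc_breaks` (contig break positions, filled by [plant_anomalies()]).
#' @export
evolve_isolates <- function(ancestor, config, cfg = codon_config()) {
  anc <- ancestor$genome$contigs[[1]]
  L <- nchar(anc)
  ch0 <- strsplit(anc, "", fixed = TRUE)[[1]]
  genes <- ancestor$genes
  gs <- genes$start
  ge <- genes$end
  gstr <- genes$strand
  overlaps_gene <- function(a, b) {
    if (nrow(genes) == 0L) return(FALSE)
    i <- findInterval(b - 1L, gs)
    i >= 1L && ge[i] > a
  }

  lapply(seq_len(config$n_genomes), function(k) {
    iso_id <- sprintf("iso%02d", k)
    ch <- ch0

    snp_pos <- integer(0)
    snp_base <- character(0)
    cand <- which(stats::runif(L) < config$snp_rate) - 1L
    for (p in cand) {
      ref <- ch[p + 1L]
      alts <- sample(setdiff(DNA_BASES, ref))
      gi <- if (nrow(genes)) findInterval(p, gs) else 0L
      ingene <- gi >= 1L && p < ge[gi]
      chosen <- NA_character_
      for (alt in alts) {
        if (!ingene || snp_ok(ch, p, alt, gs[gi], ge[gi], gstr[gi], cfg)) {
          chosen <- alt
          break
        }
      }
      if (!is.na(chosen)) {
        ch[p + 1L] <- chosen
        snp_pos <- c(snp_pos, p)
        snp_base <- c(snp_base, chosen)
      }
    }

    ev <- list()
    cand <- sort(which(stats::runif(L) < config$indel_rate) - 1L)
    last_end <- -10L
    for (p in cand) {
      l <- sample_range(config$indel_len_range[1], config$indel_len_range[2], 1L)
      type <- sample(c("ins", "del"), 1L)
      if (p < 1L || p + l + 1L > L) next
      if (p <= last_end + 1L) next
      if (overlaps_gene(p - 1L, p + l + 1L)) next
      ev[[length(ev) + 1L]] <- data.frame(
        type = type, anc_pos = p, len = l,
        payload = if (type == "ins") rand_dna(l) else "",
        stringsAsFactors = FALSE
      )
      last_end <- p + l
    }
    ev <- if (length(ev)) do.call(rbind, ev) else
      data.frame(type = character(0), anc_pos = integer(0), len = integer(0),
                 payload = character(0), stringsAsFactors = FALSE)

    # assemble the isolate sequence
    pieces <- character(0)
    cur <- 0L
    if (nrow(ev)) {
      for (i in order(ev$anc_pos)) {
        p <- ev$anc_pos[i]
        if (ev$type[i] == "del") {
          pieces <- c(pieces,
                      if (p > cur) paste(ch[(cur + 1L):p], collapse = "") else "")
          cur <- p + ev$len[i]
        } else {
          pieces <- c(pieces,
                      if (p > cur) paste(ch[(cur + 1L):p], collapse = "") else "",
                      ev$payload[i])
          cur <- p
        }
      }
    }
    seq <- paste0(paste(pieces, collapse = ""),
                  paste(ch[(cur + 1L):L], collapse = ""))

    lift <- make_lift(ev)
    iso_genes <- if (nrow(genes)) {
      gene_table(
        gene_id = paste(iso_id, genes$gene_id, sep = "_"),
        genome_id = iso_id, contig_id = "c1",
        start = lift(genes$start), end = lift(genes$end - 1L) + 1L,
        strand = genes$strand
      )
    } else gene_table()

    log <- rbind(
      ev,
      if (length(snp_pos)) {
        data.frame(type = "snp", anc_pos = snp_pos, len = 1L,
                   payload = snp_base, stringsAsFactors = FALSE)
      } else NULL
    )
    log <- log[order(log$anc_pos), , drop = FALSE]
    rownames(log) <- NULL

    list(genome_id = iso_id, seq = seq, genes = iso_genes, log = log,
         breaks = integer(0), anc_breaks = integer(0))
  })
}

# --------------------------------------------------------------------------
# Anomaly planting

plant_tis_shift <- function(iso, anc_gene, cfg) {
  gid <- paste(iso$genome_id, anc_gene$gene_id, sep = "_")
  i <- which(iso$genes$gene_id == gid)
  if (length(i) != 1L) return(NULL)
  row <- iso$genes[i, ]
  len <- row$end - row$start
  ncd <- len %/% 3L
  kmax <- floor(0.4 * ncd)
  if (kmax < 2L) return(NULL)
  gseq <- extract_oriented(iso$seq, row$start, row$end, row$strand)
  cods <- split_codons(gseq)
  cis <- (2:kmax)[cods[(2:kmax) + 1L] %in% cfg$start_codons]
  if (length(cis) == 0L) return(NULL)
  ci <- cis[1]
  shift <- 3L * ci
  if (row$strand == "+") {
    iso$genes$start[i] <- row$start + shift
  } else {
    iso$genes$end[i] <- row$end - shift
  }
  list(iso = iso,
       truth = data.frame(type = "tis_shift", anc_gene = anc_gene$gene_id,
                          genome_id = iso$genome_id, gene_id = gid,
                          shift_bp = shift, del_anc_pos = NA_integer_,
                          break_anc_pos = NA_integer_,
                          stringsAsFactors = FALSE))
}

plant_gene_split <- function(iso, anc_gene, cfg) {
  gid <- paste(iso$genome_id, anc_gene$gene_id, sep = "_")
  i <- which(iso$genes$gene_id == gid)
  if (length(i) != 1L) return(NULL)
  row <- iso$genes[i, ]
  len <- row$end - row$start
  ncd <- len %/% 3L
  gseq <- extract_oriented(iso$seq, row$start, row$end, row$strand)
  orig_cods <- split_codons(gseq)
  jlo <- max(2L, floor(0.25 * ncd))
  jhi <- floor(0.5 * ncd)
  if (jhi < jlo) return(NULL)
  hit <- NULL
  for (j in jlo:jhi) {
    o <- 3L * j
    modified <- paste0(substr(gseq, 1L, o), substr(gseq, o + 2L, len))
    ml <- len - 1L
    cods <- split_codons(modified)
    st <- which(cods %in% cfg$stop_codons)
    if (length(st) == 0L) next
    t <- st[1] - 1L                     # 0-based premature stop codon index
    if (3L * t + 3L > ml - 6L) next     # must end well before the true stop
    ms <- (j + 1L):(ncd - 2L)
    ms <- ms[orig_cods[ms + 1L] %in% cfg$start_codons]
    ms <- ms[ml - (3L * ms - 1L) >= 6L]
    if (length(ms) == 0L) next
    hit <- list(j = j, o = o, t = t, m = ms[1])
    break
  }
  if (is.null(hit)) return(NULL)

  o <- hit$o; t <- hit$t; sm <- 3L * hit$m - 1L
  p_iso <- if (row$strand == "+") row$start + o else row$end - 1L - o
  anc_p <- if (anc_gene$strand == "+") anc_gene$start + o else
    anc_gene$end - 1L - o

  # sequence edit + log entry (ancestor coordinates)
  iso$seq <- paste0(substr(iso$seq, 1L, p_iso), substr(iso$seq, p_iso + 2L,
                                                       nchar(iso$seq)))
  iso$log <- rbind(iso$log,
                   data.frame(type = "del", anc_pos = anc_p, len = 1L,
                              payload = "", stringsAsFactors = FALSE))
  iso$log <- iso$log[order(iso$log$anc_pos), , drop = FALSE]

  # all downstream annotations shift left by one
  g <- iso$genes
  shift_idx <- g$start > p_iso
  g$start[shift_idx] <- g$start[shift_idx] - 1L
  g$end[shift_idx] <- g$end[shift_idx] - 1L
  g <- g[g$gene_id != gid, , drop = FALSE]
  s <- row$start
  e_post <- row$end - 1L
  if (row$strand == "+") {
    f1 <- c(s, s + 3L * t + 3L)
    f2 <- c(s + sm, e_post)
  } else {
    f1 <- c(e_post - (3L * t + 3L), e_post)
    f2 <- c(s, e_post - sm)
  }
  frags <- gene_table(
    gene_id = paste0(gid, c("_f1", "_f2")), genome_id = iso$genome_id,
    contig_id = row$contig_id, start = c(f1[1], f2[1]), end = c(f1[2], f2[2]),
    strand = row$strand
  )
  g <- rbind(g, frags)
  g <- g[order(g$start), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("gene_table", "data.frame")
  iso$genes <- g

  list(iso = iso,
       truth = data.frame(type = "gene_split_indel", anc_gene = anc_gene$gene_id,
                          genome_id = iso$genome_id, gene_id = gid,
                          shift_bp = NA_integer_, del_anc_pos = anc_p,
                          break_anc_pos = NA_integer_,
                          stringsAsFactors = FALSE))
}

plant_deleted_annotation <- function(iso, anc_gene) {
  gid <- paste(iso$genome_id, anc_gene$gene_id, sep = "_")
  i <- which(iso$genes$gene_id == gid)
  if (length(i) != 1L) return(NULL)
  iso$genes <- iso$genes[-i, , drop = FALSE]
  rownames(iso$genes) <- NULL
  list(iso = iso,
       truth = data.frame(type = "deleted_annotation",
                          anc_gene = anc_gene$gene_id,
                          genome_id = iso$genome_id, gene_id = gid,
                          shift_bp = NA_integer_, del_anc_pos = NA_integer_,
                          break_anc_pos = NA_integer_,
                          stringsAsFactors = FALSE))
}

plant_contig_break <- function(iso, anc_gene) {
  gid <- paste(iso$genome_id, anc_gene$gene_id, sep = "_")
  i <- which(iso$genes$gene_id == gid)
  if (length(i) != 1L) return(NULL)
  row <- iso$genes[i, ]
  len <- row$end - row$start
  b <- row$start + len %/% 2L
  if (b %in% iso$breaks) return(NULL)
  anc_b <- if (anc_gene$strand == "+") anc_gene$start + (b - row$start) else
    anc_gene$start + (b - row$start)
  g <- iso$genes[-i, , drop = FALSE]
  left_partial5 <- row$strand == "-"
  frags <- gene_table(
    gene_id = paste0(gid, c("_p1", "_p2")), genome_id = iso$genome_id,
    contig_id = row$contig_id,
    start = c(row$start, b), end = c(b, row$end), strand = row$strand,
    partial5 = c(left_partial5, !left_partial5),
    partial3 = c(!left_partial5, left_partial5)
  )
  g <- rbind(g, frags)
  g <- g[order(g$start), , drop = FALSE]
  rownames(g) <- NULL
  class(g) <- c("gene_table", "data.frame")
  iso$genes <- g
  iso$breaks <- sort(c(iso$breaks, b))
  iso$anc_breaks <- sort(c(iso$anc_breaks, anc_b))
  list(iso = iso,
       truth = data.frame(type = "contig_break", anc_gene = anc_gene$gene_id,
                          genome_id = iso$genome_id, gene_id = gid,
                          shift_bp = NA_integer_, del_anc_pos = NA_integer_,
                          break_anc_pos = anc_b, stringsAsFactors = FALSE))
}

#' Plant annotation anomalies into evolved isolates
#'
#' Each planted anomaly targets a distinct ancestral gene in one randomly
#' chosen isolate. TIS shifts move the annotated start in frame to an
#' existing downstream in-frame start codon (genes without one are skipped in
#' favour of the next gene in the shuffled pool). Gene splits delete 1 bp of
#' sequence mid-gene and re-annotate the gene as two fragments bounded by the
#' induced premature stop and a downstream in-frame start. Contig breaks are
#' planted last so that coordinates are final.
#'
#' @param sim A list with `ancestor` and `isolates` (from
#'   [generate_ancestor()] / [evolve_isolates()]).
#' @param config A [sim_config()].
#' @param cfg A [codon_config()].
#' @return `sim` with modified isolates and a `truth` element: `gene_map`
#'   (gene id to ancestral gene) and `anomalies` (one row per planted event).
#' @export
plant_anomalies <- function(sim, config, cfg = codon_config()) {
  plan <- config$anomalies
  n <- config$n_genes
  truth_rows <- list()
  pool <- if (n > 0L) sample(seq_len(n)) else integer(0)
  pool_i <- 0L
  next_gene <- function() {
    pool_i <<- pool_i + 1L
    if (pool_i > length(pool)) stop2("anomaly plan exceeds suitable genes")
    pool[pool_i]
  }
  plant_one <- function(type) {
    repeat {
      gi <- next_gene()
      anc_gene <- sim$ancestor$genes[gi, ]
      k <- sample.int(config$n_genomes, 1L)
      res <- switch(type,
        tis_shift = plant_tis_shift(sim$isolates[[k]], anc_gene, cfg),
        gene_split_indel = plant_gene_split(sim$isolates[[k]], anc_gene, cfg),
        deleted_annotation = plant_deleted_annotation(sim$isolates[[k]], anc_gene),
        contig_break = plant_contig_break(sim$isolates[[k]], anc_gene)
      )
      if (!is.null(res)) {
        sim$isolates[[k]] <<- res$iso
        truth_rows[[length(truth_rows) + 1L]] <<- res$truth
        return(invisible(NULL))
      }
    }
  }
  for (type in c("tis_shift", "gene_split_indel", "deleted_annotation",
                 "contig_break")) {
    for (r in seq_len(plan[[type]])) plant_one(type)
  }

  gene_map <- do.call(rbind, lapply(sim$isolates, function(iso) {
    if (nrow(iso$genes) == 0L) return(NULL)
    anc <- sub("^[^_]+_", "", iso$genes$gene_id)
    anc <- sub("_(f[12]|p[12])$", "", anc)
    data.frame(gene_id = iso$genes$gene_id, genome_id = iso$genome_id,
               anc_gene = anc, stringsAsFactors = FALSE)
  }))
  sim$truth <- list(
    gene_map = gene_map,
    anomalies = if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(type = character(0), anc_gene = character(0),
                 genome_id = character(0), gene_id = character(0),
                 shift_bp = integer(0), del_anc_pos = integer(0),
                 break_anc_pos = integer(0), stringsAsFactors = FALSE)
  )
  sim
}

# --------------------------------------------------------------------------
# Truth alignment (star-aligned to the ancestor)

# Contig layout of an isolate after contig breaks.
isolate_contigs <- function(iso) {
  tot <- nchar(iso$seq)
  Bs <- sort(iso$breaks)
  bounds <- c(0L, Bs)
  ends <- c(Bs, tot)
  names <- if (length(Bs) == 0L) "c1" else paste0("c1_", seq_along(bounds))
  list(bounds = bounds, ends = ends, names = names)
}

#' Build the truth multiple alignment for a simulated pan-genome
#'
#' Every isolate is aligned to ancestor coordinates (a star alignment), so
#' indels become gap columns placed exactly where the mutation log says.
#' Blocks are split at planted contig breaks. Also annotates gene-split truth
#' rows with the alignment block/column of the deleted base.
#'
#' @param sim Result of [plant_anomalies()].
#' @return `sim` with a `blocks` element (same structure as [read_maf()]
#'   output) and gap columns recorded in `sim$truth$anomalies`.
#' @export
build_truth_alignment <- function(sim) {
  L <- nchar(sim$ancestor$genome$contigs[[1]])
  isolates <- sim$isolates

  ins_all <- do.call(rbind, lapply(isolates, function(iso) {
    ev <- iso$log[iso$log$type == "ins", , drop = FALSE]
    if (nrow(ev) == 0L) return(NULL)
    data.frame(pos = ev$anc_pos, len = ev$len, stringsAsFactors = FALSE)
  }))
  if (is.null(ins_all) || nrow(ins_all) == 0L) {
    sp <- integer(0); mi <- integer(0)
  } else {
    mx <- tapply(ins_all$len, ins_all$pos, max)
    sp <- as.integer(names(mx))
    o <- order(sp)
    sp <- sp[o]
    mi <- as.integer(mx)[o]
  }
  cummi <- cumsum(mi)
  basecol <- function(p) {
    if (length(sp) == 0L) return(p)
    i <- findInterval(p, sp)
    p + ifelse(i > 0L, cummi[pmax(i, 1L)], 0L)
  }
  mi_at <- function(p) {
    i <- match(p, sp)
    if (is.na(i)) 0L else mi[i]
  }
  W <- L + sum(mi)

  per_iso <- lapply(isolates, function(iso) {
    posv <- rep(-1L, W)
    txt <- rep("-", W)
    ev <- iso$log[iso$log$type %in% c("ins", "del"), , drop = FALSE]
    delmask <- rep(FALSE, L)
    dels <- ev[ev$type == "del", , drop = FALSE]
    for (i in seq_len(nrow(dels))) {
      delmask[(dels$anc_pos[i] + 1L):(dels$anc_pos[i] + dels$len[i])] <- TRUE
    }
    keep0 <- which(!delmask) - 1L
    lift <- make_lift(ev)
    ipos <- lift(keep0)
    bcol <- basecol(keep0)
    isoch <- strsplit(iso$seq, "", fixed = TRUE)[[1]]
    posv[bcol + 1L] <- ipos
    txt[bcol + 1L] <- isoch[ipos + 1L]
    inss <- ev[ev$type == "ins", , drop = FALSE]
    for (i in seq_len(nrow(inss))) {
      p <- inss$anc_pos[i]
      l <- inss$len[i]
      scol <- basecol(p) - mi_at(p)
      istart <- lift(p) - l
      cols <- (scol + 1L):(scol + l)
      posv[cols] <- istart + seq.int(0L, l - 1L)
      txt[cols] <- strsplit(inss$payload[i], "", fixed = TRUE)[[1]]
    }
    list(posv = posv, txt = txt)
  })

  cutcols <- sort(unique(unlist(lapply(isolates, function(iso) {
    vapply(iso$anc_breaks, function(b) basecol(b) - mi_at(b), 0L)
  }))))
  bounds <- unique(c(0L, cutcols[cutcols > 0L & cutcols < W], W))

  blocks <- list()
  for (bi in seq_len(length(bounds) - 1L)) {
    c0 <- bounds[bi]
    c1 <- bounds[bi + 1L]
    rows <- list()
    for (ki in seq_along(isolates)) {
      iso <- isolates[[ki]]
      pv <- per_iso[[ki]]$posv[(c0 + 1L):c1]
      nz <- pv >= 0L
      if (!any(nz)) next
      size <- sum(nz)
      start <- pv[nz][1]
      lay <- isolate_contigs(iso)
      pi <- findInterval(start, sort(iso$breaks)) + 1L
      rows[[iso$genome_id]] <- list(
        genome_id = iso$genome_id, contig_id = lay$names[pi],
        fwd_start = start - lay$bounds[pi], size = size, strand = "+",
        src_size = lay$ends[pi] - lay$bounds[pi],
        text = paste(per_iso[[ki]]$txt[(c0 + 1L):c1], collapse = "")
      )
    }
    if (length(rows) == 0L) next
    blocks[[length(blocks) + 1L]] <- new_block(
      sprintf("b%d", length(blocks) + 1L), rows, c1 - c0)
  }
  names(blocks) <- vapply(blocks, `[[`, "", "block_id")
  sim$blocks <- blocks

  # gap column of each planted gene-split deletion
  an <- sim$truth$anomalies
  if (!is.null(an) && nrow(an)) {
    an$gap_block <- NA_character_
    an$gap_col <- NA_integer_
    splits <- which(an$type == "gene_split_indel")
    for (i in splits) {
      col <- basecol(an$del_anc_pos[i])
      bi <- findInterval(col, bounds)
      an$gap_block[i] <- blocks[[bi]]$block_id
      an$gap_col[i] <- col - bounds[bi]
    }
    sim$truth$anomalies <- an
  }
  sim
}

# Materialize an isolate into its deliverable genome + annotations (contig
# breaks applied, coordinates contig-local).
materialize_isolate <- function(iso) {
  lay <- isolate_contigs(iso)
  contigs <- substring(iso$seq, lay$bounds + 1L, lay$ends)
  names(contigs) <- lay$names
  genome <- genome_sequence(iso$genome_id, contigs)
  genes <- iso$genes
  if (nrow(genes)) {
    Bs <- sort(iso$breaks)
    pi <- findInterval(genes$start, Bs) + 1L
    if (any(genes$end > lay$ends[pi])) stop2("gene crosses a contig break")
    genes$contig_id <- lay$names[pi]
    genes$start <- genes$start - lay$bounds[pi]
    genes$end <- genes$end - lay$bounds[pi]
  }
  list(genome = genome, genes = genes)
}

#' Simulate a complete ground-truthed pan-genome
#'
#' Runs [generate_ancestor()], [evolve_isolates()], [plant_anomalies()] and
#' [build_truth_alignment()] under a single seeded RNG stream, and optionally
#' writes FASTA + GFF3 per isolate, the truth MAF, and truth tables to
#' `outdir`.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory.
#' @param cfg A [codon_config()].
#' @return A list of class `pangenome_sim` with `ancestor`, `isolates`,
#'   `genomes` (named list of [genome_sequence()]), `genes` (combined
#'   [gene_table()]), `blocks`, `truth`, `config` and (when written) `paths`.
#' @export
simulate_pangenome <- function(config = sim_config(), outdir = NULL,
                               cfg = codon_config()) {
  set.seed(config$seed)
  anc <- generate_ancestor(config, cfg)
  sim <- list(config = config, ancestor = anc,
              isolates = evolve_isolates(anc, config, cfg))
  sim <- plant_anomalies(sim, config, cfg)
  sim <- build_truth_alignment(sim)

  mats <- lapply(sim$isolates, materialize_isolate)
  sim$genomes <- stats::setNames(lapply(mats, `[[`, "genome"),
                                 vapply(sim$isolates, `[[`, "", "genome_id"))
  genes <- do.call(rbind, lapply(mats, `[[`, "genes"))
  rownames(genes) <- NULL
  class(genes) <- c("gene_table", "data.frame")
  sim$genes <- genes

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(fasta = character(0), gff3 = character(0))
    for (id in names(sim$genomes)) {
      fp <- file.path(outdir, paste0(id, ".fasta"))
      gp <- file.path(outdir, paste0(id, ".gff3"))
      write_fasta(sim$genomes[[id]], fp)
      write_gff3(genes[genes$genome_id == id, , drop = FALSE], gp)
      paths$fasta[id] <- fp
      paths$gff3[id] <- gp
    }
    paths$maf <- file.path(outdir, "alignment.maf")
    write_maf(sim$blocks, paths$maf)
    paths$truth_genes <- file.path(outdir, "truth_genes.tsv")
    write_tsv(sim$truth$gene_map, paths$truth_genes)
    paths$truth_anomalies <- file.path(outdir, "truth_anomalies.tsv")
    write_tsv(sim$truth$anomalies, paths$truth_anomalies)
    sim$paths <- paths
  }
  class(sim) <- "pangenome_sim"
  sim
}

#' @export
print.pangenome_sim <- function(x, ...) {
  cat("<pangenome_sim> ", x$config$n_genomes, " isolates, ",
      x$config$genome_len, " bp, ", x$config$n_genes, " ancestral genes, ",
      nrow(x$truth$anomalies), " planted anomalies\n", sep = "")
  invisible(x)
}
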