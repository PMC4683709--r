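## genome_io: genomes + GFF3 annotation -> validated gene models -> introns.
##
## A gene model is kept only if its CDS length is a multiple of three and it
## translates cleanly (no internal stop, no ambiguous codon); everything else
## goes to a rejects report with a reason code, mirroring the usual
## annotation-error screen applied before comparative intron analysis.

#' Read a genome FASTA file
#'
#' Sequences are upper-cased and restricted to the alphabet ACGTN: IUPAC
#' ambiguity codes other than N are mapped to N with a warning.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet] (names are chromosome ids).
#' @export
read_genome_fasta <- function(path) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence identifier(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  chr <- toupper(as.character(seqs))
  n_amb <- sum(vapply(chr, function(s) {
    sum(!strsplit(s, "", fixed = TRUE)[[1]] %in% c("A", "C", "G", "T", "N"))
  }, numeric(1)))
  if (n_amb > 0) {
    warning(n_amb, " ambiguous base(s) mapped to N in ", path)
    chr <- vapply(chr, function(s) gsub("[^ACGTN]", "N", s), character(1))
  }
  out <- Biostrings::DNAStringSet(unname(chr))
  names(out) <- ids
  out
}

new_gene_model <- function(gene_id, species_id, chrom_id, strand,
                           cds_segments, spliced_cds, protein) {
  structure(
    list(gene_id = gene_id, species_id = species_id, chrom_id = chrom_id,
         strand = strand, cds_segments = cds_segments,
         spliced_cds = spliced_cds, protein = protein),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s (%s) %s%s, %d CDS segment(s), %d nt>\n",
              x$gene_id, x$species_id, x$chrom_id, x$strand,
              nrow(x$cds_segments), nchar(x$spliced_cds)))
  invisible(x)
}

## splice CDS segments (0-based half-open, transcript order) off a chromosome
splice_segments <- function(chrom_seq, segments, strand) {
  parts <- vapply(seq_len(nrow(segments)), function(i) {
    s <- as.character(Biostrings::subseq(
      chrom_seq, start = segments[i, 1] + 1L, end = segments[i, 2]))
    if (strand == "-") revcomp_chr(s) else s
  }, character(1))
  paste(parts, collapse = "")
}

#' Build validated gene models from GFF3 annotation
#'
#' Parses gene/mRNA/CDS features, keeps one transcript per gene (the longest
#' spliced CDS when several are annotated), splices and translates each CDS,
#' and rejects genes that fail validation. GFF3 coordinates (1-based
#' inclusive) are converted to the package's internal 0-based half-open
#' convention.
#'
#' @param gff3_path path to a GFF3 annotation file.
#' @param genomes named [Biostrings::DNAStringSet] of chromosome sequences.
#' @param species_id species label stored on each model.
#' @return list with `models` (named list of `gene_model`) and `rejects`
#'   (data.frame with columns `gene_id`, `reason`; reasons are
#'   `not_mult3`, `bad_translation`, `out_of_bounds`, `internal_stop`).
#' @export
build_gene_models <- function(gff3_path, genomes, species_id = "NA") {
  stopifnot(file.exists(gff3_path))
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  ty <- tolower(as.character(gr$type))

  mrna <- gr[ty == "mrna" | ty == "transcript"]
  cds <- gr[ty == "cds"]
  if (length(cds) == 0L) {
    return(list(models = list(),
                rejects = data.frame(gene_id = character(),
                                     reason = character())))
  }
  cds_parent <- vapply(cds$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1]])
  }, character(1))
  mrna_id <- as.character(mrna$ID)
  mrna_gene <- vapply(mrna$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else as.character(p[[1]])
  }, character(1))
  ## orphan mRNAs are their own gene
  mrna_gene[is.na(mrna_gene)] <- mrna_id[is.na(mrna_gene)]

  models <- list()
  rejects <- list()
  reject <- function(id, reason) {
    rejects[[length(rejects) + 1L]] <<- data.frame(gene_id = id,
                                                   reason = reason)
  }

  cand <- list()  # per gene: candidate transcripts
  for (i in seq_along(mrna_id)) {
    tid <- mrna_id[i]
    gid <- mrna_gene[i]
    seg_idx <- which(cds_parent == tid)
    if (length(seg_idx) == 0L) next
    seg <- cds[seg_idx]
    chrom <- as.character(GenomicRanges::seqnames(seg))[1]
    strand <- as.character(GenomicRanges::strand(seg))[1]
    if (!strand %in% c("+", "-")) strand <- "+"
    m <- cbind(start = GenomicRanges::start(seg) - 1L,
               end = GenomicRanges::end(seg))
    m <- m[order(m[, 1]), , drop = FALSE]
    if (strand == "-") m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    cand[[gid]] <- c(cand[[gid]], list(list(
      transcript_id = tid, chrom = chrom, strand = strand, segments = m)))
  }

  for (gid in names(cand)) {
    tr <- cand[[gid]]
    lens <- vapply(tr, function(t) sum(t$segments[, 2] - t$segments[, 1]),
                   numeric(1))
    t <- tr[[which.max(lens)]]
    m <- t$segments
    if (!t$chrom %in% names(genomes)) { reject(gid, "out_of_bounds"); next }
    chrom_seq <- genomes[[t$chrom]]
    if (any(m[, 1] < 0) || any(m[, 2] > length(chrom_seq)) ||
        any(m[, 2] <= m[, 1])) { reject(gid, "out_of_bounds"); next }
    g_sorted <- m[order(m[, 1]), , drop = FALSE]
    if (nrow(g_sorted) > 1L &&
        any(g_sorted[-1, 1] < g_sorted[-nrow(g_sorted), 2])) {
      reject(gid, "out_of_bounds"); next
    }
    total <- sum(m[, 2] - m[, 1])
    if (total %% 3L != 0L) { reject(gid, "not_mult3"); next }
    spliced <- splice_segments(chrom_seq, m, t$strand)
    prot <- translate_cds(spliced)
    ## trailing stop allowed; strip it from the stored protein
    core <- sub("\\*$", "", prot)
    if (grepl("*", core, fixed = TRUE)) { reject(gid, "internal_stop"); next }
    if (grepl("X", core, fixed = TRUE)) { reject(gid, "bad_translation"); next }
    models[[gid]] <- new_gene_model(gid, species_id, t$chrom, t$strand,
                                    m, spliced, core)
  }

  rejects <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(gene_id = character(), reason = character())
  list(models = models, rejects = rejects)
}

#' Extract introns from a gene model
#'
#' Introns are the genomic gaps between consecutive CDS segments, numbered
#' 5'→3' along the transcript. `cds_offset` is the number of spliced-CDS
#' nucleotides upstream of the intron; `phase = cds_offset %% 3`.
#'
#' @param gene a `gene_model`.
#' @param genome optional [Biostrings::DNAStringSet]; when given, intron
#'   sequences (transcript orientation) and 2-nt boundary dinucleotides are
#'   filled in.
#' @return data.frame with one row per intron: `gene_id`, `ordinal`,
#'   `cds_offset`, `phase`, `length`, `gstart`, `gend` (0-based half-open
#'   genomic), `sequence`, `donor2`, `acceptor2`.
#' @export
extract_introns <- function(gene, genome = NULL) {
  stopifnot(inherits(gene, "gene_model"))
  m <- gene$cds_segments
  empty <- data.frame(gene_id = character(), chrom = character(),
                      ordinal = integer(),
                      cds_offset = integer(), phase = integer(),
                      length = integer(), gstart = integer(),
                      gend = integer(), sequence = character(),
                      donor2 = character(), acceptor2 = character())
  if (nrow(m) < 2L) return(empty)
  g_sorted <- m[order(m[, 1]), , drop = FALSE]
  if (any(g_sorted[-1, 1] < g_sorted[-nrow(g_sorted), 2]))
    stop("overlapping CDS segments in gene ", gene$gene_id)

  n <- nrow(m) - 1L
  seg_len <- m[, 2] - m[, 1]
  cds_offset <- cumsum(seg_len)[seq_len(n)]
  if (gene$strand == "+") {
    gstart <- m[seq_len(n), 2]
    gend <- m[seq_len(n) + 1L, 1]
  } else {
    gstart <- m[seq_len(n) + 1L, 2]
    gend <- m[seq_len(n), 1]
  }
  len <- gend - gstart
  seqs <- rep(NA_character_, n)
  if (!is.null(genome) && gene$chrom_id %in% names(genome)) {
    chrom_seq <- genome[[gene$chrom_id]]
    seqs <- vapply(seq_len(n), function(i) {
      s <- as.character(Biostrings::subseq(chrom_seq, start = gstart[i] + 1L,
                                           end = gend[i]))
      if (gene$strand == "-") revcomp_chr(s) else s
    }, character(1))
  }
  data.frame(
    gene_id = gene$gene_id, chrom = gene$chrom_id, ordinal = seq_len(n),
    cds_offset = as.integer(cds_offset),
    phase = as.integer(cds_offset %% 3L),
    length = as.integer(len), gstart = as.integer(gstart),
    gend = as.integer(gend), sequence = seqs,
    donor2 = ifelse(is.na(seqs), NA_character_, substr(seqs, 1L, 2L)),
    acceptor2 = ifelse(is.na(seqs), NA_character_,
                       substr(seqs, nchar(seqs) - 1L, nchar(seqs)))
  )
}

#' Write gene models back to GFF3
#'
#' Inverse of [build_gene_models()]: produces gene/mRNA/CDS rows in 1-based
#' inclusive coordinates so that re-reading reproduces identical segments.
#'
#' @param models named list of `gene_model`.
#' @param path output path.
#' @export
write_gene_models_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in models) {
    m <- g$cds_segments
    lo <- min(m[, 1]) + 1L
    hi <- max(m[, 2])
    mid <- paste0(g$gene_id, ".t1")
    writeLines(sprintf("%s\tintronevo\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom_id, lo, hi, g$strand, g$gene_id), con)
    writeLines(sprintf("%s\tintronevo\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$chrom_id, lo, hi, g$strand, mid, g$gene_id), con)
    for (i in seq_len(nrow(m))) {
      writeLines(sprintf(
        "%s\tintronevo\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
        g$chrom_id, m[i, 1] + 1L, m[i, 2], g$strand, mid, i, mid), con)
    }
  }
  invisible(path)
}
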