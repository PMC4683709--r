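## orthology: reciprocal-best-hit ortholog detection, protein-guided codon
## alignment, projection of intron positions onto alignment columns, and the
## alignment-quality / junction-evidence filters applied before any
## loss/gain call.
##
## Intron positions are compared at codon + phase resolution: two introns
## are the same site iff they fall in the same aligned-CDS column with the
## same phase.

BLAST6_COLS <- c("query_id", "subject_id", "percent_identity", "aln_length",
                 "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read BLAST tabular output (outfmt 6)
#'
#' @param path path to a 12-column tab-separated hit table.
#' @return data.frame with the standard outfmt-6 columns.
#' @export
read_blast_tab <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) {
    df <- as.data.frame(setNames(
      lapply(BLAST6_COLS, function(x) character()), BLAST6_COLS))
    return(df)
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = BLAST6_COLS)
  df
}

best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$query_id, -hits$bitscore, hits$evalue,
             -hits$percent_identity, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  first <- !duplicated(h$query_id)
  ## flag queries whose top two hits tie on every criterion
  key <- paste(h$bitscore, h$evalue, h$percent_identity)
  amb <- h$query_id[which(!first & key == c("", key[-length(key)]) &
                            h$query_id == c("", h$query_id[-nrow(h)]))]
  if (length(amb) > 0L) {
    message("ambiguous best hit (full tie) for: ",
            paste(unique(amb), collapse = ", "),
            "; broken by subject id")
  }
  h[first, , drop = FALSE]
}

#' One-to-one orthologs by reciprocal best hits
#'
#' Hits are first filtered on E-value and percent identity; the best hit per
#' query is the highest bitscore (ties broken by lowest E-value, highest
#' identity, then lexicographic subject id, with a logged ambiguity flag).
#' A pair is retained iff each gene is the other's best hit.
#'
#' @param hits_ab,hits_ba hit tables (A-vs-B and B-vs-A) as returned by
#'   [read_blast_tab()].
#' @param evalue_max maximum E-value (default `1e-10`).
#' @param identity_min minimum percent identity (default 25).
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba,
                                 evalue_max = 1e-10, identity_min = 25) {
  keep <- function(h) h[h$evalue <= evalue_max &
                          h$percent_identity >= identity_min, , drop = FALSE]
  ab <- best_hit_per_query(keep(hits_ab))
  ba <- best_hit_per_query(keep(hits_ba))
  if (nrow(ab) == 0L || nrow(ba) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character()))
  }
  back <- stats::setNames(ba$subject_id, ba$query_id)
  ok <- !is.na(back[ab$subject_id]) & back[ab$subject_id] == ab$query_id
  out <- data.frame(gene_a = ab$query_id[ok], gene_b = ab$subject_id[ok],
                    stringsAsFactors = FALSE)
  out[order(out$gene_a), , drop = FALSE]
}

#' Global protein alignment with affine gaps
#'
#' Needleman-Wunsch global alignment under BLOSUM62 with affine gap costs
#' (open 10, extend 0.5), via [Biostrings::pairwiseAlignment()].
#'
#' @param protein_a,protein_b amino-acid strings (no gaps).
#' @return list with `aligned_a`, `aligned_b` (equal-length gapped strings)
#'   and `score`.
#' @export
align_proteins <- function(protein_a, protein_b) {
  stopifnot(nzchar(protein_a), nzchar(protein_b))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein_a), Biostrings::AAString(protein_b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  list(aligned_a = as.character(Biostrings::alignedPattern(pa)),
       aligned_b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

## expand an aligned protein to an aligned CDS: each residue becomes its
## codon, each '-' becomes '---'
codon_expand <- function(aligned_protein, cds) {
  chars <- strsplit(aligned_protein, "", fixed = TRUE)[[1]]
  ngap <- sum(chars != "-")
  if (nchar(cds) < 3L * ngap) {
    stop("CDS shorter than 3x aligned residues")
  }
  out <- character(length(chars))
  pos <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "-") {
      out[i] <- "---"
    } else {
      out[i] <- substr(cds, 3L * pos + 1L, 3L * pos + 3L)
      pos <- pos + 1L
    }
  }
  paste(out, collapse = "")
}

#' Build a codon alignment for an ortholog pair
#'
#' Aligns the two proteins (or accepts a supplied protein alignment) and
#' codon-expands it against each spliced CDS.
#'
#' @param gene_a,gene_b `gene_model` objects.
#' @param aligned optional pre-computed protein alignment (list with
#'   `aligned_a`, `aligned_b`), e.g. from an external aligner.
#' @return list of class `coding_alignment` with the gapped protein and CDS
#'   tiers plus gene ids.
#' @export
codon_alignment <- function(gene_a, gene_b, aligned = NULL) {
  if (is.null(aligned)) aligned <- align_proteins(gene_a$protein,
                                                  gene_b$protein)
  cds_a <- codon_expand(aligned$aligned_a, gene_a$spliced_cds)
  cds_b <- codon_expand(aligned$aligned_b, gene_b$spliced_cds)
  structure(list(
    gene_a = gene_a$gene_id, gene_b = gene_b$gene_id,
    aligned_protein_a = aligned$aligned_a,
    aligned_protein_b = aligned$aligned_b,
    aligned_cds_a = cds_a, aligned_cds_b = cds_b,
    chars_a = strsplit(cds_a, "", fixed = TRUE)[[1]],
    chars_b = strsplit(cds_b, "", fixed = TRUE)[[1]]
  ), class = "coding_alignment")
}

## cached character vectors of the aligned CDS tiers
aln_chars <- function(alignment, side) {
  cached <- alignment[[paste0("chars_", side)]]
  if (!is.null(cached)) return(cached)
  strsplit(alignment[[paste0("aligned_cds_", side)]], "",
           fixed = TRUE)[[1]]
}

## 0-based aligned-CDS column of the nucleotide following `offset` ungapped
## nucleotides of `aligned_cds`
offset_to_column <- function(aligned_cds, offset) {
  chars <- strsplit(aligned_cds, "", fixed = TRUE)[[1]]
  nongap <- cumsum(chars != "-")
  col <- which(nongap == offset + 1L & chars != "-")[1]
  if (is.na(col)) stop("intron offset ", offset, " beyond CDS length")
  col - 1L
}

## inverse: ungapped offset just before a 0-based aligned column
column_to_offset <- function(aligned_cds, column) {
  if (column == 0L) return(0L)
  chars <- strsplit(substr(aligned_cds, 1L, column), "", fixed = TRUE)[[1]]
  sum(chars != "-")
}

## cached-vector variants used on hot paths
offset_to_column_aln <- function(alignment, side, offset) {
  nz <- which(aln_chars(alignment, side) != "-")
  col <- nz[offset + 1L]
  if (is.na(col)) stop("intron offset ", offset, " beyond CDS length")
  col - 1L
}

column_to_offset_aln <- function(alignment, side, column) {
  if (column == 0L) return(0L)
  sum(aln_chars(alignment, side)[seq_len(column)] != "-")
}

#' Project intron positions of two orthologs onto their codon alignment
#'
#' Each intron is mapped to the aligned-CDS column given by its `cds_offset`
#' counted in the ungapped coordinates of its own sequence. Introns of the
#' two species form one conserved site iff they land in the same column with
#' the same phase; otherwise each yields a discordant site.
#'
#' @param alignment a `coding_alignment`.
#' @param introns_a,introns_b intron tables from [extract_introns()].
#' @return data.frame of intron site calls: `gene_a`, `gene_b`, `column`,
#'   `phase`, `status` (`conserved`, `discordant_a_only`,
#'   `discordant_b_only`), per-species `offset_*`, `ordinal_*`, `gstart_*`,
#'   `gend_*` (NA on the intron-less side).
#' @export
project_intron_sites <- function(alignment, introns_a, introns_b) {
  stopifnot(inherits(alignment, "coding_alignment"))
  site_row <- function(introns, aligned_cds, side) {
    if (nrow(introns) == 0L) return(NULL)
    cols <- vapply(introns$cds_offset, function(o) {
      tryCatch(offset_to_column_aln(alignment, side, o),
               error = function(e) stop("gene ", introns$gene_id[1], ": ",
                                        conditionMessage(e)))
    }, numeric(1))
    data.frame(column = as.integer(cols), phase = introns$phase,
               offset = introns$cds_offset, ordinal = introns$ordinal,
               gstart = introns$gstart, gend = introns$gend,
               chrom = introns$chrom, side = side)
  }
  a <- site_row(introns_a, alignment$aligned_cds_a, "a")
  b <- site_row(introns_b, alignment$aligned_cds_b, "b")
  blank <- data.frame(
    gene_a = character(), gene_b = character(), column = integer(),
    phase = integer(), status = character(),
    offset_a = integer(), ordinal_a = integer(), gstart_a = integer(),
    gend_a = integer(), chrom_a = character(), offset_b = integer(),
    ordinal_b = integer(), gstart_b = integer(), gend_b = integer(),
    chrom_b = character())
  if (is.null(a) && is.null(b)) return(blank)

  keys_a <- if (is.null(a)) character() else paste(a$column, a$phase)
  keys_b <- if (is.null(b)) character() else paste(b$column, b$phase)
  rows <- list()
  add <- function(col, phase, status, ra = NULL, rb = NULL) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_a = alignment$gene_a, gene_b = alignment$gene_b,
      column = col, phase = phase, status = status,
      offset_a = if (is.null(ra)) NA_integer_ else ra$offset,
      ordinal_a = if (is.null(ra)) NA_integer_ else ra$ordinal,
      gstart_a = if (is.null(ra)) NA_integer_ else ra$gstart,
      gend_a = if (is.null(ra)) NA_integer_ else ra$gend,
      chrom_a = if (is.null(ra)) NA_character_ else ra$chrom,
      offset_b = if (is.null(rb)) NA_integer_ else rb$offset,
      ordinal_b = if (is.null(rb)) NA_integer_ else rb$ordinal,
      gstart_b = if (is.null(rb)) NA_integer_ else rb$gstart,
      gend_b = if (is.null(rb)) NA_integer_ else rb$gend,
      chrom_b = if (is.null(rb)) NA_character_ else rb$chrom)
  }
  if (!is.null(a)) {
    for (i in seq_len(nrow(a))) {
      j <- match(keys_a[i], keys_b)
      if (!is.na(j)) add(a$column[i], a$phase[i], "conserved",
                         a[i, ], b[j, ])
      else add(a$column[i], a$phase[i], "discordant_a_only", a[i, ], NULL)
    }
  }
  if (!is.null(b)) {
    for (j in seq_len(nrow(b))) {
      if (!(keys_b[j] %in% keys_a)) {
        add(b$column[j], b$phase[j], "discordant_b_only", NULL, b[j, ])
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$column, out$phase), , drop = FALSE]
}

#' Alignment similarity in a window flanking a site
#'
#' For each side of an aligned-CDS column, the fraction of window columns in
#' which the two sequences carry identical non-gap nucleotides. Gap columns
#' count as mismatches; windows truncated by the alignment end use the
#' available column count as denominator.
#'
#' @param alignment a `coding_alignment`.
#' @param aln_column 0-based aligned-CDS column of the site.
#' @param window columns per side (default 45).
#' @return named numeric `c(left =, right =)`.
#' @export
flank_similarity <- function(alignment, aln_column, window = 45) {
  stopifnot(window > 0)
  a <- aln_chars(alignment, "a")
  b <- aln_chars(alignment, "b")
  L <- length(a)
  side <- function(from, to) {
    from <- max(1L, from); to <- min(L, to)
    if (from > to) return(NA_real_)
    idx <- from:to
    sum(a[idx] == b[idx] & a[idx] != "-") / length(idx)
  }
  c(left = side(aln_column - window + 1L, aln_column),
    right = side(aln_column + 1L, aln_column + window))
}

#' Whole-alignment similarity
#'
#' Fraction of alignment columns with identical non-gap nucleotides.
#' @param alignment a `coding_alignment`.
#' @return scalar in \[0, 1\].
#' @export
alignment_similarity <- function(alignment) {
  a <- aln_chars(alignment, "a")
  b <- aln_chars(alignment, "b")
  sum(a == b & a != "-") / length(a)
}

#' Discard sites with low-quality flanking alignment
#'
#' A site is marked `discarded_low_quality` when either flank similarity is
#' below `min_similarity`. The first quartile (type-7) of supplied
#' whole-alignment similarities is reported so the threshold can be
#' re-derived per dataset.
#'
#' @param sites site table carrying `sim_left`/`sim_right` columns.
#' @param min_similarity threshold (default 0.5).
#' @param alignment_similarities optional numeric vector of per-pair
#'   whole-alignment similarities; its first quartile is attached as
#'   attribute `q1`.
#' @return the site table with `status` updated; attribute `q1` when
#'   computable.
#' @export
filter_sites <- function(sites, min_similarity = 0.5,
                         alignment_similarities = NULL) {
  if (nrow(sites) > 0L) {
    low <- !is.na(sites$sim_left) & !is.na(sites$sim_right) &
      (sites$sim_left < min_similarity | sites$sim_right < min_similarity)
    ## one-sided truncation to nothing: treat missing side as unassessable
    low <- low | (is.na(sites$sim_left) & !is.na(sites$sim_right) &
                    sites$sim_right < min_similarity)
    low <- low | (is.na(sites$sim_right) & !is.na(sites$sim_left) &
                    sites$sim_left < min_similarity)
    sites$status[low] <- "discarded_low_quality"
  }
  if (!is.null(alignment_similarities) &&
      length(alignment_similarities) > 0L) {
    attr(sites, "q1") <- unname(stats::quantile(alignment_similarities,
                                                0.25, type = 7))
  }
  sites
}

#' Read splice-junction evidence from BED
#'
#' Accepts 6-column junction BED (`chrom start end name count strand`) or
#' BED12, in which case one junction per block gap is derived. Coordinates
#' stay 0-based half-open.
#'
#' @param path BED file path.
#' @return data.frame `chrom`, `start`, `end`, `count`.
#' @export
read_junctions_bed <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  rows <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L || is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3])))) {
      stop("malformed BED line ", i, " in ", path)
    }
    start <- as.integer(f[2]); end <- as.integer(f[3])
    count <- suppressWarnings(as.numeric(f[5]))
    if (is.na(count)) stop("malformed BED line ", i, " in ", path)
    if (length(f) >= 12L) {
      nblk <- as.integer(f[10])
      sizes <- as.integer(strsplit(f[11], ",")[[1]])[seq_len(nblk)]
      starts <- as.integer(strsplit(f[12], ",")[[1]])[seq_len(nblk)]
      if (nblk >= 2L) {
        for (k in seq_len(nblk - 1L)) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = f[1], start = start + starts[k] + sizes[k],
            end = start + starts[k + 1L], count = count)
        }
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(chrom = f[1], start = start,
                                              end = end, count = count)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), count = numeric()))
  }
  do.call(rbind, rows)
}

#' Confirm extant introns at discordant sites against junction evidence
#'
#' An extant intron at a discordant site is confirmed iff a junction with
#' `count >= min_reads` matches both splice sites exactly (same chromosome,
#' identical 0-based start and end). Unconfirmed introns mark the site
#' `discarded_junction`. When a species has no junction data, its sites are
#' retained unchanged: absence of evidence is not treated as evidence
#' against, and a message is logged.
#'
#' @param sites site table from [project_intron_sites()] (with `chrom_a`,
#'   `chrom_b` columns present).
#' @param junctions_a,junctions_b junction tables from
#'   [read_junctions_bed()], or NULL when unavailable.
#' @param min_reads minimum supporting read count (default 1).
#' @return the site table with `status` updated.
#' @export
junction_filter <- function(sites, junctions_a = NULL, junctions_b = NULL,
                            min_reads = 1) {
  if (nrow(sites) == 0L) return(sites)
  confirm <- function(chrom, gstart, gend, jx) {
    any(jx$chrom == chrom & jx$start == gstart & jx$end == gend &
          jx$count >= min_reads)
  }
  check_side <- function(status_tag, jx, chrom_col, gs_col, ge_col) {
    if (is.null(jx)) {
      message("no junction data for side ", status_tag,
              "; sites retained unchanged")
      return()
    }
    for (i in which(sites$status == status_tag)) {
      if (!confirm(sites[[chrom_col]][i], sites[[gs_col]][i],
                   sites[[ge_col]][i], jx)) {
        sites$status[i] <<- "discarded_junction"
      }
    }
  }
  check_side("discordant_a_only", junctions_a, "chrom_a", "gstart_a",
             "gend_a")
  check_side("discordant_b_only", junctions_b, "chrom_b", "gstart_b",
             "gend_b")
  sites
}
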