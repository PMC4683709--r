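## loss_features: per-event characterisation of inferred intron losses.
## The quantities here discriminate between the three mechanistic models of
## intron loss: reverse transcription (precise, 3'-biased, adjacent
## co-losses, GC-elevated flanks via biased gene conversion), simple genomic
## deletion (flanking exonic indels), and NHEJ double-strand-break repair
## (short direct repeats at the lost-intron boundaries).

#' Classify a loss as precise or imprecise
#'
#' A precise loss leaves no insertion/deletion in the flanking exonic
#' sequence: no gap column within `window` aligned-CDS columns on either
#' side of the lost-intron position. Otherwise the loss is imprecise and
#' the summed gap length in the window is reported.
#'
#' @param alignment a `coding_alignment` for the ortholog pair.
#' @param aln_column 0-based aligned-CDS column of the lost-intron site.
#' @param window aligned columns inspected per side (default 15).
#' @return list `precise` (logical), `flank_indel_bp` (integer).
#' @export
classify_precision <- function(alignment, aln_column, window = 15) {
  a <- aln_chars(alignment, "a")
  b <- aln_chars(alignment, "b")
  L <- length(a)
  from <- max(1L, aln_column - window + 1L)
  to <- min(L, aln_column + window)
  idx <- from:to
  gaps <- sum(a[idx] == "-") + sum(b[idx] == "-")
  list(precise = gaps == 0L, flank_indel_bp = as.integer(gaps))
}

#' Count adjacent-loss pairs
#'
#' Within each gene, counts pairs of lost introns with consecutive ordinals
#' (ancestral gene structure); a run of three adjacent lost introns counts
#' as two pairs. Counts are summed over genes.
#'
#' @param lost data.frame with columns `gene_id`, `ordinal`.
#' @return integer pair count.
#' @export
adjacent_loss_pairs <- function(lost) {
  if (nrow(lost) == 0L) return(0L)
  total <- 0L
  for (g in unique(lost$gene_id)) {
    o <- sort(unique(lost$ordinal[lost$gene_id == g]))
    if (length(o) > 1L) total <- total + sum(diff(o) == 1L)
  }
  as.integer(total)
}

#' Direct-repeat lengths at intron boundaries
#'
#' `repeat_len_5p` is the longest k (up to `k_max`) for which the first k nt
#' of the intron equal the first k nt of the downstream exon;
#' `repeat_len_3p` the longest k for which the last k nt of the upstream
#' exon equal the last k nt of the intron. Either repeat permits a deletion
#' that removes the intron precisely, the microhomology signature expected
#' under NHEJ-mediated loss.
#'
#' @param upstream_exon,intron_seq,downstream_exon nucleotide strings in
#'   transcript orientation.
#' @param k_max maximum repeat length searched (default 10).
#' @return named integer `c(repeat_len_5p =, repeat_len_3p =)`.
#' @export
direct_repeat_length <- function(upstream_exon, intron_seq, downstream_exon,
                                 k_max = 10) {
  lcp <- function(x, y) {
    n <- min(nchar(x), nchar(y), k_max)
    k <- 0L
    while (k < n && substr(x, k + 1L, k + 1L) == substr(y, k + 1L, k + 1L)) {
      k <- k + 1L
    }
    k
  }
  rev_chr <- function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                               collapse = "")
  c(repeat_len_5p = lcp(intron_seq, downstream_exon),
    repeat_len_3p = lcp(rev_chr(upstream_exon), rev_chr(intron_seq)))
}

#' Compare boundary-repeat frequency between lost and conserved introns
#'
#' Builds the 2x2 table of sites with maximal boundary repeat >= k versus
#' < k in the two site sets and applies the Pearson chi-square test.
#'
#' @param lost_repeats,conserved_repeats integer vectors of per-site maximal
#'   repeat lengths.
#' @param k repeat-length threshold.
#' @return list `table` (2x2 matrix), `chi2`, `p`.
#' @export
repeat_frequency_compare <- function(lost_repeats, conserved_repeats, k) {
  tab <- matrix(c(sum(lost_repeats >= k), sum(lost_repeats < k),
                  sum(conserved_repeats >= k), sum(conserved_repeats < k)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("lost", "conserved"),
                                c("ge_k", "lt_k")))
  ct <- chi_square_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  list(table = tab, chi2 = ct$chi2, p = ct$p)
}

#' Relative position of an intron within its gene
#'
#' Spliced-CDS length upstream of the intron divided by total spliced-CDS
#' length: 0 marks the 5' end, 1 the 3' end. Reverse-transcription-mediated
#' loss predicts lost introns to sit 3' of conserved ones, because partial
#' cDNAs anchor at the 3' end of the transcript.
#'
#' @param cds_offset nt of spliced CDS upstream of the intron.
#' @param cds_length total spliced-CDS length.
#' @return fraction in (0, 1).
#' @export
relative_intron_position <- function(cds_offset, cds_length) {
  stopifnot(cds_length > 0)
  cds_offset / cds_length
}

#' GC content of exonic windows flanking an intron position
#'
#' Takes up to `window` bp of spliced CDS (exonic sequence only — windows
#' never cross into neighbouring introns) on each side of the position and
#' pools both sides: GC = (G+C) / (non-N bases). Windows truncated by the
#' CDS ends use whatever sequence is available.
#'
#' @param spliced_cds spliced CDS of the gene.
#' @param cds_offset intron position (nt upstream of the intron).
#' @param window bp per side, one of 50/100/200 conventionally
#'   (default 100).
#' @return list `gc` (pooled fraction), `left`, `right` (per-side
#'   fractions), `left_seq`, `right_seq`.
#' @export
flank_gc <- function(spliced_cds, cds_offset, window = 100) {
  left <- substr_clip(spliced_cds, cds_offset - window + 1L, cds_offset)
  right <- substr_clip(spliced_cds, cds_offset + 1L, cds_offset + window)
  list(gc = gc_fraction(paste0(left, right)),
       left = gc_fraction(left), right = gc_fraction(right),
       left_seq = left, right_seq = right)
}

#' Flank GC relative to the gene's conserved introns
#'
#' Ratio of the site's flank GC to the median flank GC over the conserved
#' introns of the same gene. This normalisation removes gene- and
#' species-level GC differences so that loss-associated GC elevation can be
#' compared across genomes with different base composition.
#'
#' @param site_gc flank GC at the queried site.
#' @param conserved_gcs_same_gene numeric vector of flank GC values at the
#'   gene's conserved intron positions.
#' @return ratio, or `NA` if no conserved intron is available or the median
#'   is zero (warned).
#' @export
relative_flank_gc <- function(site_gc, conserved_gcs_same_gene) {
  cons <- conserved_gcs_same_gene[!is.na(conserved_gcs_same_gene)]
  if (length(cons) == 0L) return(NA_real_)
  m <- stats::median(cons)
  if (m == 0) {
    warning("median conserved-intron flank GC is zero; ratio undefined")
    return(NA_real_)
  }
  site_gc / m
}

## codon prefixes whose third position is 4-fold degenerate (standard code)
FOURFOLD_PREFIXES <- c("CT", "GT", "TC", "CC", "AC", "GC", "CG", "GG")

#' GC at 4-fold degenerate sites in the flanking windows
#'
#' Restricts the flank windows to whole codons (partial codons at the window
#' edges are trimmed), keeps codons whose first two bases determine a
#' 4-fold degenerate family, and returns the GC fraction at their third
#' positions.
#'
#' @inheritParams flank_gc
#' @return fraction, or `NA` when the windows contain no 4-fold codon.
#' @export
fourfold_gc <- function(spliced_cds, cds_offset, window = 100) {
  thirds <- character(0)
  collect <- function(win_start, win_end) {
    ## trim to codon boundaries of the CDS reading frame
    win_start <- max(1L, win_start); win_end <- min(nchar(spliced_cds),
                                                    win_end)
    if (win_start > win_end) return()
    first <- win_start + (3L - (win_start - 1L) %% 3L) %% 3L
    last <- win_end - (win_end %% 3L)
    if (first > last) return()
    for (p in seq(first, last - 2L, by = 3L)) {
      codon <- substr(spliced_cds, p, p + 2L)
      if (substr(codon, 1L, 2L) %in% FOURFOLD_PREFIXES) {
        thirds <<- c(thirds, substr(codon, 3L, 3L))
      }
    }
  }
  collect(cds_offset - window + 1L, cds_offset)
  collect(cds_offset + 1L, cds_offset + window)
  if (length(thirds) == 0L) return(NA_real_)
  gc_fraction(paste(thirds, collapse = ""))
}
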