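## gain_source: evidence filters for putative intron gains. A convincing
## gain needs an identifiable source sequence; BLAST hits of the gained
## intron against the genomes are screened on E-value, query coverage and
## identity, after discarding the trivial self-hit at the intron's own
## locus. The module also summarises reverse-transcriptase copy numbers,
## the proxy used to compare reverse-transcription activity (and hence
## expected RT-mediated intron-loss rates) between species.

#' Filter candidate source sequences for gained introns
#'
#' Self-hits (same chromosome, >= 1 bp overlap with the intron's own
#' genomic interval) are rejected first; surviving hits must pass all three
#' thresholds conjunctively. Coverage is query (intron) coverage,
#' `aln_length / intron_length`, capped at 1; similarity is
#' `percent_identity / 100`.
#'
#' @param hits hit table ([read_blast_tab()]); `query_id` must name gained
#'   introns present in `intron_info`.
#' @param intron_info data.frame with columns `intron_id`, `length`,
#'   `chrom`, `gstart`, `gend` (the intron's own locus).
#' @param evalue_max E-value threshold (default `1e-10`).
#' @param cov_min coverage threshold (default 0.80).
#' @param sim_min similarity threshold (default 0.85).
#' @return data.frame: one row per hit with `intron_id`, `subject_id`,
#'   `coverage`, `similarity`, `evalue`, `verdict` in `retained`,
#'   `rejected_self`, `rejected_evalue`, `rejected_coverage`,
#'   `rejected_similarity`.
#' @export
filter_source_hits <- function(hits, intron_info, evalue_max = 1e-10,
                               cov_min = 0.80, sim_min = 0.85) {
  if (nrow(hits) == 0L) {
    return(data.frame(intron_id = character(), subject_id = character(),
                      coverage = numeric(), similarity = numeric(),
                      evalue = numeric(), verdict = character()))
  }
  unknown <- setdiff(hits$query_id, intron_info$intron_id)
  if (length(unknown) > 0L) {
    stop("hits reference unknown intron id(s): ",
         paste(unknown, collapse = ", "))
  }
  info <- intron_info[match(hits$query_id, intron_info$intron_id), ]
  coverage <- pmin(1, hits$aln_length / info$length)
  similarity <- hits$percent_identity / 100
  s_lo <- pmin(hits$sstart, hits$send) - 1L  # to 0-based half-open
  s_hi <- pmax(hits$sstart, hits$send)
  self <- hits$subject_id == info$chrom &
    s_lo < info$gend & s_hi > info$gstart
  verdict <- ifelse(self, "rejected_self",
             ifelse(hits$evalue > evalue_max, "rejected_evalue",
             ifelse(coverage < cov_min, "rejected_coverage",
             ifelse(similarity < sim_min, "rejected_similarity",
                    "retained"))))
  data.frame(intron_id = hits$query_id, subject_id = hits$subject_id,
             coverage = coverage, similarity = similarity,
             evalue = hits$evalue, verdict = verdict)
}

#' Canonical splice-boundary check
#'
#' @param intron_seq intron sequence in transcript orientation.
#' @return TRUE iff the sequence starts with GT and ends with AG.
#' @export
splice_boundary_check <- function(intron_seq) {
  stopifnot(nzchar(intron_seq))
  startsWith(intron_seq, "GT") & endsWith(intron_seq, "AG")
}

#' Reverse-transcriptase copy-number summary
#'
#' For each species, counts the distinct annotated protein models hit by at
#' least one reverse-transcriptase query passing the E-value threshold, and
#' reports the ratio between the first two species.
#'
#' @param query_hits_by_species named list of BLASTP hit tables, one per
#'   species.
#' @param evalue_max E-value threshold (default `1e-10`).
#' @return list `counts` (named integer vector) and `ratio`
#'   (first / second species, `NA` when the denominator is zero).
#' @export
rt_copy_numbers <- function(query_hits_by_species, evalue_max = 1e-10) {
  counts <- vapply(query_hits_by_species, function(h) {
    if (nrow(h) == 0L) return(0L)
    length(unique(h$subject_id[h$evalue <= evalue_max]))
  }, integer(1))
  ratio <- NA_real_
  if (length(counts) >= 2L && counts[2] > 0L) {
    ratio <- unname(counts[1] / counts[2])
  }
  list(counts = counts, ratio = ratio)
}
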