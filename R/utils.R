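## Small shared helpers. Coordinates are 0-based half-open internally;
## GFF3 I/O converts to/from 1-based inclusive.

#' GC fraction of a nucleotide string
#'
#' N (and any other non-ACGT character) counts as non-GC and is excluded
#' from the denominator.
#'
#' @param x character scalar of nucleotides (upper case).
#' @return fraction in \[0, 1\], or `NA` if no A/C/G/T base is present.
#' @export
gc_fraction <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  b <- strsplit(x, "", fixed = TRUE)[[1]]
  acgt <- b %in% c("A", "C", "G", "T")
  if (!any(acgt)) return(NA_real_)
  sum(b == "G" | b == "C") / sum(acgt)
}

## reverse complement of a plain character string
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## translate a spliced CDS (character); returns AA string, stops as '*',
## codons containing N (or any non-ACGT base) as 'X'
translate_cds <- function(x) {
  n <- nchar(x)
  if (n < 3L) return("")
  starts <- seq.int(1L, n - 2L, by = 3L)
  aa <- unname(Biostrings::GENETIC_CODE[substring(x, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## substring that tolerates out-of-range bounds by clipping
substr_clip <- function(x, start, stop) {
  n <- nchar(x)
  start <- max(1L, start)
  stop <- min(n, stop)
  if (start > stop) return("")
  substr(x, start, stop)
}

## deterministic RNG scope: evaluate expr with a local seed, restoring state
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
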