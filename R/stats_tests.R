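## stats: inferential machinery. The central question is whether adjacent
## introns are lost together more often than independent losses would
## produce. Two nulls are provided: a Monte-Carlo resampling of the lost
## set's size from the pool of lost + extant introns, and an exact
## distribution obtained by dynamic programming within genes and
## convolution across genes under uniform independent loss placement.

#' Resampling null for adjacent-loss pairs
#'
#' Each replicate draws `n_lost` introns uniformly without replacement from
#' the pool and counts adjacent-ordinal pairs. The primary p-value follows
#' the plain tail convention p = #\{replicates >= observed\}/R; the shrunk
#' estimator (x+1)/(R+1) is reported alongside.
#'
#' @param pool data.frame with columns `gene_id`, `ordinal` (lost and
#'   extant introns of one species).
#' @param n_lost number of introns drawn per replicate.
#' @param observed observed adjacent-pair count.
#' @param R replicates (default 10000).
#' @param seed RNG seed, recorded in the result.
#' @return list `observed_pairs`, `R`, `tail_count`, `p_value`,
#'   `p_value_shrunk`, `seed`, `replicates` (integer vector of pair counts).
#' @export
resample_adjacent_pairs <- function(pool, n_lost, observed, R = 10000,
                                    seed = 1L) {
  stopifnot(R >= 1, n_lost <= nrow(pool))
  if (observed < 0) stop("observed pair count must be >= 0")
  if (anyDuplicated(pool[, c("gene_id", "ordinal")]) > 0L) {
    stop("duplicate (gene_id, ordinal) entries in intron pool")
  }
  ## encode introns so that key+1 is the next ordinal of the same gene and
  ## cannot collide across genes
  gidx <- as.integer(factor(pool$gene_id))
  base <- max(pool$ordinal) + 2L
  keys <- gidx * base + pool$ordinal
  reps <- with_seed(seed, {
    vapply(seq_len(R), function(i) {
      s <- sample(keys, n_lost)
      sum((s + 1L) %in% s)
    }, integer(1))
  })
  tail_count <- sum(reps >= observed)
  list(observed_pairs = observed, R = R, tail_count = tail_count,
       p_value = tail_count / R,
       p_value_shrunk = (tail_count + 1) / (R + 1),
       seed = seed, replicates = reps)
}

## distribution of adjacent-pair counts when k of n ordinals are chosen
## uniformly at random: DP over positions, state = (chosen so far, last
## position chosen?), accumulating pair counts. Returns probability vector
## over 0..max(k-1, 0).
adjacent_pair_distribution <- function(n, k) {
  stopifnot(n >= 0, k >= 0)
  if (k > n) stop("k_lost (", k, ") exceeds n_introns (", n, ")")
  if (k <= 1L || n <= 1L) return(stats::setNames(1, "0"))
  maxj <- k - 1L
  ## counts[c+1, j+1, last+1] = #ways after current prefix
  counts <- array(0, dim = c(k + 1L, maxj + 1L, 2L))
  counts[1L, 1L, 1L] <- 1
  for (pos in seq_len(n)) {
    nxt <- array(0, dim = dim(counts))
    for (c in 0:min(pos - 1L, k)) {
      for (j in 0:maxj) {
        for (last in 0:1) {
          w <- counts[c + 1L, j + 1L, last + 1L]
          if (w == 0) next
          ## skip this position
          nxt[c + 1L, j + 1L, 1L] <- nxt[c + 1L, j + 1L, 1L] + w
          ## choose this position
          if (c < k) {
            j2 <- j + last
            if (j2 <= maxj) {
              nxt[c + 2L, j2 + 1L, 2L] <- nxt[c + 2L, j2 + 1L, 2L] + w
            }
          }
        }
      }
    }
    counts <- nxt
  }
  ways <- counts[k + 1L, , 1L] + counts[k + 1L, , 2L]
  p <- ways / sum(ways)
  stats::setNames(p, as.character(0:maxj))
}

#' Exact null distribution of total adjacent-loss pairs
#'
#' Under the assumption that each intron is lost independently (uniform
#' placement of each gene's k losses among its n ancestral intron
#' ordinals), computes the per-gene distribution of adjacent-pair counts by
#' dynamic programming and convolves across genes to the clade-wide
#' distribution of the total.
#'
#' @param genes data.frame with columns `n_introns`, `k_lost` (one row per
#'   gene carrying at least one loss; genes with `k_lost = 0` contribute
#'   nothing and may be omitted).
#' @param observed optional observed total; when given, the upper-tail
#'   probability P(total >= observed) is attached.
#' @return list `per_gene` (list of named probability vectors), `total`
#'   (named probability vector over total pair counts), `p_tail` (or NA).
#' @export
adjacency_null_distribution <- function(genes, observed = NULL) {
  per_gene <- lapply(seq_len(nrow(genes)), function(i) {
    adjacent_pair_distribution(genes$n_introns[i], genes$k_lost[i])
  })
  total <- c("0" = 1)
  for (pg in per_gene) {
    new_len <- length(total) + length(pg) - 1L
    conv <- numeric(new_len)
    for (i in seq_along(total)) {
      for (j in seq_along(pg)) {
        conv[i + j - 1L] <- conv[i + j - 1L] + total[i] * pg[j]
      }
    }
    total <- stats::setNames(conv, as.character(seq_len(new_len) - 1L))
  }
  p_tail <- NA_real_
  if (!is.null(observed)) {
    support <- as.integer(names(total))
    p_tail <- sum(total[support >= observed])
  }
  list(per_gene = per_gene, total = total, p_tail = p_tail)
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction by default. A table with a zero margin carries
#' no information: chi2 = 0, p = 1, with a warning.
#'
#' @param a,b,c,d cell counts, row-wise.
#' @param correction apply the Yates continuity correction.
#' @return list `chi2`, `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d, correction = FALSE) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  stopifnot(all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in 2x2 table; test undefined")
    return(list(chi2 = 0, p = 1))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correction))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

#' Mann-Whitney U test
#'
#' Exact when both samples are small (min(n, m) <= 8) and untied, normal
#' approximation with tie and continuity correction otherwise; thin wrapper
#' around [stats::wilcox.test()] reporting the U statistic.
#'
#' @param x,y numeric samples.
#' @param alternative `two.sided` (default), `less`, or `greater`.
#' @return list `U`, `p`.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1L) return(list(U = length(x) * length(y) / 2,
                                                 p = 1))
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && min(length(x), length(y)) <= 8
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = unname(wt$p.value))
}

#' Wilcoxon signed-rank test of relative positions against 0.5
#'
#' Tests whether relative intron positions are symmetric around the gene
#' midpoint; zeros (positions exactly 0.5) are dropped. Exact for n <= 25
#' without ties, normal approximation otherwise.
#'
#' @param positions numeric vector of relative positions in \[0, 1\].
#' @param alternative passed to [stats::wilcox.test()].
#' @return list `V`, `p`, `n_used`.
#' @export
wilcoxon_signed_rank <- function(positions, alternative = "two.sided") {
  d <- positions - 0.5
  d <- d[d != 0]
  if (length(d) == 0L) return(list(V = 0, p = 1, n_used = 0L))
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(
    d, alternative = alternative, exact = exact, correct = TRUE))
  list(V = unname(wt$statistic), p = unname(wt$p.value),
       n_used = length(d))
}
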