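# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check.

# Gotoh affine-gap global alignment score (score only), matching the
# convention where a gap of length L costs gapOpening + gapExtension * L.
nw_affine_score <- function(a, b, open = 10, ext = 0.5) {
  submat <- get_blosum62()
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (x aligned to '-')
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[x[i], y[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             X[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Brute-force Dollo minimum: enumerate every assignment of internal-node
# (and unknown-tip) states; valid when the character originates at most
# once (root presence counts as the origin). Returns the minimal total
# number of events (origin + losses).
dollo_brute_min <- function(profile, tree) {
  ntip <- length(tree$tip.label)
  n_nodes <- max(tree$edge)
  internal <- (ntip + 1L):n_nodes
  tips_state <- setNames(rep(NA, ntip), tree$tip.label)
  known <- names(profile)[profile != "unknown"]
  tips_state[known] <- profile[known] == "present"
  free_tips <- which(is.na(tips_state))
  best <- Inf
  n_free <- length(free_tips) + length(internal)
  for (mask in 0:(2^n_free - 1)) {
    st <- logical(n_nodes)
    st[seq_len(ntip)][!is.na(tips_state)] <-
      tips_state[!is.na(tips_state)]
    bits <- as.logical(bitwAnd(mask, 2^(seq_len(n_free) - 1L)))
    if (length(free_tips) > 0) {
      st[free_tips] <- bits[seq_along(free_tips)]
    }
    st[internal] <- bits[(length(free_tips) + 1L):n_free]
    root <- ntip + 1L
    gains <- as.integer(st[root])
    losses <- 0L
    for (k in seq_len(nrow(tree$edge))) {
      p <- tree$edge[k, 1]; c <- tree$edge[k, 2]
      if (!st[p] && st[c]) gains <- gains + 1L
      if (st[p] && !st[c]) losses <- losses + 1L
    }
    if (gains > 1L) next
    if (any(st[seq_len(ntip)][!is.na(tips_state)] !=
            tips_state[!is.na(tips_state)])) next
    best <- min(best, gains + losses)
  }
  best
}

# Exhaustive distribution of adjacent-pair counts over all C(n, k) subsets.
adjacent_pairs_enum <- function(n, k) {
  if (k == 0L || n == 0L || k == 1L) return(c("0" = 1))
  subsets <- utils::combn(n, k)
  pairs <- apply(subsets, 2, function(s) sum(diff(sort(s)) == 1L))
  tab <- table(factor(pairs, levels = 0:(k - 1)))
  p <- as.numeric(tab) / ncol(subsets)
  setNames(p, as.character(0:(k - 1)))
}

# Pearson chi-square by the scalar formula, upper-tail p.
chi2_scalar <- function(a, b, c, d) {
  n <- a + b + c + d
  e <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  o <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  chi2 <- sum((o - e)^2 / e)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}
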