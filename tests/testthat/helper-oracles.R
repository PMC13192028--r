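# Independent brute-force oracles used across tests. These deliberately take
# the slowest, most literal route so they share no code with the package.

# Adjusted Rand index by explicit pair counting over all cell pairs.
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a && same_b) s11 <- s11 + 1
      else if (same_a && !same_b) s10 <- s10 + 1
      else if (!same_a && same_b) s01 <- s01 + 1
      else s00 <- s00 + 1
    }
  }
  total <- s11 + s10 + s01 + s00
  expected <- (s11 + s10) * (s11 + s01) / total
  maxi <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxi == expected) return(1)
  (s11 - expected) / (maxi - expected)
}

# Two-sample KS statistic as the sup distance of empirical CDFs, evaluated
# by a double loop over every observed value.
oracle_ks_D <- function(a, b) {
  pts <- c(a, b)
  d <- 0
  for (x in pts) {
    fa <- sum(a <= x) / length(a)
    fb <- sum(b <= x) / length(b)
    d <- max(d, abs(fa - fb))
  }
  d
}

# Benjamini-Hochberg step-up by direct enumeration of the definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    q[ord[i]] <- running
  }
  q
}

# Two-sided Fisher exact p by summing hypergeometric point probabilities
# no larger than the observed one (fixed margins).
oracle_fisher_p <- function(n_a, total_a, n_b, total_b) {
  m1 <- n_a + n_b                      # clone row margin
  m0 <- (total_a - n_a) + (total_b - n_b)
  k_range <- max(0, m1 - total_b):min(m1, total_a)
  probs <- dhyper(k_range, m1, m0, total_a)
  p_obs <- dhyper(n_a, m1, m0, total_a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Quantile by literal sort-and-interpolate (type-7 definition).
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Tiny hand-buildable tensor: `spec` is a data.frame with one row per
# (barcode, position, base, strand, count).
toy_tensor <- function(spec, barcodes, positions, ref) {
  counts <- array(0L, dim = c(length(barcodes), length(positions), 4L, 2L))
  for (r in seq_len(nrow(spec))) {
    i <- match(spec$barcode[r], barcodes)
    j <- match(spec$position[r], positions)
    b <- match(spec$base[r], c("A", "C", "G", "T"))
    s <- match(spec$strand[r], c("plus", "minus"))
    counts[i, j, b, s] <- counts[i, j, b, s] + spec$count[r]
  }
  mt_tensor(counts, barcodes, positions, ref)
}

# Random additive tree + its exact leaf-to-leaf distance matrix.
random_additive_tree <- function(n_taxa) {
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(n) runif(n, 0.5, 3))
  list(tree = tree, dist = ape::cophenetic.phylo(tree))
}
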