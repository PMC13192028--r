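#' Assign cells to mtDNA-defined clonotypes
#'
#' Clusters cells on their heteroplasmy profiles: heteroplasmies are
#' square-root transformed (variance stabilization for fractions near 0), a
#' k-nearest-neighbor graph is built on cosine distance, and Louvain
#' community detection with a fixed seed partitions the graph. Clusters are
#' relabeled by decreasing size (1 = largest); clusters whose mean profile
#' has no variant reaching `min_marker_het` carry no clonal signal and
#' collapse into the background label 0. Cells with all-zero profiles (no
#' informative variant observed) go to label 0 directly.
#'
#' Missing heteroplasmy entries are treated as 0 for clustering (absence of
#' evidence) but excluded from per-clone mean profiles, so low coverage
#' cannot manufacture pseudo-clones.
#'
#' @param het heteroplasmy matrix (cells x variants, `NA` = missing).
#' @param k neighbors in the kNN graph (default 20; reduced with a warning
#'   when fewer cells are available).
#' @param resolution Louvain resolution parameter (default 1).
#' @param min_marker_het minimum mean heteroplasmy some variant must reach in
#'   a cluster for it to count as a clone (default 0.02).
#' @param merge_similarity clusters whose mean sqrt-heteroplasmy profiles
#'   have cosine similarity at or above this are merged (default 0.9);
#'   community detection on a kNN graph tends to split homogeneous
#'   populations, and clusters with near-identical profiles carry no
#'   distinguishing marker.
#' @param seed integer seed controlling community detection.
#' @return Object of class `mt_clones`: `labels` (named integer vector,
#'   0 = background), `sizes`, `profiles` (clone x variant mean
#'   heteroplasmy, background included as row "0"), `params`.
#' @export
call_clonotypes <- function(het, k = 20L, resolution = 1,
                            min_marker_het = 0.02, merge_similarity = 0.9,
                            seed = 1L) {
  stopifnot(ncol(het) >= 1)
  cells <- rownames(het) %||% as.character(seq_len(nrow(het)))
  X <- sqrt(het)
  X[is.na(X)] <- 0
  norms <- sqrt(rowSums(X^2))
  nonzero <- which(norms > 0)
  labels <- setNames(integer(nrow(het)), cells)

  if (length(nonzero) >= 2) {
    Xn <- X[nonzero, , drop = FALSE] / norms[nonzero]
    S <- tcrossprod(Xn)
    n <- nrow(S)
    kk <- min(k, n - 1L)
    if (kk < k) warning("k reduced to ", kk, " (only ", n, " cells)")
    diag(S) <- -Inf
    # k nearest neighbors per cell, deterministic tie-break by index
    nbr <- apply(S, 1, function(s) order(-s, seq_along(s))[seq_len(kk)])
    from <- rep(seq_len(n), each = kk)
    to <- as.vector(nbr)
    w <- pmax(S[cbind(from, to)], 1e-6)
    g <- igraph::graph_from_data_frame(
      data.frame(from = from, to = to, weight = w),
      directed = FALSE, vertices = data.frame(name = seq_len(n)))
    g <- igraph::simplify(g, edge.attr.comb = "max")
    memb <- with_seed(seed, {
      igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
    })
    labels[nonzero] <- as.integer(memb[as.character(seq_len(n))])
  } else if (length(nonzero) == 1) {
    labels[nonzero] <- 1L
  }

  labels <- merge_similar_clusters(het, labels, merge_similarity)
  labels <- relabel_by_size(labels)
  prof <- clone_profiles(het, labels)
  # clusters without any marker-level variant are background
  keep <- rownames(prof)[apply(prof, 1, function(p) {
    any(!is.na(p) & p >= min_marker_het)
  })]
  labels[!(as.character(labels) %in% keep)] <- 0L
  labels <- relabel_by_size(labels)
  prof <- clone_profiles(het, labels)
  structure(list(labels = labels, sizes = table(labels), profiles = prof,
                 params = list(k = k, resolution = resolution,
                               min_marker_het = min_marker_het,
                               merge_similarity = merge_similarity,
                               seed = seed)),
            class = "mt_clones")
}

# Iteratively merge the most similar pair of non-background clusters until
# all pairwise profile cosine similarities fall below the threshold.
merge_similar_clusters <- function(het, labels, merge_similarity) {
  repeat {
    lv <- setdiff(sort(unique(labels)), 0L)
    if (length(lv) < 2) break
    prof <- clone_profiles(het, labels)
    P <- sqrt(prof[as.character(lv), , drop = FALSE])
    P[is.na(P)] <- 0
    Pn <- P / pmax(sqrt(rowSums(P^2)), 1e-12)
    S <- tcrossprod(Pn)
    diag(S) <- -Inf
    top <- which(S == max(S), arr.ind = TRUE)[1, ]
    if (S[top[1], top[2]] < merge_similarity) break
    pair <- sort(lv[top])
    labels[labels == pair[2]] <- pair[1]
  }
  labels
}

# Relabel non-background clusters 1..K by decreasing size (ties by old label).
relabel_by_size <- function(labels) {
  nz <- labels[labels != 0L]
  if (!length(nz)) return(labels)
  tab <- table(nz)
  ord <- names(tab)[order(-as.integer(tab), as.integer(names(tab)))]
  map <- setNames(seq_along(ord), ord)
  labels[labels != 0L] <- map[as.character(nz)]
  labels
}

# Mean heteroplasmy profile per label, missing entries excluded.
clone_profiles <- function(het, labels) {
  lv <- sort(unique(labels))
  prof <- t(vapply(lv, function(l) {
    colMeans(het[labels == l, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(het))))
  rownames(prof) <- as.character(lv)
  prof[is.nan(prof)] <- NA_real_
  prof
}

#' @export
print.mt_clones <- function(x, ...) {
  n_clones <- sum(names(x$sizes) != "0")
  cat(sprintf("<mt_clones> %d cells in %d clones (+%d background)\n",
              length(x$labels), n_clones,
              sum(x$labels == 0L)))
  print(x$sizes)
  invisible(x)
}

#' Adjusted Rand index between two cell partitions
#'
#' Chance-corrected agreement between two labelings of the same cells;
#' 1 = identical partitions, ~0 = independent.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  r <- mclust::adjustedRandIndex(a, b)
  if (is.nan(r)) {
    # degenerate partitions (all singletons / one block): chance correction
    # is undefined; fall back to exact co-membership agreement
    same_a <- outer(a, a, "==")
    same_b <- outer(b, b, "==")
    r <- if (identical(same_a, same_b)) 1 else 0
  }
  r
}

#' Clonotype stability under cell downsampling
#'
#' Re-calls clonotypes on random subsets of cells and scores agreement with
#' the full-data assignment (adjusted Rand index restricted to retained
#' cells). A sample is called stable at a retention fraction when the median
#' agreement over replicates reaches `threshold`. Stable subclone definitions
#' indicate the clustering reflects real population structure rather than
#' sampling noise.
#'
#' @param het heteroplasmy matrix.
#' @param fractions retention fractions (default `c(0.75, 0.5)`).
#' @param n_reps replicates per fraction (default 25).
#' @param threshold median-agreement level for the "stable" call
#'   (default 0.7).
#' @param seed integer seed.
#' @param ... passed to [call_clonotypes()].
#' @return Object of class `mt_stability`: `replicates` data.frame
#'   (`fraction`, `rep`, `n_cells`, `agreement`), `summary` data.frame
#'   (`fraction`, `median_agreement`, `stable`), `baseline` (`mt_clones`).
#' @export
downsample_stability <- function(het, fractions = c(0.75, 0.5),
                                 n_reps = 25L, threshold = 0.7,
                                 seed = 1L, ...) {
  stopifnot(n_reps >= 1, all(fractions > 0), all(fractions <= 1))
  args <- list(...)
  k <- args$k %||% formals(call_clonotypes)$k
  base <- call_clonotypes(het, seed = seed, ...)
  seeds <- derive_seeds(seed, length(fractions) * n_reps)
  rows <- list()
  s <- 0L
  for (f in fractions) {
    for (r in seq_len(n_reps)) {
      s <- s + 1L
      n_keep <- round(f * nrow(het))
      if (n_keep < 2 * k) {
        warning(sprintf("fraction %.2f leaves %d cells (< 2k); skipped",
                        f, n_keep))
        next
      }
      keep <- with_seed(seeds[s], sample.int(nrow(het), n_keep))
      sub <- suppressWarnings(
        call_clonotypes(het[keep, , drop = FALSE], seed = seeds[s], ...))
      rows[[s]] <- data.frame(
        fraction = f, rep = r, n_cells = n_keep,
        agreement = adjusted_rand_index(base$labels[keep], sub$labels))
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(fractions, function(f) {
    ag <- reps$agreement[reps$fraction == f]
    data.frame(fraction = f,
               median_agreement = if (length(ag)) median(ag) else NA_real_,
               stable = if (length(ag)) median(ag) >= threshold else NA)
  }))
  structure(list(replicates = reps, summary = summ, baseline = base,
                 threshold = threshold),
            class = "mt_stability")
}

#' @export
print.mt_stability <- function(x, ...) {
  cat("<mt_stability> downsampling agreement (ARI vs full data)\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Clone frequency dynamics between paired samples
#'
#' Matches clones across two samples by their marker profiles (greedy
#' best-first on cosine similarity of square-root mean heteroplasmy, ties
#' broken by clone label) and tests each matched clone's frequency change
#' with a two-sided Fisher exact test on the (clone, other) x (A, B) table,
#' Benjamini-Hochberg corrected across clones. A clone is `dynamic` when
#' q <= `alpha` and its frequency fold change is at least `fc_threshold` in
#' either direction; clones below `min_cells` in both samples, or unmatched,
#' are `not_testable`; everything else is `stable`.
#'
#' @param a,b `mt_clones` objects for the two samples.
#' @param min_cells minimum clone size in at least one sample (default 10).
#' @param fc_threshold frequency fold-change threshold (default 1.5).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return data.frame of class `mt_clone_dynamics`: `clone_a`, `clone_b`,
#'   `n_a`, `n_b`, `freq_a`, `freq_b`, `fold_change`, `p`, `q`, `class`.
#' @export
clone_dynamics <- function(a, b, min_cells = 10L, fc_threshold = 1.5,
                           alpha = 0.05) {
  match_tab <- match_clones(a$profiles, b$profiles)
  tot_a <- length(a$labels); tot_b <- length(b$labels)
  eps <- 1e-4
  rows <- lapply(seq_len(nrow(match_tab)), function(i) {
    ca <- match_tab$clone_a[i]; cb <- match_tab$clone_b[i]
    na <- if (is.na(ca)) 0L else sum(a$labels == ca)
    nb <- if (is.na(cb)) 0L else sum(b$labels == cb)
    fa <- na / tot_a; fb <- nb / tot_b
    fc <- (fb + eps) / (fa + eps)
    p <- if (!is.na(ca) && !is.na(cb) && (na >= min_cells || nb >= min_cells)) {
      clone_fisher_p(na, tot_a, nb, tot_b)
    } else {
      NA_real_
    }
    data.frame(clone_a = ca, clone_b = cb, n_a = na, n_b = nb,
               freq_a = fa, freq_b = fb, fold_change = fc, p = p)
  })
  out <- do.call(rbind, rows)
  testable <- !is.na(out$p)
  out$q <- NA_real_
  out$q[testable] <- p.adjust(out$p[testable], method = "BH")
  out$class <- ifelse(!testable, "not_testable",
                      ifelse(out$q <= alpha &
                               (out$fold_change >= fc_threshold |
                                  out$fold_change <= 1 / fc_threshold),
                             "dynamic", "stable"))
  class(out) <- c("mt_clone_dynamics", "data.frame")
  out
}

#' Two-sided Fisher exact p-value for a clone frequency change
#'
#' Tests the 2x2 table (clone cells, other cells) x (sample A, sample B).
#'
#' @param n_a,n_b clone cell counts in samples A and B.
#' @param total_a,total_b total cell counts in samples A and B.
#' @return two-sided exact p-value.
#' @export
clone_fisher_p <- function(n_a, total_a, n_b, total_b) {
  stopifnot(n_a <= total_a, n_b <= total_b)
  fisher.test(matrix(c(n_a, total_a - n_a, n_b, total_b - n_b), 2))$p.value
}

# Greedy best-first clone matching on cosine similarity of sqrt profiles.
# Background label "0" is excluded; unmatched clones get NA partners.
match_clones <- function(prof_a, prof_b) {
  ca <- setdiff(rownames(prof_a), "0")
  cb <- setdiff(rownames(prof_b), "0")
  shared <- intersect(colnames(prof_a), colnames(prof_b))
  pairs <- data.frame(clone_a = integer(), clone_b = integer())
  if (length(ca) && length(cb) && length(shared)) {
    A <- sqrt(prof_a[ca, shared, drop = FALSE]); A[is.na(A)] <- 0
    B <- sqrt(prof_b[cb, shared, drop = FALSE]); B[is.na(B)] <- 0
    An <- A / pmax(sqrt(rowSums(A^2)), 1e-12)
    Bn <- B / pmax(sqrt(rowSums(B^2)), 1e-12)
    S <- tcrossprod(An, Bn)
    cand <- expand.grid(i = seq_along(ca), j = seq_along(cb))
    cand$sim <- S[cbind(cand$i, cand$j)]
    cand <- cand[order(-cand$sim, as.integer(ca[cand$i]),
                       as.integer(cb[cand$j])), , drop = FALSE]
    used_a <- used_b <- logical(0)
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (ca[i] %in% names(used_a) || cb[j] %in% names(used_b)) next
      pairs <- rbind(pairs, data.frame(clone_a = as.integer(ca[i]),
                                       clone_b = as.integer(cb[j])))
      used_a[ca[i]] <- TRUE; used_b[cb[j]] <- TRUE
    }
  }
  un_a <- setdiff(as.integer(ca), pairs$clone_a)
  un_b <- setdiff(as.integer(cb), pairs$clone_b)
  if (length(un_a)) pairs <- rbind(pairs, data.frame(clone_a = un_a,
                                                     clone_b = NA_integer_))
  if (length(un_b)) pairs <- rbind(pairs, data.frame(clone_a = NA_integer_,
                                                     clone_b = un_b))
  pairs
}

#' Per-sample subclone count and size distribution
#'
#' @param assignments named list of `mt_clones` objects or clone label
#'   vectors (one per sample).
#' @return data.frame: `sample`, `n_cells`, `n_subclones` (background label 0
#'   excluded), `gini` and `entropy`/`normalized_entropy` of clone sizes.
#' @export
subclone_summary <- function(assignments) {
  if (inherits(assignments, "mt_clones")) {
    assignments <- list(sample = assignments)
  }
  rows <- lapply(names(assignments), function(nm) {
    a <- assignments[[nm]]
    labels <- if (inherits(a, "mt_clones")) a$labels else a
    sizes <- table(labels[labels != 0L])
    p <- as.numeric(sizes) / sum(sizes)
    ent <- if (length(p)) -sum(p * log(p)) else 0
    data.frame(sample = nm, n_cells = length(labels),
               n_subclones = length(sizes),
               gini = gini_coefficient(as.numeric(sizes)),
               entropy = ent,
               normalized_entropy = if (length(p) > 1) ent / log(length(p)) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

gini_coefficient <- function(x) {
  if (!length(x) || sum(x) == 0) return(0)
  x <- sort(x)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
}
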