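#' Neighbor-joining tree of clones or cells
#'
#' Builds an unrooted tree from heteroplasmy profiles with the Saitou-Nei
#' neighbor-joining algorithm. The default distance is Euclidean on
#' square-root heteroplasmy of the mean profiles. Neighbor joining recovers
#' additive distance matrices exactly; negative branch-length estimates
#' (possible on non-additive input) are clamped to 0 with the deficit
#' donated to the sibling edge so the total tree length is preserved, and
#' the adjustment is recorded in the `clamped` attribute.
#'
#' @param profiles numeric matrix (rows = clones or cells, columns =
#'   variants) of mean heteroplasmies, or a `dist` object / symmetric
#'   distance matrix used as-is.
#' @param transform transformation applied to profiles before the Euclidean
#'   distance (default `sqrt`; use `identity` for raw values).
#' @param max_leaves per-cell trees are subsampled to at most this many rows
#'   (default 500), seeded.
#' @param seed seed for the subsampling.
#' @return An [ape::phylo] tree (class `phylo`), serializable with
#'   [ape::write.tree()].
#' @export
nj_tree <- function(profiles, transform = sqrt, max_leaves = 500L,
                    seed = 1L) {
  if (inherits(profiles, "dist")) {
    d <- profiles
  } else if (is.matrix(profiles) && isSymmetric(unname(profiles)) &&
             nrow(profiles) == ncol(profiles) &&
             all(abs(diag(profiles)) < 1e-12)) {
    d <- stats::as.dist(profiles)
  } else {
    profiles <- as.matrix(profiles)
    if (nrow(profiles) > max_leaves) {
      keep <- with_seed(seed, sort(sample.int(nrow(profiles), max_leaves)))
      profiles <- profiles[keep, , drop = FALSE]
    }
    X <- transform(profiles)
    X[is.na(X)] <- 0
    d <- dist(X)
  }
  dm <- as.matrix(d)
  if (anyNA(dm)) {
    bad <- which(is.na(dm), arr.ind = TRUE)[1, ]
    stop("NaN distance between '", rownames(dm)[bad[1]], "' and '",
         colnames(dm)[bad[2]], "'")
  }
  n <- attr(d, "Size")
  if (n < 2) stop("need at least 2 profiles")
  labels <- attr(d, "Labels") %||% as.character(seq_len(n))
  if (n == 2) {
    tree <- structure(list(
      edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
      edge.length = rep(dm[1, 2] / 2, 2),
      tip.label = labels, Nnode = 1L), class = "phylo")
    return(tree)
  }
  tree <- ape::nj(d)
  clamp_negative_branches(tree)
}

# Clamp negative NJ branch estimates to 0, donating the deficit to the
# sibling edge (the other edge sharing the parent node).
clamp_negative_branches <- function(tree) {
  clamped <- 0L
  repeat {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[which.min(tree$edge.length[neg])]
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sibs)) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
    }
    clamped <- clamped + 1L
    if (clamped > length(tree$edge.length)) break
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- clamped
  tree
}

#' Summarize a B cell receptor repertoire
#'
#' Per sample: the dominant (largest) heavy-chain clonotype and its
#' frequency, the polyclonal fraction (cells outside the dominant
#' clonotype's lineage), clonotype richness and the clone-size spectrum.
#' Cells without a clonotype (`NA`) are excluded from denominators.
#'
#' @param repertoire data.frame with columns `cell_id`, `clone_id` and
#'   optionally `sample` (single sample assumed otherwise).
#' @return data.frame of class `mt_repertoire_summary`: `sample`, `n_cells`,
#'   `n_clonotypes`, `dominant_clonotype`, `dominant_freq`,
#'   `polyclonal_fraction`; clone-size tables in the `spectrum` attribute.
#' @export
repertoire_summary <- function(repertoire) {
  stopifnot(all(c("cell_id", "clone_id") %in% names(repertoire)))
  if (is.null(repertoire$sample)) repertoire$sample <- "sample"
  spectra <- list()
  rows <- lapply(unique(repertoire$sample), function(s) {
    r <- repertoire[repertoire$sample == s & !is.na(repertoire$clone_id), ,
                    drop = FALSE]
    sizes <- sort(table(r$clone_id), decreasing = TRUE)
    spectra[[s]] <<- sizes
    dom <- names(sizes)[1]
    data.frame(sample = s, n_cells = nrow(r), n_clonotypes = length(sizes),
               dominant_clonotype = dom,
               dominant_freq = as.numeric(sizes[1]) / nrow(r),
               polyclonal_fraction = 1 - as.numeric(sizes[1]) / nrow(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "spectrum") <- spectra
  class(out) <- c("mt_repertoire_summary", "data.frame")
  out
}

#' Concordance between mtDNA clones and BCR clonotypes
#'
#' Cross-tabulates the two partitions over their shared cell universe and
#' reports the adjusted Rand index, the majority BCR clonotype and purity of
#' each mtDNA clone, and a long-format flow table ready for alluvial
#' plotting. High concordance means the mtDNA clonal structure recapitulates
#' the B cell receptor lineage, validating mtDNA mutations as lineage
#' barcodes.
#'
#' @param mt an `mt_clones` object or named label vector (names = cells).
#' @param bcr data.frame with `cell_id`, `clone_id`.
#' @return Object of class `mt_concordance`: `table` (contingency), `ari`,
#'   `purity` data.frame (`mt_clone`, `n`, `majority_bcr`, `purity`),
#'   `flows` (long format: `mt_clone`, `bcr_clone`, `n`), `n_cells`.
#' @export
clone_concordance <- function(mt, bcr) {
  labels <- if (inherits(mt, "mt_clones")) mt$labels else mt
  stopifnot(!is.null(names(labels)),
            all(c("cell_id", "clone_id") %in% names(bcr)))
  shared <- intersect(names(labels), bcr$cell_id[!is.na(bcr$clone_id)])
  if (!length(shared)) stop("no shared cells between mtDNA and BCR tables")
  ml <- labels[shared]
  bl <- setNames(bcr$clone_id, bcr$cell_id)[shared]
  tab <- table(mt_clone = ml, bcr_clone = bl)
  flows <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(flows) <- c("mt_clone", "bcr_clone", "n")
  flows <- flows[flows$n > 0, , drop = FALSE]
  rownames(flows) <- NULL
  purity <- do.call(rbind, lapply(rownames(tab), function(cl) {
    counts <- tab[cl, ]
    data.frame(mt_clone = cl, n = sum(counts),
               majority_bcr = names(counts)[which.max(counts)],
               purity = max(counts) / sum(counts),
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, ari = adjusted_rand_index(ml, bl),
                 purity = purity, flows = flows, n_cells = length(shared)),
            class = "mt_concordance")
}

#' @export
print.mt_concordance <- function(x, ...) {
  cat(sprintf("<mt_concordance> %d shared cells, ARI = %.3f\n",
              x$n_cells, x$ari))
  print(x$purity, digits = 3, row.names = FALSE)
  invisible(x)
}
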