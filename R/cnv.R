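#' Overlapping genome bins
#'
#' Tiles each contig with overlapping windows (default 10 Mb, step 2 Mb;
#' 0-based half-open coordinates). Terminal bins shorter than `bin_size` are
#' kept and flagged `short`; their counts are length-normalized downstream.
#'
#' @param genome named numeric vector of contig sizes (bp), or path to a
#'   `chrom.sizes` file.
#' @param bin_size window size in bp (default 10 Mb).
#' @param step step size in bp (default 2 Mb).
#' @return data.frame: `chrom`, `start`, `end`, `length`, `short`.
#' @export
make_bins <- function(genome, bin_size = 1e7, step = 2e6) {
  if (is.character(genome) && length(genome) == 1) {
    genome <- read_chrom_sizes(genome)
  }
  stopifnot(!is.null(names(genome)), all(genome > 0), step > 0,
            bin_size >= step)
  out <- lapply(names(genome), function(chrom) {
    size <- genome[[chrom]]
    starts <- seq(0, size - 1, by = step)
    ends <- pmin(starts + bin_size, size)
    data.frame(chrom = chrom, start = starts, end = ends,
               length = ends - starts, short = (ends - starts) < bin_size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Count fragments per cell in overlapping genome bins
#'
#' Each fragment is assigned by its midpoint and counted once in every bin
#' covering that midpoint (with overlapping bins a fragment lands in up to
#' `bin_size/step` bins); midpoint assignment keeps the contribution of a
#' fragment independent of its length. Fragments on contigs absent from the
#' bin set are skipped and tallied.
#'
#' @param fragments BED-like data.frame (`chrom`, `start`, `end`, `barcode`,
#'   optional `count`; 0-based half-open) or path to a fragments.tsv file.
#' @param bins data.frame from [make_bins()].
#' @param barcodes optional character vector fixing the cell universe
#'   (default: barcodes present in the fragment set).
#' @return Object of class `genome_bin_matrix`: `bins`, `counts` (sparse
#'   cells x bins matrix), `cell_depth` (total fragments per cell),
#'   `n_skipped` (fragments on unknown contigs).
#' @export
bin_fragments <- function(fragments, bins, barcodes = NULL) {
  if (is.character(fragments) && length(fragments) == 1) {
    fragments <- read_fragments(fragments)
  }
  stopifnot(all(c("chrom", "start", "end", "barcode") %in% names(fragments)))
  cnt <- fragments$count %||% rep(1L, nrow(fragments))
  if (is.null(barcodes)) barcodes <- sort(unique(fragments$barcode))
  step <- if (nrow(bins) > 1) {
    d <- diff(bins$start[bins$chrom == bins$chrom[1]])
    if (length(d)) d[1] else bins$length[1]
  } else {
    bins$length[1]
  }
  bin_size <- max(bins$length)
  max_cover <- ceiling(bin_size / step)

  cell_idx <- match(fragments$barcode, barcodes)
  known_chrom <- fragments$chrom %in% bins$chrom
  keep <- known_chrom & !is.na(cell_idx)
  n_skipped <- sum(!known_chrom)

  mid <- floor((fragments$start + fragments$end) / 2)
  # per-chrom offsets into the global bin index and bin counts
  chroms <- unique(bins$chrom)
  first_bin <- match(chroms, bins$chrom)
  n_bins_chrom <- as.integer(table(factor(bins$chrom, levels = chroms)))
  names(first_bin) <- names(n_bins_chrom) <- chroms

  ci <- cell_idx[keep]
  mi <- mid[keep]
  chi <- match(fragments$chrom[keep], chroms)
  wt <- cnt[keep]
  n_cells <- length(barcodes)
  acc <- numeric(n_cells * nrow(bins))
  j0 <- floor(mi / step)
  nb <- n_bins_chrom[chi]
  fb <- first_bin[chi]
  for (o in seq_len(max_cover) - 1L) {
    j_local <- j0 - o
    ok <- j_local >= 0 & j_local < nb
    if ((o + 1) * step > bin_size) {
      ok <- ok & (mi - j_local * step < bin_size)
    }
    # terminal short bins: midpoint must fall before the bin end
    jg <- fb[ok] + j_local[ok]
    inside <- mi[ok] < bins$end[jg]
    code <- (jg[inside] - 1) * n_cells + ci[ok][inside]
    w <- wt[ok][inside]
    if (all(w == 1L)) {
      hits <- tabulate(code, nbins = length(acc))
      acc <- acc + hits
    } else {
      agg <- rowsum(w, code)
      acc[as.numeric(rownames(agg))] <- acc[as.numeric(rownames(agg))] + agg
    }
  }
  counts <- Matrix::Matrix(matrix(acc, n_cells, nrow(bins),
                                  dimnames = list(barcodes, NULL)),
                           sparse = TRUE)
  depth <- numeric(length(barcodes))
  agg <- rowsum(wt, ci)
  depth[as.integer(rownames(agg))] <- agg
  structure(list(bins = bins, counts = counts,
                 cell_depth = setNames(depth, barcodes),
                 n_skipped = n_skipped),
            class = "genome_bin_matrix")
}

#' @export
print.genome_bin_matrix <- function(x, ...) {
  cat(sprintf("<genome_bin_matrix> %d cells x %d bins on %d contig(s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$bins$chrom))))
  invisible(x)
}

#' Copy-number deviation of a target population from a reference
#'
#' After scaling every cell's bin counts to a common sequencing depth (the
#' cohort median total fragments) and length-normalizing short terminal
#' bins, computes per-bin reference mean and SD of normalized counts and a
#' standardized deviation of the target population mean:
#' `z = (mean(target) - mu_ref) / (sd_ref * sqrt(1/n_target + 1/n_ref))`
#' (the two-sample standard error; both population means are estimates, and
#' omitting the reference term inflates null z-scores). Because
#' per-cell depth scaling couples a large planted event to every other bin
#' (a gained contig depresses all other bins after total-depth
#' normalization), the z vector is median-centered across bins by default.
#' Segments are maximal runs of at least `min_bins` consecutive bins on a
#' contig with `|z| >= z_threshold` and consistent sign.
#'
#' @param binmat a [bin_fragments()] result.
#' @param target_cells,reference_cells barcode vectors selecting the two
#'   populations (reference: e.g. T cells, assumed copy-neutral).
#' @param min_ref_cells minimum reference population size (default 50).
#' @param z_threshold per-bin deviation threshold (default 3).
#' @param min_bins minimum run length for a segment call (default 5).
#' @param center median-center the z vector across bins (default `TRUE`).
#' @param per_cell also return the per-cell z matrix for the target cells.
#' @return Object of class `cnv_profile`: `z` (per-bin data.frame with
#'   `chrom`, `start`, `end`, `z`, `masked`), `segments` (`chrom`, `start`,
#'   `end`, `direction`, `mean_z`, `n_bins`), optionally `cell_z`, `params`.
#' @export
cnv_deviation <- function(binmat, target_cells, reference_cells,
                          min_ref_cells = 50L, z_threshold = 3,
                          min_bins = 5L, center = TRUE, per_cell = FALSE) {
  stopifnot(inherits(binmat, "genome_bin_matrix"))
  barcodes <- rownames(binmat$counts)
  ti <- match(target_cells, barcodes)
  ri <- match(reference_cells, barcodes)
  if (anyNA(ti) || anyNA(ri)) stop("unknown cell barcodes")
  if (length(ri) < min_ref_cells) {
    stop("reference population below min_ref_cells (", length(ri), " < ",
         min_ref_cells, ")")
  }
  depth <- binmat$cell_depth[c(ti, ri)]
  sf <- median(depth) / pmax(binmat$cell_depth, 1)
  norm <- binmat$counts * sf  # row scaling
  len_factor <- max(binmat$bins$length) / binmat$bins$length
  norm <- t(t(as.matrix(norm)) * len_factor)

  mu <- colMeans(norm[ri, , drop = FALSE])
  sdev <- apply(norm[ri, , drop = FALSE], 2, sd)
  masked <- sdev == 0
  mt <- colMeans(norm[ti, , drop = FALSE])
  z <- (mt - mu) / (sdev * sqrt(1 / length(ti) + 1 / length(ri)))
  z[masked] <- NA_real_
  if (center) z <- z - median(z, na.rm = TRUE)

  zdf <- data.frame(binmat$bins[, c("chrom", "start", "end")], z = z,
                    masked = masked)
  segments <- call_segments(zdf, z_threshold, min_bins)
  out <- list(z = zdf, segments = segments,
              params = list(z_threshold = z_threshold, min_bins = min_bins,
                            center = center, n_target = length(ti),
                            n_reference = length(ri)))
  if (per_cell) {
    cz <- sweep(sweep(norm[ti, , drop = FALSE], 2, mu), 2, sdev, "/")
    cz[, masked] <- NA_real_
    out$cell_z <- cz
  }
  structure(out, class = "cnv_profile")
}

# Maximal runs of consecutive same-sign bins with |z| >= threshold.
call_segments <- function(zdf, z_threshold, min_bins) {
  state <- ifelse(is.na(zdf$z) | abs(zdf$z) < z_threshold, 0,
                  sign(zdf$z))
  key <- paste(zdf$chrom, state)
  runs <- rle(key)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  segs <- list()
  for (r in seq_along(runs$lengths)) {
    i1 <- starts[r]; i2 <- ends[r]
    if (state[i1] == 0 || runs$lengths[r] < min_bins) next
    segs[[length(segs) + 1]] <- data.frame(
      chrom = zdf$chrom[i1], start = zdf$start[i1], end = zdf$end[i2],
      direction = if (state[i1] > 0) "gain" else "loss",
      mean_z = mean(zdf$z[i1:i2]), n_bins = i2 - i1 + 1L,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, segs) %||%
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               direction = character(), mean_z = numeric(),
               n_bins = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat(sprintf("<cnv_profile> %d bins (%d masked), %d segment(s)\n",
              nrow(x$z), sum(x$z$masked), nrow(x$segments)))
  if (nrow(x$segments)) print(x$segments, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
plot.cnv_profile <- function(x, ...) {
  chrom_f <- factor(x$z$chrom, levels = unique(x$z$chrom))
  idx <- seq_len(nrow(x$z))
  plot(idx, x$z$z, col = as.integer(chrom_f), pch = 16, cex = 0.5,
       xlab = "bin", ylab = "deviation z", ...)
  graphics::abline(h = c(-x$params$z_threshold, x$params$z_threshold),
                   lty = 2, col = "grey40")
  invisible(x)
}
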