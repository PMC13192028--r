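#' Simulate a ground-truthed single-cell mtDNA population
#'
#' Generates a per-cell, per-position, per-base, per-strand mtDNA read-count
#' tensor together with the underlying truth, a B cell receptor clonotype
#' table and (if `fragment_depth > 0`) a chromatin fragment set. The noise
#' model follows the genetics of mitochondrial lineage tracing: every marker
#' mutation has a clone-specific founding heteroplasmy `h`; each cell of the
#' clone draws a latent heteroplasmy from Beta(h*c, (1-h)*c) (stochastic
#' segregation during cell division); position coverage is negative binomial;
#' alternate reads are binomial in the latent heteroplasmy; genuine alternate
#' reads split evenly across strands while artifact variants split with
#' probability `strand_bias_artifact`. Germline variants are near-fixed in
#' every cell. Nuclear fragments are Poisson per copy-number segment with
#' rate proportional to segment length times copy/2; BCR clonotypes follow
#' the mtDNA clone for clonal cells and are unique singletons for the
#' polyclonal background.
#'
#' @param config a [sim_config()].
#' @return A list of class `mt_simulation` with elements `tensor`
#'   ([mt_tensor()]), `truth` (cell labels, variant table, CNVs, BCR truth),
#'   `bcr` (AIRR-style data.frame: `cell_id`, `clone_id`, `junction_aa`) and
#'   `fragments` (BED-like data.frame or `NULL`).
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, {
    params <- build_truth_params(config)
    sim_sample(params, config, prefix = "cell")
  })
}

#' Simulate two timepoints of the same clonal population
#'
#' Sample B is regenerated from the same clone structure (same variants,
#' same founding heteroplasmies) with cells drawn independently; only the
#' variants listed in `config$injected_shifts` have their founding
#' heteroplasmy multiplied (clipped to 0.95) in sample B. With no injected
#' shifts the two samples are exchangeable, giving a global null for shift
#' tests.
#'
#' @param config a [sim_config()]; `injected_shifts` entries are lists with
#'   `variant` (marker index or variant id) and `multiplier`.
#' @return list with elements `A`, `B` (each an `mt_simulation`) and `truth`
#'   (the shared variant/clone parameters plus the shift descriptors).
#' @export
simulate_paired_timepoints <- function(config) {
  validate_sim_config(config)
  seeds <- derive_seeds(config$seed, 3L)
  params <- with_seed(seeds[1], build_truth_params(config))
  params_b <- apply_shifts(params, config$injected_shifts)
  a <- with_seed(seeds[2], sim_sample(params, config, prefix = "A"))
  b <- with_seed(seeds[3], sim_sample(params_b, config, prefix = "B"))
  list(A = a, B = b,
       truth = list(variants = params$variants,
                    shifted = params_b$variants$shifted,
                    clone_prob = params$clone_prob))
}

# Clone- and variant-level generating parameters (consumes RNG).
build_truth_params <- function(config) {
  n_mark <- config$n_clones * config$markers_per_clone
  if (is.null(config$positions)) {
    pos <- sample.int(MT_GENOME_LENGTH,
                      n_mark + config$n_germline_variants +
                        config$n_artifact_variants)
    positions <- list(
      marker = pos[seq_len(n_mark)],
      germline = pos[n_mark + seq_len(config$n_germline_variants)],
      artifact = pos[n_mark + config$n_germline_variants +
                       seq_len(config$n_artifact_variants)]
    )
  } else {
    positions <- config$positions
    stopifnot(length(positions$marker %||% integer()) == n_mark)
  }
  all_pos <- c(positions$marker, positions$germline, positions$artifact)
  n_var <- length(all_pos)
  ref <- sample(BASES, n_var, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), "")
  class <- rep(c("marker", "germline", "artifact"),
               c(length(positions$marker %||% integer()),
                 length(positions$germline %||% integer()),
                 length(positions$artifact %||% integer())))
  clone <- rep(NA_integer_, n_var)
  if (n_mark > 0) clone[class == "marker"] <- rep(seq_len(config$n_clones),
                                                  each = config$markers_per_clone)
  h <- numeric(n_var)
  h[class == "marker"] <- runif(n_mark, config$founding_heteroplasmy_range[1],
                                config$founding_heteroplasmy_range[2])
  h[class == "germline"] <- config$germline_heteroplasmy
  h[class == "artifact"] <- config$artifact_heteroplasmy
  variants <- data.frame(
    id = format_variant_id(all_pos, ref, alt),
    pos = as.integer(all_pos), ref = ref, alt = alt,
    class = class, clone = clone, founding_h = h,
    shifted = FALSE,
    stringsAsFactors = FALSE
  )
  variants <- variants[order(variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  clone_prob <- if (config$n_clones > 0) rep(1 / config$n_clones,
                                             config$n_clones) else numeric()
  list(variants = variants, clone_prob = clone_prob)
}

apply_shifts <- function(params, shifts) {
  v <- params$variants
  marker_idx <- which(v$class == "marker")
  for (s in shifts) {
    i <- if (is.character(s$variant)) {
      match(s$variant, v$id)
    } else {
      marker_idx[s$variant]
    }
    if (is.na(i) || length(i) != 1L) {
      stop("injected shift on unknown variant: ", s$variant)
    }
    v$founding_h[i] <- min(v$founding_h[i] * s$multiplier, 0.95)
    v$shifted[i] <- TRUE
  }
  params$variants <- v
  params
}

# Draw one sample of cells from fixed generating parameters (consumes RNG).
sim_sample <- function(params, config, prefix = "cell") {
  v <- params$variants
  n_cells <- config$n_cells
  n_var <- nrow(v)
  barcodes <- sprintf("%s%04d", prefix, seq_len(n_cells))

  n_poly <- rbinom(1, n_cells, config$polyclonal_fraction)
  clone_of <- integer(n_cells)  # 0 = polyclonal background
  mono <- if (n_cells > n_poly) sample.int(n_cells, n_cells - n_poly) else integer()
  if (length(mono) && config$n_clones > 0) {
    clone_of[mono] <- sample.int(config$n_clones, length(mono),
                                 replace = TRUE, prob = params$clone_prob)
  }

  # founding heteroplasmy per cell x variant
  H0 <- matrix(0, n_cells, n_var)
  for (j in seq_len(n_var)) {
    H0[, j] <- switch(v$class[j],
      marker = ifelse(clone_of == v$clone[j], v$founding_h[j], 0),
      germline = v$founding_h[j],
      artifact = v$founding_h[j]
    )
  }

  c0 <- config$dispersion_c
  P <- matrix(0, n_cells, n_var)
  nz <- which(H0 > 0)
  P[nz] <- rbeta(length(nz), H0[nz] * c0, (1 - H0[nz]) * c0)

  D <- matrix(rnbinom(n_cells * n_var, mu = config$mean_depth,
                      size = config$depth_dispersion), n_cells, n_var)
  ALT <- matrix(rbinom(n_cells * n_var, D, P), n_cells, n_var)
  split_p <- ifelse(v$class == "artifact", config$strand_bias_artifact, 0.5)
  ALT_plus <- matrix(rbinom(n_cells * n_var, ALT,
                            rep(split_p, each = n_cells)), n_cells, n_var)
  REF <- D - ALT
  REF_plus <- matrix(rbinom(n_cells * n_var, REF, 0.5), n_cells, n_var)

  counts <- array(0L, dim = c(n_cells, n_var, 4L, 2L))
  for (j in seq_len(n_var)) {
    ai <- match(v$alt[j], BASES)
    ri <- match(v$ref[j], BASES)
    counts[, j, ai, 1L] <- ALT_plus[, j]
    counts[, j, ai, 2L] <- ALT[, j] - ALT_plus[, j]
    counts[, j, ri, 1L] <- REF_plus[, j]
    counts[, j, ri, 2L] <- REF[, j] - REF_plus[, j]
  }
  tensor <- mt_tensor(counts, barcodes, v$pos, v$ref)

  bcr_clone <- ifelse(clone_of > 0, sprintf("IGH.clone%02d", clone_of),
                      sprintf("IGH.%s", barcodes))
  junctions <- sim_junctions(unique(bcr_clone))
  bcr <- data.frame(cell_id = barcodes, clone_id = bcr_clone,
                    junction_aa = junctions[bcr_clone],
                    stringsAsFactors = FALSE)

  fragments <- if (config$fragment_depth > 0) {
    sim_fragments(barcodes, config)
  } else {
    NULL
  }

  truth <- list(
    cell_clone = setNames(clone_of, barcodes),
    variants = v,
    latent_heteroplasmy = {
      L <- P
      dimnames(L) <- list(barcodes, v$id); L
    },
    planted_cnvs = config$planted_cnvs,
    cell_bcr = setNames(bcr_clone, barcodes)
  )
  structure(list(tensor = tensor, truth = truth, bcr = bcr,
                 fragments = fragments, config = config),
            class = "mt_simulation")
}

# Short CDR3-like amino-acid strings, one per clonotype.
sim_junctions <- function(clonotypes) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  setNames(vapply(seq_along(clonotypes), function(i) {
    paste0("CAR", paste(sample(aa, 9, replace = TRUE), collapse = ""), "W")
  }, ""), clonotypes)
}

# Chromatin fragments: Poisson per copy-number segment, uniform placement.
sim_fragments <- function(barcodes, config) {
  segs <- cnv_segment_table(config$genome, config$planted_cnvs)
  lambda <- config$fragment_depth * (segs$len / sum(config$genome)) *
    segs$copy / 2
  n_cells <- length(barcodes)
  counts <- matrix(rpois(n_cells * nrow(segs), rep(lambda, each = n_cells)),
                   n_cells, nrow(segs))
  total <- sum(counts)
  cell_idx <- rep(rep(seq_len(n_cells), nrow(segs)), as.vector(counts))
  seg_idx <- rep(rep(seq_len(nrow(segs)), each = n_cells), as.vector(counts))
  size <- config$fragment_size
  start <- segs$start[seg_idx] +
    floor(runif(total) * pmax(segs$len[seg_idx] - size, 1))
  frags <- data.frame(
    chrom = segs$chrom[seg_idx],
    start = as.numeric(start),
    end = as.numeric(start + size),
    barcode = barcodes[cell_idx],
    count = 1L,
    stringsAsFactors = FALSE
  )
  ord <- order(match(frags$chrom, names(config$genome)), frags$start)
  frags <- frags[ord, , drop = FALSE]
  rownames(frags) <- NULL
  frags
}

# Partition the genome into copy-number segments (0-based half-open).
cnv_segment_table <- function(genome, planted_cnvs) {
  out <- list()
  for (chrom in names(genome)) {
    size <- genome[[chrom]]
    ev <- if (is.null(planted_cnvs)) NULL else
      planted_cnvs[planted_cnvs$chrom == chrom, , drop = FALSE]
    cuts <- sort(unique(c(0, size, ev$start, pmin(ev$end, size))))
    for (i in seq_len(length(cuts) - 1)) {
      s <- cuts[i]; e <- cuts[i + 1]
      copy <- 2
      if (!is.null(ev) && nrow(ev)) {
        hit <- which(ev$start <= s & ev$end >= e)
        if (length(hit)) copy <- ev$copy[hit[1]]
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = s, end = e, len = e - s, copy = copy,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
print.mt_simulation <- function(x, ...) {
  tr <- x$truth
  cat(sprintf(
    "<mt_simulation> %d cells, %d variants (%d marker / %d germline / %d artifact), %d clones\n",
    length(tr$cell_clone), nrow(tr$variants),
    sum(tr$variants$class == "marker"), sum(tr$variants$class == "germline"),
    sum(tr$variants$class == "artifact"),
    length(setdiff(unique(tr$cell_clone), 0L))))
  if (!is.null(x$fragments)) {
    cat(sprintf("  fragments: %s records\n",
                format(nrow(x$fragments), big.mark = ",")))
  }
  invisible(x)
}
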