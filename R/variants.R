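#' Per-cell heteroplasmy matrix
#'
#' Heteroplasmy of a variant in a cell is the fraction of that cell's reads
#' at the variant position supporting the alternate allele, with both strands
#' summed: `(alt+ + alt-) / (total+ + total-)`. Entries are `NA` (missing,
#' not zero) when the position's total coverage in that cell is below
#' `min_coverage` — low coverage gives no usable estimate, and downstream
#' code treats absence of evidence differently from evidence of absence.
#'
#' @param tensor an [mt_tensor()].
#' @param variant_ids character vector of ids like `"7161G>A"`.
#' @param min_coverage minimum total reads at the position for a usable
#'   per-cell estimate (default 5).
#' @return numeric matrix, cells x variants, values in `[0,1]` or `NA`.
#' @export
compute_heteroplasmy <- function(tensor, variant_ids, min_coverage = 5L) {
  stopifnot(min_coverage >= 1L)
  v <- resolve_variants(tensor, variant_ids)
  cov <- tensor_coverage(tensor)
  het <- matrix(NA_real_, length(tensor$barcodes), nrow(v),
                dimnames = list(tensor$barcodes, v$id))
  for (k in seq_len(nrow(v))) {
    alt <- variant_alt_counts(tensor, v$pos[k], v$alt[k])
    tot <- cov[, v$col[k]]
    ok <- tot >= min_coverage
    het[ok, k] <- (alt[ok, 1] + alt[ok, 2]) / tot[ok]
  }
  het
}

#' Per-variant quality statistics
#'
#' For each variant: the number of cells in which it is detected (covered
#' cells with heteroplasmy at or above `detection_threshold`), the mean
#' per-cell heteroplasmy over covered cells, the variance-to-mean ratio (VMR)
#' of per-cell heteroplasmy (sample variance, n-1 denominator; 0 when the
#' mean is 0), and the strand concordance — the Pearson correlation between
#' per-cell plus- and minus-strand alternate read counts over covered,
#' detected cells. Genuine heteroplasmic variants show variable per-cell
#' heteroplasmy (high VMR) supported equally by both strands (high
#' concordance); sequencing artifacts concentrate on one strand.
#'
#' Concordance is undefined (`NA`, treated as failing) with fewer than two
#' detected cells or when either strand's counts are constant.
#'
#' @inheritParams compute_heteroplasmy
#' @param detection_threshold minimum per-cell heteroplasmy to call the
#'   variant detected in a cell (default 0.01).
#' @return data.frame of class `mt_variant_stats`, one row per variant:
#'   `id`, `n_cells_detected`, `mean_heteroplasmy`, `vmr`,
#'   `strand_concordance`.
#' @export
variant_statistics <- function(tensor, variant_ids,
                               detection_threshold = 0.01,
                               min_coverage = 5L) {
  v <- resolve_variants(tensor, variant_ids)
  het <- compute_heteroplasmy(tensor, variant_ids, min_coverage)
  out <- data.frame(id = v$id, n_cells_detected = NA_integer_,
                    mean_heteroplasmy = NA_real_, vmr = NA_real_,
                    strand_concordance = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(v))) {
    h <- het[, k]
    covered <- !is.na(h)
    hc <- h[covered]
    detected <- covered & !is.na(h) & h >= detection_threshold
    out$n_cells_detected[k] <- sum(detected)
    m <- if (length(hc)) mean(hc) else NA_real_
    out$mean_heteroplasmy[k] <- m
    out$vmr[k] <- if (!length(hc) || is.na(m) || m == 0) 0 else var(hc) / m
    if (sum(detected) >= 2) {
      alt <- variant_alt_counts(tensor, v$pos[k], v$alt[k])
      p <- alt[detected, 1]; q <- alt[detected, 2]
      if (sd(p) > 0 && sd(q) > 0) {
        out$strand_concordance[k] <- cor(p, q)
      }
    }
  }
  class(out) <- c("mt_variant_stats", "data.frame")
  out
}

#' Select high-confidence variants
#'
#' A variant passes when it is detected in more than `min_cells` cells, its
#' variance-to-mean ratio exceeds `vmr_threshold`, its strand concordance
#' exceeds `concordance_threshold`, it is not blacklisted, and it does not
#' appear homoplasmic (mean heteroplasmy at or above `homoplasmy_cutoff` in
#' every compartment) — homoplasmic germline variants carry no lineage
#' information and obscure subclone structure. Each failing condition is
#' recorded in `fail_reasons`.
#'
#' @param stats an `mt_variant_stats` data.frame from [variant_statistics()].
#' @param blacklist variant ids excluded outright (default the recurrent
#'   artifact `310T>C`).
#' @param min_cells detection must exceed this cell count (strict `>`,
#'   default 4).
#' @param vmr_threshold strict lower bound on VMR (default 0.01).
#' @param concordance_threshold strict lower bound on strand concordance
#'   (default 0.65).
#' @param homoplasmy_cutoff mean-heteroplasmy level above which a variant
#'   appears homoplasmic (default 0.9).
#' @param compartment_means optional variants x compartments matrix of mean
#'   heteroplasmies (rows matching `stats$id`); when supplied, the
#'   homoplasmy rule requires the cutoff to be exceeded in every compartment,
#'   otherwise `stats$mean_heteroplasmy` is used.
#' @return `stats` with added logical `pass` and character `fail_reasons`
#'   columns.
#' @export
filter_variants <- function(stats, blacklist = "310T>C",
                            min_cells = 4L, vmr_threshold = 0.01,
                            concordance_threshold = 0.65,
                            homoplasmy_cutoff = 0.9,
                            compartment_means = NULL) {
  reasons <- vector("list", nrow(stats))
  add <- function(i, r) reasons[[i]] <<- c(reasons[[i]], r)
  for (i in seq_len(nrow(stats))) {
    if (!isTRUE(stats$n_cells_detected[i] > min_cells)) add(i, "n_cells")
    if (!isTRUE(stats$vmr[i] > vmr_threshold)) add(i, "vmr")
    sc <- stats$strand_concordance[i]
    if (is.na(sc) || !(sc > concordance_threshold)) add(i, "strand_concordance")
    if (stats$id[i] %in% blacklist) add(i, "blacklist")
    homoplasmic <- if (!is.null(compartment_means)) {
      all(compartment_means[stats$id[i], ] >= homoplasmy_cutoff, na.rm = TRUE)
    } else {
      isTRUE(stats$mean_heteroplasmy[i] >= homoplasmy_cutoff)
    }
    if (homoplasmic) add(i, "homoplasmic")
  }
  stats$pass <- lengths(reasons) == 0
  stats$fail_reasons <- vapply(reasons, function(r) {
    paste(r, collapse = ",")
  }, "")
  stats
}

#' @export
print.mt_variant_stats <- function(x, ...) {
  cat(sprintf("<mt_variant_stats> %d variants", nrow(x)))
  if ("pass" %in% names(x)) cat(sprintf(" (%d pass)", sum(x$pass)))
  cat("\n")
  print.data.frame(head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Normalized mtDNA mutation burden per cell group
#'
#' Counts, per group (e.g. donor x cell type), the variants with mean
#' heteroplasmy above `min_mean_het` among a fixed-size downsample of the
#' group's cells, normalized by the group's mean per-cell mtDNA coverage
#' relative to the mean over all sampled cells. Downsampling to a common cell
#' number and depth normalization make burdens comparable across groups of
#' very different sizes and sequencing depths.
#'
#' @param het heteroplasmy matrix (cells x variants, `NA` = missing).
#' @param groups factor/character of group labels, one per cell (in
#'   `rownames(het)` order).
#' @param cell_coverage numeric mean mtDNA coverage per cell, same order.
#' @param n_downsample cells sampled (without replacement) per group; groups
#'   with fewer cells are skipped (default 100).
#' @param min_mean_het mean-heteroplasmy floor for counting a variant
#'   (default 0.01).
#' @param seed integer seed for the downsampling.
#' @return data.frame: `group`, `n_cells`, `n_variants`, `mean_coverage`,
#'   `burden` (depth-normalized variant count). Skipped groups are recorded
#'   in the `skipped` attribute.
#' @export
mutation_burden <- function(het, groups, cell_coverage, n_downsample = 100L,
                            min_mean_het = 0.01, seed = 1L) {
  stopifnot(nrow(het) == length(groups),
            length(cell_coverage) == length(groups))
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  skipped <- character()
  rows <- list()
  sampled_cov <- list()
  seeds <- derive_seeds(seed, length(lv))
  picks <- list()
  for (i in seq_along(lv)) {
    idx <- which(groups == lv[i])
    if (length(idx) < n_downsample) {
      skipped <- c(skipped, lv[i])
      next
    }
    picks[[lv[i]]] <- with_seed(seeds[i], sample(idx, n_downsample))
    sampled_cov[[lv[i]]] <- cell_coverage[picks[[lv[i]]]]
  }
  cohort_cov <- mean(unlist(sampled_cov))
  for (g in names(picks)) {
    idx <- picks[[g]]
    mh <- colMeans(het[idx, , drop = FALSE], na.rm = TRUE)
    n_var <- sum(mh > min_mean_het, na.rm = TRUE)
    gcov <- mean(sampled_cov[[g]])
    rows[[g]] <- data.frame(group = g, n_cells = length(idx),
                            n_variants = n_var, mean_coverage = gcov,
                            burden = n_var / (gcov / cohort_cov),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||% data.frame()
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Cross-donor recurrence of variants
#'
#' @param donor_variants named list, one character vector of passing variant
#'   ids per donor.
#' @return data.frame `variant`, `n_donors`, `recurrent`; attributes
#'   `n_variants_total` (donor-variant pairs counted once per donor) and
#'   `fraction_nonrecurrent`.
#' @export
recurrence_table <- function(donor_variants) {
  stopifnot(length(donor_variants) >= 1)
  per_donor <- lapply(donor_variants, unique)
  tab <- table(unlist(per_donor, use.names = FALSE))
  out <- data.frame(variant = names(tab), n_donors = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$recurrent <- out$n_donors > 1L
  out <- out[order(-out$n_donors, out$variant), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_variants_total") <- nrow(out)
  attr(out, "fraction_nonrecurrent") <- mean(!out$recurrent)
  out
}

#' Genotype cells from targeted amplicon counts
#'
#' Per-cell somatic genotype from targeted mutant/wildtype read counts: a
#' cell is only assigned with at least `min_reads` total reads at the locus;
#' it is called mutant when strictly more reads support the mutant allele,
#' wildtype otherwise (ties are wildtype).
#'
#' @param counts data.frame with columns `cell`, `n_mutant_reads`,
#'   `n_wildtype_reads`.
#' @param min_reads minimum total reads for an assignment (default 10).
#' @return `counts` with an added `call` column in
#'   `{"mutant","wildtype","unassigned"}`.
#' @export
genotype_cells <- function(counts, min_reads = 10L) {
  stopifnot(all(c("n_mutant_reads", "n_wildtype_reads") %in% names(counts)),
            all(counts$n_mutant_reads >= 0),
            all(counts$n_wildtype_reads >= 0))
  total <- counts$n_mutant_reads + counts$n_wildtype_reads
  counts$call <- ifelse(total < min_reads, "unassigned",
                        ifelse(counts$n_mutant_reads > counts$n_wildtype_reads,
                               "mutant", "wildtype"))
  counts
}
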