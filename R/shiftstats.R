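#' Mean-heteroplasmy shift screen between paired samples
#'
#' For each variant present in both samples, compares per-cell heteroplasmy
#' vectors with a two-sided Wilcoxon rank-sum test, Benjamini-Hochberg
#' corrected across all tested variants, and computes the fold change of
#' mean heteroplasmies (sample B over A, pseudocount 1e-4 on the means). A
#' variant is flagged `shifted_mean` when q <= `alpha` and the fold change
#' is at least `fc_threshold` in either direction — the significance filter
#' alone would flag tiny, biologically irrelevant shifts in well-powered
#' comparisons. Variants missing from either sample are `not_testable`.
#'
#' @param het_a,het_b heteroplasmy matrices (cells x variants, `NA` =
#'   missing) or named lists of per-variant heteroplasmy vectors.
#' @param fc_threshold fold-change threshold (default 1.5, applied
#'   symmetrically: >= 1.5 or <= 1/1.5).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return data.frame of class `mt_shift_results`: `id`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `fold_change`, `wilcoxon_p`, `wilcoxon_q`, `class`.
#' @export
mean_shift_screen <- function(het_a, het_b, fc_threshold = 1.5,
                              alpha = 0.05) {
  va <- het_columns(het_a); vb <- het_columns(het_b)
  ids <- union(names(va), names(vb))
  eps <- 1e-4
  rows <- lapply(ids, function(id) {
    a <- va[[id]]; b <- vb[[id]]
    na <- length(a); nb <- length(b)
    ma <- if (na) mean(a) else NA_real_
    mb <- if (nb) mean(b) else NA_real_
    fc <- (mb + eps) / (ma + eps)
    p <- if (na >= 1 && nb >= 1) {
      suppressWarnings(wilcox.test(a, b, exact = (na < 25 && nb < 25))$p.value)
    } else {
      NA_real_
    }
    data.frame(id = id, n_a = na, n_b = nb, mean_a = ma, mean_b = mb,
               fold_change = fc, wilcoxon_p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tested <- !is.na(out$wilcoxon_p)
  out$wilcoxon_q <- NA_real_
  out$wilcoxon_q[tested] <- p.adjust(out$wilcoxon_p[tested], method = "BH")
  out$class <- ifelse(!tested, "not_testable",
                      ifelse(out$wilcoxon_q <= alpha &
                               (out$fold_change >= fc_threshold |
                                  out$fold_change <= 1 / fc_threshold),
                             "shifted_mean", "stable"))
  class(out) <- c("mt_shift_results", "data.frame")
  out
}

#' Kolmogorov-Smirnov distribution-shift test between paired samples
#'
#' Heteroplasmy distributions can shift shape without moving the mean
#' (subclonal skewing), so each variant's per-cell heteroplasmy vectors are
#' compared with a two-sample Kolmogorov-Smirnov test (asymptotic p-values,
#' heteroplasmy vectors are heavily tied at 0), BH-corrected over the
#' testable variants only. Testability is gated on non-missing cell counts:
#' with `gate = "both"` (default, conservative) both samples need at least
#' `min_cells` cells; `gate = "any"` requires only one.
#'
#' @inheritParams mean_shift_screen
#' @param min_cells cell-count gate for KS testability (default 100).
#' @param gate `"both"` or `"any"` (which samples must meet `min_cells`).
#' @return data.frame of class `mt_shift_results`: `id`, `n_a`, `n_b`,
#'   `ks_D`, `ks_p`, `ks_q`, `testable_ks`, `class` (`shifted_distribution`
#'   when q <= `alpha`).
#' @export
ks_shift_test <- function(het_a, het_b, min_cells = 100L, alpha = 0.05,
                          gate = c("both", "any")) {
  gate <- match.arg(gate)
  va <- het_columns(het_a); vb <- het_columns(het_b)
  ids <- union(names(va), names(vb))
  rows <- lapply(ids, function(id) {
    a <- va[[id]]; b <- vb[[id]]
    na <- length(a); nb <- length(b)
    ok <- if (gate == "both") {
      na >= min_cells && nb >= min_cells
    } else {
      (na >= min_cells || nb >= min_cells) && na >= 1 && nb >= 1
    }
    if (ok) {
      kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
      data.frame(id = id, n_a = na, n_b = nb, ks_D = unname(kt$statistic),
                 ks_p = kt$p.value, testable_ks = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(id = id, n_a = na, n_b = nb, ks_D = NA_real_,
                 ks_p = NA_real_, testable_ks = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$ks_q <- NA_real_
  out$ks_q[out$testable_ks] <- p.adjust(out$ks_p[out$testable_ks],
                                        method = "BH")
  out$class <- ifelse(!out$testable_ks, "not_testable",
                      ifelse(out$ks_q <= alpha, "shifted_distribution",
                             "stable"))
  class(out) <- c("mt_shift_results", "data.frame")
  out
}

#' Combined mean- and distribution-shift classification
#'
#' Runs [mean_shift_screen()] and [ks_shift_test()] (each with its own BH
#' family: all tested variants for the mean screen, gated variants for KS)
#' and merges them into a single classification per variant:
#' `shifted_both`, `shifted_mean`, `shifted_distribution`, `stable`, or
#' `not_testable` (untestable by both screens).
#'
#' @inheritParams ks_shift_test
#' @param fc_threshold fold-change threshold for the mean screen.
#' @return data.frame of class `mt_shift_results` with all fields of both
#'   screens plus the combined `class`.
#' @export
shift_tests <- function(het_a, het_b, fc_threshold = 1.5, alpha = 0.05,
                        min_cells = 100L, gate = c("both", "any")) {
  ms <- mean_shift_screen(het_a, het_b, fc_threshold, alpha)
  ks <- ks_shift_test(het_a, het_b, min_cells, alpha, gate)
  names(ms)[names(ms) == "class"] <- "class_mean"
  names(ks)[names(ks) == "class"] <- "class_ks"
  out <- merge(ms, ks[, c("id", "ks_D", "ks_p", "ks_q", "testable_ks",
                          "class_ks")], by = "id", sort = FALSE)
  sm <- out$class_mean == "shifted_mean"
  sd_ <- out$class_ks == "shifted_distribution"
  out$class <- ifelse(out$class_mean == "not_testable" & !out$testable_ks,
                      "not_testable",
                      ifelse(sm & sd_, "shifted_both",
                             ifelse(sm, "shifted_mean",
                                    ifelse(sd_, "shifted_distribution",
                                           "stable"))))
  class(out) <- c("mt_shift_results", "data.frame")
  out
}

#' @export
print.mt_shift_results <- function(x, ...) {
  cat(sprintf("<mt_shift_results> %d variants\n", nrow(x)))
  print(table(x$class))
  invisible(x)
}

#' Quantile-quantile curve of two heteroplasmy distributions
#'
#' Pairs the empirical quantiles of two samples on a shared probability grid
#' (type-7 interpolation). A variant whose heteroplasmy skews toward higher
#' or lower values between samples shows up as a deviation from the x = y
#' line; the maximum vertical deviation is reported.
#'
#' @param a,b numeric vectors of per-cell heteroplasmies (each length >= 2).
#' @param n_quantiles number of grid points (default 100).
#' @return data.frame of class `mt_qq` with columns `prob`, `q_a`, `q_b`;
#'   attribute `max_deviation`.
#' @export
qq_curve <- function(a, b, n_quantiles = 100L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("qq_curve needs at least 2 non-missing values per sample")
  }
  probs <- seq(0, 1, length.out = n_quantiles)
  qa <- unname(quantile(a, probs, type = 7))
  qb <- unname(quantile(b, probs, type = 7))
  out <- data.frame(prob = probs, q_a = qa, q_b = qb)
  attr(out, "max_deviation") <- max(abs(qb - qa))
  class(out) <- c("mt_qq", "data.frame")
  out
}

#' @export
plot.mt_qq <- function(x, ...) {
  plot(x$q_a, x$q_b, xlab = "quantiles, sample A",
       ylab = "quantiles, sample B", pch = 16, cex = 0.6,
       xlim = c(0, max(x$q_a, x$q_b)), ylim = c(0, max(x$q_a, x$q_b)), ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  invisible(x)
}

#' Compartment enrichment of variants
#'
#' Classifies each variant as `enriched` in the monoclonal compartment,
#' `depleted`, or `shared` by comparing per-cell heteroplasmies between
#' physiologic and monoclonal cells (Wilcoxon rank-sum, BH across variants,
#' 1.5-fold-change threshold on means toward the monoclonal compartment).
#' Variants enriched in the expanded clone mark its outgrowth; shared
#' variants point to a common ancestor of both compartments. Variants with
#' fewer than `min_cells` covered cells in either compartment are reported
#' `shared` with `powered = FALSE`.
#'
#' @param het_physiologic,het_monoclonal heteroplasmy matrices or named
#'   lists of per-variant vectors for the two compartments.
#' @param fc_threshold fold-change threshold (default 1.5).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param min_cells minimum covered cells per compartment (default 10).
#' @return data.frame of class `mt_compartment`: `id`, `n_physiologic`,
#'   `n_monoclonal`, `fold_change` (monoclonal over physiologic),
#'   `wilcoxon_p`, `wilcoxon_q`, `powered`, `class`.
#' @export
compartment_enrichment <- function(het_physiologic, het_monoclonal,
                                   fc_threshold = 1.5, alpha = 0.05,
                                   min_cells = 10L) {
  vp <- het_columns(het_physiologic); vm <- het_columns(het_monoclonal)
  ids <- union(names(vp), names(vm))
  eps <- 1e-4
  rows <- lapply(ids, function(id) {
    p <- vp[[id]]; m <- vm[[id]]
    powered <- length(p) >= min_cells && length(m) >= min_cells
    mp <- if (length(p)) mean(p) else NA_real_
    mm <- if (length(m)) mean(m) else NA_real_
    fc <- (mm + eps) / (mp + eps)
    pv <- if (powered) {
      suppressWarnings(wilcox.test(p, m)$p.value)
    } else {
      NA_real_
    }
    data.frame(id = id, n_physiologic = length(p), n_monoclonal = length(m),
               fold_change = fc, wilcoxon_p = pv, powered = powered,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$wilcoxon_q <- NA_real_
  out$wilcoxon_q[out$powered] <- p.adjust(out$wilcoxon_p[out$powered],
                                          method = "BH")
  out$class <- "shared"
  sig <- out$powered & !is.na(out$wilcoxon_q) & out$wilcoxon_q <= alpha
  out$class[sig & out$fold_change >= fc_threshold] <- "enriched"
  out$class[sig & out$fold_change <= 1 / fc_threshold] <- "depleted"
  class(out) <- c("mt_compartment", "data.frame")
  out
}

# Normalize matrix / list input to a named list of non-missing vectors.
het_columns <- function(het) {
  if (is.matrix(het) || is.data.frame(het)) {
    het <- as.matrix(het)
    cols <- lapply(seq_len(ncol(het)), function(j) {
      x <- het[, j]
      x[!is.na(x)]
    })
    names(cols) <- colnames(het) %||% as.character(seq_len(ncol(het)))
    cols[lengths(cols) > 0]
  } else if (is.list(het)) {
    stopifnot(!is.null(names(het)))
    lapply(het, function(x) x[!is.na(x)])
  } else {
    stop("expected a matrix or a named list of heteroplasmy vectors")
  }
}
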