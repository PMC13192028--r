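#' Configuration for the synthetic single-cell mtDNA generator
#'
#' Collects and validates every parameter of the simulator. Defaults emulate a
#' (pre)malignant B cell sample profiled with mitochondrial single-cell ATAC:
#' a handful of expanded clones carrying private marker mutations at
#' intermediate founding heteroplasmy, a polyclonal background, near-fixed
#' germline variants, strand-biased artifacts, highly dispersed per-cell
#' mtDNA coverage, and (optionally) nuclear chromatin fragments with planted
#' copy-number events plus clone-linked B cell receptor labels.
#'
#' @param n_cells number of cells.
#' @param n_clones number of expanded clones carrying marker mutations.
#' @param polyclonal_fraction fraction of cells in the polyclonal background
#'   (no marker mutations, singleton BCR clonotypes).
#' @param markers_per_clone marker mtDNA mutations private to each clone.
#' @param founding_heteroplasmy_range range (in (0,1)) from which each
#'   marker's founding heteroplasmy is drawn uniformly.
#' @param dispersion_c beta concentration for per-cell heteroplasmy around the
#'   founding value; models stochastic mitochondrial segregation. A cell's
#'   latent heteroplasmy is Beta(h*c, (1-h)*c), so larger `c` means tighter
#'   clustering around the founding value `h`.
#' @param n_germline_variants homoplasmic-appearing germline variants
#'   (heteroplasmy ~ 1 in every cell).
#' @param n_artifact_variants strand-biased artifact variants present at low
#'   heteroplasmy in all cells.
#' @param artifact_heteroplasmy baseline heteroplasmy of artifact variants.
#' @param germline_heteroplasmy founding heteroplasmy of germline variants.
#' @param mean_depth mean per-cell read depth at each stored position.
#' @param depth_dispersion negative-binomial size parameter of the depth
#'   distribution (smaller = more dispersed coverage).
#' @param strand_bias_artifact probability an artifact alternate read maps to
#'   the plus strand (genuine variants use 0.5).
#' @param injected_shifts list of `list(variant = <index or id>,
#'   multiplier = <x>)` applied to founding heteroplasmies of the second
#'   timepoint in [simulate_paired_timepoints()]. Indices refer to marker
#'   variants in order.
#' @param planted_cnvs `NULL` or data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open, bp) and `copy` (1 or 3 against the diploid
#'   baseline 2).
#' @param fragment_depth expected chromatin fragments per cell (0 disables
#'   fragment simulation).
#' @param genome named numeric vector of contig sizes (bp) for fragment and
#'   CNV simulation.
#' @param fragment_size fragment length in bp.
#' @param positions optional list with elements `marker`, `germline`,
#'   `artifact` giving explicit mtDNA positions; they must be disjoint.
#' @param seed integer seed; the generator is fully reproducible given the
#'   config.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells = 1000L,
                       n_clones = 5L,
                       polyclonal_fraction = 0.2,
                       markers_per_clone = 3L,
                       founding_heteroplasmy_range = c(0.1, 0.6),
                       dispersion_c = 50,
                       n_germline_variants = 3L,
                       n_artifact_variants = 3L,
                       artifact_heteroplasmy = 0.05,
                       germline_heteroplasmy = 0.995,
                       mean_depth = 100,
                       depth_dispersion = 2,
                       strand_bias_artifact = 0.05,
                       injected_shifts = list(),
                       planted_cnvs = NULL,
                       fragment_depth = 5000,
                       genome = c(chr1 = 120e6, chr2 = 80e6, chr3 = 100e6),
                       fragment_size = 150L,
                       positions = NULL,
                       seed = 1L) {
  cfg <- list(
    n_cells = as.integer(n_cells), n_clones = as.integer(n_clones),
    polyclonal_fraction = polyclonal_fraction,
    markers_per_clone = as.integer(markers_per_clone),
    founding_heteroplasmy_range = as.numeric(founding_heteroplasmy_range),
    dispersion_c = dispersion_c,
    n_germline_variants = as.integer(n_germline_variants),
    n_artifact_variants = as.integer(n_artifact_variants),
    artifact_heteroplasmy = artifact_heteroplasmy,
    germline_heteroplasmy = germline_heteroplasmy,
    mean_depth = mean_depth, depth_dispersion = depth_dispersion,
    strand_bias_artifact = strand_bias_artifact,
    injected_shifts = injected_shifts,
    planted_cnvs = planted_cnvs,
    fragment_depth = fragment_depth,
    genome = genome, fragment_size = as.integer(fragment_size),
    positions = positions,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_cells >= 1L, cfg$n_clones >= 0L, cfg$markers_per_clone >= 0L,
    cfg$polyclonal_fraction >= 0, cfg$polyclonal_fraction <= 1,
    length(cfg$founding_heteroplasmy_range) == 2,
    cfg$founding_heteroplasmy_range[1] > 0,
    cfg$founding_heteroplasmy_range[2] < 1,
    diff(cfg$founding_heteroplasmy_range) >= 0,
    cfg$dispersion_c > 0,
    cfg$n_germline_variants >= 0L, cfg$n_artifact_variants >= 0L,
    cfg$artifact_heteroplasmy > 0, cfg$artifact_heteroplasmy < 1,
    cfg$germline_heteroplasmy > 0, cfg$germline_heteroplasmy < 1,
    cfg$mean_depth > 0, cfg$depth_dispersion > 0,
    cfg$strand_bias_artifact >= 0, cfg$strand_bias_artifact <= 1,
    cfg$fragment_depth >= 0, cfg$fragment_size >= 1L,
    length(cfg$genome) >= 1, all(cfg$genome > 0),
    !is.null(names(cfg$genome))
  )
  if (!is.null(cfg$planted_cnvs)) {
    pc <- cfg$planted_cnvs
    stopifnot(
      is.data.frame(pc),
      all(c("chrom", "start", "end", "copy") %in% names(pc)),
      all(pc$copy %in% c(1, 3)),
      all(pc$chrom %in% names(cfg$genome)),
      all(pc$start >= 0), all(pc$end > pc$start)
    )
  }
  if (!is.null(cfg$positions)) {
    p <- unlist(cfg$positions, use.names = FALSE)
    if (anyDuplicated(p)) {
      stop("marker/germline/artifact variant positions collide")
    }
    stopifnot(all(p >= 1), all(p <= MT_GENOME_LENGTH))
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %d cells, %d clones (x%d markers), %.0f%% polyclonal,",
           " c=%g, depth=%g (NB size %g), seed=%d\n"),
    x$n_cells, x$n_clones, x$markers_per_clone,
    100 * x$polyclonal_fraction, x$dispersion_c, x$mean_depth,
    x$depth_dispersion, x$seed))
  invisible(x)
}
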