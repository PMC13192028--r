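#' Run the full synthetic lineage-tracing pipeline
#'
#' Chains every stage end-to-end on simulated data: generate a paired
#' (timepoint A / timepoint B) clonal population plus a copy-neutral
#' reference population, write all raw inputs, call and filter mtDNA
#' variants on the pooled cells, compute per-sample heteroplasmy matrices,
#' assign clonotypes, test clone dynamics and heteroplasmy shifts between
#' timepoints, infer copy number from fragments against the reference,
#' build a neighbor-joining clone tree, and score mtDNA/BCR concordance.
#' Each stage writes its outputs under `out_dir` and is recorded in a JSON
#' manifest (`manifest.json`) with parameters and MD5 hashes of every file;
#' re-running with the same config and seed is byte-identical.
#'
#' @param out_dir output directory.
#' @param config a [sim_config()]; its `seed` drives every stage.
#' @param params named list overriding analysis defaults: `min_coverage`,
#'   `detection_threshold`, `min_cells`, `vmr_threshold`,
#'   `concordance_threshold`, `homoplasmy_cutoff`, `blacklist`, `k`,
#'   `resolution`, `fc_threshold`, `alpha`, `ks_min_cells`, `bin_size`,
#'   `step`, `z_threshold`, `min_bins`, `n_reference_cells`.
#' @return The manifest (named list), invisibly; all artifacts on disk.
#' @export
run_pipeline <- function(out_dir, config = sim_config(), params = list()) {
  p <- utils::modifyList(list(
    min_coverage = 5L, detection_threshold = 0.01, min_cells = 4L,
    vmr_threshold = 0.01, concordance_threshold = 0.65,
    homoplasmy_cutoff = 0.9, blacklist = "310T>C",
    k = 20L, resolution = 1, fc_threshold = 1.5, alpha = 0.05,
    ks_min_cells = 100L, bin_size = 1e7, step = 2e6,
    z_threshold = 3, min_bins = 5L, n_reference_cells = 100L
  ), params)
  if (config$fragment_depth > 0 && p$n_reference_cells < 1) {
    stop("CNV stage enabled but no reference cells configured")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  log_stage <- function(name, ...) {
    info <- list(...)
    stages[[name]] <<- info
    message(sprintf("[%s] %s", name,
                    paste(names(info), unlist(info), sep = "=",
                          collapse = " ")))
  }

  # -- simulate ---------------------------------------------------------
  pair <- simulate_paired_timepoints(config)
  for (s in c("A", "B")) {
    sdir <- file.path(out_dir, s)
    write_base_counts(pair[[s]]$tensor, file.path(sdir, "counts"))
    write_airr(pair[[s]]$bcr, file.path(sdir, "bcr.tsv"))
    if (!is.null(pair[[s]]$fragments)) {
      write_fragments(pair[[s]]$fragments, file.path(sdir, "fragments.tsv"))
    }
  }
  write_sim_config(config, file.path(out_dir, "config.yaml"))
  truth <- pair$truth
  jsonlite::write_json(
    list(variants = truth$variants, shifted = truth$shifted),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  log_stage("simulate", cells_A = length(pair$A$truth$cell_clone),
            cells_B = length(pair$B$truth$cell_clone),
            variants = nrow(truth$variants))

  # -- call-variants (filters on cells pooled across timepoints) --------
  ids <- truth$variants$id
  stats_pooled <- pool_variant_statistics(
    list(pair$A$tensor, pair$B$tensor), ids,
    p$detection_threshold, p$min_coverage)
  calls <- filter_variants(stats_pooled, blacklist = p$blacklist,
                           min_cells = p$min_cells,
                           vmr_threshold = p$vmr_threshold,
                           concordance_threshold = p$concordance_threshold,
                           homoplasmy_cutoff = p$homoplasmy_cutoff)
  write.table(calls, file.path(out_dir, "variants.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  passing <- calls$id[calls$pass]
  log_stage("call-variants", tested = nrow(calls), pass = length(passing))
  if (!length(passing)) stop("no variant passed the filters")

  # -- heteroplasmy + clonotypes per sample -----------------------------
  seeds <- derive_seeds(config$seed, 4L)
  het <- clones <- list()
  for (i in 1:2) {
    s <- c("A", "B")[i]
    het[[s]] <- compute_heteroplasmy(pair[[s]]$tensor, passing,
                                     p$min_coverage)
    write_het_matrix(het[[s]], file.path(out_dir, s, "heteroplasmy"))
    clones[[s]] <- call_clonotypes(het[[s]], k = p$k,
                                   resolution = p$resolution,
                                   seed = seeds[i])
    write.table(data.frame(cell = names(clones[[s]]$labels),
                           clone = unname(clones[[s]]$labels)),
                file.path(out_dir, s, "clones.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    log_stage(paste0("clonotype-", s),
              clones = sum(names(clones[[s]]$sizes) != "0"))
  }

  # -- dynamics + shift tests -------------------------------------------
  dyn <- clone_dynamics(clones$A, clones$B, fc_threshold = p$fc_threshold,
                        alpha = p$alpha)
  write.table(dyn, file.path(out_dir, "dynamics.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  shifts <- shift_tests(het$A, het$B, fc_threshold = p$fc_threshold,
                        alpha = p$alpha, min_cells = p$ks_min_cells)
  write.table(shifts, file.path(out_dir, "shift_results.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  log_stage("shift-test", tested = sum(shifts$class != "not_testable"),
            shifted = sum(shifts$class %in%
                            c("shifted_mean", "shifted_distribution",
                              "shifted_both")))

  # -- CNV vs a simulated copy-neutral reference ------------------------
  if (config$fragment_depth > 0) {
    ref_cfg <- config
    ref_cfg$n_cells <- as.integer(p$n_reference_cells)
    ref_cfg$planted_cnvs <- NULL
    ref_cfg$seed <- seeds[3]
    ref <- simulate_population(ref_cfg)
    ref_frags <- ref$fragments
    ref_frags$barcode <- paste0("ref_", ref_frags$barcode)
    frags <- rbind(pair$A$fragments, ref_frags)
    bins <- make_bins(config$genome, p$bin_size, p$step)
    bm <- bin_fragments(frags, bins)
    cnv <- cnv_deviation(bm,
                         target_cells = pair$A$tensor$barcodes,
                         reference_cells = paste0("ref_", ref$tensor$barcodes),
                         min_ref_cells = min(p$n_reference_cells, 50L),
                         z_threshold = p$z_threshold, min_bins = p$min_bins)
    write.table(cnv$z, file.path(out_dir, "cnv_zscores.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(cnv$segments, file.path(out_dir, "cnv_segments.bed"),
                sep = "\t", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
    log_stage("cnv", bins = nrow(cnv$z), segments = nrow(cnv$segments))
  }

  # -- tree + concordance -----------------------------------------------
  prof <- clones$A$profiles
  prof <- prof[rownames(prof) != "0", , drop = FALSE]
  if (nrow(prof) >= 2) {
    tree <- nj_tree(prof)
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    log_stage("tree", leaves = nrow(prof))
  }
  conc <- clone_concordance(clones$A, pair$A$bcr)
  write.table(conc$flows, file.path(out_dir, "concordance.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(repertoire_summary(pair$A$bcr),
              file.path(out_dir, "repertoire_summary.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  log_stage("concordance", ari = round(conc$ari, 4))

  # -- manifest ---------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    package_version = as.character(packageVersion("mtlineage")),
    seed = config$seed,
    params = p,
    stages = stages,
    files = lapply(setNames(files, files), function(f) {
      unname(tools::md5sum(file.path(out_dir, f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# Variant statistics over cells pooled from several tensors (longitudinal
# samples of one donor share their filter statistics).
pool_variant_statistics <- function(tensors, variant_ids,
                                    detection_threshold = 0.01,
                                    min_coverage = 5L) {
  pooled <- do.call(rbind_tensors, tensors)
  variant_statistics(pooled, variant_ids, detection_threshold, min_coverage)
}

# Stack tensors over cells; positions and reference bases must agree.
rbind_tensors <- function(...) {
  ts <- list(...)
  stopifnot(length(ts) >= 1)
  pos <- ts[[1]]$positions
  ref <- ts[[1]]$ref
  for (t in ts[-1]) {
    if (!identical(t$positions, pos) || !identical(t$ref, ref)) {
      stop("tensors disagree on positions or reference bases")
    }
  }
  barcodes <- unlist(lapply(seq_along(ts), function(i) {
    paste0("s", i, "_", ts[[i]]$barcodes)
  }))
  counts <- array(0L, dim = c(length(barcodes), length(pos), 4L, 2L))
  at <- 0L
  for (t in ts) {
    n <- length(t$barcodes)
    counts[at + seq_len(n), , , ] <- t$counts
    at <- at + n
  }
  mt_tensor(counts, barcodes, pos, ref)
}
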