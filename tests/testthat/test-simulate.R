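test_that("identical config and seed give byte-identical simulations", {
  cfg <- sim_config(n_cells = 120, seed = 42, fragment_depth = 400)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$tensor$counts, s2$tensor$counts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$bcr, s2$bcr)
  expect_identical(s1$fragments, s2$fragments)
})

test_that("degenerate dispersion concentrates heteroplasmy at the founding value", {
  cfg <- sim_config(n_cells = 300, n_clones = 1, polyclonal_fraction = 0,
                    markers_per_clone = 1,
                    founding_heteroplasmy_range = c(0.5, 0.5),
                    dispersion_c = 1e6, n_germline_variants = 0,
                    n_artifact_variants = 0, mean_depth = 200,
                    depth_dispersion = 1e6, fragment_depth = 0, seed = 3)
  sim <- simulate_population(cfg)
  het <- compute_heteroplasmy(sim$tensor, sim$truth$variants$id)
  h <- het[!is.na(het)]
  expect_equal(mean(h), 0.5, tolerance = 0.01)
  # only the binomial sampling floor remains: sd ~ sqrt(0.25/200)
  expect_lt(sd(h), 2 * sqrt(0.25 / 200))
})

test_that("a single clone without background yields one clonotype downstream", {
  cfg <- sim_config(n_cells = 200, n_clones = 1, polyclonal_fraction = 0,
                    n_artifact_variants = 0, n_germline_variants = 0,
                    fragment_depth = 0, seed = 5)
  sim <- simulate_population(cfg)
  expect_true(all(sim$truth$cell_clone == 1L))
  het <- compute_heteroplasmy(sim$tensor, sim$truth$variants$id)
  cl <- call_clonotypes(het, seed = 1)
  expect_equal(length(unique(cl$labels)), 1L)
  expect_true(all(cl$labels == 1L))
})

test_that("per-clone marker means match founding heteroplasmies (beta-binomial moments)", {
  cfg <- sim_config(n_cells = 1000, n_clones = 5, dispersion_c = 50,
                    mean_depth = 100, fragment_depth = 0, seed = 7)
  sim <- simulate_population(cfg)
  v <- sim$truth$variants
  het <- compute_heteroplasmy(sim$tensor, v$id)
  markers <- which(v$class == "marker")
  for (j in markers) {
    cells <- names(sim$truth$cell_clone)[sim$truth$cell_clone == v$clone[j]]
    h <- het[cells, v$id[j]]
    h <- h[!is.na(h)]
    se <- sd(h) / sqrt(length(h))
    expect_lt(abs(mean(h) - v$founding_h[j]), 3 * se)
  }
})

test_that("empirical clone means converge to founding values as cells grow", {
  dev_at <- function(n) {
    cfg <- sim_config(n_cells = n, n_clones = 3, polyclonal_fraction = 0,
                      fragment_depth = 0, seed = 19)
    sim <- simulate_population(cfg)
    v <- sim$truth$variants
    het <- compute_heteroplasmy(sim$tensor, v$id)
    devs <- sapply(which(v$class == "marker"), function(j) {
      cells <- sim$truth$cell_clone == v$clone[j]
      abs(mean(het[cells, v$id[j]], na.rm = TRUE) - v$founding_h[j])
    })
    mean(devs)
  }
  expect_lt(dev_at(2000), dev_at(200))
})

test_that("paired timepoints share generating parameters unless shifted", {
  cfg <- sim_config(n_cells = 150, fragment_depth = 0, seed = 9)
  pair <- simulate_paired_timepoints(cfg)
  expect_identical(pair$A$truth$variants$founding_h,
                   pair$B$truth$variants$founding_h)
  expect_false(any(pair$truth$shifted))

  cfg2 <- sim_config(n_cells = 150, fragment_depth = 0, seed = 9,
                     injected_shifts = list(list(variant = 2, multiplier = 3)))
  pair2 <- simulate_paired_timepoints(cfg2)
  vA <- pair2$A$truth$variants
  vB <- pair2$B$truth$variants
  i <- which(pair2$truth$shifted)
  expect_length(i, 1)
  expect_equal(vB$founding_h[i], min(vA$founding_h[i] * 3, 0.95))
  expect_equal(vB$founding_h[-i], vA$founding_h[-i])
})

test_that("injected shift on an unknown variant errors", {
  cfg <- sim_config(n_cells = 50, fragment_depth = 0, seed = 1,
                    injected_shifts = list(list(variant = "9999A>C",
                                                multiplier = 2)))
  expect_error(simulate_paired_timepoints(cfg), "unknown variant")
})

test_that("paired empirical mean differences track the generating shift", {
  ratios <- sapply(1:10, function(s) {
    cfg <- sim_config(n_cells = 300, n_clones = 2, polyclonal_fraction = 0,
                      markers_per_clone = 1,
                      founding_heteroplasmy_range = c(0.1, 0.2),
                      fragment_depth = 0, seed = s,
                      injected_shifts = list(list(variant = 1,
                                                  multiplier = 3)))
    pair <- simulate_paired_timepoints(cfg)
    id <- pair$truth$variants$id[pair$truth$shifted]
    clone <- pair$truth$variants$clone[pair$truth$shifted]
    hA <- compute_heteroplasmy(pair$A$tensor, id)
    hB <- compute_heteroplasmy(pair$B$tensor, id)
    inA <- pair$A$truth$cell_clone == clone
    inB <- pair$B$truth$cell_clone == clone
    mean(hB[inB, 1], na.rm = TRUE) / mean(hA[inA, 1], na.rm = TRUE)
  })
  expect_equal(mean(ratios), 3, tolerance = 0.15)
})

test_that("explicit variant position collisions are rejected", {
  expect_error(
    sim_config(n_clones = 1, markers_per_clone = 1,
               n_germline_variants = 1, n_artifact_variants = 0,
               positions = list(marker = 100L, germline = 100L,
                                artifact = integer())),
    "collide")
  expect_error(sim_config(planted_cnvs = data.frame(
    chrom = "chr1", start = 0, end = 1e6, copy = 4)))
})

test_that("fragment totals scale with planted copy number", {
  cnvs <- data.frame(chrom = c("chr2", "chr3"), start = c(0, 60e6),
                     end = c(80e6, 100e6), copy = c(3, 1))
  cfg <- sim_config(n_cells = 250, seed = 13, planted_cnvs = cnvs,
                    fragment_depth = 2000)
  sim <- simulate_population(cfg)
  fr <- sim$fragments
  rate <- function(chrom, lo, hi) {
    mid <- (fr$start + fr$end) / 2
    sum(fr$chrom == chrom & mid >= lo & mid < hi) / (hi - lo)
  }
  base <- rate("chr1", 0, 120e6)         # diploid baseline
  expect_equal(rate("chr2", 0, 80e6) / base, 1.5, tolerance = 0.1)
  expect_equal(rate("chr3", 60e6, 100e6) / base, 0.5, tolerance = 0.1)
  expect_equal(rate("chr3", 0, 60e6) / base, 1.0, tolerance = 0.1)
})

test_that("artifact variants sit below the strand-concordance filter", {
  fails <- sapply(1:20, function(s) {
    cfg <- sim_config(n_cells = 200, n_clones = 2, n_artifact_variants = 2,
                      strand_bias_artifact = 0.1, fragment_depth = 0,
                      seed = 1000 + s)
    sim <- simulate_population(cfg)
    ids <- sim$truth$variants$id[sim$truth$variants$class == "artifact"]
    st <- variant_statistics(sim$tensor, ids)
    all(is.na(st$strand_concordance) | st$strand_concordance <= 0.65)
  })
  expect_gte(mean(fails), 0.95)
})
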