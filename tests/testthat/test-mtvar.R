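make_two_cell_tensor <- function() {
  # cell1: 90 ref / 10 alt at pos 100 (G>A); cell2: zero coverage there
  spec <- data.frame(
    barcode = c("c1", "c1", "c1", "c1"),
    position = 100L,
    base = c("G", "G", "A", "A"),
    strand = c("plus", "minus", "plus", "minus"),
    count = c(45L, 45L, 5L, 5L))
  toy_tensor(spec, c("c1", "c2"), 100L, "G")
}

test_that("heteroplasmy is summed-strand alt fraction, missing without coverage", {
  tensor <- make_two_cell_tensor()
  het <- compute_heteroplasmy(tensor, "100G>A", min_coverage = 5)
  expect_equal(het["c1", "100G>A"], 0.10)
  expect_true(is.na(het["c2", "100G>A"]))
})

test_that("an ALT equal to the reference base is rejected", {
  tensor <- make_two_cell_tensor()
  expect_error(compute_heteroplasmy(tensor, "100G>G"), "ALT equals reference")
  expect_error(compute_heteroplasmy(tensor, "100C>A"), "REF mismatch")
})

test_that("heteroplasmy matches a brute-force loop over raw counts", {
  cfg <- sim_config(n_cells = 50, n_clones = 3, fragment_depth = 0, seed = 21)
  sim <- simulate_population(cfg)
  v <- sim$truth$variants
  het <- compute_heteroplasmy(sim$tensor, v$id, min_coverage = 5)
  for (j in seq_len(nrow(v))) {
    jj <- match(v$pos[j], sim$tensor$positions)
    for (i in seq_along(sim$tensor$barcodes)) {
      tot <- sum(sim$tensor$counts[i, jj, , ])
      alt <- sum(sim$tensor$counts[i, jj, v$alt[j], ])
      expected <- if (tot < 5) NA_real_ else alt / tot
      expect_equal(unname(het[i, j]), expected)
    }
  }
  # recomputation from the tensor is idempotent and bounded
  expect_identical(het, compute_heteroplasmy(sim$tensor, v$id, 5))
  expect_true(all(het >= 0 & het <= 1, na.rm = TRUE))
})

test_that("constant heteroplasmy gives zero VMR and identical strands give concordance 1", {
  # 5 cells, constant heteroplasmy 0.5, alt reads identical on both strands
  alt <- c(10L, 20L, 30L, 40L, 50L)
  spec <- do.call(rbind, lapply(1:5, function(i) {
    data.frame(barcode = paste0("c", i), position = 500L,
               base = c("T", "T", "C", "C"),
               strand = c("plus", "minus", "plus", "minus"),
               count = c(alt[i], alt[i], alt[i], alt[i]))
  }))
  tensor <- toy_tensor(spec, paste0("c", 1:5), 500L, "T")
  st <- variant_statistics(tensor, "500T>C")
  expect_equal(st$vmr, 0)
  expect_equal(st$strand_concordance, 1)
  expect_equal(st$n_cells_detected, 5L)
})

test_that("concordance is undefined (failing) with fewer than two detected cells", {
  tensor <- make_two_cell_tensor()
  st <- variant_statistics(tensor, "100G>A")
  expect_true(is.na(st$strand_concordance))
  filt <- filter_variants(st)
  expect_false(filt$pass)
  expect_match(filt$fail_reasons, "strand_concordance")
})

test_that("raising the detection threshold never increases detected cells", {
  cfg <- sim_config(n_cells = 100, fragment_depth = 0, seed = 31)
  sim <- simulate_population(cfg)
  ids <- sim$truth$variants$id
  prev <- rep(Inf, length(ids))
  for (thr in c(0.005, 0.01, 0.05, 0.2)) {
    st <- variant_statistics(sim$tensor, ids, detection_threshold = thr)
    expect_true(all(st$n_cells_detected <= prev))
    prev <- st$n_cells_detected
  }
})

test_that("filter boundaries follow the stated rules", {
  row <- function(id = "1000A>G", n = 10L, vmr = 0.5, sc = 0.9, mh = 0.3) {
    structure(data.frame(id = id, n_cells_detected = n,
                         mean_heteroplasmy = mh, vmr = vmr,
                         strand_concordance = sc,
                         stringsAsFactors = FALSE),
              class = c("mt_variant_stats", "data.frame"))
  }
  # detection in exactly 4 cells fails the strict "> 4 cells" rule
  expect_false(filter_variants(row(n = 4L))$pass)
  expect_true(filter_variants(row(n = 5L))$pass)
  # blacklisted artifact rejected despite perfect statistics
  st <- filter_variants(row(id = "310T>C"))
  expect_false(st$pass)
  expect_match(st$fail_reasons, "blacklist")
  # boundary values of the strict > filters
  expect_false(filter_variants(row(vmr = 0.01))$pass)
  expect_false(filter_variants(row(sc = 0.65))$pass)
  # homoplasmic-appearing variant excluded
  expect_false(filter_variants(row(mh = 0.95))$pass)
  # spec example: n=5, vmr=0.02, concordance=0.9, mean 0.3 passes
  expect_true(filter_variants(row(n = 5L, vmr = 0.02, sc = 0.9))$pass)
})

test_that("homoplasmy exclusion consults every compartment when provided", {
  st <- structure(data.frame(id = "1000A>G", n_cells_detected = 50L,
                             mean_heteroplasmy = 0.95, vmr = 0.5,
                             strand_concordance = 0.9,
                             stringsAsFactors = FALSE),
                  class = c("mt_variant_stats", "data.frame"))
  cm_all_high <- matrix(c(0.95, 0.93), 1, dimnames = list("1000A>G", NULL))
  cm_one_low <- matrix(c(0.95, 0.40), 1, dimnames = list("1000A>G", NULL))
  expect_false(filter_variants(st, compartment_means = cm_all_high)$pass)
  expect_true(filter_variants(st, compartment_means = cm_one_low)$pass)
})

test_that("mutation burden is zero without variants, deterministic, and depth-normalized", {
  set.seed(1)
  het <- matrix(0, 250, 4, dimnames = list(paste0("c", 1:250), NULL))
  groups <- rep(c("g1", "g2"), c(125, 125))
  coverage <- rep(50, 250)
  b0 <- mutation_burden(het, groups, coverage, n_downsample = 100, seed = 2)
  expect_true(all(b0$burden == 0))

  het[1:125, 1:3] <- 0.2  # three real variants in g1 only
  b1 <- mutation_burden(het, groups, coverage, n_downsample = 100, seed = 2)
  b2 <- mutation_burden(het, groups, coverage, n_downsample = 100, seed = 2)
  expect_identical(b1, b2)
  expect_equal(b1$n_variants[b1$group == "g1"], 3L)
  # doubling g1 coverage halves its normalized burden relative to count
  coverage2 <- ifelse(groups == "g1", 100, 50)
  b3 <- mutation_burden(het, groups, coverage2, n_downsample = 100, seed = 2)
  g1 <- function(b) b$burden[b$group == "g1"]
  expect_lt(g1(b3), g1(b1))
  # undersized groups are skipped and reported
  b4 <- mutation_burden(het, rep(c("g1", "tiny"), c(240, 10)), coverage,
                        n_downsample = 100, seed = 2)
  expect_equal(attr(b4, "skipped"), "tiny")
})

test_that("groups with more clone markers carry a higher burden", {
  wins <- sapply(1:10, function(s) {
    mk <- function(n_clones, seed) {
      cfg <- sim_config(n_cells = 150, n_clones = n_clones,
                        markers_per_clone = 1, polyclonal_fraction = 0,
                        n_germline_variants = 0, n_artifact_variants = 0,
                        fragment_depth = 0, seed = seed)
      sim <- simulate_population(cfg)
      het <- compute_heteroplasmy(sim$tensor, sim$truth$variants$id)
      list(het = het, cov = rowMeans(tensor_coverage(sim$tensor)))
    }
    mbl <- mk(8, s)       # MBL-like: 8 clone markers
    bcell <- mk(2, s + 500)  # physiologic-like: 2
    het <- matrix(NA_real_, 300, ncol(mbl$het) + ncol(bcell$het))
    het[1:150, 1:ncol(mbl$het)] <- mbl$het
    het[151:300, ncol(mbl$het) + seq_len(ncol(bcell$het))] <- bcell$het
    rownames(het) <- paste0("c", 1:300)
    b <- mutation_burden(het, rep(c("MBL", "B"), c(150, 150)),
                         c(mbl$cov, bcell$cov), n_downsample = 100,
                         seed = s)
    b$burden[b$group == "MBL"] > b$burden[b$group == "B"]
  })
  expect_gte(mean(wins), 0.9)
})

test_that("recurrence counts match brute force and flag non-recurrent variants", {
  donors <- list(d1 = c("100A>G", "200C>T"),
                 d2 = c("100A>G", "300G>A"),
                 d3 = c("100A>G"))
  tab <- recurrence_table(donors)
  for (v in tab$variant) {
    expected <- sum(vapply(donors, function(d) v %in% d, TRUE))
    expect_equal(tab$n_donors[tab$variant == v], expected)
  }
  expect_equal(tab$n_donors[tab$variant == "100A>G"], 3L)
  expect_false(tab$recurrent[tab$variant == "200C>T"])
  expect_equal(attr(tab, "fraction_nonrecurrent"), 2 / 3)
})

test_that("amplicon genotyping follows the 10-read and majority rules", {
  counts <- data.frame(cell = c("a", "b", "c", "d"),
                       n_mutant_reads = c(9L, 6L, 5L, 5L),
                       n_wildtype_reads = c(0L, 5L, 6L, 5L))
  calls <- genotype_cells(counts)$call
  expect_equal(calls, c("unassigned", "mutant", "wildtype", "wildtype"))
})
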