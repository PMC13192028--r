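test_that("a two-leaf tree splits the distance evenly", {
  d <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tree <- nj_tree(d)
  expect_s3_class(tree, "phylo")
  expect_equal(sort(tree$tip.label), c("a", "b"))
  expect_equal(tree$edge.length, c(1.5, 1.5))
})

test_that("a four-taxon additive matrix is recovered exactly", {
  # tree ((A:2,B:3):1,(C:4,D:5)) -> pairwise path lengths
  d <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 9, 0), 4, byrow = TRUE,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(tree)[LETTERS[1:4], LETTERS[1:4]], d,
               tolerance = 1e-10)
  # AB | CD split present
  splits <- ape::prop.part(ape::unroot(tree))
  expect_true(all(tree$edge.length >= 0))
})

test_that("additive matrices are recovered for random trees of 4 to 8 taxa", {
  skip_if_not_installed("phangorn")
  set.seed(14)
  for (r in 1:10) {
    gen <- random_additive_tree(sample(4:8, 1))
    tree <- nj_tree(gen$dist)
    labs <- rownames(gen$dist)
    expect_equal(ape::cophenetic.phylo(tree)[labs, labs], gen$dist,
                 tolerance = 1e-8)
    expect_equal(phangorn::RF.dist(ape::unroot(tree),
                                   ape::unroot(gen$tree)), 0)
  }
})

test_that("leaf order does not change the unrooted topology", {
  skip_if_not_installed("phangorn")
  set.seed(15)
  gen <- random_additive_tree(6)
  perm <- sample(rownames(gen$dist))
  t1 <- nj_tree(gen$dist)
  t2 <- nj_tree(gen$dist[perm, perm])
  expect_equal(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)), 0)
})

test_that("negative branch estimates are clamped with length donated to the sibling", {
  # strongly non-additive matrix known to produce negative NJ branches
  d <- matrix(c(0, 1, 10, 9,
                1, 0, 9, 10,
                10, 9, 0, 1,
                9, 10, 1, 0), 4, byrow = TRUE,
              dimnames = list(letters[1:4], letters[1:4]))
  raw <- ape::nj(stats::as.dist(d))
  tree <- nj_tree(d)
  expect_true(all(tree$edge.length >= 0))
  expect_equal(sum(tree$edge.length), sum(raw$edge.length), tolerance = 1e-10)
})

test_that("NaN distances raise an error naming the offending pair", {
  d <- matrix(c(0, 1, NA, 1, 0, 2, NA, 2, 0), 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  expect_error(nj_tree(stats::as.dist(d)), "x.*z|z.*x")
})

test_that("subclones sharing ancestral variants group together in the tree", {
  skip_if_not_installed("phangorn")
  # clones 1+2 share an ancestral variant, 3+4 another: expected split 12|34
  prof <- rbind(
    c(0.5, 0.30, 0.00, 0, 0),
    c(0.5, 0.00, 0.25, 0, 0),
    c(0.0, 0.00, 0.00, 0.6, 0.3),
    c(0.0, 0.00, 0.00, 0.6, 0.0))
  rownames(prof) <- paste0("clone", 1:4)
  tree <- nj_tree(prof)
  expected <- ape::read.tree(text = "((clone1,clone2),(clone3,clone4));")
  expect_equal(phangorn::RF.dist(ape::unroot(tree), ape::unroot(expected)), 0)
})

test_that("repertoire summaries handle degenerate clone structures", {
  mono <- data.frame(cell_id = paste0("c", 1:40), clone_id = "IGH.A",
                     junction_aa = "CARW")
  s1 <- repertoire_summary(mono)
  expect_equal(s1$polyclonal_fraction, 0)
  expect_equal(s1$n_clonotypes, 1L)

  singles <- data.frame(cell_id = paste0("c", 1:40),
                        clone_id = paste0("IGH.", 1:40))
  s2 <- repertoire_summary(singles)
  expect_equal(s2$dominant_freq, 1 / 40)
  expect_equal(s2$polyclonal_fraction, 39 / 40)
})

test_that("the simulated polyclonal fraction is recovered consistently", {
  ests <- sapply(1:10, function(s) {
    cfg <- sim_config(n_cells = 400, n_clones = 1, polyclonal_fraction = 0.33,
                      fragment_depth = 0, seed = 300 + s)
    sim <- simulate_population(cfg)
    repertoire_summary(sim$bcr)$polyclonal_fraction
  })
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.33), 3 * se + 1e-8)
})

test_that("identical partitions give ARI 1 and pure clones", {
  labels <- setNames(rep(1:4, each = 25), paste0("c", 1:100))
  bcr <- data.frame(cell_id = names(labels),
                    clone_id = paste0("IGH.", labels))
  cc <- clone_concordance(labels, bcr)
  expect_equal(cc$ari, 1.0)
  expect_true(all(cc$purity$purity == 1))
  expect_equal(sum(cc$flows$n), 100)
})

test_that("independent partitions give near-zero concordance", {
  set.seed(16)
  aris <- replicate(50, {
    labels <- setNames(sample(1:5, 1000, replace = TRUE), paste0("c", 1:1000))
    bcr <- data.frame(cell_id = names(labels),
                      clone_id = sample(paste0("IGH.", 1:5), 1000,
                                        replace = TRUE))
    clone_concordance(labels, bcr)$ari
  })
  expect_lt(max(abs(aris)), 0.05)
})

test_that("concordance ARI equals brute-force pair counting", {
  set.seed(17)
  labels <- setNames(sample(1:4, 120, replace = TRUE), paste0("c", 1:120))
  bcr_lab <- sample(paste0("IGH.", 1:3), 120, replace = TRUE)
  bcr <- data.frame(cell_id = names(labels), clone_id = bcr_lab)
  cc <- clone_concordance(labels, bcr)
  expect_equal(cc$ari, oracle_ari(unname(labels), bcr_lab),
               tolerance = 1e-12)
  expect_error(clone_concordance(
    setNames(1L, "zz"), data.frame(cell_id = "c1", clone_id = "IGH.A")),
    "no shared cells")
})

test_that("simulated clone-linked BCR labels align with recovered mtDNA clones", {
  cfg <- sim_config(n_cells = 600, fragment_depth = 0, seed = 29)
  sim <- simulate_population(cfg)
  st <- filter_variants(variant_statistics(sim$tensor,
                                           sim$truth$variants$id))
  het <- compute_heteroplasmy(sim$tensor, st$id[st$pass])
  cl <- call_clonotypes(het, seed = 29)
  cc <- clone_concordance(cl, sim$bcr)
  dominant <- cc$purity[cc$purity$mt_clone != "0", ]
  biggest <- dominant[which.max(dominant$n), ]
  expect_gte(biggest$purity, 0.9)
})
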