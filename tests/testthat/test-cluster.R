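test_that("correlation distance matches hand-computed Pearson r", {
  x <- c(0.1, 0.4, 0.6, 0.9)
  y <- c(0.2, 0.3, 0.7, 0.8)
  F2 <- rbind(X = x, Y = y, Z = 1 - x)
  colnames(F2) <- paste0("M", 1:4)
  d <- correlation_distance_matrix(F2)
  expect_equal(d["X", "Y"], 1 - cor(x, y), tolerance = 1e-12)
  expect_equal(d["X", "X"], 0)
  expect_equal(d["X", "Z"], 2, tolerance = 1e-12)   # perfect anti-correlation
  Fz <- rbind(X = x, W = rep(0.5, 4))
  colnames(Fz) <- paste0("M", 1:4)
  expect_error(correlation_distance_matrix(Fz), "zero-variance")
})

test_that("UPGMA merge heights match the brute-force average-linkage oracle", {
  ## 3-leaf toy: d(A,B) = 1, d(.,C) = 4
  D <- matrix(c(0, 1, 4, 1, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma_tree(D)
  expect_equal(tree$height, oracle_upgma_heights(D), tolerance = 1e-12)
  expect_equal(tree$height, c(1, 4), tolerance = 1e-12)

  ## a larger random distance matrix agrees with the oracle too
  set.seed(17)
  P <- matrix(runif(60), 6, 10,
              dimnames = list(paste0("S", 1:6), paste0("M", 1:10)))
  D6 <- correlation_distance_matrix(P)
  t6 <- upgma_tree(D6)
  expect_equal(t6$height, oracle_upgma_heights(D6), tolerance = 1e-10)
  ## heights are monotone non-decreasing
  expect_true(all(diff(t6$height) >= -1e-12))

  ## ultrametric input is reproduced exactly
  Du <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(upgma_tree(Du)$height, c(2, 6), tolerance = 1e-12)

  ## leaf order permutation leaves the topology unchanged
  perm <- c(4, 2, 6, 1, 3, 5)
  tp <- upgma_tree(D6[perm, perm])
  key <- function(tr) {
    sets <- lapply(seq_along(tr$height), function(i) NULL)
    m <- tr$merge
    out <- vector("list", nrow(m))
    for (i in seq_len(nrow(m))) {
      g <- function(j) if (j < 0) tr$labels[-j] else out[[j]]
      out[[i]] <- sort(c(g(m[i, 1]), g(m[i, 2])))
    }
    sort(vapply(out, paste, character(1), collapse = ","))
  }
  expect_identical(key(tp), key(upgma_tree(D6)))
})

test_that("multiscale bootstrap AU support is reproducible and calibrated on strong structure", {
  cfg <- marker_sim_config(n_cultivars = 3, n_markers = 300, fst = 0.08,
                           depth_mean = 300, seed = 55)
  sim <- simulate_marker_dataset(cfg)
  ff <- apply_filter_config(sim$counts, filter_config(20, 0.3))
  sup1 <- multiscale_bootstrap_au(ff$freq, B = 200, seed = 7)
  sup2 <- multiscale_bootstrap_au(ff$freq, B = 200, seed = 7)
  expect_identical(sup1$au, sup2$au)
  expect_true(all(sup1$au >= 0 & sup1$au <= 1))
  expect_true(all(sup1$bp >= 0 & sup1$bp <= 1))

  ## true cultivar clades under strong differentiation get AU >= 0.95
  tab <- completely_distinct_from_tree(sup1, sim$meta, threshold = 0.95)
  expect_true(all(tab$has_exclusive_node))
  expect_true(all(tab$distinct))
  ## root (all leaves) is always recovered: AU = 1
  n_leaves <- vapply(sup1$leaves, length, integer(1))
  expect_equal(sup1$au[which.max(n_leaves)], 1)
})

test_that("the exclusive-clade rule enforces exactness and the threshold", {
  meta <- sample_meta(paste0(rep(c("A", "B"), each = 3), "_", rep(1:3, 2)),
                      rep(c("A", "B"), each = 3), rep(1:3, 2))
  mk_support <- function(leaf_sets, aus) {
    s <- data.frame(node = seq_along(leaf_sets), bp = aus, au = aus,
                    v = NA_real_, c = NA_real_, flag = "")
    s$leaves <- leaf_sets
    class(s) <- c("cluster_support", "data.frame")
    s
  }
  ## exact bulk set with AU 0.96 -> distinct
  sup <- mk_support(list(c("A_1", "A_2", "A_3"),
                         c("B_1", "B_2", "B_3", "A_1")), c(0.96, 0.99))
  tab <- completely_distinct_from_tree(sup, meta)
  expect_true(tab$distinct[tab$cultivar_id == "A"])
  ## B's node contains a foreign sample -> not exclusive -> not distinct
  expect_false(tab$distinct[tab$cultivar_id == "B"])
  ## threshold boundary: AU just below 0.95 fails
  sup2 <- mk_support(list(c("A_1", "A_2", "A_3")), 0.949)
  expect_false(completely_distinct_from_tree(sup2, meta)$distinct[1])
  ## scattered bulks: no exclusive node at all
  tabA <- completely_distinct_from_tree(
    mk_support(list(c("A_1", "B_1")), 0.99), meta)
  expect_false(any(tabA$distinct))
})

test_that("null data rarely produce spuriously supported cultivar clades", {
  cfg <- marker_sim_config(n_cultivars = 6, n_markers = 400, fst = 0,
                           depth_mean = 60, seed = 98)
  sim <- simulate_marker_dataset(cfg)
  ff <- apply_filter_config(sim$counts, filter_config(10, 0.5))
  cl <- cluster_bootstrap_distinct(ff$freq, sim$meta, B = 200, seed = 3)
  expect_lte(length(cl$distinct_cultivars), 1L)
})

test_that("newick export carries AU labels for annotated nodes", {
  d <- fix_marker_small()
  sup <- multiscale_bootstrap_au(d$freq, B = 50, seed = 2)
  nwk <- tempfile(fileext = ".nwk")
  phy <- write_newick_au(sup, nwk)
  expect_true(file.exists(nwk))
  txt <- readLines(nwk)
  expect_match(txt, "A_1")
  expect_s3_class(phy, "phylo")
  expect_equal(ape::Ntip(phy), 18L)
})
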