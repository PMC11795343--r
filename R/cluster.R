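#' Correlation-based distance between bulk samples
#'
#' `d(x, y) = 1 - r` where `r` is the Pearson correlation of the two
#' samples' allele-frequency vectors across markers; `d` lies in `[0, 2]`.
#'
#' @param freqs complete samples x markers frequency matrix (>= 2 markers).
#' @return symmetric samples x samples distance matrix with zero diagonal.
#' @export
correlation_distance_matrix <- function(freqs) {
  check_freq_matrix(freqs)
  stop_if(ncol(freqs) < 2, "need at least 2 markers")
  sds <- apply(freqs, 1, stats::sd)
  stop_if(any(sds < .Machine$double.eps),
          "zero-variance sample frequency vector(s): ",
          paste(rownames(freqs)[sds < .Machine$double.eps], collapse = ", "))
  d <- 1 - stats::cor(t(freqs))
  diag(d) <- 0
  d
}

#' UPGMA dendrogram
#'
#' Agglomerative clustering with unweighted average linkage on a distance
#' matrix (the inter-cluster distance is the mean of all member pair
#' distances), yielding an ultrametric tree with non-decreasing merge
#' heights.
#'
#' @param dist symmetric distance matrix or `dist` object.
#' @return `hclust` object (method `"average"`).
#' @export
upgma_tree <- function(dist) {
  stats::hclust(stats::as.dist(dist), method = "average")
}

## leaf-index sets of every internal node of an hclust tree, as sorted
## integer vectors; names are canonical keys used for bootstrap containment
node_leaf_sets <- function(tree) {
  n <- length(tree$order) - 0L
  merges <- tree$merge
  sets <- vector("list", nrow(merges))
  for (i in seq_len(nrow(merges))) {
    get <- function(j) if (j < 0) -j else sets[[j]]
    sets[[i]] <- sort(c(get(merges[i, 1]), get(merges[i, 2])))
  }
  names(sets) <- vapply(sets, paste, character(1), collapse = ",")
  sets
}

#' Multiscale bootstrap AU support for UPGMA clusters
#'
#' For each scale `r`, draws `B` marker resamples of size `round(r * M)`
#' with replacement, rebuilds the UPGMA tree on the correlation distance, and
#' records per observed node the bootstrap probability `BP_r` (fraction of
#' resampled trees containing the exact leaf set). The approximately
#' unbiased (AU) value comes from a weighted least-squares fit of
#' `qnorm(1 - BP_r) ~ v sqrt(r) + c / sqrt(r)` with binomial-variance
#' weights (BP clamped to `[0.5/B, 1 - 0.5/B]`), giving `AU = 1 - pnorm(v -
#' c)`. Nodes recovered in every resample at every scale get `AU = 1`; a
#' degenerate fit falls back to `BP` at `r = 1` (flagged).
#'
#' @param freqs complete samples x markers frequency matrix.
#' @param tree observed UPGMA `hclust` tree (rebuilt from `freqs` when
#'   `NULL`).
#' @param scales relative resample sizes (default `seq(0.5, 1.4, 0.1)`).
#' @param B bootstrap replicates per scale (default 1000).
#' @param seed RNG seed.
#' @return data.frame of class `cluster_support`: one row per internal node
#'   with `node`, `leaves` (list column of sample ids), `bp` (at `r` nearest
#'   1), `au`, `v`, `c`, `flag`; attributes `tree`, `scales`, `B`, `seed`,
#'   `bp_by_scale`.
#' @export
multiscale_bootstrap_au <- function(freqs, tree = NULL,
                                    scales = seq(0.5, 1.4, by = 0.1),
                                    B = 1000L, seed = NULL) {
  stop_if(ncol(freqs) < 2, "need at least 2 markers")
  if (is.null(tree)) tree <- upgma_tree(correlation_distance_matrix(freqs))
  sets <- node_leaf_sets(tree)
  keys <- names(sets)
  M <- ncol(freqs)
  counts <- matrix(0L, length(keys), length(scales),
                   dimnames = list(keys, paste0("r", scales)))
  with_seed(seed, {
    for (si in seq_along(scales)) {
      m <- max(2L, round(scales[si] * M))
      for (b in seq_len(B)) {
        idx <- sample.int(M, m, replace = TRUE)
        Xb <- freqs[, idx, drop = FALSE]
        sds <- apply(Xb, 1, stats::sd)
        if (any(sds < .Machine$double.eps)) next
        tb <- stats::hclust(stats::as.dist(1 - stats::cor(t(Xb))),
                            method = "average")
        kb <- names(node_leaf_sets(tb))
        hitidx <- match(kb, keys)
        hitidx <- hitidx[!is.na(hitidx)]
        counts[hitidx, si] <- counts[hitidx, si] + 1L
      }
    }
  })
  bp <- counts / B
  r1 <- which.min(abs(scales - 1))
  out <- lapply(seq_along(keys), function(i) {
    bpi <- bp[i, ]
    flag <- ""
    if (all(bpi >= 1)) {
      au <- 1; v <- NA_real_; cc <- NA_real_
    } else {
      bpc <- pmin(pmax(bpi, 0.5 / B), 1 - 0.5 / B)
      z <- stats::qnorm(1 - bpc)
      w <- B * stats::dnorm(z)^2 / (bpc * (1 - bpc))
      X <- cbind(sqrt(scales), 1 / sqrt(scales))
      fit <- tryCatch(stats::lm.wfit(X, z, w), error = function(e) NULL)
      if (is.null(fit) || anyNA(fit$coefficients)) {
        au <- bpi[r1]; v <- NA_real_; cc <- NA_real_
        flag <- "degenerate fit: AU = BP"
      } else {
        v <- fit$coefficients[1]; cc <- fit$coefficients[2]
        au <- 1 - stats::pnorm(v - cc)
      }
    }
    data.frame(node = i, bp = bp[i, r1], au = min(max(au, 0), 1),
               v = unname(v), c = unname(cc), flag = flag)
  })
  out <- do.call(rbind, out)
  out$leaves <- lapply(sets, function(s) tree$labels[s])
  attr(out, "tree") <- tree
  attr(out, "scales") <- scales
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  attr(out, "bp_by_scale") <- bp
  class(out) <- c("cluster_support", "data.frame")
  out
}

#' Completely distinct cultivars from an AU-annotated tree
#'
#' A cultivar is completely distinct under the cluster criterion when some
#' internal node's leaf set equals exactly the cultivar's bulk set (its
#' replicates cluster exclusively together) and that node's AU support is at
#' least `threshold`.
#'
#' @param support `cluster_support` from [multiscale_bootstrap_au()].
#' @param meta [sample_meta()] table.
#' @param threshold AU support threshold (default 0.95).
#' @return data.frame with `cultivar_id`, `has_exclusive_node`, `au`,
#'   `distinct`; attribute `distinct_cultivars`.
#' @export
completely_distinct_from_tree <- function(support, meta, threshold = 0.95) {
  check_meta(meta)
  node_keys <- vapply(support$leaves, function(l) paste(sort(l), collapse = ","),
                      character(1))
  ids <- sort(unique(meta$cultivar_id))
  rows <- lapply(ids, function(cv) {
    bulks <- sort(meta$sample_id[meta$cultivar_id == cv])
    key <- paste(bulks, collapse = ",")
    j <- match(key, node_keys)
    au <- if (is.na(j)) NA_real_ else support$au[j]
    data.frame(cultivar_id = cv, has_exclusive_node = !is.na(j), au = au,
               distinct = !is.na(j) && au >= threshold)
  })
  out <- do.call(rbind, rows)
  attr(out, "distinct_cultivars") <- out$cultivar_id[out$distinct]
  out
}

#' Cluster-bootstrap distinctness criterion
#'
#' Convenience wrapper: correlation distance, UPGMA tree, multiscale
#' bootstrap AU support, and the exclusive-clade rule. This criterion makes
#' no pairwise calls; its verdict is the list of completely distinct
#' cultivars.
#'
#' @inheritParams multiscale_bootstrap_au
#' @param meta [sample_meta()] table.
#' @param threshold AU threshold (default 0.95).
#' @return list of class `cluster_criterion` with `tree`, `support`,
#'   `table`, `distinct_cultivars`.
#' @export
cluster_bootstrap_distinct <- function(freqs, meta,
                                       scales = seq(0.5, 1.4, by = 0.1),
                                       B = 1000L, threshold = 0.95,
                                       seed = NULL) {
  check_meta(meta, rownames(freqs))
  tree <- upgma_tree(correlation_distance_matrix(freqs))
  support <- multiscale_bootstrap_au(freqs, tree, scales = scales, B = B,
                                     seed = seed)
  tab <- completely_distinct_from_tree(support, meta, threshold)
  structure(list(tree = tree, support = support, table = tab,
                 distinct_cultivars = attr(tab, "distinct_cultivars")),
            class = "cluster_criterion")
}

#' @export
print.cluster_criterion <- function(x, ...) {
  cat(sprintf("Cluster-bootstrap criterion: %d completely distinct cultivar(s)",
              length(x$distinct_cultivars)))
  if (length(x$distinct_cultivars))
    cat(": ", paste(x$distinct_cultivars, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Export an AU-annotated UPGMA tree as newick
#'
#' Internal node labels carry `AU x 100` (rounded to one decimal).
#'
#' @param support `cluster_support`.
#' @param path output newick path.
#' @return invisibly, the `phylo` object written.
#' @export
write_newick_au <- function(support, path) {
  tree <- attr(support, "tree")
  phy <- ape::as.phylo(tree)
  ## map hclust internal nodes to phylo node numbers via shared leaf sets
  parts <- ape::prop.part(phy)
  part_keys <- vapply(parts, function(p)
    paste(sort(attr(parts, "labels")[p]), collapse = ","), character(1))
  node_keys <- vapply(support$leaves, function(l)
    paste(sort(l), collapse = ","), character(1))
  lab <- rep("", phy$Nnode)
  m <- match(part_keys, node_keys)
  lab[!is.na(m)] <- format(round(100 * support$au[m[!is.na(m)]], 1),
                           trim = TRUE)
  phy$node.label <- lab
  ape::write.tree(phy, file = path)
  invisible(phy)
}
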