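#' Cultivar-level mean profiles
#'
#' Builds the cultivar x variable matrix of one information layer. For
#' marker data (`freqs` + `meta`), the profile is the mean bulk frequency per
#' cultivar (no standardization: frequencies share a common scale). For
#' trait data (`trait_plot_table`), cultivar means over blocks are
#' z-standardized per trait (traits have incommensurate units); zero-variance
#' traits are dropped with a warning.
#'
#' @param x samples x markers frequency matrix, or a `trait_plot_table`.
#' @param meta [sample_meta()] table (marker layer only).
#' @return cultivar x variable numeric matrix.
#' @export
cultivar_mean_profiles <- function(x, meta = NULL) {
  if (inherits(x, "trait_plot_table")) {
    schema <- attr(x, "schema")
    means <- sapply(schema$name, function(tr) tapply(x[[tr]], x$cultivar, mean))
    sds <- apply(means, 2, stats::sd)
    if (any(sds < .Machine$double.eps)) {
      warning("dropping zero-variance trait(s): ",
              paste(colnames(means)[sds < .Machine$double.eps], collapse = ", "))
      means <- means[, sds >= .Machine$double.eps, drop = FALSE]
    }
    return(scale(means))
  }
  check_meta(meta, rownames(x))
  labels <- meta$cultivar_id[match(rownames(x), meta$sample_id)]
  ids <- sort(unique(labels))
  prof <- t(sapply(ids, function(cv)
    colMeans(x[labels == cv, , drop = FALSE])))
  rownames(prof) <- ids
  prof
}

#' Euclidean distance matrix of profiles
#'
#' @param profiles entities x variables numeric matrix.
#' @return symmetric distance matrix with zero diagonal.
#' @export
euclidean_distance_matrix <- function(profiles) {
  stop_if(anyNA(profiles), "profiles must be complete")
  as.matrix(stats::dist(profiles))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with a one-sided
#' (upper) permutation p-value over random entity relabelings of one matrix
#' (consistency being the alternative of interest). Delegates the
#' permutation machinery to `vegan::mantel`.
#'
#' @param d1,d2 distance matrices over the same entities in the same order.
#' @param nperm permutations (default 10000).
#' @param seed RNG seed.
#' @return list of class `mantel_result` with `r`, `p`, `n_permutations`,
#'   `seed`.
#' @export
mantel_test <- function(d1, d2, nperm = 10000L, seed = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  stop_if(!identical(dim(d1), dim(d2)), "distance matrices differ in size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)))
    stop_if(!identical(rownames(d1), rownames(d2)),
            "distance matrices must share entity order")
  v1 <- d1[upper.tri(d1)]
  stop_if(stats::sd(v1) < .Machine$double.eps ||
            stats::sd(d2[upper.tri(d2)]) < .Machine$double.eps,
          "constant distance triangle: Mantel r undefined")
  m <- with_seed(seed, vegan::mantel(stats::as.dist(d1), stats::as.dist(d2),
                                     permutations = nperm))
  structure(list(r = unname(m$statistic), p = m$signif,
                 n_permutations = nperm, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f, one-sided p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_permutations))
  invisible(x)
}

#' Classical MDS (principal coordinates) with Kruskal stress-1
#'
#' Double-centers the squared distance matrix, eigendecomposes, and builds
#' coordinates from the positive eigenvalues only. For each dimensionality
#' `k` up to `k_max`, Kruskal's stress-1
#' `sqrt(sum((delta - dhat_k)^2) / sum(delta^2))` quantifies how faithfully
#' the k-dimensional configuration distances `dhat_k` reproduce the input
#' distances `delta`.
#'
#' @param dist distance matrix (>= 3 entities).
#' @param k_max maximum embedding dimension (default 4; truncated with a
#'   warning when fewer positive eigenvalues exist).
#' @return list of class `mds_result` with `coordinates` (entities x k),
#'   `eigenvalues` (all, descending), `stress` (named vector over
#'   `1..k`), `k`.
#' @export
classical_mds <- function(dist, k_max = 4L) {
  D <- as.matrix(dist)
  stop_if(nrow(D) < 3, "need at least 3 entities")
  fit <- stats::cmdscale(stats::as.dist(D), k = nrow(D) - 1, eig = TRUE)
  eig <- fit$eig
  npos <- sum(eig > 1e-8 * max(abs(eig)))
  k <- min(k_max, npos)
  if (k < k_max) warning("only ", npos, " positive eigenvalue(s); k truncated")
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("D", seq_len(k))
  delta <- D[upper.tri(D)]
  stress <- vapply(seq_len(k), function(kk) {
    dk <- as.matrix(stats::dist(coords[, seq_len(kk), drop = FALSE]))
    sqrt(sum((delta - dk[upper.tri(dk)])^2) / sum(delta^2))
  }, numeric(1))
  names(stress) <- paste0("k", seq_len(k))
  structure(list(coordinates = coords, eigenvalues = eig, stress = stress,
                 k = k),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("Classical MDS: %d entities embedded in %d dimension(s); stress-1: %s\n",
              nrow(x$coordinates), x$k,
              paste(sprintf("%s=%.3f", names(x$stress), x$stress),
                    collapse = ", ")))
  invisible(x)
}

#' Summary table across criteria and their combinations
#'
#' For every criterion and every union combination of 2+ criteria: the
#' number and proportion of distinct pairs, the number and proportion of
#' completely distinct cultivars, and the list of remaining non-distinct
#' pairs.
#'
#' @param results named list of `distinctness_result` objects over a shared
#'   cultivar set.
#' @return list of class `distinctness_summary` with `table` (one row per
#'   criterion/combination) and `non_distinct` (named list of pair
#'   data.frames).
#' @export
summarize_distinctness <- function(results) {
  stop_if(length(results) < 1, "need at least one result")
  if (is.null(names(results)))
    names(results) <- vapply(results, function(r) r$criterion, character(1))
  ids <- results[[1]]$cultivar_ids
  for (r in results)
    stop_if(!identical(sort(r$cultivar_ids), sort(ids)),
            "mismatched cultivar sets")
  entries <- as.list(results)
  if (length(results) >= 2) {
    for (k in 2:length(results)) {
      for (set in utils::combn(names(results), k, simplify = FALSE)) {
        nm <- paste(set, collapse = "+")
        entries[[nm]] <- combine_distinctness(results[set], criterion = nm)
      }
    }
  }
  C <- length(ids)
  tab <- do.call(rbind, lapply(names(entries), function(nm) {
    r <- entries[[nm]]
    data.frame(criterion = nm,
               n_distinct_pairs = r$n_distinct_pairs,
               pct_distinct_pairs = round(100 * r$n_distinct_pairs / r$n_pairs, 1),
               n_completely_distinct = r$n_completely_distinct,
               pct_completely_distinct = round(100 * r$n_completely_distinct / C, 1))
  }))
  nd <- lapply(entries, function(r) {
    m <- !r$pair_distinct & upper.tri(r$pair_distinct)
    hit <- which(m, arr.ind = TRUE)
    data.frame(a = ids[hit[, 1]], b = ids[hit[, 2]])
  })
  structure(list(table = tab, non_distinct = nd),
            class = "distinctness_summary")
}

#' @export
print.distinctness_summary <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}
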