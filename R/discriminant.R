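#' Pair-wise PCA of the six bulks of a cultivar pair
#'
#' A separate dimensionality reduction is computed per comparison: centered
#' PCA of the 2 x 3 bulk samples of the pair, retaining at most five axes
#' (the rank bound for six observations).
#'
#' @param freqs complete frequency matrix restricted to the six bulks
#'   (2 cultivars x 3 bulks).
#' @return `pca_model` with at most 5 axes.
#' @export
pair_pca_project <- function(freqs) {
  stop_if(nrow(freqs) != 6, "pair PCA expects exactly 6 samples (2 x 3 bulks)")
  pca <- center_and_pca(freqs)
  keep <- min(5L, pca$n_axes)
  pca$scores <- pca$scores[, seq_len(keep), drop = FALSE]
  pca$loadings <- pca$loadings[, seq_len(keep), drop = FALSE]
  pca$eigenvalues <- pca$eigenvalues[seq_len(keep)]
  pca$n_axes <- keep
  pca
}

#' Linear discriminant classification of one validation fold
#'
#' Fits a two-class linear discriminant on the `k` leading PC scores of the
#' four training bulks (two per cultivar) and assigns each test bulk to the
#' nearer class under the Mahalanobis metric of the pooled within-class
#' covariance. With two samples per class the pooled covariance is singular
#' for `k > 2`; the Moore-Penrose pseudo-inverse is used, which degenerates
#' gracefully to nearest-centroid in the null directions. Exact ties go to
#' the alphabetically first cultivar.
#'
#' @param train training score matrix (4 x >= k) with cultivar labels
#'   `train_labels` (two classes, two samples each).
#' @param train_labels length-4 label vector.
#' @param test test score matrix (rows to classify).
#' @param k number of leading axes to use.
#' @return character vector of predicted labels for the rows of `test`.
#' @export
lda_classify_fold <- function(train, train_labels, test, k) {
  stop_if(k < 1 || k > ncol(train), "k out of range")
  classes <- sort(unique(as.character(train_labels)))
  stop_if(length(classes) != 2, "training set must contain both classes")
  tr <- train[, seq_len(k), drop = FALSE]
  te <- test[, seq_len(k), drop = FALSE]
  centroids <- do.call(rbind, lapply(classes, function(cl)
    colMeans(tr[train_labels == cl, , drop = FALSE])))
  rownames(centroids) <- classes
  W <- matrix(0, k, k)
  for (cl in classes) {
    Xc <- sweep(tr[train_labels == cl, , drop = FALSE], 2,
                centroids[cl, ])
    W <- W + crossprod(Xc)
  }
  W <- W / max(nrow(tr) - length(classes), 1)
  Winv <- MASS::ginv(W)
  d2 <- sapply(classes, function(cl) {
    diff <- sweep(te, 2, centroids[cl, ])
    rowSums((diff %*% Winv) * diff)
  })
  d2 <- matrix(d2, nrow = nrow(te), dimnames = list(NULL, classes))
  apply(d2, 1, function(row) classes[which.min(row)])
}

#' Discriminant distinctness of one cultivar pair
#'
#' Three validation rounds: round `r` holds out the bulk with index `r` of
#' each cultivar, trains the discriminant on the remaining four bulks, and
#' predicts the two held-out bulks — so each of the six samples is predicted
#' exactly once. The procedure is evaluated for `k = 1..5` leading PC axes;
#' the pair is distinct when all six predictions are correct for at least one
#' `k`.
#'
#' @param freqs complete samples x markers frequency matrix (all samples).
#' @param meta [sample_meta()] table.
#' @param pair character vector of the two cultivar ids.
#' @return list of class `pair_lda_result` with `pair`, `correct_by_k`
#'   (named integer vector, values in 0..6), `distinct`, `best_k`.
#' @export
pair_discriminant_distinct <- function(freqs, meta, pair) {
  check_meta(meta, rownames(freqs))
  stop_if(length(pair) != 2, "pair must name two cultivars")
  sub <- meta[meta$cultivar_id %in% pair, ]
  stop_if(!all(table(sub$cultivar_id) == 3),
          "each cultivar of the pair needs exactly 3 bulks")
  sub <- sub[order(sub$cultivar_id, sub$bulk_index), ]
  X <- freqs[sub$sample_id, , drop = FALSE]
  pca <- tryCatch(pair_pca_project(X), error = function(e) NULL)
  if (is.null(pca) || all(pca$eigenvalues < 1e-12)) {
    ## six identical samples: no usable axes, trivially non-distinct
    correct <- stats::setNames(rep(NA_integer_, 5), paste0("k", 1:5))
    return(structure(list(pair = sort(pair), correct_by_k = correct,
                          distinct = FALSE, best_k = NA_integer_),
                     class = "pair_lda_result"))
  }
  kmax <- pca$n_axes
  correct <- stats::setNames(rep(NA_integer_, 5), paste0("k", 1:5))
  for (k in seq_len(min(5L, kmax))) {
    n_ok <- 0L
    for (r in 1:3) {
      hold <- sub$bulk_index == r
      pred <- lda_classify_fold(pca$scores[!hold, , drop = FALSE],
                                sub$cultivar_id[!hold],
                                pca$scores[hold, , drop = FALSE], k)
      n_ok <- n_ok + sum(pred == sub$cultivar_id[hold])
    }
    correct[k] <- n_ok
  }
  distinct <- any(correct == 6L, na.rm = TRUE)
  best_k <- if (distinct) which(correct == 6L)[1] else NA_integer_
  structure(list(pair = sort(pair), correct_by_k = correct,
                 distinct = distinct, best_k = best_k),
            class = "pair_lda_result")
}

#' Discriminant distinctness criterion over all pairs
#'
#' Runs [pair_discriminant_distinct()] for every cultivar pair.
#'
#' @param freqs complete samples x markers frequency matrix.
#' @param meta [sample_meta()] table.
#' @return `distinctness_result` with attribute `pair_table` (per-pair
#'   correct counts by axis number and verdict).
#' @export
discriminant_distinctness <- function(freqs, meta) {
  check_meta(meta, rownames(freqs))
  ids <- sort(unique(meta$cultivar_id))
  pairs <- cultivar_pairs(ids)
  pd <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    r <- pair_discriminant_distinct(freqs, meta, c(pairs$a[i], pairs$b[i]))
    pd[pairs$a[i], pairs$b[i]] <- pd[pairs$b[i], pairs$a[i]] <- r$distinct
    rows[[i]] <- data.frame(a = pairs$a[i], b = pairs$b[i],
                            t(as.matrix(r$correct_by_k)),
                            distinct = r$distinct, best_k = r$best_k)
  }
  tab <- do.call(rbind, rows)
  hit <- tab[tab$distinct, ]
  ev <- evidence_rows(hit$a, hit$b, "discriminant",
                      paste0("k=", hit$best_k), hit$best_k, NA_real_)
  res <- distinctness_result(ids, pd, ev, criterion = "discriminant")
  attr(res, "pair_table") <- tab
  res
}
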