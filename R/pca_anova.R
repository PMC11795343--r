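#' Column-centered PCA of bulk allele frequencies
#'
#' Singular-value decomposition of the column-centered (not variance-scaled)
#' samples x markers matrix. Frequencies share a common [0, 1] scale, so
#' unit-variance scaling would only up-weight markers near the MAF threshold.
#' Each axis is oriented so that its largest-magnitude loading is positive,
#' making score signs reproducible under marker permutation.
#'
#' @param freqs complete (imputed) samples x markers numeric matrix.
#' @return list of class `pca_model` with `center` (per-marker means),
#'   `scores` (samples x axes), `loadings` (markers x axes), `eigenvalues`
#'   (variance per axis, non-increasing), `n_axes`, `flag`.
#' @export
center_and_pca <- function(freqs) {
  check_freq_matrix(freqs)
  stop_if(anyNA(freqs), "PCA needs a complete (imputed) matrix")
  stop_if(nrow(freqs) < 2, "need at least 2 samples")
  center <- colMeans(freqs)
  X <- sweep(freqs, 2, center)
  k <- min(nrow(X) - 1L, ncol(X))
  sv <- svd(X, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  ## orient each axis so its largest-|loading| is positive
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sv$u %*% diag(d, k) %*% diag(flip, k)
  loadings <- sv$v %*% diag(flip, k)
  dimnames(scores) <- list(rownames(freqs), paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(colnames(freqs), paste0("PC", seq_len(k)))
  eig <- d^2 / (nrow(X) - 1)
  flag <- if (all(eig < 1e-12)) "constant matrix: all eigenvalues zero" else NULL
  structure(list(center = center, scores = scores, loadings = loadings,
                 eigenvalues = eig, n_axes = k, flag = flag),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  pct <- 100 * x$eigenvalues / max(sum(x$eigenvalues), .Machine$double.eps)
  cat(sprintf("pca_model: %d samples, %d axes; leading axes explain %s%%\n",
              nrow(x$scores), x$n_axes,
              paste(round(pct[seq_len(min(3, x$n_axes))], 1), collapse = ", ")))
  invisible(x)
}

#' One-way ANOVA with LSD on one axis of PC scores
#'
#' Cultivars are groups and their bulks the replicates; the error term is the
#' within-cultivar (between-bulk) variation. With `b` bulks per cultivar the
#' least significant difference is `t(1 - alpha/2, df_e) sqrt(2 MSE / b)`;
#' unbalanced designs use a per-pair LSD with the harmonic-mean replicate
#' number (flagged). Pairs are distinct on strict exceedance.
#'
#' @param scores numeric vector of PC scores (one per sample).
#' @param labels cultivar label per sample (>= 2 bulks per cultivar).
#' @param alpha significance level (default 0.01).
#' @return list of class `axis_anova` with `F`, `p`, `mse`, `df_e`, `lsd`,
#'   `means`, `distinct` (cultivars x cultivars logical), `flag`.
#' @export
oneway_anova_pc <- function(scores, labels, alpha = 0.01) {
  labels <- factor(labels)
  stop_if(any(table(labels) < 2), "every cultivar needs >= 2 bulks")
  fit <- stats::aov(scores ~ labels)
  an <- suppressWarnings(stats::anova(fit))  # perfect-fit warning handled below
  mse <- an["Residuals", "Mean Sq"]
  df_e <- an["Residuals", "Df"]
  means <- tapply(scores, labels, mean)
  ns <- table(labels)
  flag <- NULL
  tq <- stats::qt(1 - alpha / 2, df_e)
  if (length(unique(ns)) == 1) {
    lsd <- tq * sqrt(2 * max(mse, 0) / ns[1])
    lsd_pair <- matrix(lsd, length(means), length(means))
  } else {
    flag <- "unbalanced bulk counts: per-pair harmonic-mean LSD"
    lsd_pair <- tq * sqrt(max(mse, 0) * outer(1 / as.numeric(ns),
                                              1 / as.numeric(ns), "+"))
    lsd <- stats::median(lsd_pair[upper.tri(lsd_pair)])
  }
  if (mse < .Machine$double.eps)
    flag <- c(flag, "zero within-cultivar variance")
  distinct <- abs(outer(means, means, "-")) > lsd_pair
  diag(distinct) <- FALSE
  dimnames(distinct) <- list(names(means), names(means))
  structure(list(F = an["labels", "F value"], p = an["labels", "Pr(>F)"],
                 mse = mse, df_e = df_e, lsd = unname(lsd), means = means,
                 distinct = distinct, flag = flag),
            class = "axis_anova")
}

#' Sequential per-axis distinctness scan
#'
#' Scans PC axes in order of decreasing eigenvalue, running
#' [oneway_anova_pc()] on each and accumulating distinct pairs. An axis
#' "observes cultivar differences" when it adds at least one previously
#' non-distinct pair (default rule) or, under `stop_rule = "significant_F"`,
#' when its cultivar F test is significant at `alpha`. Scanning stops after
#' `stop_after` consecutive axes observing no differences, or at the last
#' informative axis (eigenvalue >= 1e-12). The evidence records, per pair,
#' the first axis that distinguished it.
#'
#' @param pca `pca_model` from [center_and_pca()].
#' @param labels cultivar label per sample (row of `pca$scores`).
#' @param alpha LSD significance level (default 0.01).
#' @param stop_after consecutive uninformative axes tolerated (default 3).
#' @param stop_rule `"new_pairs"` or `"significant_F"`.
#' @return `distinctness_result` with attributes `axes_used` (number of axes
#'   scanned) and `axis_table` (per-axis F, p, MSE, LSD, new pairs).
#' @export
sequential_axis_distinctness <- function(pca, labels, alpha = 0.01,
                                         stop_after = 3L,
                                         stop_rule = c("new_pairs",
                                                       "significant_F")) {
  stop_rule <- match.arg(stop_rule)
  labels <- as.character(labels)
  ids <- sort(unique(labels))
  C <- length(ids)
  pd <- matrix(FALSE, C, C, dimnames = list(ids, ids))
  first_axis <- matrix(NA_integer_, C, C, dimnames = list(ids, ids))
  scan <- which(pca$eigenvalues >= 1e-12)
  rows <- list()
  idle <- 0L
  used <- 0L
  for (ax in scan) {
    a <- oneway_anova_pc(pca$scores[, ax], labels, alpha = alpha)
    dm <- a$distinct[ids, ids]
    new <- dm & !pd
    n_new <- sum(new[upper.tri(new)])
    first_axis[new & is.na(first_axis)] <- ax
    pd <- pd | dm
    used <- ax
    rows[[length(rows) + 1]] <- data.frame(
      axis = ax, eigenvalue = pca$eigenvalues[ax], F = a$F, p = a$p,
      mse = a$mse, df_e = a$df_e, lsd = a$lsd, n_new_pairs = n_new,
      n_cum_pairs = sum(pd[upper.tri(pd)]))
    informative <- if (stop_rule == "new_pairs") n_new > 0 else a$p < alpha
    idle <- if (informative) 0L else idle + 1L
    if (idle >= stop_after) break
  }
  hit <- which(pd & upper.tri(pd), arr.ind = TRUE)
  ev <- evidence_rows(ids[hit[, 1]], ids[hit[, 2]], "pca_anova",
                      paste0("PC", first_axis[hit]), NA_real_, alpha)
  res <- distinctness_result(ids, pd, ev, criterion = "pca_anova")
  attr(res, "axes_used") <- used
  attr(res, "axis_table") <- do.call(rbind, rows)
  res
}

#' PCA + sequential ANOVA distinctness criterion
#'
#' Convenience wrapper: centered PCA of the bulk frequency matrix followed by
#' the sequential per-axis scan, mapping samples to cultivars via metadata.
#'
#' @param freqs complete samples x markers frequency matrix.
#' @param meta [sample_meta()] table covering the rownames of `freqs`.
#' @inheritParams sequential_axis_distinctness
#' @return `distinctness_result` (see [sequential_axis_distinctness()]).
#' @export
pca_anova_distinctness <- function(freqs, meta, alpha = 0.01, stop_after = 3L,
                                   stop_rule = "new_pairs") {
  check_meta(meta, rownames(freqs))
  labels <- meta$cultivar_id[match(rownames(freqs), meta$sample_id)]
  pca <- center_and_pca(freqs)
  sequential_axis_distinctness(pca, labels, alpha = alpha,
                               stop_after = stop_after, stop_rule = stop_rule)
}

#' Shapiro-Wilk normality check of PC scores
#'
#' Report-only diagnostic of the per-axis normality assumption behind the
#' LSD; never alters distinctness calls. Constant axes yield `NA` (flagged).
#'
#' @param scores samples x axes score matrix (or a single numeric vector).
#' @param axes axes to check (default: all with >= 3 values).
#' @return data.frame with `axis`, `W`, `p`, `flag`.
#' @export
shapiro_wilk_check <- function(scores, axes = NULL) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1)
  axes <- axes %||% seq_len(ncol(scores))
  out <- lapply(axes, function(j) {
    x <- scores[, j]
    if (length(x) < 3 || stats::sd(x) < .Machine$double.eps)
      return(data.frame(axis = j, W = NA_real_, p = NA_real_,
                        flag = "degenerate"))
    s <- stats::shapiro.test(x)
    data.frame(axis = j, W = unname(s$statistic), p = s$p.value, flag = "")
  })
  do.call(rbind, out)
}
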