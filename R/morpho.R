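#' Aggregate plant-level records to plot means
#'
#' Spaced-plant trials record individual plants; the analysis works on plot
#' means. Rows are averaged per (block, cultivar); for binary plant-level
#' traits (e.g. a flower-color indicator) the mean is the plot fraction.
#' Input already at plot level (no `plant` column) passes through unchanged.
#'
#' @param table data.frame with `block`, `cultivar`, optionally `plant`, and
#'   trait columns.
#' @param schema `trait_schema`.
#' @return `trait_plot_table` (one row per block x cultivar).
#' @export
aggregate_plot_means <- function(table, schema) {
  if (!"plant" %in% names(table))
    return(validate_trait_table(as.data.frame(table), schema))
  key <- interaction(table$block, table$cultivar, drop = TRUE)
  stop_if(any(tabulate(key) == 0), "empty plot encountered")
  agg <- stats::aggregate(table[, schema$name, drop = FALSE],
                          by = list(block = table$block,
                                    cultivar = table$cultivar), FUN = mean)
  validate_trait_table(agg, schema)
}

#' Randomized-complete-block ANOVA for one trait
#'
#' Two-way additive fixed model (cultivar + block) on plot values.
#' Proportion traits are angular-transformed (`asin(sqrt(y))`) before
#' fitting, per standard practice for plot fractions; all reported means are
#' on the analysis scale. The error degrees of freedom are
#' `(C - 1)(B - 1)`.
#'
#' @param table `trait_plot_table`.
#' @param trait trait name.
#' @param alpha working significance level for the LSD (default 0.01).
#' @return list of class `trait_anova` with `trait`, `transform`, `means`
#'   (named cultivar means, analysis scale), `mse`, `df_e`, `F`, `p`,
#'   `n_blocks`, `lsd`, `alpha`, `flag`.
#' @export
rcbd_anova <- function(table, trait, alpha = 0.01) {
  schema <- attr(table, "schema")
  stop_if(is.null(schema) || !trait %in% schema$name,
          "trait '", trait, "' not in the table schema")
  kind <- schema$kind[schema$name == trait]
  d <- data.frame(y = table[[trait]],
                  cultivar = factor(table$cultivar),
                  block = factor(table$block))
  B <- nlevels(d$block)
  C <- nlevels(d$cultivar)
  stop_if(B < 2, "need at least 2 blocks for an error term")
  transform <- "none"
  if (kind == "proportion") {
    d$y <- asin(sqrt(d$y))
    transform <- "angular"
  }
  fit <- stats::aov(y ~ cultivar + block, data = d)
  an <- suppressWarnings(stats::anova(fit))  # perfect-fit warning handled below
  mse <- an["Residuals", "Mean Sq"]
  df_e <- an["Residuals", "Df"]
  means <- tapply(d$y, d$cultivar, mean)
  flag <- NULL
  if (mse < .Machine$double.eps) {
    flag <- "zero error mean square; F unbounded"
    Fval <- Inf
    p <- 0
  } else {
    Fval <- an["cultivar", "F value"]
    p <- an["cultivar", "Pr(>F)"]
  }
  lsd <- stats::qt(1 - alpha / 2, df_e) * sqrt(2 * max(mse, 0) / B)
  structure(list(trait = trait, transform = transform,
                 means = means, mse = mse, df_e = df_e, F = Fval, p = p,
                 n_blocks = B, lsd = lsd, alpha = alpha, flag = flag),
            class = "trait_anova")
}

#' @export
print.trait_anova <- function(x, ...) {
  cat(sprintf("RCBD ANOVA for %s (%s transform): F = %.3f, p = %.3g, MSE = %.4g (df %d), LSD(%g) = %.4g\n",
              x$trait, x$transform, x$F, x$p, x$mse, x$df_e, x$alpha, x$lsd))
  if (!is.null(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Pairwise distinctness by Fisher's LSD
#'
#' A pair of cultivars differs for the trait when the absolute difference of
#' their means strictly exceeds `LSD = t(1 - alpha/2, df_e) sqrt(2 MSE / B)`.
#' With a zero error mean square every unequal pair of means is declared
#' distinct (flagged upstream).
#'
#' @param anova `trait_anova` from [rcbd_anova()] (or any list with `means`,
#'   `mse`, `df_e`, `n_blocks`).
#' @param alpha significance level; defaults to the level stored in `anova`.
#' @return symmetric logical matrix (cultivars x cultivars) with attribute
#'   `lsd`.
#' @export
lsd_pairwise_distinct <- function(anova, alpha = NULL) {
  alpha <- alpha %||% anova$alpha %||% 0.01
  lsd <- stats::qt(1 - alpha / 2, anova$df_e) *
    sqrt(2 * max(anova$mse, 0) / anova$n_blocks)
  m <- abs(outer(anova$means, anova$means, "-")) > lsd
  diag(m) <- FALSE
  attr(m, "lsd") <- lsd
  m
}

#' Pairwise distinctness on a 1-9 rating scale
#'
#' For traits scored on a discrete 1-9 scale, a pair of cultivars is
#' considered to differ when their mean ratings (over blocks) differ by more
#' than `threshold` units (strictly; default 1.5).
#'
#' @param table `trait_plot_table`.
#' @param trait rating trait name.
#' @param threshold rating-difference threshold.
#' @return symmetric logical matrix with attribute `threshold`.
#' @export
rating_scale_distinct <- function(table, trait, threshold = 1.5) {
  schema <- attr(table, "schema")
  stop_if(is.null(schema) || schema$kind[schema$name == trait] != "rating_1_9",
          "'", trait, "' is not a rating_1_9 trait")
  means <- tapply(table[[trait]], table$cultivar, mean)
  m <- abs(outer(means, means, "-")) > threshold
  diag(m) <- FALSE
  attr(m, "threshold") <- threshold
  m
}

#' Combine per-trait distinctness matrices
#'
#' A pair of cultivars is distinct when at least one trait distinguishes it;
#' the evidence lists the contributing traits per pair.
#'
#' @param matrices named list of symmetric logical matrices over a common
#'   cultivar set (one per trait).
#' @param criterion criterion label for the result.
#' @return `distinctness_result`.
#' @export
combine_trait_distinctness <- function(matrices, criterion = "morpho") {
  stop_if(length(matrices) < 1, "need at least one trait matrix")
  ids <- rownames(matrices[[1]])
  pd <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  ev <- list()
  for (nm in names(matrices)) {
    m <- matrices[[nm]]
    stop_if(!identical(sort(rownames(m)), sort(ids)),
            "inconsistent cultivar sets across trait matrices")
    m <- m[ids, ids]
    pd <- pd | m
    hit <- which(m & upper.tri(m), arr.ind = TRUE)
    ev[[nm]] <- evidence_rows(ids[hit[, 1]], ids[hit[, 2]], criterion, nm,
                              NA_real_, attr(matrices[[nm]], "lsd") %||%
                                attr(matrices[[nm]], "threshold") %||% NA_real_)
  }
  distinctness_result(ids, pd, do.call(rbind, ev), criterion = criterion)
}

#' Full morphophysiological distinctness criterion
#'
#' Applies, per trait: the rating rule (difference > `rating_threshold`
#' units) to `rating_1_9` traits, and an RCBD ANOVA with Fisher's LSD at
#' `alpha` to quantitative and (angular-transformed) proportion traits; then
#' combines traits by union.
#'
#' @param table `trait_plot_table`.
#' @param alpha LSD significance level (default 0.01).
#' @param rating_threshold rating-difference threshold (default 1.5).
#' @return `distinctness_result` with attribute `anovas` (per-trait
#'   `trait_anova` objects for the ANOVA-tested traits).
#' @export
morpho_distinctness <- function(table, alpha = 0.01, rating_threshold = 1.5) {
  schema <- attr(table, "schema")
  stop_if(is.null(schema), "table carries no trait schema")
  mats <- list()
  anovas <- list()
  for (i in seq_len(nrow(schema))) {
    tr <- schema$name[i]
    if (schema$kind[i] == "rating_1_9") {
      mats[[tr]] <- rating_scale_distinct(table, tr, rating_threshold)
    } else {
      a <- rcbd_anova(table, tr, alpha = alpha)
      anovas[[tr]] <- a
      mats[[tr]] <- lsd_pairwise_distinct(a)
    }
  }
  res <- combine_trait_distinctness(mats, criterion = "morpho")
  attr(res, "anovas") <- anovas
  res
}

#' Phenotypic correlations between traits
#'
#' Pearson correlations of cultivar means (over blocks) on the raw scale,
#' with two-sided t tests on `C - 2` degrees of freedom and conventional
#' significance flags.
#'
#' @param table `trait_plot_table`.
#' @return list of class `trait_correlations` with matrices `r`, `p` and
#'   character matrix `flag` (`""`, `"*"`, `"**"`, `"***"`); zero-variance
#'   traits yield `NA` with flag `"undef"`.
#' @export
trait_correlations <- function(table) {
  schema <- attr(table, "schema")
  stop_if(is.null(schema), "table carries no trait schema")
  means <- sapply(schema$name, function(tr) tapply(table[[tr]], table$cultivar, mean))
  C <- nrow(means)
  stop_if(C < 3, "need at least 3 cultivars")
  sds <- apply(means, 2, stats::sd)
  r <- suppressWarnings(stats::cor(means))
  tstat <- r * sqrt(C - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), C - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  flag <- matrix("", ncol(means), ncol(means), dimnames = dimnames(r))
  flag[p < 0.05] <- "*"
  flag[p < 0.01] <- "**"
  flag[p < 0.001] <- "***"
  undef <- sds < .Machine$double.eps
  r[undef, ] <- r[, undef] <- NA
  p[undef, ] <- p[, undef] <- NA
  flag[undef, ] <- flag[, undef] <- "undef"
  diag(r) <- ifelse(undef, NA, 1)
  structure(list(r = r, p = p, flag = flag), class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, ...) {
  out <- matrix(paste0(formatC(x$r, digits = 2, format = "f"), x$flag),
                nrow(x$r), dimnames = dimnames(x$r))
  print(out, quote = FALSE)
  invisible(x)
}
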