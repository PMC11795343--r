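#' Marker filter configuration
#'
#' @param min_reads minimum reads per (sample, marker) cell; shallower cells
#'   become missing.
#' @param max_missing maximum tolerated fraction of missing cells per marker.
#' @param maf_min minor-allele-frequency threshold on the folded mean
#'   frequency over samples (markers with `min(f, 1-f) <= maf_min` dropped).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_reads, max_missing, maf_min = 0.05) {
  stop_if(min_reads < 1, "min_reads must be >= 1")
  stop_if(max_missing <= 0 || max_missing > 1, "max_missing must be in (0, 1]")
  stop_if(maf_min < 0 || maf_min >= 0.5, "maf_min must be in [0, 0.5)")
  structure(list(min_reads = as.integer(min_reads), max_missing = max_missing,
                 maf_min = maf_min),
            class = "filter_config")
}

#' @export
format.filter_config <- function(x, ...) {
  sprintf("reads>=%d_miss<=%g_maf>%g", x$min_reads, x$max_missing, x$maf_min)
}

#' Enumerate filter configurations
#'
#' Cartesian product of depth and missing-rate thresholds, in deterministic
#' order (`min_reads` ascending, then `max_missing` ascending). The standard
#' screen uses depths {10, 20, 30, 40} and missing rates
#' {1%, 5%, 10%, 20%, 30%}: 20 configurations.
#'
#' @param min_reads_set,max_missing_set threshold choices.
#' @param maf_min shared MAF threshold.
#' @return list of `filter_config` objects.
#' @export
enumerate_filter_configs <- function(min_reads_set = c(10L, 20L, 30L, 40L),
                                     max_missing_set = c(0.01, 0.05, 0.10,
                                                         0.20, 0.30),
                                     maf_min = 0.05) {
  stop_if(length(min_reads_set) < 1 || length(max_missing_set) < 1,
          "threshold sets must be non-empty")
  grid <- expand.grid(max_missing = sort(max_missing_set),
                      min_reads = sort(min_reads_set))
  grid <- grid[order(grid$min_reads, grid$max_missing), ]
  lapply(seq_len(nrow(grid)), function(i)
    filter_config(grid$min_reads[i], grid$max_missing[i], maf_min))
}

#' Apply a filter configuration to read counts
#'
#' Five-stage pipeline producing a complete allele-frequency matrix:
#' 1. cells with `ref + alt < min_reads` become missing;
#' 2. frequency `alt / (ref + alt)` for surviving cells;
#' 3. markers with missing fraction `> max_missing` are dropped;
#' 4. markers whose folded mean frequency `min(f, 1-f)` (mean over non-missing
#'    samples) is `<= maf_min` are dropped;
#' 5. remaining missing cells are imputed with the marker mean frequency.
#'
#' @param counts `read_count_matrix`.
#' @param cfg `filter_config`.
#' @return list of class `filtered_freqs` with `freq` (complete samples x
#'   retained-markers matrix), `retained` (marker ids in input order),
#'   `attrition` (markers surviving each stage), `mean_depth` (mean depth of
#'   retained cells before masking), `cfg`.
#' @export
apply_filter_config <- function(counts, cfg) {
  depth <- counts$ref + counts$alt
  masked <- depth < cfg$min_reads
  freq <- counts$alt / depth
  freq[masked] <- NA_real_
  miss_frac <- colMeans(is.na(freq))
  keep_miss <- miss_frac <= cfg$max_missing
  fbar <- colMeans(freq, na.rm = TRUE)
  folded <- pmin(fbar, 1 - fbar)
  keep_maf <- keep_miss & !is.na(folded) & folded > cfg$maf_min
  attrition <- c(input = ncol(freq),
                 after_missing_rate = sum(keep_miss),
                 after_maf = sum(keep_maf))
  stop_if(!any(keep_maf),
          "all markers filtered out (attrition: ",
          paste(names(attrition), attrition, sep = "=", collapse = ", "), ")")
  f <- freq[, keep_maf, drop = FALSE]
  ## mean imputation: conserves each marker's mean frequency
  for (j in which(colSums(is.na(f)) > 0))
    f[is.na(f[, j]), j] <- mean(f[, j], na.rm = TRUE)
  structure(list(freq = f,
                 retained = counts$marker_ids[keep_maf],
                 attrition = attrition,
                 mean_depth = mean(depth[, keep_maf][!masked[, keep_maf]]),
                 cfg = cfg),
            class = "filtered_freqs")
}

#' @export
print.filtered_freqs <- function(x, ...) {
  cat(sprintf("filtered_freqs [%s]: %d markers retained (of %d), mean depth %.1f\n",
              format(x$cfg), length(x$retained), x$attrition["input"],
              x$mean_depth))
  invisible(x)
}

#' Grid search over filter configurations
#'
#' Runs a distinctness criterion under every configuration and selects the
#' optimum: the configuration with the most distinct pairs, ties broken by
#' more completely distinct cultivars, then fewer retained markers, then
#' enumeration order. Configurations on which the criterion fails are
#' recorded and excluded from the optimum.
#'
#' @param counts `read_count_matrix`.
#' @param configs list of `filter_config` (e.g.
#'   [enumerate_filter_configs()]).
#' @param criterion function taking the complete frequency matrix and
#'   returning a `distinctness_result`.
#' @return list of class `filter_grid_result` with `table` (one row per
#'   config: thresholds, markers retained, mean depth, counts, error) and
#'   `optimum` (the selected `filter_config`), `optimum_index`,
#'   `optimum_result`.
#' @export
grid_search <- function(counts, configs, criterion) {
  stop_if(length(configs) < 1, "need at least one configuration")
  rows <- vector("list", length(configs))
  results <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    row <- data.frame(min_reads = cfg$min_reads, max_missing = cfg$max_missing,
                      maf_min = cfg$maf_min, n_markers = NA_integer_,
                      mean_depth = NA_real_, n_distinct_pairs = NA_integer_,
                      n_completely_distinct = NA_integer_,
                      error = NA_character_)
    out <- tryCatch({
      ff <- apply_filter_config(counts, cfg)
      res <- criterion(ff$freq)
      row$n_markers <- length(ff$retained)
      row$mean_depth <- ff$mean_depth
      row$n_distinct_pairs <- res$n_distinct_pairs
      row$n_completely_distinct <- res$n_completely_distinct
      results[[i]] <- res
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    rows[[i]] <- out
  }
  tab <- do.call(rbind, rows)
  ok <- which(is.na(tab$error))
  stop_if(length(ok) == 0, "criterion failed on every configuration")
  ord <- ok[order(-tab$n_distinct_pairs[ok], -tab$n_completely_distinct[ok],
                  tab$n_markers[ok], ok)]
  best <- ord[1]
  structure(list(table = tab, optimum = configs[[best]],
                 optimum_index = best, optimum_result = results[[best]]),
            class = "filter_grid_result")
}

#' @export
print.filter_grid_result <- function(x, ...) {
  cat("Filter grid search over", nrow(x$table), "configurations\n")
  print(x$table, row.names = FALSE)
  cat("optimum:", format(x$optimum), "\n")
  invisible(x)
}
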