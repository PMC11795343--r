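#' Pairwise distinctness result
#'
#' Container for the verdict of a distinctness criterion over a set of
#' cultivars: a symmetric boolean pair matrix, per-pair supporting evidence,
#' and summary counts. A cultivar is "completely distinct" when it is distinct
#' from every other cultivar.
#'
#' @param cultivar_ids character vector of cultivar identifiers.
#' @param pair_distinct symmetric logical matrix (cultivars x cultivars) with
#'   `FALSE` diagonal; `NULL` means no pair distinct.
#' @param evidence data.frame with columns `a`, `b`, `criterion`, `feature`,
#'   `statistic`, `p_or_threshold` describing what distinguished each pair.
#' @param criterion single string naming the criterion that produced the
#'   result.
#' @return object of class `distinctness_result` with elements
#'   `cultivar_ids`, `pair_distinct`, `evidence`, `criterion`,
#'   `n_pairs`, `n_distinct_pairs`, `completely_distinct`,
#'   `n_completely_distinct`.
#' @export
distinctness_result <- function(cultivar_ids, pair_distinct = NULL,
                                evidence = NULL, criterion = "unnamed") {
  ids <- as.character(cultivar_ids)
  stop_if(anyDuplicated(ids) > 0, "cultivar ids must be unique")
  C <- length(ids)
  if (is.null(pair_distinct)) {
    pair_distinct <- matrix(FALSE, C, C, dimnames = list(ids, ids))
  }
  stop_if(!is.matrix(pair_distinct) || !is.logical(pair_distinct) ||
            nrow(pair_distinct) != C || ncol(pair_distinct) != C,
          "pair_distinct must be a CxC logical matrix")
  dimnames(pair_distinct) <- list(ids, ids)
  stop_if(!isTRUE(all(pair_distinct == t(pair_distinct))),
          "pair_distinct must be symmetric")
  diag(pair_distinct) <- FALSE
  if (is.null(evidence)) {
    evidence <- data.frame(a = character(), b = character(),
                           criterion = character(), feature = character(),
                           statistic = numeric(), p_or_threshold = numeric(),
                           stringsAsFactors = FALSE)
  }
  comp <- if (C > 1) apply(pair_distinct | diag(TRUE, C), 1, all) else
    stats::setNames(logical(C), ids)
  res <- list(cultivar_ids = ids,
              pair_distinct = pair_distinct,
              evidence = evidence,
              criterion = criterion,
              n_pairs = (C * (C - 1L)) %/% 2L,
              n_distinct_pairs = sum(pair_distinct[upper.tri(pair_distinct)]),
              completely_distinct = ids[comp],
              n_completely_distinct = sum(comp))
  class(res) <- "distinctness_result"
  res
}

#' @export
print.distinctness_result <- function(x, ...) {
  cat("Distinctness result [", x$criterion, "]\n", sep = "")
  cat(sprintf("  %d cultivars, %d/%d distinct pairs (%.1f%%)\n",
              length(x$cultivar_ids), x$n_distinct_pairs, x$n_pairs,
              100 * x$n_distinct_pairs / max(1, x$n_pairs)))
  cat(sprintf("  %d completely distinct cultivar(s)", x$n_completely_distinct))
  if (x$n_completely_distinct > 0)
    cat(": ", paste(x$completely_distinct, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Union of distinctness results
#'
#' Combines several criteria: a pair is distinct under the combination when it
#' is distinct under at least one component criterion. Evidence rows are
#' concatenated.
#'
#' @param results list of `distinctness_result` objects over the same
#'   cultivar set.
#' @param criterion name for the combined result.
#' @return `distinctness_result`.
#' @export
combine_distinctness <- function(results, criterion = "combined") {
  stop_if(length(results) < 1, "need at least one result")
  ids <- results[[1]]$cultivar_ids
  for (r in results)
    stop_if(!identical(sort(r$cultivar_ids), sort(ids)),
            "all results must share the same cultivar set")
  pd <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  ev <- list()
  for (r in results) {
    pd <- pd | r$pair_distinct[ids, ids]
    ev[[length(ev) + 1]] <- r$evidence
  }
  distinctness_result(ids, pd, do.call(rbind, ev), criterion = criterion)
}

## evidence-row helper shared by the criterion modules
evidence_rows <- function(a, b, criterion, feature, statistic, p_or_threshold) {
  if (length(a) == 0)
    return(data.frame(a = character(), b = character(), criterion = character(),
                      feature = character(), statistic = numeric(),
                      p_or_threshold = numeric(), stringsAsFactors = FALSE))
  data.frame(a = a, b = b, criterion = criterion, feature = feature,
             statistic = statistic, p_or_threshold = p_or_threshold,
             stringsAsFactors = FALSE)
}
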