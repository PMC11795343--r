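#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' Enumerate unordered cultivar pairs
#'
#' @param ids character vector of cultivar identifiers.
#' @return data.frame with columns `a` and `b`, one row per unordered pair,
#'   in lexicographic enumeration order (`a` before `b` in `ids` order).
#' @examples
#' cultivar_pairs(c("A", "B", "C"))
#' @export
cultivar_pairs <- function(ids) {
  ids <- as.character(ids)
  stop_if(anyDuplicated(ids) > 0, "cultivar ids must be unique")
  n <- length(ids)
  if (n < 2) return(data.frame(a = character(), b = character()))
  idx <- utils::combn(n, 2)
  data.frame(a = ids[idx[1, ]], b = ids[idx[2, ]], stringsAsFactors = FALSE)
}

## local RNG scope: runs `expr` under `seed` (if non-NULL) and restores the
## caller's RNG state afterwards, so simulation calls do not perturb each other
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## derive a distinct child seed from a base seed; kept < 2^31
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}

check_freq_matrix <- function(freq) {
  stop_if(!is.matrix(freq) || !is.numeric(freq),
          "allele frequencies must be a numeric matrix (samples x markers)")
  stop_if(is.null(rownames(freq)), "frequency matrix needs sample ids as rownames")
  rng <- range(freq, na.rm = TRUE)
  stop_if(rng[1] < 0 || rng[2] > 1, "allele frequencies must lie in [0, 1]")
  invisible(freq)
}

check_meta <- function(meta, sample_ids = NULL) {
  stop_if(!is.data.frame(meta) ||
            !all(c("sample_id", "cultivar_id", "bulk_index") %in% names(meta)),
          "meta must be a data.frame with sample_id, cultivar_id, bulk_index")
  stop_if(anyDuplicated(meta$sample_id) > 0, "sample_id must be unique")
  stop_if(any(meta$bulk_index < 1), "bulk_index must be >= 1")
  if (!is.null(sample_ids))
    stop_if(!all(sample_ids %in% meta$sample_id),
            "metadata is missing some samples present in the data")
  invisible(meta)
}

#' Sample metadata constructor
#'
#' Builds the bulk-sample metadata table linking sequenced DNA bulks to
#' cultivars. Each bulk of pooled plants acts as one replicate of its cultivar.
#'
#' @param sample_id unique sample identifiers.
#' @param cultivar_id cultivar each bulk belongs to.
#' @param bulk_index replicate index of the bulk within its cultivar (>= 1).
#' @param n_plants number of plants pooled per bulk (default 200).
#' @return data.frame of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, cultivar_id, bulk_index, n_plants = 200L) {
  meta <- data.frame(sample_id = as.character(sample_id),
                     cultivar_id = as.character(cultivar_id),
                     bulk_index = as.integer(bulk_index),
                     n_plants = as.integer(n_plants),
                     stringsAsFactors = FALSE)
  check_meta(meta)
  class(meta) <- c("sample_meta", "data.frame")
  meta
}
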