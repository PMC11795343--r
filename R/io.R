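#' Read-count matrix constructor
#'
#' Paired reference/alternate read counts for bulked samples at biallelic
#' markers. A cell with `ref + alt == 0` is treated as missing throughout the
#' package (never a sentinel frequency).
#'
#' @param ref,alt integer matrices (samples x markers) of reference and
#'   alternate allele read counts, with sample ids as rownames and marker ids
#'   as colnames.
#' @return object of class `read_count_matrix` with elements `ref`, `alt`,
#'   `sample_ids`, `marker_ids`.
#' @export
read_count_matrix <- function(ref, alt) {
  stop_if(!is.matrix(ref) || !is.matrix(alt), "ref and alt must be matrices")
  stop_if(!identical(dim(ref), dim(alt)), "ref and alt dimensions differ")
  stop_if(is.null(rownames(ref)) || is.null(colnames(ref)),
          "ref needs sample ids (rownames) and marker ids (colnames)")
  stop_if(any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE),
          "read counts must be non-negative")
  ref[is.na(ref)] <- 0L
  alt[is.na(alt)] <- 0L
  storage.mode(ref) <- "integer"
  storage.mode(alt) <- "integer"
  dimnames(alt) <- dimnames(ref)
  x <- list(ref = ref, alt = alt,
            sample_ids = rownames(ref), marker_ids = colnames(ref))
  class(x) <- "read_count_matrix"
  x
}

#' @export
print.read_count_matrix <- function(x, ...) {
  depth <- x$ref + x$alt
  cat(sprintf("read_count_matrix: %d samples x %d markers, mean depth %.1f, %.1f%% missing cells\n",
              length(x$sample_ids), length(x$marker_ids),
              mean(depth[depth > 0]), 100 * mean(depth == 0)))
  invisible(x)
}

#' Read bulked-sample read counts
#'
#' Reads paired ref/alt read counts from either a long-format TSV
#' (`sample_id`, `marker_id`, `ref_reads`, `alt_reads`) or a VCF with a
#' per-sample allele-depth (`AD`) field. Only biallelic VCF records are used;
#' multiallelic records are skipped with a warning. A (sample, marker) pair
#' absent from a TSV becomes a missing (0, 0) cell.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return `read_count_matrix`.
#' @export
read_read_counts <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") read_read_counts_tsv(path) else read_read_counts_vcf(path)
}

read_read_counts_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "marker_id", "ref_reads", "alt_reads")
  stop_if(!all(need %in% names(d)),
          "long TSV needs columns: ", paste(need, collapse = ", "))
  stop_if(any(d$ref_reads < 0) || any(d$alt_reads < 0),
          "negative read counts in ", path)
  key <- paste(d$sample_id, d$marker_id, sep = "\r")
  stop_if(anyDuplicated(key) > 0, "duplicate (sample, marker) rows in ", path)
  samples <- unique(d$sample_id)
  markers <- unique(d$marker_id)
  ref <- matrix(0L, length(samples), length(markers),
                dimnames = list(samples, markers))
  alt <- ref
  i <- cbind(match(d$sample_id, samples), match(d$marker_id, markers))
  ref[i] <- as.integer(d$ref_reads)
  alt[i] <- as.integer(d$alt_reads)
  read_count_matrix(ref, alt)
}

read_read_counts_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt_field <- vcfR::getALT(v)
  biallelic <- !grepl(",", alt_field) & nzchar(alt_field) & alt_field != "."
  if (any(!biallelic))
    warning(sum(!biallelic), " non-biallelic VCF record(s) skipped")
  stop_if(!any(biallelic), "no biallelic records in ", path)
  ad <- vcfR::extract.gt(v, element = "AD")
  stop_if(is.null(ad), "VCF has no AD (allele depth) field")
  ad <- ad[biallelic, , drop = FALSE]
  ids <- paste(vcfR::getCHROM(v), vcfR::getPOS(v), sep = "_")[biallelic]
  parse_part <- function(k) {
    x <- suppressWarnings(
      as.integer(vapply(strsplit(ifelse(is.na(ad), "0,0", ad), ","),
                        function(p) if (length(p) >= k) p[k] else "0",
                        character(1))))
    x[is.na(x)] <- 0L
    matrix(x, nrow = nrow(ad), dimnames = dimnames(ad))
  }
  ref <- t(parse_part(1))
  alt <- t(parse_part(2))
  colnames(ref) <- colnames(alt) <- ids
  read_count_matrix(ref, alt)
}

#' Write read counts as long-format TSV
#'
#' The canonical exchange format: one row per non-missing (sample, marker)
#' cell with columns `sample_id`, `marker_id`, `ref_reads`, `alt_reads`.
#' Missing (0, 0) cells are omitted and re-created on read.
#'
#' @param counts `read_count_matrix`.
#' @param path output path.
#' @export
write_read_counts <- function(counts, path) {
  depth <- counts$ref + counts$alt
  keep <- which(depth > 0, arr.ind = TRUE)
  d <- data.frame(sample_id = counts$sample_ids[keep[, 1]],
                  marker_id = counts$marker_ids[keep[, 2]],
                  ref_reads = counts$ref[keep],
                  alt_reads = counts$alt[keep])
  d <- d[order(match(d$sample_id, counts$sample_ids),
               match(d$marker_id, counts$marker_ids)), ]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Trait schema constructor
#'
#' Declares the traits of a spaced-plant trial: the trait kind drives both the
#' simulation model and the analysis (angular transform for proportions, the
#' 1.5-unit rule for 1-9 ratings).
#'
#' @param name trait names.
#' @param kind one of `"quantitative"`, `"rating_1_9"`, `"proportion"` per
#'   trait.
#' @param denominator plants per plot for proportion traits (default 25);
#'   `NA` for other kinds.
#' @return data.frame of class `trait_schema`.
#' @export
trait_schema <- function(name, kind, denominator = NA_integer_) {
  kind <- match.arg(kind, c("quantitative", "rating_1_9", "proportion"),
                    several.ok = TRUE)
  s <- data.frame(name = as.character(name), kind = kind,
                  denominator = as.integer(denominator),
                  stringsAsFactors = FALSE)
  s$denominator[s$kind == "proportion" & is.na(s$denominator)] <- 25L
  s$denominator[s$kind != "proportion"] <- NA_integer_
  class(s) <- c("trait_schema", "data.frame")
  s
}

#' Read a plot-level trait table
#'
#' Expects a TSV with columns `block`, `cultivar`, then one column per trait
#' named in the schema. Proportion traits may be given as fractions in
#' `[0, 1]` or as `"count/denominator"` strings (converted to fractions).
#' Validates the RCBD structure: every (block, cultivar) combination exactly
#' once, ratings within `[1, 9]`, proportions within `[0, 1]`.
#'
#' @param path TSV path.
#' @param schema `trait_schema`.
#' @return data.frame of class `trait_plot_table` with attribute `schema`.
#' @export
read_trait_table <- function(path, schema) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  stop_if(!all(c("block", "cultivar") %in% names(d)),
          "trait table needs 'block' and 'cultivar' columns")
  stop_if(!all(schema$name %in% names(d)), "trait table is missing trait columns: ",
          paste(setdiff(schema$name, names(d)), collapse = ", "))
  for (i in seq_len(nrow(schema))) {
    tr <- schema$name[i]
    v <- d[[tr]]
    if (schema$kind[i] == "proportion" && any(grepl("/", v))) {
      parts <- strsplit(v, "/", fixed = TRUE)
      v <- vapply(parts, function(p) as.numeric(p[1]) /
                    if (length(p) > 1) as.numeric(p[2]) else 1, numeric(1))
    } else v <- as.numeric(v)
    d[[tr]] <- v
  }
  d$block <- as.character(d$block)
  d$cultivar <- as.character(d$cultivar)
  validate_trait_table(d, schema)
}

validate_trait_table <- function(d, schema) {
  key <- paste(d$block, d$cultivar, sep = "\r")
  stop_if(anyDuplicated(key) > 0, "duplicated (block, cultivar) rows")
  full <- expand.grid(block = unique(d$block), cultivar = unique(d$cultivar))
  miss <- !paste(full$block, full$cultivar, sep = "\r") %in% key
  stop_if(any(miss), "incomplete block design: missing ",
          sum(miss), " (block, cultivar) cell(s)")
  for (i in seq_len(nrow(schema))) {
    v <- d[[schema$name[i]]]
    if (schema$kind[i] == "rating_1_9")
      stop_if(any(v < 1 | v > 9, na.rm = TRUE),
              "rating trait '", schema$name[i], "' outside [1, 9]")
    if (schema$kind[i] == "proportion")
      stop_if(any(v < 0 | v > 1, na.rm = TRUE),
              "proportion trait '", schema$name[i], "' outside [0, 1]")
  }
  attr(d, "schema") <- schema
  class(d) <- c("trait_plot_table", "data.frame")
  d
}

#' Write a plot-level trait table as TSV
#' @param table `trait_plot_table`.
#' @param path output path.
#' @export
write_trait_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write distinctness reports
#'
#' Emits, for each named `distinctness_result`, a TSV pair matrix
#' (`<name>_pairs.tsv`) and one JSON summary (`summary.json`) with per-
#' criterion and per-combination counts: number and proportion of distinct
#' pairs and of completely distinct cultivars. Combinations are unions over
#' all non-empty subsets of criteria when 2-4 criteria are supplied.
#'
#' @param results named list of `distinctness_result` objects sharing one
#'   cultivar set.
#' @param path output directory (created if absent).
#' @return invisibly, the summary list written to JSON.
#' @export
write_distinctness_report <- function(results, path) {
  stop_if(length(results) < 1, "need at least one result")
  if (is.null(names(results)) || any(!nzchar(names(results))))
    names(results) <- vapply(results, function(r) r$criterion, character(1))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  stop_if(!dir.exists(path), "cannot create output directory ", path)
  summ <- list()
  one_summary <- function(r) {
    list(n_pairs = r$n_pairs,
         n_distinct_pairs = r$n_distinct_pairs,
         pct_distinct_pairs = round(100 * r$n_distinct_pairs / max(1, r$n_pairs), 1),
         n_completely_distinct = r$n_completely_distinct,
         pct_completely_distinct = round(100 * r$n_completely_distinct /
                                           length(r$cultivar_ids), 1),
         completely_distinct = r$completely_distinct)
  }
  for (nm in names(results)) {
    r <- results[[nm]]
    utils::write.table(r$pair_distinct,
                       file.path(path, paste0(nm, "_pairs.tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
    summ$criteria[[nm]] <- one_summary(r)
  }
  if (length(results) >= 2 && length(results) <= 4) {
    nms <- names(results)
    for (k in 2:length(nms)) {
      for (set in utils::combn(nms, k, simplify = FALSE)) {
        cmb <- combine_distinctness(results[set],
                                    criterion = paste(set, collapse = "+"))
        summ$combinations[[paste(set, collapse = "+")]] <- one_summary(cmb)
      }
    }
  }
  jsonlite::write_json(summ, file.path(path, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summ)
}
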