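#' Marker simulation configuration
#'
#' Parameters for simulating cultivar allele frequencies, finite-plant bulks
#' and pool-seq read counts. The sampling structure mirrors a bulked-sample
#' variety trial: each cultivar is a population with its own allele
#' frequencies; a bulk pools `n_plants` plants, each contributing `ploidy`
#' allele copies; sequencing draws reads binomially from the bulk frequency
#' at a negative-binomially distributed depth.
#'
#' Cultivar differentiation follows the Balding-Nichols model: ancestral
#' frequencies `p ~ Beta(a, b)` and cultivar frequencies
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, so `F` maps directly onto Fst. Two panel
#' presets are provided: `"dartag"` (1770 markers, mean depth 579, 1% missing)
#' and `"gbs"` (17937 markers, mean depth 56, 10% missing).
#'
#' @param n_cultivars number of cultivars (default 18).
#' @param panel `"dartag"` or `"gbs"` preset; sets `n_markers`, `depth_mean`
#'   and `missing_rate` unless overridden.
#' @param n_markers number of biallelic markers.
#' @param fst differentiation parameter F in `[0, 1)`.
#' @param ancestral_beta shape pair (a, b) of the ancestral frequency Beta.
#' @param n_bulks bulks (replicates) per cultivar (default 3).
#' @param n_plants plants pooled per bulk (default 200).
#' @param ploidy allele copies per plant (default 4, autotetraploid).
#' @param depth_mean mean sequencing depth per (sample, marker) cell.
#' @param depth_dispersion negative-binomial size parameter.
#' @param missing_rate probability a cell is zeroed (made missing).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return list of class `marker_sim_config`.
#' @export
marker_sim_config <- function(n_cultivars = 18L, panel = c("dartag", "gbs"),
                              n_markers = NULL, fst = 0.05,
                              ancestral_beta = c(0.7, 0.7),
                              n_bulks = 3L, n_plants = 200L, ploidy = 4L,
                              depth_mean = NULL, depth_dispersion = 5,
                              missing_rate = NULL, seed = NULL) {
  panel <- match.arg(panel)
  preset <- switch(panel,
                   dartag = list(n_markers = 1770L, depth_mean = 579,
                                 missing_rate = 0.01),
                   gbs = list(n_markers = 17937L, depth_mean = 56,
                              missing_rate = 0.10))
  cfg <- list(n_cultivars = as.integer(n_cultivars), panel = panel,
              n_markers = as.integer(n_markers %||% preset$n_markers),
              fst = fst, ancestral_beta = ancestral_beta,
              n_bulks = as.integer(n_bulks), n_plants = as.integer(n_plants),
              ploidy = as.integer(ploidy),
              depth_mean = depth_mean %||% preset$depth_mean,
              depth_dispersion = depth_dispersion,
              missing_rate = missing_rate %||% preset$missing_rate,
              seed = seed)
  stop_if(cfg$fst < 0 || cfg$fst >= 1, "fst must be in [0, 1)")
  stop_if(cfg$depth_mean <= 0, "depth_mean must be > 0")
  stop_if(cfg$missing_rate < 0 || cfg$missing_rate >= 1,
          "missing_rate must be in [0, 1)")
  stop_if(any(c(cfg$n_cultivars, cfg$n_markers, cfg$n_bulks, cfg$n_plants,
                cfg$ploidy) < 1), "all counts must be >= 1")
  class(cfg) <- "marker_sim_config"
  cfg
}

#' Simulate true cultivar allele frequencies
#'
#' Balding-Nichols draw: per marker, an ancestral frequency from
#' `Beta(a, b)`, then one frequency per cultivar from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`. With `F = 0` every cultivar gets the
#' ancestral frequency (no differentiation).
#'
#' @param cfg `marker_sim_config`.
#' @return matrix cultivars x markers of true allele frequencies, with
#'   cultivar ids `LETTERS`-style rownames and marker ids `M1..` colnames;
#'   ancestral frequencies kept in attribute `ancestral`.
#' @export
simulate_cultivar_frequencies <- function(cfg) {
  with_seed(cfg$seed, {
    a <- cfg$ancestral_beta[1]; b <- cfg$ancestral_beta[2]
    p <- stats::rbeta(cfg$n_markers, a, b)
    C <- cfg$n_cultivars
    if (cfg$fst == 0) {
      f <- matrix(rep(p, each = C), nrow = C)
    } else {
      scale <- (1 - cfg$fst) / cfg$fst
      f <- matrix(stats::rbeta(C * cfg$n_markers,
                               rep(p, each = C) * scale,
                               rep(1 - p, each = C) * scale),
                  nrow = C)
    }
    dimnames(f) <- list(cultivar_labels(C), paste0("M", seq_len(cfg$n_markers)))
    attr(f, "ancestral") <- p
    f
  })
}

cultivar_labels <- function(C) {
  if (C <= 26) LETTERS[seq_len(C)]
  else paste0("C", formatC(seq_len(C), width = nchar(C), flag = "0"))
}

#' Simulate bulk allele frequencies
#'
#' A bulk of `n_plants` plants carries `ploidy * n_plants` allele copies; the
#' bulk frequency is a binomial draw over those copies, independently per
#' bulk. This is the only source of within-cultivar (between-bulk) variation.
#'
#' @param true_freqs cultivars x markers matrix from
#'   [simulate_cultivar_frequencies()].
#' @param cfg `marker_sim_config`.
#' @return list with `freq` (samples x markers matrix of bulk frequencies,
#'   sample ids `<cultivar>_<bulk>`) and `meta` (a [sample_meta()] table).
#' @export
simulate_bulk_frequencies <- function(true_freqs, cfg) {
  with_seed(child_seed(cfg$seed, 1L), {
    copies <- cfg$ploidy * cfg$n_plants
    stop_if(copies < 1, "ploidy * n_plants must be >= 1")
    cultivars <- rownames(true_freqs)
    M <- ncol(true_freqs)
    n <- length(cultivars) * cfg$n_bulks
    freq <- matrix(NA_real_, n, M)
    ids <- character(n)
    meta <- vector("list", n)
    r <- 0L
    for (ci in seq_along(cultivars)) for (bi in seq_len(cfg$n_bulks)) {
      r <- r + 1L
      ids[r] <- paste0(cultivars[ci], "_", bi)
      freq[r, ] <- stats::rbinom(M, copies, true_freqs[ci, ]) / copies
      meta[[r]] <- data.frame(sample_id = ids[r], cultivar_id = cultivars[ci],
                              bulk_index = bi, n_plants = cfg$n_plants)
    }
    dimnames(freq) <- list(ids, colnames(true_freqs))
    meta <- do.call(rbind, meta)
    class(meta) <- c("sample_meta", "data.frame")
    list(freq = freq, meta = meta)
  })
}

#' Simulate pool-seq read counts from bulk frequencies
#'
#' Depth per cell is negative-binomial (`mu = depth_mean`,
#' `size = depth_dispersion`, emulating GBS-style overdispersion); alternate
#' reads are binomial at the bulk frequency; cells are zeroed (made missing)
#' with probability `missing_rate`.
#'
#' @param bulk_freqs samples x markers matrix of bulk allele frequencies.
#' @param cfg `marker_sim_config`.
#' @return `read_count_matrix`.
#' @export
simulate_read_counts <- function(bulk_freqs, cfg) {
  with_seed(child_seed(cfg$seed, 2L), {
    n <- length(bulk_freqs)
    depth <- stats::rnbinom(n, mu = cfg$depth_mean, size = cfg$depth_dispersion)
    if (cfg$missing_rate > 0)
      depth[stats::runif(n) < cfg$missing_rate] <- 0L
    alt <- stats::rbinom(n, depth, as.vector(bulk_freqs))
    ref <- matrix(as.integer(depth - alt), nrow = nrow(bulk_freqs),
                  dimnames = dimnames(bulk_freqs))
    alt <- matrix(as.integer(alt), nrow = nrow(bulk_freqs),
                  dimnames = dimnames(bulk_freqs))
    read_count_matrix(ref, alt)
  })
}

#' Simulate a complete marker dataset
#'
#' Convenience wrapper chaining cultivar frequencies, bulks and read counts.
#'
#' @param cfg `marker_sim_config`.
#' @return list with `counts` (`read_count_matrix`), `meta` ([sample_meta()]),
#'   `bulk_freq` (true bulk frequencies) and `true_freq` (cultivar
#'   frequencies).
#' @export
simulate_marker_dataset <- function(cfg) {
  true_freq <- simulate_cultivar_frequencies(cfg)
  bulks <- simulate_bulk_frequencies(true_freq, cfg)
  counts <- simulate_read_counts(bulks$freq, cfg)
  list(counts = counts, meta = bulks$meta,
       bulk_freq = bulks$freq, true_freq = true_freq)
}

#' Method-of-moments Fst estimate from cultivar frequencies
#'
#' Averages, over markers, the ratio of the between-cultivar variance to
#' `p(1-p)` of the mean frequency — the Balding-Nichols moment relation.
#' Used mainly to verify parameter recovery of the simulator.
#'
#' @param true_freqs cultivars x markers matrix.
#' @return scalar Fst estimate.
#' @export
estimate_fst_mom <- function(true_freqs) {
  pbar <- colMeans(true_freqs)
  v <- apply(true_freqs, 2, stats::var)
  keep <- pbar > 0.01 & pbar < 0.99
  mean(v[keep] / (pbar[keep] * (1 - pbar[keep])))
}

#' Default alfalfa DUS trait schema
#'
#' The eight standard morphophysiological traits of an alfalfa spaced-plant
#' registration trial: growth habit (1-9 rating), plant height in spring,
#' onset of flowering, dark-flower and variegated-flower plant proportions,
#' stem length, regrowth height after harvest, and autumn plant height.
#'
#' @return `trait_schema` with 8 rows.
#' @export
alfalfa_trait_schema <- function() {
  trait_schema(
    name = c("PGH", "PHS", "OF", "DFP", "VFP", "SL", "PHH", "PHA"),
    kind = c("rating_1_9", "quantitative", "quantitative", "proportion",
             "proportion", "quantitative", "quantitative", "quantitative"),
    denominator = c(NA, NA, NA, 25L, 25L, NA, NA, NA))
}

#' Default between-cultivar trait correlation matrix
#'
#' Correlation targets for the trait simulator, reflecting the strong
#' winter-activity syndrome of alfalfa cultivars: plant height in spring and
#' autumn, regrowth height and stem length are mutually highly correlated and
#' strongly anti-correlated with onset of flowering, while growth habit and
#' the flower-color proportions are largely independent of the height block.
#'
#' @return 8 x 8 positive-definite correlation matrix.
#' @export
alfalfa_trait_correlations <- function() {
  tr <- c("PGH", "PHS", "OF", "DFP", "VFP", "SL", "PHH", "PHA")
  R <- diag(8)
  dimnames(R) <- list(tr, tr)
  set <- function(a, b, x) {
    R[a, b] <<- x
    R[b, a] <<- x
  }
  set("PGH", "PHS", 0.32); set("PGH", "OF", -0.07); set("PGH", "DFP", -0.61)
  set("PGH", "VFP", 0.10); set("PGH", "SL", 0.39); set("PGH", "PHH", 0.27)
  set("PGH", "PHA", 0.29)
  set("PHS", "OF", -0.91); set("PHS", "DFP", -0.59); set("PHS", "VFP", 0.12)
  set("PHS", "SL", 0.82); set("PHS", "PHH", 0.89); set("PHS", "PHA", 0.98)
  set("OF", "DFP", 0.33); set("OF", "VFP", -0.08); set("OF", "SL", -0.62)
  set("OF", "PHH", -0.74); set("OF", "PHA", -0.90)
  set("DFP", "VFP", -0.35); set("DFP", "SL", -0.55); set("DFP", "PHH", -0.58)
  set("DFP", "PHA", -0.56)
  set("VFP", "SL", 0.19); set("VFP", "PHH", 0.04); set("VFP", "PHA", 0.09)
  set("SL", "PHH", 0.86); set("SL", "PHA", 0.84)
  set("PHH", "PHA", 0.91)
  R
}

#' Trait trial simulation configuration
#'
#' Parameters for an RCBD spaced-plant trial at plot level. Cultivar means
#' are drawn multivariate-normal with the supplied between-cultivar
#' correlation matrix and per-trait means/SDs; plot values add a block effect
#' (one scalar per block per trait, independent across traits) and a plot
#' error. Rating plot values are rounded and clipped to `[1, 9]`; proportion
#' plot values are realized as `Binomial(plants_per_plot, p)/plants_per_plot`.
#'
#' @param n_cultivars number of cultivars (default 18).
#' @param n_blocks complete blocks (default 4).
#' @param plants_per_plot spaced plants per plot (default 25).
#' @param schema `trait_schema` (default [alfalfa_trait_schema()]).
#' @param trait_mean,trait_sd per-trait cultivar-mean location and
#'   between-cultivar SD (named by trait).
#' @param correlation between-cultivar trait correlation matrix (default
#'   [alfalfa_trait_correlations()]).
#' @param block_sd,plot_error_sd per-trait SDs of block effects and plot
#'   errors (defaults: 20% and 40% of `trait_sd`).
#' @param seed integer seed or `NULL`.
#' @return list of class `trait_sim_config`.
#' @export
trait_sim_config <- function(n_cultivars = 18L, n_blocks = 4L,
                             plants_per_plot = 25L,
                             schema = alfalfa_trait_schema(),
                             trait_mean = NULL, trait_sd = NULL,
                             correlation = NULL,
                             block_sd = NULL, plot_error_sd = NULL,
                             seed = NULL) {
  defaults_mean <- c(PGH = 2, PHS = 33, OF = 136, DFP = 0.2, VFP = 0.05,
                     SL = 110, PHH = 43, PHA = 30)
  defaults_sd <- c(PGH = 0.5, PHS = 8, OF = 3.5, DFP = 0.2, VFP = 0.04,
                   SL = 10, PHH = 5.5, PHA = 7.5)
  tn <- schema$name
  trait_mean <- (trait_mean %||% defaults_mean)[tn]
  trait_sd <- (trait_sd %||% defaults_sd)[tn]
  stop_if(anyNA(trait_mean) || anyNA(trait_sd),
          "trait_mean/trait_sd must cover every schema trait")
  correlation <- correlation %||% alfalfa_trait_correlations()
  correlation <- correlation[tn, tn, drop = FALSE]
  stop_if(!isTRUE(all.equal(correlation, t(correlation))) ||
            !isTRUE(all.equal(unname(diag(correlation)), rep(1, length(tn)))),
          "correlation must be symmetric with unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  stop_if(min(ev) < -1e-8, "correlation matrix is not positive semi-definite")
  cfg <- list(n_cultivars = as.integer(n_cultivars),
              n_blocks = as.integer(n_blocks),
              plants_per_plot = as.integer(plants_per_plot),
              schema = schema, trait_mean = trait_mean, trait_sd = trait_sd,
              correlation = correlation,
              block_sd = (block_sd %||% (0.2 * trait_sd))[tn],
              plot_error_sd = (plot_error_sd %||% (0.4 * trait_sd))[tn],
              seed = seed)
  stop_if(any(c(cfg$n_cultivars, cfg$n_blocks, cfg$plants_per_plot) < 1),
          "all counts must be >= 1")
  class(cfg) <- "trait_sim_config"
  cfg
}

#' Simulate an RCBD plot-level trait table
#'
#' @param cfg `trait_sim_config`.
#' @return `trait_plot_table` (one row per block x cultivar) with attributes
#'   `schema` and `cultivar_means` (the latent cultivar means actually drawn).
#' @export
simulate_trait_table <- function(cfg) {
  with_seed(cfg$seed, {
    tn <- cfg$schema$name
    Tn <- length(tn)
    C <- cfg$n_cultivars
    B <- cfg$n_blocks
    ev <- eigen(cfg$correlation, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), Tn)
    z <- matrix(stats::rnorm(C * Tn), C, Tn) %*% t(L)
    mu <- sweep(sweep(z, 2, cfg$trait_sd, "*"), 2, cfg$trait_mean, "+")
    dimnames(mu) <- list(cultivar_labels(C), tn)
    ## keep latent means inside their legal supports
    for (j in seq_len(Tn)) {
      if (cfg$schema$kind[j] == "proportion") mu[, j] <- pmin(pmax(mu[, j], 0), 1)
      if (cfg$schema$kind[j] == "rating_1_9") mu[, j] <- pmin(pmax(mu[, j], 1), 9)
    }
    blocks <- matrix(stats::rnorm(B * Tn, 0, rep(cfg$block_sd, each = B)),
                     B, Tn, dimnames = list(NULL, tn))
    rows <- expand.grid(block = paste0("B", seq_len(B)),
                        cultivar = rownames(mu),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    vals <- matrix(NA_real_, nrow(rows), Tn, dimnames = list(NULL, tn))
    bi <- match(rows$block, paste0("B", seq_len(B)))
    ci <- match(rows$cultivar, rownames(mu))
    for (j in seq_len(Tn)) {
      y <- mu[ci, j] + blocks[bi, j] +
        stats::rnorm(nrow(rows), 0, cfg$plot_error_sd[j])
      kind <- cfg$schema$kind[j]
      if (kind == "rating_1_9") y <- pmin(pmax(round(y), 1), 9)
      if (kind == "proportion") {
        p <- pmin(pmax(y, 0), 1)
        n <- cfg$plants_per_plot
        y <- stats::rbinom(length(p), n, p) / n
      }
      vals[, j] <- y
    }
    d <- cbind(rows, as.data.frame(vals))
    d <- validate_trait_table(d, cfg$schema)
    attr(d, "cultivar_means") <- mu
    d
  })
}
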