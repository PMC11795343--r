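## Shared fixtures, built once per test run.

.fixtures <- new.env()

## small differentiated marker dataset: 6 cultivars x 3 bulks, 400 markers
fix_marker_small <- function() {
  if (is.null(.fixtures$marker_small)) {
    cfg <- marker_sim_config(n_cultivars = 6, panel = "dartag",
                             n_markers = 400, fst = 0.03, seed = 421)
    sim <- simulate_marker_dataset(cfg)
    ff <- apply_filter_config(sim$counts, filter_config(20, 0.30))
    .fixtures$marker_small <- list(cfg = cfg, sim = sim, freq = ff$freq,
                                   meta = sim$meta)
  }
  .fixtures$marker_small
}

## trait table fixture: 18 cultivars x 4 blocks, default schema
fix_traits <- function() {
  if (is.null(.fixtures$traits)) {
    cfg <- trait_sim_config(seed = 77)
    .fixtures$traits <- list(cfg = cfg, table = simulate_trait_table(cfg))
  }
  .fixtures$traits
}

## brute-force RCBD / one-way sums of squares from definitions
oracle_anova_ss <- function(y, groups, blocks = NULL) {
  gm <- mean(y)
  ss_total <- sum((y - gm)^2)
  ss_g <- sum(tapply(y, groups, function(v) length(v) * (mean(v) - gm)^2))
  if (is.null(blocks))
    return(list(ss_group = ss_g, ss_error = ss_total - ss_g,
                df_error = length(y) - length(unique(groups))))
  ss_b <- sum(tapply(y, blocks, function(v) length(v) * (mean(v) - gm)^2))
  list(ss_group = ss_g, ss_block = ss_b,
       ss_error = ss_total - ss_g - ss_b,
       df_error = (length(unique(groups)) - 1) * (length(unique(blocks)) - 1))
}

## brute-force average-linkage merge sequence on a labelled distance matrix;
## returns merge heights (inter-cluster mean distances) in merge order
oracle_upgma_heights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < bd) { bd <- d; best <- c(i, j) }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

## brute-force Nei (1972) distance for two frequency vectors
oracle_nei <- function(p, q) {
  jx <- sum(p^2 + (1 - p)^2)
  jy <- sum(q^2 + (1 - q)^2)
  jxy <- sum(p * q + (1 - p) * (1 - q))
  -log(jxy / sqrt(jx * jy))
}
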