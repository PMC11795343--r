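test_that("cultivar frequency model behaves across the F range", {
  cfg0 <- marker_sim_config(n_cultivars = 5, n_markers = 200, fst = 0, seed = 1)
  f0 <- simulate_cultivar_frequencies(cfg0)
  expect_true(all(apply(f0, 2, function(x) length(unique(x))) == 1))

  ## high F: frequencies concentrate near 0 or 1
  cfg9 <- marker_sim_config(n_cultivars = 20, n_markers = 500, fst = 0.9,
                            ancestral_beta = c(50, 50), seed = 2)
  f9 <- simulate_cultivar_frequencies(cfg9)
  expect_gt(mean(f9 < 0.1 | f9 > 0.9), 0.7)

  ## same seed => bit-identical output
  expect_identical(simulate_cultivar_frequencies(cfg9),
                   simulate_cultivar_frequencies(cfg9))
})

test_that("method-of-moments recovers the simulated F within 10%", {
  cfg <- marker_sim_config(n_cultivars = 18, n_markers = 10000, fst = 0.05,
                           seed = 3)
  f <- simulate_cultivar_frequencies(cfg)
  expect_lt(abs(estimate_fst_mom(f) - 0.05) / 0.05, 0.10)
})

test_that("bulk frequencies are binomial draws over allele copies", {
  cfg <- marker_sim_config(n_cultivars = 2, n_markers = 5000, fst = 0,
                           n_plants = 200, ploidy = 4, seed = 4)
  truth <- simulate_cultivar_frequencies(cfg)
  truth[] <- 0
  b0 <- simulate_bulk_frequencies(truth, cfg)
  expect_true(all(b0$freq == 0))

  truth2 <- simulate_cultivar_frequencies(cfg)
  bulks <- simulate_bulk_frequencies(truth2, cfg)
  ## Var(bulk - true) ~ p(1-p)/800 across markers
  p <- truth2[1, ]
  dev <- sweep(bulks$freq[bulks$meta$cultivar_id == "A", , drop = FALSE], 2, p)
  keep <- p > 0.2 & p < 0.8
  ratio <- mean(dev[, keep]^2) / mean((p * (1 - p) / 800)[keep])
  expect_lt(abs(ratio - 1), 0.1)

  ## bulks of the same cultivar differ for intermediate p
  expect_gt(sd(bulks$freq[1:3, which(keep)[1]]), 0)
})

test_that("between-bulk variance shrinks as bulk size grows", {
  vars <- sapply(c(10, 50, 200), function(np) {
    cfg <- marker_sim_config(n_cultivars = 4, n_markers = 1000, fst = 0.02,
                             n_plants = np, seed = 5)
    truth <- simulate_cultivar_frequencies(cfg)
    bulks <- simulate_bulk_frequencies(truth, cfg)
    lab <- bulks$meta$cultivar_id
    mean(sapply(unique(lab), function(cv)
      mean(apply(bulks$freq[lab == cv, ], 2, var))))
  })
  expect_true(all(diff(vars) < 0))
})

test_that("read-count depth and frequency models match their targets", {
  cfg <- marker_sim_config(n_cultivars = 6, n_markers = 6000, fst = 0,
                           depth_mean = 56, depth_dispersion = 20,
                           missing_rate = 0, panel = "gbs", seed = 6)
  truth <- simulate_cultivar_frequencies(cfg)
  bulks <- simulate_bulk_frequencies(truth, cfg)
  rc <- simulate_read_counts(bulks$freq, cfg)
  depth <- rc$ref + rc$alt
  expect_lt(abs(mean(depth) - 56) / 56, 0.02)      # >= 1e5 cells
  ## alt/depth tracks the bulk frequency
  obs <- rc$alt[depth > 0] / depth[depth > 0]
  expect_lt(abs(mean(obs - bulks$freq[depth > 0])), 0.005)

  cfgm <- marker_sim_config(n_cultivars = 2, n_markers = 500, fst = 0,
                            depth_mean = 60, missing_rate = 0.3, seed = 7)
  rcm <- simulate_read_counts(bulks$freq[1:6, 1:500], cfgm)
  expect_gt(mean(rcm$ref + rcm$alt == 0), 0.2)
})

test_that("trait simulation respects the RCBD structure and trait kinds", {
  schema <- trait_schema(c("T1", "T2"), c("quantitative", "quantitative"))
  cor2 <- diag(2); dimnames(cor2) <- list(c("T1", "T2"), c("T1", "T2"))
  cfg <- trait_sim_config(n_cultivars = 5, n_blocks = 3, schema = schema,
                          trait_mean = c(T1 = 10, T2 = 50),
                          trait_sd = c(T1 = 2, T2 = 5), correlation = cor2,
                          block_sd = c(T1 = 0, T2 = 0),
                          plot_error_sd = c(T1 = 0, T2 = 0), seed = 8)
  tt <- simulate_trait_table(cfg)
  expect_equal(nrow(tt), 15L)
  mu <- attr(tt, "cultivar_means")
  ## zero error SDs: plot values equal the cultivar means exactly
  for (cv in rownames(mu))
    expect_equal(unique(tt$T1[tt$cultivar == cv]), unname(mu[cv, "T1"]))

  ## proportion trait with p = 0 gives all-zero plot fractions
  schema_p <- trait_schema("VF", "proportion", 25L)
  corp <- matrix(1, 1, 1, dimnames = list("VF", "VF"))
  cfgp <- trait_sim_config(n_cultivars = 4, n_blocks = 2, schema = schema_p,
                           trait_mean = c(VF = 0), trait_sd = c(VF = 0),
                           correlation = corp, block_sd = c(VF = 0),
                           plot_error_sd = c(VF = 0), seed = 9)
  ttp <- simulate_trait_table(cfgp)
  expect_true(all(ttp$VF == 0))

  ## full default schema stays within trait supports
  tt8 <- fix_traits()$table
  expect_true(all(tt8$PGH >= 1 & tt8$PGH <= 9))
  expect_true(all(tt8$DFP >= 0 & tt8$DFP <= 1))
  expect_identical(simulate_trait_table(fix_traits()$cfg), tt8)
})

test_that("trait correlation targets are recovered at many cultivars", {
  cfg <- trait_sim_config(n_cultivars = 200, seed = 10)
  tt <- simulate_trait_table(cfg)
  mu <- attr(tt, "cultivar_means")
  r <- cor(mu[, "PHS"], mu[, "PHA"])
  expect_lt(abs(r - 0.98), 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(marker_sim_config(fst = 1), "fst")
  expect_error(marker_sim_config(depth_mean = 0), "depth_mean")
  bad <- matrix(c(1, 2, 2, 1), 2,
                dimnames = list(c("T1", "T2"), c("T1", "T2")))
  schema <- trait_schema(c("T1", "T2"), c("quantitative", "quantitative"))
  expect_error(trait_sim_config(schema = schema,
                                trait_mean = c(T1 = 0, T2 = 0),
                                trait_sd = c(T1 = 1, T2 = 1),
                                correlation = bad),
               "positive semi-definite")
})
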