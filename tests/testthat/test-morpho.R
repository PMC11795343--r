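test_that("plant records aggregate to plot means and pass through if already plot-level", {
  schema <- trait_schema(c("PH", "VF"), c("quantitative", "proportion"), c(NA, 25L))
  plants <- expand.grid(block = c("B1", "B2"), cultivar = c("A", "B"),
                        plant = 1:25, stringsAsFactors = FALSE)
  plants$PH <- 40 + as.integer(factor(plants$cultivar)) + plants$plant * 0.1
  plants$VF <- 0
  plants$VF[plants$block == "B1" & plants$cultivar == "A" & plants$plant <= 3] <- 1
  plot_tbl <- aggregate_plot_means(plants, schema)
  expect_equal(nrow(plot_tbl), 4L)
  expect_equal(plot_tbl$VF[plot_tbl$block == "B1" & plot_tbl$cultivar == "A"], 0.12)
  expect_equal(plot_tbl$PH[plot_tbl$cultivar == "B"][1],
               mean(42 + (1:25) * 0.1))
  ## idempotence
  again <- aggregate_plot_means(plot_tbl, schema)
  expect_equal(as.data.frame(again), as.data.frame(plot_tbl))
})

test_that("RCBD ANOVA matches the brute-force sum-of-squares oracle", {
  schema <- trait_schema("Y", "quantitative")
  d <- data.frame(block = rep(c("B1", "B2"), 3),
                  cultivar = rep(c("A", "B", "C"), each = 2),
                  Y = c(10, 12, 15, 14, 20, 23))
  tt <- aggregate_plot_means(d, schema)
  a <- rcbd_anova(tt, "Y")
  o <- oracle_anova_ss(d$Y, d$cultivar, d$block)
  expect_equal(a$mse, o$ss_error / o$df_error, tolerance = 1e-10)
  expect_equal(a$df_e, o$df_error)
  expect_equal(as.numeric(a$means), c(11, 14.5, 21.5))
  expect_equal(a$F, (o$ss_group / 2) / (o$ss_error / o$df_error),
               tolerance = 1e-10)

  ## angular transform applied to proportions: asin(sqrt(0.5)) = pi/4
  schema_p <- trait_schema("P", "proportion", 25L)
  dp <- data.frame(block = rep(c("B1", "B2"), 2),
                   cultivar = rep(c("A", "B"), each = 2),
                   P = c(0.5, 0.5, 0.2, 0.3))
  ap <- rcbd_anova(aggregate_plot_means(dp, schema_p), "P")
  expect_equal(ap$transform, "angular")
  expect_equal(unname(ap$means["A"]), pi / 4, tolerance = 1e-12)

  ## zero within-noise data: MSE ~ 0, flagged, F unbounded
  d0 <- d; d0$Y <- rep(c(1, 2, 3), each = 2)
  a0 <- rcbd_anova(aggregate_plot_means(d0, schema), "Y")
  expect_true(!is.null(a0$flag))
  expect_true(is.infinite(a0$F))
  expect_error(rcbd_anova(aggregate_plot_means(d[d$block == "B1", ], schema), "Y"),
               "blocks")
})

test_that("Fisher's LSD calls pairs on strict exceedance", {
  ## derived from the t table: t(0.995, 51) = 2.6757, LSD = 2.6757*sqrt(2/4)
  an <- list(means = c(A = 0, B = 10, C = 0), mse = 1, df_e = 51, n_blocks = 4)
  m <- lsd_pairwise_distinct(an, alpha = 0.01)
  expect_equal(attr(m, "lsd"), 2.6757 * sqrt(2 / 4), tolerance = 1e-4)
  expect_true(m["A", "B"])
  expect_false(m["A", "C"])          # equal means never distinct
  ## |diff| exactly equal to LSD is NOT distinct (strict inequality)
  lsd <- attr(m, "lsd")
  an2 <- list(means = c(A = 0, B = lsd), mse = 1, df_e = 51, n_blocks = 4)
  expect_false(lsd_pairwise_distinct(an2, alpha = 0.01)["A", "B"])
})

test_that("the 1.5-unit rating rule uses strict exceedance of cultivar means", {
  schema <- trait_schema("PGH", "rating_1_9")
  d <- data.frame(block = rep(c("B1", "B2"), 3),
                  cultivar = rep(c("A", "B", "C"), each = 2),
                  PGH = c(1, 1, 3, 3, 3.5, 3.5))
  tt <- aggregate_plot_means(d, schema)
  m <- rating_scale_distinct(tt, "PGH")
  expect_true(m["A", "B"])     # |1 - 3| = 2 > 1.5
  expect_false(m["B", "C"])    # |3 - 3.5| = 0.5
  ## boundary: 2 vs 3.5 differs by exactly 1.5 -> not distinct
  d$PGH <- c(2, 2, 3.5, 3.5, 9, 9)
  m2 <- rating_scale_distinct(aggregate_plot_means(d, schema), "PGH")
  expect_false(m2["A", "B"])
  expect_error(rating_scale_distinct(tt, "PGH", threshold = 1.5), NA)
})

test_that("trait combination is a union and grows monotonically", {
  ids <- c("A", "B", "C")
  m1 <- matrix(FALSE, 3, 3, dimnames = list(ids, ids))
  m2 <- m1
  m1["A", "B"] <- m1["B", "A"] <- TRUE
  m2["B", "C"] <- m2["C", "B"] <- TRUE
  r1 <- combine_trait_distinctness(list(t1 = m1))
  r12 <- combine_trait_distinctness(list(t1 = m1, t2 = m2))
  expect_equal(r1$n_distinct_pairs, 1L)
  expect_equal(r12$n_distinct_pairs, 2L)
  expect_gte(r12$n_distinct_pairs, r1$n_distinct_pairs)
  expect_setequal(r12$evidence$feature, c("t1", "t2"))
  bad <- m2[1:2, 1:2]
  expect_error(combine_trait_distinctness(list(t1 = m1, t2 = bad)),
               "inconsistent")
})

test_that("distinctness calls are invariant to back-transforming reported means", {
  ## angular transform is monotone on [0,1]: the same pairs exceed the LSD
  ## threshold computed on the analysis scale regardless of the display scale
  tt <- fix_traits()$table
  a <- rcbd_anova(tt, "DFP")
  m <- lsd_pairwise_distinct(a)
  back <- sin(a$means)^2
  expect_true(all(abs(back - tapply(tt$DFP, tt$cultivar, mean)) < 0.2))
  expect_equal(dim(m), c(18L, 18L))
})

test_that("full morpho criterion runs on a study-sized trial", {
  tt <- fix_traits()$table
  res <- morpho_distinctness(tt)
  expect_s3_class(res, "distinctness_result")
  expect_equal(res$n_pairs, 153L)
  expect_gt(res$n_distinct_pairs, 0L)
  anovas <- attr(res, "anovas")
  expect_length(anovas, 7L)                       # PGH uses the rating rule
  expect_true(all(sapply(anovas, `[[`, "df_e") == 51L))
  ## per-pair trait counts lie in 0..8
  counts <- table(paste(res$evidence$a, res$evidence$b))
  expect_true(all(counts >= 0 & counts <= 8))
})

test_that("trait correlations match the closed-form t test", {
  tt <- fix_traits()$table
  tc <- trait_correlations(tt)
  expect_equal(unname(diag(tc$r)), rep(1, 8))
  ## n = 18, r = 0.6 -> t = 3.0, p < 0.01: check the flag machinery agrees
  r <- 0.6; n <- 18
  p <- 2 * pt(r * sqrt(n - 2) / sqrt(1 - r^2), n - 2, lower.tail = FALSE)
  expect_lt(p, 0.01)
  hi <- which(abs(tc$r) > 0.6 & upper.tri(tc$r), arr.ind = TRUE)
  if (nrow(hi) > 0) expect_true(all(tc$p[hi] < 0.01))

  ## perfect anti-correlation on constructed means
  schema <- trait_schema(c("U", "V"), c("quantitative", "quantitative"))
  d <- expand.grid(block = c("B1", "B2"), cultivar = c("A", "B", "C"),
                   stringsAsFactors = FALSE)
  d$U <- rep(c(1, 2, 3), each = 2)
  d$V <- -d$U
  tc2 <- trait_correlations(aggregate_plot_means(d, schema))
  expect_equal(tc2$r["U", "V"], -1)
  expect_equal(tc2$flag["U", "V"], "***")

  ## zero-variance trait flagged undefined
  d$V <- 5
  tc3 <- trait_correlations(aggregate_plot_means(d, schema))
  expect_true(is.na(tc3$r["U", "V"]))
  expect_equal(tc3$flag["U", "V"], "undef")
})
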