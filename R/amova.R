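#' Nei's standard genetic distance between bulk samples
#'
#' For biallelic loci with frequencies p and q in two samples,
#' `J_X = sum(p^2 + (1-p)^2)`, `J_Y` analogously,
#' `J_XY = sum(p q + (1-p)(1-q))`, and
#' `D = -ln(J_XY / sqrt(J_X J_Y))`. Computed directly from bulk allele
#' frequencies (the 1972 form; bulks are frequency estimates, not genotype
#' samples with known n). Fixed-for-opposite-alleles pairs give `J_XY = 0`
#' and an infinite distance, which is capped at the largest finite value
#' observed plus one (flagged).
#'
#' @param freqs complete samples x markers frequency matrix.
#' @return symmetric numeric matrix (samples x samples) with zero diagonal;
#'   attribute `capped` lists any capped pairs.
#' @export
nei_distance_matrix <- function(freqs) {
  check_freq_matrix(freqs)
  stop_if(anyNA(freqs), "Nei distance needs a complete matrix")
  P <- freqs
  J <- tcrossprod(P) + tcrossprod(1 - P)
  jx <- diag(J)
  I <- J / sqrt(outer(jx, jx))
  D <- -log(pmin(I, 1))
  diag(D) <- 0
  capped <- NULL
  if (any(!is.finite(D))) {
    inf <- !is.finite(D)
    cap <- max(D[!inf], 1) + 1
    capped <- which(inf & upper.tri(inf), arr.ind = TRUE)
    D[inf] <- cap
  }
  dimnames(D) <- list(rownames(freqs), rownames(freqs))
  attr(D, "capped") <- capped
  D
}

amova_ss <- function(d2, idx_groups) {
  N <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / N
  ss_within <- 0
  for (g in idx_groups) {
    sub <- d2[g, g, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(g)
  }
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

phi_from_ss <- function(ss, n, N) {
  ms_among <- ss["among"] / 1
  ms_within <- ss["within"] / (N - 2)
  sigma_w <- ms_within
  sigma_a <- (ms_among - ms_within) / n
  denom <- sigma_a + sigma_w
  phi <- if (denom <= 0) 0 else sigma_a / denom
  c(phi = unname(phi), sigma_a = unname(sigma_a), sigma_w = unname(sigma_w))
}

#' Pairwise AMOVA on a 6x6 (or 2n x 2n) distance sub-matrix
#'
#' Two-group analysis of molecular variance on squared distances: the total
#' sum of squares is partitioned into among- and within-cultivar components,
#' and the fixation-index analogue `Phi_ST` is tested by permuting the
#' sample-to-group assignment. `mode = "exhaustive"` enumerates all
#' `choose(N, n)` assignments (the exhaustive p-value is the fraction of
#' assignments with a permuted `Phi_ST >=` the observed one, the observed
#' assignment included); `mode = "random"` draws `nperm` assignments and uses
#' the add-one estimator. `mode = "auto"` selects exhaustive enumeration when
#' `choose(N, n) <= 10000`.
#'
#' @param dist distance matrix over the `2n` bulks of the pair (first `n`
#'   rows = group 1 unless `groups` given).
#' @param groups length-`2n` group label vector.
#' @param nperm random permutations (default 10000).
#' @param mode `"auto"`, `"exhaustive"` or `"random"`.
#' @param seed RNG seed for random mode.
#' @return list of class `amova_result` with sums of squares, variance
#'   components, `phi_st`, `p_value`, `n_permutations`, `mode`, `seed`.
#' @export
amova_pair <- function(dist, groups, nperm = 10000L,
                       mode = c("auto", "exhaustive", "random"), seed = NULL) {
  mode <- match.arg(mode)
  N <- nrow(dist)
  groups <- as.character(groups)
  stop_if(length(groups) != N, "groups must label every sample")
  lv <- unique(groups)
  stop_if(length(lv) != 2, "AMOVA pair needs exactly two groups")
  n <- sum(groups == lv[1])
  stop_if(N != 2 * n, "groups must be of equal size")
  d2 <- as.matrix(dist)^2
  obs_groups <- list(which(groups == lv[1]), which(groups == lv[2]))
  ss <- amova_ss(d2, obs_groups)
  ph <- phi_from_ss(ss, n, N)
  n_comb <- choose(N, n)
  if (mode == "auto") mode <- if (n_comb <= 10000) "exhaustive" else "random"
  if (mode == "exhaustive") {
    combs <- utils::combn(N, n)
    phis <- apply(combs, 2, function(g1)
      phi_from_ss(amova_ss(d2, list(g1, setdiff(seq_len(N), g1))), n, N)["phi"])
    p <- sum(phis >= ph["phi"] - 1e-12) / n_comb
    nperm_used <- n_comb
  } else {
    phis <- with_seed(seed, replicate(nperm, {
      g1 <- sample.int(N, n)
      phi_from_ss(amova_ss(d2, list(g1, setdiff(seq_len(N), g1))), n, N)["phi"]
    }))
    p <- (sum(phis >= ph["phi"] - 1e-12) + 1) / (nperm + 1)
    nperm_used <- nperm
  }
  structure(list(ss_among = unname(ss["among"]), ss_within = unname(ss["within"]),
                 ss_total = unname(ss["total"]),
                 df_among = 1L, df_within = N - 2L,
                 sigma2_among = ph["sigma_a"], sigma2_within = ph["sigma_w"],
                 phi_st = ph["phi"], p_value = p, n_permutations = nperm_used,
                 mode = mode, seed = seed),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA: Phi_ST = %.4f, p = %.4g (%s, %d assignments)\n",
              x$phi_st, x$p_value, x$mode, x$n_permutations))
  invisible(x)
}

#' AMOVA distinctness criterion over all cultivar pairs
#'
#' Computes Nei's distance over all bulks, then a two-group AMOVA on the
#' distance sub-matrix of each cultivar pair; a pair is distinct when its
#' permutation p-value is below `alpha`. Note the analytic floor: with three
#' bulks per cultivar only `choose(6, 3) = 20` assignments exist and the
#' observed partition and its mirror always tie it, so the minimum attainable
#' exhaustive p-value is 2/20 = 0.1 — the criterion cannot declare
#' distinctness at `alpha = 0.05` regardless of the data.
#'
#' @param freqs complete samples x markers frequency matrix.
#' @param meta [sample_meta()] table.
#' @param alpha significance threshold (default 0.05).
#' @param nperm,mode,seed passed to [amova_pair()].
#' @return `distinctness_result` with attribute `pair_table` (per-pair SS,
#'   `Phi_ST`, p).
#' @export
amova_all_pairs <- function(freqs, meta, alpha = 0.05, nperm = 10000L,
                            mode = "auto", seed = NULL) {
  check_meta(meta, rownames(freqs))
  D <- nei_distance_matrix(freqs)
  ids <- sort(unique(meta$cultivar_id))
  pairs <- cultivar_pairs(ids)
  pd <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sel <- meta$sample_id[meta$cultivar_id %in% c(pairs$a[i], pairs$b[i])]
    grp <- meta$cultivar_id[match(sel, meta$sample_id)]
    a <- amova_pair(D[sel, sel], grp, nperm = nperm, mode = mode,
                    seed = child_seed(seed, i))
    pd[pairs$a[i], pairs$b[i]] <- pd[pairs$b[i], pairs$a[i]] <-
      a$p_value < alpha
    rows[[i]] <- data.frame(a = pairs$a[i], b = pairs$b[i],
                            phi_st = a$phi_st, p = a$p_value, mode = a$mode)
  }
  tab <- do.call(rbind, rows)
  hit <- tab[pd[cbind(tab$a, tab$b)], ]
  ev <- evidence_rows(hit$a, hit$b, "amova", "Phi_ST", hit$phi_st, hit$p)
  res <- distinctness_result(ids, pd, ev, criterion = "amova")
  attr(res, "pair_table") <- tab
  res
}
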