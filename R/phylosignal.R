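lower_tri <- function(m) m[lower.tri(m)]

#' Mantel test between two species distance matrices
#'
#' Pearson correlation over the `n(n-1)/2` off-diagonal pairs, with a
#' permutation p-value obtained by permuting the labels of the second
#' matrix: `p = (1 + #{null r >= r_obs}) / (1 + n_perm)`, one-sided toward
#' positive association (a positive, significant correlation between
#' phylogenetic and expression distances is the signal being tested for).
#'
#' @param dist_a,dist_b [species_dist()] matrices on the same labels.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return a `mantel_result`: list `r`, `p`, `n_perm`, `seed`, `null_r`.
#' @export
mantel_test <- function(dist_a, dist_b, n_perm = 999, seed = 1L) {
  labs <- rownames(dist_a)
  if (!setequal(labs, rownames(dist_b)))
    stop("matrices must share species labels", call. = FALSE)
  B <- dist_b[labs, labs]
  la <- lower_tri(dist_a)
  lb <- lower_tri(B)
  if (stats::sd(la) == 0 || stats::sd(lb) == 0)
    stop("constant off-diagonal distances: Mantel r undefined", call. = FALSE)
  r_obs <- stats::cor(la, lb)
  n <- length(labs)
  null_r <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      stats::cor(la, lower_tri(B[p, p]))
    }, numeric(1))
  })
  p <- (1 + sum(null_r >= r_obs)) / (1 + n_perm)
  structure(list(r = r_obs, p = p, n_perm = n_perm, seed = seed,
                 null_r = null_r),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.3f, p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_perm))
  invisible(x)
}

# Sum of sister-clade differences for a binary trait, with nodal values
# estimated by the contrasts-style weighted down-pass (Felsenstein pruning:
# node value = branch-length-weighted mean of its daughters, daughter edges
# extended by l1*l2/(l1+l2)). `clade_mean` is the simpler unweighted
# alternative for sensitivity checks.
d_sum <- function(phy, tipvals, node_estimation = c("contrasts", "clade_mean")) {
  node_estimation <- match.arg(node_estimation)
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  nv <- numeric(ntip + nnode)
  nv[seq_len(ntip)] <- tipvals[phy$tip.label]
  adj <- numeric(ntip + nnode)          # branch lengths, contrast-adjusted
  adj[phy$edge[, 2]] <- pmax(phy$edge.length, 1e-12)
  children <- split(phy$edge[, 2], phy$edge[, 1])
  post <- unique(ape::reorder.phylo(phy, "postorder")$edge[, 1])
  total <- 0
  for (nd in post) {
    kids <- children[[as.character(nd)]]
    if (node_estimation == "contrasts") {
      wl <- 1 / adj[kids]
      nv[nd] <- sum(nv[kids] * wl) / sum(wl)
      if (length(kids) == 2L)
        adj[nd] <- adj[nd] + prod(adj[kids]) / sum(adj[kids])
    } else {
      nv[nd] <- mean(nv[kids])
    }
    # at a bifurcation the weighted mean lies between the daughters, so
    # |v1 - v| + |v2 - v| = |v1 - v2|, the sister-clade difference
    total <- total + sum(abs(nv[kids] - nv[nd]))
  }
  total
}

# Threshold-Brownian binary traits: simulate Brownian motion down the tree
# and mark the k highest tips as 1, matching the observed prevalence.
threshold_brownian <- function(phy, k, n_sim) {
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  root <- ntip + 1L
  # preorder edges
  pre <- ape::reorder.phylo(phy, "cladewise")$edge
  el <- phy$edge.length[match(paste(pre[, 1], pre[, 2]),
                              paste(phy$edge[, 1], phy$edge[, 2]))]
  out <- matrix(FALSE, ntip, n_sim, dimnames = list(phy$tip.label, NULL))
  for (s in seq_len(n_sim)) {
    x <- numeric(nn)
    inc <- stats::rnorm(nrow(pre), 0, sqrt(pmax(el, 1e-12)))
    for (e in seq_len(nrow(pre))) x[pre[e, 2]] <- x[pre[e, 1]] + inc[e]
    tips <- x[seq_len(ntip)]
    out[order(tips, decreasing = TRUE)[seq_len(k)], s] <- TRUE
  }
  out
}

#' Fritz-Purvis D statistic for a binary trait
#'
#' Measures phylogenetic signal in a binary character as the observed sum
#' of sister-clade differences `d_obs` scaled between two null
#' expectations: random tip shuffles and threshold-Brownian evolution
#' (continuous Brownian values thresholded at the observed prevalence).
#' Under the `fritz_purvis` convention
#' `D = (d_obs - mean_d_brownian) / (mean_d_random - mean_d_brownian)`, so
#' random traits give D near 1 and Brownian traits D near 0; `as_printed`
#' adds 1 so the Brownian anchor sits at 1 (more labile traits larger).
#' Significance is a permutation test: `p` is the (add-one smoothed)
#' proportion of tip-shuffled `d` values at or below `d_obs`, i.e. the
#' probability of being at least as phylogenetically clumped as observed.
#'
#' @param phylogeny an [ape::phylo] tree with branch lengths.
#' @param binary_trait named logical/0-1 vector over the tips.
#' @param n_perm tip shuffles for the random null (default 999).
#' @param n_brownian threshold-Brownian simulations (default 999).
#' @param seed integer seed.
#' @param convention `"fritz_purvis"` (default) or `"as_printed"`.
#' @param node_estimation `"contrasts"` (default) or `"clade_mean"`.
#' @return a `d_stat_result`: `d_obs`, `mean_d_random`, `mean_d_brownian`,
#'   `D` (chosen convention), `D_fritz_purvis`, `D_as_printed`, `p`,
#'   `convention`; all numeric fields NA for a constant trait.
#' @export
d_statistic <- function(phylogeny, binary_trait, n_perm = 999,
                        n_brownian = 999, seed = 1L,
                        convention = c("fritz_purvis", "as_printed"),
                        node_estimation = c("contrasts", "clade_mean")) {
  convention <- match.arg(convention)
  node_estimation <- match.arg(node_estimation)
  tr <- binary_trait[phylogeny$tip.label]
  if (anyNA(tr)) stop("trait must be defined on every tip", call. = FALSE)
  tr <- as.numeric(as.logical(tr))
  names(tr) <- phylogeny$tip.label
  k <- sum(tr)
  na_result <- structure(list(d_obs = NA_real_, mean_d_random = NA_real_,
                              mean_d_brownian = NA_real_, D = NA_real_,
                              D_fritz_purvis = NA_real_,
                              D_as_printed = NA_real_, p = NA_real_,
                              convention = convention),
                         class = "d_stat_result")
  if (k == 0 || k == length(tr)) return(na_result)
  d_obs <- d_sum(phylogeny, tr, node_estimation)
  ntip <- length(tr)
  with_seed(seed, {
    d_rand <- vapply(seq_len(n_perm), function(i) {
      sh <- tr[sample.int(ntip)]
      names(sh) <- names(tr)
      d_sum(phylogeny, sh, node_estimation)
    }, numeric(1))
    bm <- threshold_brownian(phylogeny, k, n_brownian)
    d_brown <- vapply(seq_len(n_brownian), function(i) {
      v <- as.numeric(bm[, i]); names(v) <- rownames(bm)
      d_sum(phylogeny, v, node_estimation)
    }, numeric(1))
    mr <- mean(d_rand); mb <- mean(d_brown)
    D_fp <- if (abs(mr - mb) < .Machine$double.eps) NA_real_
            else (d_obs - mb) / (mr - mb)
    p <- (1 + sum(d_rand <= d_obs)) / (1 + n_perm)
    structure(list(d_obs = d_obs, mean_d_random = mr, mean_d_brownian = mb,
                   D = if (convention == "fritz_purvis") D_fp else D_fp + 1,
                   D_fritz_purvis = D_fp, D_as_printed = D_fp + 1,
                   p = p, convention = convention,
                   null_d_random = d_rand, null_d_brownian = d_brown),
              class = "d_stat_result")
  })
}

#' @export
print.d_stat_result <- function(x, ...) {
  if (is.na(x$d_obs)) {
    cat("D statistic: degenerate (constant trait)\n")
  } else {
    cat(sprintf("D = %.3f (%s; fritz_purvis %.3f, as_printed %.3f), p = %.4g\n",
                x$D, x$convention, x$D_fritz_purvis, x$D_as_printed, x$p))
  }
  invisible(x)
}

#' D statistics for every GO column of a significance matrix
#'
#' @param phylogeny species tree.
#' @param significance_matrix species x GO logical matrix.
#' @param n_perm,n_brownian,seed,convention passed to [d_statistic()];
#'   column `j` uses `seed + j - 1`.
#' @return data frame `go_id`, `D`, `D_fritz_purvis`, `D_as_printed`, `p`,
#'   `degenerate`.
#' @export
d_statistic_table <- function(phylogeny, significance_matrix, n_perm = 999,
                              n_brownian = 999, seed = 1L,
                              convention = "fritz_purvis") {
  cols <- colnames(significance_matrix)
  rows <- lapply(seq_along(cols), function(j) {
    res <- d_statistic(phylogeny, significance_matrix[, j],
                       n_perm = n_perm, n_brownian = n_brownian,
                       seed = as.integer((as.numeric(seed) + j - 1) %% 2147483647),
                       convention = convention)
    data.frame(go_id = cols[j], D = res$D,
               D_fritz_purvis = res$D_fritz_purvis,
               D_as_printed = res$D_as_printed, p = res$p,
               degenerate = is.na(res$d_obs), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
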