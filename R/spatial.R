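#' Empirical semivariogram
#'
#' Matheron estimator: `gamma(h) = 1/(2 N_h) * sum (z_i - z_j)^2` over
#' point pairs whose separation falls in each distance bin. Bins of equal
#' width up to `max_lag` (default half the maximum pairwise distance);
#' empty bins are dropped.
#'
#' @param cores data frame with `x_m`, `y_m`, `vwc` columns.
#' @param n_bins number of lag bins (default 12).
#' @param max_lag maximum lag distance in metres.
#' @return data frame `lag` (bin midpoint), `gamma`, `n_pairs`.
#' @export
empirical_variogram <- function(cores, n_bins = 12, max_lag = NULL) {
  if (nrow(cores) < 2) stop("need at least two cores", call. = FALSE)
  h <- stats::dist(cores[, c("x_m", "y_m")])
  dz2 <- stats::dist(cores$vwc)^2
  if (is.null(max_lag)) max_lag <- max(h) / 2
  if (max_lag <= 0) stop("`max_lag` must be positive", call. = FALSE)
  brk <- seq(0, max_lag, length.out = n_bins + 1L)
  bin <- cut(as.vector(h), brk, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(bin)
  g <- tapply(as.vector(dz2)[keep], bin[keep], function(v) mean(v) / 2)
  n <- tapply(rep(1, sum(keep)), bin[keep], sum)
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  idx <- as.integer(names(g))
  data.frame(lag = mid[idx], gamma = as.numeric(g),
             n_pairs = as.integer(n))
}

vgm_gamma <- function(model, h) {
  a <- model$range; n <- model$nugget; s <- model$psill
  base <- switch(model$model,
    spherical = ifelse(h >= a, s, s * (1.5 * h / a - 0.5 * (h / a)^3)),
    exponential = s * (1 - exp(-3 * h / a)),
    stop("unknown variogram model: ", model$model, call. = FALSE))
  out <- n + base
  out[h == 0] <- 0  # gamma(0) = 0 by definition; nugget is the limit h -> 0+
  out
}

#' Fit a variogram model by weighted least squares
#'
#' Minimises `sum w_k (gamma_emp_k - gamma_model_k)^2` with weights
#' `w_k = n_pairs_k / lag_k^2` over (nugget, partial sill, range) with
#' nonnegativity bounds, using a deterministic multi-start grid of initial
#' values and L-BFGS-B.
#'
#' @param lag_table output of [empirical_variogram()].
#' @param model `"spherical"` or `"exponential"`.
#' @return a `variogram_model`: list with `model`, `nugget`, `psill`,
#'   `range`, `objective`, `lag_table`.
#' @export
fit_variogram <- function(lag_table, model = c("spherical", "exponential")) {
  model <- match.arg(model)
  if (nrow(lag_table) < 3) stop("need at least three nonempty bins", call. = FALSE)
  w <- lag_table$n_pairs / lag_table$lag^2
  hv <- lag_table$lag; gv <- lag_table$gamma
  obj <- function(par) {
    m <- list(model = model, nugget = par[1], psill = par[2], range = par[3])
    sum(w * (gv - vgm_gamma(m, hv))^2)
  }
  gmax <- max(gv); hmax <- max(hv)
  if (gmax <= 0) {
    warning("flat variogram (all semivariances zero); sill set to 0",
            call. = FALSE)
    return(structure(list(model = model, nugget = 0, psill = 0,
                          range = hmax, objective = 0,
                          lag_table = lag_table, flat = TRUE),
                     class = "variogram_model"))
  }
  starts <- expand.grid(nugget = c(0, 0.25, 0.5) * min(gv[gv >= 0], gmax),
                        psill = c(0.5, 1) * gmax,
                        range = c(0.25, 0.5, 0.75, 1) * hmax)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                   lower = c(0, 0, hmax * 1e-4),
                   upper = c(Inf, Inf, hmax * 10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("variogram fit failed to converge from any start", call. = FALSE)
  out <- structure(list(model = model, nugget = best$par[1],
                        psill = best$par[2], range = best$par[3],
                        objective = best$value, lag_table = lag_table),
                   class = "variogram_model")
  if (out$psill < 1e-8 * gmax)
    warning("fitted partial sill is ~0 (flat variogram); range is unidentified",
            call. = FALSE)
  out
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("%s variogram: nugget = %.4g, partial sill = %.4g, range = %.4g m\n",
              x$model, x$nugget, x$psill, x$range))
  invisible(x)
}

#' Ordinary kriging
#'
#' Solves the ordinary-kriging system in semivariance form (Lagrange
#' multiplier enforcing unit-sum weights) and predicts at the target
#' points. With a zero nugget the prediction at a core location reproduces
#' its measured value exactly. Duplicate core locations are averaged with a
#' warning.
#'
#' @param cores data frame `x_m`, `y_m`, `vwc`.
#' @param variogram a [fit_variogram()] model (or any list with `model`,
#'   `nugget`, `psill`, `range`).
#' @param target_points two-column matrix/data frame of target x, y (m).
#' @return list with `prediction` (numeric per target), `weights`
#'   (n_cores x n_targets matrix), `lagrange` (per target).
#' @export
ordinary_krige <- function(cores, variogram, target_points) {
  if (nrow(cores) < 1) stop("need at least one core", call. = FALSE)
  xy <- as.matrix(cores[, c("x_m", "y_m")])
  z <- cores$vwc
  key <- paste(xy[, 1], xy[, 2])
  if (anyDuplicated(key)) {
    warning("duplicate core locations averaged", call. = FALSE)
    uk <- unique(key)
    z <- as.numeric(tapply(z, factor(key, levels = uk), mean))
    xy <- xy[match(uk, key), , drop = FALSE]
  }
  n <- nrow(xy)
  tp <- as.matrix(target_points)
  m <- nrow(tp)
  if (n == 1L) {
    return(list(prediction = rep(z, m),
                weights = matrix(1, 1, m), lagrange = rep(0, m)))
  }
  H <- as.matrix(stats::dist(xy))
  A <- rbind(cbind(vgm_gamma(variogram, H), 1), c(rep(1, n), 0))
  ht <- sqrt(outer(tp[, 1], xy[, 1], `-`)^2 + outer(tp[, 2], xy[, 2], `-`)^2)
  B <- rbind(t(vgm_gamma(variogram, ht)), 1)
  W <- solve(A, B)
  list(prediction = as.vector(t(W[seq_len(n), , drop = FALSE]) %*% z),
       weights = W[seq_len(n), , drop = FALSE],
       lagrange = W[n + 1L, ])
}

#' Krige soil moisture onto the subplot grid
#'
#' Fits (or accepts) a variogram and predicts vwc at every subplot centre.
#'
#' @param cores soil-core data frame.
#' @param nx,ny,cell grid dimensions and cell size (m).
#' @param model variogram model family.
#' @param variogram optional prefit model (skips fitting).
#' @return list with `grid` (nx x ny matrix of kriged vwc) and `variogram`.
#' @export
krige_moisture_map <- function(cores, nx, ny, cell = 20,
                               model = "exponential", variogram = NULL) {
  if (is.null(variogram)) {
    lag <- empirical_variogram(cores)
    variogram <- fit_variogram(lag, model)
  }
  targets <- subplot_centers(nx, ny, cell)
  kr <- ordinary_krige(cores, variogram, targets)
  list(grid = matrix(kr$prediction, nx, ny), variogram = variogram)
}

torus_shift <- function(m, dx, dy) {
  nx <- nrow(m); ny <- ncol(m)
  m[((seq_len(nx) - 1L + dx) %% nx) + 1L,
    ((seq_len(ny) - 1L + dy) %% ny) + 1L, drop = FALSE]
}

#' Torus-translation correlation test
#'
#' Pearson correlation between two subplot maps with a p-value from an
#' exhaustive torus translation: `map_b` is cyclically shifted by every
#' (dx, dy) offset in subplot units (optionally also its three
#' reflections), `r` is recomputed at every shift over jointly non-missing
#' cells, and `p` is the proportion of null `|r| >= |r_obs|` (the identity
#' shift is part of the null, so `p >= 1/n_shifts`). Missing cells travel
#' with their map.
#'
#' @param map_a,map_b numeric matrices on the same grid (NA allowed).
#' @param mode `"translations"` (default) or `"translations+reflections"`.
#' @param sided `"two"` (default, on `|r|`) or `"one"` (tail in the sign of
#'   the observed correlation).
#' @return a `torus_cor`: list `r_obs`, `p`, `null_r`, `n_shifts`, `mode`,
#'   `n_cells`.
#' @export
torus_correlation <- function(map_a, map_b,
                              mode = c("translations",
                                       "translations+reflections"),
                              sided = c("two", "one")) {
  mode <- match.arg(mode)
  sided <- match.arg(sided)
  if (!identical(dim(map_a), dim(map_b)))
    stop("maps must share a grid", call. = FALSE)
  joint <- !is.na(map_a) & !is.na(map_b)
  if (sum(joint) < 3) stop("fewer than 3 jointly non-missing cells", call. = FALSE)
  const <- function(m) {
    v <- m[!is.na(m)]
    length(v) < 2 || max(v) - min(v) < .Machine$double.eps
  }
  if (const(map_a) || const(map_b))
    stop("correlation undefined for a constant map", call. = FALSE)
  variants <- list(map_b)
  if (mode == "translations+reflections") {
    variants <- c(variants, list(map_b[nrow(map_b):1, , drop = FALSE],
                                 map_b[, ncol(map_b):1, drop = FALSE],
                                 map_b[nrow(map_b):1, ncol(map_b):1,
                                       drop = FALSE]))
  }
  nx <- nrow(map_a); ny <- ncol(map_a)
  null_r <- numeric(0)
  for (v in variants) {
    for (dy in 0:(ny - 1L)) for (dx in 0:(nx - 1L)) {
      bs <- torus_shift(v, dx, dy)
      r <- suppressWarnings(
        stats::cor(as.vector(map_a), as.vector(bs),
                   use = "pairwise.complete.obs"))
      null_r <- c(null_r, r)
    }
  }
  r_obs <- null_r[1L]  # identity shift of the untransformed map
  nr <- null_r[!is.na(null_r)]
  p <- if (sided == "two") mean(abs(nr) >= abs(r_obs))
       else if (r_obs >= 0) mean(nr >= r_obs) else mean(nr <= r_obs)
  structure(list(r_obs = r_obs, p = p, null_r = null_r,
                 n_shifts = length(null_r), mode = mode,
                 n_cells = sum(joint)),
            class = "torus_cor")
}

#' @export
print.torus_cor <- function(x, ...) {
  cat(sprintf("torus translation: r = %.3f, p = %.4g (%d shifts, %s)\n",
              x$r_obs, x$p, x$n_shifts, x$mode))
  invisible(x)
}

#' Place point soil-core values on the subplot grid
#'
#' Averages core vwc within each containing subplot; subplots without cores
#' are NA. Used for the point-mode correlation (only core-bearing subplots
#' enter the Pearson correlation).
#'
#' @param cores soil-core data frame.
#' @param nx,ny,cell grid geometry.
#' @return nx x ny matrix.
#' @export
cores_to_grid <- function(cores, nx, ny, cell = 20) {
  ix <- pmin(nx, pmax(1L, floor(cores$x_m / cell) + 1L))
  iy <- pmin(ny, pmax(1L, floor(cores$y_m / cell) + 1L))
  m <- matrix(NA_real_, nx, ny)
  agg <- tapply(cores$vwc, list((iy - 1L) * nx + ix), mean)
  idx <- as.integer(names(agg))
  m[idx] <- as.numeric(agg)
  m
}
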