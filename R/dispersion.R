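#' Abundance-weighted mean pairwise distance
#'
#' `MPD = sum_ij delta_ij f_i f_j / sum_ij f_i f_j` over the species present
#' in the sample. By default the sums run over heterospecific pairs only
#' (`i != j`); `include_conspecific = TRUE` evaluates the unrestricted
#' double sum, whose zero-distance conspecific terms deflate MPD in
#' monodominant samples.
#'
#' @param abundances named numeric vector of counts per species.
#' @param distance_matrix a [species_dist()] matrix covering those species.
#' @param include_conspecific include `i == j` terms (default `FALSE`).
#' @return scalar MPD, or `NA` when fewer than two species are present.
#' @export
mpd <- function(abundances, distance_matrix, include_conspecific = FALSE) {
  present <- names(abundances)[abundances > 0]
  if (length(present) < 2) return(NA_real_)
  f <- abundances[present]
  D <- distance_matrix[present, present, drop = FALSE]
  num <- as.numeric(t(f) %*% D %*% f)  # diag(D) = 0, so i = j adds nothing
  den <- sum(f)^2 - if (include_conspecific) 0 else sum(f^2)
  num / den
}

# Vectorised MPD over all subplots: F is subplot x species, D species x
# species aligned to F's columns. Returns list(mpd, n_present).
mpd_all_subplots <- function(F, D, include_conspecific = FALSE) {
  num <- rowSums((F %*% D) * F)
  tot <- rowSums(F)
  den <- tot^2 - if (include_conspecific) 0 else rowSums(F^2)
  n_present <- rowSums(F > 0)
  out <- num / den
  out[n_present < 2 | den <= 0] <- NA_real_
  list(mpd = out, n_present = n_present)
}

#' Standardized effect size of MPD per subplot
#'
#' Compares the observed abundance-weighted MPD of every subplot with a
#' taxa-label null: per iteration one permutation of the species labels on
#' the distance matrix is drawn for the full pool and MPD is recomputed for
#' every subplot. `ses = (mpd_obs - null_mean) / null_sd`; negative values
#' mean co-occurring species are more similar than expected. Subplots with
#' fewer than two species present, or with a zero null standard deviation,
#' get a missing ses.
#'
#' @param community a `community` (see [gen_community()] or
#'   [read_community()]).
#' @param distance_matrix a [species_dist()] covering the species pool.
#' @param n_null number of label permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @param include_conspecific passed to the MPD computation.
#' @return a `ses_map`: data frame with `subplot`, `x_index`, `y_index`,
#'   `mpd_obs`, `null_mean`, `null_sd`, `ses`, `n_species_present`;
#'   attributes `source`, `n_null`, `seed`, `nx`, `ny`, `cell`.
#' @export
ses_mpd_map <- function(community, distance_matrix, n_null = 999, seed = 1L,
                        include_conspecific = FALSE) {
  if (n_null < 2) stop("`n_null` must be at least 2", call. = FALSE)
  F <- community$abund
  labs <- colnames(F)
  missing <- setdiff(labs, rownames(distance_matrix))
  if (length(missing))
    stop("species missing from distance matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  D <- distance_matrix[labs, labs]
  off <- D[upper.tri(D)]
  if (length(off) && max(off) - min(off) < 1e-12 && length(labs) > 2)
    warning("distance matrix is degenerate (all pairwise distances equal); ",
            "all ses will be missing", call. = FALSE)
  obs <- mpd_all_subplots(F, D, include_conspecific)
  n <- length(labs)
  sum_x <- numeric(nrow(F)); sum_x2 <- numeric(nrow(F))
  with_seed(seed, {
    for (it in seq_len(n_null)) {
      perm <- sample.int(n)
      Dp <- D[perm, perm]
      dimnames(Dp) <- dimnames(D)
      nm <- mpd_all_subplots(F, Dp, include_conspecific)$mpd
      sum_x <- sum_x + nm
      sum_x2 <- sum_x2 + nm^2
    }
  })
  null_mean <- sum_x / n_null
  null_var <- pmax(0, (sum_x2 - n_null * null_mean^2) / (n_null - 1))
  null_sd <- sqrt(null_var)
  ses <- (obs$mpd - null_mean) / null_sd
  ses[!is.finite(ses)] <- NA_real_
  out <- data.frame(subplot = seq_len(nrow(F)),
                    x_index = community$x_index,
                    y_index = community$y_index,
                    mpd_obs = obs$mpd,
                    null_mean = null_mean, null_sd = null_sd, ses = ses,
                    n_species_present = obs$n_present)
  structure(out, class = c("ses_map", "data.frame"),
            source = attr(distance_matrix, "source"),
            n_null = n_null, seed = seed,
            nx = community$nx, ny = community$ny, cell = community$cell)
}

#' Lay a ses_map out on its subplot grid
#'
#' @param map a `ses_map`.
#' @param what column to grid (default `"ses"`).
#' @return an nx x ny matrix (NA where undefined).
#' @export
ses_grid <- function(map, what = "ses") {
  nx <- attr(map, "nx"); ny <- attr(map, "ny")
  m <- matrix(NA_real_, nx, ny)
  m[cbind(map$x_index, map$y_index)] <- map[[what]]
  m
}

#' Per-GO-term dispersion maps
#'
#' For each GO term (column of the binary significance matrix) builds the
#' 0/1 mismatch dissimilarity and computes the subplot ses map. Uses a
#' closed form for binary distances: with `F1` the summed abundance of
#' significantly enriched species in a subplot and `F0` the rest,
#' `MPD = 2 F1 F0 / denominator` — identical to the generic route, column
#' by column, permutation by permutation. Monomorphic columns yield
#' all-missing maps.
#'
#' @param community a `community`.
#' @param significance_matrix species x GO logical matrix.
#' @param n_null permutations per term.
#' @param seed master seed; term `j` uses `seed + j - 1`.
#' @return named list of `ses_map` objects (one per GO column).
#' @export
per_go_ses <- function(community, significance_matrix, n_null = 999,
                       seed = 1L) {
  F <- community$abund
  labs <- colnames(F)
  missing <- setdiff(labs, rownames(significance_matrix))
  if (length(missing))
    stop("species missing from significance matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  S <- significance_matrix[labs, , drop = FALSE] + 0
  tot <- rowSums(F)
  sumsq <- rowSums(F^2)
  den <- tot^2 - sumsq
  n_present <- rowSums(F > 0)
  bad <- n_present < 2 | den <= 0
  n <- length(labs)
  maps <- lapply(seq_len(ncol(S)), function(j) {
    x <- S[, j]
    term_seed <- as.integer((as.numeric(seed) + j - 1) %% 2147483647)
    f1 <- as.vector(F %*% x)
    obs <- 2 * f1 * (tot - f1) / den
    obs[bad] <- NA_real_
    X <- with_seed(term_seed, {
      vapply(seq_len(n_null), function(i) x[sample.int(n)], numeric(n))
    })
    F1n <- F %*% X
    Mn <- 2 * F1n * (tot - F1n) / den
    Mn[bad, ] <- NA_real_
    null_mean <- rowMeans(Mn)
    null_sd <- sqrt(pmax(0, rowSums((Mn - null_mean)^2) / (n_null - 1)))
    ses <- (obs - null_mean) / null_sd
    ses[!is.finite(ses)] <- NA_real_
    out <- data.frame(subplot = seq_len(nrow(F)),
                      x_index = community$x_index,
                      y_index = community$y_index,
                      mpd_obs = obs, null_mean = null_mean,
                      null_sd = null_sd, ses = ses,
                      n_species_present = n_present)
    structure(out, class = c("ses_map", "data.frame"),
              source = paste0("per-GO:", colnames(S)[j]),
              n_null = n_null, seed = term_seed,
              nx = community$nx, ny = community$ny, cell = community$cell)
  })
  names(maps) <- colnames(S)
  maps
}

#' Rank GO terms by mean dispersion effect size
#'
#' Averages ses over subplots (missing excluded) per GO term and sorts
#' ascending: the most negative mean ses — the strongest co-occurrence of
#' similarly enriched species — ranks first. Ties break by GO id; terms
#' with all-missing maps are flagged degenerate and ranked last.
#'
#' @param maps named list of `ses_map` objects from [per_go_ses()].
#' @param namespaces optional named vector mapping GO id to namespace.
#' @return data frame `go_id`, `namespace`, `mean_ses`, `n_subplots`,
#'   `degenerate`, `rank`.
#' @export
rank_go_terms <- function(maps, namespaces = NULL) {
  if (length(maps) == 0L) stop("no maps supplied", call. = FALSE)
  ids <- names(maps)
  mean_ses <- vapply(maps, function(m) {
    v <- m$ses[!is.na(m$ses)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  n_sub <- vapply(maps, function(m) sum(!is.na(m$ses)), integer(1))
  degen <- is.na(mean_ses)
  ord <- order(degen, mean_ses, ids)
  out <- data.frame(go_id = ids[ord],
                    namespace = if (is.null(namespaces)) NA_character_
                                else unname(namespaces[ids[ord]]),
                    mean_ses = mean_ses[ord],
                    n_subplots = n_sub[ord],
                    degenerate = degen[ord],
                    stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Aggregate subplots into coarser grain
#'
#' Sums abundances over `factor x factor` blocks of subplots (e.g. factor 2
#' gives 40 x 40 m, factor 5 gives 100 x 100 m from 20-m cells). Incomplete
#' blocks at the grid edge are dropped; the number of dropped subplots is
#' recorded in attribute `dropped_subplots`.
#'
#' @param community a `community`.
#' @param factor positive integer aggregation factor.
#' @return a `community` at the coarser grain.
#' @export
aggregate_subplots <- function(community, factor) {
  factor <- as.integer(factor)
  if (factor < 1) stop("`factor` must be >= 1", call. = FALSE)
  if (factor > community$nx || factor > community$ny)
    stop("`factor` exceeds grid dimensions", call. = FALSE)
  if (factor == 1L) {
    attr(community, "dropped_subplots") <- 0L
    return(community)
  }
  nx2 <- community$nx %/% factor
  ny2 <- community$ny %/% factor
  bx <- (community$x_index - 1L) %/% factor + 1L
  by <- (community$y_index - 1L) %/% factor + 1L
  keep <- bx <= nx2 & by <= ny2
  block <- (by[keep] - 1L) * nx2 + bx[keep]
  ab <- rowsum(community$abund[keep, , drop = FALSE], block)
  ab <- ab[order(as.integer(rownames(ab))), , drop = FALSE]
  g <- expand.grid(ix = seq_len(nx2), iy = seq_len(ny2))
  out <- structure(list(abund = unname(as.matrix(ab)),
                        x_index = g$ix, y_index = g$iy,
                        cell = community$cell * factor,
                        nx = nx2, ny = ny2),
                   class = "community")
  colnames(out$abund) <- colnames(community$abund)
  attr(out, "dropped_subplots") <- sum(!keep)
  out
}
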