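#' Generate a spatially autocorrelated soil-moisture surface
#'
#' Simulates volumetric water content on the subplot grid as a Gaussian
#' random field whose covariance follows the configured exponential
#' variogram (practical-range convention, `C(h) = sill * exp(-3 h / range)`,
#' plus a nugget on the diagonal), then min-max rescales to `[0, 1]`.
#'
#' @param config a [sim_config()].
#' @param seed optional seed; defaults to a stage seed derived from
#'   `config$seed`.
#' @param rescale rescale to `[0, 1]` (the default). `FALSE` returns the raw
#'   field, useful for checking the variogram of the generating process.
#' @return a `moisture_grid`: list with `values` (an `grid_nx` x `grid_ny`
#'   matrix), `nx`, `ny` and `cell` (cell side, metres).
#' @export
gen_moisture_surface <- function(config, seed = NULL, rescale = TRUE) {
  validate_sim_config(config)
  if (is.null(seed)) seed <- derive_seed(config$seed, "moisture")
  nx <- config$grid_nx; ny <- config$grid_ny; cell <- 20
  centers <- subplot_centers(nx, ny, cell)
  n <- nrow(centers)
  sill <- config$vario_sill; nug <- config$vario_nugget
  rng <- config$vario_range
  z <- with_seed(seed, {
    eps <- stats::rnorm(n)
    if (sill == 0 && nug == 0) {
      rep(0, n)
    } else {
      h <- as.matrix(stats::dist(centers))
      C <- sill * exp(-3 * h / rng)
      diag(C) <- sill + nug
      # small ridge keeps the Cholesky stable for near-singular covariances
      L <- chol(C + diag(1e-10, n))
      as.vector(crossprod(L, eps))
    }
  })
  if (rescale) {
    if (diff(range(z)) < .Machine$double.eps) z <- rep(0.5, n)
    else z <- (z - min(z)) / (max(z) - min(z))
  }
  structure(list(values = matrix(z, nrow = nx, ncol = ny),
                 nx = nx, ny = ny, cell = cell),
            class = "moisture_grid")
}

subplot_centers <- function(nx, ny, cell = 20) {
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  cbind(x = (g$ix - 0.5) * cell, y = (g$iy - 0.5) * cell)
}

#' Generate a rooted ultrametric phylogeny
#'
#' Coalescent tree with `n_species` tips labelled `sp01 ... spNN`, standing
#' in for a dated chronogram. Depth is rescaled to 1 so patristic distances
#' are comparable across replicates.
#'
#' @param n_species number of tips (>= 2).
#' @param seed integer seed.
#' @return an [ape::phylo] object, rooted, bifurcating, ultrametric.
#' @export
gen_phylogeny <- function(n_species, seed = 1L) {
  if (n_species < 2) stop("`n_species` must be >= 2", call. = FALSE)
  labs <- species_labels(n_species)
  tr <- with_seed(seed, ape::rcoal(n_species, tip.label = labs))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr
}

species_labels <- function(n) sprintf("sp%02d", seq_len(n))

go_term_ids <- function(n_bp, n_mf) {
  list(bp = sprintf("BP:%04d", seq_len(n_bp)),
       mf = sprintf("MF:%04d", seq_len(n_mf)))
}

#' Assign species to drought-response guilds
#'
#' Each species belongs to exactly one guild; each guild has a moisture
#' optimum (evenly spread across the rescaled moisture range) and a set of
#' drought-responsive ("active") GO terms. With `phylo_coupling = 1` guilds
#' coincide with clades of the phylogeny; with `phylo_coupling = 0` guild
#' labels are independent of the tree, emulating the absence of
#' phylogenetic signal in expression response. Active GO sets are disjoint
#' across guilds whenever `guild_enrichment_frac * n_guilds <= 1`.
#'
#' @param config a [sim_config()].
#' @param phylogeny the species tree from [gen_phylogeny()].
#' @param seed optional stage seed.
#' @return a `guild_assignment`: list with `guild` (named integer vector),
#'   `optima` (per-guild vwc optimum), `active_go` (per-guild character
#'   vectors of GO ids) and `go_ids` (the namespace-split universe).
#' @export
gen_guilds <- function(config, phylogeny, seed = NULL) {
  validate_sim_config(config)
  if (is.null(seed)) seed <- derive_seed(config$seed, "guilds")
  n <- config$n_species; k <- config$n_guilds
  if (ape::Ntip(phylogeny) != n)
    stop("phylogeny has ", ape::Ntip(phylogeny), " tips, expected ", n,
         call. = FALSE)
  labs <- sort(phylogeny$tip.label)
  with_seed(seed, {
    # clade-based labels from cutting the tree's cophenetic dendrogram
    coph <- ape::cophenetic.phylo(phylogeny)[labs, labs]
    hc <- stats::hclust(stats::as.dist(coph), method = "average")
    clade_lab <- stats::cutree(hc, k = k)[labs]
    rand_lab <- sample(rep_len(seq_len(k), n))
    use_clade <- stats::runif(n) < config$phylo_coupling
    guild <- ifelse(use_clade, clade_lab, rand_lab)
    names(guild) <- labs
    # deterministically fill any empty guild from the largest one
    repeat {
      sizes <- tabulate(guild, nbins = k)
      if (all(sizes > 0L)) break
      empty <- which(sizes == 0L)[1L]
      donor <- which.max(sizes)
      guild[which(guild == donor)[1L]] <- empty
    }
    optima <- (seq_len(k) - 0.5) / k
    ids <- go_term_ids(config$n_go_bp, config$n_go_mf)
    active_go <- pick_active_go(ids, k, config$guild_enrichment_frac)
    structure(list(guild = guild, optima = optima,
                   active_go = active_go, go_ids = ids),
              class = "guild_assignment")
  })
}

pick_active_go <- function(ids, k, frac) {
  pick_ns <- function(terms) {
    m <- length(terms)
    n_active <- max(if (frac > 0) 1L else 0L, floor(frac * m))
    if (n_active == 0L) return(replicate(k, character(0), simplify = FALSE))
    pool <- sample(terms)
    if (n_active * k <= m) {
      # disjoint blocks
      lapply(seq_len(k), function(g) pool[((g - 1) * n_active + 1):(g * n_active)])
    } else {
      lapply(seq_len(k), function(g) sample(terms, n_active))
    }
  }
  bp <- pick_ns(ids$bp); mf <- pick_ns(ids$mf)
  lapply(seq_len(k), function(g) c(bp[[g]], mf[[g]]))
}

#' Assemble a community on the moisture surface
#'
#' Gaussian-niche habitat filtering: species `s` in subplot `q` has Poisson
#' abundance with mean
#' `mean_abundance * n_species * w_s(q) / sum_s' w_s'(q)` where
#' `w_s(q) = exp(-lambda * (m_q - opt_s)^2 / (2 * niche_sd^2))` and `opt_s`
#' is the optimum of the species' guild. `lambda = 0` (no filtering) makes
#' all species exchangeable with expected abundance `mean_abundance`.
#'
#' @param guilds a [gen_guilds()] result.
#' @param moisture a [gen_moisture_surface()] result.
#' @param config a [sim_config()].
#' @param seed optional stage seed.
#' @return a `community`: list with `abund` (subplot x species integer
#'   matrix, rows ordered column-major over the grid), `x_index`, `y_index`,
#'   `cell`, `nx`, `ny`.
#' @export
gen_community <- function(guilds, moisture, config, seed = NULL) {
  validate_sim_config(config)
  if (is.null(seed)) seed <- derive_seed(config$seed, "community")
  m <- as.vector(moisture$values)
  labs <- names(guilds$guild)
  opt <- guilds$optima[guilds$guild]
  lam <- config$filter_strength
  w <- exp(-lam * outer(m, opt, function(mq, o) (mq - o)^2) /
             (2 * config$niche_sd^2))
  mu <- config$mean_abundance * config$n_species * w / rowSums(w)
  ab <- with_seed(seed, {
    matrix(stats::rpois(length(mu), as.vector(mu)), nrow = nrow(mu))
  })
  colnames(ab) <- labs
  g <- expand.grid(ix = seq_len(moisture$nx), iy = seq_len(moisture$ny))
  structure(list(abund = ab, x_index = g$ix, y_index = g$iy,
                 cell = moisture$cell, nx = moisture$nx, ny = moisture$ny),
            class = "community")
}

#' Generate per-species differential-expression gene tables
#'
#' Every GO term of the shared universe is annotated in every species (with
#' `drop_go_frac > 0` a random fraction of (species, term) pairs is removed
#' to exercise the shared-universe filter). A gene annotated to any of its
#' species' active GO terms is differentially expressed with probability
#' `de_rate_in`, otherwise `de_rate_out`; a species' active set is its
#' guild's shared set, with mesic-guild species swapping part of it for
#' species-specific terms under `coherence_gradient` (see [sim_config()]).
#' DE genes draw
#' `|log2FC| = |Normal(lfc_mean, lfc_sd)| + 1` with random sign and
#' p-values `10^-Uniform(3, 10)`; background genes draw
#' `log2FC ~ Normal(0, 0.2)` and `p ~ Uniform(0, 1)`.
#'
#' @param guilds a [gen_guilds()] result.
#' @param config a [sim_config()].
#' @param seed optional stage seed.
#' @return named list (one per species) of data frames with columns
#'   `gene_id`, `log2fc`, `pvalue`, `go_terms` (semicolon-separated), plus a
#'   `de_truth` attribute per table.
#' @export
gen_gene_tables <- function(guilds, config, seed = NULL) {
  validate_sim_config(config)
  if (config$de_rate_in < config$de_rate_out)
    warning("de_rate_in < de_rate_out: enrichment power is inverted",
            call. = FALSE)
  if (is.null(seed)) seed <- derive_seed(config$seed, "genes")
  labs <- names(guilds$guild)
  terms <- unlist(guilds$go_ids, use.names = FALSE)
  ng <- config$n_genes
  # mean genes annotated per GO term (before guaranteeing coverage)
  p_annot <- min(1, 30 / ng)
  with_seed(seed, {
    tabs <- lapply(labs, function(sp) {
      g <- guilds$guild[[sp]]
      guild_set <- guilds$active_go[[g]]
      # response-coherence gradient: mesic-guild species trade a share of
      # the guild's shared terms for idiosyncratic ones, so the coherent
      # (mutually similar) drought response concentrates in xeric guilds
      shared_frac <- 1 - config$coherence_gradient * guilds$optima[g]
      n_shared <- round(shared_frac * length(guild_set))
      active <- guild_set[seq_len(n_shared)]
      n_idio <- length(guild_set) - n_shared
      if (n_idio > 0) {
        other <- setdiff(terms, guild_set)
        if (length(other))
          active <- c(active, sample(other, min(n_idio, length(other))))
      }
      ann <- matrix(stats::runif(ng * length(terms)) < p_annot,
                    nrow = ng, ncol = length(terms))
      empty <- which(colSums(ann) == 0L)
      for (j in empty) ann[sample.int(ng, 1L), j] <- TRUE
      if (config$drop_go_frac > 0) {
        drop <- stats::runif(length(terms)) < config$drop_go_frac
        ann[, drop] <- FALSE
      }
      in_active <- if (length(active))
        rowSums(ann[, terms %in% active, drop = FALSE]) > 0L
      else rep(FALSE, ng)
      de <- stats::runif(ng) <
        ifelse(in_active, config$de_rate_in, config$de_rate_out)
      lfc <- stats::rnorm(ng, 0, 0.2)
      pv <- stats::runif(ng)
      nde <- sum(de)
      if (nde > 0) {
        lfc[de] <- sample(c(-1, 1), nde, replace = TRUE) *
          (abs(stats::rnorm(nde, config$lfc_mean, config$lfc_sd)) + 1)
        pv[de] <- 10^(-stats::runif(nde, 3, 10))
      }
      go_str <- vapply(seq_len(ng), function(i) {
        paste(terms[ann[i, ]], collapse = ";")
      }, character(1))
      out <- data.frame(gene_id = sprintf("%s_g%05d", sp, seq_len(ng)),
                        log2fc = lfc, pvalue = pv, go_terms = go_str,
                        stringsAsFactors = FALSE)
      attr(out, "de_truth") <- de
      out
    })
    names(tabs) <- labs
    tabs
  })
}

#' Generate species-level covariates
#'
#' Produces an 8-trait table, a days-to-wilting vector, and a three-column
#' tolerance table (shade, water-logging, drought). Traits mix a per-guild
#' mean with independent noise at weight `trait_coupling` and are
#' standardized. Drought tolerance is monotone in the guild moisture
#' optimum (drier optimum, higher tolerance); days to wilting follows the
#' same axis on a positive scale. With `tolerance_repulsion` the shade and
#' water-logging tolerances are evenly spread within each guild across the
#' full range, so that co-occurring (same-guild) species are more dissimilar
#' than random for those axes.
#'
#' @param guilds a [gen_guilds()] result.
#' @param config a [sim_config()].
#' @param seed optional stage seed.
#' @return list with `traits` (species x 8 matrix), `wilting_days` (named
#'   vector, days), `tolerances` (species x 3 matrix).
#' @export
gen_species_covariates <- function(guilds, config, seed = NULL) {
  validate_sim_config(config)
  if (is.null(seed)) seed <- derive_seed(config$seed, "covariates")
  labs <- names(guilds$guild)
  n <- length(labs); k <- length(guilds$optima)
  g <- guilds$guild
  trait_names <- c("foliar_n", "foliar_p", "sla", "wood_density",
                   "seed_mass", "leaf_area", "max_height", "foliar_c")
  with_seed(seed, {
    cpl <- config$trait_coupling
    traits <- vapply(trait_names, function(tn) {
      gm <- stats::rnorm(k)
      v <- cpl * gm[g] + (1 - cpl) * stats::rnorm(n)
      as.vector(scale(v))
    }, numeric(n))
    rownames(traits) <- labs

    tc <- config$tolerance_coupling
    dry_axis <- as.vector(scale(1 - guilds$optima[g]))  # drier optimum -> larger
    wilting <- pmax(1, 25 + 10 * (tc * dry_axis + (1 - tc) * stats::rnorm(n)))
    names(wilting) <- labs

    drought_tol <- tc * dry_axis + (1 - tc) * stats::rnorm(n)
    repel <- function() {
      # each guild spans the full range on an even lattice (over-dispersion
      # of same-guild species), plus residual noise
      v <- numeric(n)
      for (gg in seq_len(k)) {
        idx <- which(g == gg)
        lat <- seq(-1.5, 1.5, length.out = length(idx))
        v[idx] <- sample(lat)
      }
      tc * v + (1 - tc) * stats::rnorm(n)
    }
    plain <- function() tc * stats::rnorm(k)[g] + (1 - tc) * stats::rnorm(n)
    shade <- if (config$tolerance_repulsion) repel() else plain()
    wlog <- if (config$tolerance_repulsion) repel() else plain()
    tol <- cbind(shade = as.vector(scale(shade)),
                 water_logging = as.vector(scale(wlog)),
                 drought = as.vector(scale(drought_tol)))
    rownames(tol) <- labs
    list(traits = traits, wilting_days = wilting, tolerances = tol)
  })
}

#' Sample soil cores on a nested 40-m design
#'
#' Places a core at every interior node of a 40 x 40 m lattice; at every
#' other node (checkerboard) three satellite cores are added at 2, 8 and
#' 20 m in one uniform-random direction (resampled until all satellites fall
#' inside the plot). Measured vwc is the surface value of the containing
#' subplot plus Gaussian measurement noise, clamped to `[0, 1]`.
#'
#' @param moisture a [gen_moisture_surface()] result.
#' @param seed integer seed.
#' @param sigma_meas measurement noise sd (vwc units).
#' @return data frame with columns `x_m`, `y_m`, `vwc`, `type`
#'   ("node"/"satellite").
#' @export
gen_soil_cores <- function(moisture, seed = 1L, sigma_meas = 0.02) {
  nx <- moisture$nx; ny <- moisture$ny; cell <- moisture$cell
  if (nx < 2 || ny < 2) stop("grid must be at least 2 x 2 subplots", call. = FALSE)
  W <- nx * cell; H <- ny * cell
  gx <- 40 * seq_len(max(0L, ceiling(W / 40) - 1L))
  gy <- 40 * seq_len(max(0L, ceiling(H / 40) - 1L))
  nodes <- expand.grid(x = gx, y = gy)
  ij <- expand.grid(i = seq_along(gx), j = seq_along(gy))
  sat_node <- (ij$i + ij$j) %% 2 == 0
  with_seed(seed, {
    rows <- list(data.frame(x_m = nodes$x, y_m = nodes$y, type = "node",
                            stringsAsFactors = FALSE))
    for (ni in which(sat_node)) {
      repeat {
        th <- stats::runif(1, 0, 2 * pi)
        sx <- nodes$x[ni] + c(2, 8, 20) * cos(th)
        sy <- nodes$y[ni] + c(2, 8, 20) * sin(th)
        if (all(sx >= 0 & sx <= W & sy >= 0 & sy <= H)) break
      }
      rows[[length(rows) + 1L]] <-
        data.frame(x_m = sx, y_m = sy, type = "satellite",
                   stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    ix <- pmin(nx, pmax(1L, floor(out$x_m / cell) + 1L))
    iy <- pmin(ny, pmax(1L, floor(out$y_m / cell) + 1L))
    v <- moisture$values[cbind(ix, iy)]
    if (sigma_meas > 0) v <- v + stats::rnorm(nrow(out), 0, sigma_meas)
    out$vwc <- pmin(1, pmax(0, v))
    out[, c("x_m", "y_m", "vwc", "type")]
  })
}

#' Generate a complete synthetic study dataset
#'
#' Runs every generator with per-stage seeds derived from `config$seed` and
#' bundles the results with the ground truth (guild membership, optima,
#' active GO sets). The whole dataset is a pure function of the
#' configuration.
#'
#' @param config a [sim_config()].
#' @return a `sim_dataset` list: `config`, `moisture`, `phylogeny`,
#'   `guilds`, `community`, `gene_tables`, `covariates`, `soil_cores`.
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  moisture <- gen_moisture_surface(config)
  tree <- gen_phylogeny(config$n_species, derive_seed(config$seed, "tree"))
  guilds <- gen_guilds(config, tree)
  community <- gen_community(guilds, moisture, config)
  gene_tables <- gen_gene_tables(guilds, config)
  covariates <- gen_species_covariates(guilds, config)
  cores <- gen_soil_cores(moisture, derive_seed(config$seed, "cores"),
                          sigma_meas = config$sigma_meas)
  structure(list(config = config, moisture = moisture, phylogeny = tree,
                 guilds = guilds, community = community,
                 gene_tables = gene_tables, covariates = covariates,
                 soil_cores = cores),
            class = "sim_dataset")
}
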