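#' Simulation configuration
#'
#' Builds and validates the configuration that drives the synthetic-data
#' generator. Defaults emulate the study system: 21 canopy tree species in
#' 630 subplots of 20 x 20 m tiling a 25.2-ha plot (35 x 18 grid), a shared
#' GO universe of 59 biological-process and 45 molecular-function terms,
#' guild-structured drought response, and Gaussian-niche community assembly
#' along a spatially autocorrelated soil-moisture field.
#'
#' @param n_species number of species.
#' @param grid_nx,grid_ny subplot grid dimensions (20-m cells).
#' @param n_guilds number of drought-response guilds.
#' @param n_genes genes per species.
#' @param n_go_bp,n_go_mf shared GO terms per namespace.
#' @param guild_enrichment_frac fraction of GO terms (per namespace) that are
#'   drought-responsive in each guild.
#' @param de_rate_in,de_rate_out per-gene probability of differential
#'   expression for genes annotated to a guild-active GO term vs. others.
#' @param lfc_mean,lfc_sd effect-size distribution of DE genes; the absolute
#'   log2 fold change is `|Normal(lfc_mean, lfc_sd)| + 1`.
#' @param filter_strength habitat-filtering coefficient (lambda >= 0); 0 gives
#'   a neutral, species-exchangeable community.
#' @param niche_sd Gaussian niche breadth in volumetric-water-content units.
#' @param mean_abundance expected stems per species per subplot when
#'   filtering is off.
#' @param vario_range,vario_sill,vario_nugget moisture-field variogram
#'   parameters (range in metres; practical-range exponential covariance).
#' @param sigma_meas soil-core measurement noise (vwc units).
#' @param trait_coupling,phylo_coupling,tolerance_coupling mixing weights in
#'   `[0, 1]` tying traits, guild labels and tolerances to the guild truth.
#' @param tolerance_repulsion if `TRUE`, shade and water-logging tolerances
#'   are over-dispersed within guilds (each guild spans the full tolerance
#'   range on an even lattice), producing positive dispersion effect sizes.
#' @param coherence_gradient in `[0, 1]`: how strongly drought-response
#'   coherence declines toward mesic guilds. A species keeps fraction
#'   `1 - coherence_gradient * optimum` of its guild's shared active GO
#'   terms and swaps the rest for species-specific terms, so xeric-guild
#'   species respond coherently while mesic species respond
#'   idiosyncratically (stress-gradient filtering); 0 makes every guild
#'   equally coherent.
#' @param drop_go_frac fraction of (species, GO) annotation pairs removed, to
#'   exercise the shared-universe filter. Default 0 keeps every term in every
#'   species.
#' @param seed integer master seed; stage seeds are derived from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_species = 21,
                       grid_nx = 35, grid_ny = 18,
                       n_guilds = 3,
                       n_genes = 3000,
                       n_go_bp = 59, n_go_mf = 45,
                       guild_enrichment_frac = 0.2,
                       de_rate_in = 0.5, de_rate_out = 0.05,
                       lfc_mean = 1.5, lfc_sd = 1,
                       filter_strength = 0.5,
                       niche_sd = 0.25,
                       mean_abundance = 4,
                       vario_range = 100, vario_sill = 1, vario_nugget = 0.1,
                       sigma_meas = 0.02,
                       trait_coupling = 0.4,
                       phylo_coupling = 0,
                       tolerance_coupling = 0.5,
                       tolerance_repulsion = TRUE,
                       coherence_gradient = 0.4,
                       drop_go_frac = 0,
                       seed = 1L) {
  cfg <- list(
    n_species = as.integer(n_species),
    grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
    n_guilds = as.integer(n_guilds),
    n_genes = as.integer(n_genes),
    n_go_bp = as.integer(n_go_bp), n_go_mf = as.integer(n_go_mf),
    guild_enrichment_frac = guild_enrichment_frac,
    de_rate_in = de_rate_in, de_rate_out = de_rate_out,
    lfc_mean = lfc_mean, lfc_sd = lfc_sd,
    filter_strength = filter_strength,
    niche_sd = niche_sd,
    mean_abundance = mean_abundance,
    vario_range = vario_range, vario_sill = vario_sill,
    vario_nugget = vario_nugget,
    sigma_meas = sigma_meas,
    trait_coupling = trait_coupling,
    phylo_coupling = phylo_coupling,
    tolerance_coupling = tolerance_coupling,
    tolerance_repulsion = isTRUE(tolerance_repulsion),
    coherence_gradient = coherence_gradient,
    drop_go_frac = drop_go_frac,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_species", "grid_nx", "grid_ny", "n_guilds", "n_genes")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop("`", f, "` must be a single count >= 1", call. = FALSE)
  }
  if (cfg$n_go_bp < 0L || cfg$n_go_mf < 0L || cfg$n_go_bp + cfg$n_go_mf < 1L)
    stop("need at least one GO term across namespaces", call. = FALSE)
  probs <- c("guild_enrichment_frac", "de_rate_in", "de_rate_out",
             "trait_coupling", "phylo_coupling", "tolerance_coupling",
             "coherence_gradient", "drop_go_frac")
  for (f in probs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("`", f, "` must be a probability in [0, 1]", call. = FALSE)
  }
  if (cfg$filter_strength < 0) stop("`filter_strength` must be >= 0", call. = FALSE)
  if (cfg$niche_sd <= 0) stop("`niche_sd` must be > 0", call. = FALSE)
  if (cfg$mean_abundance < 0) stop("`mean_abundance` must be >= 0", call. = FALSE)
  if (cfg$vario_range <= 0) stop("`vario_range` must be > 0", call. = FALSE)
  if (cfg$vario_sill < 0 || cfg$vario_nugget < 0)
    stop("variogram sill and nugget must be >= 0", call. = FALSE)
  if (cfg$n_guilds > cfg$n_species)
    stop("`n_guilds` cannot exceed `n_species`", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d species, %d x %d subplot grid (%d subplots), %d guilds\n",
              x$n_species, x$grid_nx, x$grid_ny, x$grid_nx * x$grid_ny,
              x$n_guilds))
  cat(sprintf("  %d genes/species; GO universe %d BP + %d MF\n",
              x$n_genes, x$n_go_bp, x$n_go_mf))
  cat(sprintf("  filter_strength = %g, niche_sd = %g, seed = %d\n",
              x$filter_strength, x$niche_sd, x$seed))
  invisible(x)
}

# Deterministic per-stage seed derived from the master seed; kept within
# 32-bit integer range.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
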