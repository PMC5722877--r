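test_that("moisture surface respects variance, seed and range contracts", {
  cfg0 <- sim_config(grid_nx = 8, grid_ny = 6, vario_sill = 0,
                     vario_nugget = 0, seed = 5)
  m0 <- gen_moisture_surface(cfg0)
  expect_true(all(m0$values == m0$values[1, 1]))  # zero-variance field

  cfg <- sim_config(grid_nx = 8, grid_ny = 6, seed = 5)
  m1 <- gen_moisture_surface(cfg, seed = 1)
  m2 <- gen_moisture_surface(cfg, seed = 2)
  expect_false(identical(m1$values, m2$values))
  expect_identical(gen_moisture_surface(cfg, seed = 1)$values, m1$values)
  for (m in list(m1, m2)) {
    expect_true(all(m$values >= 0 & m$values <= 1))
    expect_equal(range(m$values), c(0, 1))
  }
  expect_error(sim_config(vario_range = 0), "vario_range")
  expect_error(sim_config(vario_sill = -1), "sill")
})

test_that("pure-nugget field has a flat variogram at the nugget level", {
  cfg <- sim_config(grid_nx = 10, grid_ny = 10, vario_sill = 0,
                    vario_nugget = 0.5)
  gammas <- sapply(1:10, function(s) {
    m <- gen_moisture_surface(cfg, seed = s, rescale = FALSE)
    cores <- data.frame(x_m = subplot_centers(10, 10)[, 1],
                        y_m = subplot_centers(10, 10)[, 2],
                        vwc = as.vector(m$values))
    empirical_variogram(cores, n_bins = 6)$gamma
  })
  lag_means <- rowMeans(gammas)
  expect_true(all(abs(lag_means - 0.5) < 0.1))
  expect_lt(max(lag_means) - min(lag_means), 0.1)  # flat
})

test_that("phylogeny generator yields seeded, bifurcating ultrametric trees", {
  tr <- gen_phylogeny(21, seed = 3)
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 21)
  expect_equal(tr$Nnode, 20)  # bifurcating rooted
  depths <- ape::node.depth.edgelength(tr)[1:21]
  expect_lt(max(depths) - min(depths), 1e-9)  # ultrametric

  tr2 <- gen_phylogeny(2, seed = 3)
  d <- ape::cophenetic.phylo(tr2)
  expect_equal(d["sp01", "sp02"], 2 * max(ape::node.depth.edgelength(tr2)))

  expect_identical(ape::write.tree(gen_phylogeny(10, seed = 9)),
                   ape::write.tree(gen_phylogeny(10, seed = 9)))
  expect_error(gen_phylogeny(1), ">= 2")
})

test_that("guild assignment respects coupling, coverage and clade limits", {
  cfg1 <- sim_config(n_species = 10, n_guilds = 1, seed = 4)
  tr <- gen_phylogeny(10, seed = 4)
  g1 <- gen_guilds(cfg1, tr)
  expect_true(all(g1$guild == 1L))
  expect_length(g1$optima, 1)

  cfg2 <- sim_config(n_species = 10, n_guilds = 2, phylo_coupling = 1, seed = 4)
  g2 <- gen_guilds(cfg2, tr)
  # guilds must be the two clades of the root split
  root_kids <- tr$edge[tr$edge[, 1] == 11, 2]
  clade_tips <- ape::extract.clade(tr, root_kids[root_kids > 10][1])$tip.label
  if (any(root_kids <= 10))
    clade_tips <- union(clade_tips, tr$tip.label[root_kids[root_kids <= 10]])
  in_clade <- names(g2$guild) %in% clade_tips
  expect_true(length(unique(g2$guild[in_clade])) == 1)
  expect_true(length(unique(g2$guild[!in_clade])) == 1)
  expect_false(g2$guild[in_clade][1] == g2$guild[!in_clade][1])

  cfg3 <- sim_config(seed = 4)
  g3 <- gen_guilds(cfg3, gen_phylogeny(21, seed = 4))
  expect_true(all(tabulate(g3$guild, 3) > 0))  # each guild non-empty
  expect_true(all(g3$optima > 0 & g3$optima < 1))
  # disjoint active sets when frac * n_guilds <= 1
  expect_equal(anyDuplicated(unlist(g3$active_go)), 0L)
  expect_error(gen_guilds(sim_config(n_species = 3, n_guilds = 5), tr),
               "exceed")
})

test_that("neutral community matches Poisson expectation; filtering dominates", {
  cfg <- sim_config(filter_strength = 0, seed = 11, grid_nx = 20, grid_ny = 15,
                    mean_abundance = 4)
  tr <- gen_phylogeny(21, seed = 11)
  gl <- gen_guilds(cfg, tr)
  mo <- gen_moisture_surface(cfg)
  cm <- gen_community(gl, mo, cfg)
  means <- colMeans(cm$abund)
  se <- sqrt(4 / nrow(cm$abund))
  expect_true(all(abs(means - 4) < 3 * se))

  cfg0 <- sim_config(mean_abundance = 0, seed = 11)
  cm0 <- gen_community(gen_guilds(cfg0, tr), gen_moisture_surface(cfg0), cfg0)
  expect_true(all(cm0$abund == 0))

  # strong filtering: subplots dominated by the guild nearest in optimum
  cfgF <- sim_config(filter_strength = 50, niche_sd = 0.1, seed = 12,
                     mean_abundance = 10)
  glF <- gen_guilds(cfgF, gen_phylogeny(21, seed = 12))
  moF <- gen_moisture_surface(cfgF)
  cmF <- gen_community(glF, moF, cfgF)
  m <- as.vector(moF$values)
  set.seed(1)
  hits <- sapply(sample(which(rowSums(cmF$abund) > 0), 20), function(q) {
    top_sp <- colnames(cmF$abund)[which.max(cmF$abund[q, ])]
    glF$guild[[top_sp]] == which.min(abs(glF$optima - m[q]))
  })
  expect_gte(mean(hits), 0.9)
})

test_that("gene tables encode the DE truth and the drop switch", {
  cfg <- sim_config(n_species = 6, n_genes = 400, n_go_bp = 8, n_go_mf = 6,
                    de_rate_in = 1, de_rate_out = 0, coherence_gradient = 0,
                    seed = 21)
  tr <- gen_phylogeny(6, seed = 21)
  gl <- gen_guilds(cfg, tr)
  tabs <- gen_gene_tables(gl, cfg)
  for (sp in names(tabs)) {
    active <- gl$active_go[[gl$guild[[sp]]]]
    gos <- strsplit(tabs[[sp]]$go_terms, ";", fixed = TRUE)
    in_active <- vapply(gos, function(g) any(g %in% active), logical(1))
    expect_identical(attr(tabs[[sp]], "de_truth"), in_active)
  }

  # power inversion warns
  cfg_w <- sim_config(de_rate_in = 0.01, de_rate_out = 0.5, seed = 21,
                      n_species = 3, n_genes = 100)
  gl_w <- gen_guilds(cfg_w, gen_phylogeny(3, seed = 21))
  expect_warning(gen_gene_tables(gl_w, cfg_w), "inverted")

  # drop switch removes terms from some species
  cfg_d <- sim_config(n_species = 6, n_genes = 300, n_go_bp = 10, n_go_mf = 5,
                      drop_go_frac = 0.3, seed = 22)
  gl_d <- gen_guilds(cfg_d, gen_phylogeny(6, seed = 22))
  tabs_d <- gen_gene_tables(gl_d, cfg_d)
  per_species <- lapply(tabs_d, function(t)
    setdiff(unique(unlist(strsplit(t$go_terms, ";"))), ""))
  expect_lt(length(Reduce(intersect, per_species)),
            length(unique(unlist(per_species))))
})

test_that("null enrichment rates give odds ratios near 1 on average", {
  cfg <- sim_config(n_species = 4, n_genes = 2000, n_go_bp = 30, n_go_mf = 20,
                    de_rate_in = 0.2, de_rate_out = 0.2, seed = 31)
  gl <- gen_guilds(cfg, gen_phylogeny(4, seed = 31))
  prof <- enrich_all(gen_gene_tables(gl, cfg))
  expect_lt(abs(mean(log(prof$odds_ratio))), 0.25)
})

test_that("species covariates track guild structure per the couplings", {
  tr <- gen_phylogeny(21, seed = 41)
  # coupling 0: trait variance explained by guild is small
  cfg0 <- sim_config(trait_coupling = 0, seed = 41)
  cov0 <- gen_species_covariates(gen_guilds(cfg0, tr), cfg0)
  ratio <- function(v, g) {
    fit <- stats::aov(v ~ factor(g))
    s <- summary(fit)[[1]]$`Sum Sq`
    s[1] / sum(s)
  }
  g <- gen_guilds(cfg0, tr)$guild
  r0 <- mean(apply(cov0$traits, 2, ratio, g = g))
  expect_lt(r0, 0.25)

  # coupling 1: species within one guild identical
  cfg1 <- sim_config(trait_coupling = 1, tolerance_coupling = 1, seed = 41)
  gl1 <- gen_guilds(cfg1, tr)
  cov1 <- gen_species_covariates(gl1, cfg1)
  for (gg in unique(gl1$guild)) {
    rows <- cov1$traits[gl1$guild == gg, , drop = FALSE]
    expect_lt(max(apply(rows, 2, function(x) max(x) - min(x))), 1e-9)
  }
  expect_true(all(is.finite(cov1$wilting_days) & cov1$wilting_days > 0))
  # drought tolerance monotone in guild optimum (drier optimum -> higher)
  gm <- tapply(cov1$tolerances[, "drought"], gl1$guild, mean)
  expect_true(all(diff(gm[order(gl1$optima)]) < 0))
})

test_that("soil-core design places the 40-m lattice with nested satellites", {
  cfg <- sim_config(seed = 51)  # 35 x 18 -> 700 m x 360 m
  mo <- gen_moisture_surface(cfg)
  cores <- gen_soil_cores(mo, seed = 51, sigma_meas = 0)
  nodes <- cores[cores$type == "node", ]
  expect_equal(nrow(nodes), 17 * 8)  # interior lattice 40..680 x 40..320
  expect_setequal(unique(nodes$x_m), seq(40, 680, 40))
  expect_setequal(unique(nodes$y_m), seq(40, 320, 40))
  sats <- cores[cores$type == "satellite", ]
  expect_equal(nrow(sats) %% 3, 0)
  expect_true(all(cores$x_m >= 0 & cores$x_m <= 700 &
                    cores$y_m >= 0 & cores$y_m <= 360))
  # sigma 0: values equal the containing subplot's surface value
  ix <- floor(cores$x_m / 20) + 1; iy <- floor(cores$y_m / 20) + 1
  expect_equal(cores$vwc, mo$values[cbind(ix, iy)])
  expect_identical(cores, gen_soil_cores(mo, seed = 51, sigma_meas = 0))
})

test_that("the full dataset is a pure function of (config, seed)", {
  cfg <- sim_config(seed = 61, n_genes = 200, grid_nx = 8, grid_ny = 6)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$community$abund, d2$community$abund)
  expect_identical(d1$gene_tables, d2$gene_tables)
  expect_identical(d1$soil_cores, d2$soil_cores)
  expect_identical(ape::write.tree(d1$phylogeny), ape::write.tree(d2$phylogeny))
  d3 <- simulate_dataset(sim_config(seed = 62, n_genes = 200,
                                    grid_nx = 8, grid_ny = 6))
  expect_false(identical(d1$community$abund, d3$community$abund))
})
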