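# Shared fixtures, built once per test run. All synthetic, all seeded.

.cache <- new.env(parent = emptyenv())

# Moderate default-structure dataset used across modules.
shared_dataset <- function() {
  if (is.null(.cache$ds)) {
    cfg <- sim_config(seed = 101, n_genes = 1500)
    .cache$ds <- simulate_dataset(cfg)
  }
  .cache$ds
}

shared_profile <- function() {
  if (is.null(.cache$prof)) .cache$prof <- enrich_all(shared_dataset()$gene_tables)
  .cache$prof
}

# Strong, clean guild signal with the literal guild-active sets
# (coherence_gradient = 0) for truth-recovery tests.
truth_dataset <- function() {
  if (is.null(.cache$truth)) {
    cfg <- sim_config(seed = 202, n_genes = 1500, coherence_gradient = 0,
                      de_rate_in = 0.8, de_rate_out = 0.02)
    .cache$truth <- simulate_dataset(cfg)
  }
  .cache$truth
}

truth_profile <- function() {
  if (is.null(.cache$truth_prof))
    .cache$truth_prof <- enrich_all(truth_dataset()$gene_tables)
  .cache$truth_prof
}

# Tiny community: 3 species, a handful of subplots, for enumeration oracles.
tiny_community <- function(abund) {
  structure(list(abund = abund,
                 x_index = seq_len(nrow(abund)),
                 y_index = rep(1L, nrow(abund)),
                 cell = 20, nx = nrow(abund), ny = 1L),
            class = "community")
}

rand_species_dist <- function(n, labels = species_labels(n)) {
  x <- matrix(stats::runif(n * 3), n)
  m <- as.matrix(stats::dist(x))
  dimnames(m) <- list(labels, labels)
  species_dist(m)
}

# All permutations of 1..n (small n only), for exhaustive null oracles.
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# Naive double-loop MPD, the independent oracle for the vectorised code.
mpd_naive <- function(abund, D, include_conspecific = FALSE) {
  sp <- names(abund)[abund > 0]
  if (length(sp) < 2) return(NA_real_)
  num <- 0; den <- 0
  for (i in sp) for (j in sp) {
    if (!include_conspecific && i == j) next
    num <- num + D[i, j] * abund[i] * abund[j]
    den <- den + abund[i] * abund[j]
  }
  unname(num / den)
}

# Brute-force hypergeometric upper tail from first principles (choose()
# ratios over the support), independent of phyper/fisher.test.
fisher_oracle <- function(a, b, c, d) {
  n_de <- a + b; n_non <- c + d; k <- a + c
  lo <- max(0, k - n_non); hi <- min(k, n_de)
  support <- lo:hi
  probs <- choose(n_de, support) * choose(n_non, k - support) /
    choose(n_de + n_non, k)
  sum(probs[support >= a])
}

# Gene table + DE vector realising a prescribed 2x2 enrichment table.
mk_fisher_fixture <- function(a, b, c, d) {
  n <- a + b + c + d
  list(de = c(rep(TRUE, a + b), rep(FALSE, c + d)),
       tab = data.frame(gene_id = paste0("g", seq_len(n)), log2fc = 0,
                        pvalue = 0.5,
                        go_terms = c(rep("GO:X", a), rep("", b),
                                     rep("GO:X", c), rep("", d))))
}
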