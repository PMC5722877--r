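#' Read / write a phylogeny in newick format
#'
#' Validating wrappers over [ape::read.tree()] / [ape::write.tree()]: the
#' tree must parse, carry branch lengths, and have labelled tips.
#' Round-tripping preserves topology and branch lengths to numerical
#' precision.
#'
#' @param path file path.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("cannot parse newick in ", path, call. = FALSE)
  if (is.null(tr$edge.length))
    stop("newick tree in ", path, " has no branch lengths", call. = FALSE)
  if (is.null(tr$tip.label) || any(!nzchar(tr$tip.label)))
    stop("newick tree in ", path, " has unlabeled tips", call. = FALSE)
  tr
}

#' @rdname read_newick
#' @param tree an [ape::phylo] object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read / write a community matrix
#'
#' CSV schema: `subplot_id`, `x_index`, `y_index`, then one integer
#' abundance column per species. Counts must be nonnegative integers and
#' (x, y) pairs unique.
#'
#' @param path file path.
#' @param cell subplot cell size in metres (default 20).
#' @return a `community` object.
#' @export
read_community <- function(path, cell = 20) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subplot_id", "x_index", "y_index")
  if (!all(need %in% names(df)))
    stop("community file must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  sp_cols <- setdiff(names(df), need)
  if (length(sp_cols) == 0L) stop("no species columns found", call. = FALSE)
  ab <- as.matrix(df[, sp_cols, drop = FALSE])
  if (any(ab < 0) || any(ab != round(ab)))
    stop("abundances must be nonnegative integers", call. = FALSE)
  if (anyDuplicated(df[, c("x_index", "y_index")]))
    stop("duplicate subplot coordinates", call. = FALSE)
  ord <- order(df$y_index, df$x_index)
  df <- df[ord, ]; ab <- ab[ord, , drop = FALSE]
  structure(list(abund = ab, x_index = df$x_index, y_index = df$y_index,
                 cell = cell, nx = max(df$x_index), ny = max(df$y_index)),
            class = "community")
}

#' @rdname read_community
#' @param community a `community` object.
#' @export
write_community <- function(community, path) {
  df <- data.frame(subplot_id = seq_len(nrow(community$abund)),
                   x_index = community$x_index,
                   y_index = community$y_index)
  df <- cbind(df, as.data.frame(community$abund))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write per-species gene tables
#'
#' TSV schema: `gene_id`, `log2fc`, `pvalue`, `go_terms`
#' (semicolon-separated GO ids, possibly empty). Gene ids must be unique
#' and p-values in `[0, 1]`.
#'
#' @param path file path.
#' @return a validated gene-table data frame.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "pvalue", "go_terms")
  if (!all(need %in% names(df)))
    stop("gene table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene ids in ", path, call. = FALSE)
  check_pvalues(df$pvalue)
  df$go_terms[is.na(df$go_terms)] <- ""
  df[, need]
}

#' @rdname read_gene_table
#' @param gene_table a gene-table data frame.
#' @export
write_gene_table <- function(gene_table, path) {
  utils::write.table(gene_table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Cross-validate species labels across inputs
#'
#' All supplied label sets must be identical; the error names the
#' symmetric difference for each offending pair.
#'
#' @param ... named character vectors of species labels.
#' @return invisibly, the common sorted label set.
#' @export
cross_validate_labels <- function(...) {
  sets <- list(...)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("label sets must be named", call. = FALSE)
  ref <- sort(sets[[1]])
  for (nm in names(sets)[-1]) {
    s <- sort(sets[[nm]])
    if (!identical(ref, s)) {
      only_a <- setdiff(ref, s); only_b <- setdiff(s, ref)
      stop("species labels differ between ", names(sets)[1], " and ", nm,
           ": only in ", names(sets)[1], ": {",
           paste(only_a, collapse = ", "), "}; only in ", nm, ": {",
           paste(only_b, collapse = ", "), "}", call. = FALSE)
    }
  }
  invisible(ref)
}

#' Read / write species distance matrices as labelled CSV
#'
#' First column `species`, remaining columns one per species, in matching
#' order.
#'
#' @param mat a [species_dist()] matrix.
#' @param path file path.
#' @param source tag applied on read.
#' @return the path (write) or a [species_dist()] matrix (read).
#' @export
write_dist_csv <- function(mat, path) {
  df <- data.frame(species = rownames(mat), as.data.frame(unclass(mat)[, ]),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_csv
#' @export
read_dist_csv <- function(path, source = "scalar") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  species_dist(m, source = source)
}

write_ses_csv <- function(map, path) {
  utils::write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the community CSV, newick tree, per-species gene TSVs, trait /
#' tolerance / wilting CSVs, soil-core CSV, moisture-grid CSV and a truth
#' JSON (guild membership, optima, active GO sets).
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of files written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "genes"), showWarnings = FALSE)
  files <- c()
  p <- function(...) file.path(dir, ...)
  write_community(dataset$community, p("community.csv"))
  files["community"] <- p("community.csv")
  write_newick(dataset$phylogeny, p("phylogeny.nwk"))
  files["phylogeny"] <- p("phylogeny.nwk")
  for (sp in names(dataset$gene_tables)) {
    f <- p("genes", paste0(sp, ".tsv"))
    write_gene_table(dataset$gene_tables[[sp]], f)
    files[paste0("genes_", sp)] <- f
  }
  cv <- dataset$covariates
  utils::write.csv(data.frame(species = rownames(cv$traits), cv$traits),
                   p("traits.csv"), row.names = FALSE)
  files["traits"] <- p("traits.csv")
  utils::write.csv(data.frame(species = names(cv$wilting_days),
                              wilting_days = unname(cv$wilting_days)),
                   p("wilting.csv"), row.names = FALSE)
  files["wilting"] <- p("wilting.csv")
  utils::write.csv(data.frame(species = rownames(cv$tolerances),
                              cv$tolerances),
                   p("tolerances.csv"), row.names = FALSE)
  files["tolerances"] <- p("tolerances.csv")
  utils::write.csv(dataset$soil_cores, p("soil_cores.csv"), row.names = FALSE)
  files["soil_cores"] <- p("soil_cores.csv")
  mg <- dataset$moisture
  utils::write.csv(data.frame(subplot_id = seq_along(as.vector(mg$values)),
                              x_index = rep(seq_len(mg$nx), mg$ny),
                              y_index = rep(seq_len(mg$ny), each = mg$nx),
                              vwc = as.vector(mg$values)),
                   p("moisture.csv"), row.names = FALSE)
  files["moisture"] <- p("moisture.csv")
  truth <- list(guild = as.list(dataset$guilds$guild),
                optima = dataset$guilds$optima,
                active_go = dataset$guilds$active_go,
                config = unclass(dataset$config))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files["truth"] <- p("truth.json")
  invisible(files)
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Simulates a dataset from `config`, then runs every analysis stage:
#' enrichment (shared universe, Fisher + BY), similarity matrices for all
#' sources, subplot dispersion (ses maps per source, per-GO maps, GO
#' ranking), spatial analyses (variogram, kriging, point- and kriged-mode
#' torus correlations) and phylogenetic signal (Mantel, per-GO D). All
#' outputs are written under `out_dir` together with a manifest listing
#' per-file MD5 digests and the seeds used; rerunning with the same config
#' produces byte-identical outputs. Stage wall times go to `run.log`,
#' which is not part of the manifest.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory.
#' @param n_null permutations for the dispersion nulls (default 999).
#' @param n_go_terms number of GO terms to carry through the per-GO
#'   dispersion and D-statistic stages (default all; lower for quick runs).
#' @return invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, n_null = 999, n_go_terms = Inf) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  t_all <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- expr
    cat(sprintf("%s: %.2fs\n", name, proc.time()[["elapsed"]] - t0),
        file = log_path, append = TRUE)
    val
  }
  seeds <- list(master = config$seed,
                dispersion = derive_seed(config$seed, "dispersion"),
                per_go = derive_seed(config$seed, "per_go"),
                mantel = derive_seed(config$seed, "mantel"),
                dstat = derive_seed(config$seed, "dstat"))

  ds <- stage("simulate", simulate_dataset(config))
  data_files <- write_dataset(ds, file.path(out_dir, "data"))

  prof <- stage("enrich", enrich_all(ds$gene_tables))
  prof_ns <- split_profile(prof)
  enr_files <- c()
  for (what in c("odds_ratio", "p_by", "significant")) {
    f <- file.path(out_dir, paste0("enrichment_", what, ".csv"))
    utils::write.csv(data.frame(species = rownames(prof[[what]]),
                                prof[[what]] + 0, check.names = FALSE),
                     f, row.names = FALSE)
    enr_files[what] <- f
  }

  dists <- stage("similarity", {
    d <- list()
    for (ns in names(prof_ns)) {
      d[[paste0("expression-", ns)]] <-
        expression_distances(prof_ns[[ns]],
                             source = paste0("expression-", ns))$distances
    }
    d[["traits"]] <- trait_pc_distances(ds$covariates$traits)
    d[["phylogeny"]] <- patristic_distances(ds$phylogeny)
    d[["wilting"]] <- scalar_distances(ds$covariates$wilting_days,
                                       source = "wilting")
    for (tl in colnames(ds$covariates$tolerances)) {
      d[[paste0("tolerance-", tl)]] <-
        scalar_distances(ds$covariates$tolerances[, tl],
                         source = paste0("tolerance-", tl))
    }
    d
  })
  dist_files <- c()
  for (nm in names(dists)) {
    f <- file.path(out_dir, paste0("dist_", nm, ".csv"))
    write_dist_csv(dists[[nm]], f)
    dist_files[nm] <- f
  }

  maps <- stage("dispersion", {
    lapply(dists, function(D)
      ses_mpd_map(ds$community, D, n_null = n_null,
                  seed = seeds$dispersion))
  })
  ses_files <- c()
  for (nm in names(maps)) {
    f <- file.path(out_dir, paste0("ses_", nm, ".csv"))
    write_ses_csv(maps[[nm]], f)
    ses_files[nm] <- f
  }

  go_rank <- stage("per_go", {
    sig <- prof$significant
    keep <- colnames(sig)
    if (is.finite(n_go_terms)) keep <- keep[seq_len(min(n_go_terms, length(keep)))]
    go_maps <- per_go_ses(ds$community, sig[, keep, drop = FALSE],
                          n_null = n_null, seed = seeds$per_go)
    rank_go_terms(go_maps, namespaces = prof$namespaces)
  })
  utils::write.csv(go_rank, file.path(out_dir, "go_ranking.csv"),
                   row.names = FALSE)

  spat <- stage("spatial", {
    kr <- krige_moisture_map(ds$soil_cores, ds$community$nx,
                             ds$community$ny, ds$community$cell)
    pt <- cores_to_grid(ds$soil_cores, ds$community$nx, ds$community$ny,
                        ds$community$cell)
    rows <- list()
    for (nm in names(maps)) {
      sg <- ses_grid(maps[[nm]])
      for (mode in c("point", "kriged")) {
        b <- if (mode == "point") pt else kr$grid
        tc <- tryCatch(torus_correlation(sg, b), error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          source = nm, mode = mode,
          r = if (is.null(tc)) NA_real_ else tc$r_obs,
          p = if (is.null(tc)) NA_real_ else tc$p,
          n = if (is.null(tc)) NA_integer_ else tc$n_cells,
          stringsAsFactors = FALSE)
      }
    }
    list(report = do.call(rbind, rows), kriged = kr)
  })
  utils::write.csv(spat$report, file.path(out_dir, "moisture_correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(subplot_id = seq_along(as.vector(spat$kriged$grid)),
               x_index = rep(seq_len(ds$community$nx), ds$community$ny),
               y_index = rep(seq_len(ds$community$ny), each = ds$community$nx),
               vwc_kriged = as.vector(spat$kriged$grid)),
    file.path(out_dir, "moisture_kriged.csv"), row.names = FALSE)

  signal <- stage("signal", {
    phylo_d <- dists[["phylogeny"]]
    mt <- lapply(grep("^expression-", names(dists), value = TRUE),
                 function(nm) {
      m <- mantel_test(phylo_d, dists[[nm]], n_perm = n_null,
                       seed = seeds$mantel)
      data.frame(source = nm, r = m$r, p = m$p, stringsAsFactors = FALSE)
    })
    sig <- prof$significant
    keep <- colnames(sig)
    if (is.finite(n_go_terms)) keep <- keep[seq_len(min(n_go_terms, length(keep)))]
    dt <- d_statistic_table(ds$phylogeny, sig[, keep, drop = FALSE],
                            n_perm = min(n_null, 199),
                            n_brownian = min(n_null, 199),
                            seed = seeds$dstat)
    list(mantel = do.call(rbind, mt), d = dt)
  })
  utils::write.csv(signal$mantel, file.path(out_dir, "mantel.csv"),
                   row.names = FALSE)
  utils::write.csv(signal$d, file.path(out_dir, "d_statistics.csv"),
                   row.names = FALSE)

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs,
                     c(log_path, file.path(out_dir, "manifest.json")))
  digests <- tools::md5sum(sort(outputs))
  manifest <- list(
    package_version = as.character(utils::packageVersion("drydisp")),
    config = unclass(config),
    seeds = seeds,
    n_null = n_null,
    mean_ses = lapply(maps, function(m) mean(m$ses, na.rm = TRUE)),
    files = as.list(stats::setNames(unname(digests),
                                    sub(paste0("^", out_dir, "/?"), "",
                                        names(digests))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cat(sprintf("total: %.2fs\n", proc.time()[["elapsed"]] - t_all),
      file = log_path, append = TRUE)
  invisible(manifest)
}
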