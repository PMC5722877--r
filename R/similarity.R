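#' Species distance matrix constructor
#'
#' Validates and tags an n x n dissimilarity matrix: symmetric, zero
#' diagonal, nonnegative, unique labels. All similarity sources funnel
#' through this constructor so downstream dispersion code can rely on the
#' invariants.
#'
#' @param mat square numeric matrix with dimnames.
#' @param source tag: one of `"expression-BP"`, `"expression-MF"`,
#'   `"trait-PC"`, `"phylogeny"`, `"scalar"`, `"per-GO"`, or free text.
#' @return the matrix with attribute `source`.
#' @export
species_dist <- function(mat, source = "scalar") {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop("distance matrix must be square", call. = FALSE)
  labs <- rownames(mat)
  if (is.null(labs) || is.null(colnames(mat)) || !identical(labs, colnames(mat)))
    stop("distance matrix must have matching row/column labels", call. = FALSE)
  if (anyDuplicated(labs)) stop("species labels must be unique", call. = FALSE)
  if (any(mat < 0)) stop("dissimilarities must be nonnegative", call. = FALSE)
  if (any(abs(diag(mat)) > 1e-12)) stop("diagonal must be zero", call. = FALSE)
  if (any(abs(mat - t(mat)) > 1e-9)) stop("matrix must be symmetric", call. = FALSE)
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 0
  attr(mat, "source") <- source
  mat
}

#' Hierarchically cluster species by their enrichment profiles
#'
#' Agglomerative clustering of species row-vectors. Odds-ratio profiles are
#' clustered with Euclidean distance on `log2(OR)` (ratio scale
#' stabilised); binary significance profiles with Euclidean distance on
#' 0/1 (same ordering as squared Jaccard here) or Jaccard. Rows are sorted
#' by label first so ties break deterministically.
#'
#' @param x species x feature matrix (rows named by species).
#' @param linkage one of `"average"` (default), `"single"`, `"complete"`,
#'   `"ward"`.
#' @param metric `"euclidean"` (default) or `"jaccard"` (binary rows).
#' @param log2_transform take `log2` of the values first (for odds ratios).
#' @return an [stats::hclust] object.
#' @export
hierarchical_cluster <- function(x, linkage = c("average", "single",
                                                "complete", "ward"),
                                 metric = c("euclidean", "jaccard"),
                                 log2_transform = FALSE) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  if (nrow(x) < 2) stop("need at least two species to cluster", call. = FALSE)
  x <- x[sort(rownames(x)), , drop = FALSE]
  if (log2_transform) x <- log2(x)
  if (any(apply(x, 1, stats::var) == 0))
    warning("one or more species have constant profiles", call. = FALSE)
  d <- if (metric == "euclidean") stats::dist(x)
       else stats::dist(x, method = "binary")
  method <- if (linkage == "ward") "ward.D2" else linkage
  stats::hclust(d, method = method)
}

#' Cophenetic distances from a dendrogram
#'
#' The dissimilarity between two species implied by the clustering: under
#' the default `"path"` convention it is twice the merge height of their
#' lowest common cluster (the tip-to-tip branch length through the
#' dendrogram); `"height"` returns the merge height itself (half the path,
#' identical ranking).
#'
#' @param dendrogram an [stats::hclust] object.
#' @param source tag stored on the result.
#' @param convention `"path"` (default) or `"height"`.
#' @return a [species_dist()] matrix (ultrametric).
#' @export
cophenetic_distances <- function(dendrogram, source = "expression",
                                 convention = c("path", "height")) {
  convention <- match.arg(convention)
  m <- as.matrix(stats::cophenetic(dendrogram))
  if (convention == "path") m <- 2 * m
  ord <- sort(rownames(m))
  species_dist(m[ord, ord], source = source)
}

#' Euclidean distances on leading principal-component axes of traits
#'
#' Columns are standardized (zero mean, unit variance; zero-variance traits
#' dropped with a warning), scores come from an SVD-based PCA, the sign of
#' each axis is fixed so the largest-magnitude loading is positive, and the
#' pairwise Euclidean distance over the first `n_axes` score axes is
#' returned.
#'
#' @param trait_table species x trait numeric matrix (rownames = species).
#' @param n_axes number of PC axes (default 2).
#' @return a [species_dist()] matrix tagged `"trait-PC"`.
#' @export
trait_pc_distances <- function(trait_table, n_axes = 2) {
  x <- as.matrix(trait_table)
  if (anyNA(x)) stop("trait table contains missing values", call. = FALSE)
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance trait(s): ",
            paste(colnames(x)[v == 0], collapse = ", "), call. = FALSE)
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < n_axes)
    stop("need at least ", n_axes, " informative traits", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  scores <- sweep(pc$x, 2, flip, `*`)[, seq_len(n_axes), drop = FALSE]
  m <- as.matrix(stats::dist(scores))
  ord <- sort(rownames(m))
  species_dist(m[ord, ord], source = "trait-PC")
}

#' Patristic distances from a phylogeny
#'
#' Sum of branch lengths along the tip-to-tip path, for the species set of
#' the analysis.
#'
#' @param phylogeny an [ape::phylo] tree with branch lengths.
#' @param species optional character vector; defaults to all tips.
#' @return a [species_dist()] matrix tagged `"phylogeny"`.
#' @export
patristic_distances <- function(phylogeny, species = NULL) {
  if (is.null(species)) species <- phylogeny$tip.label
  missing <- setdiff(species, phylogeny$tip.label)
  if (length(missing))
    stop("species missing from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- ape::cophenetic.phylo(phylogeny)
  ord <- sort(species)
  species_dist(m[ord, ord], source = "phylogeny")
}

#' Absolute-difference distances from a scalar species attribute
#'
#' `delta_ij = |x_i - x_j|`, used for days-to-wilting and each tolerance
#' score. Species with missing values are dropped with a warning.
#'
#' @param values named numeric vector (names = species).
#' @param source tag stored on the result.
#' @return a [species_dist()] matrix.
#' @export
scalar_distances <- function(values, source = "scalar") {
  if (is.null(names(values))) stop("values must be named by species", call. = FALSE)
  if (anyNA(values)) {
    warning("dropping species with missing values: ",
            paste(names(values)[is.na(values)], collapse = ", "), call. = FALSE)
    values <- values[!is.na(values)]
  }
  values <- values[sort(names(values))]
  m <- abs(outer(values, values, `-`))
  dimnames(m) <- list(names(values), names(values))
  species_dist(m, source = source)
}

#' Mismatch distances from a binary enrichment state
#'
#' `delta_ij = 0` when both species share the enrichment state
#' (significant-significant or nonsignificant-nonsignificant) and 1 when
#' they differ; complementing the column leaves the matrix unchanged.
#'
#' @param states named logical (or 0/1) vector per species.
#' @param source tag stored on the result.
#' @return a [species_dist()] matrix tagged `"per-GO"` by default.
#' @export
binary_state_distances <- function(states, source = "per-GO") {
  if (is.null(names(states))) stop("states must be named by species", call. = FALSE)
  s <- as.logical(states)[order(names(states))]
  names(s) <- sort(names(states))
  m <- outer(s, s, function(a, b) as.numeric(xor(a, b)))
  dimnames(m) <- list(names(s), names(s))
  species_dist(m, source = source)
}

#' Expression dissimilarities from an enrichment profile
#'
#' The headline expression distance: species are clustered on the binary
#' significance matrix (the dendrogram actually used downstream), and
#' cophenetic path lengths are returned. The odds-ratio dendrogram
#' (`use = "odds_ratio"`, Euclidean on log2 OR) is retained as an
#' alternative.
#'
#' @param profile an `enrichment_profile` (single namespace).
#' @param use `"significance"` (default) or `"odds_ratio"`.
#' @param linkage passed to [hierarchical_cluster()].
#' @param source tag for the resulting matrix.
#' @return list with `dendrogram` ([stats::hclust]) and `distances`
#'   ([species_dist()]).
#' @export
expression_distances <- function(profile,
                                 use = c("significance", "odds_ratio"),
                                 linkage = "average",
                                 source = "expression") {
  use <- match.arg(use)
  x <- if (use == "significance") profile$significant + 0
       else profile$odds_ratio
  dend <- hierarchical_cluster(x, linkage = linkage,
                               log2_transform = use == "odds_ratio")
  list(dendrogram = dend,
       distances = cophenetic_distances(dend, source = source))
}
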