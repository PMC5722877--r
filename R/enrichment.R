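#' Benjamini-Hochberg adjustment
#'
#' Thin, validating wrapper over [stats::p.adjust()] (step-up `p * m / rank`
#' with monotone enforcement, capped at 1).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  check_pvalues(pvalues)
  stats::p.adjust(pvalues, method = "BH")
}

#' Benjamini-Yekutieli adjustment
#'
#' BH multiplied by `c(m) = sum(1/i)` before monotone enforcement; valid
#' under arbitrary dependence and pointwise at least as large as BH.
#'
#' @inheritParams bh_adjust
#' @return adjusted p-values in input order.
#' @export
by_adjust <- function(pvalues) {
  check_pvalues(pvalues)
  stats::p.adjust(pvalues, method = "BY")
}

check_pvalues <- function(p) {
  if (length(p) && (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)))
    stop("p-values must be numeric in [0, 1]", call. = FALSE)
  invisible(p)
}

#' Call differentially expressed genes
#'
#' A gene is DE when `|log2fc| >= lfc_cutoff` and its BH-adjusted p-value is
#' below `alpha_de`; the direction of the change is ignored.
#'
#' @param gene_table data frame with `log2fc` and `pvalue` columns.
#' @param lfc_cutoff absolute log2-fold-change cutoff (default 1).
#' @param alpha_de FDR threshold on the BH-adjusted p-value (default 0.05).
#' @return logical vector, one element per gene.
#' @export
call_de <- function(gene_table, lfc_cutoff = 1, alpha_de = 0.05) {
  if (nrow(gene_table) == 0L) return(logical(0))
  check_pvalues(gene_table$pvalue)
  abs(gene_table$log2fc) >= lfc_cutoff &
    bh_adjust(gene_table$pvalue) < alpha_de
}

split_go <- function(go_strings) {
  strsplit(ifelse(is.na(go_strings), "", go_strings), ";", fixed = TRUE)
}

table_go_terms <- function(gene_table) {
  unique(unlist(split_go(gene_table$go_terms), use.names = FALSE))
}

#' Shared GO universe across species
#'
#' Returns, in lexicographic order, exactly the GO terms annotated to at
#' least one gene in *every* species; terms missing from any species are
#' excluded from all downstream analyses.
#'
#' @param gene_tables named list of per-species gene tables.
#' @return character vector of GO ids.
#' @export
shared_go_universe <- function(gene_tables) {
  if (length(gene_tables) == 0L) stop("need at least one species", call. = FALSE)
  sets <- lapply(gene_tables, table_go_terms)
  sets <- lapply(sets, function(s) setdiff(s, ""))
  univ <- Reduce(intersect, sets)
  if (length(univ) == 0L) {
    cov <- table(unlist(sets))
    top <- utils::head(sort(cov, decreasing = TRUE), 5L)
    stop("no GO term is annotated in all ", length(sets), " species; ",
         "best coverage: ",
         paste(sprintf("%s (%d)", names(top), as.integer(top)), collapse = ", "),
         call. = FALSE)
  }
  sort(univ)
}

#' Fisher gene-set enrichment for one species
#'
#' For each GO term of the shared universe, builds the 2x2 table of DE
#' status against term membership over all genes of the species, computes a
#' one-sided (over-representation) hypergeometric p-value, the sample odds
#' ratio `a*d / (b*c)` with a Haldane-Anscombe +0.5 on every cell when any
#' cell is zero, and Benjamini-Yekutieli adjusts across the universe.
#'
#' @param de_vector logical DE calls from [call_de()].
#' @param gene_table the species' gene table.
#' @param universe GO ids from [shared_go_universe()].
#' @param alpha_enrich significance threshold on the BY-adjusted p-value.
#' @param alternative `"greater"` (over-representation, default) or
#'   `"two.sided"`.
#' @return data frame, one row per universe term: counts `a, b, c, d`,
#'   `odds_ratio`, `p_fisher`, `p_by`, `significant`, `zero_annotated`.
#' @export
fisher_enrichment <- function(de_vector, gene_table, universe,
                              alpha_enrich = 0.05,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(universe) == 0L) stop("universe is empty", call. = FALSE)
  stopifnot(length(de_vector) == nrow(gene_table))
  terms_by_gene <- split_go(gene_table$go_terms)
  n <- length(de_vector)
  n_de <- sum(de_vector)
  # membership counts per universe term
  gene_idx <- rep.int(seq_len(n), lengths(terms_by_gene))
  term_f <- factor(unlist(terms_by_gene, use.names = FALSE), levels = universe)
  keep <- !is.na(term_f)
  in_go <- tabulate(term_f[keep], nbins = length(universe))
  de_by_gene <- de_vector[gene_idx]
  a <- tabulate(term_f[keep & de_by_gene], nbins = length(universe))
  c_ <- in_go - a
  b <- n_de - a
  d <- (n - n_de) - c_
  p <- if (alternative == "greater") {
    stats::phyper(a - 1, n_de, n - n_de, in_go, lower.tail = FALSE)
  } else {
    vapply(seq_along(universe), function(i) {
      stats::fisher.test(matrix(c(a[i], b[i], c_[i], d[i]), 2L))$p.value
    }, numeric(1))
  }
  or <- ifelse(a * d > 0 & b * c_ > 0,
               (a * d) / (b * c_),
               ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)))
  p_by <- by_adjust(p)
  data.frame(go_id = universe, a = a, b = b, c = c_, d = d,
             odds_ratio = or, p_fisher = p, p_by = p_by,
             significant = p_by < alpha_enrich,
             zero_annotated = in_go == 0L,
             stringsAsFactors = FALSE)
}

#' Assemble species-by-GO enrichment matrices
#'
#' Aligns per-species [fisher_enrichment()] rows on a common universe into
#' odds-ratio, p-value and significance matrices; when a `namespaces`
#' vector is supplied the profile can later be split per namespace with
#' [split_profile()].
#'
#' @param rows named list (per species) of [fisher_enrichment()] outputs.
#' @param namespaces optional named character vector mapping GO id to
#'   namespace (e.g. "BP"/"MF").
#' @return an `enrichment_profile`: list of matrices `odds_ratio`,
#'   `p_fisher`, `p_by`, `significant` (species x GO), `universe`,
#'   `species`, `namespaces`.
#' @export
enrichment_matrices <- function(rows, namespaces = NULL) {
  if (length(rows) == 0L) stop("no species rows", call. = FALSE)
  univ <- rows[[1]]$go_id
  for (sp in names(rows)) {
    if (!identical(rows[[sp]]$go_id, univ))
      stop("universe mismatch for species ", sp, call. = FALSE)
  }
  sp <- names(rows)
  pull <- function(col) {
    m <- do.call(rbind, lapply(rows, function(r) r[[col]]))
    dimnames(m) <- list(sp, univ)
    m
  }
  sig <- pull("significant")
  const_cols <- colnames(sig)[apply(sig, 2, function(x) length(unique(x)) == 1L)]
  if (length(const_cols))
    attr(sig, "constant_columns") <- const_cols
  structure(list(odds_ratio = pull("odds_ratio"),
                 p_fisher = pull("p_fisher"),
                 p_by = pull("p_by"),
                 significant = sig,
                 universe = univ, species = sp, namespaces = namespaces),
            class = "enrichment_profile")
}

#' Split an enrichment profile by GO namespace
#'
#' @param profile an [enrichment_matrices()] result with `namespaces` set.
#' @return named list of `enrichment_profile` objects, one per namespace.
#' @export
split_profile <- function(profile) {
  ns <- profile$namespaces
  if (is.null(ns)) stop("profile has no namespace information", call. = FALSE)
  ns <- ns[profile$universe]
  out <- lapply(split(profile$universe, ns), function(terms) {
    structure(list(odds_ratio = profile$odds_ratio[, terms, drop = FALSE],
                   p_fisher = profile$p_fisher[, terms, drop = FALSE],
                   p_by = profile$p_by[, terms, drop = FALSE],
                   significant = profile$significant[, terms, drop = FALSE],
                   universe = terms, species = profile$species,
                   namespaces = profile$namespaces[terms]),
              class = "enrichment_profile")
  })
  out
}

#' Run the full enrichment stage over a set of gene tables
#'
#' Convenience wrapper: DE calls, shared universe, per-species Fisher tests
#' with BY correction, matrix assembly. GO namespaces are inferred from the
#' id prefix (text before `":"`).
#'
#' @inheritParams shared_go_universe
#' @inheritParams call_de
#' @inheritParams fisher_enrichment
#' @return an `enrichment_profile`.
#' @export
enrich_all <- function(gene_tables, lfc_cutoff = 1, alpha_de = 0.05,
                       alpha_enrich = 0.05,
                       alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- shared_go_universe(gene_tables)
  rows <- lapply(gene_tables, function(tab) {
    fisher_enrichment(call_de(tab, lfc_cutoff, alpha_de), tab, universe,
                      alpha_enrich = alpha_enrich, alternative = alternative)
  })
  ns <- sub(":.*$", "", universe)
  names(ns) <- universe
  enrichment_matrices(rows, namespaces = ns)
}
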