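#' Threshold a fold-change table
#'
#' Selects genes beyond a fold-change cutoff: up-regulated genes have
#' `log2fc > cutoff`, down-regulated `log2fc < -cutoff`. The default cutoff
#' is the exact `log2(fold)` (about 0.58496 for 1.5-fold), with strict
#' inequality; pass `cutoff` explicitly to replicate analyses that used a
#' rounded constant such as 0.587.
#'
#' @param table Data frame with columns `gene_id` and `log2fc` (unique ids,
#'   finite values).
#' @param fold Fold-change threshold as a ratio (> 1).
#' @param direction `"up"` or `"down"`.
#' @param cutoff Log2 cutoff; default `log2(fold)`.
#' @return Character vector of gene ids.
#' @export
threshold_genes <- function(table, fold = 1.5, direction = c("up", "down"),
                            cutoff = log2(fold)) {
  direction <- match.arg(direction)
  stopifnot(all(c("gene_id", "log2fc") %in% names(table)))
  if (fold <= 1) stop("fold must be > 1")
  if (anyDuplicated(table$gene_id)) stop("gene ids must be unique")
  if (any(!is.finite(table$log2fc))) stop("log2fc values must be finite")
  if (direction == "up") table$gene_id[table$log2fc > cutoff]
  else table$gene_id[table$log2fc < -cutoff]
}

# upper-tail P(X >= x) for X ~ Binomial(n, p), by exact summation
binom_upper_tail <- function(x, n, p) {
  if (x <= 0) return(1)
  pbinom(x - 1, n, p, lower.tail = FALSE)
}

#' Venn overlap of two gene sets with enrichment p-value
#'
#' Partitions two gene sets over a shared universe and tests whether their
#' intersection exceeds chance. The default null follows a binomial
#' statistic: the probability of at least `n_intersection` successes in
#' `n_A` trials with success probability `n_B / n_universe`, computed by
#' exact summation of the upper tail. A hypergeometric null (both margins
#' fixed; one-sided Fisher) is available as an alternative since the two are
#' not identical for small universes.
#'
#' @param setA,setB Character vectors of gene ids, subsets of `universe`.
#' @param universe Character vector of all assayed genes.
#' @param null `"binomial"` (default) or `"hypergeometric"`.
#' @return An object of class `overlap_result`: `n_universe`, `n_A`, `n_B`,
#'   `n_intersection`, `n_A_only`, `n_B_only`, `p_enrichment`, `null`.
#' @export
venn_overlap <- function(setA, setB, universe,
                         null = c("binomial", "hypergeometric")) {
  null <- match.arg(null)
  setA <- unique(setA)
  setB <- unique(setB)
  universe <- unique(universe)
  outA <- setdiff(setA, universe)
  outB <- setdiff(setB, universe)
  if (length(outA) || length(outB))
    stop("sets must be subsets of the universe; offenders: ",
         paste(head(c(outA, outB), 10L), collapse = ", "))
  nU <- length(universe)
  nA <- length(setA)
  nB <- length(setB)
  nI <- length(intersect(setA, setB))
  p <- if (null == "binomial") binom_upper_tail(nI, nA, nB / nU)
       else phyper(nI - 1, nB, nU - nB, nA, lower.tail = FALSE)
  structure(list(n_universe = nU, n_A = nA, n_B = nB, n_intersection = nI,
                 n_A_only = nA - nI, n_B_only = nB - nI,
                 p_enrichment = p, null = null),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap: |A| = %d, |B| = %d, |A n B| = %d (universe %d)\n%s p = %.3g\n",
    x$n_A, x$n_B, x$n_intersection, x$n_universe, x$null, x$p_enrichment))
  invisible(x)
}

#' Overlap two fold-change tables at a fold threshold
#'
#' Convenience wrapper: thresholds both tables in one direction and overlaps
#' the resulting sets. The default universe is the genes present in BOTH
#' tables, since the overlap is only defined on jointly assayed genes.
#'
#' @param table_a,table_b Fold-change data frames (`gene_id`, `log2fc`).
#' @param fold Fold threshold (ratio > 1).
#' @param direction `"up"` or `"down"`.
#' @param universe Optional explicit universe; default is the intersection of
#'   the two tables' gene ids.
#' @param null Null model, see [venn_overlap()].
#' @param cutoff Log2 cutoff override, see [threshold_genes()].
#' @return An `overlap_result`.
#' @export
overlap_fc_tables <- function(table_a, table_b, fold = 1.5,
                              direction = c("up", "down"), universe = NULL,
                              null = c("binomial", "hypergeometric"),
                              cutoff = log2(fold)) {
  direction <- match.arg(direction)
  if (is.null(universe))
    universe <- intersect(table_a$gene_id, table_b$gene_id)
  a <- intersect(threshold_genes(table_a, fold, direction, cutoff), universe)
  b <- intersect(threshold_genes(table_b, fold, direction, cutoff), universe)
  venn_overlap(a, b, universe, null = null)
}

#' Gene-set enrichment against a user-supplied annotation map
#'
#' For each term in the map, tests whether the gene set is enriched for the
#' term's members with the same upper-tail binomial statistic as
#' [venn_overlap()] (trials = |gene set|, success probability = term size /
#' universe size), plus a Benjamini-Hochberg adjusted column.
#'
#' @param gene_set Character vector of gene ids (subset of `universe`).
#' @param annotation_map Data frame with columns `gene_id`, `term`; genes
#'   must lie within the universe.
#' @param universe Character vector of all assayed genes.
#' @param adjust Add a BH-adjusted p column (default TRUE).
#' @return Data frame per term: `term`, `n_term`, `n_overlap`, `p`, and
#'   `p_adj` when `adjust`, sorted by `p`.
#' @export
set_enrichment <- function(gene_set, annotation_map, universe,
                           adjust = TRUE) {
  stopifnot(all(c("gene_id", "term") %in% names(annotation_map)))
  if (!nrow(annotation_map)) stop("annotation map is empty")
  bad <- setdiff(annotation_map$gene_id, universe)
  if (length(bad))
    stop("annotation map covers genes outside the universe: ",
         paste(head(bad, 10L), collapse = ", "))
  gene_set <- intersect(unique(gene_set), universe)
  nU <- length(unique(universe))
  nS <- length(gene_set)
  terms <- split(annotation_map$gene_id, annotation_map$term)
  res <- data.frame(term = names(terms),
                    n_term = vapply(terms, function(g) length(unique(g)),
                                    integer(1)),
                    n_overlap = vapply(terms, function(g)
                      length(intersect(unique(g), gene_set)), integer(1)),
                    stringsAsFactors = FALSE)
  res$p <- mapply(function(x, m) binom_upper_tail(x, nS, m / nU),
                  res$n_overlap, res$n_term)
  if (adjust) res$p_adj <- p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Chi-square test of a 1:1 segregation ratio
#'
#' Tests observed mutant / wild-type progeny counts against the 1:1
#' expectation of a non-complementation cross:
#' `chi2 = sum((obs - exp)^2 / exp)` with `exp = total / 2` for each class,
#' and the p-value from the chi-square distribution with 1 degree of freedom.
#'
#' @param n_mutant,n_wildtype Non-negative progeny counts (total > 0).
#' @return List with `chi2`, `p`, `df`.
#' @export
segregation_chi2 <- function(n_mutant, n_wildtype) {
  stopifnot(n_mutant >= 0, n_wildtype >= 0)
  total <- n_mutant + n_wildtype
  if (total == 0) stop("both counts are zero")
  e <- total / 2
  chi2 <- (n_mutant - e)^2 / e + (n_wildtype - e)^2 / e
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE), df = 1L)
}
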