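# Hypergeometric over-representation of flat annotation term sets with
# Benjamini-Hochberg FDR. Term sets are flat: no ontology hierarchy is
# propagated.

#' Hypergeometric upper-tail probability
#'
#' `P(X >= x)` for X hypergeometric: drawing `query` genes from a population
#' of `population` genes of which `n` carry the term.
#'
#' @param x Query genes carrying the term.
#' @param n Population genes carrying the term.
#' @param query Query set size.
#' @param population Population size.
#' @return The exact upper-tail probability.
#' @export
hypergeom_upper <- function(x, n, query, population) {
  if (x < 0 || n < 0 || query < 0 || population < 0 ||
      x > min(n, query) || n > population || query > population)
    stop("inconsistent hypergeometric counts", call. = FALSE)
  stats::phyper(x - 1, n, population - n, query, lower.tail = FALSE)
}

#' Term over-representation in a gene set
#'
#' One upper-tail hypergeometric test per term observed at least once in the
#' query, with Benjamini-Hochberg adjustment over the tested terms only
#' (terms with x = 0 are not tested, which fixes the BH denominator at the
#' number of observed terms).
#'
#' @param query Character vector of query gene ids (subset of population).
#' @param annotation Data frame with columns `gene`, `term` (one row per
#'   gene/term pair).
#' @param population Optional character vector; defaults to all genes with
#'   at least one annotation (the reference set).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return Data frame sorted by `padj` then `term`: term, x, n, query_size,
#'   population_size, p, padj, significant.
#' @export
enrich <- function(query, annotation, population = NULL, alpha = 0.05) {
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  if (is.null(population)) population <- unique(annotation$gene)
  if (length(population) == 0) stop("empty population", call. = FALSE)
  query <- unique(query)
  extra <- setdiff(query, population)
  if (length(extra) > 0)
    stop("query gene(s) outside the population: ",
         paste(utils::head(extra, 5), collapse = ", "), call. = FALSE)
  ann <- annotation[annotation$gene %in% population, , drop = FALSE]
  ann <- unique(ann[, c("gene", "term")])
  n_by_term <- table(ann$term)
  x_by_term <- table(ann$term[ann$gene %in% query])
  terms <- names(x_by_term)[x_by_term >= 1]
  if (length(terms) == 0)
    return(data.frame(term = character(0), x = integer(0), n = integer(0),
                      query_size = integer(0), population_size = integer(0),
                      p = numeric(0), padj = numeric(0),
                      significant = logical(0)))
  x <- as.integer(x_by_term[terms])
  n <- as.integer(n_by_term[terms])
  p <- vapply(seq_along(terms), function(i)
    hypergeom_upper(x[i], n[i], length(query), length(population)),
    numeric(1))
  padj <- bh_adjust(p)
  out <- data.frame(term = terms, x = x, n = n,
                    query_size = length(query),
                    population_size = length(population),
                    p = p, padj = padj, significant = padj < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$padj, out$term), , drop = FALSE]
}
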