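# In-paralog pair classification by DE status (P1-P3) and cluster
# membership (Pk1-Pk3), pattern-similarity fractions and pairwise Pearson
# correlations.

#' Classify paralog pairs by differential expression (P1/P2/P3)
#'
#' P1: both genes differentially expressed in the comparison; P2: exactly
#' one; P3: neither. Labels are exhaustive and mutually exclusive.
#'
#' @param pairs Data frame with `gene1`, `gene2`.
#' @param de_res A `de_result` table for the species and comparison.
#' @return List: `class` (per-pair labels) and `counts` (P1, P2, P3).
#' @export
classify_p <- function(pairs, de_res) {
  i1 <- match(pairs$gene1, de_res$gene)
  i2 <- match(pairs$gene2, de_res$gene)
  if (anyNA(i1) || anyNA(i2)) {
    miss <- unique(c(pairs$gene1[is.na(i1)], pairs$gene2[is.na(i2)]))
    stop("gene(s) absent from DE table: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  nde <- de_res$is_deg[i1] + de_res$is_deg[i2]
  cls <- c("P3", "P2", "P1")[nde + 1]
  counts <- table(factor(cls, levels = c("P1", "P2", "P3")))
  list(class = cls,
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Classify paralog pairs by cluster membership (Pk1/Pk2/Pk3)
#'
#' Pk1: both genes assigned to a coexpression cluster; Pk2: only one;
#' Pk3: neither.
#'
#' @param pairs Data frame with `gene1`, `gene2`.
#' @param clustered Character vector of clustered gene ids, or a named
#'   label vector whose names are the clustered genes.
#' @return List: `class` (per-pair labels) and `counts` (Pk1, Pk2, Pk3).
#' @export
classify_pk <- function(pairs, clustered) {
  if (!is.null(names(clustered))) clustered <- names(clustered)
  nin <- (pairs$gene1 %in% clustered) + (pairs$gene2 %in% clustered)
  cls <- c("Pk3", "Pk2", "Pk1")[nin + 1]
  counts <- table(factor(cls, levels = c("Pk1", "Pk2", "Pk3")))
  list(class = cls,
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' Expression-pattern similarity of paralog pairs
#'
#' For P1 pairs in a comparison, similarity means an identical up-regulated
#' stage; for Pk1 pairs, an identical archetype label.
#'
#' @param pairs Data frame with `gene1`, `gene2`.
#' @param de_results Named list of `de_result` tables (one per comparison).
#' @param arch Named character vector, gene -> archetype label (clustered
#'   genes only).
#' @return List: `p1_same_fraction` (per comparison, NA if no P1 pairs),
#'   `pk1_same_fraction`, and the underlying counts.
#' @export
pattern_similarity <- function(pairs, de_results, arch) {
  p1 <- lapply(de_results, function(res) {
    cl <- classify_p(pairs, res)$class
    sel <- cl == "P1"
    if (!any(sel)) return(list(fraction = NA_real_, n = 0L))
    u1 <- up_stage_of(res, pairs$gene1[sel])
    u2 <- up_stage_of(res, pairs$gene2[sel])
    list(fraction = mean(u1 == u2), n = sum(sel))
  })
  pk <- classify_pk(pairs, arch)$class
  sel <- pk == "Pk1"
  pk1 <- if (!any(sel)) list(fraction = NA_real_, n = 0L) else {
    a1 <- arch[pairs$gene1[sel]]; a2 <- arch[pairs$gene2[sel]]
    list(fraction = mean(a1 == a2), n = sum(sel))
  }
  list(p1_same_fraction = vapply(p1, `[[`, 0, "fraction"),
       p1_n = vapply(p1, `[[`, 0L, "n"),
       pk1_same_fraction = pk1$fraction, pk1_n = pk1$n)
}

#' Pairwise Pearson correlation of paralog pairs
#'
#' Standard Pearson correlation over the species' samples (replicate-level
#' values). Undefined (NA) when either gene is absent or has zero variance;
#' undefined pairs are excluded from the high-correlation fraction's
#' denominator.
#'
#' @param pairs Data frame with `gene1`, `gene2`.
#' @param expr Numeric expression matrix (e.g. VST), genes x samples.
#' @param threshold High-correlation cutoff (default 0.9).
#' @return List: `pcc` (per pair, NA where undefined), `fraction_above`
#'   (share of defined pairs with pcc > threshold), `n_defined`.
#' @export
pair_pcc <- function(pairs, expr, threshold = 0.9) {
  pcc <- rep(NA_real_, nrow(pairs))
  ok <- pairs$gene1 %in% rownames(expr) & pairs$gene2 %in% rownames(expr)
  for (i in which(ok)) {
    x <- expr[pairs$gene1[i], ]; y <- expr[pairs$gene2[i], ]
    if (stats::sd(x) > 0 && stats::sd(y) > 0)
      pcc[i] <- stats::cor(x, y)
  }
  nd <- sum(!is.na(pcc))
  list(pcc = pcc,
       fraction_above = if (nd > 0) mean(pcc > threshold, na.rm = TRUE)
                        else NA_real_,
       n_defined = nd, threshold = threshold)
}
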