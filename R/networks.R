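# Bait-gene correlation subnetworks with percentile-derived cutoffs,
# homolog-family grouping of partners, and cross-network comparison.

#' Correlation profile of a bait gene
#'
#' Pearson correlation of the bait's expression against every other gene of
#' the matrix, over the species' samples. Zero-variance candidates are NA.
#'
#' @param bait Bait gene id (must be a row of `expr` with nonzero variance).
#' @param expr Numeric expression matrix, genes x samples.
#' @return Named numeric vector over all genes except the bait.
#' @export
pcc_profile <- function(bait, expr) {
  if (!bait %in% rownames(expr))
    stop("bait not in matrix: ", bait, call. = FALSE)
  b <- expr[bait, ]
  if (stats::sd(b) == 0)
    stop("bait has constant expression: ", bait, call. = FALSE)
  others <- setdiff(rownames(expr), bait)
  sds <- apply(expr[others, , drop = FALSE], 1, stats::sd)
  pcc <- rep(NA_real_, length(others))
  names(pcc) <- others
  ok <- sds > 0
  if (any(ok))
    pcc[ok] <- as.vector(stats::cor(b, t(expr[others[ok], , drop = FALSE])))
  pcc
}

#' Percentile cutoffs of a correlation distribution
#'
#' The negative and positive cutoffs are the empirical quantiles of the
#' finite correlation values at `lower_rank` and `upper_rank`, using linear
#' interpolation between order statistics (quantile type 7), so results are
#' reproducible bit for bit.
#'
#' @param pcc Numeric vector of correlations (NAs dropped).
#' @param lower_rank,upper_rank Quantile ranks (defaults 0.05 and 0.95).
#' @return Named numeric pair `c(negative, positive)`.
#' @export
percentile_cutoffs <- function(pcc, lower_rank = 0.05, upper_rank = 0.95) {
  v <- pcc[is.finite(pcc)]
  if (length(v) < 20)
    stop("need >= 20 finite correlation values for stable quantiles",
         call. = FALSE)
  q <- stats::quantile(v, c(lower_rank, upper_rank), names = FALSE, type = 7)
  c(negative = q[1], positive = q[2])
}

#' Build a bait correlation subnetwork
#'
#' Edges connect the bait to every gene with correlation at or above the
#' positive cutoff (sign `positive`) or at or below the negative cutoff
#' (sign `negative`); the bait itself is excluded. In absolute-threshold
#' mode the cutoffs are `c(-t, t)`.
#'
#' @param bait Bait gene id.
#' @param expr Numeric expression matrix, genes x samples.
#' @param cutoffs Numeric pair `c(negative, positive)`; computed with
#'   [percentile_cutoffs()] on the bait's profile when omitted.
#' @param abs_threshold If given (e.g. 0.8), use `|pcc| >= abs_threshold`
#'   instead of percentile cutoffs.
#' @param lower_rank,upper_rank Passed to [percentile_cutoffs()].
#' @return A `bait_network`: `bait`, `edges` data frame (partner, pcc,
#'   sign), `cutoffs`, and optionally `families` once annotated.
#' @export
build_network <- function(bait, expr, cutoffs = NULL, abs_threshold = NULL,
                          lower_rank = 0.05, upper_rank = 0.95) {
  pcc <- pcc_profile(bait, expr)
  if (!is.null(abs_threshold))
    cutoffs <- c(negative = -abs_threshold, positive = abs_threshold)
  if (is.null(cutoffs))
    cutoffs <- percentile_cutoffs(pcc, lower_rank, upper_rank)
  if (cutoffs[1] > cutoffs[2])
    stop("cutoffs must be ordered (negative <= positive)", call. = FALSE)
  keep <- !is.na(pcc) & (pcc >= cutoffs[2] | pcc <= cutoffs[1])
  edges <- data.frame(partner = names(pcc)[keep],
                      pcc = unname(pcc[keep]),
                      sign = ifelse(pcc[keep] >= cutoffs[2],
                                    "positive", "negative"),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(bait = bait, edges = edges, cutoffs = cutoffs),
            class = "bait_network")
}

#' @export
print.bait_network <- function(x, ...) {
  cat(sprintf("Bait network for %s: %d edges (%d positive, %d negative), cutoffs [%.3f, %.3f]\n",
              x$bait, nrow(x$edges), sum(x$edges$sign == "positive"),
              sum(x$edges$sign == "negative"),
              x$cutoffs[1], x$cutoffs[2]))
  invisible(x)
}

#' Group network partners into homolog families
#'
#' Partners belonging to the same orthogroup share a family id (the group
#' id); partners without a group become singleton families.
#'
#' @param network A `bait_network`.
#' @param hs A `homology_set`.
#' @return The network with a `families` named character vector
#'   (partner -> family id) attached.
#' @export
annotate_families <- function(network, hs) {
  gene2group <- stats::setNames(
    rep(names(hs$groups), lengths(hs$groups)),
    unlist(hs$groups, use.names = FALSE))
  fam <- gene2group[network$edges$partner]
  single <- is.na(fam)
  fam[single] <- paste0("single:", network$edges$partner[single])
  network$families <- stats::setNames(unname(fam), network$edges$partner)
  network
}

family_signs <- function(network) {
  if (is.null(network$families))
    stop("network lacks family annotation; call annotate_families()",
         call. = FALSE)
  fam <- network$families[network$edges$partner]
  sgn <- tapply(network$edges$sign, fam, function(s) {
    u <- unique(s)
    if (length(u) == 1) u else "mixed"
  })
  stats::setNames(as.character(sgn), names(sgn))
}

#' Compare two bait networks at the homolog-family level
#'
#' Families present in both networks are listed with their per-network
#' correlation sign and a concordance flag (same non-mixed sign in both).
#' Same-species comparisons (the isoform use case) are allowed but flagged.
#'
#' @param net_A,net_B `bait_network`s with family annotation.
#' @return List: `families` data frame (family, sign_A, sign_B, concordant),
#'   `summary` counts (shared, concordant, discordant, unique_A, unique_B),
#'   `same_species` flag.
#' @export
compare_networks <- function(net_A, net_B) {
  sA <- family_signs(net_A); sB <- family_signs(net_B)
  shared <- intersect(names(sA), names(sB))
  fams <- data.frame(family = shared,
                     sign_A = unname(sA[shared]),
                     sign_B = unname(sB[shared]),
                     stringsAsFactors = FALSE)
  fams$concordant <- fams$sign_A == fams$sign_B &
    fams$sign_A != "mixed"
  spec <- function(net) unique(sub("\\|.*$", "", net$bait))
  list(families = fams,
       summary = c(shared = length(shared),
                   concordant = sum(fams$concordant),
                   discordant = sum(!fams$concordant),
                   unique_A = length(setdiff(names(sA), shared)),
                   unique_B = length(setdiff(names(sB), shared))),
       same_species = identical(spec(net_A), spec(net_B)))
}
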