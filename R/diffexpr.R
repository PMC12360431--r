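# Negative-binomial differential expression between consecutive stages.
#
# A closed-form Wald test on the log2 ratio of pseudocounted group means
# replaces a full GLM fit: the standard error comes from the delta method
# under NB(mean, dispersion) with a method-of-moments dispersion estimate
# shrunk toward the across-gene median. Desk-scale and oracle-checkable.

.comparisons <- list(PCvsG = c(earlier = "PC", later = "G"),
                     GvsS = c(earlier = "G", later = "S"))

#' Per-gene NB dispersion estimate
#'
#' Method of moments on size-factor-normalized counts with stage means
#' removed: `alpha_g = max((s2_g - m_g) / m_g^2, 1e-8)` where `s2_g` is the
#' pooled within-stage variance and `m_g` the grand mean, then shrunk halfway
#' on the log scale toward the across-gene median.
#'
#' @param counts Integer matrix, genes x samples.
#' @param design Design data frame (`sample`, `stage`, `replicate`).
#' @param factors Optional size factors; computed if omitted.
#' @return Named numeric vector of dispersions (floor 1e-8).
#' @export
estimate_dispersion <- function(counts, design, factors = NULL) {
  stages <- unique(design$stage)
  reps <- table(design$stage)
  if (any(reps < 2))
    stop("stage(s) with a single replicate: ",
         paste(names(reps)[reps < 2], collapse = ", "),
         "; use a pooled dispersion estimate instead", call. = FALSE)
  if (is.null(factors)) factors <- size_factors(counts)
  norm <- sweep(counts[, design$sample, drop = FALSE], 2, factors, "/")
  m <- rowMeans(norm)
  ss <- 0
  for (st in stages) {
    sub <- norm[, design$stage == st, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
  }
  s2 <- ss / (ncol(norm) - length(stages))
  raw <- pmax((s2 - m) / m^2, 1e-8)
  raw[!is.finite(raw)] <- 1e-8       # all-zero genes
  med <- stats::median(raw[m > 0])
  if (!is.finite(med) || med <= 0) med <- 1e-8
  out <- exp((log(raw) + log(med)) / 2)
  names(out) <- rownames(counts)
  pmax(out, 1e-8)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper over the standard step-up FDR adjustment: sort p
#' ascending, `q_i = p_i * n / i`, enforce monotonicity from the largest rank
#' down, cap at 1, return in input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Wald differential expression test between two consecutive stages
#'
#' Per gene, `log2fc = log2((m_later + 0.5) / (m_earlier + 0.5))` on
#' size-factor-normalized group means, with the standard error from the delta
#' method under NB(mean, dispersion): the variance of a group mean of n
#' replicates is `(m + alpha m^2) / n`. The Wald statistic `log2fc / SE` gets
#' a two-sided normal p-value; adjustment is Benjamini-Hochberg. Genes with
#' zero counts in every sample of both groups are reported with p = 1 (not
#' dropped), keeping matrix alignment.
#'
#' @param counts Integer matrix, genes x samples (one species).
#' @param design Design data frame for those samples.
#' @param comparison `"PCvsG"` or `"GvsS"`.
#' @param lfc_threshold Fold-change threshold on |log2fc| (default 1).
#' @param alpha Adjusted-p significance level (default 0.05).
#' @param boundary `"gte"` (default): DEG iff |log2fc| >= threshold and
#'   padj < alpha; `"gt"`: |log2fc| > threshold and padj <= alpha.
#' @param dispersion Optional per-gene dispersions; estimated if omitted.
#' @param factors Optional size factors; computed if omitted.
#' @return A data frame of class `de_result`: gene, comparison, base_mean,
#'   log2fc, se, stat, p, padj, is_deg, up_stage.
#' @export
de_test <- function(counts, design, comparison,
                    lfc_threshold = 1, alpha = 0.05,
                    boundary = c("gte", "gt"),
                    dispersion = NULL, factors = NULL) {
  boundary <- match.arg(boundary)
  if (!comparison %in% names(.comparisons))
    stop("comparison must be one of: ",
         paste(names(.comparisons), collapse = ", "), call. = FALSE)
  cmp <- .comparisons[[comparison]]
  for (st in cmp)
    if (sum(design$stage == st) < 2)
      stop("need >= 2 replicates at stage ", st, call. = FALSE)
  if (is.null(factors)) factors <- size_factors(counts)
  if (is.null(dispersion))
    dispersion <- estimate_dispersion(counts, design, factors)
  norm <- sweep(counts[, design$sample, drop = FALSE], 2, factors, "/")
  grp <- function(st) norm[, design$stage == st, drop = FALSE]
  e <- grp(cmp["earlier"]); l <- grp(cmp["later"])
  me <- rowMeans(e); ml <- rowMeans(l)
  log2fc <- log2((ml + 0.5) / (me + 0.5))
  var_mean <- function(m, n) (m + dispersion * m^2) / n
  se2 <- (var_mean(ml, ncol(l)) / (ml + 0.5)^2 +
          var_mean(me, ncol(e)) / (me + 0.5)^2) / log(2)^2
  se <- sqrt(se2)
  stat <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(stat))
  allzero <- me == 0 & ml == 0
  p[allzero] <- 1; stat[allzero] <- 0; log2fc[allzero] <- 0
  padj <- bh_adjust(p)
  is_deg <- if (boundary == "gte")
    abs(log2fc) >= lfc_threshold & padj < alpha
  else
    abs(log2fc) > lfc_threshold & padj <= alpha
  up_stage <- rep("none", length(p))
  up_stage[is_deg & log2fc > 0] <- cmp[["later"]]
  up_stage[is_deg & log2fc < 0] <- cmp[["earlier"]]
  res <- data.frame(gene = rownames(counts), comparison = comparison,
                    base_mean = (me + ml) / 2, log2fc = log2fc, se = se,
                    stat = stat, p = p, padj = padj, is_deg = is_deg,
                    up_stage = up_stage,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  res
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("Differential expression, %s: %d genes, %d DEGs (%s up %d, %s up %d)\n",
              x$comparison[1], nrow(x), sum(x$is_deg),
              .comparisons[[x$comparison[1]]]["earlier"],
              sum(x$up_stage == .comparisons[[x$comparison[1]]]["earlier"]),
              .comparisons[[x$comparison[1]]]["later"],
              sum(x$up_stage == .comparisons[[x$comparison[1]]]["later"])))
  print.data.frame(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Partition DEGs by up-regulated stage and build the clustering input set
#'
#' @param results Named list of `de_result` tables, one per comparison
#'   (`PCvsG`, `GvsS`), for one species.
#' @return List: `up` (per comparison, per stage, character vectors of genes
#'   up-regulated there), `union` (all DEGs across comparisons: the
#'   clustering input set), `totals` (per comparison and overall DEG counts).
#' @export
deg_sets <- function(results) {
  up <- lapply(results, function(r) {
    stages <- setdiff(unique(r$up_stage), "none")
    stats::setNames(lapply(stages, function(st)
      r$gene[r$up_stage == st]), stages)
  })
  degs <- lapply(results, function(r) r$gene[r$is_deg])
  union_set <- unique(unlist(degs, use.names = FALSE))
  list(up = up, union = union_set,
       totals = c(vapply(degs, length, 0L), total = length(union_set)))
}
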