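# Normalization (TPM, median-of-ratios size factors, variance-stabilizing
# log transform), quartile abundance tables and the isoform census.

#' Transcripts-per-million normalization
#'
#' Per sample: `rate_g = count_g / (length_g / 1000)`;
#' `TPM_g = 1e6 * rate_g / sum(rates)`. Columns sum to 1e6.
#'
#' @param counts Non-negative integer matrix, genes x samples, rownames set.
#' @param lengths Named vector of transcript lengths in nt (> 0), covering
#'   every gene in `counts`.
#' @return Numeric matrix of the same shape with attribute `kind = "TPM"`.
#' @export
compute_tpm <- function(counts, lengths) {
  genes <- rownames(counts)
  missing <- setdiff(genes, names(lengths))
  if (length(missing) > 0)
    stop("missing length for gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  len <- lengths[genes]
  if (any(len <= 0)) stop("lengths must be > 0", call. = FALSE)
  rate <- counts / (len / 1000)
  cs <- colSums(rate)
  if (any(cs == 0))
    stop("sample(s) with no expressed gene: ",
         paste(colnames(counts)[cs == 0], collapse = ", "), call. = FALSE)
  tpm <- sweep(rate, 2, cs, "/") * 1e6
  attr(tpm, "kind") <- "TPM"
  tpm
}

#' Median-of-ratios size factors
#'
#' Classic count normalization: the factor of a sample is the median, over
#' genes whose geometric mean across samples is positive, of the ratio of the
#' sample's count to that geometric mean.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  if (all(counts == 0)) stop("all-zero count matrix", call. = FALSE)
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use))
    stop("no gene with positive counts in every sample; ",
         "size factors are undefined", call. = FALSE)
  geo <- exp(log_geo[use])
  sf <- apply(counts, 2, function(x) stats::median(x[use] / geo))
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor(s)", call. = FALSE)
  sf
}

#' Variance-stabilizing log transform
#'
#' `log2(count / factor + 1)`, monotone in the count for a fixed factor. This
#' is a dependency-free stand-in for a parametric variance-stabilizing
#' transform; it anchors zero counts at 0 and flattens the NB mean-variance
#' trend on the log scale.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @param factors Optional per-sample positive size factors; computed with
#'   [size_factors()] when omitted.
#' @return Numeric matrix with attribute `kind = "VST"`.
#' @export
vst_transform <- function(counts, factors = NULL) {
  if (is.null(factors)) factors <- size_factors(counts)
  if (any(factors <= 0)) stop("factors must be positive", call. = FALSE)
  v <- log2(sweep(counts, 2, factors, "/") + 1)
  attr(v, "kind") <- "VST"
  v
}

#' Quartile abundance table with chi-square goodness of fit
#'
#' For one stage, the per-transcript mean TPM over the stage's replicates is
#' computed; transcripts with mean TPM > 0 are ranked (ties broken by stable
#' row order) and split into four equal-size bins Q1 (lowest) to Q4 (highest)
#' of the pooled coding + noncoding distribution. Each class's bin counts are
#' tested against the uniform expectation `total/4` with a chi-square
#' goodness-of-fit test on 3 degrees of freedom, no continuity correction.
#'
#' @param tpm TPM matrix from [compute_tpm()].
#' @param design Sample design data frame with `sample` and `stage` columns.
#' @param coding Named logical vector (TRUE = coding) covering the rows.
#' @param stage Stage to analyse; must be present in the design.
#' @return Data frame with one row per class: bin counts `Q1..Q4`, `total`,
#'   `chisq`, `df`, `p`.
#' @export
quartile_table <- function(tpm, design, coding, stage) {
  if (!identical(attr(tpm, "kind"), "TPM"))
    stop("`tpm` must be a TPM matrix (see compute_tpm)", call. = FALSE)
  if (!stage %in% design$stage)
    stop("stage not present in design: ", stage, call. = FALSE)
  cols <- design$sample[design$stage == stage]
  m <- rowMeans(tpm[, cols, drop = FALSE])
  expressed <- m > 0
  idx <- which(expressed)
  n <- length(idx)
  r <- rank(m[idx], ties.method = "first")
  bin <- ceiling(4 * r / n)
  cls <- ifelse(coding[rownames(tpm)[idx]], "coding", "noncoding")
  out <- lapply(c("coding", "noncoding"), function(cl) {
    o <- tabulate(bin[cls == cl], nbins = 4)
    tot <- sum(o)
    if (tot > 0) {
      e <- tot / 4
      stat <- sum((o - e)^2 / e)
      p <- stats::pchisq(stat, df = 3, lower.tail = FALSE)
    } else {
      stat <- 0; p <- NA_real_
    }
    data.frame(class = cl, Q1 = o[1], Q2 = o[2], Q3 = o[3], Q4 = o[4],
               total = tot, chisq = stat, df = 3L, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$stage <- stage
  res
}

#' Isoform census
#'
#' Tallies, per species, how many genes have k = 1, 2, 3, ... transcripts and
#' the share of multi-isoform (alternatively spliced) genes at each k.
#'
#' @param tx2gene Data frame with columns `gene` and `transcript` (optionally
#'   `species`; otherwise all rows are treated as one species).
#' @return Data frame with columns `species`, `k`, `n_genes`,
#'   `frac_of_as_genes` (NA at k = 1).
#' @export
isoform_census <- function(tx2gene) {
  stopifnot(all(c("gene", "transcript") %in% names(tx2gene)))
  if (anyDuplicated(tx2gene$transcript))
    stop("duplicate transcript ids", call. = FALSE)
  sp <- if ("species" %in% names(tx2gene)) tx2gene$species else "all"
  parts <- split(tx2gene$gene, sp)
  out <- lapply(names(parts), function(s) {
    per_gene <- table(parts[[s]])
    dist <- table(factor(per_gene, levels = seq_len(max(per_gene))))
    k <- as.integer(names(dist))
    n <- as.integer(dist)
    keep <- n > 0 | k == 1
    k <- k[keep]; n <- n[keep]
    n_as <- sum(n[k >= 2])
    data.frame(species = s, k = k, n_genes = n,
               frac_of_as_genes = ifelse(k >= 2 & n_as > 0, n / n_as, NA),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Coding / noncoding composition summary
#'
#' @param coding Logical vector, TRUE = coding.
#' @return Data frame with `class`, `n`, `percent` (two decimals).
#' @export
coding_noncoding_summary <- function(coding) {
  n <- c(coding = sum(coding), noncoding = sum(!coding))
  data.frame(class = names(n), n = as.integer(n),
             percent = round(100 * n / sum(n), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}
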