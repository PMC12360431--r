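# K-means coexpression clustering of the DEG union and mapping of clusters
# to the six stage archetypes.

#' Standardize genes for clustering
#'
#' Per gene (row): subtract the mean and divide by the standard deviation over
#' the species' samples. Zero-variance genes become all-zero rows and are
#' flagged; they are excluded from clustering downstream.
#'
#' @param x Numeric matrix (e.g. a VST matrix), genes x samples.
#' @param genes Optional subset of rownames to standardize (default all).
#' @return List: `z` (standardized matrix), `zero_variance` (character vector
#'   of flagged genes).
#' @export
standardize_genes <- function(x, genes = rownames(x)) {
  missing <- setdiff(genes, rownames(x))
  if (length(missing) > 0)
    stop("gene(s) not in matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  m <- x[genes, , drop = FALSE]
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  flagged <- rownames(m)[sdv == 0]
  sdv[sdv == 0] <- 1
  z <- (m - mu) / sdv
  z[flagged, ] <- 0
  list(z = z, zero_variance = flagged)
}

# k-means++ seeding: first center uniform, subsequent centers with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 else rep(1, n)
    centers[j + 1] <- sample.int(n, 1, prob = probs)
    nd <- rowSums((x - matrix(x[centers[j + 1], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' K-means clustering with k-means++ restarts
#'
#' Runs `restarts` independent k-means fits, each initialized by k-means++
#' seeding, and keeps the fit with the lowest total within-cluster sum of
#' squares. Deterministic for a fixed `seed`. If a restart produces an empty
#' cluster it is re-seeded with a fresh k-means++ draw.
#'
#' @param x Numeric matrix, genes x samples (standardized rows recommended).
#' @param k Number of clusters (default 6).
#' @param max_iter Maximum iterations per run (default 1000).
#' @param restarts Number of random restarts (default 10).
#' @param seed Integer seed.
#' @return List of class `coexpr_clusters`: `cluster` (named integer vector),
#'   `centers` (k x samples), `tot_withinss`, `k`.
#' @export
kmeans_cluster <- function(x, k = 6, max_iter = 1000, restarts = 10, seed = 1) {
  if (nrow(x) < k)
    stop("fewer genes (", nrow(x), ") than clusters (", k, ")", call. = FALSE)
  if (nrow(x) == k) {
    # one point per cluster: the optimum is exact
    return(structure(list(cluster = stats::setNames(seq_len(k), rownames(x)),
                          centers = x, tot_withinss = 0, k = k),
                     class = "coexpr_clusters"))
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- NULL
    for (attempt in 1:10) {
      init <- kmeanspp_init(x, k)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = init, iter.max = max_iter)),
        error = function(e) NULL)
      if (!is.null(fit) && all(fit$size > 0)) break
    }
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed on every restart", call. = FALSE)
  structure(list(cluster = stats::setNames(best$cluster, rownames(x)),
                 centers = best$centers,
                 tot_withinss = best$tot.withinss, k = k),
            class = "coexpr_clusters")
}

#' @export
print.coexpr_clusters <- function(x, ...) {
  cat(sprintf("K-means coexpression clustering: %d genes, k = %d, within-SS = %.2f\n",
              length(x$cluster), x$k, x$tot_withinss))
  print(table(cluster = x$cluster))
  if (!is.null(attr(x, "archetypes"))) {
    cat("archetype labels:\n")
    print(attr(x, "archetypes"))
  }
  invisible(x)
}

#' Elbow curve over candidate cluster numbers
#'
#' For each k, the best-of-`restarts` total within-cluster sum of squares;
#' the suggested k maximizes the second difference of the log within-SS
#' curve (the "elbow": the point where relative improvement collapses).
#'
#' @param x Numeric matrix, genes x samples.
#' @param k_max Largest k to evaluate (>= 2).
#' @param restarts Restarts per k (default 10).
#' @param seed Integer seed.
#' @return Data frame (`k`, `tot_withinss`) with attribute `suggested_k`.
#' @export
elbow_curve <- function(x, k_max, restarts = 10, seed = 1) {
  if (k_max < 2) stop("k_max must be >= 2", call. = FALSE)
  if (nrow(x) < k_max)
    stop("fewer genes than k_max", call. = FALSE)
  ss <- numeric(k_max)
  ss[1] <- sum(sweep(x, 2, colMeans(x))^2)
  for (k in 2:k_max)
    ss[k] <- kmeans_cluster(x, k = k, restarts = restarts,
                            seed = seed + k)$tot_withinss
  out <- data.frame(k = seq_len(k_max), tot_withinss = ss)
  if (k_max >= 3) {
    # curvature of the log curve: relative drops, so the plateau after the
    # true k dominates rather than the large absolute early drops
    ls <- log(pmax(ss, .Machine$double.eps))
    d2 <- ls[1:(k_max - 2)] - 2 * ls[2:(k_max - 1)] + ls[3:k_max]
    attr(out, "suggested_k") <- which.max(d2) + 1L
  }
  out
}

# all permutations of seq_len(n); n = 6 gives 720 rows
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Map six clusters to the six stage archetypes
#'
#' Per cluster, the centroid's three stage means are z-scored and scored
#' against each z-scored archetype template by cosine similarity; the
#' bijection maximizing the total similarity over all 6! assignments is
#' returned (ties broken by the first optimum in lowest-cluster-index order).
#'
#' @param fit A `coexpr_clusters` with k = 6.
#' @param design Design data frame for the clustered matrix's samples.
#' @return Named character vector, cluster index -> archetype label, with
#'   attribute `similarity` (per-cluster cosine similarity).
#' @export
assign_archetypes <- function(fit, design) {
  if (fit$k != 6)
    stop("archetype mapping is defined only for k = 6", call. = FALSE)
  stages <- dev_stages()
  cent <- fit$centers
  stage_means <- sapply(stages, function(st)
    rowMeans(cent[, design$sample[design$stage == st], drop = FALSE]))
  zrow <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  zc <- t(apply(stage_means, 1, zrow))
  zt <- t(apply(archetype_templates(), 1, zrow))
  cosim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sim <- matrix(0, 6, 6, dimnames = list(1:6, rownames(zt)))
  for (i in 1:6) for (j in 1:6) sim[i, j] <- cosim(zc[i, ], zt[j, ])
  perms <- all_perms(6)
  score <- vapply(seq_len(nrow(perms)), function(r)
    sum(sim[cbind(1:6, perms[r, ])]), numeric(1))
  best <- perms[which.max(score), ]
  labels <- stats::setNames(rownames(zt)[best], as.character(1:6))
  attr(labels, "similarity") <- stats::setNames(sim[cbind(1:6, best)],
                                                labels)
  labels
}

#' Per-gene archetype labels from a labelled clustering
#'
#' @param fit A `coexpr_clusters` with k = 6.
#' @param design Design data frame (used to label clusters).
#' @param labels Optional precomputed cluster -> archetype map.
#' @return Named character vector, gene -> archetype label (C1..C6).
#' @export
cluster_archetype_labels <- function(fit, design, labels = NULL) {
  if (is.null(labels)) labels <- assign_archetypes(fit, design)
  stats::setNames(unname(labels[as.character(fit$cluster)]),
                  names(fit$cluster))
}

#' Cluster (or archetype) size summary
#'
#' @param labels Character/factor vector of per-gene cluster or archetype
#'   labels.
#' @return Data frame with `cluster`, `n`, `percent` (two decimals), largest
#'   first.
#' @export
cluster_size_summary <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  data.frame(cluster = names(tab), n = as.integer(tab),
             percent = round(100 * as.integer(tab) / length(labels), 2),
             row.names = NULL, stringsAsFactors = FALSE)
}
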