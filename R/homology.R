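# Orthogroup parsing, relationship classification, and all cross-species
# ortholog expression comparisons (shared/exclusive DE, synchrony,
# stage- and cluster-overlap, gastrula core modules).

#' Parse an orthogroup file
#'
#' One group per line, `GROUPID: taxon|gene taxon|gene ...`. Relationship
#' classes are assigned per group from the per-species member counts:
#' `one2one` (1 + 1), `one2many_A` (many A, one B), `one2many_B` (one A, many
#' B), `many2many`; groups with members from a single species are classed
#' `other` and contribute no ortholog pairs.
#'
#' @param path Path to a groups file (or a character vector of lines via
#'   `lines`).
#' @param species Optional character pair fixing which taxon is A and which
#'   is B; inferred (sorted) from the file when omitted.
#' @param lines Alternative to `path`: the lines themselves.
#' @return A `homology_set` (see [sample_homology()]); `paralog_pairs` is
#'   empty and can be attached from a pair table.
#' @export
parse_groups <- function(path = NULL, species = NULL, lines = NULL) {
  if (is.null(lines)) lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- regmatches(lines, regexec("^(\\S+):\\s*(.*)$", lines))
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0)
    stop("malformed group line(s) at: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  gid <- vapply(parts, `[`, "", 2)
  if (anyDuplicated(gid)) stop("duplicate group ids", call. = FALSE)
  members <- lapply(parts, function(p)
    strsplit(p[3], "\\s+")[[1]])
  no_taxon <- which(vapply(members, function(m)
    any(!grepl("^[^|]+\\|.+$", m)), logical(1)))
  if (length(no_taxon) > 0)
    stop("member without 'taxon|' prefix at line(s): ",
         paste(utils::head(no_taxon, 5), collapse = ", "), call. = FALSE)
  taxa <- sort(unique(sub("\\|.*$", "", unlist(members))))
  if (is.null(species)) {
    if (length(taxa) > 2)
      stop("more than two taxa in file: ",
           paste(taxa, collapse = ", "), call. = FALSE)
    species <- taxa
  }
  spA <- species[1]; spB <- species[2]
  groups <- stats::setNames(members, gid)
  cls <- vapply(members, function(m) {
    tax <- sub("\\|.*$", "", m)
    nA <- sum(tax == spA); nB <- sum(tax == spB)
    if (nA == 1 && nB == 1) "one2one"
    else if (nA > 1 && nB == 1) "one2many_A"
    else if (nA == 1 && nB > 1) "one2many_B"
    else if (nA > 1 && nB > 1) "many2many"
    else "other"
  }, character(1))
  names(cls) <- gid
  pair_list <- lapply(which(cls != "other"), function(i) {
    m <- members[[i]]
    tax <- sub("\\|.*$", "", m)
    eg <- expand.grid(gene_A = m[tax == spA], gene_B = m[tax == spB],
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    eg$group <- gid[i]; eg$class <- cls[i]
    eg
  })
  pairs <- if (length(pair_list) > 0) do.call(rbind, pair_list)
  else data.frame(gene_A = character(0), gene_B = character(0),
                  group = character(0), class = character(0))
  rownames(pairs) <- NULL
  structure(list(groups = groups, class = cls, pairs = pairs,
                 paralog_pairs = list(), species = species),
            class = "homology_set")
}

#' @export
print.homology_set <- function(x, ...) {
  cat(sprintf("Homology set: %d groups, %d ortholog pairs (%s vs %s)\n",
              length(x$groups), nrow(x$pairs),
              x$species[1], x$species[2]))
  print(table(class = x$class))
  invisible(x)
}

#' One-to-one ortholog pairs of a homology set
#' @param hs A `homology_set`.
#' @return Data frame of pairs with class `one2one`.
#' @export
one2one_pairs <- function(hs) {
  hs$pairs[hs$pairs$class == "one2one", , drop = FALSE]
}

#' Relationship-class summary
#'
#' @param hs A `homology_set`.
#' @return List: `n_groups`, `n_pairs`, `group_counts` per class,
#'   `group_percent` per class (one decimal), `pair_counts` per class.
#' @export
relationship_summary <- function(hs) {
  lev <- c(.relationship_classes,
           if (any(hs$class == "other")) "other")
  gc <- table(factor(hs$class, levels = lev))
  pc <- table(factor(hs$pairs$class, levels = lev))
  list(n_groups = length(hs$groups),
       n_pairs = nrow(hs$pairs),
       group_counts = stats::setNames(as.integer(gc), lev),
       group_percent = stats::setNames(
         round(100 * as.integer(gc) / max(length(hs$groups), 1), 1), lev),
       pair_counts = stats::setNames(as.integer(pc), lev))
}

#' Partition one-to-one ortholog pairs by cross-species DE status
#'
#' A species' DEG set is the union of its DEGs over both stage comparisons.
#'
#' @param pairs One-to-one pair data frame (`gene_A`, `gene_B`).
#' @param degs_A,degs_B Character vectors of DEG ids per species.
#' @return List: `counts` (both / only_A / only_B / neither) and `cell`
#'   (per-pair assignment, same order as `pairs`).
#' @export
shared_de_partition <- function(pairs, degs_A, degs_B) {
  inA <- pairs$gene_A %in% degs_A
  inB <- pairs$gene_B %in% degs_B
  cell <- ifelse(inA & inB, "both",
          ifelse(inA, "only_A", ifelse(inB, "only_B", "neither")))
  counts <- table(factor(cell, levels = c("both", "only_A", "only_B",
                                          "neither")))
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       cell = cell)
}

up_stage_of <- function(res, genes) {
  stats::setNames(res$up_stage[match(genes, res$gene)], genes)
}

#' Stage synchrony of orthologs differentially expressed in both species
#'
#' Restricted to one-to-one pairs where both genes are DEGs in the given
#' comparison: a pair is same-stage iff the two genes share the up-regulated
#' stage. The percent is `100 * same / (same + asynchronous)`, rounded to the
#' nearest integer.
#'
#' @param pairs One-to-one pair data frame.
#' @param res_A,res_B `de_result` tables for the comparison, per species.
#' @param comparison `"PCvsG"` or `"GvsS"`.
#' @return List: `same_by_stage` (named counts), `same`, `asynchronous`,
#'   `n_both_de`, `percent_same`.
#' @export
synchrony_stats <- function(pairs, res_A, res_B, comparison) {
  if (!comparison %in% names(.comparisons))
    stop("unknown comparison: ", comparison, call. = FALSE)
  upA <- up_stage_of(res_A, pairs$gene_A)
  upB <- up_stage_of(res_B, pairs$gene_B)
  both <- !is.na(upA) & !is.na(upB) & upA != "none" & upB != "none"
  same <- both & upA == upB
  stages <- unname(.comparisons[[comparison]])
  same_by_stage <- stats::setNames(
    vapply(stages, function(st) sum(same & upA == st), 0L), stages)
  n_same <- sum(same); n_async <- sum(both) - n_same
  list(same_by_stage = same_by_stage, same = n_same,
       asynchronous = n_async, n_both_de = sum(both),
       percent_same = if (sum(both) > 0)
         round(100 * n_same / sum(both)) else NA_real_)
}

# stages a gene is up-regulated in, across both comparisons
up_stages_union <- function(results, genes) {
  out <- stats::setNames(vector("list", length(genes)), genes)
  for (r in results) {
    up <- r$up_stage[match(genes, r$gene)]
    hit <- which(!is.na(up) & up != "none")
    for (i in hit) out[[i]] <- union(out[[i]], up[i])
  }
  out
}

#' Stage-overlap matrix of one-to-one DEG orthologs
#'
#' Cell (sA, sB) counts pairs whose A gene is up-regulated at sA in either
#' comparison and whose B gene is up-regulated at sB in either comparison; a
#' pair can contribute to several cells.
#'
#' @param results_A,results_B Named lists of `de_result` tables per species.
#' @param pairs One-to-one pair data frame.
#' @return 3 x 3 integer matrix over stages PC, G, S.
#' @export
stage_overlap_matrix <- function(results_A, results_B, pairs) {
  stages <- dev_stages()
  upA <- up_stages_union(results_A, pairs$gene_A)
  upB <- up_stages_union(results_B, pairs$gene_B)
  m <- matrix(0L, 3, 3, dimnames = list(A = stages, B = stages))
  for (i in seq_len(nrow(pairs))) {
    sa <- upA[[i]]; sb <- upB[[i]]
    if (length(sa) > 0 && length(sb) > 0)
      m[sa, sb] <- m[sa, sb] + 1L
  }
  m
}

#' Archetype overlap of orthologs clustered in both species
#'
#' Cell (Ci, Cj) counts pairs with the A gene in archetype Ci and the B gene
#' in Cj. The same-archetype percent uses all supplied pairs as denominator
#' (pairs with an unlabelled member are counted there but excluded from the
#' matrix and reported separately).
#'
#' @param pairs Pair data frame (typically the both-DE one-to-one pairs).
#' @param arch_A,arch_B Named character vectors, gene -> archetype label.
#' @return List: `matrix` (6 x 6), `trace`, `n_pairs`, `n_unlabelled`,
#'   `percent_same` (one decimal).
#' @export
cluster_overlap <- function(pairs, arch_A, arch_B) {
  labs <- paste0("C", 1:6)
  la <- arch_A[pairs$gene_A]; lb <- arch_B[pairs$gene_B]
  ok <- !is.na(la) & !is.na(lb)
  m <- table(factor(la[ok], levels = labs), factor(lb[ok], levels = labs))
  m <- matrix(as.integer(m), 6, 6, dimnames = list(A = labs, B = labs))
  tr <- sum(diag(m))
  n <- nrow(pairs)
  list(matrix = m, trace = tr, n_pairs = n,
       n_unlabelled = sum(!ok),
       percent_same = if (n > 0) round(100 * tr / n, 1) else NA_real_)
}

#' Orthologs up-regulated at gastrula in both species
#'
#' A pair is included iff each gene has up_stage G in at least one comparison
#' in its species.
#'
#' @param pairs One-to-one pair data frame.
#' @param results_A,results_B Named lists of `de_result` tables.
#' @return The subset of `pairs`.
#' @export
gastrula_core <- function(pairs, results_A, results_B) {
  upA <- up_stages_union(results_A, pairs$gene_A)
  upB <- up_stages_union(results_B, pairs$gene_B)
  keep <- vapply(seq_len(nrow(pairs)), function(i)
    "G" %in% upA[[i]] && "G" %in% upB[[i]], logical(1))
  pairs[keep, , drop = FALSE]
}

#' Ortholog pairs with both members in gastrula-up archetypes
#'
#' Membership test of both genes against the archetypes with increased
#' gastrula expression (C2, C3, C4); any combination of the three counts.
#'
#' @param pairs Pair data frame.
#' @param arch_A,arch_B Named character vectors, gene -> archetype label.
#' @return The subset of `pairs`.
#' @export
g_cluster_core <- function(pairs, arch_A, arch_B) {
  gset <- c("C2", "C3", "C4")
  la <- arch_A[pairs$gene_A]; lb <- arch_B[pairs$gene_B]
  keep <- !is.na(la) & !is.na(lb) & la %in% gset & lb %in% gset
  pairs[keep, , drop = FALSE]
}
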