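# End-to-end orchestration: simulate -> normalize -> DE -> cluster ->
# homology -> paralogs -> networks -> enrich -> report, deterministic for a
# fixed seed, with TSV outputs and a machine-readable manifest.

#' Run the full two-species comparison pipeline
#'
#' Generates (or takes) a synthetic dataset, then per species computes size
#' factors, VST and TPM matrices, differential expression for both stage
#' comparisons, the DEG union, K-means clustering (k = 6) with archetype
#' labels; then the cross-species ortholog comparisons, the paralog
#' classifications and correlations, one bait network per species with a
#' family-level comparison, term enrichment of the gastrula-up archetype,
#' and the summary report. When `outdir` is given, every table is written as
#' TSV and a manifest with md5 checksums is recorded.
#'
#' @param config A [synth_config()]; its seed drives all randomness.
#' @param outdir Optional output directory.
#' @param dataset Optional pre-built `synth_dataset` (defaults to
#'   `simulate_dataset(config)`).
#' @param k Number of coexpression clusters (default 6; archetype labelling
#'   requires 6).
#' @return A `pipeline_result` bundle with components `dataset`,
#'   `per_species` (normalization, DE, clustering per species), `ortho`
#'   (cross-species comparisons), `paralogs`, `networks`, `enrichment`,
#'   `report`, and `manifest` when written.
#' @export
run_pipeline <- function(config, outdir = NULL, dataset = NULL, k = 6) {
  if (is.null(dataset)) dataset <- simulate_dataset(config)
  spp <- config$species
  lengths_all <- stats::setNames(dataset$truth$genes$length,
                                 dataset$truth$genes$gene)
  coding_all <- stats::setNames(dataset$truth$genes$coding,
                                dataset$truth$genes$gene)

  per_species <- list()
  for (i in seq_along(spp)) {
    sp <- spp[i]
    cm <- dataset$counts[[sp]]
    sf <- size_factors(cm$counts)
    vst <- vst_transform(cm$counts, sf)
    tpm <- compute_tpm(cm$counts, lengths_all)
    de <- list(
      PCvsG = de_test(cm$counts, cm$design, "PCvsG", factors = sf),
      GvsS = de_test(cm$counts, cm$design, "GvsS", factors = sf))
    sets <- deg_sets(de)
    clus <- NULL; arch <- NULL
    std <- standardize_genes(vst, intersect(sets$union, rownames(vst)))
    clusterable <- setdiff(rownames(std$z), std$zero_variance)
    if (length(clusterable) >= k) {
      clus <- kmeans_cluster(std$z[clusterable, , drop = FALSE], k = k,
                             seed = sub_seed(config$seed, 40 + i))
      if (k == 6) {
        labels <- assign_archetypes(clus, cm$design)
        attr(clus, "archetypes") <- labels
        arch <- cluster_archetype_labels(clus, cm$design, labels)
      }
    }
    quart <- do.call(rbind, lapply(dev_stages(), function(st)
      quartile_table(tpm, cm$design, coding_all, st)))
    per_species[[sp]] <- list(size_factors = sf, vst = vst, tpm = tpm,
                              de = de, deg_sets = sets, clustering = clus,
                              archetypes = arch, quartiles = quart)
  }

  A <- per_species[[spp[1]]]; B <- per_species[[spp[2]]]
  hs <- dataset$homology
  o2o <- one2one_pairs(hs)
  part <- shared_de_partition(o2o, A$deg_sets$union, B$deg_sets$union)
  both_de <- o2o[part$cell == "both", , drop = FALSE]
  ortho <- list(
    relationship = relationship_summary(hs),
    partition = part,
    synchrony = list(
      PCvsG = synchrony_stats(o2o, A$de$PCvsG, B$de$PCvsG, "PCvsG"),
      GvsS = synchrony_stats(o2o, A$de$GvsS, B$de$GvsS, "GvsS")),
    stage_overlap = stage_overlap_matrix(A$de, B$de, o2o),
    cluster_overlap = if (!is.null(A$archetypes) && !is.null(B$archetypes))
      cluster_overlap(both_de, A$archetypes, B$archetypes),
    gastrula_core = gastrula_core(o2o, A$de, B$de),
    g_cluster_core = if (!is.null(A$archetypes) && !is.null(B$archetypes))
      g_cluster_core(both_de, A$archetypes, B$archetypes))

  paralogs <- list()
  for (sp in spp) {
    ps <- per_species[[sp]]
    pp <- hs$paralog_pairs[[sp]]
    if (is.null(pp) || nrow(pp) == 0) next
    pk <- classify_pk(pp, ps$archetypes)
    paralogs[[sp]] <- list(
      p = lapply(ps$de, function(res) classify_p(pp, res)),
      pk = pk,
      similarity = if (!is.null(ps$archetypes))
        pattern_similarity(pp, ps$de, ps$archetypes),
      # high-correlation fraction is reported over the co-clustered (Pk1)
      # pairs, the subset for which the comparison is meaningful
      pcc = pair_pcc(pp[pk$class == "Pk1", , drop = FALSE], ps$vst))
  }

  networks <- NULL
  baits <- vapply(spp, function(sp) {
    ps <- per_species[[sp]]
    cand <- if (!is.null(ps$archetypes)) names(ps$archetypes)
            else ps$deg_sets$union
    if (length(cand) == 0) return(NA_character_)
    cand[which.max(rowMeans(ps$vst[cand, , drop = FALSE]))]
  }, character(1))
  if (!anyNA(baits)) {
    nets <- lapply(seq_along(spp), function(i)
      annotate_families(
        build_network(baits[i], per_species[[spp[i]]]$vst), hs))
    names(nets) <- spp
    networks <- list(baits = baits, networks = nets,
                     comparison = compare_networks(nets[[1]], nets[[2]]))
  }

  enrichment <- lapply(stats::setNames(spp, spp), function(sp) {
    arch <- per_species[[sp]]$archetypes
    if (is.null(arch)) return(NULL)
    pop_sp <- unique(dataset$go$gene[
      sub("\\|.*$", "", dataset$go$gene) == sp])
    q <- intersect(names(arch)[arch == "C3"], pop_sp)
    if (length(q) == 0) return(NULL)
    enrich(q, dataset$go, population = pop_sp)
  })

  res <- structure(list(dataset = dataset, per_species = per_species,
                        ortho = ortho, paralogs = paralogs,
                        networks = networks, enrichment = enrichment),
                   class = "pipeline_result")
  res$report <- report(res)
  if (!is.null(outdir)) res$manifest <- write_pipeline(res, outdir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  spp <- x$dataset$config$species
  cat("Two-species developmental expression comparison\n")
  for (sp in spp)
    cat(sprintf("  %s: %d genes, DEG union %d\n", sp,
                nrow(x$per_species[[sp]]$vst),
                length(x$per_species[[sp]]$deg_sets$union)))
  cat(sprintf("  one-to-one pairs: %d; DE in both: %d\n",
              sum(x$ortho$partition$counts),
              x$ortho$partition$counts["both"]))
  if (!is.null(x$ortho$cluster_overlap))
    cat(sprintf("  same-archetype orthologs: %d (%.1f%%)\n",
                x$ortho$cluster_overlap$trace,
                x$ortho$cluster_overlap$percent_same))
  invisible(x)
}

#' Summary report tables
#'
#' Assembles the pipeline's headline tables: DEG counts per comparison and
#' stage, coding/noncoding DEG composition, cluster sizes with shares,
#' ortholog partition, synchrony percents, cluster-overlap matrix with trace
#' percent, paralog P/Pk distributions with similarity and high-correlation
#' fractions, and the network comparison summary. Cells are taken from the
#' owning modules' outputs, not recomputed.
#'
#' @param res A `pipeline_result`.
#' @return Named list of data frames / vectors.
#' @export
report <- function(res) {
  spp <- res$dataset$config$species
  coding_all <- stats::setNames(res$dataset$truth$genes$coding,
                                res$dataset$truth$genes$gene)
  deg_counts <- do.call(rbind, lapply(spp, function(sp) {
    s <- res$per_species[[sp]]$deg_sets
    data.frame(species = sp,
               comparison = names(s$totals)[1:2],
               n_deg = unname(s$totals[1:2]),
               union = unname(s$totals["total"]),
               stringsAsFactors = FALSE)
  }))
  coding_deg <- do.call(rbind, lapply(spp, function(sp) {
    u <- res$per_species[[sp]]$deg_sets$union
    if (length(u) == 0) return(NULL)
    cs <- coding_noncoding_summary(coding_all[u])
    cs$species <- sp
    cs
  }))
  cluster_sizes <- do.call(rbind, lapply(spp, function(sp) {
    arch <- res$per_species[[sp]]$archetypes
    if (is.null(arch)) return(NULL)
    cs <- cluster_size_summary(arch)
    cs$species <- sp
    cs
  }))
  para <- do.call(rbind, lapply(names(res$paralogs), function(sp) {
    pl <- res$paralogs[[sp]]
    rows <- lapply(names(pl$p), function(cmp)
      data.frame(species = sp, comparison = cmp,
                 class = names(pl$p[[cmp]]$counts),
                 n = unname(pl$p[[cmp]]$counts),
                 stringsAsFactors = FALSE))
    rows[[length(rows) + 1]] <- data.frame(
      species = sp, comparison = "clusters",
      class = names(pl$pk$counts), n = unname(pl$pk$counts),
      stringsAsFactors = FALSE)
    do.call(rbind, rows)
  }))
  list(deg_counts = deg_counts,
       coding_deg = coding_deg,
       cluster_sizes = cluster_sizes,
       ortholog_partition = res$ortho$partition$counts,
       relationship_percent = res$ortho$relationship$group_percent,
       synchrony_percent = vapply(res$ortho$synchrony, `[[`, 0,
                                  "percent_same"),
       cluster_overlap_percent = if (!is.null(res$ortho$cluster_overlap))
         res$ortho$cluster_overlap$percent_same else NA_real_,
       paralog_classes = para,
       paralog_pcc_fraction = vapply(res$paralogs, function(pl)
         pl$pcc$fraction_above, numeric(1)),
       network_summary = if (!is.null(res$networks))
         res$networks$comparison$summary)
}

write_pipeline <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  spp <- res$dataset$config$species
  paths <- character(0)
  wtsv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  for (sp in spp) {
    ps <- res$per_species[[sp]]
    for (cmp in names(ps$de))
      wtsv(as.data.frame(ps$de[[cmp]]),
           sprintf("de_%s_%s.tsv", sp, cmp))
    if (!is.null(ps$clustering)) {
      arch <- ps$archetypes
      wtsv(data.frame(gene = names(ps$clustering$cluster),
                      cluster = unname(ps$clustering$cluster),
                      archetype = unname(arch[names(ps$clustering$cluster)])),
           sprintf("clusters_%s.tsv", sp))
      wtsv(data.frame(cluster = seq_len(ps$clustering$k),
                      ps$clustering$centers, check.names = FALSE),
           sprintf("centroids_%s.tsv", sp))
    }
    wtsv(ps$quartiles, sprintf("quartiles_%s.tsv", sp))
    wtsv(data.frame(gene = rownames(ps$tpm), round(ps$tpm, 4),
                    check.names = FALSE), sprintf("tpm_%s.tsv", sp))
  }
  wtsv(data.frame(cell = names(res$ortho$partition$counts),
                  n = unname(res$ortho$partition$counts)),
       "ortholog_partition.tsv")
  ov <- res$ortho$stage_overlap
  wtsv(data.frame(stage_A = rownames(ov), ov, check.names = FALSE),
       "stage_overlap.tsv")
  if (!is.null(res$ortho$cluster_overlap)) {
    co <- res$ortho$cluster_overlap
    wtsv(data.frame(archetype_A = rownames(co$matrix), co$matrix,
                    check.names = FALSE), "cluster_overlap.tsv")
  }
  wtsv(res$ortho$gastrula_core, "gastrula_core_pairs.tsv")
  manifest <- list(
    seed = res$dataset$config$seed,
    n_orthogroups = res$dataset$config$n_orthogroups,
    files = as.list(tools::md5sum(paths)))
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  manifest
}
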