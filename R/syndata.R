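# Synthetic two-species developmental dataset generator.
#
# Counts are negative binomial with a single shared dispersion so that the
# differential-expression module's model is exactly the generating model and
# parameter-recovery tests are well-posed. Every gene carries a stage
# archetype (C1..C6, or "flat" for non-regulated genes) and the generator
# records full ground truth for recovery tests.

#' Developmental stages, in temporal order
#' @export
dev_stages <- function() c("PC", "G", "S")

#' Stage archetype templates
#'
#' The six coexpression archetypes are binary up-regulation patterns over the
#' three stages: C1 up in PC; C2 up in PC and G; C3 up in G only; C4 up in G
#' and S; C5 up in S only; C6 up in PC and S.
#'
#' @return A 6 x 3 0/1 matrix, rows `C1..C6`, columns `PC`, `G`, `S`.
#' @export
archetype_templates <- function() {
  m <- matrix(c(
    1, 0, 0,
    1, 1, 0,
    0, 1, 0,
    0, 1, 1,
    0, 0, 1,
    1, 0, 1), nrow = 6, byrow = TRUE,
    dimnames = list(paste0("C", 1:6), dev_stages()))
  m
}

.relationship_classes <- c("one2one", "one2many_A", "one2many_B", "many2many")

#' Configuration for the synthetic dataset generator
#'
#' The defaults reproduce the statistical structure of a two-coral-species
#' embryonic RNA-seq comparison at desk scale: an 86/10/2/2 percent split of
#' homology relationship classes, three replicates of three stages, a planted
#' 4-fold (log2 = 2) up-state effect, and ortholog/paralog archetype
#' conservation rates of 0.13 and (0.47, 0.83) respectively.
#'
#' @param seed Integer root seed; all randomness in the generator flows from it.
#' @param n_orthogroups Number of orthogroups shared by the two species.
#' @param relationship_mix Named proportions over
#'   `one2one`, `one2many_A`, `one2many_B`, `many2many` (must sum to 1).
#'   `one2many_A` means several species-A members per single B member.
#' @param n_paralog_pairs Integer pair, in-paralog pairs to plant per species.
#' @param archetype_probs Named proportions over `C1..C6` and `flat`
#'   (must sum to 1); `flat` genes are not differentially expressed.
#' @param conserved_fraction_orthologs Probability that a one-to-one ortholog
#'   pair with a non-flat archetype shares the archetype across species.
#' @param conserved_fraction_paralogs Length-2 fraction per species for
#'   in-paralog pairs.
#' @param base_mean_log_mu,base_mean_log_sigma Log-normal parameters of the
#'   baseline expression mean.
#' @param effect_log2fc Planted log2 fold change of the up state (>= 0).
#' @param nb_dispersion Shared negative-binomial dispersion (> 0).
#' @param n_replicates Replicates per stage.
#' @param noncoding_fraction Fraction of genes flagged noncoding.
#' @param n_go_terms,go_terms_per_gene Size of the flat annotation vocabulary
#'   and terms drawn per gene.
#' @param enriched_term_archetype_bias Sampling-weight multiplier (>= 1) of the
#'   designated term (the first term id) for genes of archetype C3; used to
#'   plant a detectable over-representation signal.
#' @param species Character pair of species/taxon prefixes used in gene ids.
#' @param as_fraction Per-species fraction of genes with alternative isoforms.
#' @param as_geom_p Geometric parameter for extra isoforms beyond the second.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed,
                         n_orthogroups = 3000,
                         relationship_mix = c(one2one = 0.86, one2many_A = 0.10,
                                              one2many_B = 0.02, many2many = 0.02),
                         n_paralog_pairs = c(500, 200),
                         archetype_probs = c(C1 = 1/12, C2 = 1/12, C3 = 1/12,
                                             C4 = 1/12, C5 = 1/12, C6 = 1/12,
                                             flat = 0.5),
                         conserved_fraction_orthologs = 0.13,
                         conserved_fraction_paralogs = c(0.47, 0.83),
                         base_mean_log_mu = log(100),
                         base_mean_log_sigma = 1.2,
                         effect_log2fc = 2.0,
                         nb_dispersion = 0.05,
                         n_replicates = 3,
                         noncoding_fraction = 0.10,
                         n_go_terms = 50,
                         go_terms_per_gene = 3,
                         enriched_term_archetype_bias = 4,
                         species = c("adi", "ate"),
                         as_fraction = c(0.12, 0.02),
                         as_geom_p = 0.7) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  seed <- as.integer(seed)
  cfg <- list(seed = seed, n_orthogroups = as.integer(n_orthogroups),
              relationship_mix = relationship_mix,
              n_paralog_pairs = as.integer(n_paralog_pairs),
              archetype_probs = archetype_probs,
              conserved_fraction_orthologs = conserved_fraction_orthologs,
              conserved_fraction_paralogs = conserved_fraction_paralogs,
              base_mean_log_mu = base_mean_log_mu,
              base_mean_log_sigma = base_mean_log_sigma,
              effect_log2fc = effect_log2fc,
              nb_dispersion = nb_dispersion,
              n_replicates = as.integer(n_replicates),
              noncoding_fraction = noncoding_fraction,
              n_go_terms = as.integer(n_go_terms),
              go_terms_per_gene = as.integer(go_terms_per_gene),
              enriched_term_archetype_bias = enriched_term_archetype_bias,
              species = species,
              as_fraction = as_fraction,
              as_geom_p = as_geom_p)
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  mix <- cfg$relationship_mix
  if (!setequal(names(mix), .relationship_classes))
    stop("relationship_mix must be named over: ",
         paste(.relationship_classes, collapse = ", "), call. = FALSE)
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
    stop("relationship_mix proportions must be non-negative and sum to 1",
         call. = FALSE)
  ap <- cfg$archetype_probs
  if (!setequal(names(ap), c(paste0("C", 1:6), "flat")))
    stop("archetype_probs must be named over C1..C6 and 'flat'", call. = FALSE)
  if (any(ap < 0) || abs(sum(ap) - 1) > 1e-9)
    stop("archetype_probs must be non-negative and sum to 1", call. = FALSE)
  fr <- c(cfg$conserved_fraction_orthologs, cfg$conserved_fraction_paralogs,
          cfg$noncoding_fraction, cfg$as_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (cfg$n_orthogroups < 0 || any(cfg$n_paralog_pairs < 0))
    stop("counts must be >= 0", call. = FALSE)
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  if (cfg$effect_log2fc < 0) stop("effect_log2fc must be >= 0", call. = FALSE)
  if (cfg$enriched_term_archetype_bias < 1)
    stop("enriched_term_archetype_bias must be >= 1", call. = FALSE)
  if (length(cfg$species) != 2 || anyDuplicated(cfg$species))
    stop("species must be two distinct prefixes", call. = FALSE)
  invisible(cfg)
}

# Deterministic sub-seed per generator stage, kept within 32-bit range.
sub_seed <- function(seed, stream) {
  (as.numeric(seed) * 131 + stream) %% 2147483647
}

#' Sample a two-species homology structure
#'
#' Draws orthogroup relationship classes from `relationship_mix`, populates the
#' groups with `taxon|gene` member ids, enumerates all cross-species ortholog
#' pairs, and plants dedicated within-species in-paralog pairs.
#'
#' @param config A [synth_config()].
#' @return A `homology_set`: `groups` (named list of member id vectors),
#'   `class` (relationship class per group), `pairs` (all cross-species pairs
#'   with group and class), `paralog_pairs` (per-species data frames), and
#'   `species`.
#' @export
sample_homology <- function(config) {
  validate_synth_config(config)
  set.seed(sub_seed(config$seed, 1))
  spA <- config$species[1]; spB <- config$species[2]
  n <- config$n_orthogroups
  mix <- config$relationship_mix[.relationship_classes]
  cls <- if (n > 0)
    sample(.relationship_classes, n, replace = TRUE, prob = mix)
  else character(0)
  # many-side group sizes: at least 2, light Poisson tail
  sizeA <- ifelse(cls %in% c("one2many_A", "many2many"),
                  2L + stats::rpois(n, 0.5), 1L)
  sizeB <- ifelse(cls %in% c("one2many_B", "many2many"),
                  2L + stats::rpois(n, 0.5), 1L)
  idsA <- if (n > 0) split(
    sprintf("%s|g%05d", spA, seq_len(sum(sizeA))),
    rep(seq_len(n), sizeA)) else list()
  idsB <- if (n > 0) split(
    sprintf("%s|g%05d", spB, seq_len(sum(sizeB))),
    rep(seq_len(n), sizeB)) else list()
  gid <- sprintf("OG%05d", seq_len(n))
  groups <- stats::setNames(lapply(seq_len(n), function(i)
    c(idsA[[i]], idsB[[i]])), gid)
  names(cls) <- gid
  pairs <- if (n > 0) do.call(rbind, lapply(seq_len(n), function(i) {
    eg <- expand.grid(gene_A = idsA[[i]], gene_B = idsB[[i]],
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    eg$group <- gid[i]; eg$class <- cls[i]
    eg
  })) else data.frame(gene_A = character(0), gene_B = character(0),
                      group = character(0), class = character(0))
  rownames(pairs) <- NULL
  # dedicated in-paralog pairs, outside the orthogroups
  par_pairs <- list()
  for (k in 1:2) {
    sp <- config$species[k]
    np <- config$n_paralog_pairs[k]
    g1 <- sprintf("%s|p%05d", sp, seq_len(np) * 2L - 1L)
    g2 <- sprintf("%s|p%05d", sp, seq_len(np) * 2L)
    par_pairs[[sp]] <- data.frame(gene1 = g1, gene2 = g2,
                                  stringsAsFactors = FALSE)
  }
  structure(list(groups = groups, class = cls, pairs = pairs,
                 paralog_pairs = par_pairs, species = config$species),
            class = "homology_set")
}

# Draw an archetype for each "lead" gene and a partner archetype that is
# identical with probability f. Flat status is shared within a pair and a
# non-conserved partner of a non-flat gene draws a *different non-flat*
# archetype: this is what makes the same-archetype fraction among both-non-flat
# pairs equal f in expectation.
plant_pair_archetypes <- function(n, probs, f) {
  arch <- paste0("C", 1:6)
  lead <- sample(names(probs), n, replace = TRUE, prob = probs)
  partner <- lead
  conserved <- rep(NA, n)
  nonflat <- lead != "flat"
  conserved[nonflat] <- stats::runif(sum(nonflat)) < f
  div <- which(nonflat & !conserved)
  for (i in div) {
    others <- setdiff(arch, lead[i])
    partner[i] <- sample(others, 1, prob = probs[others])
  }
  data.frame(lead = lead, partner = partner, conserved = conserved,
             stringsAsFactors = FALSE)
}

#' Generate the complete labelled synthetic dataset
#'
#' Orchestrates homology sampling, archetype planting, count simulation per
#' species, gene metadata (lengths, coding flags, isoform map) and GO
#' annotation, all deterministically from `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A `synth_dataset` bundle: `config`, `homology`, `truth` (per-gene
#'   table and per-pair conserved flags), `counts` (per species, each a list
#'   with integer matrix `counts` and `design` data frame), `tx2gene`, and
#'   `go` annotation (gene/term pairs).
#' @export
simulate_dataset <- function(config) {
  validate_synth_config(config)
  hs <- sample_homology(config)
  truth <- plant_truth(hs, config)
  counts <- lapply(stats::setNames(config$species, config$species),
                   function(sp) simulate_counts(truth, config, species = sp))
  tx2gene <- make_isoform_map(truth, config)
  go <- make_go_annotation(truth, config)
  structure(list(config = config, homology = hs, truth = truth,
                 counts = counts, tx2gene = tx2gene, go = go),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("Synthetic two-species developmental dataset\n")
  cat("  species:     ", paste(x$config$species, collapse = ", "), "\n")
  cat("  orthogroups: ", length(x$homology$groups), "\n")
  for (sp in x$config$species)
    cat(sprintf("  %s: %d genes x %d samples\n", sp,
                nrow(x$counts[[sp]]$counts), ncol(x$counts[[sp]]$counts)))
  invisible(x)
}

plant_truth <- function(hs, config) {
  set.seed(sub_seed(config$seed, 2))
  spA <- config$species[1]; spB <- config$species[2]
  probs <- config$archetype_probs
  genes <- data.frame(gene = character(0), species = character(0),
                      group = character(0), archetype = character(0),
                      stringsAsFactors = FALSE)
  o2o <- hs$pairs[hs$pairs$class == "one2one", , drop = FALSE]
  ortho_truth <- data.frame(gene_A = character(0), gene_B = character(0),
                            conserved = logical(0))
  if (nrow(o2o) > 0) {
    pl <- plant_pair_archetypes(nrow(o2o), probs,
                                config$conserved_fraction_orthologs)
    genes <- rbind(genes,
      data.frame(gene = o2o$gene_A, species = spA, group = o2o$group,
                 archetype = pl$lead, stringsAsFactors = FALSE),
      data.frame(gene = o2o$gene_B, species = spB, group = o2o$group,
                 archetype = pl$partner, stringsAsFactors = FALSE))
    ortho_truth <- data.frame(gene_A = o2o$gene_A, gene_B = o2o$gene_B,
                              conserved = pl$conserved)
  }
  # members of non-one2one groups draw archetypes independently
  other_groups <- names(hs$class)[hs$class != "one2one"]
  if (length(other_groups) > 0) {
    mem <- unlist(hs$groups[other_groups], use.names = FALSE)
    grp <- rep(other_groups, lengths(hs$groups[other_groups]))
    genes <- rbind(genes, data.frame(
      gene = mem, species = sub("\\|.*$", "", mem), group = grp,
      archetype = sample(names(probs), length(mem), replace = TRUE,
                         prob = probs),
      stringsAsFactors = FALSE))
  }
  # dedicated paralog genes
  para_truth <- list()
  for (k in 1:2) {
    sp <- config$species[k]
    pp <- hs$paralog_pairs[[sp]]
    if (nrow(pp) > 0) {
      pl <- plant_pair_archetypes(nrow(pp), probs,
                                  config$conserved_fraction_paralogs[k])
      genes <- rbind(genes,
        data.frame(gene = pp$gene1, species = sp, group = NA_character_,
                   archetype = pl$lead, stringsAsFactors = FALSE),
        data.frame(gene = pp$gene2, species = sp, group = NA_character_,
                   archetype = pl$partner, stringsAsFactors = FALSE))
      para_truth[[sp]] <- data.frame(gene1 = pp$gene1, gene2 = pp$gene2,
                                     conserved = pl$conserved)
    } else {
      para_truth[[sp]] <- data.frame(gene1 = character(0),
                                     gene2 = character(0),
                                     conserved = logical(0))
    }
  }
  stopifnot(!anyDuplicated(genes$gene))
  genes$coding <- stats::runif(nrow(genes)) >= config$noncoding_fraction
  # transcript length only matters for TPM; log-uniform 500-5000 nt
  genes$length <- round(exp(stats::runif(nrow(genes), log(500), log(5000))))
  rownames(genes) <- NULL
  list(genes = genes, ortholog_pairs = ortho_truth,
       paralog_pairs = para_truth)
}

#' Simulate a negative-binomial count matrix for one species
#'
#' Count for gene g in sample s is NB with mean
#' `mu_g * 2^(effect_log2fc * up_g(stage_s)) * sf_s` and dispersion
#' `nb_dispersion`, where `up_g` is the gene's archetype up-indicator and
#' `sf_s` a per-sample size factor drawn log-uniform in [0.7, 1.4].
#'
#' @param truth Truth tables from the generator (`genes` component used).
#' @param config A [synth_config()].
#' @param species Which species to simulate (defaults to the first).
#' @return List with integer matrix `counts` (genes x samples), `design`
#'   data frame (sample, species, stage, replicate) and `size_factors`.
#' @export
simulate_counts <- function(truth, config, species = config$species[1]) {
  validate_synth_config(config)
  k <- match(species, config$species)
  if (is.na(k)) stop("unknown species: ", species, call. = FALSE)
  set.seed(sub_seed(config$seed, 10 + k))
  g <- truth$genes[truth$genes$species == species, , drop = FALSE]
  if (any(is.na(g$archetype)))
    stop("every gene needs an archetype", call. = FALSE)
  stages <- dev_stages()
  nrep <- config$n_replicates
  design <- data.frame(
    sample = paste(species, rep(stages, each = nrep), rep(seq_len(nrep), 3),
                   sep = "_"),
    species = species,
    stage = rep(stages, each = nrep),
    replicate = rep(seq_len(nrep), 3),
    stringsAsFactors = FALSE)
  ns <- nrow(design)
  mu <- stats::rlnorm(nrow(g), config$base_mean_log_mu,
                      config$base_mean_log_sigma)
  sf <- exp(stats::runif(ns, log(0.7), log(1.4)))
  tmpl <- archetype_templates()
  up <- matrix(0, nrow(g), 3, dimnames = list(g$gene, stages))
  nonflat <- g$archetype != "flat"
  up[nonflat, ] <- tmpl[g$archetype[nonflat], , drop = FALSE]
  mean_mat <- (mu * 2^(config$effect_log2fc * up[, design$stage, drop = FALSE])) *
    rep(sf, each = nrow(g))
  counts <- matrix(stats::rnbinom(length(mean_mat), mu = mean_mat,
                                  size = 1 / config$nb_dispersion),
                   nrow = nrow(g), ncol = ns,
                   dimnames = list(g$gene, design$sample))
  storage.mode(counts) <- "integer"
  list(counts = counts, design = design, size_factors = sf)
}

make_isoform_map <- function(truth, config) {
  set.seed(sub_seed(config$seed, 20))
  out <- list()
  for (k in 1:2) {
    sp <- config$species[k]
    g <- truth$genes$gene[truth$genes$species == sp]
    if (length(g) == 0) {
      out[[sp]] <- data.frame(species = character(0), gene = character(0),
                              transcript = character(0),
                              stringsAsFactors = FALSE)
      next
    }
    as_flag <- stats::runif(length(g)) < config$as_fraction[k]
    n_iso <- ifelse(as_flag, 2L + stats::rgeom(length(g), config$as_geom_p), 1L)
    out[[sp]] <- data.frame(
      species = rep(sp, sum(n_iso)),
      gene = rep(g, n_iso),
      transcript = paste0(rep(g, n_iso),
                          ".", unlist(lapply(n_iso, seq_len))),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

make_go_annotation <- function(truth, config) {
  set.seed(sub_seed(config$seed, 30))
  terms <- sprintf("GO:%07d", seq_len(config$n_go_terms))
  g <- truth$genes
  npick <- min(config$go_terms_per_gene, config$n_go_terms)
  picks <- lapply(seq_len(nrow(g)), function(i) {
    w <- rep(1, config$n_go_terms)
    if (g$archetype[i] == "C3") w[1] <- config$enriched_term_archetype_bias
    sample(terms, npick, prob = w)
  })
  data.frame(gene = rep(g$gene, each = npick),
             term = unlist(picks), stringsAsFactors = FALSE)
}

#' Write a synthetic dataset bundle to disk
#'
#' Emits per-species counts TSV, gene metadata TSV, an orthogroup file in the
#' `GROUPID: taxon|gene taxon|gene ...` dialect, paralog-pair TSVs, GO
#' annotation TSV, transcript map TSV, ground-truth tables and the resolved
#' configuration (YAML, seed included).
#'
#' @param bundle A `synth_dataset` from [simulate_dataset()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "synth_dataset"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create ", outdir, call. = FALSE)
  paths <- c()
  wtsv <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
  }
  for (sp in bundle$config$species) {
    cm <- bundle$counts[[sp]]$counts
    wtsv(data.frame(gene = rownames(cm), cm, check.names = FALSE),
         paste0("counts_", sp, ".tsv"))
    wtsv(bundle$homology$paralog_pairs[[sp]],
         paste0("paralog_pairs_", sp, ".tsv"))
  }
  wtsv(bundle$truth$genes, "gene_metadata.tsv")
  wtsv(bundle$go, "go_annotation.tsv")
  wtsv(bundle$tx2gene, "tx2gene.tsv")
  wtsv(bundle$truth$ortholog_pairs, "truth_ortholog_pairs.tsv")
  for (sp in bundle$config$species)
    wtsv(bundle$truth$paralog_pairs[[sp]],
         paste0("truth_paralog_pairs_", sp, ".tsv"))
  gp <- file.path(outdir, "orthogroups.txt")
  write_groups(bundle$homology, gp)
  paths[["orthogroups.txt"]] <- gp
  cp <- file.path(outdir, "config.yaml")
  # named vectors become YAML maps so names survive the round trip
  cfg_list <- lapply(unclass(bundle$config), function(v)
    if (!is.null(names(v))) as.list(v) else v)
  yaml::write_yaml(cfg_list, cp, precision = 12)
  paths[["config.yaml"]] <- cp
  invisible(unlist(paths))
}

#' Write an orthogroup file in the groups text dialect
#' @param hs A `homology_set`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_groups <- function(hs, path) {
  lines <- vapply(seq_along(hs$groups), function(i)
    paste0(names(hs$groups)[i], ": ",
           paste(hs$groups[[i]], collapse = " ")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a counts TSV written by [write_dataset()]
#'
#' Sample columns must follow the `<species>_<stage>_<replicate>` convention,
#' from which the design is reconstructed.
#'
#' @param path Counts TSV with a leading `gene` column.
#' @return List with integer matrix `counts` and `design` data frame.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  storage.mode(counts) <- "integer"
  parts <- strsplit(colnames(counts), "_", fixed = TRUE)
  bad <- lengths(parts) != 3
  if (any(bad))
    stop("malformed sample column name(s): ",
         paste(colnames(counts)[bad], collapse = ", "), call. = FALSE)
  design <- data.frame(
    sample = colnames(counts),
    species = vapply(parts, `[`, "", 1),
    stage = vapply(parts, `[`, "", 2),
    replicate = as.integer(vapply(parts, `[`, "", 3)),
    stringsAsFactors = FALSE)
  list(counts = counts, design = design)
}

#' Read a synthetic-generator configuration written by [write_dataset()]
#' @param path YAML config path.
#' @return A `synth_config`.
#' @export
read_synth_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(synth_config, lapply(x, function(v)
    if (is.list(v)) unlist(v) else v))
}
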