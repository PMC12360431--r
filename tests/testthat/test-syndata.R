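test_that("degenerate relationship mixes produce the expected group shapes", {
  cfg <- synth_config(seed = 3, n_orthogroups = 10,
                      relationship_mix = c(one2one = 1, one2many_A = 0,
                                           one2many_B = 0, many2many = 0),
                      n_paralog_pairs = c(0, 0))
  hs <- sample_homology(cfg)
  expect_length(hs$groups, 10)
  expect_true(all(lengths(hs$groups) == 2))
  expect_true(all(hs$class == "one2one"))
  expect_equal(nrow(hs$pairs), 10)

  empty <- sample_homology(synth_config(seed = 3, n_orthogroups = 0,
                                        n_paralog_pairs = c(0, 0)))
  expect_length(empty$groups, 0)
  expect_equal(nrow(empty$pairs), 0)
})

test_that("sampled relationship classes realize the mix within binomial error", {
  mix <- c(one2one = 0.86, one2many_A = 0.10, one2many_B = 0.02,
           many2many = 0.02)
  cfg <- synth_config(seed = 42, n_orthogroups = 5000,
                      relationship_mix = mix, n_paralog_pairs = c(0, 0))
  hs <- sample_homology(cfg)
  obs <- table(factor(hs$class, levels = names(mix))) / 5000
  expect_true(all(abs(as.numeric(obs) - mix) < 0.02))
  # gene ids are species-prefixed and globally unique
  members <- unlist(hs$groups)
  expect_false(anyDuplicated(members) > 0)
  expect_true(all(grepl("^(adi|ate)\\|", members)))
})

test_that("configuration validation rejects bad proportions and counts", {
  expect_error(synth_config(seed = 1,
                            relationship_mix = c(one2one = 0.9,
                                                 one2many_A = 0.2,
                                                 one2many_B = 0,
                                                 many2many = 0)),
               "sum to 1")
  expect_error(synth_config(seed = 1, conserved_fraction_orthologs = 1.2),
               "fractions")
  expect_error(synth_config(seed = 1, nb_dispersion = 0), "nb_dispersion")
  expect_error(synth_config(), "seed")
})

test_that("counts are reproducible from the seed and differ across seeds", {
  cfg <- small_config(seed = 5)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$counts$adi$counts, d2$counts$adi$counts)
  expect_identical(d1$homology$groups, d2$homology$groups)
  d3 <- simulate_dataset(small_config(seed = 6))
  expect_false(identical(d1$counts$adi$counts, d3$counts$adi$counts))
})

test_that("count variance approaches the mean in the small-dispersion limit", {
  # size-factor-corrected NB counts have var/mean ~ 1 when dispersion -> 0
  # and are clearly overdispersed at dispersion 0.5
  ratio_med <- function(disp) {
    cfg <- synth_config(seed = 9, n_orthogroups = 500,
                        n_paralog_pairs = c(0, 0),
                        effect_log2fc = 0, nb_dispersion = disp)
    truth <- list(genes = simulate_dataset(cfg)$truth$genes)
    sim <- simulate_counts(truth, cfg, "adi")
    x <- sweep(sim$counts, 2, sim$size_factors, "/")
    m <- rowMeans(x)
    v <- apply(x, 1, var)
    median((v / (m * mean(1 / sim$size_factors)))[m > 5])
  }
  expect_lt(abs(ratio_med(1e-8) - 1), 0.2)
  expect_gt(ratio_med(0.5), 3)
})

test_that("planted ortholog conservation matches the configured fraction", {
  f <- 0.5
  cfg <- synth_config(seed = 21, n_orthogroups = 4000,
                      conserved_fraction_orthologs = f,
                      n_paralog_pairs = c(0, 0))
  ds <- simulate_dataset(cfg)
  g <- ds$truth$genes
  arch <- setNames(g$archetype, g$gene)
  op <- ds$truth$ortholog_pairs
  a <- arch[op$gene_A]; b <- arch[op$gene_B]
  both_nonflat <- a != "flat" & b != "flat"
  phat <- mean((a == b)[both_nonflat])
  n <- sum(both_nonflat)
  ci <- 2.58 * sqrt(f * (1 - f) / n)
  expect_lt(abs(phat - f), ci)
  # recorded conserved flags agree with identical labels
  expect_true(all((a == b)[!is.na(op$conserved) & op$conserved]))
})

test_that("written datasets round-trip through the readers", {
  cfg <- small_config(seed = 13)
  ds <- simulate_dataset(cfg)
  out <- withr::local_tempdir()
  write_dataset(ds, out)
  for (sp in cfg$species) {
    back <- read_counts_tsv(file.path(out, paste0("counts_", sp, ".tsv")))
    expect_identical(back$counts, ds$counts[[sp]]$counts)
    expect_identical(back$design, ds$counts[[sp]]$design)
  }
  hs2 <- parse_groups(file.path(out, "orthogroups.txt"))
  expect_identical(hs2$groups, ds$homology$groups)
  expect_identical(hs2$class, ds$homology$class)
  expect_identical(hs2$pairs[order(hs2$pairs$gene_A, hs2$pairs$gene_B), ],
                   ds$homology$pairs[order(ds$homology$pairs$gene_A,
                                           ds$homology$pairs$gene_B), ],
                   ignore_attr = TRUE)
  cfg2 <- read_synth_config(file.path(out, "config.yaml"))
  expect_equal(cfg2$relationship_mix, cfg$relationship_mix)
  expect_identical(cfg2$seed, cfg$seed)
})

test_that("the groups file uses the one-line-per-group dialect", {
  cfg <- synth_config(seed = 2, n_orthogroups = 3,
                      relationship_mix = c(one2one = 1, one2many_A = 0,
                                           one2many_B = 0, many2many = 0),
                      n_paralog_pairs = c(0, 0))
  hs <- sample_homology(cfg)
  path <- withr::local_tempfile()
  write_groups(hs, path)
  lines <- readLines(path)
  expect_length(lines, 3)
  expect_true(all(grepl("^OG\\d+: (adi|ate)\\|\\S+( (adi|ate)\\|\\S+)+$",
                        lines)))
})

test_that("empty datasets write valid headers-only files", {
  cfg <- synth_config(seed = 2, n_orthogroups = 0,
                      n_paralog_pairs = c(0, 0))
  ds <- simulate_dataset(cfg)
  out <- withr::local_tempdir()
  expect_no_error(write_dataset(ds, out))
  meta <- read.delim(file.path(out, "gene_metadata.tsv"))
  expect_equal(nrow(meta), 0)
  expect_true(all(c("gene", "species", "archetype") %in% names(meta)))
})
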