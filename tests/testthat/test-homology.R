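test_that("groups parsing classifies relationships and enumerates pairs", {
  hs <- parse_groups(lines = c("OG1: A|g1 B|g2",
                               "OG2: A|g1b B|g3 B|g4"),
                     species = c("A", "B"))
  expect_equal(unname(hs$class), c("one2one", "one2many_B"))
  expect_equal(nrow(hs$pairs), 3)
  expect_equal(nrow(one2one_pairs(hs)), 1)
  expect_error(parse_groups(lines = "OG1: A|g1 nogene"), "taxon")
  expect_error(parse_groups(lines = "not a group line"), "malformed")
})

test_that("class counts on a large random file equal a brute-force recount", {
  set.seed(6)
  lines <- vapply(1:1000, function(i) {
    nA <- sample(0:3, 1, prob = c(0.1, 0.6, 0.2, 0.1))
    nB <- sample(0:3, 1, prob = c(0.1, 0.6, 0.2, 0.1))
    if (nA + nB == 0) nA <- 1
    mem <- c(sprintf("A|a%d_%d", i, seq_len(nA)),
             sprintf("B|b%d_%d", i, seq_len(nB)))
    paste0("OG", i, ": ", paste(mem, collapse = " "))
  }, character(1))
  hs <- parse_groups(lines = lines, species = c("A", "B"))
  # independent tally from the membership lists
  for (i in seq_along(hs$groups)) {
    tax <- sub("\\|.*", "", hs$groups[[i]])
    nA <- sum(tax == "A"); nB <- sum(tax == "B")
    expected <- if (nA == 1 && nB == 1) "one2one"
      else if (nA > 1 && nB == 1) "one2many_A"
      else if (nA == 1 && nB > 1) "one2many_B"
      else if (nA > 1 && nB > 1) "many2many" else "other"
    expect_identical(unname(hs$class[i]), expected)
  }
  expect_equal(nrow(hs$pairs),
               sum(vapply(hs$groups, function(m) {
                 tax <- sub("\\|.*", "", m)
                 sum(tax == "A") * sum(tax == "B")
               }, numeric(1))))
})

test_that("relationship percentages are reported to one decimal", {
  # 5,965 one-to-one of 6,896 groups is 86.5%
  lines <- c(sprintf("OG%d: A|x%d B|y%d", 1:5965, 1:5965, 1:5965),
             sprintf("OG%d: A|m%d A|m%db B|y%d", 5966:6896, 5966:6896,
                     5966:6896, 5966:6896))
  hs <- parse_groups(lines = lines, species = c("A", "B"))
  rs <- relationship_summary(hs)
  expect_equal(rs$n_groups, 6896)
  expect_equal(unname(rs$group_percent["one2one"]), 86.5)
  # degenerate: all one2one is 100.0; percentages sum to ~100
  rs2 <- relationship_summary(parse_groups(lines = lines[1:100],
                                           species = c("A", "B")))
  expect_equal(unname(rs2$group_percent["one2one"]), 100)
  expect_lt(abs(sum(rs$group_percent) - 100), 0.11)
})

test_that("the shared-DE partition is exhaustive and matches brute force", {
  set.seed(9)
  pairs <- data.frame(gene_A = paste0("A|a", 1:200),
                      gene_B = paste0("B|b", 1:200))
  degs_A <- sample(pairs$gene_A, 80)
  degs_B <- sample(pairs$gene_B, 60)
  part <- shared_de_partition(pairs, degs_A, degs_B)
  expect_equal(sum(part$counts), 200L)
  oracle <- integer(4)
  for (i in 1:200) {
    a <- pairs$gene_A[i] %in% degs_A; b <- pairs$gene_B[i] %in% degs_B
    j <- if (a && b) 1 else if (a) 2 else if (b) 3 else 4
    oracle[j] <- oracle[j] + 1L
  }
  expect_equal(unname(part$counts), oracle)
  none <- shared_de_partition(pairs, character(0), character(0))
  expect_equal(unname(none$counts["neither"]), 200L)
  only <- shared_de_partition(pairs[1, ], pairs$gene_A[1], character(0))
  expect_equal(only$cell, "only_A")
})

test_that("synchrony percentages reproduce the published worked examples", {
  # 131 + 229 same-stage vs 256 asynchronous -> 58%
  mk <- function(nPC, nG, nAsync, comparison, stages) {
    n <- nPC + nG + nAsync
    pairs <- data.frame(gene_A = paste0("A|a", 1:n),
                        gene_B = paste0("B|b", 1:n))
    upA <- c(rep(stages[1], nPC), rep(stages[2], nG),
             rep(stages[1], nAsync))
    upB <- c(rep(stages[1], nPC), rep(stages[2], nG),
             rep(stages[2], nAsync))
    list(pairs = pairs,
         res_A = fake_de(pairs$gene_A, upA, comparison),
         res_B = fake_de(pairs$gene_B, upB, comparison))
  }
  fx <- mk(131, 229, 256, "PCvsG", c("PC", "G"))
  s <- synchrony_stats(fx$pairs, fx$res_A, fx$res_B, "PCvsG")
  expect_equal(s$percent_same, 58)
  expect_equal(unname(s$same_by_stage), c(131L, 229L))
  expect_equal(s$asynchronous, 256L)

  fx2 <- mk(50, 56, 573, "GvsS", c("G", "S"))
  s2 <- synchrony_stats(fx2$pairs, fx2$res_A, fx2$res_B, "GvsS")
  expect_equal(s2$percent_same, 16)
  expect_equal(s2$n_both_de, 679L)

  all_same <- mk(10, 5, 0, "PCvsG", c("PC", "G"))
  expect_equal(synchrony_stats(all_same$pairs, all_same$res_A,
                               all_same$res_B, "PCvsG")$percent_same, 100)
})

test_that("the stage-overlap matrix equals a brute-force double loop", {
  set.seed(17)
  n <- 150
  pairs <- data.frame(gene_A = paste0("A|a", 1:n),
                      gene_B = paste0("B|b", 1:n))
  rand_up <- function(genes, comparison, stages) {
    fake_de(genes, sample(c(stages, "none"), length(genes), replace = TRUE),
            comparison)
  }
  res_A <- list(PCvsG = rand_up(pairs$gene_A, "PCvsG", c("PC", "G")),
                GvsS = rand_up(pairs$gene_A, "GvsS", c("G", "S")))
  res_B <- list(PCvsG = rand_up(pairs$gene_B, "PCvsG", c("PC", "G")),
                GvsS = rand_up(pairs$gene_B, "GvsS", c("G", "S")))
  m <- stage_overlap_matrix(res_A, res_B, pairs)
  stages <- c("PC", "G", "S")
  oracle <- matrix(0L, 3, 3, dimnames = list(A = stages, B = stages))
  ups <- function(res, gene) {
    out <- character(0)
    for (r in res) {
      u <- r$up_stage[r$gene == gene]
      if (length(u) == 1 && u != "none") out <- union(out, u)
    }
    out
  }
  for (i in 1:n) {
    for (sa in ups(res_A, pairs$gene_A[i]))
      for (sb in ups(res_B, pairs$gene_B[i]))
        oracle[sa, sb] <- oracle[sa, sb] + 1L
  }
  expect_equal(m, oracle)
  # identical one-sided labels give a diagonal matrix
  same <- fake_de(pairs$gene_A, rep(c("PC", "G", "S"), each = 50), "PCvsG")
  sameB <- fake_de(pairs$gene_B, rep(c("PC", "G", "S"), each = 50), "PCvsG")
  md <- stage_overlap_matrix(list(same), list(sameB), pairs)
  expect_equal(sum(md) - sum(diag(md)), 0)
  # empty DE gives the zero matrix
  z <- stage_overlap_matrix(list(fake_de(pairs$gene_A, rep("none", n))),
                            list(fake_de(pairs$gene_B, rep("none", n))),
                            pairs)
  expect_true(all(z == 0))
})

test_that("cluster overlap reproduces the published trace and percent", {
  diag_counts <- c(75, 9, 12, 82, 28, 9)
  n_total <- 1629
  n_off <- n_total - sum(diag_counts)
  labs <- paste0("C", 1:6)
  a_diag <- rep(labs, diag_counts)
  # off-diagonal pairs: cycle through label pairs that never coincide
  a_off <- rep(labs, length.out = n_off)
  b_off <- rep(labs[c(2:6, 1)], length.out = n_off)
  pairs <- data.frame(gene_A = paste0("A|a", 1:n_total),
                      gene_B = paste0("B|b", 1:n_total))
  arch_A <- setNames(c(a_diag, a_off), pairs$gene_A)
  arch_B <- setNames(c(a_diag, b_off), pairs$gene_B)
  co <- cluster_overlap(pairs, arch_A, arch_B)
  expect_equal(co$trace, 215L)
  expect_equal(co$percent_same, 13.2)
  expect_equal(unname(diag(co$matrix)), diag_counts)
  expect_equal(sum(co$matrix) + co$n_unlabelled, co$n_pairs)

  # identical assignments on both sides give 100%
  co2 <- cluster_overlap(pairs, arch_A, setNames(arch_A, pairs$gene_B))
  expect_equal(co2$percent_same, 100)

  # brute-force tally oracle on a random fixture with missing labels
  set.seed(23)
  aa <- setNames(sample(c(labs, NA), 300, replace = TRUE),
                 paste0("A|r", 1:300))
  bb <- setNames(sample(c(labs, NA), 300, replace = TRUE),
                 paste0("B|r", 1:300))
  rp <- data.frame(gene_A = names(aa), gene_B = names(bb))
  co3 <- cluster_overlap(rp, aa, bb)
  oracle <- matrix(0L, 6, 6, dimnames = list(A = labs, B = labs))
  unlab <- 0L
  for (i in 1:300) {
    la <- aa[[i]]; lb <- bb[[i]]
    if (is.na(la) || is.na(lb)) unlab <- unlab + 1L
    else oracle[la, lb] <- oracle[la, lb] + 1L
  }
  expect_equal(co3$matrix, oracle)
  expect_equal(co3$n_unlabelled, unlab)
})

test_that("gastrula-core filters match their definitions and brute force", {
  pairs <- data.frame(gene_A = paste0("A|a", 1:4),
                      gene_B = paste0("B|b", 1:4))
  res_A <- list(
    PCvsG = fake_de(pairs$gene_A, c("G", "G", "PC", "none"), "PCvsG"),
    GvsS = fake_de(pairs$gene_A, c("none", "none", "G", "S"), "GvsS"))
  res_B <- list(
    PCvsG = fake_de(pairs$gene_B, c("G", "none", "G", "none"), "PCvsG"),
    GvsS = fake_de(pairs$gene_B, c("none", "S", "none", "G"), "GvsS"))
  core <- gastrula_core(pairs, res_A, res_B)
  # pair 1: both up in G; pair 2: B up only in S; pair 3: A up G via GvsS
  expect_setequal(core$gene_A, c("A|a1", "A|a3"))

  labs <- paste0("C", 1:6)
  arch_A <- setNames(c("C3", "C2", "C5", "C4"), pairs$gene_A)
  arch_B <- setNames(c("C3", "C5", "C4", "C2"), pairs$gene_B)
  gc <- g_cluster_core(pairs, arch_A, arch_B)
  expect_setequal(gc$gene_A, c("A|a1", "A|a4"))   # (C3,C3) and (C4,C2)
  # brute-force filter oracle
  set.seed(3)
  aa <- setNames(sample(labs, 200, replace = TRUE), paste0("A|x", 1:200))
  bb <- setNames(sample(labs, 200, replace = TRUE), paste0("B|y", 1:200))
  rp <- data.frame(gene_A = names(aa), gene_B = names(bb))
  got <- g_cluster_core(rp, aa, bb)
  keep <- aa %in% c("C2", "C3", "C4") & bb %in% c("C2", "C3", "C4")
  expect_equal(got$gene_A, rp$gene_A[keep])
})
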