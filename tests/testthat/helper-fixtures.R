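# Shared fixture builders. Everything is generated in code; no stored data.

# minimal DE-result-like table, enough for the set/synchrony operations
fake_de <- function(gene, up_stage, comparison = "PCvsG") {
  data.frame(gene = gene, comparison = comparison,
             log2fc = ifelse(up_stage == "none", 0, 2),
             p = 0.001, padj = 0.001,
             is_deg = up_stage != "none", up_stage = up_stage,
             stringsAsFactors = FALSE)
}

# a two-stage count matrix with planted fold changes on the first n_de genes
planted_counts <- function(n_de, n_null, base_mean, lfc, disp, nrep,
                           seed = 1) {
  set.seed(seed)
  n <- n_de + n_null
  mu <- matrix(base_mean, n, 2 * nrep)
  mu[seq_len(n_de), nrep + seq_len(nrep)] <- base_mean * 2^lfc
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / disp), n,
                   dimnames = list(sprintf("g%04d", seq_len(n)),
                                   c(paste0("sp_PC_", seq_len(nrep)),
                                     paste0("sp_G_", seq_len(nrep)))))
  storage.mode(counts) <- "integer"
  design <- data.frame(sample = colnames(counts), species = "sp",
                       stage = rep(c("PC", "G"), each = nrep),
                       replicate = rep(seq_len(nrep), 2),
                       stringsAsFactors = FALSE)
  list(counts = counts, design = design)
}

# rows drawn from the six archetype templates over 9 samples (3 per stage),
# with Gaussian noise; returns matrix + true labels
archetype_matrix <- function(n_per, noise_sd, seed = 1) {
  set.seed(seed)
  tmpl <- archetype_templates()
  labels <- rep(rownames(tmpl), each = n_per)
  base <- tmpl[labels, rep(1:3, each = 3)]
  x <- base + matrix(rnorm(length(base), sd = noise_sd), nrow(base))
  rownames(x) <- sprintf("g%04d", seq_along(labels))
  colnames(x) <- paste("sp", rep(c("PC", "G", "S"), each = 3), 1:3,
                       sep = "_")
  list(x = x, labels = setNames(labels, rownames(x)),
       design = data.frame(sample = colnames(x), species = "sp",
                           stage = rep(c("PC", "G", "S"), each = 3),
                           replicate = rep(1:3, 3),
                           stringsAsFactors = FALSE))
}

# small synthetic config for fast end-to-end runs
small_config <- function(seed = 11, ...) {
  synth_config(seed = seed, n_orthogroups = 250,
               n_paralog_pairs = c(60, 40), ...)
}
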