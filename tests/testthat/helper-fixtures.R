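# shared fixtures: small cohort configurations and a brute-force evaluation
# of the specificity pipeline used as an independent oracle

`%||%` <- function(a, b) if (is.null(a)) b else a

small_config <- function(seed = 1L, ...) {
  args <- list(
    n_cancers = 3,
    samples_per_cancer_tumor = 10,
    samples_per_cancer_normal = 5,
    n_genes = 60,
    sites_per_gene = 4,
    n_gpcr_genes = 12,
    n_specific_genes_per_cancer = 2,
    n_dm_genes_per_cancer = 4,
    missing_rate = 0.02,
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(cohort_config, args)
}

# a deterministic toy gene-beta matrix: genes x (cancers x samples)
toy_gene_beta <- function(n_genes = 3, n_cancers = 3, n_samples = 4,
                          seed = 99) {
  set.seed(seed)
  cancers <- paste0("ca", seq_len(n_cancers))
  sheet <- tibble::tibble(
    sample_id = paste0(rep(cancers, each = n_samples), "_s", seq_len(n_samples)),
    cancer_type = rep(cancers, each = n_samples),
    tissue = "tumor",
    batch = "discovery",
    split = "train"
  )
  gb <- matrix(
    round(runif(n_genes * nrow(sheet), 0.05, 0.95), 3),
    n_genes, nrow(sheet),
    dimnames = list(paste0("g", seq_len(n_genes)), sheet$sample_id)
  )
  list(gene_beta = gb, sheet = sheet)
}

# Independent brute-force evaluation of the specificity pipeline with
# explicit loops; shares no code with the package implementation.
brute_force_specificity <- function(gene_beta, sheet) {
  tumor <- sheet[sheet$tissue == "tumor", ]
  cancers <- sort(unique(tumor$cancer_type))
  genes <- rownames(gene_beta)
  n_g <- length(genes)
  n_c <- length(cancers)

  m <- matrix(0, n_g, n_c, dimnames = list(genes, cancers))
  sd_mat <- m
  for (i in seq_len(n_g)) {
    for (j in seq_len(n_c)) {
      ids <- tumor$sample_id[tumor$cancer_type == cancers[j]]
      vals <- as.numeric(gene_beta[i, ids])
      s <- length(vals)
      m[i, j] <- sum(vals) / s
      mu <- m[i, j]
      sd_mat[i, j] <- sqrt(sum((vals - mu)^2) / (s - 1))
    }
  }
  p <- m
  for (i in seq_len(n_g)) p[i, ] <- m[i, ] / sum(m[i, ])
  h <- numeric(n_g)
  for (i in seq_len(n_g)) {
    acc <- 0
    for (j in seq_len(n_c)) {
      if (p[i, j] > 0) acc <- acc - p[i, j] * log2(p[i, j])
    }
    h[i] <- acc
  }
  mbar <- stats::setNames(numeric(n_c), cancers)
  for (j in seq_len(n_c)) mbar[j] <- sum(m[, j]) / n_g
  cv <- m
  t_mat <- m
  for (i in seq_len(n_g)) {
    for (j in seq_len(n_c)) {
      cv[i, j] <- sd_mat[i, j] / mbar[j] * 100
      t_mat[i, j] <- (h[i] * m[i, j]) / (cv[i, j] * mbar[j])
    }
  }
  xbar <- numeric(n_g)
  m_score <- t_mat
  assigned <- character(n_g)
  for (i in seq_len(n_g)) {
    xbar[i] <- sum(t_mat[i, ]) / n_c
    rng <- max(t_mat[i, ]) - min(t_mat[i, ])
    for (j in seq_len(n_c)) m_score[i, j] <- (t_mat[i, j] - xbar[i]) / rng
    assigned[i] <- cancers[which.max(m_score[i, ])]
  }
  list(
    m = m, p = p, H = h, mbar = mbar, SD = sd_mat, C = cv,
    T = t_mat, Xbar = xbar, M = m_score,
    assigned = stats::setNames(assigned, genes)
  )
}

# long-table cell lookup for comparing against brute force
grsdm_cell <- function(res, gene, cancer, col) {
  tab <- res$table
  tab[tab$gene == gene & tab$cancer_type == cancer, ][[col]]
}
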