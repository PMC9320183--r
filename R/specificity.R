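#' Per-cancer mean gene betas
#'
#' For each gene, the mean beta over each cancer type's tumor samples —
#' the quantity `m[i, N]` that seeds the specificity computation.
#'
#' @param gene_beta Genes x samples matrix of gene-level betas.
#' @param sheet Sample sheet; only `tissue == "tumor"` samples are used.
#' @return Genes x cancers matrix `m` with values in \[0, 1\].
#' @export
gene_cancer_means <- function(gene_beta, sheet) {
  sub <- sheet[sheet$tissue == "tumor" & sheet$sample_id %in% colnames(gene_beta), ]
  cancers <- sort(unique(sub$cancer_type))
  if (any(table(sub$cancer_type) < 1L)) {
    stop("every cancer needs >= 1 tumor sample", call. = FALSE)
  }
  m <- sapply(cancers, function(cn) {
    rowMeans(gene_beta[, sub$sample_id[sub$cancer_type == cn], drop = FALSE])
  })
  if (is.null(dim(m))) m <- matrix(m, ncol = length(cancers))
  dimnames(m) <- list(rownames(gene_beta), cancers)
  m
}

#' Relative methylation probabilities across cancers
#'
#' Normalizes each gene's per-cancer means to sum to one:
#' `p[i, N] = m[i, N] / sum_N m[i, N]`. Genes whose means are all zero have
#' no defined distribution and are removed with a warning.
#'
#' @param m Genes x cancers mean-beta matrix.
#' @return Row-stochastic matrix `p` of the same shape (minus excluded
#'   genes).
#' @export
relative_probabilities <- function(m) {
  rs <- rowSums(m)
  if (any(rs == 0)) {
    warning(sprintf(
      "%d genes with all-zero means excluded from specificity scoring",
      sum(rs == 0)
    ))
    m <- m[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  m / rs
}

#' Shannon entropy of a methylation probability profile
#'
#' `H = -sum_N p_N log2 p_N` in bits, with `0 log2 0 := 0`. For a gene's
#' relative methylation probabilities across `N` cancers, `H` ranges from 0
#' (all methylation concentrated in one cancer) to `log2(N)` (uniform).
#'
#' @param p Probability vector (sums to 1) or row-stochastic matrix; rows
#'   are treated as profiles.
#' @return Entropy in bits (vector if `p` is a matrix).
#' @export
#' @examples
#' shannon_entropy(c(0.25, 0.25, 0.25, 0.25)) # 2 bits
#' shannon_entropy(c(1, 0, 0)) # 0 bits
shannon_entropy <- function(p) {
  if (is.matrix(p)) {
    return(apply(p, 1, shannon_entropy))
  }
  if (any(p < 0)) stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-8) {
    stop("probabilities must sum to 1", call. = FALSE)
  }
  terms <- ifelse(p > 0, p * log2(p), 0)
  -sum(terms)
}

#' Within-cancer heterogeneity terms
#'
#' Computes, on tumor samples, the pieces that penalize within-cancer
#' variability: `mbar[N]`, the mean of `m[i, N]` over genes in cancer `N`;
#' `SD[i, N]`, the sample standard deviation (n-1 denominator) of gene `i`'s
#' beta across cancer `N`'s samples; and the coefficient of variation
#' `C[i, N] = SD[i, N] / mbar[N] x 100`.
#'
#' @param gene_beta Genes x samples matrix.
#' @param sheet Sample sheet; tumor samples are used.
#' @param m Genes x cancers mean matrix from [gene_cancer_means()]; its
#'   genes and cancers define the output.
#' @return A list: `mbar` (named vector per cancer), `sd` and `cv`
#'   (genes x cancers matrices).
#' @export
heterogeneity_terms <- function(gene_beta, sheet, m) {
  cancers <- colnames(m)
  sub <- sheet[sheet$tissue == "tumor" & sheet$sample_id %in% colnames(gene_beta), ]
  counts <- table(sub$cancer_type)[cancers]
  if (any(is.na(counts)) || any(counts < 2L)) {
    stop("every cancer needs >= 2 tumor samples for a standard deviation",
      call. = FALSE
    )
  }
  mbar <- colMeans(m)
  sd_mat <- sapply(cancers, function(cn) {
    apply(
      gene_beta[rownames(m), sub$sample_id[sub$cancer_type == cn],
        drop = FALSE
      ],
      1, sd
    )
  })
  dimnames(sd_mat) <- dimnames(m)
  cv <- sweep(sd_mat, 2, mbar, "/") * 100
  list(mbar = mbar, sd = sd_mat, cv = cv)
}

#' Cancer gene-specificity score
#'
#' `T[i, N] = (H[i] * m[i, N]) / (C[i, N] * mbar[N])`: a gene's entropy-
#' weighted methylation level in cancer `N`, divided by the heterogeneity
#' indicator (coefficient of variation times the cancer's gene-average
#' beta). Cells with `C` below `epsilon` are floored at `epsilon` with a
#' warning to avoid division blow-ups on near-constant genes.
#'
#' @param h Per-gene entropy vector.
#' @param m Genes x cancers mean matrix.
#' @param cv Genes x cancers coefficient-of-variation matrix (percent).
#' @param mbar Per-cancer gene-average means.
#' @param epsilon Floor for `C` (default 1e-6).
#' @return Genes x cancers matrix of specificity values `T >= 0`.
#' @export
specificity_score <- function(h, m, cv, mbar, epsilon = 1e-6) {
  stopifnot(length(h) == nrow(m), all(dim(cv) == dim(m)),
    length(mbar) == ncol(m), epsilon > 0
  )
  if (any(mbar <= 0)) {
    stop("per-cancer gene-average beta must be positive", call. = FALSE)
  }
  if (any(cv < epsilon)) {
    warning(sprintf(
      "%d near-constant cells had their coefficient of variation floored at %g",
      sum(cv < epsilon), epsilon
    ))
    cv <- pmax(cv, epsilon)
  }
  (h * m) / sweep(cv, 2, mbar, "*")
}

#' Dissociation scores and unique gene-to-cancer assignment
#'
#' Centers each gene's specificity values on their cross-cancer mean and
#' scales by the range: `M[i, N] = (T[i, N] - mean_N T[i, .]) /
#' (max_N T[i, .] - min_N T[i, .])`. By construction each gene's `M` values
#' sum to zero and lie in \[-1, 1\], and the cancer maximizing `M` (equally,
#' `T`) is the gene's unique specific assignment. Genes with constant `T`
#' across cancers have no defined score and are excluded with a warning.
#'
#' @param t_mat Genes x cancers specificity matrix.
#' @return A list: `xbar` (per-gene mean of `T`), `m_score` (genes x
#'   cancers dissociation matrix), `assignment` (tibble `gene`,
#'   `cancer_type`, `M`, `T`), `excluded` (genes with constant `T`).
#' @export
dissociation_score <- function(t_mat) {
  if (ncol(t_mat) < 2L) {
    stop("specificity needs >= 2 cancer types", call. = FALSE)
  }
  t_range <- apply(t_mat, 1, max) - apply(t_mat, 1, min)
  excluded <- rownames(t_mat)[t_range == 0]
  if (length(excluded) > 0L) {
    warning(sprintf(
      "%d genes with constant specificity across cancers marked non-specific",
      length(excluded)
    ))
    t_mat <- t_mat[t_range > 0, , drop = FALSE]
    t_range <- t_range[t_range > 0]
  }
  xbar <- rowMeans(t_mat)
  m_score <- (t_mat - xbar) / t_range
  best <- max.col(m_score, ties.method = "first")
  assignment <- tibble::tibble(
    gene = rownames(t_mat),
    cancer_type = colnames(t_mat)[best],
    M = m_score[cbind(seq_len(nrow(m_score)), best)],
    T = t_mat[cbind(seq_len(nrow(t_mat)), best)]
  )
  list(
    xbar = xbar, m_score = m_score,
    assignment = assignment, excluded = excluded
  )
}

#' Identify cancer-specific DNA methylation genes
#'
#' Runs the full specificity computation on gene-level betas: per-cancer
#' tumor means, relative methylation probabilities, Shannon entropy,
#' within-cancer heterogeneity (SD and coefficient of variation), the
#' specificity score `T` and the dissociation score `M`, assigning every
#' scoreable gene to exactly one cancer type. When `genes` is supplied
#' (typically the characteristic GPCR-related set from
#' [characteristic_gene_union()]) the computation is restricted to it.
#'
#' @param gene_beta Genes x samples matrix of gene betas.
#' @param sheet Sample sheet; tumor samples are used.
#' @param genes Optional gene subset to score.
#' @param epsilon Floor for the coefficient of variation (default 1e-6).
#' @return An object of class `grsdm_result`: list with `table` (long
#'   tibble of every per-gene, per-cancer quantity), `assignments` (one row
#'   per gene, sorted by `M` within cancer), `excluded` (tibble of genes
#'   left unscored and why), `cancers` and `n_samples`.
#' @seealso [tidy.grsdm_result()], [glance.grsdm_result()],
#'   [autoplot.grsdm_result()]
#' @export
identify_grsdm <- function(gene_beta, sheet, genes = NULL, epsilon = 1e-6) {
  if (!is.null(genes)) {
    missing_genes <- setdiff(genes, rownames(gene_beta))
    if (length(missing_genes) > 0L) {
      warning(sprintf("%d requested genes absent from the beta matrix",
        length(missing_genes)
      ))
    }
    gene_beta <- gene_beta[intersect(genes, rownames(gene_beta)), ,
      drop = FALSE
    ]
  }
  if (nrow(gene_beta) == 0L) stop("no genes to score", call. = FALSE)

  m <- gene_cancer_means(gene_beta, sheet)
  if (ncol(m) < 2L) {
    stop("specificity is undefined for a single cancer type", call. = FALSE)
  }
  p <- relative_probabilities(m)
  m <- m[rownames(p), , drop = FALSE]
  h <- shannon_entropy(p)
  het <- heterogeneity_terms(gene_beta, sheet, m)
  t_mat <- specificity_score(h, m, het$cv, het$mbar, epsilon = epsilon)
  diss <- dissociation_score(t_mat)

  kept <- diss$assignment$gene
  excluded <- dplyr::bind_rows(
    tibble::tibble(
      gene = setdiff(rownames(gene_beta), rownames(p)),
      reason = "all-zero mean betas"
    ),
    tibble::tibble(gene = diss$excluded, reason = "constant specificity")
  )

  long <- tidyr::expand_grid(
    gene = kept, cancer_type = colnames(m)
  )
  ij <- cbind(
    match(long$gene, rownames(m)),
    match(long$cancer_type, colnames(m))
  )
  long$m <- m[ij]
  long$p <- p[ij]
  long$H <- unname(h[long$gene])
  long$mbar <- unname(het$mbar[long$cancer_type])
  long$SD <- het$sd[ij]
  long$C <- het$cv[ij]
  long$T <- t_mat[cbind(
    match(long$gene, rownames(t_mat)),
    match(long$cancer_type, colnames(t_mat))
  )]
  long$Xbar <- unname(diss$xbar[long$gene])
  long$M <- diss$m_score[cbind(
    match(long$gene, rownames(diss$m_score)),
    match(long$cancer_type, colnames(diss$m_score))
  )]
  assigned_to <- stats::setNames(
    diss$assignment$cancer_type, diss$assignment$gene
  )
  long$assigned <- long$cancer_type == assigned_to[long$gene]

  assignments <- dplyr::arrange(
    diss$assignment, .data$cancer_type, dplyr::desc(.data$M)
  )

  structure(
    list(
      table = long,
      assignments = assignments,
      excluded = excluded,
      cancers = colnames(m),
      n_samples = table(
        sheet$cancer_type[sheet$tissue == "tumor" &
          sheet$sample_id %in% colnames(gene_beta)]
      )
    ),
    class = "grsdm_result"
  )
}

#' @export
print.grsdm_result <- function(x, ...) {
  cat("<grsdm_result>\n")
  cat(sprintf(
    "  %d genes scored across %d cancers; %d excluded\n",
    nrow(x$assignments), length(x$cancers), nrow(x$excluded)
  ))
  counts <- table(x$assignments$cancer_type)
  cat("  genes per cancer: ")
  cat(paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a specificity result into its long per-gene, per-cancer table
#'
#' @param x A `grsdm_result`.
#' @param ... Unused.
#' @return Tibble with one row per gene x cancer holding `m`, `p`, `H`,
#'   `mbar`, `SD`, `C`, `T`, `Xbar`, `M` and the `assigned` flag.
#' @export
tidy.grsdm_result <- function(x, ...) {
  x$table
}

#' One-row summary of a specificity result
#'
#' @param x A `grsdm_result`.
#' @param ... Unused.
#' @return Tibble: `n_genes`, `n_cancers`, `n_excluded`, `max_M`,
#'   `median_H`.
#' @export
glance.grsdm_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$assignments),
    n_cancers = length(x$cancers),
    n_excluded = nrow(x$excluded),
    max_M = max(x$assignments$M),
    median_H = median(x$table$H[!duplicated(x$table$gene)])
  )
}
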