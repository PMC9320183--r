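#' Two-sided Welch t-test for two groups of beta values
#'
#' Thin wrapper around [stats::t.test()] (unequal variances, Satterthwaite
#' degrees of freedom) with explicit handling of degenerate inputs: when both
#' groups have zero variance the test is undefined, so equal means return
#' `t = 0, p = 1` and unequal means return `t = +/-Inf, p = 0`, flagged
#' `degenerate`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A one-row tibble: `t_stat`, `df`, `p_value`, `degenerate`.
#' @export
#' @examples
#' welch_t_test(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
welch_t_test <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  vx <- var(x)
  vy <- var(y)
  if (vx == 0 && vy == 0) {
    d <- mean(x) - mean(y)
    return(tibble::tibble(
      t_stat = if (d == 0) 0 else sign(d) * Inf,
      df = NA_real_,
      p_value = if (d == 0) 1 else 0,
      degenerate = TRUE
    ))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  tibble::tibble(
    t_stat = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    degenerate = FALSE
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment via [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Call differentially methylated sites for one cancer type
#'
#' Runs a per-probe Welch t-test of tumor versus normal betas within the
#' cancer's training samples, adjusts p-values by Benjamini-Hochberg within
#' the cancer, and flags significance as the conjunction
#' `p < p_threshold AND fdr < fdr_threshold`. Direction is `hyper` when the
#' tumor mean exceeds the normal mean, else `hypo`.
#'
#' @param beta Probes x samples beta matrix (imputed).
#' @param sheet Sample sheet with `split` filled (see [split_samples()]).
#' @param ann Probe annotation supplying the probe-to-gene map.
#' @param cancer Cancer type to test.
#' @param p_threshold,fdr_threshold Significance thresholds (defaults 0.05).
#' @param use_split Which split to test on (default `"train"`); `NULL` uses
#'   all samples of the cancer.
#' @return A tibble: `cancer_type`, `probe_id`, `gene`, `t_stat`, `p_value`,
#'   `fdr`, `direction`, `significant`.
#' @export
call_dm_sites <- function(beta, sheet, ann, cancer,
                          p_threshold = 0.05, fdr_threshold = 0.05,
                          use_split = "train") {
  sub <- sheet[sheet$cancer_type == cancer, ]
  if (!is.null(use_split)) sub <- sub[sub$split %in% use_split, ]
  tumor_ids <- sub$sample_id[sub$tissue == "tumor"]
  normal_ids <- sub$sample_id[sub$tissue == "normal"]
  if (length(normal_ids) < 2L) {
    stop(sprintf(
      "cancer %s lacks normal samples and is excluded from DM calling",
      cancer
    ), call. = FALSE)
  }
  if (length(tumor_ids) < 2L) {
    stop(sprintf("cancer %s has < 2 tumor samples", cancer), call. = FALSE)
  }
  xt <- beta[, tumor_ids, drop = FALSE]
  xn <- beta[, normal_ids, drop = FALSE]
  res <- purrr::map(seq_len(nrow(beta)), function(i) {
    welch_t_test(xt[i, ], xn[i, ])
  })
  res <- dplyr::bind_rows(res)
  gene <- ann$gene[match(rownames(beta), ann$probe_id)]
  out <- tibble::tibble(
    cancer_type = cancer,
    probe_id = rownames(beta),
    gene = gene,
    t_stat = res$t_stat,
    p_value = res$p_value,
    fdr = bh_fdr(res$p_value),
    direction = ifelse(rowMeans(xt) >= rowMeans(xn), "hyper", "hypo")
  )
  out$significant <- out$p_value < p_threshold & out$fdr < fdr_threshold
  out
}

#' Aggregate probe betas to gene-level betas
#'
#' The gene-level beta of a sample is the unweighted mean of the gene's
#' retained promoter probes, skipping missing probe values (exact once the
#' matrix is imputed). Genes annotated but left without any retained probe
#' are dropped with a warning.
#'
#' @param beta Probes x samples beta matrix.
#' @param ann Probe annotation with `probe_id` and `gene`.
#' @return Genes x samples matrix of gene betas.
#' @export
aggregate_to_genes <- function(beta, ann) {
  gene <- ann$gene[match(rownames(beta), ann$probe_id)]
  if (anyNA(gene)) {
    stop("every retained probe must map to a gene", call. = FALSE)
  }
  obs <- !is.na(beta)
  x0 <- beta
  x0[!obs] <- 0
  sums <- rowsum(x0, gene)
  counts <- rowsum(obs * 1, gene)
  out <- sums / counts
  out[counts == 0] <- NA_real_
  lost <- setdiff(unique(ann$gene), rownames(out))
  if (length(lost) > 0L) {
    warning(sprintf("%d annotated genes have no retained probes", length(lost)))
  }
  out
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric tail test `P(X >= overlap)` of a query gene set
#' against each supplied gene set, with Benjamini-Hochberg adjustment across
#' sets. Significance at `fdr < 0.05`.
#'
#' @param query_genes Character vector (subset of `universe`).
#' @param gene_sets Named list of character vectors (subsets of `universe`).
#' @param universe Character vector of all eligible genes.
#' @return A tibble: `set`, `set_size`, `query_size`, `overlap`, `p_value`,
#'   `fdr`, `significant`.
#' @export
hypergeom_enrichment <- function(query_genes, gene_sets, universe) {
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (!all(query_genes %in% universe)) {
    stop("query genes must be contained in the universe", call. = FALSE)
  }
  query_genes <- unique(query_genes)
  n_u <- length(unique(universe))
  n_q <- length(query_genes)
  rows <- purrr::imap(gene_sets, function(gs, nm) {
    gs <- unique(intersect(gs, universe))
    k <- length(intersect(gs, query_genes))
    p <- phyper(k - 1, length(gs), n_u - length(gs), n_q, lower.tail = FALSE)
    tibble::tibble(
      set = nm, set_size = length(gs), query_size = n_q,
      overlap = k, p_value = p
    )
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- bh_fdr(out$p_value)
  out$significant <- out$fdr < 0.05
  out
}
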