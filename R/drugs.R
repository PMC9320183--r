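#' Ridge-regression prediction of drug IC50 in cohort samples
#'
#' For each drug, fits ridge regression of cell-line log-IC50 on gene
#' expression standardized gene-wise with the cell-line panel's means and
#' SDs, with an unpenalized intercept (the training-mean IC50, since the
#' standardized design has column means zero). The same cell-line
#' standardization is applied to the cohort's sample expression before
#' coefficients are transferred, so predictions live on the training IC50
#' scale. All drugs share one penalized normal-equations factorization.
#'
#' As `lambda -> 0` on a full-rank design the fit approaches ordinary least
#' squares; as `lambda -> Inf` predictions shrink to each drug's training
#' mean.
#'
#' @param panel A `drug_panel` (see [generate_drug_panel()]) or any list
#'   with `cellline_expression` (genes x lines), `ic50` (lines x drugs) and
#'   `sample_expression` (genes x samples).
#' @param lambda Ridge penalty, strictly positive (default 1).
#' @return Object of class `ridge_ic50`: list with `predictions`
#'   (samples x drugs matrix), `coefficients` (genes x drugs),
#'   `intercepts`, `lambda`, `train_cor` (per-drug Pearson correlation of
#'   fitted vs observed training IC50).
#' @export
ridge_ic50_predict <- function(panel, lambda = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("`lambda` must be a single positive number", call. = FALSE)
  }
  x <- panel$cellline_expression
  y <- panel$ic50
  xs <- panel$sample_expression
  genes <- intersect(rownames(x), rownames(xs))
  if (length(genes) == 0L) {
    stop("no shared genes between cell-line and sample expression",
      call. = FALSE
    )
  }
  x <- x[genes, , drop = FALSE]
  xs <- xs[genes, , drop = FALSE]
  if (ncol(x) < 2L) stop("need >= 2 cell lines", call. = FALSE)
  if (any(is.na(y))) stop("missing IC50 values for trained drugs", call. = FALSE)

  mu <- rowMeans(x)
  sig <- apply(x, 1, sd)
  sig[sig == 0] <- 1 # constant genes carry no signal; leave them centered
  z <- t((x - mu) / sig) # lines x genes
  zs <- t((xs - mu) / sig) # samples x genes

  k <- crossprod(z) + diag(lambda, ncol(z))
  beta <- solve(k, crossprod(z, y)) # genes x drugs
  intercepts <- colMeans(y)
  fitted <- z %*% beta + rep(intercepts, each = nrow(z))
  preds <- zs %*% beta + rep(intercepts, each = nrow(zs))
  dimnames(beta) <- list(colnames(z), colnames(y))

  structure(
    list(
      predictions = preds,
      coefficients = beta,
      intercepts = intercepts,
      lambda = lambda,
      train_cor = sapply(
        seq_len(ncol(y)),
        function(j) cor(fitted[, j], y[, j])
      )
    ),
    class = "ridge_ic50"
  )
}

#' @export
print.ridge_ic50 <- function(x, ...) {
  cat(sprintf(
    "<ridge_ic50> %d drugs, %d genes, lambda %.3g; mean training cor %.3f\n",
    ncol(x$coefficients), nrow(x$coefficients), x$lambda, mean(x$train_cor)
  ))
  invisible(x)
}

#' @rdname ridge_ic50_predict
#' @param x A `ridge_ic50`.
#' @param ... Unused.
#' @return `tidy()`: long tibble `sample_id`, `drug`, `predicted_ic50`;
#'   `glance()`: one row with `lambda`, `n_drugs`, `n_genes`,
#'   `mean_train_cor`.
#' @export
tidy.ridge_ic50 <- function(x, ...) {
  tibble::as_tibble(x$predictions, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id",
      names_to = "drug", values_to = "predicted_ic50"
    )
}

#' @rdname ridge_ic50_predict
#' @export
glance.ridge_ic50 <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda,
    n_drugs = ncol(x$coefficients),
    n_genes = nrow(x$coefficients),
    mean_train_cor = mean(x$train_cor)
  )
}

# Spearman correlation with a two-sided p-value; exact for n < 10 (no
# ties), t-approximation otherwise
spearman_test <- function(x, y) {
  n <- length(x)
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = n < 10)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Screen gene-drug pairs by methylation/IC50 Spearman correlation
#'
#' Correlates each gene's per-sample beta with each drug's predicted IC50
#' over the shared samples (tie-aware Spearman, two-sided p). A pair is a
#' hit when `rho < rho_threshold` AND `p < p_threshold` — both strict, so a
#' negative correlation marks drugs to which hypermethylated samples are
#' predicted sensitive. Constant vectors have undefined rank correlation
#' and are skipped with a warning.
#'
#' @param grsdm_beta Genes x samples matrix of the screened genes' betas.
#' @param predicted_ic50 Samples x drugs matrix (see
#'   [ridge_ic50_predict()]).
#' @param rho_threshold Correlation threshold (default -0.4).
#' @param p_threshold P-value threshold (default 0.05).
#' @param min_pairs Minimum paired samples per test (default 5).
#' @return Tibble: `gene`, `drug`, `n`, `rho`, `p_value`, `passes`.
#' @export
drug_correlation <- function(grsdm_beta, predicted_ic50,
                             rho_threshold = -0.4, p_threshold = 0.05,
                             min_pairs = 5) {
  samples <- intersect(colnames(grsdm_beta), rownames(predicted_ic50))
  if (length(samples) < min_pairs) {
    stop(sprintf("need >= %d shared samples", min_pairs), call. = FALSE)
  }
  combos <- tidyr::expand_grid(
    gene = rownames(grsdm_beta), drug = colnames(predicted_ic50)
  )
  n_skipped <- 0L
  rows <- purrr::map(seq_len(nrow(combos)), function(i) {
    g <- combos$gene[i]
    d <- combos$drug[i]
    xv <- grsdm_beta[g, samples]
    yv <- predicted_ic50[samples, d]
    if (sd(xv) == 0 || sd(yv) == 0) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    st <- spearman_test(xv, yv)
    tibble::tibble(
      gene = g, drug = d, n = length(samples),
      rho = st$rho, p_value = st$p,
      passes = st$rho < rho_threshold & st$p < p_threshold
    )
  })
  if (n_skipped > 0L) {
    warning(sprintf("%d constant gene/drug pairs skipped", n_skipped))
  }
  dplyr::bind_rows(rows)
}
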