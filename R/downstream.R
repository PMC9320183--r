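#' Kruskal-Wallis overview of per-gene methylation differences
#'
#' Rank-based Kruskal-Wallis test of each gene's beta across cancer types
#' (tumor samples), with tie correction and a chi-squared p-value on
#' `n_cancers - 1` degrees of freedom. A gene whose values are all tied has
#' no rank information and returns `p = 1` with a warning.
#'
#' @param gene_beta Genes x samples matrix.
#' @param sheet Sample sheet; tumor samples are used.
#' @return Tibble: `gene`, `statistic`, `df`, `p_value`.
#' @export
kruskal_wallis_overview <- function(gene_beta, sheet) {
  sub <- sheet[sheet$tissue == "tumor" & sheet$sample_id %in% colnames(gene_beta), ]
  grp <- factor(sub$cancer_type)
  if (nlevels(grp) < 2L || any(table(grp) < 2L)) {
    stop("need >= 2 cancers with >= 2 tumor samples each", call. = FALSE)
  }
  x <- gene_beta[, sub$sample_id, drop = FALSE]
  n_tied <- 0L
  rows <- purrr::map(rownames(x), function(g) {
    v <- x[g, ]
    if (length(unique(v)) == 1L) {
      n_tied <<- n_tied + 1L
      return(tibble::tibble(
        gene = g, statistic = 0, df = nlevels(grp) - 1L, p_value = 1
      ))
    }
    kw <- kruskal.test(v, grp)
    tibble::tibble(
      gene = g, statistic = unname(kw$statistic),
      df = unname(kw$parameter), p_value = kw$p.value
    )
  })
  if (n_tied > 0L) {
    warning(sprintf("%d all-tied genes returned p = 1", n_tied))
  }
  dplyr::bind_rows(rows)
}

#' Random-forest multi-class cancer classification with one-vs-rest AUCs
#'
#' Trains a probability random forest on the training-split tumor samples
#' of the supplied genes (typically the assigned specific genes), predicts
#' the test split, and reports a one-vs-rest AUC per cancer plus their
#' unweighted macro-average. A cancer absent from the test split is skipped
#' with a warning.
#'
#' @param gene_beta Genes x samples matrix.
#' @param sheet Sample sheet with `split` filled.
#' @param genes Genes used as features (default: all rows).
#' @param num_trees Forest size (default 500).
#' @param seed Integer seed.
#' @return Object of class `multiclass_auc`: list with `per_class` (tibble
#'   `cancer_type`, `auc`, `n_test`), `macro_auc`, `n_train`, `n_test`.
#' @export
rf_multiclass_auc <- function(gene_beta, sheet, genes = rownames(gene_beta),
                              num_trees = 500, seed = 1L) {
  sub <- sheet[sheet$tissue == "tumor" & sheet$sample_id %in% colnames(gene_beta), ]
  train <- sub[sub$split == "train", ]
  test <- sub[sub$split == "test", ]
  if (nrow(train) == 0L || nrow(test) == 0L) {
    stop("need non-empty train and test splits", call. = FALSE)
  }
  if (length(unique(train$cancer_type)) < 2L) {
    stop("need >= 2 cancer types in training data", call. = FALSE)
  }
  genes <- intersect(genes, rownames(gene_beta))
  x_train <- t(gene_beta[genes, train$sample_id, drop = FALSE])
  x_test <- t(gene_beta[genes, test$sample_id, drop = FALSE])
  y_train <- factor(train$cancer_type)
  fit <- ranger::ranger(
    x = x_train, y = y_train, probability = TRUE,
    num.trees = num_trees, seed = seed, num.threads = 1
  )
  prob <- predict(fit, x_test)$predictions
  per_class <- purrr::map(levels(y_train), function(cn) {
    is_cn <- test$cancer_type == cn
    if (!any(is_cn)) {
      warning(sprintf("cancer %s absent from test split; skipped", cn))
      return(NULL)
    }
    tibble::tibble(
      cancer_type = cn,
      auc = auc_rank(is_cn, prob[, cn]),
      n_test = sum(is_cn)
    )
  })
  per_class <- dplyr::bind_rows(per_class)
  structure(
    list(
      per_class = per_class,
      macro_auc = mean(per_class$auc),
      n_train = nrow(train), n_test = nrow(test)
    ),
    class = "multiclass_auc"
  )
}

#' @export
print.multiclass_auc <- function(x, ...) {
  cat(sprintf(
    "<multiclass_auc> macro AUC %.3f over %d classes (train %d, test %d)\n",
    x$macro_auc, nrow(x$per_class), x$n_train, x$n_test
  ))
  invisible(x)
}

#' @rdname rf_multiclass_auc
#' @param x A `multiclass_auc`.
#' @param ... Unused.
#' @export
tidy.multiclass_auc <- function(x, ...) x$per_class

#' @rdname rf_multiclass_auc
#' @export
glance.multiclass_auc <- function(x, ...) {
  tibble::tibble(
    macro_auc = x$macro_auc,
    n_classes = nrow(x$per_class),
    n_train = x$n_train,
    n_test = x$n_test
  )
}

#' Kaplan-Meier screening of a gene by mean-beta split
#'
#' Within one cancer, samples are split into high and low groups at the
#' mean beta of the gene across those samples (or across
#' `threshold_samples` when a training-only threshold is wanted), and the
#' two groups are compared with a log-rank test. The gene is flagged
#' prognostic at `p < 0.05`.
#'
#' @param gene_beta Genes x samples matrix.
#' @param surv Survival tibble (`sample_id`, `time`, `event`,
#'   `cancer_type`).
#' @param gene Gene to screen.
#' @param cancer Cancer type whose samples are used.
#' @param threshold_samples Optional sample ids over which the mean-beta
#'   threshold is computed (defaults to the analyzed samples).
#' @return One-row tibble: `gene`, `cancer_type`, `threshold`, `n_high`,
#'   `n_low`, `chisq`, `p_value`, `prognostic`.
#' @export
km_logrank_screen <- function(gene_beta, surv, gene, cancer,
                              threshold_samples = NULL) {
  ids <- surv$sample_id[surv$cancer_type == cancer]
  ids <- intersect(ids, colnames(gene_beta))
  if (length(ids) < 4L) {
    stop("need >= 4 samples with survival and methylation", call. = FALSE)
  }
  thr_ids <- if (is.null(threshold_samples)) ids else intersect(threshold_samples, ids)
  threshold <- mean(gene_beta[gene, thr_ids])
  v <- gene_beta[gene, ids]
  high <- v > threshold
  if (sum(high) < 2L || sum(!high) < 2L) {
    warning("non-informative threshold: a group has < 2 samples")
    return(tibble::tibble(
      gene = gene, cancer_type = cancer, threshold = threshold,
      n_high = sum(high), n_low = sum(!high),
      chisq = NA_real_, p_value = NA_real_, prognostic = NA
    ))
  }
  s <- surv[match(ids, surv$sample_id), ]
  sd_fit <- survival::survdiff(
    survival::Surv(s$time, s$event) ~ high
  )
  p <- pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
  tibble::tibble(
    gene = gene, cancer_type = cancer, threshold = threshold,
    n_high = sum(high), n_low = sum(!high),
    chisq = unname(sd_fit$chisq), p_value = p, prognostic = p < 0.05
  )
}

#' Validate a gene's cancer assignment in an independent cohort
#'
#' A gene is consistent in the validation cohort when (a) its mean tumor
#' beta is maximal in its assigned cancer and (b) a one-vs-rest Wilcoxon
#' rank-sum test (assigned cancer's samples versus all other cancers',
#' alternative: greater) gives `p < p_threshold`. Genes whose assigned
#' cancer is absent from the cohort are `untestable`.
#'
#' @param assignments Tibble `gene`, `cancer_type` (e.g. from
#'   [identify_grsdm()]'s `assignments`).
#' @param gene_beta Validation genes x samples matrix.
#' @param sheet Validation sample sheet.
#' @param p_threshold Consistency threshold (default 1e-4).
#' @return Tibble: `gene`, `cancer_type`, `max_cancer`, `p_value`,
#'   `verdict` (`consistent` / `inconsistent` / `untestable`).
#' @export
validate_grsdm <- function(assignments, gene_beta, sheet,
                           p_threshold = 1e-4) {
  sub <- sheet[sheet$tissue == "tumor" & sheet$sample_id %in% colnames(gene_beta), ]
  cancers <- unique(sub$cancer_type)
  rows <- purrr::map(seq_len(nrow(assignments)), function(i) {
    g <- assignments$gene[i]
    cn <- assignments$cancer_type[i]
    if (!g %in% rownames(gene_beta) || !cn %in% cancers) {
      return(tibble::tibble(
        gene = g, cancer_type = cn, max_cancer = NA_character_,
        p_value = NA_real_, verdict = "untestable"
      ))
    }
    v <- gene_beta[g, sub$sample_id]
    means <- tapply(v, sub$cancer_type, mean)
    max_cancer <- names(which.max(means))
    in_cn <- sub$cancer_type == cn
    p <- suppressWarnings(
      wilcox.test(v[in_cn], v[!in_cn], alternative = "greater")$p.value
    )
    tibble::tibble(
      gene = g, cancer_type = cn, max_cancer = max_cancer,
      p_value = p,
      verdict = if (max_cancer == cn && p < p_threshold) {
        "consistent"
      } else {
        "inconsistent"
      }
    )
  })
  dplyr::bind_rows(rows)
}
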