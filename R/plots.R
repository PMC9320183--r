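#' Heatmap of dissociation scores with the gene-to-cancer assignment
#'
#' Tiles genes by cancers colored by the dissociation score `M`; the
#' assigned (maximal) cell of each gene is outlined. Genes are ordered by
#' their assigned cancer so the specific blocks align on the diagonal.
#'
#' @param object A `grsdm_result` from [identify_grsdm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grsdm_result <- function(object, ...) {
  tab <- object$table
  gene_order <- object$assignments$gene
  tab$gene <- factor(tab$gene, levels = rev(gene_order))
  ggplot2::ggplot(
    tab,
    ggplot2::aes(x = .data$cancer_type, y = .data$gene, fill = .data$M)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(
      data = tab[tab$assigned, ],
      fill = NA, color = "black", linewidth = 0.4
    ) +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b", midpoint = 0
    ) +
    ggplot2::labs(
      x = "cancer type", y = NULL, fill = "M",
      title = "Dissociation scores and specific assignments"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Kaplan-Meier curves for a mean-beta split
#'
#' Draws the high/low methylation Kaplan-Meier curves underlying
#' [km_logrank_screen()] for one gene in one cancer.
#'
#' @param gene_beta Genes x samples matrix.
#' @param surv Survival tibble.
#' @param gene,cancer Gene and cancer to plot.
#' @return A ggplot object.
#' @export
plot_km <- function(gene_beta, surv, gene, cancer) {
  ids <- intersect(
    surv$sample_id[surv$cancer_type == cancer], colnames(gene_beta)
  )
  v <- gene_beta[gene, ids]
  group <- ifelse(v > mean(v), "high", "low")
  s <- surv[match(ids, surv$sample_id), ]
  fit <- survival::survfit(
    survival::Surv(s$time, s$event) ~ group
  )
  df <- tibble::tibble(
    time = fit$time,
    surv = fit$surv,
    group = rep(
      sub("^group=", "", names(fit$strata)),
      fit$strata
    )
  )
  start <- tibble::tibble(
    time = 0, surv = 1, group = unique(df$group)
  )
  ggplot2::ggplot(
    rbind(start, df),
    ggplot2::aes(x = .data$time, y = .data$surv, color = .data$group)
  ) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time", y = "survival probability", color = "methylation",
      title = sprintf("%s in %s: mean-beta split", gene, cancer)
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of one-vs-rest AUCs per cancer
#'
#' @param object A `multiclass_auc` from [rf_multiclass_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.multiclass_auc <- function(object, ...) {
  ggplot2::ggplot(
    object$per_class,
    ggplot2::aes(x = .data$cancer_type, y = .data$auc)
  ) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::geom_hline(
      yintercept = object$macro_auc, linetype = "dashed"
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "cancer type", y = "one-vs-rest AUC",
      title = sprintf("Macro AUC %.3f", object$macro_auc)
    ) +
    ggplot2::theme_minimal()
}
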