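#' Configuration for a synthetic pan-cancer methylation cohort
#'
#' Bundles the knobs of the synthetic-data generator. The defaults describe a
#' desk-scale study: 8 cancer types with 30 tumor and 15 normal samples each,
#' 500 genes carrying 4 promoter-region CpG probes, 40 genes flagged as
#' GPCR-related, and per cancer 3 planted cancer-specific genes plus 10
#' planted tumor-vs-normal differentially methylated genes.
#'
#' Planted structure: each cancer receives `n_specific_genes_per_cancer`
#' genes whose beta is raised by `specific_effect` in that cancer's tumor
#' samples only (making them cancer-specific), and `n_dm_genes_per_cancer`
#' genes whose probes are raised by `dm_effect` in that cancer's tumor
#' samples (tumor-vs-normal signal). All planted gene sets are pairwise
#' disjoint, and every cancer-specific gene is included in the GPCR-related
#' list. Noise is added on the beta scale and values are clipped to
#' \[0, 1\].
#'
#' @param n_cancers Number of cancer types.
#' @param samples_per_cancer_tumor,samples_per_cancer_normal Tumor and normal
#'   sample counts per cancer.
#' @param n_genes Total genes; each carries `sites_per_gene` probes.
#' @param sites_per_gene CpG probes per gene.
#' @param n_gpcr_genes Genes flagged GPCR-related (includes all planted
#'   specific genes).
#' @param n_specific_genes_per_cancer Planted cancer-specific genes per cancer.
#' @param n_dm_genes_per_cancer Planted tumor-vs-normal DM genes per cancer.
#' @param specific_effect Beta shift of a specific gene in its assigned
#'   cancer's tumor samples, in (0, 1].
#' @param dm_effect Tumor-vs-normal beta shift of planted DM probes.
#' @param noise_sd Within-group standard deviation on the beta scale.
#' @param missing_rate Fraction of entries set to missing, in \[0, 1).
#' @param batch_shift Additive beta offset applied to the validation cohort.
#' @param baseline_range Range from which per-gene baseline betas are drawn
#'   uniformly.
#' @param promoter_frac Fraction of probes placed inside the promoter window;
#'   the remainder fall outside so the promoter filter has work to do.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#'
#' @return A validated list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_cancers = 3, n_genes = 50, seed = 7)
#' cfg$n_cancers
cohort_config <- function(n_cancers = 8,
                          samples_per_cancer_tumor = 30,
                          samples_per_cancer_normal = 15,
                          n_genes = 500,
                          sites_per_gene = 4,
                          n_gpcr_genes = 40,
                          n_specific_genes_per_cancer = 3,
                          n_dm_genes_per_cancer = 10,
                          specific_effect = 0.4,
                          dm_effect = 0.3,
                          noise_sd = 0.05,
                          missing_rate = 0.02,
                          batch_shift = 0.1,
                          baseline_range = c(0.15, 0.45),
                          promoter_frac = 0.8,
                          seed = 1L) {
  cfg <- list(
    n_cancers = as.integer(n_cancers),
    samples_per_cancer_tumor = as.integer(samples_per_cancer_tumor),
    samples_per_cancer_normal = as.integer(samples_per_cancer_normal),
    n_genes = as.integer(n_genes),
    sites_per_gene = as.integer(sites_per_gene),
    n_gpcr_genes = as.integer(n_gpcr_genes),
    n_specific_genes_per_cancer = as.integer(n_specific_genes_per_cancer),
    n_dm_genes_per_cancer = as.integer(n_dm_genes_per_cancer),
    specific_effect = specific_effect,
    dm_effect = dm_effect,
    noise_sd = noise_sd,
    missing_rate = missing_rate,
    batch_shift = batch_shift,
    baseline_range = baseline_range,
    promoter_frac = promoter_frac,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  counts <- c(
    "n_cancers", "samples_per_cancer_tumor", "samples_per_cancer_normal",
    "n_genes", "sites_per_gene", "n_gpcr_genes",
    "n_specific_genes_per_cancer", "sites_per_gene"
  )
  for (nm in counts) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] < 1L) {
      stop(sprintf("`%s` must be a single count >= 1", nm), call. = FALSE)
    }
  }
  if (cfg$n_dm_genes_per_cancer < 0L) {
    stop("`n_dm_genes_per_cancer` must be >= 0", call. = FALSE)
  }
  n_planted <- cfg$n_cancers *
    (cfg$n_specific_genes_per_cancer + cfg$n_dm_genes_per_cancer)
  if (n_planted > cfg$n_genes) {
    stop("planted genes exceed `n_genes`: reduce per-cancer planted counts",
      call. = FALSE
    )
  }
  if (cfg$n_cancers * cfg$n_specific_genes_per_cancer > cfg$n_gpcr_genes ||
    cfg$n_gpcr_genes > cfg$n_genes) {
    stop(paste(
      "`n_gpcr_genes` must hold every planted specific gene and cannot",
      "exceed `n_genes`"
    ), call. = FALSE)
  }
  if (!(cfg$specific_effect > 0 && cfg$specific_effect <= 1)) {
    stop("`specific_effect` must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$dm_effect < 0 || cfg$dm_effect > 1) {
    stop("`dm_effect` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$missing_rate > 0.7) {
    stop(paste(
      "degenerate design: `missing_rate` above 0.7 would leave every site",
      "beyond the missingness filter"
    ), call. = FALSE)
  }
  if (length(cfg$baseline_range) != 2L ||
    cfg$baseline_range[1] > cfg$baseline_range[2] ||
    cfg$baseline_range[1] < 0 || cfg$baseline_range[2] > 1) {
    stop("`baseline_range` must be an increasing pair within [0, 1]",
      call. = FALSE
    )
  }
  if (cfg$promoter_frac < 0 || cfg$promoter_frac > 1) {
    stop("`promoter_frac` must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf(
    "  %d cancers x (%d tumor + %d normal) samples\n",
    x$n_cancers, x$samples_per_cancer_tumor, x$samples_per_cancer_normal
  ))
  cat(sprintf(
    "  %d genes x %d probes (%d GPCR-related)\n",
    x$n_genes, x$sites_per_gene, x$n_gpcr_genes
  ))
  cat(sprintf(
    "  planted per cancer: %d specific (+%.2f beta), %d DM (+%.2f beta)\n",
    x$n_specific_genes_per_cancer, x$specific_effect,
    x$n_dm_genes_per_cancer, x$dm_effect
  ))
  cat(sprintf(
    "  noise sd %.3f, missing %.1f%%, batch shift %.2f, seed %d\n",
    x$noise_sd, 100 * x$missing_rate, x$batch_shift, x$seed
  ))
  invisible(x)
}
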