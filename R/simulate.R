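#' Generate a synthetic probe annotation table
#'
#' Lays out `n_genes` genes on autosomes, each with a transcription start
#' site, a strand and `sites_per_gene` CpG probes. A fraction
#' `promoter_frac` of each gene's probes is placed inside the strand-aware
#' promoter window (2000 bp upstream to 500 bp downstream of the TSS,
#' half-open at the downstream edge); the rest fall outside it, so the
#' promoter filter is exercised on the generated data.
#'
#' Coordinates are 0-based. For a probe at position `pos` with TSS `tss`,
#' the signed offset in the direction of transcription is `pos - tss` on the
#' `+` strand and `tss - pos` on the `-` strand; the promoter window is
#' `[-2000, 500)` in offset space.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `probe_id`, `chrom`, `pos`, `strand`,
#'   `gene`, `tss`.
#' @export
#' @examples
#' ann <- generate_annotation(cohort_config(n_cancers = 2, n_genes = 10))
#' head(ann)
generate_annotation <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  with_seed(config$seed + 1L, {
    genes <- sprintf("gene%04d", seq_len(config$n_genes))
    chrom <- paste0("chr", sample(1:22, config$n_genes, replace = TRUE))
    tss <- sample(10000:2e6, config$n_genes, replace = TRUE)
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)

    k <- config$sites_per_gene
    n_in <- round(config$promoter_frac * k)
    rows <- purrr::map(seq_len(config$n_genes), function(g) {
      # offsets in transcription direction; window is [-2000, 500)
      inside <- sample(-2000:499, n_in, replace = TRUE)
      outside <- sample(c(-6000:-2001, 500:4000), k - n_in, replace = TRUE)
      off <- c(inside, outside)
      pos <- if (strand[g] == "+") tss[g] + off else tss[g] - off
      tibble::tibble(
        chrom = chrom[g], pos = pos, strand = strand[g],
        gene = genes[g], tss = tss[g]
      )
    })
    ann <- dplyr::bind_rows(rows)
    ann$probe_id <- sprintf("cg%06d", seq_len(nrow(ann)))
    dplyr::select(
      ann, "probe_id", "chrom", "pos", "strand", "gene", "tss"
    )
  })
}

#' Generate a synthetic discovery cohort with planted ground truth
#'
#' Simulates a probes-by-samples beta-value matrix for `n_cancers` cancer
#' types with tumor and normal samples, plants cancer-specific genes (beta
#' raised by `specific_effect` in exactly one cancer's tumors) and
#' tumor-vs-normal differentially methylated genes (probes raised by
#' `dm_effect` in one cancer's tumors), adds Gaussian noise on the beta
#' scale with clipping to \[0, 1\], and knocks out entries at
#' `missing_rate`. The planted assignments are returned so downstream
#' stages can be scored against known truth.
#'
#' @param config A [cohort_config()].
#' @param annotation Optional annotation from [generate_annotation()];
#'   regenerated from `config` when omitted.
#' @return A list with elements `beta` (matrix, probes x samples, `NA` for
#'   missing), `sheet` (sample-sheet tibble: `sample_id`, `cancer_type`,
#'   `tissue`, `batch`, `split`), `truth` (planted structure, see Details)
#'   and `gpcr_genes` (character vector).
#'
#' @details `truth` is a list: `specific_gene_map` (tibble `gene`,
#'   `cancer_type`), `dm_genes` and `dm_sites` (tibbles keyed by
#'   `cancer_type`), `survival_risk_genes` (one specific gene per cancer),
#'   `baseline` (named per-gene baseline betas) and `gpcr_genes`.
#' @export
generate_cohort <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  if (is.null(annotation)) annotation <- generate_annotation(config)

  with_seed(config$seed + 2L, {
    genes <- sprintf("gene%04d", seq_len(config$n_genes))
    cancers <- sprintf("cancer%02d", seq_len(config$n_cancers))

    baseline <- stats::setNames(
      runif(config$n_genes, config$baseline_range[1], config$baseline_range[2]),
      genes
    )

    # planted genes: pairwise-disjoint specific and DM sets
    n_spec <- config$n_specific_genes_per_cancer
    n_dm <- config$n_dm_genes_per_cancer
    planted <- sample(genes, config$n_cancers * (n_spec + n_dm))
    spec_genes <- planted[seq_len(config$n_cancers * n_spec)]
    dm_pool <- setdiff(planted, spec_genes)
    specific_gene_map <- tibble::tibble(
      gene = spec_genes,
      cancer_type = rep(cancers, each = n_spec)
    )
    dm_genes <- tibble::tibble(
      gene = dm_pool,
      cancer_type = rep(cancers, each = n_dm)[seq_along(dm_pool)]
    )

    gpcr_extra <- sample(
      setdiff(genes, spec_genes),
      config$n_gpcr_genes - length(spec_genes)
    )
    gpcr_genes <- sort(c(spec_genes, gpcr_extra))

    sheet <- cohort_sheet(config, cancers, batch = "discovery")
    beta <- simulate_beta(
      config, annotation, sheet, baseline,
      specific_gene_map, dm_genes,
      extra_shift = 0
    )
    beta <- insert_missing(beta, config$missing_rate)

    dm_sites <- dplyr::inner_join(
      annotation[, c("probe_id", "gene")], dm_genes,
      by = "gene"
    )[, c("cancer_type", "probe_id", "gene")]

    truth <- list(
      specific_gene_map = specific_gene_map,
      dm_genes = dm_genes,
      dm_sites = tibble::as_tibble(dm_sites),
      survival_risk_genes = specific_gene_map[
        !duplicated(specific_gene_map$cancer_type),
      ],
      baseline = baseline,
      gpcr_genes = gpcr_genes
    )
    list(beta = beta, sheet = sheet, truth = truth, gpcr_genes = gpcr_genes)
  })
}

# sample sheet for one batch
cohort_sheet <- function(config, cancers, batch, suffix = "") {
  rows <- purrr::map(cancers, function(cn) {
    tibble::tibble(
      sample_id = c(
        sprintf("%s%s_T%03d", cn, suffix, seq_len(config$samples_per_cancer_tumor)),
        sprintf("%s%s_N%03d", cn, suffix, seq_len(config$samples_per_cancer_normal))
      ),
      cancer_type = cn,
      tissue = rep(
        c("tumor", "normal"),
        c(config$samples_per_cancer_tumor, config$samples_per_cancer_normal)
      )
    )
  })
  sheet <- dplyr::bind_rows(rows)
  sheet$batch <- batch
  sheet$split <- NA_character_
  sheet
}

# mean structure + noise + clipping; extra_shift models a cohort-wide batch
# offset
simulate_beta <- function(config, annotation, sheet, baseline,
                          specific_gene_map, dm_genes, extra_shift) {
  n_probe <- nrow(annotation)
  n_samp <- nrow(sheet)
  mu <- matrix(
    baseline[annotation$gene],
    nrow = n_probe, ncol = n_samp,
    dimnames = list(annotation$probe_id, sheet$sample_id)
  )
  tumor <- sheet$tissue == "tumor"
  spec_cancer <- stats::setNames(
    specific_gene_map$cancer_type, specific_gene_map$gene
  )
  probe_spec <- spec_cancer[annotation$gene] # NA for non-specific genes
  dm_cancer <- stats::setNames(dm_genes$cancer_type, dm_genes$gene)
  probe_dm <- dm_cancer[annotation$gene]
  for (j in which(tumor)) {
    cn <- sheet$cancer_type[j]
    hit_spec <- !is.na(probe_spec) & probe_spec == cn
    hit_dm <- !is.na(probe_dm) & probe_dm == cn
    mu[hit_spec, j] <- mu[hit_spec, j] + config$specific_effect
    mu[hit_dm, j] <- mu[hit_dm, j] + config$dm_effect
  }
  noise <- if (config$noise_sd > 0) {
    matrix(rnorm(n_probe * n_samp, sd = config$noise_sd), n_probe, n_samp)
  } else {
    0
  }
  clip01(mu + noise + extra_shift)
}

# knock out entries uniformly at random; exact count up to rounding
insert_missing <- function(beta, rate) {
  if (rate <= 0) {
    return(beta)
  }
  n_missing <- round(rate * length(beta))
  idx <- sample(length(beta), n_missing)
  beta[idx] <- NA_real_
  beta
}

#' Generate a validation cohort sharing the discovery cohort's planted truth
#'
#' Draws new samples for the same cancers with the same planted
#' gene-to-cancer structure, adds a constant `batch_shift` to every beta
#' (the between-cohort batch effect) and a fresh noise realization. No
#' missing values are inserted; validation-series matrices are assumed
#' complete after their own preprocessing.
#'
#' @param config A [cohort_config()].
#' @param truth The `truth` element returned by [generate_cohort()].
#' @param annotation Annotation used for the discovery cohort.
#' @return A list with `beta` and `sheet`; samples carry
#'   `batch = "validation"` and `split = "validation"`.
#' @export
generate_validation_cohort <- function(config, truth, annotation = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(annotation)) annotation <- generate_annotation(config)
  with_seed(config$seed + 3L, {
    cancers <- sort(unique(truth$specific_gene_map$cancer_type))
    sheet <- cohort_sheet(config, cancers, batch = "validation", suffix = "v")
    sheet$split <- "validation"
    beta <- simulate_beta(
      config, annotation, sheet, truth$baseline,
      truth$specific_gene_map, truth$dm_genes,
      extra_shift = config$batch_shift
    )
    list(beta = beta, sheet = sheet)
  })
}

#' Simulate survival outcomes linked to methylation of risk genes
#'
#' Event times follow an exponential proportional-hazards model: sample `s`
#' has hazard `baseline_hazard * exp(gamma * sum_g (beta[g, s] - mean_g))`
#' over the risk genes `g`. Censoring is independent exponential, calibrated
#' so that a fraction `censoring_rate` of samples is censored under the null;
#' `censoring_rate = 1` censors everything.
#'
#' @param sheet Sample sheet; all its samples receive outcomes.
#' @param gene_beta Genes x samples beta matrix (see [aggregate_to_genes()]).
#' @param risk_genes Character vector of genes driving hazard (may be empty).
#' @param gamma Log-hazard slope per unit beta (default 2).
#' @param baseline_hazard Baseline exponential rate (default 0.1, i.e. mean
#'   null survival time 10 in arbitrary follow-up units).
#' @param censoring_rate Target fraction censored, in \[0, 1\].
#' @param seed Integer seed.
#' @return A tibble `sample_id`, `time` (> 0), `event` (0/1), `cancer_type`.
#' @export
generate_survival <- function(sheet, gene_beta, risk_genes = character(),
                              gamma = 2, baseline_hazard = 0.1,
                              censoring_rate = 0.3, seed = 1L) {
  stopifnot(
    all(sheet$sample_id %in% colnames(gene_beta)),
    censoring_rate >= 0, censoring_rate <= 1, baseline_hazard > 0
  )
  risk_genes <- intersect(risk_genes, rownames(gene_beta))
  with_seed(seed, {
    n <- nrow(sheet)
    lp <- rep(0, n)
    if (length(risk_genes) > 0 && gamma != 0) {
      sub <- gene_beta[risk_genes, sheet$sample_id, drop = FALSE]
      centered <- sub - rowMeans(sub)
      lp <- gamma * colSums(centered)
    }
    hazard <- baseline_hazard * exp(lp)
    t_event <- rexp(n, rate = hazard)
    if (censoring_rate >= 1) {
      time <- rexp(n, rate = baseline_hazard)
      event <- rep(0L, n)
    } else if (censoring_rate == 0) {
      time <- t_event
      event <- rep(1L, n)
    } else {
      cens_rate <- baseline_hazard * censoring_rate / (1 - censoring_rate)
      t_cens <- rexp(n, rate = cens_rate)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    }
    tibble::tibble(
      sample_id = sheet$sample_id,
      time = time,
      event = event,
      cancer_type = sheet$cancer_type
    )
  })
}

#' Simulate a drug-sensitivity panel with planted methylation-IC50 links
#'
#' Builds a GDSC-style training panel — cell-line expression (genes x lines)
#' and per-drug log-IC50 values generated from a sparse linear model of
#' expression — plus an expression matrix for the cohort's tumor samples.
#' For each drug, one planted cancer-specific gene is designated its
#' methylation partner: the drug's support-gene expression in tumor samples
#' is constructed so the drug's true linear response decreases as the
#' partner gene's methylation rises, giving a negative Spearman correlation
#' between partner-gene beta and (true or well-predicted) IC50.
#'
#' @param config A [cohort_config()].
#' @param truth Planted truth from [generate_cohort()].
#' @param gene_beta Genes x samples beta matrix of the cohort.
#' @param sheet Sample sheet matching `gene_beta`.
#' @param n_drugs Number of drugs (default 6).
#' @param n_celllines Number of training cell lines (default 60).
#' @param support_size Genes per drug's true linear model (default 5).
#' @param ic50_noise_sd Noise sd on the cell-line IC50s (default 0.25).
#' @param expr_noise_sd Noise sd on sample expression (default 0.3).
#' @param coupling Scale of the methylation-to-expression coupling for
#'   planted pairs (default 2).
#' @return A list of class `drug_panel`: `cellline_expression`, `ic50`
#'   (lines x drugs), `sample_expression` (genes x tumor samples),
#'   `drug_pairs` (tibble `drug`, `gene`, `cancer_type`) and
#'   `drug_coefficients` (list of named weight vectors).
#' @export
generate_drug_panel <- function(config, truth, gene_beta, sheet,
                                n_drugs = 6, n_celllines = 60,
                                support_size = 5,
                                ic50_noise_sd = 0.25,
                                expr_noise_sd = 0.3,
                                coupling = 2) {
  stopifnot(inherits(config, "cohort_config"), n_drugs >= 1, n_celllines >= 2)
  with_seed(config$seed + 4L, {
    genes <- rownames(gene_beta)
    tumor_ids <- sheet$sample_id[sheet$tissue == "tumor"]
    drugs <- sprintf("drug%02d", seq_len(n_drugs))
    lines <- sprintf("line%03d", seq_len(n_celllines))

    pair_genes <- rep_len(truth$specific_gene_map$gene, n_drugs)
    pair_map <- stats::setNames(
      truth$specific_gene_map$cancer_type, truth$specific_gene_map$gene
    )
    free_genes <- setdiff(genes, pair_genes)
    if (length(free_genes) < n_drugs * support_size) {
      stop("not enough genes for disjoint drug supports", call. = FALSE)
    }
    supports <- split(
      sample(free_genes, n_drugs * support_size),
      rep(seq_len(n_drugs), each = support_size)
    )
    weights <- purrr::map(supports, function(gs) {
      stats::setNames(runif(length(gs), 0.5, 1.5) * sample(c(-1, 1), length(gs), TRUE), gs)
    })
    names(weights) <- drugs

    cell_expr <- matrix(
      rnorm(length(genes) * n_celllines), length(genes), n_celllines,
      dimnames = list(genes, lines)
    )
    ic50 <- sapply(drugs, function(d) {
      w <- weights[[d]]
      drop(crossprod(cell_expr[names(w), , drop = FALSE], w)) +
        rnorm(n_celllines, sd = ic50_noise_sd)
    })
    rownames(ic50) <- lines

    # tumor-sample expression: support genes of drug d track the partner
    # gene's methylation with sign opposite to their IC50 weight, so the
    # drug's linear response falls as partner methylation rises
    sample_expr <- matrix(
      rnorm(length(genes) * length(tumor_ids), sd = 1),
      length(genes), length(tumor_ids),
      dimnames = list(genes, tumor_ids)
    )
    for (i in seq_len(n_drugs)) {
      pg <- pair_genes[i]
      z <- as.numeric(scale(gene_beta[pg, tumor_ids]))
      w <- weights[[i]]
      for (g in names(w)) {
        sample_expr[g, ] <- -sign(w[g]) * coupling * z +
          rnorm(length(tumor_ids), sd = expr_noise_sd)
      }
    }

    structure(
      list(
        cellline_expression = cell_expr,
        ic50 = ic50,
        sample_expression = sample_expr,
        drug_pairs = tibble::tibble(
          drug = drugs,
          gene = pair_genes,
          cancer_type = unname(pair_map[pair_genes])
        ),
        drug_coefficients = weights
      ),
      class = "drug_panel"
    )
  })
}
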