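test_that("kruskal-wallis overview matches the two-group rank-sum relationship", {
  fix <- toy_gene_beta(n_genes = 4, n_cancers = 2, n_samples = 8)
  res <- kruskal_wallis_overview(fix$gene_beta, fix$sheet)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$statistic >= 0))
  # with two groups the KW chi-squared p equals the normal-approximation
  # Wilcoxon rank-sum p without continuity correction
  grp <- fix$sheet$cancer_type
  for (g in rownames(fix$gene_beta)) {
    w <- suppressWarnings(wilcox.test(
      fix$gene_beta[g, ] ~ grp,
      exact = FALSE, correct = FALSE
    ))
    expect_equal(
      res$p_value[res$gene == g], w$p.value,
      tolerance = 1e-10
    )
  }
  # an all-tied gene returns p = 1 with a warning
  gb <- fix$gene_beta
  gb["g1", ] <- 0.5
  expect_warning(res2 <- kruskal_wallis_overview(gb, fix$sheet), "tied")
  expect_identical(res2$p_value[res2$gene == "g1"], 1)
})

test_that("planted specific genes reject under kruskal-wallis", {
  cfg <- small_config(seed = 13)
  ann <- generate_annotation(cfg)
  coh <- generate_cohort(cfg, ann)
  gb <- aggregate_to_genes(coh$beta, ann)
  res <- kruskal_wallis_overview(
    gb[coh$truth$specific_gene_map$gene, ], coh$sheet
  )
  expect_true(all(res$p_value < 0.05))
})

test_that("km screening returns p = 1 for identical group survival", {
  gb <- matrix(
    rep(c(0.2, 0.8), each = 6), 1, 12,
    dimnames = list("g1", paste0("s", 1:12))
  )
  # the two beta groups carry identical event patterns
  surv <- tibble::tibble(
    sample_id = paste0("s", 1:12),
    time = rep(c(1, 2, 3, 4, 5, 6), 2),
    event = rep(c(1L, 1L, 0L, 1L, 0L, 1L), 2),
    cancer_type = "ca1"
  )
  res <- km_logrank_screen(gb, surv, "g1", "ca1")
  expect_equal(res$chisq, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  expect_false(res$prognostic)
})

test_that("km screening warns when the mean split is non-informative", {
  gb <- matrix(c(0.9, rep(0.1, 7)), 1, 8,
    dimnames = list("g1", paste0("s", 1:8))
  )
  surv <- tibble::tibble(
    sample_id = paste0("s", 1:8),
    time = 1:8, event = rep(1L, 8), cancer_type = "ca1"
  )
  expect_warning(res <- km_logrank_screen(gb, surv, "g1", "ca1"), "non-informative")
  expect_true(is.na(res$p_value))
})

test_that("validation verdicts distinguish planted, noise and missing cancers", {
  cfg <- small_config(seed = 17)
  ann <- generate_annotation(cfg)
  coh <- generate_cohort(cfg, ann)
  val <- generate_validation_cohort(cfg, coh$truth, ann)
  gbv <- aggregate_to_genes(val$beta, ann)
  truth <- coh$truth$specific_gene_map
  res <- validate_grsdm(truth, gbv, val$sheet)
  expect_true(all(res$verdict == "consistent"))
  # a noise gene assigned arbitrarily should not validate
  noise_gene <- setdiff(rownames(gbv), c(truth$gene, coh$truth$dm_genes$gene))[1]
  fake <- tibble::tibble(gene = noise_gene, cancer_type = "cancer01")
  res_fake <- validate_grsdm(fake, gbv, val$sheet)
  expect_identical(res_fake$verdict, "inconsistent")
  # assigned cancer absent from the validation cohort
  missing <- tibble::tibble(gene = truth$gene[1], cancer_type = "cancer99")
  expect_identical(validate_grsdm(missing, gbv, val$sheet)$verdict, "untestable")
})

test_that("ridge prediction recovers a noise-free linear model and shrinks to the mean", {
  set.seed(23)
  genes <- paste0("g", 1:10)
  lines <- paste0("l", 1:40)
  samples <- paste0("s", 1:15)
  x <- matrix(rnorm(400), 10, 40, dimnames = list(genes, lines))
  xs <- matrix(rnorm(150), 10, 15, dimnames = list(genes, samples))
  w <- rnorm(10)
  ic50 <- cbind(drugA = drop(crossprod(x, w)))
  panel <- list(cellline_expression = x, ic50 = ic50, sample_expression = xs)
  fit <- ridge_ic50_predict(panel, lambda = 1e-8)
  truth <- drop(crossprod(xs, w))
  expect_equal(unname(fit$predictions[, "drugA"]), unname(truth),
    tolerance = 1e-6
  )
  # lambda -> Inf: predictions converge to the training-mean IC50
  fit_inf <- ridge_ic50_predict(panel, lambda = 1e12)
  expect_equal(
    unname(fit_inf$predictions[, "drugA"]),
    rep(mean(ic50), 15),
    tolerance = 1e-6
  )
  expect_error(ridge_ic50_predict(panel, lambda = -1), "positive")
  expect_error(ridge_ic50_predict(panel, lambda = 0), "positive")
  # tidy/glance surface
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 15L)
  expect_identical(glance(fit)$n_drugs, 1L)
})

test_that("drug correlation hits exactly the strict negative-correlation conjunction", {
  beta <- matrix(seq(0.1, 0.9, length.out = 12), 1, 12,
    dimnames = list("g1", paste0("s", 1:12))
  )
  dec <- matrix(rev(seq_len(12)), 12, 1,
    dimnames = list(paste0("s", 1:12), "drugA")
  )
  res <- drug_correlation(beta, dec)
  expect_equal(res$rho, -1)
  expect_true(res$passes)
  inc <- matrix(seq_len(12), 12, 1,
    dimnames = list(paste0("s", 1:12), "drugA")
  )
  res2 <- drug_correlation(beta, inc)
  expect_equal(res2$rho, 1)
  expect_false(res2$passes) # positive correlation is never a hit
  # rho exactly -0.4 fails the strict inequality regardless of p
  b4 <- matrix(1:4 / 10, 1, 4, dimnames = list("g1", paste0("s", 1:4)))
  i4 <- matrix(c(3, 2, 4, 1), 4, 1,
    dimnames = list(paste0("s", 1:4), "drugA")
  )
  res3 <- drug_correlation(b4, i4, min_pairs = 4)
  expect_equal(res3$rho, -0.4, tolerance = 1e-12)
  expect_false(res3$passes)
  # constant vectors are skipped with a warning
  bc <- rbind(beta, g2 = rep(0.5, 12))
  rownames(bc) <- c("g1", "g2")
  expect_warning(res4 <- drug_correlation(bc, dec), "constant")
  expect_identical(res4$gene, "g1")
})

test_that("multi-class AUC object carries per-class and macro summaries", {
  cfg <- small_config(seed = 19)
  ann <- generate_annotation(cfg)
  coh <- generate_cohort(cfg, ann)
  sheet <- split_samples(coh$sheet, seed = 4)
  gb <- aggregate_to_genes(coh$beta, ann)
  mc <- rf_multiclass_auc(gb, sheet,
    genes = coh$truth$specific_gene_map$gene, seed = 2
  )
  expect_s3_class(mc, "multiclass_auc")
  expect_identical(nrow(mc$per_class), 3L)
  expect_true(all(mc$per_class$auc >= 0 & mc$per_class$auc <= 1))
  expect_equal(mc$macro_auc, mean(mc$per_class$auc))
  # deterministic under seed
  mc2 <- rf_multiclass_auc(gb, sheet,
    genes = coh$truth$specific_gene_map$gene, seed = 2
  )
  expect_identical(mc$macro_auc, mc2$macro_auc)
  expect_s3_class(autoplot(mc), "ggplot")
  expect_identical(glance(mc)$n_classes, 3L)
})
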