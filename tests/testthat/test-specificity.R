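test_that("every cell of the specificity table matches brute-force evaluation", {
  fix <- toy_gene_beta(n_genes = 3, n_cancers = 3, n_samples = 4)
  res <- identify_grsdm(fix$gene_beta, fix$sheet)
  oracle <- brute_force_specificity(fix$gene_beta, fix$sheet)
  for (g in rownames(fix$gene_beta)) {
    for (cn in unique(fix$sheet$cancer_type)) {
      for (col in c("m", "p", "SD", "C", "T", "M")) {
        expect_equal(
          grsdm_cell(res, g, cn, col), oracle[[col]][g, cn],
          tolerance = 1e-10,
          label = sprintf("%s[%s, %s]", col, g, cn)
        )
      }
      expect_equal(grsdm_cell(res, g, cn, "mbar"),
        oracle$mbar[[cn]],
        tolerance = 1e-10
      )
    }
    expect_equal(grsdm_cell(res, g, "ca1", "H"), oracle$H[[match(g, rownames(fix$gene_beta))]],
      tolerance = 1e-10
    )
    expect_equal(grsdm_cell(res, g, "ca1", "Xbar"),
      oracle$Xbar[[match(g, rownames(fix$gene_beta))]],
      tolerance = 1e-10
    )
    expect_identical(
      res$assignments$cancer_type[res$assignments$gene == g],
      unname(oracle$assigned[g])
    )
  }
})

test_that("entropy attains its extremes and matches direct evaluation", {
  expect_identical(shannon_entropy(c(0.25, 0.25, 0.25, 0.25)), 2)
  expect_identical(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(rep(1 / 8, 8)), 3, tolerance = 1e-12)
  # direct evaluation: -(0.8 log2 0.8 + 2 * 0.1 log2 0.1)
  expect_equal(
    shannon_entropy(c(0.8, 0.1, 0.1)),
    -(0.8 * log2(0.8) + 0.2 * log2(0.1)),
    tolerance = 1e-12
  )
  expect_equal(shannon_entropy(c(0.8, 0.1, 0.1)), 0.9219281, tolerance = 1e-6)
  expect_error(shannon_entropy(c(-0.1, 1.1)), "non-negative")
  expect_error(shannon_entropy(c(0.4, 0.4)), "sum to 1")
})

test_that("relative probabilities are row-stochastic and drop all-zero genes", {
  m <- rbind(
    g1 = c(0.3, 0.3, 0.3),
    g2 = c(0.8, 0.1, 0.1),
    g3 = c(0.6, 0.2, 0)
  )
  colnames(m) <- paste0("ca", 1:3)
  p <- relative_probabilities(m)
  expect_equal(unname(p["g1", ]), rep(1 / 3, 3))
  expect_equal(unname(p["g2", ]), c(0.8, 0.1, 0.1))
  expect_equal(unname(rowSums(p)), rep(1, 3))
  m0 <- rbind(m, g4 = c(0, 0, 0))
  expect_warning(p0 <- relative_probabilities(m0), "all-zero")
  expect_false("g4" %in% rownames(p0))
})

test_that("specificity score is linear in m and floors tiny coefficients of variation", {
  h <- c(g1 = 1)
  m <- matrix(0.5, 1, 1, dimnames = list("g1", "ca1"))
  cv <- matrix(50, 1, 1, dimnames = list("g1", "ca1"))
  t1 <- specificity_score(h, m, cv, c(ca1 = 0.5))
  expect_equal(unname(t1[1, 1]), 0.02, tolerance = 1e-12)
  t2 <- specificity_score(h, 2 * m, cv, c(ca1 = 0.5))
  expect_equal(unname(t2[1, 1]), 2 * unname(t1[1, 1]), tolerance = 1e-12)
  expect_warning(
    t3 <- specificity_score(h, m, matrix(0, 1, 1), c(ca1 = 0.5)),
    "floored"
  )
  expect_true(is.finite(t3[1, 1]))
})

test_that("dissociation scores satisfy their algebraic identities", {
  t_mat <- matrix(c(0.9, 0.1, 0.2), 1,
    dimnames = list("g1", paste0("ca", 1:3))
  )
  d <- dissociation_score(t_mat)
  expect_equal(unname(d$xbar), 0.4)
  expect_equal(unname(d$m_score[1, ]), c(0.625, -0.375, -0.25))
  expect_equal(sum(d$m_score[1, ]), 0, tolerance = 1e-12)
  expect_identical(d$assignment$cancer_type, "ca1")
  # property over random matrices: sum 0, |M| <= 1, argmax M == argmax T
  set.seed(12)
  for (rep in 1:20) {
    tm <- matrix(runif(40, 0, 5), 8, 5,
      dimnames = list(paste0("g", 1:8), paste0("ca", 1:5))
    )
    dd <- dissociation_score(tm)
    expect_equal(unname(rowSums(dd$m_score)), rep(0, 8), tolerance = 1e-12)
    expect_true(all(abs(dd$m_score) <= 1 + 1e-12))
    expect_identical(
      max.col(dd$m_score, ties.method = "first"),
      max.col(tm, ties.method = "first")
    )
  }
  # constant rows are excluded as non-specific
  tc <- matrix(1, 2, 3, dimnames = list(c("g1", "g2"), paste0("ca", 1:3)))
  tc[2, ] <- c(1, 2, 3)
  expect_warning(dc <- dissociation_score(tc), "constant")
  expect_identical(dc$assignment$gene, "g2")
})

test_that("grsdm identification is equivariant under cancer relabeling", {
  fix <- toy_gene_beta(n_genes = 5, n_cancers = 3, n_samples = 5)
  res <- identify_grsdm(fix$gene_beta, fix$sheet)
  relabel <- c(ca1 = "zz1", ca2 = "zz2", ca3 = "zz3")
  sheet2 <- fix$sheet
  sheet2$cancer_type <- unname(relabel[sheet2$cancer_type])
  res2 <- identify_grsdm(fix$gene_beta, sheet2)
  expect_identical(
    unname(relabel[res$assignments$cancer_type]),
    res2$assignments$cancer_type
  )
  expect_identical(res$assignments$gene, res2$assignments$gene)
  expect_equal(res$assignments$M, res2$assignments$M, tolerance = 1e-12)
})

test_that("grsdm identification rejects a single cancer type", {
  fix <- toy_gene_beta(n_genes = 3, n_cancers = 1, n_samples = 5)
  expect_error(identify_grsdm(fix$gene_beta, fix$sheet), "single cancer")
})

test_that("scaling one gene's betas scales m and SD but not p or H", {
  fix <- toy_gene_beta(n_genes = 4, n_cancers = 3, n_samples = 5)
  gb2 <- fix$gene_beta
  gb2["g1", ] <- 0.5 * gb2["g1", ]
  r1 <- identify_grsdm(fix$gene_beta, fix$sheet)
  r2 <- identify_grsdm(gb2, fix$sheet)
  for (cn in paste0("ca", 1:3)) {
    expect_equal(grsdm_cell(r2, "g1", cn, "m"),
      0.5 * grsdm_cell(r1, "g1", cn, "m"),
      tolerance = 1e-12
    )
    expect_equal(grsdm_cell(r2, "g1", cn, "SD"),
      0.5 * grsdm_cell(r1, "g1", cn, "SD"),
      tolerance = 1e-12
    )
    expect_equal(grsdm_cell(r2, "g1", cn, "p"),
      grsdm_cell(r1, "g1", cn, "p"),
      tolerance = 1e-12
    )
  }
  expect_equal(grsdm_cell(r2, "g1", "ca1", "H"),
    grsdm_cell(r1, "g1", "ca1", "H"),
    tolerance = 1e-12
  )
})

test_that("tidy, glance and autoplot expose the result surface", {
  fix <- toy_gene_beta()
  res <- identify_grsdm(fix$gene_beta, fix$sheet)
  tab <- tidy(res)
  expect_s3_class(tab, "tbl_df")
  expect_true(all(
    c("gene", "cancer_type", "m", "p", "H", "SD", "C", "T", "Xbar", "M", "assigned") %in%
      names(tab)
  ))
  expect_identical(sum(tab$assigned), nrow(res$assignments))
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_cancers, 3L)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
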