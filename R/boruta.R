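#' Configuration for the Boruta feature-selection loop
#'
#' @param n_iterations Maximum Boruta iterations (default 100, minimum 10).
#' @param alpha Significance level of the binomial hit tests (default 0.05).
#' @param forest_size Trees per random forest (default 200).
#' @param seed Integer seed; drives both shadow permutations and forests.
#' @return A list of class `boruta_config`.
#' @export
boruta_config <- function(n_iterations = 100, alpha = 0.05,
                          forest_size = 200, seed = 1L) {
  stopifnot(n_iterations >= 10, alpha > 0, alpha < 1, forest_size >= 10)
  structure(
    list(
      n_iterations = as.integer(n_iterations), alpha = alpha,
      forest_size = as.integer(forest_size), seed = as.integer(seed)
    ),
    class = "boruta_config"
  )
}

#' Boruta all-relevant feature selection
#'
#' Native implementation of the Boruta procedure. Each iteration permutes
#' still-in-play features into "shadow" copies — the shadow ensemble is kept
#' at the full initial feature count (at least five) throughout, so the
#' max-shadow bar stays the best of that many permutations even after
#' rejections shrink the real feature set — fits a random forest on real
#' plus shadow features, and scores a "hit" for a real feature whose
#' impurity importance exceeds the maximum shadow importance. Hits accumulate across iterations; a Bonferroni-
#' corrected two-sided binomial test against chance (probability 1/2)
#' confirms features with significantly many hits and rejects features with
#' significantly few. Rejected features leave the forest. Features still
#' tentative after `n_iterations` are resolved by the median-importance
#' "rough fix": confirmed if their median importance across iterations beats
#' the median of the per-iteration best-shadow importance.
#'
#' @param x Features x samples numeric matrix with feature-id rownames.
#' @param y Binary labels, one per sample (factor or coercible).
#' @param cfg A [boruta_config()].
#' @return A tibble: `feature_id`, `status` (`confirmed` / `rejected` /
#'   `tentative`), `hit_count`, `n_trials`, `median_importance`,
#'   `rough_fixed`; the per-iteration importance record is attached as
#'   attribute `importance_history` (iterations x features matrix) together
#'   with `shadow_max_history`.
#' @export
boruta_select <- function(x, y, cfg = boruta_config()) {
  stopifnot(inherits(cfg, "boruta_config"), nrow(x) >= 1)
  y <- factor(y)
  if (nlevels(y) != 2L) {
    stop("labels must contain exactly two classes", call. = FALSE)
  }
  if (min(table(y)) < 2L) {
    stop("need >= 2 samples per class", call. = FALSE)
  }
  feats <- rownames(x)
  if (is.null(feats)) feats <- paste0("f", seq_len(nrow(x)))
  n_feat <- length(feats)
  xs <- t(x) # samples x features for the forest

  with_seed(cfg$seed, {
    status <- stats::setNames(rep("tentative", n_feat), feats)
    hits <- stats::setNames(rep(0L, n_feat), feats)
    trials <- stats::setNames(rep(0L, n_feat), feats)
    imp_hist <- matrix(NA_real_, cfg$n_iterations, n_feat,
      dimnames = list(NULL, feats)
    )
    shadow_max <- rep(NA_real_, cfg$n_iterations)

    n_shadow <- max(n_feat, 5L)
    for (iter in seq_len(cfg$n_iterations)) {
      in_play <- feats[status != "rejected"]
      if (!any(status == "tentative")) break
      real <- xs[, in_play, drop = FALSE]
      shadow_src <- in_play[rep_len(seq_along(in_play), n_shadow)]
      shadow <- sapply(shadow_src, function(f) sample(xs[, f]))
      colnames(shadow) <- paste0("shadow_", seq_len(n_shadow))
      fit <- ranger::ranger(
        x = cbind(real, shadow), y = y,
        num.trees = cfg$forest_size, importance = "impurity",
        classification = TRUE, num.threads = 1,
        seed = sample.int(.Machine$integer.max, 1)
      )
      imp <- fit$variable.importance
      smax <- max(imp[colnames(shadow)])
      shadow_max[iter] <- smax
      imp_hist[iter, in_play] <- imp[in_play]
      hit <- imp[in_play] > smax
      hits[in_play] <- hits[in_play] + as.integer(hit)
      trials[in_play] <- trials[in_play] + 1L

      tent <- feats[status == "tentative"]
      p_conf <- pbinom(hits[tent] - 1L, trials[tent], 0.5, lower.tail = FALSE)
      p_rej <- pbinom(hits[tent], trials[tent], 0.5)
      status[tent[p_conf * n_feat < cfg$alpha]] <- "confirmed"
      status[tent[p_rej * n_feat < cfg$alpha]] <- "rejected"
    }

    med_imp <- apply(imp_hist, 2, median, na.rm = TRUE)
    med_shadow <- median(shadow_max, na.rm = TRUE)
    rough <- status == "tentative"
    status[rough & med_imp > med_shadow] <- "confirmed"
    status[rough & !(med_imp > med_shadow)] <- "rejected"

    out <- tibble::tibble(
      feature_id = feats,
      status = unname(status),
      hit_count = unname(hits),
      n_trials = unname(trials),
      median_importance = unname(med_imp),
      rough_fixed = unname(rough)
    )
    attr(out, "importance_history") <- imp_hist
    attr(out, "shadow_max_history") <- shadow_max
    out
  })
}

#' Decision-tree tumor/normal classification AUC
#'
#' Trains a CART tree (Gini impurity, unrestricted depth, no internal
#' cross-validation) on the training features and reports the area under the
#' ROC curve of its class probabilities on the test set.
#'
#' @param x_train,x_test Features x samples matrices.
#' @param y_train,y_test Binary labels.
#' @return AUC in \[0, 1\].
#' @export
decision_tree_auc <- function(x_train, y_train, x_test, y_test) {
  y_train <- factor(y_train)
  if (nlevels(y_train) != 2L) {
    stop("training labels must contain both classes", call. = FALSE)
  }
  y_test <- factor(y_test, levels = levels(y_train))
  if (length(unique(y_test)) < 2L) {
    stop("test set contains a single class; AUC undefined", call. = FALSE)
  }
  df_train <- as.data.frame(t(x_train))
  df_train$.y <- y_train
  fit <- rpart::rpart(.y ~ .,
    data = df_train, method = "class",
    control = rpart::rpart.control(
      xval = 0, cp = 0, minsplit = 2, minbucket = 1
    )
  )
  prob <- predict(fit, as.data.frame(t(x_test)))[, levels(y_train)[2]]
  auc_rank(y_test == levels(y_train)[2], prob)
}

# AUC via pROC; direction fixed so reversed scores give 1 - AUC
auc_rank <- function(positive, score) {
  stopifnot(any(positive), any(!positive))
  roc <- pROC::roc(
    response = factor(positive, levels = c(FALSE, TRUE)),
    predictor = score, quiet = TRUE, direction = "<"
  )
  as.numeric(pROC::auc(roc))
}

#' Characteristic GPCR-related gene set across cancers
#'
#' Maps each cancer's Boruta-confirmed features (probes) to genes, takes the
#' union over cancers, and intersects it with the supplied GPCR-related gene
#' list.
#'
#' @param verdicts Named list of [boruta_select()] results, one per cancer.
#' @param ann Probe annotation (`probe_id`, `gene`).
#' @param gpcr_genes Character vector of GPCR-related genes.
#' @return Sorted character vector of characteristic GPCR-related genes;
#'   empty with a warning if the intersection is empty.
#' @export
characteristic_gene_union <- function(verdicts, ann, gpcr_genes) {
  confirmed <- unique(unlist(purrr::map(verdicts, function(v) {
    v$feature_id[v$status == "confirmed"]
  })))
  genes <- unique(ann$gene[match(confirmed, ann$probe_id)])
  genes <- genes[!is.na(genes)]
  out <- sort(intersect(genes, gpcr_genes))
  if (length(out) == 0L) {
    warning("no characteristic genes intersect the GPCR-related list")
  }
  out
}
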