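#' Restrict a beta matrix to promoter-region probes
#'
#' Keeps probes whose position falls in the strand-aware promoter window
#' around the annotated TSS. With upstream `u` and downstream `d`, a probe
#' with signed offset `off` from the TSS in the direction of transcription
#' (`pos - tss` on `+`, `tss - pos` on `-`) is retained iff
#' `-u <= off < d` — the window is closed at the upstream edge and open at
#' the downstream edge. Probe order is preserved.
#'
#' @param beta Probes x samples beta matrix with probe-id rownames.
#' @param ann Probe annotation tibble (`probe_id`, `strand`, `pos`, `tss`).
#' @param upstream,downstream Window extents in bp (defaults 2000 and 500).
#' @return The subsetted beta matrix.
#' @export
promoter_filter <- function(beta, ann, upstream = 2000, downstream = 500) {
  stopifnot(upstream >= 0, downstream >= 0)
  idx <- match(rownames(beta), ann$probe_id)
  if (anyNA(idx)) {
    stop("probes missing from the annotation: ",
      paste(head(rownames(beta)[is.na(idx)], 3), collapse = ", "),
      call. = FALSE
    )
  }
  strand <- ann$strand[idx]
  if (any(!strand %in% c("+", "-"))) {
    stop("probe with unknown strand in annotation", call. = FALSE)
  }
  off <- ifelse(strand == "+",
    ann$pos[idx] - ann$tss[idx],
    ann$tss[idx] - ann$pos[idx]
  )
  keep <- off >= -upstream & off < downstream
  beta[keep, , drop = FALSE]
}

#' Drop probes with excessive missingness
#'
#' A probe is removed when its count of missing betas strictly exceeds
#' `max_missing_frac` of the number of samples; a probe sitting exactly on
#' the boundary is kept.
#'
#' @param beta Probes x samples beta matrix.
#' @param max_missing_frac Maximum tolerated missing fraction (default 0.7).
#' @return The filtered beta matrix.
#' @export
filter_missing <- function(beta, max_missing_frac = 0.7) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1)
  keep <- rowSums(is.na(beta)) <= max_missing_frac * ncol(beta)
  out <- beta[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    stop("no probes survive the missingness filter", call. = FALSE)
  }
  out
}

#' KNN imputation of missing beta values
#'
#' Fills each missing entry with the unweighted mean, at that sample, of the
#' `k` nearest probes. Distance between two probes is the root mean squared
#' difference over their jointly observed samples; only probes observed at
#' the target sample are candidates, and distance ties break by probe order
#' so the result is deterministic. Observed entries are never altered.
#'
#' @param beta Probes x samples beta matrix.
#' @param k Number of neighbor probes (default 10).
#' @return The completed matrix; all values in \[0, 1\].
#' @export
knn_impute <- function(beta, k = 10) {
  stopifnot(k >= 1)
  obs <- !is.na(beta)
  if (any(rowSums(obs) == 0L)) {
    stop("probe with no observed values cannot be imputed", call. = FALSE)
  }
  if (all(obs)) {
    return(beta)
  }
  n <- nrow(beta)
  x0 <- beta
  x0[!obs] <- 0
  o <- obs * 1
  # pairwise mean squared difference over jointly observed samples:
  # sum_shared (xi - xj)^2 = sum xi^2*oj + sum xj^2*oi - 2 sum xi xj
  a <- tcrossprod(x0^2, o)
  b <- tcrossprod(x0)
  nshared <- tcrossprod(o)
  d2 <- (a + t(a) - 2 * b) / nshared
  d2[nshared == 0] <- Inf
  diag(d2) <- Inf

  out <- beta
  need <- which(rowSums(!obs) > 0L)
  for (i in need) {
    # stable ordering: ties by probe index
    ord <- order(d2[i, ], seq_len(n))
    for (s in which(!obs[i, ])) {
      cand <- ord[obs[ord, s] & is.finite(d2[i, ord])]
      if (length(cand) == 0L) {
        stop(sprintf(
          "no informative neighbors for probe %s at sample %s",
          rownames(beta)[i], colnames(beta)[s]
        ), call. = FALSE)
      }
      nb <- cand[seq_len(min(k, length(cand)))]
      out[i, s] <- mean(beta[nb, s])
    }
  }
  out
}

#' Harmonize batches by per-probe location-scale adjustment
#'
#' For each probe, every batch's values are standardized with that batch's
#' mean and SD (population form, denominator `n`, so that identical batches
#' are a fixed point) and rescaled to the probe's pooled mean and SD, removing
#' between-batch location and scale differences while preserving
#' within-batch rank order. A batch with zero SD at a probe is shifted to
#' the pooled mean without rescaling. Output is clipped to \[0, 1\].
#'
#' This is a deliberately simple bridge between cohorts: a per-probe
#' location-scale alignment with no hierarchical shrinkage across probes.
#'
#' @param beta Probes x samples beta matrix (no missing values).
#' @param sheet Sample sheet supplying the `batch` of each sample.
#' @return The adjusted matrix.
#' @export
batch_adjust <- function(beta, sheet) {
  stopifnot(all(colnames(beta) %in% sheet$sample_id))
  batch <- sheet$batch[match(colnames(beta), sheet$sample_id)]
  batches <- unique(batch)
  if (length(batches) < 2L) {
    warning("single batch: returning input unchanged")
    return(beta)
  }
  if (any(table(batch) < 2L)) {
    stop("every batch needs >= 2 samples", call. = FALSE)
  }
  # population (1/n) SDs so that identical batches are a fixed point
  row_sd_pop <- function(x) {
    sqrt(rowMeans((x - rowMeans(x))^2))
  }
  pooled_mean <- rowMeans(beta)
  pooled_sd <- row_sd_pop(beta)
  out <- beta
  for (b in batches) {
    cols <- which(batch == b)
    bm <- rowMeans(beta[, cols, drop = FALSE])
    bs <- row_sd_pop(beta[, cols, drop = FALSE])
    scale_fac <- ifelse(bs > 0, pooled_sd / bs, 1)
    out[, cols] <- (beta[, cols, drop = FALSE] - bm) * scale_fac + pooled_mean
  }
  clip01(out)
}

#' Stratified train/test split of a sample sheet
#'
#' Assigns each sample to `train` or `test`, stratified within every
#' cancer-by-tissue stratum: `round(train_frac * n)` samples of a stratum of
#' size `n` go to training. A stratum of size 1 is assigned wholly to
#' training with a warning. Deterministic given `seed`.
#'
#' @param sheet Sample sheet tibble.
#' @param train_frac Training fraction in (0, 1); default 0.7 for a 7:3
#'   split.
#' @param seed Integer seed.
#' @return The sheet with its `split` column filled.
#' @export
split_samples <- function(sheet, train_frac = 0.7, seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  with_seed(seed, {
    sheet$split <- NA_character_
    strata <- split(
      seq_len(nrow(sheet)),
      paste(sheet$cancer_type, sheet$tissue)
    )
    for (idx in strata) {
      n <- length(idx)
      if (n == 1L) {
        warning("stratum of size 1 assigned wholly to train")
        sheet$split[idx] <- "train"
        next
      }
      n_train <- round(train_frac * n)
      tr <- sample(idx, n_train)
      sheet$split[tr] <- "train"
      sheet$split[setdiff(idx, tr)] <- "test"
    }
    sheet
  })
}
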