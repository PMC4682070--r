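# Hierarchy of heterogeneity: spatial clonal structure, proximity
# correlation with permutation nulls, variance decomposition across
# cellular conditions, heritable-variation CV, and the three-feature
# metastatic-signature classification.

#' Identify spatial colonies (clones) by single-linkage clustering
#'
#' Cells grown from sparse seeding form spatially distinct colonies;
#' single-linkage clustering with cutoff `linkage_distance` recovers them
#' from cell positions. Colonies with fewer than `min_size` members are
#' left unassigned (NA).
#'
#' @param records data.frame with global positions `x`, `y`.
#' @param linkage_distance merge cutoff in the position units.
#' @param min_size minimum colony size (default 5).
#' @return Integer vector of colony ids (NA = unassigned), in record
#'   order.
#' @export
identify_colonies <- function(records, linkage_distance, min_size = 5L) {
  if (is.null(records$x) || is.null(records$y) || any(is.na(records$x)))
    stop("records must carry positions", call. = FALSE)
  n <- nrow(records)
  if (n == 1L) return(NA_integer_)
  hc <- stats::hclust(stats::dist(cbind(records$x, records$y)),
                      method = "single")
  cl <- stats::cutree(hc, h = linkage_distance)
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  out <- rep(NA_integer_, n)
  for (i in seq_along(keep)) out[cl == keep[i]] <- i
  out
}

#' Pairwise proximity correlation with a permutation null band
#'
#' For every unordered cell pair whose separation falls in a distance bin,
#' the two feature values enter the Pearson correlation with symmetric
#' duplication (each pair contributes both orderings), making the
#' estimator exchangeable. The null band is the 2.5/97.5 percentile of
#' the per-bin correlations after randomly permuting feature values across
#' cells.
#'
#' @param records data.frame with `x`, `y` and the feature column.
#' @param feature `"R_N"` or `"R_C"`.
#' @param distance_bins numeric vector of bin breaks (length >= 3).
#' @param n_permutations number of permutations (>= 100, default 1000).
#' @param seed integer seed for the permutations.
#' @param phase_filter optional phase (e.g. `"G0G1"`) to restrict cells.
#' @return data.frame: bin_lo, bin_hi, n_pairs, r, null_lo, null_hi (NA
#'   rows for empty bins).
#' @export
proximity_correlation <- function(records, feature = "R_N",
                                  distance_bins, n_permutations = 1000L,
                                  seed = 1L, phase_filter = NULL) {
  if (length(distance_bins) < 3L)
    stop("need at least 2 distance bins", call. = FALSE)
  if (n_permutations < 100L)
    stop("need at least 100 permutations", call. = FALSE)
  if (!is.null(phase_filter))
    records <- records[records$phase %in% phase_filter, , drop = FALSE]
  v <- records[[feature]]
  n <- length(v)
  d <- as.matrix(stats::dist(cbind(records$x, records$y)))
  iu <- which(upper.tri(d), arr.ind = TRUE)
  pd <- d[iu]
  bin <- cut(pd, distance_bins, labels = FALSE)
  nb <- length(distance_bins) - 1L

  bin_cor <- function(vals) {
    vapply(seq_len(nb), function(b) {
      sel <- which(bin == b)
      if (length(sel) < 3L) return(NA_real_)
      a <- vals[iu[sel, 1L]]; bb <- vals[iu[sel, 2L]]
      suppressWarnings(stats::cor(c(a, bb), c(bb, a)))
    }, numeric(1))
  }
  r_obs <- bin_cor(v)
  set.seed(as.integer(seed))
  null_mat <- matrix(NA_real_, n_permutations, nb)
  for (p in seq_len(n_permutations))
    null_mat[p, ] <- bin_cor(v[sample.int(n)])
  data.frame(bin_lo = distance_bins[-length(distance_bins)],
             bin_hi = distance_bins[-1L],
             n_pairs = as.integer(tabulate(bin, nb)),
             r = r_obs,
             null_lo = apply(null_mat, 2L, stats::quantile, 0.025,
                             na.rm = TRUE, names = FALSE),
             null_hi = apply(null_mat, 2L, stats::quantile, 0.975,
                             na.rm = TRUE, names = FALSE))
}

#' Variance decomposition of size across cellular conditions
#'
#' Population variance of each size feature within condition subsets
#' (all cells, singlets, crowded, G0/G1, G2/M) and the within-clone
#' variance (mean over colonies with >= `min_size` members of the
#' within-colony variance, for all cells and for G0/G1 cells), every entry
#' scaled by the all-population variance so the "all" entry is exactly 1.
#'
#' @param records data.frame with `R_N`, `R_C`, `phase`,
#'   `density_category`, `colony_id`.
#' @param features size columns to decompose (default R_N, R_C).
#' @param min_size minimum colony size (default 5).
#' @return Long data.frame: feature, condition, scaled_variance, n
#'   (NA scaled_variance when a subset is unavailable).
#' @export
variance_decomposition <- function(records, features = c("R_N", "R_C"),
                                   min_size = 5L) {
  subset_var <- function(v) if (length(v) >= 2L) stats::var(v) else NA_real_
  within_clone <- function(sub) {
    ok <- !is.na(sub$colony_id)
    sub <- sub[ok, , drop = FALSE]
    if (!nrow(sub)) return(c(NA_real_, 0L))
    sizes <- table(sub$colony_id)
    keep <- names(sizes)[sizes >= min_size]
    if (!length(keep)) return(c(NA_real_, 0L))
    vs <- vapply(keep, function(cid)
      stats::var(sub$value[sub$colony_id == cid]), numeric(1))
    c(mean(vs), sum(sizes[keep]))
  }
  out <- list()
  for (f in features) {
    rec <- records
    rec$value <- rec[[f]]
    v_all <- subset_var(rec$value)
    if (!is.finite(v_all) || v_all <= 0)
      stop("all-population variance of ", f, " is not positive",
           call. = FALSE)
    entry <- function(condition, sel) {
      v <- rec$value[sel]
      data.frame(feature = f, condition = condition,
                 scaled_variance = subset_var(v) / v_all,
                 n = length(v), stringsAsFactors = FALSE)
    }
    rows <- list(
      entry("all", rep(TRUE, nrow(rec))),
      entry("singlet", rec$density_category == "singlet"),
      entry("crowded", rec$density_category == "crowded"),
      entry("G0G1", rec$phase == "G0G1"),
      entry("G2M", rec$phase == "G2M"))
    wc_all <- within_clone(rec)
    rows[[length(rows) + 1L]] <-
      data.frame(feature = f, condition = "within_clone_all",
                 scaled_variance = wc_all[1L] / v_all, n = wc_all[2L],
                 stringsAsFactors = FALSE)
    wc_g1 <- within_clone(rec[rec$phase == "G0G1", , drop = FALSE])
    rows[[length(rows) + 1L]] <-
      data.frame(feature = f, condition = "within_clone_G0G1",
                 scaled_variance = wc_g1[1L] / v_all, n = wc_g1[2L],
                 stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

#' Heritable variation: CV of colony-mean sizes
#'
#' Between-clone (heritable) phenotype variation is measured as the
#' coefficient of variation of the per-colony mean nucleus and cell size,
#' optionally restricted to G0/G1 cells to exclude cell-cycle effects.
#'
#' @param records data.frame with `R_N`, `R_C`, `colony_id`, `phase`.
#' @param phase_filter optional phase restriction (e.g. `"G0G1"`).
#' @param min_size minimum colony size (default 5).
#' @return Named numeric vector `c(R_N =, R_C =)` of CVs across colony
#'   means; errors if fewer than 3 qualifying colonies.
#' @export
heritable_variation <- function(records, phase_filter = NULL, min_size = 5L) {
  if (!is.null(phase_filter))
    records <- records[records$phase %in% phase_filter, , drop = FALSE]
  records <- records[!is.na(records$colony_id), , drop = FALSE]
  sizes <- table(records$colony_id)
  keep <- names(sizes)[sizes >= min_size]
  if (length(keep) < 3L)
    stop("need at least 3 colonies with >= min_size cells", call. = FALSE)
  out <- vapply(c("R_N", "R_C"), function(f) {
    means <- vapply(keep, function(cid)
      mean(records[[f]][records$colony_id == cid]), numeric(1))
    coefficient_of_variation(means)
  }, numeric(1))
  out
}

#' Three-feature heterogeneity signature of one sample
#'
#' CV of nucleus size among clustered cells (rho_D > 0), CV of cell size
#' among singlet cells (rho_D = 0), and Shannon entropy of nucleus shape
#' modes among singlet cells -- the subpopulation-conditioned features in
#' which metastasis-derived and primary-tumor-derived samples separate
#' most clearly.
#'
#' @param records cell records of one sample (`R_N`, `R_C`,
#'   `density_category`, `nucleus_mode`).
#' @param K_N global number of nucleus modes.
#' @return Named numeric vector: cv_nucleus_size_clustered,
#'   cv_cell_size_singlet, entropy_nucleus_shape_singlet.
#' @export
signature_features <- function(records, K_N) {
  records <- records[!is.na(records$density_category), , drop = FALSE]
  clustered <- records[records$density_category != "singlet", , drop = FALSE]
  singlet <- records[records$density_category == "singlet", , drop = FALSE]
  cvn <- if (nrow(clustered) >= 2L)
    coefficient_of_variation(clustered$R_N) else NA_real_
  cvc <- if (nrow(singlet) >= 2L)
    coefficient_of_variation(singlet$R_C) else NA_real_
  ent <- if (nrow(singlet) >= 1L) {
    p <- as.numeric(table(factor(singlet$nucleus_mode,
                                 levels = seq_len(K_N)))) / nrow(singlet)
    shannon_entropy(p)
  } else NA_real_
  c(cv_nucleus_size_clustered = cvn, cv_cell_size_singlet = cvc,
    entropy_nucleus_shape_singlet = ent)
}

#' Signature-based classification with subsampling cross-validation
#'
#' For each subsample size and repeat, the stated number of cells is drawn
#' from every sample, the three signature features are recomputed on the
#' subsample, and each sample is classified by leave-one-sample-out
#' nearest-centroid on z-scored features (z-scoring and centroids from the
#' training samples only). Reports the mean accuracy per subsample size.
#'
#' @param records multi-sample cell records (`sample_id` plus the
#'   signature columns).
#' @param group_labels named character vector: class label per sample_id
#'   (>= 2 samples per class).
#' @param subsample_sizes integer vector of per-sample cell counts to
#'   test.
#' @param n_repeats random subsampling repeats per size (default 20).
#' @param seed integer seed.
#' @param K_N global number of nucleus modes.
#' @return List with `signatures` (full-sample feature data.frame),
#'   `accuracy` (data.frame: subsample_size, mean_accuracy, sd_accuracy).
#' @export
signature_and_classification <- function(records, group_labels,
                                         subsample_sizes, n_repeats = 20L,
                                         seed = 1L, K_N = NULL) {
  sids <- names(group_labels)
  if (is.null(sids)) stop("group_labels must be named by sample_id",
                          call. = FALSE)
  if (any(table(group_labels) < 2L))
    stop("leave-one-sample-out needs >= 2 samples per class", call. = FALSE)
  if (is.null(K_N)) K_N <- max(records$nucleus_mode)
  per_sample <- lapply(sids, function(s)
    records[records$sample_id == s, , drop = FALSE])
  names(per_sample) <- sids
  avail <- vapply(per_sample, nrow, integer(1))
  if (any(subsample_sizes > min(avail)))
    stop("subsample sizes exceed available cells", call. = FALSE)

  feats_of <- function(tabs) {
    m <- t(vapply(tabs, signature_features, numeric(3), K_N = K_N))
    rownames(m) <- sids
    m
  }
  classify_loo <- function(m) {
    correct <- 0L
    for (i in seq_along(sids)) {
      tr <- m[-i, , drop = FALSE]
      mu <- colMeans(tr); sdv <- apply(tr, 2L, stats::sd)
      sdv[sdv == 0 | !is.finite(sdv)] <- 1
      z <- sweep(sweep(tr, 2L, mu), 2L, sdv, `/`)
      zt <- (m[i, ] - mu) / sdv
      cls <- unique(group_labels)
      cent <- t(vapply(cls, function(cl)
        colMeans(z[group_labels[-i] == cl, , drop = FALSE]), numeric(3)))
      d2 <- rowSums(sweep(cent, 2L, zt)^2)
      if (cls[which.min(d2)] == group_labels[i]) correct <- correct + 1L
    }
    correct / length(sids)
  }

  signatures <- as.data.frame(feats_of(per_sample))
  signatures$sample_id <- sids
  signatures$class_label <- unname(group_labels[sids])

  set.seed(as.integer(seed))
  acc <- lapply(subsample_sizes, function(sz) {
    accs <- vapply(seq_len(n_repeats), function(rep_i) {
      sub <- lapply(per_sample, function(tab)
        tab[sample.int(nrow(tab), sz), , drop = FALSE])
      feat_ok <- feats_of(sub)
      if (any(!is.finite(feat_ok))) return(NA_real_)
      classify_loo(feat_ok)
    }, numeric(1))
    data.frame(subsample_size = sz,
               mean_accuracy = mean(accs, na.rm = TRUE),
               sd_accuracy = stats::sd(accs[!is.na(accs)]))
  })
  list(signatures = signatures, accuracy = do.call(rbind, acc))
}
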