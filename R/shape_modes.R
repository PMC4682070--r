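# Shape modes: K-means clustering in eigenshape-score space, validity
# indices for choosing K, mode galleries and per-sample mode distributions.

#' Cluster validity indices for a hard clustering
#'
#' Xie-Beni index: total within-cluster squared scatter divided by n times
#' the minimum squared between-centroid distance (lower is better).
#' Separation index: the Dunn-style ratio of the minimum between-centroid
#' distance to the maximum cluster diameter (maximum within-cluster
#' pairwise distance; higher is better). A zero maximum diameter yields
#' the capped sentinel 1e12 so diagnostics stay finite.
#'
#' @param scores numeric n x m matrix of points.
#' @param centroids numeric K x m matrix of cluster centers.
#' @param labels integer vector in 1..K assigning each point to a cluster.
#' @return Named list with `xie_beni` and `separation`.
#' @export
cluster_validity <- function(scores, centroids, labels) {
  scores <- as.matrix(scores)
  centroids <- as.matrix(centroids)
  K <- nrow(centroids)
  if (K < 2L) stop("need at least 2 clusters", call. = FALSE)
  if (!all(seq_len(K) %in% labels))
    stop("invalid clustering: empty cluster", call. = FALSE)
  n <- nrow(scores)
  scatter <- sum((scores - centroids[labels, , drop = FALSE])^2)
  cd2 <- as.matrix(stats::dist(centroids))^2
  min_cd2 <- min(cd2[upper.tri(cd2)])
  xie_beni <- if (min_cd2 > 0) scatter / (n * min_cd2) else 1e12
  diam <- 0
  for (k in seq_len(K)) {
    pk <- scores[labels == k, , drop = FALSE]
    if (nrow(pk) > 1L) diam <- max(diam, max(stats::dist(pk)))
  }
  separation <- if (diam > 0) min(sqrt(min_cd2) / diam, 1e12) else 1e12
  list(xie_beni = xie_beni, separation = separation)
}

kmeans_restarts <- function(scores, K, seed, n_init) {
  set.seed(as.integer(seed))
  uniq <- unique(scores)
  if (nrow(uniq) < K) return(NULL)   # fewer distinct points than clusters
  best <- NULL
  for (i in seq_len(n_init)) {
    init <- uniq[sample.int(nrow(uniq), K), , drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(scores, centers = init,
                                     iter.max = 200L)),
      error = function(e) NULL)
    if (is.null(fit) || any(fit$size == 0L)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Select the number of shape modes by the Xie-Beni index
#'
#' Runs K-means (with `n_init` restarts at a fixed seed) for each K in
#' `k_min:k_max`, records the Xie-Beni and separation indices, and picks
#' the K minimizing Xie-Beni. The separation index is reported as a
#' tie-diagnostic only. A `low_confidence` flag is raised when the
#' Xie-Beni minimum is not a strict local minimum over the scanned range
#' (no clear cluster structure).
#'
#' @param scores numeric n x m score matrix.
#' @param k_min,k_max candidate range (k_min >= 2, k_max < n).
#' @param seed integer seed.
#' @param n_init K-means restarts per candidate K (default 20).
#' @return List with `k_best`, `diagnostics` (data.frame: K, xie_beni,
#'   separation, inertia), `low_confidence`.
#' @export
select_num_modes <- function(scores, k_min = 2L, k_max = 10L, seed = 1L,
                             n_init = 20L) {
  scores <- as.matrix(scores)
  if (k_min < 2L) stop("k_min must be >= 2", call. = FALSE)
  if (k_max >= nrow(scores)) stop("k_max must be < n", call. = FALSE)
  ks <- seq.int(k_min, k_max)
  xb <- sep <- inert <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)) {
    fit <- kmeans_restarts(scores, ks[i], seed + 101L * i, n_init)
    if (is.null(fit)) next
    v <- cluster_validity(scores, fit$centers, fit$cluster)
    xb[i] <- v$xie_beni; sep[i] <- v$separation
    inert[i] <- fit$tot.withinss
  }
  if (all(is.na(xb)))
    stop("mode-number selection failed: no valid clustering at any K",
         call. = FALSE)
  best_i <- which.min(xb)
  lo <- if (best_i > 1L) xb[best_i] < xb[best_i - 1L] else TRUE
  hi <- if (best_i < length(ks)) xb[best_i] < xb[best_i + 1L] else TRUE
  interior <- best_i > 1L && best_i < length(ks)
  list(k_best = ks[best_i],
       diagnostics = data.frame(K = ks, xie_beni = xb, separation = sep,
                                inertia = inert),
       low_confidence = !(lo && hi && interior))
}

#' Fit shape modes by K-means in eigenshape-score space
#'
#' K-means with `n_init` restarts keeping the lowest inertia. Mode ids are
#' reassigned in order of descending cluster size (ties broken by first
#' centroid coordinate) for a reproducible gallery order; mode outlines
#' are the eigenshape reconstructions of the centroids.
#'
#' @param scores numeric n x m score matrix.
#' @param K number of modes (>= 1, <= n).
#' @param eigen_model optional `eigenshape_model` used to reconstruct mode
#'   outlines.
#' @param seed integer seed.
#' @param n_init restarts (default 20).
#' @return A `shape_mode_model`: list with `K`, `centroids` (K x m),
#'   `labels` (per-cell mode id in 1..K), `sizes`, `mode_outlines` (list
#'   of n_points x 2 matrices or NULL), `seed`, `n_init`, `inertia`.
#' @export
fit_shape_modes <- function(scores, K, eigen_model = NULL, seed = 1L,
                            n_init = 20L) {
  scores <- as.matrix(scores)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K > nrow(scores)) stop("K must be <= number of cells", call. = FALSE)
  if (K == 1L) {
    centroids <- matrix(colMeans(scores), 1L)
    labels <- rep(1L, nrow(scores))
    inertia <- sum(sweep(scores, 2L, centroids[1L, ])^2)
  } else {
    fit <- kmeans_restarts(scores, K, seed, n_init)
    if (is.null(fit)) stop("K-means failed at K = ", K, call. = FALSE)
    ord <- order(-fit$size, fit$centers[, 1L])
    relab <- integer(K); relab[ord] <- seq_len(K)
    labels <- relab[fit$cluster]
    centroids <- fit$centers[ord, , drop = FALSE]
    inertia <- fit$tot.withinss
  }
  outlines <- if (!is.null(eigen_model))
    lapply(seq_len(K), function(k) reconstruct_outline(eigen_model,
                                                       centroids[k, ]))
  else NULL
  structure(list(K = as.integer(K), centroids = centroids,
                 labels = as.integer(labels),
                 sizes = tabulate(labels, K),
                 mode_outlines = outlines, seed = as.integer(seed),
                 n_init = as.integer(n_init), inertia = inertia),
            class = "shape_mode_model")
}

#' Assign shapes to the nearest shape-mode centroid
#'
#' @param model a `shape_mode_model`.
#' @param scores numeric n x m matrix.
#' @return Integer vector of mode ids in 1..K.
#' @export
assign_modes <- function(model, scores) {
  scores <- as.matrix(scores)
  d2 <- outer(rowSums(scores^2), rep(1, model$K)) -
    2 * scores %*% t(model$centroids) +
    outer(rep(1, nrow(scores)), rowSums(model$centroids^2))
  max.col(-d2, ties.method = "first")
}

#' Marginal and joint shape-mode distributions of one sample
#'
#' Empirical probabilities of the nucleus modes P(NS_k), cell modes
#' P(CS_j), and of paired nucleus-cell modes P(NS_k & CS_j), over the
#' global mode catalogues (zero-count modes kept with probability 0).
#'
#' @param labels_nucleus,labels_cell paired per-cell mode ids (same cells,
#'   same order).
#' @param K_N,K_C global numbers of nucleus and cell modes.
#' @param sample_id sample label.
#' @return A `mode_distribution`: list with `sample_id`, `p_nucleus`
#'   (length K_N), `p_cell` (length K_C), `p_joint` (K_N x K_C),
#'   `n_cells`.
#' @export
mode_distribution <- function(labels_nucleus, labels_cell, K_N, K_C,
                              sample_id = "S1") {
  if (length(labels_nucleus) != length(labels_cell))
    stop("paired label vectors must have the same length", call. = FALSE)
  n <- length(labels_nucleus)
  if (n == 0L) stop("no cells", call. = FALSE)
  fn <- factor(labels_nucleus, levels = seq_len(K_N))
  fc <- factor(labels_cell, levels = seq_len(K_C))
  p_joint <- table(fn, fc) / n
  structure(list(sample_id = sample_id,
                 p_nucleus = as.numeric(table(fn) / n),
                 p_cell = as.numeric(table(fc) / n),
                 p_joint = matrix(as.numeric(p_joint), K_N, K_C),
                 n_cells = n),
            class = "mode_distribution")
}
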