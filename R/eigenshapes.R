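# Eigenshape model: PCA of registered boundary-coordinate vectors.

#' Fit an eigenshape basis by principal component analysis
#'
#' Mean-centered covariance PCA of the n x 100 matrix of shape feature
#' vectors (no per-feature standardization: all coordinates share units
#' after size normalization). The retained dimension m is the smallest
#' count whose cumulative explained variance reaches
#' `variance_threshold`. Component signs are fixed so each component's
#' largest-magnitude entry is positive.
#'
#' @param features numeric n x p matrix (rows = cells, p = 2 * n_points).
#' @param variance_threshold fraction of variance to retain, in (0, 1]
#'   (default 0.95).
#' @param compartment optional label ("nucleus"/"cell") recorded on the
#'   model.
#' @return An `eigenshape_model`: list with `mean_shape` (length p),
#'   `components` (m x p, orthonormal rows), `explained_fraction` (m
#'   values, nonincreasing), `explained_full` (all fractions),
#'   `total_variance`, `variance_threshold`, `m`, `compartment`.
#' @export
fit_eigenshapes <- function(features, variance_threshold = 0.95,
                            compartment = NA_character_) {
  features <- as.matrix(features)
  if (nrow(features) < 2L)
    stop("need at least 2 shapes to fit eigenshapes", call. = FALSE)
  if (!all(is.finite(features)))
    stop("features must be finite", call. = FALSE)
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop("variance_threshold must be in (0, 1]", call. = FALSE)
  mu <- colMeans(features)
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  total <- sum(vars)
  if (total <= .Machine$double.eps * nrow(features)) {
    message("zero-variance data: eigenshape model with m = 0 components")
    return(structure(list(mean_shape = mu,
                          components = matrix(0, 0L, ncol(features)),
                          explained_fraction = numeric(0),
                          explained_full = numeric(0),
                          total_variance = 0,
                          variance_threshold = variance_threshold,
                          m = 0L, compartment = compartment),
                     class = "eigenshape_model"))
  }
  frac <- vars / total
  m <- which(cumsum(frac) >= variance_threshold - 1e-12)[1L]
  comp <- t(pc$rotation[, seq_len(m), drop = FALSE])
  dimnames(comp) <- NULL
  for (i in seq_len(m)) {
    j <- which.max(abs(comp[i, ]))
    if (comp[i, j] < 0) comp[i, ] <- -comp[i, ]
  }
  structure(list(mean_shape = mu, components = comp,
                 explained_fraction = frac[seq_len(m)],
                 explained_full = frac, total_variance = total,
                 variance_threshold = variance_threshold, m = m,
                 compartment = compartment),
            class = "eigenshape_model")
}

#' Project shapes onto an eigenshape basis and reconstruct them
#'
#' Scores are the centered features times the transposed components;
#' reconstructions are mean + scores times components. The residual
#' fraction is the reconstruction sum of squares divided by the total
#' centered sum of squares of these data (0 when the basis is complete).
#'
#' @param model an `eigenshape_model`.
#' @param features numeric n x p matrix (p matching the model).
#' @return List with `scores` (n x m), `reconstructions` (n x p),
#'   `residual_fraction` (scalar).
#' @export
project_and_reconstruct <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != length(model$mean_shape))
    stop("feature width does not match the model", call. = FALSE)
  centered <- sweep(features, 2L, model$mean_shape)
  if (model$m == 0L) {
    recon <- matrix(rep(model$mean_shape, each = nrow(features)),
                    nrow(features))
    tot <- sum(centered^2)
    return(list(scores = matrix(0, nrow(features), 0L),
                reconstructions = recon,
                residual_fraction = if (tot > 0) 1 else 0))
  }
  scores <- centered %*% t(model$components)
  recon <- sweep(scores %*% model$components, 2L, model$mean_shape, `+`)
  tot <- sum(centered^2)
  resid <- sum((features - recon)^2)
  list(scores = scores, reconstructions = recon,
       residual_fraction = if (tot > 0) resid / tot else 0)
}

#' Reconstruct a 50-point outline from eigenshape scores
#'
#' @param model an `eigenshape_model`.
#' @param scores numeric vector of length m (e.g. a cluster centroid).
#' @return An n_points x 2 matrix of (x, y) outline coordinates.
#' @export
reconstruct_outline <- function(model, scores) {
  v <- model$mean_shape +
    if (model$m > 0L) drop(rbind(scores) %*% model$components) else 0
  n <- length(v) / 2L
  cbind(v[seq_len(n)], v[n + seq_len(n)])
}

#' Save / load an eigenshape model
#'
#' Model metadata is stored as JSON next to CSV matrices for the mean,
#' components and explained fractions.
#'
#' @param model an `eigenshape_model`.
#' @param dir directory to write into.
#' @param name file-name stem (default `"eigenshapes"`).
#' @return `write_eigenshape_model` invisibly returns the JSON path;
#'   `read_eigenshape_model` returns the model.
#' @export
write_eigenshape_model <- function(model, dir, name = "eigenshapes") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(m = model$m, variance_threshold = model$variance_threshold,
               total_variance = model$total_variance,
               compartment = model$compartment)
  jpath <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(meta, jpath, auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(mean = model$mean_shape),
                   file.path(dir, paste0(name, "_mean.csv")),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(model$components),
                   file.path(dir, paste0(name, "_components.csv")),
                   row.names = FALSE)
  utils::write.csv(data.frame(explained = model$explained_full),
                   file.path(dir, paste0(name, "_explained.csv")),
                   row.names = FALSE)
  invisible(jpath)
}

#' @rdname write_eigenshape_model
#' @export
read_eigenshape_model <- function(dir, name = "eigenshapes") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, ".json")),
                              simplifyVector = TRUE)
  mean_shape <- utils::read.csv(file.path(dir, paste0(name, "_mean.csv")))$mean
  comp <- as.matrix(utils::read.csv(
    file.path(dir, paste0(name, "_components.csv"))))
  dimnames(comp) <- NULL
  if (meta$m == 0L) comp <- matrix(0, 0L, length(mean_shape))
  expl <- utils::read.csv(file.path(dir, paste0(name, "_explained.csv")))$explained
  structure(list(mean_shape = mean_shape, components = comp,
                 explained_fraction = expl[seq_len(meta$m)],
                 explained_full = expl,
                 total_variance = meta$total_variance,
                 variance_threshold = meta$variance_threshold,
                 m = as.integer(meta$m), compartment = meta$compartment),
            class = "eigenshape_model")
}
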