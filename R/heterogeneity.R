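# The five-metric heterogeneity panel: size CVs and Shannon entropies of
# shape-mode distributions.

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values numeric vector of positive values (n >= 2, mean > 0).
#' @return Nonnegative scalar.
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("mean must be positive", call. = FALSE)
  stats::sd(values) / m
}

#' Shannon entropy of a probability vector (bits)
#'
#' -sum p log2 p with 0 log 0 = 0. The vector must be nonnegative and sum
#' to 1 within 1e-6; it is renormalized before the computation.
#'
#' @param p probability vector.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0)) stop("probabilities must be nonnegative", call. = FALSE)
  s <- sum(p)
  if (abs(s - 1) > 1e-6)
    stop("probabilities must sum to 1 (within 1e-6)", call. = FALSE)
  p <- p[p > 0] / s
  -sum(p * log2(p))
}

#' Joint Shannon entropy of a probability matrix (bits)
#'
#' @param p_joint matrix of joint probabilities.
#' @return Entropy in bits.
#' @export
joint_entropy <- function(p_joint) shannon_entropy(as.numeric(p_joint))

#' Five-metric heterogeneity panel of one sample
#'
#' CV of nucleus size CV(R_N), CV of cell size CV(R_C), Shannon entropy of
#' nucleus shape modes S(NS), of cell shape modes S(CS), and of paired
#' nucleus-cell modes S(NS & CS), computed on the cells surviving the
#' optional condition filter. Mode probabilities are taken over the global
#' mode catalogues `K_N`, `K_C` so panels are comparable across samples.
#'
#' @param records data.frame of cell records with columns `R_N`, `R_C`,
#'   `nucleus_mode`, `cell_mode` (and `phase` / `density_category` when a
#'   condition is used).
#' @param K_N,K_C global numbers of nucleus and cell modes.
#' @param sample_id sample label.
#' @param condition optional named list filter, e.g.
#'   `list(phase = "G0G1")` or `list(density_category = "singlet")`.
#' @return One-row data.frame: sample_id, condition_tag, cv_nucleus_size,
#'   cv_cell_size, entropy_nucleus, entropy_cell, entropy_joint, n_cells,
#'   available. Panels with fewer than 2 surviving cells are marked
#'   `available = FALSE` with NA metrics.
#' @export
heterogeneity_panel <- function(records, K_N, K_C, sample_id = "S1",
                                condition = NULL) {
  tag <- "all"
  if (!is.null(condition)) {
    for (nm in names(condition)) {
      records <- records[records[[nm]] %in% condition[[nm]], , drop = FALSE]
      tag <- paste0(nm, "=", paste(condition[[nm]], collapse = "|"))
    }
  }
  n <- nrow(records)
  if (n < 2L) {
    return(data.frame(sample_id = sample_id, condition_tag = tag,
                      cv_nucleus_size = NA_real_, cv_cell_size = NA_real_,
                      entropy_nucleus = NA_real_, entropy_cell = NA_real_,
                      entropy_joint = NA_real_, n_cells = n,
                      available = FALSE, stringsAsFactors = FALSE))
  }
  md <- mode_distribution(records$nucleus_mode, records$cell_mode,
                          K_N, K_C, sample_id)
  data.frame(sample_id = sample_id, condition_tag = tag,
             cv_nucleus_size = coefficient_of_variation(records$R_N),
             cv_cell_size = coefficient_of_variation(records$R_C),
             entropy_nucleus = shannon_entropy(md$p_nucleus),
             entropy_cell = shannon_entropy(md$p_cell),
             entropy_joint = joint_entropy(md$p_joint),
             n_cells = n, available = TRUE, stringsAsFactors = FALSE)
}
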