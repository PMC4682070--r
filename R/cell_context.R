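# Cell-cycle and local-density context: DNA-content normalization and
# gating, cell-cell contact graphs from label masks, covariate trend
# analysis, and per-condition heterogeneity panels.

#' Normalize DNA content to the G0/G1 peak and gate cell-cycle phases
#'
#' The G0/G1 peak is located as the dominant mode of a kernel-smoothed
#' histogram of raw integrated intensities; intensities are divided by it
#' so G0/G1 maps to 1.0. Phases are gated on the normalized content:
#' G0/G1 for values <= `g1_hi`, G2/M for values >= `g2_lo`, S between.
#' The procedure is invariant to a global gain change. With fewer than 50
#' cells the result carries a `low_confidence` attribute.
#'
#' @param raw numeric vector of raw integrated DNA intensities (> 0).
#' @param g1_hi upper G0/G1 gate in fold-of-G1 units (default 1.25).
#' @param g2_lo lower G2/M gate in fold-of-G1 units (default 1.75).
#' @return data.frame with `dna_content_norm` and `phase`
#'   ("G0G1"/"S"/"G2M"); attributes `g1_peak` and `low_confidence`.
#' @export
normalize_and_gate_dna <- function(raw, g1_hi = 1.25, g2_lo = 1.75) {
  raw <- as.numeric(raw)
  if (!length(raw)) stop("no intensities", call. = FALSE)
  if (any(!is.finite(raw)))
    stop("intensities must be finite", call. = FALSE)
  low_confidence <- length(raw) < 50L
  if (stats::sd(raw) == 0) {
    peak <- raw[1L]
  } else {
    d <- stats::density(raw, n = 1024L)
    peak <- d$x[which.max(d$y)]
  }
  if (!is.finite(peak) || peak <= 0)
    stop("gating failure: no detectable G0/G1 peak", call. = FALSE)
  norm <- raw / peak
  phase <- ifelse(norm <= g1_hi, "G0G1", ifelse(norm >= g2_lo, "G2M", "S"))
  out <- data.frame(dna_content_norm = norm, phase = phase,
                    stringsAsFactors = FALSE)
  attr(out, "g1_peak") <- peak
  attr(out, "low_confidence") <- low_confidence
  out
}

#' Local-density category from a contact count
#'
#' singlet: rho_D = 0; semi-crowded: 0 < rho_D < 4; crowded: rho_D >= 4.
#'
#' @param rho_d integer vector of contact counts.
#' @return Character vector of categories.
#' @export
density_category <- function(rho_d) {
  ifelse(rho_d == 0L, "singlet", ifelse(rho_d < 4L, "semi", "crowded"))
}

#' Build the cell-cell contact graph from label masks
#'
#' Tiles are composed into a single global canvas using their pixel
#' origins (as recorded by a motorized stage manifest), so contacts that
#' straddle tile borders are preserved. Two cells are in contact iff
#' their cell masks come within `contact_gap` pixels of each other
#' (Chebyshev distance; equivalent to dilating one mask by a square brush
#' of radius `contact_gap` and testing overlap). The per-cell degree is
#' the local cell density rho_D.
#'
#' @param tiles either a single integer label matrix, or a list of
#'   `list(mask =, origin = c(x, y))` entries with globally unique labels.
#' @param contact_gap contact distance in pixels (default 1).
#' @return List with `edges` (data.frame cell_a, cell_b, cell_a <
#'   cell_b), `rho_d` (named integer vector over all labels),
#'   `density_category` (named character vector).
#' @export
build_contact_graph <- function(tiles, contact_gap = 1L) {
  if (is.matrix(tiles)) tiles <- list(list(mask = tiles, origin = c(0, 0)))
  ox <- vapply(tiles, function(t) t$origin[1L], numeric(1))
  oy <- vapply(tiles, function(t) t$origin[2L], numeric(1))
  ws <- vapply(tiles, function(t) ncol(t$mask), integer(1))
  hs <- vapply(tiles, function(t) nrow(t$mask), integer(1))
  W <- max(ox + ws); H <- max(oy + hs)
  canvas <- matrix(0L, H, W)
  for (i in seq_along(tiles)) {
    m <- tiles[[i]]$mask
    rows <- (oy[i] + 1L):(oy[i] + nrow(m))
    cols <- (ox[i] + 1L):(ox[i] + ncol(m))
    old <- canvas[rows, cols]
    clash <- old > 0L & m > 0L & old != m
    if (any(clash))
      stop("tile conflict: tiles disagree on labels at overlapping pixels ",
           "(tile ", i, ")", call. = FALSE)
    canvas[rows, cols][m > 0L] <- m[m > 0L]
  }
  labs <- sort(unique(canvas[canvas > 0L]))
  gap <- as.integer(contact_gap)
  pairs <- NULL
  for (dx in -gap:gap) for (dy in -gap:gap) {
    if (dx == 0L && dy == 0L) next
    r1 <- max(1L, 1L - dy):min(H, H - dy)
    c1 <- max(1L, 1L - dx):min(W, W - dx)
    a <- canvas[r1, c1]
    b <- canvas[r1 + dy, c1 + dx]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel))
      pairs <- rbind(pairs, unique(cbind(pmin(a[sel], b[sel]),
                                         pmax(a[sel], b[sel]))))
  }
  edges <- if (is.null(pairs)) {
    data.frame(cell_a = integer(0), cell_b = integer(0))
  } else {
    u <- unique(pairs)
    data.frame(cell_a = u[, 1L], cell_b = u[, 2L])
  }
  deg <- stats::setNames(integer(length(labs)), labs)
  if (nrow(edges)) {
    t1 <- table(factor(edges$cell_a, levels = labs))
    t2 <- table(factor(edges$cell_b, levels = labs))
    deg <- stats::setNames(as.integer(t1 + t2), labs)
  }
  list(edges = edges, rho_d = deg,
       density_category = stats::setNames(density_category(deg), labs))
}

#' Covariate trend analysis of size and mode occupancy
#'
#' Cells are sorted by the covariate (DNA content or local density; ties
#' broken by cell_id), split into `n_groups` equal-size groups (remainder
#' spread over the leading groups). Per group the mean covariate, mean
#' nucleus and cell size (normalized by the lowest group mean) and the
#' mode occupancy P(mode | group) are reported; per mode, the Pearson
#' correlation between group mean covariate and occupancy.
#'
#' @param records data.frame with columns `cell_id`, `R_N`, `R_C`,
#'   `nucleus_mode`, `cell_mode`, plus `dna_content_norm` or `rho_D`.
#' @param covariate `"dna"` or `"density"`.
#' @param n_groups number of equal-size groups (default 9).
#' @param K_N,K_C global mode counts.
#' @return List with `groups` (data.frame: group, n, mean_covariate,
#'   mean_R_N, mean_R_C, norm_R_N, norm_R_C), `occ_nucleus`, `occ_cell`
#'   (n_groups x K matrices of P(mode | group)), `correlations`
#'   (data.frame: compartment, mode, r; NA when the covariate is
#'   constant).
#' @export
covariate_trend_analysis <- function(records, covariate = c("dna", "density"),
                                     n_groups = 9L, K_N = NULL, K_C = NULL) {
  covariate <- match.arg(covariate)
  cov_col <- if (covariate == "dna") "dna_content_norm" else "rho_D"
  n <- nrow(records)
  if (n < n_groups) stop("need at least n_groups cells", call. = FALSE)
  if (is.null(K_N)) K_N <- max(records$nucleus_mode)
  if (is.null(K_C)) K_C <- max(records$cell_mode)
  ord <- order(records[[cov_col]], records$cell_id)
  records <- records[ord, , drop = FALSE]
  base <- n %/% n_groups
  rem <- n %% n_groups
  sizes <- rep(base, n_groups) + c(rep(1L, rem), rep(0L, n_groups - rem))
  grp <- rep(seq_len(n_groups), times = sizes)

  mean_cov <- tapply(records[[cov_col]], grp, mean)
  mean_rn <- tapply(records$R_N, grp, mean)
  mean_rc <- tapply(records$R_C, grp, mean)
  groups <- data.frame(group = seq_len(n_groups), n = sizes,
                       mean_covariate = as.numeric(mean_cov),
                       mean_R_N = as.numeric(mean_rn),
                       mean_R_C = as.numeric(mean_rc),
                       norm_R_N = as.numeric(mean_rn / min(mean_rn)),
                       norm_R_C = as.numeric(mean_rc / min(mean_rc)))
  occ <- function(modes, K) {
    m <- matrix(0, n_groups, K)
    for (g in seq_len(n_groups)) {
      tg <- table(factor(modes[grp == g], levels = seq_len(K)))
      m[g, ] <- as.numeric(tg) / sizes[g]
    }
    m
  }
  occ_n <- occ(records$nucleus_mode, K_N)
  occ_c <- occ(records$cell_mode, K_C)
  cor_one <- function(y) {
    if (stats::sd(groups$mean_covariate) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(groups$mean_covariate, y)
  }
  correlations <- rbind(
    data.frame(compartment = "nucleus", mode = seq_len(K_N),
               r = vapply(seq_len(K_N), function(k) cor_one(occ_n[, k]),
                          numeric(1))),
    data.frame(compartment = "cell", mode = seq_len(K_C),
               r = vapply(seq_len(K_C), function(k) cor_one(occ_c[, k]),
                          numeric(1))))
  list(groups = groups, occ_nucleus = occ_n, occ_cell = occ_c,
       correlations = correlations)
}

#' Heterogeneity panels conditioned on cell-cycle phase and local density
#'
#' One [heterogeneity_panel()] per sample per condition: each cell-cycle
#' phase (G0G1, S, G2M) and each density category (singlet, semi,
#' crowded), plus the unconditioned panel.
#'
#' @param records cell-record data.frame with `sample_id`, `phase`,
#'   `density_category`, `R_N`, `R_C`, `nucleus_mode`, `cell_mode`.
#' @param K_N,K_C global mode counts.
#' @return Long data.frame of panels (one row per sample x condition).
#' @export
conditioned_panels <- function(records, K_N, K_C) {
  out <- list()
  for (sid in unique(records$sample_id)) {
    rs <- records[records$sample_id == sid, , drop = FALSE]
    out[[length(out) + 1L]] <- heterogeneity_panel(rs, K_N, K_C, sid)
    for (ph in c("G0G1", "S", "G2M"))
      out[[length(out) + 1L]] <-
        heterogeneity_panel(rs, K_N, K_C, sid, list(phase = ph))
    for (dc in c("singlet", "semi", "crowded"))
      out[[length(out) + 1L]] <-
        heterogeneity_panel(rs, K_N, K_C, sid, list(density_category = dc))
  }
  do.call(rbind, out)
}
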