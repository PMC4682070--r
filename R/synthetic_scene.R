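# Synthetic-scene generator: ground-truthed shape populations, spatial
# layouts and rendered two-channel images for end-to-end validation of the
# imaging and shape-analysis pipeline.

#' Generate latent shape templates
#'
#' Templates are star-convex outlines defined by a radial Fourier series
#' r(theta) = 1 + sum_h [a_h cos(h theta) + b_h sin(h theta)], h = 2..H.
#' With `irregularity = 0` every template is a circle; increasing
#' `irregularity` increases the harmonic amplitudes and hence the pairwise
#' post-registration distance between templates. Amplitudes are rescaled
#' whenever the radius would dip below 0.15 so the outline stays a simple
#' closed curve with positive radius at all angles.
#'
#' @param k number of templates (>= 1).
#' @param irregularity nonnegative harmonic amplitude scale (default 0.25).
#' @param seed integer random seed; generation is deterministic given it.
#' @param n_harmonics highest Fourier harmonic (default 6).
#' @param base_scale template radius scale in pixels (default 30).
#' @param min_separation optional minimum pairwise distance between the
#'   registered feature vectors of the templates; candidates closer than
#'   this to an accepted template are redrawn (latent subtypes are
#'   distinct morphologies by construction). NULL disables the check.
#' @return List of `shape_template` objects with fields `template_id`,
#'   `control_radii` (constant term followed by cos/sin coefficient pairs),
#'   `base_scale`.
#' @export
generate_templates <- function(k, irregularity = 0.25, seed = 1L,
                               n_harmonics = 6L, base_scale = 30,
                               min_separation = NULL) {
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("k must be a positive integer", call. = FALSE)
  if (irregularity < 0) stop("irregularity must be >= 0", call. = FALSE)
  k <- as.integer(k)
  set.seed(as.integer(seed))
  hs <- seq(2L, n_harmonics)
  out <- vector("list", k)
  feats <- NULL
  i <- 1L
  tries <- 0L
  while (i <= k) {
    tries <- tries + 1L
    if (tries > 500L * k)
      stop("could not generate ", k, " templates at min_separation = ",
           min_separation, call. = FALSE)
    a <- stats::rnorm(length(hs), 0, irregularity / hs)
    b <- stats::rnorm(length(hs), 0, irregularity / hs)
    coef <- clamp_radial_coef(a, b, hs)
    tpl <- structure(list(template_id = i,
                          control_radii = c(1, as.vector(rbind(coef$a,
                                                               coef$b))),
                          harmonics = hs, a = coef$a, b = coef$b,
                          base_scale = base_scale),
                     class = "shape_template")
    if (!is.null(min_separation) && irregularity > 0) {
      rs <- register_shape(template_outline(tpl))
      f <- shape_features(rs)
      # orientation stability: the 180-degree ambiguity is resolved by the
      # sign of the x third moment; a template with near-zero skewness
      # would flip orientation under sampling noise and split its cluster
      if (abs(mean(rs$points[, 1L]^3)) < 0.05) next
      if (!is.null(feats) &&
          min(sqrt(colSums((t(feats) - f)^2))) < min_separation) next
      feats <- rbind(feats, f)
    }
    out[[i]] <- tpl
    i <- i + 1L
  }
  out
}

# keep min radius above floor by shrinking harmonic amplitudes
clamp_radial_coef <- function(a, b, hs, floor_r = 0.15) {
  th <- seq(0, 2 * pi, length.out = 720L)
  pert <- radial_perturbation(th, a, b, hs)
  lo <- 1 + min(pert)
  if (lo < floor_r) {
    s <- (1 - floor_r) / (1 - lo)
    a <- a * s; b <- b * s
  }
  list(a = a, b = b)
}

radial_perturbation <- function(theta, a, b, hs) {
  out <- numeric(length(theta))
  for (i in seq_along(hs))
    out <- out + a[i] * cos(hs[i] * theta) + b[i] * sin(hs[i] * theta)
  out
}

#' Outline polygon of a shape template
#'
#' @param template a `shape_template`.
#' @param n_vertices number of polygon vertices (default 120).
#' @param rotation rotation angle in radians applied to the outline.
#' @param scale overall scale multiplier applied to `base_scale`.
#' @param noise_a,noise_b optional additive perturbations of the cos/sin
#'   coefficients (same length as `template$a`).
#' @return An n x 2 vertex matrix centered at the origin,
#'   counterclockwise.
#' @export
template_outline <- function(template, n_vertices = 120L, rotation = 0,
                             scale = 1, noise_a = NULL, noise_b = NULL) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  a <- template$a; b <- template$b
  if (!is.null(noise_a)) a <- a + noise_a
  if (!is.null(noise_b)) b <- b + noise_b
  r <- 1 + radial_perturbation(th, a, b, template$harmonics)
  r <- pmax(r, 0.05)
  s <- template$base_scale * scale
  v <- cbind(r * cos(th + rotation), r * sin(th + rotation)) * s
  if (polygon_signed_area(v) < 0) v <- v[nrow(v):1L, , drop = FALSE]
  v
}

#' Sample a ground-truthed cell population
#'
#' Draws `n` cells: each picks a template by `weights`, a cell-cycle phase
#' (G0/G1 at DNA content 1.0, G2/M at 2.0, S uniform in (1, 2)), a random
#' orientation, and multiplicative lognormal size noise. Cell and nucleus
#' scale are multiplied by the cube root of DNA content (size grows with
#' genome content). Nucleus outlines are drawn from the same template at
#' `nucleus_scale` of the cell scale. `shape_noise = 0` reproduces
#' templates exactly up to a similarity transform.
#'
#' @param templates list from [generate_templates()].
#' @param weights probability vector over templates (sums to 1).
#' @param n number of cells.
#' @param shape_noise nonnegative sd scale of per-cell harmonic
#'   perturbations (default 0.05).
#' @param seed integer seed.
#' @param phase_probs probabilities for phases G0G1, S, G2M
#'   (default 0.6, 0.25, 0.15).
#' @param size_noise_cv lognormal CV of per-cell size noise (default 0.05).
#' @param nucleus_scale nucleus/cell linear size ratio (default 0.45).
#' @param nucleus_templates optional separate template list for nuclei;
#'   defaults to `templates` (same latent subtype drives both
#'   compartments).
#' @param sample_id sample label carried into the traces.
#' @return List with `boundaries` (boundary traces, both compartments,
#'   centered at the origin until [layout_scene()] assigns positions) and
#'   `truth` (data.frame: cell_id, template_id, phase, dna_content,
#'   colony_id, contact_count, x, y, cell_scale, nucleus_scale_abs).
#' @export
sample_population <- function(templates, weights = NULL, n = 100L,
                              shape_noise = 0.05, seed = 1L,
                              phase_probs = c(G0G1 = 0.6, S = 0.25, G2M = 0.15),
                              size_noise_cv = 0.05, nucleus_scale = 0.45,
                              nucleus_templates = NULL,
                              sample_id = "S1") {
  if (is.null(weights)) weights <- rep(1 / length(templates), length(templates))
  if (length(weights) != length(templates))
    stop("weights must match templates in length", call. = FALSE)
  if (any(weights < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must sum to 1", call. = FALSE)
  if (shape_noise < 0) stop("shape_noise must be >= 0", call. = FALSE)
  if (is.null(nucleus_templates)) nucleus_templates <- templates
  set.seed(as.integer(seed))
  n <- as.integer(n)

  tid <- sample.int(length(templates), n, replace = TRUE, prob = weights)
  phase <- sample(c("G0G1", "S", "G2M"), n, replace = TRUE,
                  prob = phase_probs / sum(phase_probs))
  dna <- ifelse(phase == "G0G1", 1,
                ifelse(phase == "G2M", 2, stats::runif(n, 1, 2)))
  size_sd <- sqrt(log(1 + size_noise_cv^2))
  size_fac <- exp(stats::rnorm(n, -size_sd^2 / 2, size_sd))
  rot <- stats::runif(n, 0, 2 * pi)

  boundaries <- vector("list", 2L * n)
  cell_scale <- numeric(n)
  for (i in seq_len(n)) {
    tpl <- templates[[tid[i]]]
    ntpl <- nucleus_templates[[tid[i]]]
    nh <- length(tpl$a)
    na_ <- if (shape_noise > 0)
      stats::rnorm(nh, 0, shape_noise / tpl$harmonics) else NULL
    nb_ <- if (shape_noise > 0)
      stats::rnorm(nh, 0, shape_noise / tpl$harmonics) else NULL
    sc <- size_fac[i] * dna[i]^(1 / 3)
    cell_scale[i] <- sc * tpl$base_scale
    vc <- template_outline(tpl, rotation = rot[i], scale = sc,
                           noise_a = na_, noise_b = nb_)
    vn <- template_outline(ntpl, rotation = rot[i], scale = sc * nucleus_scale,
                           noise_a = na_, noise_b = nb_)
    boundaries[[2L * i - 1L]] <- boundary_trace(vc, "cell", cell_id = i,
                                                sample_id = sample_id)
    boundaries[[2L * i]] <- boundary_trace(vn, "nucleus", cell_id = i,
                                           sample_id = sample_id)
  }

  truth <- data.frame(
    cell_id = seq_len(n), template_id = tid, phase = phase,
    dna_content = dna, colony_id = rep(NA_integer_, n),
    contact_count = rep(NA_integer_, n),
    x = rep(NA_real_, n), y = rep(NA_real_, n), cell_scale = cell_scale,
    sample_id = rep(sample_id, n), stringsAsFactors = FALSE)
  attr(truth, "rng_seed") <- as.integer(seed)
  list(boundaries = boundaries, truth = truth)
}

#' Lay out a population into colonies with controlled contacts
#'
#' Assigns every cell a position inside a `width` x `height` pixel field.
#' Cells are divided among `n_colonies` spatially distinct colonies
#' (centers placed far apart on a jittered grid); positions scatter around
#' the colony center with sd `colony_spread`. A `contact_fraction` of
#' cells is placed adjacent to a previously placed colony member so their
#' masks touch; all other placements are rejected until they do not
#' overlap. An optional per-colony multiplicative size factor
#' (`colony_size_cv`) models heritable size variation; it rescales the
#' boundary outlines in place.
#'
#' @param pop result of [sample_population()].
#' @param n_colonies number of colonies (>= 1).
#' @param colony_spread within-colony position sd in pixels.
#' @param contact_fraction fraction of cells placed in contact (0..1).
#' @param width,height image dimensions in pixels.
#' @param seed integer seed.
#' @param colony_size_cv CV of the per-colony lognormal size factor
#'   (default 0 = no heritable effect).
#' @param max_tries placement rejection budget per cell before a capacity
#'   error is raised.
#' @return `pop` with `truth` columns x, y, colony_id, contact_count
#'   filled, boundaries translated to their positions, and attribute
#'   `colony_factor` recording the per-colony size factors.
#' @export
layout_scene <- function(pop, n_colonies = 1L, colony_spread = 60,
                         contact_fraction = 0, width = 1024L, height = 1024L,
                         seed = 1L, colony_size_cv = 0, max_tries = 2000L) {
  truth <- pop$truth
  n <- nrow(truth)
  if (n_colonies < 1 || colony_spread < 0 || contact_fraction < 0 ||
      contact_fraction > 1)
    stop("invalid layout parameters", call. = FALSE)
  # actual outline radius of each cell (boundaries are origin-centered here)
  rad <- vapply(seq_len(n), function(i)
    sqrt(max(rowSums(pop$boundaries[[2L * i - 1L]]$vertices^2))), numeric(1))
  if (sum(pi * rad^2) > 0.45 * width * height)
    stop("capacity error: requested cells cannot fit the field",
         call. = FALSE)
  set.seed(as.integer(seed))

  margin <- max(rad) + 2
  ctr <- colony_centers(n_colonies, width, height, margin + 2 * colony_spread)
  colony <- sort(rep_len(seq_len(n_colonies), n))
  csd <- sqrt(log(1 + colony_size_cv^2))
  cfac <- if (colony_size_cv > 0)
    exp(stats::rnorm(n_colonies, -csd^2 / 2, csd)) else rep(1, n_colonies)

  # apply heritable per-colony size factor to outlines and radii
  if (colony_size_cv > 0) {
    for (i in seq_len(n)) {
      f <- cfac[colony[i]]
      pop$boundaries[[2L * i - 1L]]$vertices <-
        pop$boundaries[[2L * i - 1L]]$vertices * f
      pop$boundaries[[2L * i]]$vertices <-
        pop$boundaries[[2L * i]]$vertices * f
      rad[i] <- rad[i] * f
      truth$cell_scale[i] <- truth$cell_scale[i] * f
    }
  }

  want_contact <- rep(FALSE, n)
  if (contact_fraction > 0) {
    idx <- which(duplicated(colony))  # never the first cell of a colony
    k <- min(length(idx), round(contact_fraction * n))
    if (k > 0) want_contact[sample(idx, k)] <- TRUE
  }

  pos <- matrix(NA_real_, n, 2L)
  eff <- truth$cell_scale * 0.95    # effective touching radius
  for (i in seq_len(n)) {
    placed_same <- which(!is.na(pos[, 1L]) & colony == colony[i] & seq_len(n) < i)
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      # a contact placement that keeps colliding (e.g. attaching to an
      # already-clumped partner) falls back to ordinary placement
      contact_try <- want_contact[i] && length(placed_same) &&
        try <= max_tries %/% 2L
      if (contact_try) {
        j <- placed_same[sample.int(length(placed_same), 1L)]
        ang <- stats::runif(1, 0, 2 * pi)
        d <- (eff[i] + eff[j])
        cand <- pos[j, ] + d * c(cos(ang), sin(ang))
      } else {
        # widen the scatter progressively when placements keep colliding
        spread_i <- colony_spread * (1 + 2 * try / max_tries)
        cand <- ctr[colony[i], ] + stats::rnorm(2L, 0, spread_i)
      }
      if (cand[1L] < margin || cand[1L] > width - 1 - margin ||
          cand[2L] < margin || cand[2L] > height - 1 - margin) next
      prev <- which(!is.na(pos[, 1L]))
      if (contact_try) prev <- setdiff(prev, j)
      if (length(prev)) {
        dd <- sqrt((pos[prev, 1L] - cand[1L])^2 + (pos[prev, 2L] - cand[2L])^2)
        if (any(dd < rad[prev] + rad[i] + 3)) next
      }
      pos[i, ] <- cand
      ok <- TRUE
      break
    }
    if (!ok) stop("capacity error: could not place cell ", i,
                  " without overlap", call. = FALSE)
  }

  truth$x <- pos[, 1L]; truth$y <- pos[, 2L]
  truth$colony_id <- colony
  for (i in seq_len(n)) {
    pop$boundaries[[2L * i - 1L]]$vertices <-
      sweep(pop$boundaries[[2L * i - 1L]]$vertices, 2L, pos[i, ], `+`)
    pop$boundaries[[2L * i]]$vertices <-
      sweep(pop$boundaries[[2L * i]]$vertices, 2L, pos[i, ], `+`)
  }
  truth$contact_count <- true_contacts(pop$boundaries, truth, gap = 1)
  attr(truth, "colony_factor") <- cfac
  attr(truth, "image_dim") <- c(width = width, height = height)
  pop$truth <- truth
  pop
}

colony_centers <- function(k, width, height, margin) {
  g <- ceiling(sqrt(k))
  xs <- seq(margin, width - 1 - margin, length.out = max(g, 2L))
  ys <- seq(margin, height - 1 - margin, length.out = max(ceiling(k / g), 2L))
  grid <- as.matrix(expand.grid(x = xs, y = ys))
  grid[seq_len(k), , drop = FALSE]
}

# geometric ground-truth contacts: cell outlines within `gap` pixels
true_contacts <- function(boundaries, truth, gap = 1) {
  n <- nrow(truth)
  cnt <- integer(n)
  if (n < 2L) return(cnt)
  rad <- truth$cell_scale * 1.6
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- sqrt((truth$x[i] - truth$x[j])^2 + (truth$y[i] - truth$y[j])^2)
    if (d > rad[i] + rad[j] + gap + 1) next
    dm <- polygon_min_distance(boundaries[[2L * i - 1L]]$vertices,
                               boundaries[[2L * j - 1L]]$vertices)
    if (dm <= gap + 0.5) { cnt[i] <- cnt[i] + 1L; cnt[j] <- cnt[j] + 1L }
  }
  cnt
}

#' Positions of a 7-cell hexagonal rosette
#'
#' One center position surrounded by six neighbors at `spacing`; with
#' `spacing` below twice the cell radius the rendered masks touch, giving
#' contact degree 6 at the center and 3 on each petal.
#'
#' @param center numeric (x, y) of the rosette center.
#' @param spacing center-to-neighbor distance in pixels.
#' @return A 7 x 2 matrix of positions (center first).
#' @export
hex_rosette_positions <- function(center = c(0, 0), spacing = 50) {
  ang <- (0:5) * pi / 3
  rbind(center,
        cbind(center[1L] + spacing * cos(ang), center[2L] + spacing * sin(ang)))
}

#' Assign explicit positions to a sampled population
#'
#' Low-level alternative to [layout_scene()] for constructing exact
#' geometric fixtures (e.g. rosettes or tile-straddling pairs). Boundaries
#' are translated to the given positions; contact counts are recomputed
#' from the outlines.
#'
#' @param pop result of [sample_population()].
#' @param xy n x 2 matrix of positions.
#' @param width,height image dimensions recorded in the truth table.
#' @return `pop` with positions applied.
#' @export
place_population <- function(pop, xy, width = 512L, height = 512L) {
  xy <- as.matrix(xy)
  n <- nrow(pop$truth)
  stopifnot(nrow(xy) == n)
  pop$truth$x <- xy[, 1L]; pop$truth$y <- xy[, 2L]
  if (all(is.na(pop$truth$colony_id))) pop$truth$colony_id <- 1L
  for (i in seq_len(n)) {
    pop$boundaries[[2L * i - 1L]]$vertices <-
      sweep(pop$boundaries[[2L * i - 1L]]$vertices, 2L, xy[i, ], `+`)
    pop$boundaries[[2L * i]]$vertices <-
      sweep(pop$boundaries[[2L * i]]$vertices, 2L, xy[i, ], `+`)
  }
  pop$truth$contact_count <- true_contacts(pop$boundaries, pop$truth, gap = 1)
  attr(pop$truth, "image_dim") <- c(width = width, height = height)
  pop
}

#' Render a laid-out scene into two-channel images and label masks
#'
#' Rasterizes the cell and nucleus outlines into 16-bit-style label masks
#' (0 = background, label = cell_id) and produces a DNA-channel image whose
#' integrated intensity inside each nucleus is exactly proportional to the
#' cell's true DNA content (before noise), plus an F-actin-channel image
#' with uniform intensity inside each cell mask. Gaussian read noise at
#' the stated SNR and optional per-cell multiplicative lognormal intensity
#' noise are added to the noisy variants; noiseless variants are always
#' returned.
#'
#' @param pop laid-out population from [layout_scene()] /
#'   [place_population()].
#' @param dna_gain integrated nuclear intensity per unit DNA content
#'   (default 1000).
#' @param snr signal-to-noise ratio of the read noise (> 0, default 20).
#' @param dna_noise_cv CV of per-cell multiplicative intensity noise in the
#'   noisy DNA channel (default 0.05).
#' @param seed integer seed for the noise draws.
#' @return List: `dna`, `actin` (noisy matrices), `dna_noiseless`,
#'   `actin_noiseless`, `nucleus_mask`, `cell_mask` (integer label
#'   matrices), `truth`.
#' @export
render_scene <- function(pop, dna_gain = 1000, snr = 20, dna_noise_cv = 0.05,
                         seed = 1L) {
  if (snr <= 0) stop("snr must be > 0", call. = FALSE)
  truth <- pop$truth
  dim_ <- attr(truth, "image_dim")
  if (is.null(dim_)) stop("population has no layout; call layout_scene()",
                          call. = FALSE)
  width <- dim_[["width"]]; height <- dim_[["height"]]
  n <- nrow(truth)
  cell_mask <- matrix(0L, height, width)
  nucleus_mask <- matrix(0L, height, width)
  dna0 <- matrix(0, height, width)
  actin0 <- matrix(0, height, width)

  for (i in seq_len(n)) {
    vc <- pop$boundaries[[2L * i - 1L]]$vertices
    vn <- pop$boundaries[[2L * i]]$vertices
    if (min(vc) < -0.5 || max(vc[, 1L]) > width - 0.5 ||
        max(vc[, 2L]) > height - 0.5)
      stop("render error: boundary of cell ", truth$cell_id[i],
           " outside the image", call. = FALSE)
    ic <- rasterize_polygon(vc, width, height)
    inn <- rasterize_polygon(vn, width, height)
    cell_mask[ic] <- truth$cell_id[i]
    nucleus_mask[inn] <- truth$cell_id[i]
    actin0[ic] <- 1
    if (length(inn))
      dna0[inn] <- dna_gain * truth$dna_content[i] / length(inn)
  }
  # a nucleus pixel always lies inside its cell
  cell_mask[nucleus_mask > 0L] <- nucleus_mask[nucleus_mask > 0L]

  set.seed(as.integer(seed))
  dna <- dna0
  if (dna_noise_cv > 0 && n > 0) {
    s <- sqrt(log(1 + dna_noise_cv^2))
    f <- exp(stats::rnorm(n, -s^2 / 2, s))
    for (i in seq_len(n)) {
      sel <- nucleus_mask == truth$cell_id[i]
      dna[sel] <- dna[sel] * f[i]
    }
  }
  sig_d <- if (any(dna0 > 0)) mean(dna0[dna0 > 0]) else 1
  sig_a <- if (any(actin0 > 0)) mean(actin0[actin0 > 0]) else 1
  dna <- dna + matrix(stats::rnorm(length(dna0), 0, sig_d / snr),
                      height, width)
  actin <- actin0 + matrix(stats::rnorm(length(actin0), 0, sig_a / snr),
                           height, width)

  list(dna = dna, actin = actin, dna_noiseless = dna0,
       actin_noiseless = actin0, nucleus_mask = nucleus_mask,
       cell_mask = cell_mask, truth = truth)
}

#' Write a rendered scene to TIFF files and a truth CSV
#'
#' Channels are written as 16-bit grayscale TIFF (intensities rescaled to
#' the 16-bit range), label masks as 16-bit TIFF with 0 = background, and
#' the truth table as CSV.
#'
#' @param scene result of [render_scene()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the named vector of file paths.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(dna = file.path(dir, paste0(prefix, "_dna.tif")),
             actin = file.path(dir, paste0(prefix, "_actin.tif")),
             nucleus_mask = file.path(dir, paste0(prefix, "_nucmask.tif")),
             cell_mask = file.path(dir, paste0(prefix, "_cellmask.tif")),
             truth = file.path(dir, paste0(prefix, "_truth.csv")))
  write_gray16 <- function(img, path) {
    mx <- max(img, 1e-12)
    EBImage::writeImage(EBImage::Image(t(pmax(img, 0) / mx)), path,
                        type = "tiff", bits.per.sample = 16L)
  }
  write_gray16(scene$dna, paths[["dna"]])
  write_gray16(scene$actin, paths[["actin"]])
  EBImage::writeImage(EBImage::Image(t(scene$nucleus_mask) / 65535),
                      paths[["nucleus_mask"]], type = "tiff",
                      bits.per.sample = 16L)
  EBImage::writeImage(EBImage::Image(t(scene$cell_mask) / 65535),
                      paths[["cell_mask"]], type = "tiff",
                      bits.per.sample = 16L)
  utils::write.csv(scene$truth[, c("cell_id", "template_id", "phase",
                                   "dna_content", "colony_id",
                                   "contact_count", "x", "y")],
                   paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
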