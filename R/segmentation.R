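# Image reading, nucleus/cell segmentation, intensity measurement,
# boundary extraction and z-stack projection.

#' Gaussian low-pass filter
#'
#' Separable Gaussian filter with a normalized discrete kernel (radius
#' `ceiling(3.5 sigma)`), replicate boundary handling. `sigma = 0` returns
#' the input unchanged.
#'
#' @param img numeric matrix.
#' @param sigma Gaussian sd in pixels (>= 0).
#' @return Filtered matrix of the same size.
#' @export
gaussian_lowpass <- function(img, sigma) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (sigma == 0) return(img)
  r <- ceiling(3.5 * sigma)
  k1 <- stats::dnorm(-r:r, 0, sigma)
  k1 <- k1 / sum(k1)
  kern <- outer(k1, k1)
  as.matrix(EBImage::filter2(img, kern, boundary = "replicate"))
}

#' Project a z-stack to 2D by filtered maximum projection
#'
#' Each slice is Gaussian low-pass filtered, then the per-pixel maximum is
#' taken across z. This is the reduction used to analyze cells embedded in
#' 3D matrices with the 2D shape pipeline.
#'
#' @param stack a 3D array (rows x cols x slices) or a list of matrices.
#' @param lowpass_sigma Gaussian sd in pixels (>= 0).
#' @return A 2D matrix.
#' @export
project_zstack <- function(stack, lowpass_sigma = 1) {
  slices <- if (is.list(stack)) stack else
    lapply(seq_len(dim(stack)[3L]), function(i) stack[, , i])
  if (!length(slices)) stop("empty stack", call. = FALSE)
  out <- gaussian_lowpass(slices[[1L]], lowpass_sigma)
  for (s in slices[-1L]) out <- pmax(out, gaussian_lowpass(s, lowpass_sigma))
  out
}

#' Segment a two-channel scene into nucleus and cell label masks
#'
#' Nuclei: the DNA channel is smoothed, background-subtracted, thresholded
#' by Otsu's method, hole-filled, and touching objects are split by a
#' distance-transform watershed. Cells: a Voronoi-style watershed region
#' growing ([EBImage::propagate()]) seeded at the nuclei and restricted to
#' the actin foreground (Otsu on the smoothed actin channel). Objects
#' below `min_area` are removed and every retained nucleus lies within its
#' cell mask (matching labels).
#'
#' @param dna_image,actin_image numeric matrices of the same size.
#' @param smooth_sigma Gaussian smoothing sd in pixels (default 2).
#' @param min_area minimum object area in pixels (default 50).
#' @param watershed_tolerance height tolerance of the nucleus-splitting
#'   distance-transform watershed (default 2; higher merges more).
#' @param pixel_size microns per pixel, recorded on the result (default 1).
#' @param origin (x, y) global offset of this tile in pixels.
#' @return A `labeled_scene`: list with `nucleus_mask`, `cell_mask`
#'   (integer label matrices, matching labels), `dna`, `actin`,
#'   `pixel_size`, `origin`.
#' @export
segment_scene <- function(dna_image, actin_image, smooth_sigma = 2,
                          min_area = 50L, watershed_tolerance = 2,
                          pixel_size = 1, origin = c(0, 0)) {
  if (!all(dim(dna_image) == dim(actin_image)))
    stop("channel images must have the same shape", call. = FALSE)
  empty <- function() {
    z <- matrix(0L, nrow(dna_image), ncol(dna_image))
    structure(list(nucleus_mask = z, cell_mask = z, dna = dna_image,
                   actin = actin_image, pixel_size = pixel_size,
                   origin = origin), class = "labeled_scene")
  }
  norm01 <- function(x) {
    rg <- range(x)
    if (diff(rg) <= 0) return(NULL)
    (x - rg[1L]) / diff(rg)
  }
  dna_s <- gaussian_lowpass(dna_image, smooth_sigma)
  dna_n <- norm01(dna_s - stats::median(dna_s))
  if (is.null(dna_n)) return(empty())
  th <- EBImage::otsu(EBImage::Image(dna_n))
  nuc_bw <- EBImage::fillHull(dna_n > th)
  if (!any(nuc_bw)) return(empty())
  dm <- EBImage::distmap(nuc_bw)
  nuc_lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = watershed_tolerance))

  actin_s <- gaussian_lowpass(actin_image, smooth_sigma)
  act_n <- norm01(actin_s - stats::median(actin_s))
  if (is.null(act_n)) return(empty())
  tha <- EBImage::otsu(EBImage::Image(act_n))
  fg <- (act_n > tha) | (nuc_lab > 0)
  cell_lab <- EBImage::imageData(
    EBImage::propagate(EBImage::Image(actin_s), EBImage::Image(nuc_lab),
                       mask = EBImage::Image(fg)))
  storage.mode(nuc_lab) <- "integer"
  storage.mode(cell_lab) <- "integer"

  # drop small objects; keep only matched nucleus/cell label pairs
  na_tab <- tabulate(nuc_lab[nuc_lab > 0L])
  ca_tab <- tabulate(cell_lab[cell_lab > 0L])
  keep <- which(na_tab >= min_area &
                  ca_tab[seq_along(na_tab)] >= min_area)
  relab <- integer(max(length(na_tab), length(ca_tab)))
  relab[keep] <- seq_along(keep)
  nz <- nuc_lab > 0L
  nuc_lab[nz] <- relab[nuc_lab[nz]]
  cz <- cell_lab > 0L
  cell_lab[cz] <- relab[cell_lab[cz]]
  # enforce nucleus within cell mask
  nuc_lab[nuc_lab != cell_lab & nuc_lab > 0L & cell_lab == 0L] <- 0L

  structure(list(nucleus_mask = nuc_lab, cell_mask = cell_lab,
                 dna = dna_image, actin = actin_image,
                 pixel_size = pixel_size, origin = origin),
            class = "labeled_scene")
}

#' Wrap pre-computed label masks as a labeled scene
#'
#' Used when ground-truth masks or an external segmenter replace
#' [segment_scene()].
#'
#' @param nucleus_mask,cell_mask integer label matrices (0 = background).
#' @param dna,actin optional channel images.
#' @param pixel_size microns per pixel.
#' @param origin (x, y) global tile offset in pixels.
#' @return A `labeled_scene`.
#' @export
labeled_scene <- function(nucleus_mask, cell_mask, dna = NULL, actin = NULL,
                          pixel_size = 1, origin = c(0, 0)) {
  structure(list(nucleus_mask = nucleus_mask, cell_mask = cell_mask,
                 dna = dna, actin = actin, pixel_size = pixel_size,
                 origin = origin), class = "labeled_scene")
}

#' Extract sub-pixel boundary traces from label masks
#'
#' Traces the outer contour of every label at the 0.5 iso-level of its
#' binary mask (linear interpolation between pixel centers), so the
#' enclosed polygon area matches the label's pixel count to within a
#' one-pixel boundary band. Traces are oriented counterclockwise (positive
#' shoelace area); holes are ignored. Labels touching the tile border are
#' flagged `on_tile_border`.
#'
#' @param scene a `labeled_scene`.
#' @param compartments character vector, subset of
#'   `c("nucleus", "cell")`.
#' @param sample_id,image_id identifiers stamped on the traces.
#' @return List of [boundary_trace()] objects.
#' @export
extract_boundaries <- function(scene, compartments = c("nucleus", "cell"),
                               sample_id = NA_character_,
                               image_id = NA_character_) {
  out <- list()
  for (comp in compartments) {
    mask <- if (comp == "nucleus") scene$nucleus_mask else scene$cell_mask
    labs <- sort(unique(mask[mask > 0L]))
    for (lab in labs) {
      tr <- trace_label(mask, lab)
      if (is.null(tr)) {
        warning("label ", lab, " (", comp,
                ") has fewer than 3 contour points; dropped")
        next
      }
      # shift to global coordinates using the tile origin
      tr$poly[, 1L] <- tr$poly[, 1L] + scene$origin[1L]
      tr$poly[, 2L] <- tr$poly[, 2L] + scene$origin[2L]
      out[[length(out) + 1L]] <-
        boundary_trace(tr$poly, comp, cell_id = lab, sample_id = sample_id,
                       image_id = image_id, on_tile_border = tr$on_border)
    }
  }
  out
}

# Contour one label at the 0.5 level of its padded binary crop.
trace_label <- function(mask, lab) {
  sel <- mask == lab
  rows <- which(rowSums(sel) > 0L)
  cols <- which(colSums(sel) > 0L)
  if (!length(rows)) return(NULL)
  on_border <- rows[1L] == 1L || rows[length(rows)] == nrow(mask) ||
    cols[1L] == 1L || cols[length(cols)] == ncol(mask)
  r0 <- max(rows[1L] - 2L, 1L); r1 <- min(rows[length(rows)] + 2L, nrow(mask))
  c0 <- max(cols[1L] - 2L, 1L); c1 <- min(cols[length(cols)] + 2L, ncol(mask))
  crop <- sel[r0:r1, c0:c1]
  pad <- matrix(0, nrow(crop) + 2L, ncol(crop) + 2L)
  pad[2L:(nrow(crop) + 1L), 2L:(ncol(crop) + 1L)] <- crop
  # contourLines treats x as the first index (rows = y here) and y as the
  # second (cols = x here); convert back to (x = col, y = row), 0-based
  cl <- grDevices::contourLines(
    x = seq_len(nrow(pad)), y = seq_len(ncol(pad)), z = pad, levels = 0.5)
  if (!length(cl)) return(NULL)
  lens <- vapply(cl, function(u) length(u$x), integer(1))
  u <- cl[[which.max(lens)]]
  x <- u$y + (c0 - 1L) - 2L   # col index -> x, 0-based
  y <- u$x + (r0 - 1L) - 2L   # row index -> y, 0-based
  if (length(x) > 3L && x[1L] == x[length(x)] && y[1L] == y[length(y)]) {
    x <- x[-length(x)]; y <- y[-length(y)]
  }
  if (length(x) < 3L) return(NULL)
  list(poly = cbind(x, y), on_border = on_border)
}

#' Integrated DNA content per nucleus
#'
#' Sums background-subtracted DNA-channel intensities over each nucleus
#' label. Background is the median intensity outside all cell masks; if no
#' background pixels exist (confluent tile) the 5th percentile of the whole
#' image is used instead (with a message).
#'
#' @param dna_image numeric matrix.
#' @param scene a `labeled_scene` with nucleus and cell masks.
#' @return Named numeric vector of integrated intensities (arbitrary
#'   units), one entry per nucleus label.
#' @export
measure_dna_content <- function(dna_image, scene) {
  outside <- scene$cell_mask == 0L & scene$nucleus_mask == 0L
  if (any(outside)) {
    bg <- stats::median(dna_image[outside])
  } else {
    bg <- stats::quantile(dna_image, 0.05, names = FALSE)
    message("no background region; using global 5th percentile background")
  }
  labs <- scene$nucleus_mask[scene$nucleus_mask > 0L]
  if (!length(labs)) return(stats::setNames(numeric(0), character(0)))
  vals <- dna_image[scene$nucleus_mask > 0L] - bg
  sums <- tapply(vals, labs, sum)
  stats::setNames(as.numeric(sums), names(sums))
}

#' Per-label pixel areas of a mask
#'
#' @param mask integer label matrix.
#' @return Named integer vector of pixel counts per label.
#' @export
label_areas <- function(mask) {
  labs <- mask[mask > 0L]
  if (!length(labs)) return(stats::setNames(integer(0), character(0)))
  tab <- table(labs)
  stats::setNames(as.integer(tab), names(tab))
}

#' Read a grayscale image (or stack) from TIFF
#'
#' @param path TIFF file path.
#' @return A matrix (single page) or list of matrices (multi-page), in the
#'   row = y, col = x orientation used by the package.
#' @export
read_channel_tiff <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 2L) return(t(EBImage::imageData(img)))
  lapply(seq_len(d[3L]), function(i) t(EBImage::imageData(img)[, , i]))
}

#' Read a tile manifest and segment each tile
#'
#' The manifest CSV describes a grid scan from a motorized stage: columns
#' `dna_path`, `actin_path`, `x_origin`, `y_origin` (pixels) and
#' optionally `pixel_size`. Each tile is segmented independently and its
#' labels are offset so cell ids are globally unique; the returned scenes
#' carry their origins, so [extract_boundaries()] emits global
#' coordinates and [build_contact_graph()] can stitch contacts across
#' tile borders.
#'
#' @param manifest data.frame or path to the manifest CSV.
#' @param ... further arguments passed to [segment_scene()].
#' @return List of `labeled_scene` objects with globally unique labels.
#' @export
segment_tiles <- function(manifest, ...) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  offset <- 0L
  scenes <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    dna <- read_channel_tiff(manifest$dna_path[i])
    actin <- read_channel_tiff(manifest$actin_path[i])
    ps <- if ("pixel_size" %in% names(manifest)) manifest$pixel_size[i] else 1
    sc <- segment_scene(dna, actin, pixel_size = ps,
                        origin = c(manifest$x_origin[i],
                                   manifest$y_origin[i]), ...)
    nz <- sc$nucleus_mask > 0L
    cz <- sc$cell_mask > 0L
    sc$nucleus_mask[nz] <- sc$nucleus_mask[nz] + offset
    sc$cell_mask[cz] <- sc$cell_mask[cz] + offset
    offset <- offset + max(0L, sc$cell_mask)
    scenes[[i]] <- sc
  }
  scenes
}
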