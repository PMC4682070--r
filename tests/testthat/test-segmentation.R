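# Segmentation, boundary extraction, DNA measurement, z-projection.

make_test_scene <- function(n = 20, seed = 30, snr = 30, touching = FALSE) {
  tpl <- generate_templates(2, irregularity = 0.25, seed = seed)
  pop <- sample_population(tpl, c(0.5, 0.5), n = n, shape_noise = 0.05,
                           seed = seed + 1)
  if (touching) {
    pop <- place_population(pop, rbind(c(120, 120), c(168, 120)), 300, 300)
  } else {
    pop <- layout_scene(pop, n_colonies = 2, colony_spread = 90,
                        contact_fraction = 0, width = 900, height = 900,
                        seed = seed + 2)
  }
  render_scene(pop, snr = snr, dna_noise_cv = 0, seed = seed + 3)
}

test_that("segmentation recovers object counts and areas of a noiseless
          synthetic scene", {
  sc <- make_test_scene(20, snr = 1e6)
  seg <- segment_scene(sc$dna, sc$actin)
  n_nuc <- length(unique(seg$nucleus_mask[seg$nucleus_mask > 0]))
  n_cell <- length(unique(seg$cell_mask[seg$cell_mask > 0]))
  expect_equal(n_nuc, 20)
  expect_equal(n_cell, 20)
  # match segmented to truth labels by overlap; compare areas within 5%
  truth_areas <- label_areas(sc$cell_mask)
  seg_areas <- label_areas(seg$cell_mask)
  ov <- table(seg$cell_mask[seg$cell_mask > 0 & sc$cell_mask > 0],
              sc$cell_mask[seg$cell_mask > 0 & sc$cell_mask > 0])
  match_truth <- colnames(ov)[apply(ov, 1, which.max)]
  rel <- abs(as.numeric(seg_areas[rownames(ov)]) -
               as.numeric(truth_areas[match_truth])) /
    as.numeric(truth_areas[match_truth])
  expect_true(all(rel < 0.05))
})

test_that("segmentation recovers >= 95% of objects at snr 10", {
  sc <- make_test_scene(20, seed = 40, snr = 10)
  seg <- segment_scene(sc$dna, sc$actin)
  truth_labs <- sort(unique(sc$cell_mask[sc$cell_mask > 0]))
  recovered <- 0
  for (lab in truth_labs) {
    sel <- sc$cell_mask == lab
    seg_lab <- seg$cell_mask[sel]
    seg_lab <- seg_lab[seg_lab > 0]
    if (!length(seg_lab)) next
    best <- as.integer(names(sort(table(seg_lab), decreasing = TRUE))[1])
    inter <- sum(sel & seg$cell_mask == best)
    uni <- sum(sel | seg$cell_mask == best)
    if (inter / uni >= 0.8) recovered <- recovered + 1
  }
  expect_gte(recovered / length(truth_labs), 0.95)
})

test_that("blank images give an empty scene; shape mismatch errors", {
  blank <- matrix(0.5, 64, 64)
  seg <- segment_scene(blank, blank)
  expect_equal(sum(seg$nucleus_mask), 0)
  expect_equal(sum(seg$cell_mask), 0)
  expect_error(segment_scene(matrix(0, 10, 10), matrix(0, 12, 12)),
               "same shape")
})

test_that("touching cells are split and their contact edge is found", {
  sc <- make_test_scene(2, seed = 50, snr = 1e6, touching = TRUE)
  expect_equal(sc$truth$contact_count, c(1L, 1L))
  seg <- segment_scene(sc$dna, sc$actin)
  expect_equal(length(unique(seg$cell_mask[seg$cell_mask > 0])), 2)
  g <- build_contact_graph(seg$cell_mask)
  expect_equal(nrow(g$edges), 1)
  expect_equal(unname(g$rho_d), c(1L, 1L))
})

test_that("boundary extraction preserves label area", {
  # 10x10 square label
  m <- matrix(0L, 30, 30)
  m[10:19, 8:17] <- 1L
  scn <- labeled_scene(m, m)
  tr <- extract_boundaries(scn, "cell")[[1]]
  a <- abs(morphomodes:::polygon_signed_area(tr$vertices))
  expect_lt(abs(a - 100), 10)   # within one boundary-pixel band
  expect_gt(morphomodes:::polygon_signed_area(tr$vertices), 0)

  # disk of radius 30
  mk <- matrix(0L, 100, 100)
  for (x in 0:99) for (y in 0:99)
    if ((x - 50)^2 + (y - 50)^2 <= 900) mk[y + 1, x + 1] <- 1L
  trd <- extract_boundaries(labeled_scene(mk, mk), "cell")[[1]]
  ad <- abs(morphomodes:::polygon_signed_area(trd$vertices))
  expect_gt(ad / (pi * 900), 0.98)
  expect_lt(ad / (pi * 900), 1.02)
  expect_lt(abs(ad - sum(mk)), 0.3 * 2 * pi * 30)
})

test_that("labels touching the image edge are flagged on_tile_border", {
  m <- matrix(0L, 20, 20)
  m[1:6, 5:10] <- 1L       # touches row 1
  m[12:16, 12:16] <- 2L    # interior
  trs <- extract_boundaries(labeled_scene(m, m), "cell")
  flags <- sapply(trs, function(t) t$on_tile_border)
  ids <- sapply(trs, function(t) t$cell_id)
  expect_true(flags[ids == 1])
  expect_false(flags[ids == 2])
})

test_that("DNA measurement reproduces content ratios and ignores offsets", {
  tpl <- generate_templates(1, irregularity = 0, seed = 60)
  pop <- sample_population(tpl, 1, n = 2, seed = 61, size_noise_cv = 0)
  pop$truth$dna_content <- c(1, 2)
  pop <- place_population(pop, rbind(c(80, 80), c(220, 220)), 320, 320)
  sc <- render_scene(pop, dna_gain = 800, snr = 1e9, dna_noise_cv = 0,
                     seed = 62)
  scn <- labeled_scene(sc$nucleus_mask, sc$cell_mask)
  v <- measure_dna_content(sc$dna_noiseless, scn)
  expect_equal(unname(v[["2"]] / v[["1"]]), 2, tolerance = 0.01)
  # additive offset invariance (background subtraction)
  v2 <- measure_dna_content(sc$dna_noiseless + 0.37, scn)
  expect_equal(unname(v2[["2"]] / v2[["1"]]), unname(v[["2"]] / v[["1"]]),
               tolerance = 0.01)
  expect_lt(max(abs(v2 - v) / v), 0.01)
  # uniform zero image
  v0 <- measure_dna_content(matrix(0, 320, 320), scn)
  expect_true(all(v0 == 0))
})

test_that("z-projection: identity, max semantics and the Gaussian impulse
          oracle", {
  img <- matrix(runif(400), 20, 20)
  expect_equal(project_zstack(list(img), 0), img)

  disk <- matrix(0, 20, 20); disk[8:12, 8:12] <- 1
  out <- project_zstack(list(matrix(0, 20, 20), disk), 0)
  expect_equal(out, disk)

  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  got <- project_zstack(list(imp), 2)
  # independent closed-form kernel: normalized separable discrete Gaussian
  r <- ceiling(3.5 * 2)
  k1 <- dnorm(-r:r, 0, 2); k1 <- k1 / sum(k1)
  expect_lt(abs(max(got) - max(k1)^2), 1e-6)
  expect_equal(sum(got), 1, tolerance = 1e-6)
  expect_error(project_zstack(list(), 1), "empty")
})

test_that("a tile manifest is segmented with globally unique labels and
          stitched contacts", {
  tpl <- generate_templates(1, irregularity = 0.1, seed = 90)
  pop <- sample_population(tpl, 1, n = 2, shape_noise = 0, seed = 91,
                           size_noise_cv = 0)
  pop <- place_population(pop, rbind(c(180, 100), c(228, 100)), 400, 200)
  sc <- render_scene(pop, snr = 1e6, dna_noise_cv = 0, seed = 92)
  d <- withr::local_tempdir()
  half <- function(img, j) img[, j]
  for (side in 1:2) {
    cols <- if (side == 1) 1:200 else 201:400
    EBImage::writeImage(EBImage::Image(t(pmax(sc$dna[, cols], 0) /
                                           max(sc$dna))),
                        file.path(d, paste0("dna", side, ".tif")),
                        type = "tiff", bits.per.sample = 16L)
    EBImage::writeImage(EBImage::Image(t(pmax(sc$actin[, cols], 0) /
                                           max(sc$actin))),
                        file.path(d, paste0("actin", side, ".tif")),
                        type = "tiff", bits.per.sample = 16L)
  }
  manifest <- data.frame(dna_path = file.path(d, c("dna1.tif", "dna2.tif")),
                         actin_path = file.path(d, c("actin1.tif",
                                                     "actin2.tif")),
                         x_origin = c(0, 200), y_origin = c(0, 0))
  scenes <- segment_tiles(manifest)
  labs <- unlist(lapply(scenes, function(s)
    unique(s$cell_mask[s$cell_mask > 0])))
  expect_equal(length(labs), length(unique(labs)))   # globally unique
  g <- build_contact_graph(lapply(scenes, function(s)
    list(mask = s$cell_mask, origin = s$origin)))
  expect_equal(nrow(g$edges), 1)                     # stitched contact
  # boundaries come out in global coordinates
  tb <- extract_boundaries(scenes[[2]], "cell")
  expect_gt(min(tb[[1]]$vertices[, 1]), 199)
})

test_that("boundary traces round-trip through their CSV format", {
  tpl <- generate_templates(2, irregularity = 0.3, seed = 95)
  pop <- sample_population(tpl, c(0.5, 0.5), n = 5, seed = 96)
  f <- withr::local_tempfile(fileext = ".csv")
  write_boundaries_csv(pop$boundaries, f)
  back <- read_boundaries_csv(f)
  expect_equal(length(back), 10)
  ref <- shape_features(register_shape(pop$boundaries[[1]]))
  got_i <- which(vapply(back, function(tr)
    tr$cell_id == 1 && tr$compartment == "cell", logical(1)))
  expect_equal(shape_features(register_shape(back[[got_i]])), ref,
               tolerance = 1e-9)
})
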