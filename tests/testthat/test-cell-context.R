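# DNA gating, contact graphs, covariate trends, conditioned panels.

test_that("gating recovers phases of a noisy 2N/4N mixture", {
  set.seed(5)
  n <- 2000
  phase <- sample(c("G0G1", "S", "G2M"), n, TRUE, c(0.6, 0.25, 0.15))
  dna <- ifelse(phase == "G0G1", 1, ifelse(phase == "G2M", 2,
                                           runif(n, 1, 2)))
  raw <- 540 * dna * exp(rnorm(n, 0, 0.05))   # 5% multiplicative noise
  g <- normalize_and_gate_dna(raw)
  # threshold gates cannot resolve S-phase cells whose true content lies
  # inside the G0/G1 or G2/M gate; the recoverable truth is the phase the
  # gates imply for the noise-free content
  gate_truth <- ifelse(dna <= 1.25, "G0G1", ifelse(dna >= 1.75, "G2M", "S"))
  expect_gte(mean(g$phase == gate_truth), 0.95)
  # pure 2N and 4N cells are recovered essentially perfectly
  pure <- phase != "S"
  expect_gte(mean(g$phase[pure] == phase[pure]), 0.98)
  expect_lt(abs(median(g$dna_content_norm[phase == "G0G1"]) - 1), 0.05)
})

test_that("gating is gain-invariant and handles degenerate input", {
  set.seed(6)
  raw <- 300 * exp(rnorm(500, 0, 0.1))
  g1 <- normalize_and_gate_dna(raw)
  g2 <- normalize_and_gate_dna(raw * 2)
  expect_equal(g1$dna_content_norm, g2$dna_content_norm, tolerance = 1e-12)
  expect_identical(g1$phase, g2$phase)

  gc <- normalize_and_gate_dna(rep(7, 100))
  expect_true(all(gc$dna_content_norm == 1))
  expect_true(all(gc$phase == "G0G1"))
  gs <- normalize_and_gate_dna(rep(7, 10))
  expect_true(attr(gs, "low_confidence"))
})

test_that("a rendered hexagonal rosette has the exact contact degrees", {
  tpl <- generate_templates(1, irregularity = 0, seed = 70)
  pop <- sample_population(tpl, 1, n = 7, shape_noise = 0, seed = 71,
                           size_noise_cv = 0, phase_probs = c(1, 0, 0))
  xy <- hex_rosette_positions(c(200, 200), spacing = 55)  # radius 30 cells
  pop <- place_population(pop, xy, 400, 400)
  sc <- render_scene(pop, snr = 1e6, dna_noise_cv = 0, seed = 72)
  g <- build_contact_graph(sc$cell_mask, contact_gap = 1)
  deg <- g$rho_d[as.character(1:7)]
  expect_equal(unname(deg[1]), 6L)              # center: crowded
  expect_true(all(deg[2:7] == 3L))              # petals: semi-crowded
  expect_equal(unname(g$density_category[1]), "crowded")
  expect_true(all(g$density_category[2:7] == "semi"))
  # generator truth agrees
  expect_equal(pop$truth$contact_count, c(6L, rep(3L, 6)))
})

test_that("contact graph is invariant to tile splitting", {
  tpl <- generate_templates(1, irregularity = 0.1, seed = 73)
  pop <- sample_population(tpl, 1, n = 2, shape_noise = 0, seed = 74,
                           size_noise_cv = 0)
  # contact pair straddling the x = 200 tile boundary
  pop <- place_population(pop, rbind(c(180, 100), c(228, 100)), 400, 200)
  sc <- render_scene(pop, snr = 1e6, dna_noise_cv = 0, seed = 75)
  g_whole <- build_contact_graph(sc$cell_mask)
  expect_equal(nrow(g_whole$edges), 1)

  left <- sc$cell_mask[, 1:200]
  right <- sc$cell_mask[, 201:400]
  g_tiled <- build_contact_graph(list(
    list(mask = left, origin = c(0, 0)),
    list(mask = right, origin = c(200, 0))))
  expect_equal(g_tiled$edges, g_whole$edges)
  expect_equal(g_tiled$rho_d, g_whole$rho_d)

  # processed independently, the contact is lost: stitching is required
  g_left <- build_contact_graph(left)
  g_right <- build_contact_graph(right)
  expect_lt(nrow(g_left$edges) + nrow(g_right$edges), 1 + 1)

  # overlapping tiles that disagree on a label are rejected
  bad <- right
  bad[bad > 0] <- 9L
  expect_error(build_contact_graph(list(
    list(mask = sc$cell_mask, origin = c(0, 0)),
    list(mask = bad, origin = c(200, 0)))), "conflict")
})

test_that("isolated cells are singlets", {
  m <- matrix(0L, 50, 50)
  m[10:20, 10:20] <- 1L
  g <- build_contact_graph(m)
  expect_equal(unname(g$rho_d), 0L)
  expect_equal(unname(g$density_category), "singlet")
})

context_records <- function(n, seed = 7, mode_fun = NULL) {
  set.seed(seed)
  dna <- runif(n, 1, 2)
  mode1_p <- if (is.null(mode_fun)) rep(0.25, n) else mode_fun(dna)
  nucleus_mode <- ifelse(runif(n) < mode1_p, 1,
                         sample(2:4, n, TRUE))
  data.frame(sample_id = "S1", cell_id = 1:n,
             R_N = 10 * dna^(1 / 3), R_C = 28 * dna^(1 / 3),
             nucleus_mode = nucleus_mode,
             cell_mode = sample(1:4, n, TRUE),
             dna_content_norm = dna,
             phase = ifelse(dna < 1.25, "G0G1",
                            ifelse(dna > 1.75, "G2M", "S")),
             rho_D = rpois(n, 1),
             stringsAsFactors = FALSE)
}

test_that("equal-size grouping splits 18 cells into 9 pairs", {
  rec <- context_records(18)
  tr <- covariate_trend_analysis(rec, "dna", 9)
  expect_true(all(tr$groups$n == 2))
  expect_equal(sum(tr$groups$n), 18)
  expect_true(all(diff(tr$groups$mean_covariate) >= 0))
  expect_equal(min(tr$groups$norm_R_N), 1)
})

test_that("a mode whose occupancy rises with DNA content gets a high
          Pearson r", {
  rec <- context_records(3000, seed = 8,
                         mode_fun = function(d) 0.1 + 0.8 * (d - 1))
  rec$density_category <- density_category(rec$rho_D)
  tr <- covariate_trend_analysis(rec, "dna", 9)
  r1 <- tr$correlations$r[tr$correlations$compartment == "nucleus" &
                            tr$correlations$mode == 1]
  expect_gte(r1, 0.9)
})

test_that("null mode-covariate dependence gives small correlations on
          average", {
  set.seed(9)
  rs <- replicate(60, {
    rec <- context_records(900, seed = sample.int(1e6, 1))
    tr <- covariate_trend_analysis(rec, "dna", 9)
    tr$correlations$r[tr$correlations$compartment == "nucleus" &
                        tr$correlations$mode == 2]
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("constant covariate yields missing correlations", {
  rec <- context_records(50)
  rec$dna_content_norm <- 1
  tr <- covariate_trend_analysis(rec, "dna", 5)
  expect_true(all(is.na(tr$correlations$r)))
})

test_that("conditioned panels preserve an entropy ordering that holds in
          every condition", {
  set.seed(10)
  n <- 1200
  mk <- function(weights, sid) {
    rec <- data.frame(
      sample_id = sid, cell_id = 1:n,
      R_N = runif(n, 9, 11), R_C = runif(n, 25, 30),
      nucleus_mode = sample(1:5, n, TRUE, weights),
      cell_mode = sample(1:5, n, TRUE, weights),
      phase = sample(c("G0G1", "S", "G2M"), n, TRUE, c(0.5, 0.3, 0.2)),
      rho_D = rpois(n, 2), stringsAsFactors = FALSE)
    rec$density_category <- density_category(rec$rho_D)
    rec
  }
  recs <- rbind(mk(rep(0.2, 5), "HI"),
                mk(c(0.8, 0.05, 0.05, 0.05, 0.05), "LO"))
  panels <- conditioned_panels(recs, 5, 5)
  for (tag in unique(panels$condition_tag)) {
    hi <- panels[panels$sample_id == "HI" & panels$condition_tag == tag, ]
    lo <- panels[panels$sample_id == "LO" & panels$condition_tag == tag, ]
    if (!hi$available || !lo$available) next
    expect_gt(hi$entropy_nucleus, lo$entropy_nucleus)
    expect_gt(hi$entropy_cell, lo$entropy_cell)
    expect_gt(hi$entropy_joint, lo$entropy_joint)
  }
  # cells partition across phase conditions
  phase_tags <- paste0("phase=", c("G0G1", "S", "G2M"))
  hi_counts <- panels$n_cells[panels$sample_id == "HI" &
                                panels$condition_tag %in% phase_tags]
  expect_equal(sum(hi_counts), n)
})

test_that("samples gated entirely G0G1 mark other phase panels
          unavailable", {
  n <- 100
  rec <- data.frame(sample_id = "S1", cell_id = 1:n,
                    R_N = runif(n, 9, 11), R_C = runif(n, 25, 30),
                    nucleus_mode = sample(1:3, n, TRUE),
                    cell_mode = sample(1:3, n, TRUE),
                    phase = "G0G1", rho_D = 0L,
                    density_category = "singlet", stringsAsFactors = FALSE)
  panels <- conditioned_panels(rec, 3, 3)
  expect_false(panels$available[panels$condition_tag == "phase=S"])
  expect_false(panels$available[panels$condition_tag == "phase=G2M"])
  expect_true(panels$available[panels$condition_tag == "phase=G0G1"])
})
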