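# Clonal structure: colony identification, proximity correlation,
# variance decomposition, heritable variation, signature classification.

test_that("colony identification recovers generator colonies", {
  tpl <- generate_templates(1, irregularity = 0.1, seed = 80)
  pop <- sample_population(tpl, 1, n = 32, seed = 81)
  laid <- layout_scene(pop, n_colonies = 4, colony_spread = 30,
                       contact_fraction = 0, width = 1400, height = 1400,
                       seed = 82)
  got <- identify_colonies(laid$truth, linkage_distance = 200, min_size = 5)
  expect_false(any(is.na(got)))
  expect_equal(best_permutation_agreement(laid$truth$colony_id, got), 1.0)
})

test_that("chained cells form one colony; sparse singlets are unassigned", {
  rec <- data.frame(x = seq(0, 90, by = 10), y = 0)
  got <- identify_colonies(rec, linkage_distance = 15, min_size = 5)
  expect_true(all(got == 1))

  rec2 <- data.frame(x = c(0, 500), y = c(0, 0))
  got2 <- identify_colonies(rec2, linkage_distance = 15, min_size = 5)
  expect_true(all(is.na(got2)))
})

make_colony_records <- function(n_col = 10, m = 40, colony_cv = 0.15,
                                noise_cv = 0.05, seed = 1,
                                spread = 20, gap = 400) {
  set.seed(seed)
  colony <- rep(seq_len(n_col), each = m)
  cfac <- exp(rnorm(n_col, 0, colony_cv))
  size <- cfac[colony] * exp(rnorm(n_col * m, 0, noise_cv))
  data.frame(sample_id = "S1", cell_id = seq_len(n_col * m),
             R_N = 10 * size, R_C = 28 * size,
             phase = "G0G1", rho_D = 0L, density_category = "singlet",
             x = gap * ((colony - 1) %% 5) + rnorm(n_col * m, 0, spread),
             y = gap * ((colony - 1) %/% 5) + rnorm(n_col * m, 0, spread),
             colony_id = colony, stringsAsFactors = FALSE)
}

test_that("heritable colony effects raise near-pair correlation above the
          permutation band; far pairs show no elevation", {
  rec <- make_colony_records(n_col = 25, m = 20, seed = 2, gap = 300)
  pc <- proximity_correlation(rec, "R_N",
                              distance_bins = c(0, 80, 300, 700, 2000),
                              n_permutations = 200, seed = 3)
  expect_gt(pc$r[1], pc$null_hi[1])            # within-colony bin
  # far pairs carry only the small O(1/n_colonies) between-colony bias
  expect_lt(pc$r[4], pc$null_hi[4] + 0.02)
  expect_gt(pc$r[4], pc$null_lo[4] - 0.05)
})

test_that("zero colony effect keeps correlations inside the null band", {
  set.seed(4)
  inside <- unlist(lapply(1:10, function(s) {
    rec <- make_colony_records(n_col = 6, m = 25, colony_cv = 0,
                               noise_cv = 0.1, seed = 100 + s)
    pc <- proximity_correlation(rec, "R_N",
                                distance_bins = c(0, 80, 300, 2000),
                                n_permutations = 150, seed = s)
    ok <- !is.na(pc$r)
    pc$r[ok] <= pc$null_hi[ok] & pc$r[ok] >= pc$null_lo[ok]
  }))
  # per-bin coverage of the 95% permutation band
  expect_gte(mean(inside), 0.9)
})

test_that("variance decomposition recovers constructed components", {
  # size = colony factor x residual with equal log-variances h = e:
  # expected scaled within-clone variance e/(h+e) = 0.5
  set.seed(5)
  vals <- sapply(1:20, function(s) {
    rec <- make_colony_records(n_col = 25, m = 200, colony_cv = 0.1,
                               noise_cv = 0.1, seed = 200 + s)
    vd <- variance_decomposition(rec)
    c(vd$scaled_variance[vd$feature == "R_N" & vd$condition == "all"],
      vd$scaled_variance[vd$feature == "R_N" &
                           vd$condition == "within_clone_all"])
  })
  expect_true(all(vals[1, ] == 1))             # normalization identity
  expect_lt(abs(mean(vals[2, ]) - 0.5), 0.1)

  # permuting colony labels restores the scaled within-clone variance to 1
  rec <- make_colony_records(n_col = 25, m = 200, colony_cv = 0.1,
                             noise_cv = 0.1, seed = 6)
  set.seed(7)
  rec$colony_id <- sample(rec$colony_id)
  vdp <- variance_decomposition(rec)
  wc <- vdp$scaled_variance[vdp$feature == "R_N" &
                              vdp$condition == "within_clone_all"]
  expect_lt(abs(wc - 1), 0.1)
})

test_that("homogeneous populations have all scaled variances near 1", {
  set.seed(8)
  n <- 4000
  rec <- data.frame(sample_id = "S1", cell_id = 1:n,
                    R_N = 10 * exp(rnorm(n, 0, 0.1)),
                    R_C = 28 * exp(rnorm(n, 0, 0.1)),
                    phase = sample(c("G0G1", "S", "G2M"), n, TRUE),
                    rho_D = rpois(n, 2), colony_id = rep(1:20, each = 200),
                    stringsAsFactors = FALSE)
  rec$density_category <- density_category(rec$rho_D)
  vd <- variance_decomposition(rec)
  ok <- !is.na(vd$scaled_variance)
  expect_true(all(abs(vd$scaled_variance[ok] - 1) < 0.25))
})

test_that("heritable variation matches hand-computed colony factors", {
  # colony means {0.8, 1.0, 1.2} with negligible within-colony noise:
  # CV = sd/mean = 0.2/sqrt(3)... computed directly below
  m <- 60
  rec <- data.frame(sample_id = "S1",
                    R_N = rep(c(0.8, 1.0, 1.2), each = m),
                    R_C = rep(c(0.8, 1.0, 1.2), each = m),
                    phase = "G0G1",
                    colony_id = rep(1:3, each = m),
                    stringsAsFactors = FALSE)
  # CV uses the sample (n - 1) standard deviation throughout the package:
  # sd({0.8, 1.0, 1.2}) = 0.2, mean = 1
  hv <- heritable_variation(rec)
  expect_equal(unname(hv[["R_N"]]), sd(c(0.8, 1, 1.2)) / 1,
               tolerance = 1e-9)
  expect_equal(unname(hv[["R_N"]]), 0.2, tolerance = 1e-12)

  # identical colonies: CV of colony means = 0
  rec0 <- rec
  rec0$R_N <- rep(1, nrow(rec0)); rec0$R_C <- rep(1, nrow(rec0))
  hv0 <- heritable_variation(rec0)
  expect_equal(unname(hv0[["R_N"]]), 0)
  expect_error(heritable_variation(rec[rec$colony_id < 3, ]),
               "at least 3")
})

test_that("colony-mean CV shrinks like the standard error of the mean", {
  # identical colony distributions, per-cell CV 10%, colony size 100:
  # colony-mean CV ~ 0.1 / sqrt(100) = 1%
  set.seed(9)
  cvs <- sapply(1:20, function(s) {
    rec <- make_colony_records(n_col = 12, m = 100, colony_cv = 0,
                               noise_cv = 0.1, seed = 300 + s)
    heritable_variation(rec)[["R_N"]]
  })
  expect_gt(mean(cvs), 0.005)
  expect_lt(mean(cvs), 0.02)
})

make_group_records <- function(sid, skew, n = 500, seed = 1,
                               size_cv = 0.1) {
  set.seed(seed)
  w <- exp(-skew * (0:4)); w <- w / sum(w)
  rho <- rpois(n, 1)
  data.frame(sample_id = sid, cell_id = seq_len(n),
             R_N = 10 * exp(rnorm(n, 0, size_cv)),
             R_C = 28 * exp(rnorm(n, 0, size_cv)),
             nucleus_mode = sample(1:5, n, TRUE, w),
             cell_mode = sample(1:5, n, TRUE, w),
             phase = "G0G1", rho_D = rho,
             density_category = density_category(rho),
             stringsAsFactors = FALSE)
}

test_that("separable groups are classified accurately, with accuracy
          growing in subsample size", {
  recs <- do.call(rbind, c(
    lapply(1:3, function(i) make_group_records(paste0("PTlike", i), 0,
                                               seed = i, size_cv = 0.18)),
    lapply(1:3, function(i) make_group_records(paste0("LMlike", i), 1.6,
                                               seed = 10 + i,
                                               size_cv = 0.06))))
  labels <- setNames(rep(c("PT", "LM"), each = 3),
                     c(paste0("PTlike", 1:3), paste0("LMlike", 1:3)))
  res <- signature_and_classification(recs, labels,
                                      subsample_sizes = c(30, 100, 300, 500),
                                      n_repeats = 15, seed = 11, K_N = 5)
  acc <- res$accuracy$mean_accuracy
  expect_gte(acc[length(acc)], 0.95)
  expect_true(all(diff(acc) >= -0.05))
  # full-sample subsample reproduces the full-sample features exactly
  full <- res$signatures
  f1 <- signature_features(recs[recs$sample_id == "PTlike1", ], 5)
  expect_equal(unname(unlist(full[full$sample_id == "PTlike1",
                                  1:3])), unname(f1))
})

test_that("identical generators give chance-level accuracy", {
  recs <- do.call(rbind, lapply(1:6, function(i)
    make_group_records(paste0("S", i), 0.5, seed = 40 + i)))
  labels <- setNames(rep(c("A", "B"), 3), paste0("S", 1:6))
  res <- signature_and_classification(recs, labels,
                                      subsample_sizes = c(200),
                                      n_repeats = 40, seed = 12, K_N = 5)
  expect_lt(abs(res$accuracy$mean_accuracy - 0.5), 0.25)
})

test_that("classification preconditions are enforced", {
  recs <- make_group_records("S1", 0, seed = 1)
  expect_error(signature_and_classification(
    recs, setNames("A", "S1"), 100), ">= 2 samples")
})
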