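# End-to-end orchestration: cell-record assembly, flat key-value run
# configs, and the staged pipeline with a reproducible run manifest.

#' Assemble per-cell records from registration and context results
#'
#' Joins the nucleus and cell registrations by cell id, attaches DNA
#' gating, contact degree and positions, and computes the conventional
#' descriptors (shape factor, aspect ratio) from the cell outlines.
#'
#' @param reg result of [register_boundaries()] over both compartments.
#' @param traces the boundary traces that were registered (for the
#'   conventional descriptors).
#' @param gating optional data.frame from [normalize_and_gate_dna()]
#'   (rows in nucleus cell-id order) plus a `dna_content_raw` vector
#'   attribute, or NULL.
#' @param rho_d optional named integer vector of contact degrees keyed by
#'   cell id.
#' @param positions optional data.frame with cell_id, x, y, colony_id.
#' @return data.frame of cell records: sample_id, cell_id, R_N, R_C,
#'   nucleus_mode, cell_mode (NA until modes are fitted),
#'   dna_content_raw, dna_content_norm, phase, rho_D, density_category,
#'   x, y, colony_id, shape_factor, aspect_ratio, on_tile_border.
#' @export
build_cell_records <- function(reg, traces = NULL, gating = NULL,
                               rho_d = NULL, positions = NULL) {
  info <- reg$info
  nuc <- info[info$compartment == "nucleus", , drop = FALSE]
  cel <- info[info$compartment == "cell", , drop = FALSE]
  key <- function(d) paste(d$sample_id, d$cell_id)
  m <- match(key(nuc), key(cel))
  nuc <- nuc[!is.na(m), , drop = FALSE]
  cel <- cel[m[!is.na(m)], , drop = FALSE]
  rec <- data.frame(sample_id = nuc$sample_id, cell_id = nuc$cell_id,
                    R_N = nuc$R, R_C = cel$R,
                    nucleus_mode = NA_integer_, cell_mode = NA_integer_,
                    dna_content_raw = NA_real_, dna_content_norm = NA_real_,
                    phase = NA_character_, rho_D = NA_integer_,
                    density_category = NA_character_,
                    x = NA_real_, y = NA_real_, colony_id = NA_integer_,
                    shape_factor = NA_real_, aspect_ratio = NA_real_,
                    on_tile_border = FALSE, stringsAsFactors = FALSE)
  if (!is.null(traces)) {
    for (tr in traces) {
      if (tr$compartment != "cell") next
      i <- which(rec$cell_id == tr$cell_id &
                   rec$sample_id %in% tr$sample_id)
      if (!length(i)) next
      sd_ <- shape_descriptors(tr)
      rec$shape_factor[i] <- sd_[["shape_factor"]]
      rec$aspect_ratio[i] <- sd_[["aspect_ratio"]]
      rec$on_tile_border[i] <- tr$on_tile_border
    }
  }
  if (!is.null(gating)) {
    rec$dna_content_norm <- gating$dna_content_norm
    rec$phase <- gating$phase
    if (!is.null(attr(gating, "raw")))
      rec$dna_content_raw <- attr(gating, "raw")
  }
  if (!is.null(rho_d)) {
    idx <- match(as.character(rec$cell_id), names(rho_d))
    rec$rho_D <- as.integer(rho_d[idx])
    rec$density_category <- density_category(rec$rho_D)
  }
  if (!is.null(positions)) {
    idx <- match(rec$cell_id, positions$cell_id)
    rec$x <- positions$x[idx]
    rec$y <- positions$y[idx]
    if (!is.null(positions$colony_id))
      rec$colony_id <- positions$colony_id[idx]
  }
  rec
}

#' Read / write a flat key-value run configuration
#'
#' The config file holds one `key = value` pair per line (comments start
#' with `#`); values may be numbers, `true`/`false`, or comma-separated
#' lists. Every stochastic stage must have an explicit seed.
#'
#' @param path file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1L]])
    conv <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!any(is.na(conv))) conv
    else if (all(parts %in% c("true", "false"))) parts == "true"
    else parts
  }
  out
}

#' @rdname read_run_config
#' @param config named list of parameters.
#' @export
write_run_config <- function(config, path) {
  fmt <- function(v) {
    if (is.logical(v)) v <- ifelse(v, "true", "false")
    paste(format(v, scientific = FALSE, trim = TRUE), collapse = ", ")
  }
  writeLines(paste0(names(config), " = ", vapply(config, fmt, character(1))),
             path)
  invisible(path)
}

default_run_config <- function() {
  list(mode = "simulate", n_samples = 2, cells_per_sample = 150,
       templates_k = 4, irregularity = 0.35, shape_noise = 0.06,
       sample_skews = c(0, 1.2), sample_groups = c("A", "B"),
       n_colonies = 4, colony_spread = 60, contact_fraction = 0.25,
       colony_size_cv = 0.08, image_width = 1200, image_height = 1200,
       render = FALSE, n_points = 50, variance_threshold = 0.95,
       k_min = 2, k_max = 8, n_init = 10, g1_hi = 1.25, g2_lo = 1.75,
       contact_gap = 1, linkage_distance = 80, min_colony_size = 5,
       dna_noise_cv = 0.05, snr = 20, seed = 1)
}

#' Run the full morpho-phenotyping pipeline
#'
#' Stages, in dependency order: (simulate |) segment, register,
#' eigenshapes, shape modes, mode distributions, heterogeneity panels,
#' cell context (DNA gating, contacts, trends), heritability analyses,
#' and the signature classification. Artifacts are written as CSV/JSON
#' into `out_dir` with a manifest recording parameters, seeds and output
#' hashes, so identical configs give identical outputs.
#'
#' In `mode = "simulate"` each sample draws its cells from shared latent
#' templates with a sample-specific skew over template weights (weight of
#' template t proportional to exp(-skew * (t - 1)): skew 0 is a uniform,
#' maximally heterogeneous sample). With `render = TRUE` scenes are
#' rendered and segmented; otherwise the generator boundaries feed the
#' registration stage directly (the boundaries-only entry point).
#' In `mode = "boundaries"` pre-extracted outlines are read from
#' `boundary_csv` (columns sample_id, cell_id, compartment, vertex_index,
#' x, y) and image stages are skipped.
#'
#' @param config named list (see [read_run_config()]) or path to a config
#'   file. Missing keys fall back to documented defaults; `seed` is
#'   required.
#' @param out_dir output directory.
#' @return Invisibly, a list with the main in-memory results (records,
#'   eigenshape models, mode models, panels, manifest path).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  if (is.null(config$seed))
    stop("config validation: an explicit seed is required", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  log_stage <- function(...) message("[pipeline] ", ...)

  ## ---- inputs: simulate or load boundaries --------------------------------
  all_traces <- list()
  truth_list <- list()
  sample_ids <- character(0)
  if (identical(cfg$mode, "simulate")) {
    log_stage("simulate: ", cfg$n_samples, " samples x ",
              cfg$cells_per_sample, " cells")
    templates <- generate_templates(cfg$templates_k, cfg$irregularity,
                                    seed = seed)
    nuc_templates <- generate_templates(cfg$templates_k,
                                        cfg$irregularity * 0.6,
                                        seed = seed + 500L)
    for (s in seq_len(cfg$n_samples)) {
      sid <- sprintf("S%02d", s)
      sample_ids <- c(sample_ids, sid)
      skew <- cfg$sample_skews[[min(s, length(cfg$sample_skews))]]
      w <- exp(-skew * (seq_len(cfg$templates_k) - 1))
      w <- w / sum(w)
      pop <- sample_population(templates, w, cfg$cells_per_sample,
                               shape_noise = cfg$shape_noise,
                               seed = seed + 1000L * s, sample_id = sid,
                               nucleus_templates = nuc_templates)
      pop <- layout_scene(pop, n_colonies = cfg$n_colonies,
                          colony_spread = cfg$colony_spread,
                          contact_fraction = cfg$contact_fraction,
                          width = cfg$image_width, height = cfg$image_height,
                          seed = seed + 1000L * s + 1L,
                          colony_size_cv = cfg$colony_size_cv)
      if (isTRUE(cfg$render)) {
        scene <- render_scene(pop, snr = cfg$snr,
                              dna_noise_cv = cfg$dna_noise_cv,
                              seed = seed + 1000L * s + 2L)
        seg <- segment_scene(scene$dna, scene$actin)
        traces <- extract_boundaries(seg, sample_id = sid)
        graph <- build_contact_graph(seg$cell_mask, cfg$contact_gap)
        dna_raw <- measure_dna_content(scene$dna, seg)
        attr(traces, "graph") <- graph
        attr(traces, "dna_raw") <- dna_raw
      } else {
        traces <- pop$boundaries
      }
      truth_list[[sid]] <- pop$truth
      all_traces[[sid]] <- traces
    }
  } else if (identical(cfg$mode, "boundaries")) {
    log_stage("boundaries: reading ", cfg$boundary_csv)
    traces <- read_boundaries_csv(cfg$boundary_csv)
    sids <- vapply(traces, function(tr) tr$sample_id, character(1))
    sample_ids <- unique(sids)
    for (sid in sample_ids) all_traces[[sid]] <- traces[sids == sid]
  } else stop("unknown mode: ", cfg$mode, call. = FALSE)

  ## ---- register -----------------------------------------------------------
  traces_flat <- do.call(c, unname(all_traces))
  log_stage("register: ", length(traces_flat), " traces")
  reg <- register_boundaries(traces_flat, n_points = cfg$n_points)
  write_csv_out <- function(d, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(d, p, row.names = FALSE)
    p
  }
  reg_tab <- cbind(reg$info, as.data.frame(reg$features))
  names(reg_tab)[-(1:5)] <- c(paste0("x", seq_len(cfg$n_points)),
                              paste0("y", seq_len(cfg$n_points)))
  files <- c(registered = write_csv_out(reg_tab, "registered_shapes.csv"))

  ## ---- eigenshapes + modes per compartment --------------------------------
  models <- list(); mode_models <- list(); scores <- list()
  for (comp in c("nucleus", "cell")) {
    sel <- reg$info$compartment == comp
    feats <- reg$features[sel, , drop = FALSE]
    em <- fit_eigenshapes(feats, cfg$variance_threshold, compartment = comp)
    pr <- project_and_reconstruct(em, feats)
    ksel <- select_num_modes(pr$scores, cfg$k_min,
                             min(cfg$k_max, nrow(pr$scores) - 1L),
                             seed = seed + 7L, n_init = cfg$n_init)
    mm <- fit_shape_modes(pr$scores, ksel$k_best, em, seed = seed + 11L,
                          n_init = cfg$n_init)
    log_stage(comp, ": m = ", em$m, " eigenshapes, K = ", mm$K, " modes")
    models[[comp]] <- em
    mode_models[[comp]] <- mm
    scores[[comp]] <- pr$scores
    write_eigenshape_model(em, out_dir, paste0("eigenshapes_", comp))
    files[paste0("diagnostics_", comp)] <-
      write_csv_out(ksel$diagnostics, paste0("mode_diagnostics_", comp, ".csv"))
    files[paste0("centroids_", comp)] <-
      write_csv_out(as.data.frame(mm$centroids),
                    paste0("mode_centroids_", comp, ".csv"))
  }

  ## ---- cell records + context --------------------------------------------
  log_stage("context: gating + contacts")
  gating_all <- NULL
  pos_all <- NULL
  if (length(truth_list)) {
    truth_all <- do.call(rbind, truth_list)
    raw <- truth_all$dna_content    # generator truth as measured intensity
    gating <- normalize_and_gate_dna(raw, cfg$g1_hi, cfg$g2_lo)
    attr(gating, "raw") <- raw
    gating_all <- gating
    pos_all <- data.frame(cell_id = truth_all$cell_id, x = truth_all$x,
                          y = truth_all$y)
  }
  rec <- build_cell_records(reg, traces_flat, gating = gating_all,
                            positions = NULL)
  ## per-sample context from truth (positions, contacts, colonies)
  if (length(truth_list)) {
    for (sid in sample_ids) {
      tr <- truth_list[[sid]]
      i <- which(rec$sample_id == sid)
      m <- match(rec$cell_id[i], tr$cell_id)
      rec$x[i] <- tr$x[m]; rec$y[i] <- tr$y[m]
      rec$rho_D[i] <- tr$contact_count[m]
      rec$colony_id[i] <- tr$colony_id[m]
    }
    rec$density_category <- density_category(rec$rho_D)
  }
  nuc_sel <- reg$info$compartment == "nucleus"
  cell_sel <- reg$info$compartment == "cell"
  rec$nucleus_mode <- mode_models$nucleus$labels[
    match(paste(rec$sample_id, rec$cell_id),
          paste(reg$info$sample_id[nuc_sel], reg$info$cell_id[nuc_sel]))]
  rec$cell_mode <- mode_models$cell$labels[
    match(paste(rec$sample_id, rec$cell_id),
          paste(reg$info$sample_id[cell_sel], reg$info$cell_id[cell_sel]))]
  files["cell_records"] <- write_csv_out(rec, "cell_records.csv")

  ## ---- distributions + panels --------------------------------------------
  log_stage("profile: mode distributions + heterogeneity panels")
  K_N <- mode_models$nucleus$K; K_C <- mode_models$cell$K
  panels <- conditioned_panels(rec, K_N, K_C)
  files["panels"] <- write_csv_out(panels, "heterogeneity_panels.csv")
  dist_rows <- lapply(sample_ids, function(sid) {
    rs <- rec[rec$sample_id == sid, ]
    md <- mode_distribution(rs$nucleus_mode, rs$cell_mode, K_N, K_C, sid)
    data.frame(sample_id = sid, mode = seq_len(K_N),
               p_nucleus = md$p_nucleus,
               p_cell = c(md$p_cell, rep(NA, max(0, K_N - K_C)))[seq_len(K_N)])
  })
  files["distributions"] <- write_csv_out(do.call(rbind, dist_rows),
                                          "mode_distributions.csv")

  ## ---- trends, heritability, signature ------------------------------------
  if (!all(is.na(rec$dna_content_norm))) {
    tr_dna <- covariate_trend_analysis(rec, "dna", K_N = K_N, K_C = K_C)
    files["trend_dna"] <- write_csv_out(tr_dna$groups, "trend_dna_groups.csv")
    files["trend_dna_cor"] <- write_csv_out(tr_dna$correlations,
                                            "trend_dna_correlations.csv")
  }
  herit <- NULL
  if (!all(is.na(rec$colony_id))) {
    log_stage("heritability: variance decomposition")
    vd <- do.call(rbind, lapply(sample_ids, function(sid) {
      out <- variance_decomposition(rec[rec$sample_id == sid, ],
                                    min_size = cfg$min_colony_size)
      out$sample_id <- sid
      out
    }))
    files["variance_decomposition"] <-
      write_csv_out(vd, "variance_decomposition.csv")
    hv <- lapply(sample_ids, function(sid) {
      res <- tryCatch(heritable_variation(rec[rec$sample_id == sid, ],
                                          min_size = cfg$min_colony_size),
                      error = function(e) c(R_N = NA_real_, R_C = NA_real_))
      data.frame(sample_id = sid, cv_colony_mean_R_N = res[["R_N"]],
                 cv_colony_mean_R_C = res[["R_C"]])
    })
    herit <- do.call(rbind, hv)
    files["heritable_variation"] <- write_csv_out(herit,
                                                  "heritable_variation.csv")
  }
  sig <- do.call(rbind, lapply(sample_ids, function(sid) {
    f <- signature_features(rec[rec$sample_id == sid, ], K_N)
    data.frame(sample_id = sid, t(f))
  }))
  files["signature"] <- write_csv_out(sig, "signature_features.csv")

  ## ---- manifest -----------------------------------------------------------
  manifest <- list(package_version = as.character(utils::packageVersion("morphomodes")),
                   config = cfg, seed = seed,
                   n_cells = nrow(rec),
                   eigenshapes = list(nucleus = models$nucleus$m,
                                      cell = models$cell$m),
                   modes = list(nucleus = K_N, cell = K_C),
                   output_md5 = as.list(tools::md5sum(unname(files))))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_stage("done: ", nrow(rec), " cells, outputs in ", out_dir)
  invisible(list(records = rec, eigen_models = models,
                 mode_models = mode_models, panels = panels,
                 signature = sig, heritable = herit, files = files,
                 manifest = mpath))
}
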