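## Orchestration: configuration, stage execution (stimuli -> extraction ->
## metrics -> stats -> report), caching, and report rendering.

#' Pipeline run configuration
#'
#' @param out_dir output directory (created if missing).
#' @param stimulus_source `"builtin_bars"` (no external files) or
#'   `"image_dir"`.
#' @param image_dir directory of source object images (PNG/PPM) when
#'   `stimulus_source = "image_dir"`.
#' @param colorspace calibration space, `"cieluv"` or `"synthetic_hsv"`.
#' @param calibration a [calibration_target()]; defaults to the package
#'   defaults in the chosen space.
#' @param variants stimulus variants to build for image sources.
#' @param bar_geometry a [bar_spec()] for the builtin bars.
#' @param networks list of network specs, each
#'   `list(architecture, weights = "random"|"toy", seeds = <ints>)`.
#' @param metric first-order similarity metric (`"pearson"` or
#'   `"euclidean"`).
#' @param n_shuffles shuffle-null iterations per layer.
#' @param seed master seed.
#' @param input_px toy-network input resolution.
#' @param n_stages exposed stages of the toy network (including the final
#'   spatial average).
#' @return a `run_config` object with a stable `config_hash`.
#' @export
run_config <- function(out_dir,
                       stimulus_source = c("builtin_bars", "image_dir"),
                       image_dir = NULL,
                       colorspace = c("cieluv", "synthetic_hsv"),
                       calibration = NULL,
                       variants = c("textured", "silhouette"),
                       bar_geometry = bar_spec(),
                       networks = list(list(architecture = "toy",
                                            weights = "random", seeds = 1L)),
                       metric = "pearson",
                       n_shuffles = 100L,
                       seed = 1L,
                       input_px = 64L,
                       n_stages = 5L) {
  stimulus_source <- match.arg(stimulus_source)
  colorspace <- match.arg(colorspace)
  if (is.null(calibration)) calibration <- calibration_target(colorspace)
  if (stimulus_source == "image_dir" &&
      (is.null(image_dir) || !dir.exists(image_dir))) {
    stop("image_dir does not exist", call. = FALSE)
  }
  cfg <- list(out_dir = out_dir, stimulus_source = stimulus_source,
              image_dir = image_dir, colorspace = colorspace,
              calibration = calibration, variants = variants,
              bar_geometry = bar_geometry, networks = networks,
              metric = metric, n_shuffles = as.integer(n_shuffles),
              seed = as.integer(seed), input_px = as.integer(input_px),
              n_stages = as.integer(n_stages))
  cfg$config_hash <- digest::digest(cfg[setdiff(names(cfg), "out_dir")])
  class(cfg) <- "run_config"
  cfg
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

.write_table <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Stage 1: build the calibrated stimulus set
#'
#' Writes PNG stimuli, the manifest CSV, and an independent calibration
#' audit to `<out_dir>/stimuli/`. The builtin-bars source needs no external
#' files.
#'
#' @param config a [run_config()].
#' @return the `chromaform_stimulus_set`, invisibly (manifest includes audit
#'   columns).
#' @export
run_stimulus_stage <- function(config) {
  dir <- file.path(config$out_dir, "stimuli")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (config$stimulus_source == "builtin_bars") {
    set <- make_bars(config$bar_geometry, config$calibration)
  } else {
    set <- .stimuli_from_image_dir(config)
  }
  audit <- do.call(rbind, lapply(set$stimuli, audit_calibration))
  paths <- sprintf("%s_h%02d_%s.png", audit$object_id,
                   ifelse(is.na(audit$hue_index), 99L, audit$hue_index),
                   audit$variant)
  for (i in seq_along(set$stimuli)) {
    write_raster(set$stimuli[[i]]$raster, file.path(dir, paths[i]))
  }
  pull_audit <- function(field) vapply(set$stimuli, function(s) {
    v <- s$audit[[field]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  manifest <- cbind(set$manifest, path = paths,
                    audit[, c("achieved_mean_lum", "achieved_mean_sat")],
                    shrink_factor = pull_audit("shrink_sat"),
                    gamut_clip_count = pull_audit("gamut_clip_count"))
  .write_table(manifest, file.path(dir, "manifest.csv"))
  set$manifest <- manifest
  .stage_log("stimuli", "%d stimuli written to %s (config %s)",
             nrow(manifest), dir, config$config_hash)
  invisible(set)
}

.stimuli_from_image_dir <- function(config) {
  files <- sort(list.files(config$image_dir, pattern = "\\.(png|ppm)$",
                           full.names = TRUE))
  if (!length(files)) stop("no PNG/PPM images in image_dir", call. = FALSE)
  stimuli <- list()
  for (f in files) {
    ras <- read_raster(f)
    oid <- tools::file_path_sans_ext(basename(f))
    mask <- background_mask(ras)
    if ("textured" %in% config$variants) {
      stimuli <- c(stimuli,
                   calibrate_and_recolor(ras, oid, config$calibration, mask = mask))
    }
    if ("silhouette" %in% config$variants) {
      stimuli <- c(stimuli, lapply(0:11, function(h) {
        make_silhouette(ras, oid, h, config$calibration, mask = mask)
      }))
    }
    if ("grayscale" %in% config$variants && config$colorspace == "cieluv") {
      stimuli <- c(stimuli, list(make_grayscale(ras, oid, config$calibration,
                                                mask = mask)))
    }
  }
  stimulus_set(stimuli)
}

#' Stage 2: extract activations for every configured network
#'
#' One activation matrix per (network instance, layer), cached under
#' `<out_dir>/cache/` together with the layer-descriptor table.
#'
#' @param config a [run_config()].
#' @param stimuli the stimulus set from [run_stimulus_stage()].
#' @return named list of per-network activation lists, invisibly.
#' @export
run_extraction_stage <- function(config, stimuli) {
  cache_dir <- file.path(config$out_dir, "cache")
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  layer_tables <- list()
  for (net in config$networks) {
    for (s in net$seeds) {
      adapter <- random_init_adapter(net$architecture, seed = s,
                                     input_px = config$input_px,
                                     n_stages = config$n_stages)
      acts <- extract_activations(adapter, stimuli)
      id <- adapter$network_id
      saveRDS(acts, file.path(cache_dir, paste0(id, ".rds")))
      out[[id]] <- acts
      lt <- enumerate_layers(adapter)
      lt$network_id <- id
      layer_tables[[id]] <- lt
    }
  }
  .write_table(do.call(rbind, layer_tables), file.path(cache_dir, "layers.csv"))
  .stage_log("extract", "%d network instance(s) cached in %s", length(out), cache_dir)
  invisible(out)
}

#' Load cached activations
#' @param config a [run_config()].
#' @return the per-network activation lists saved by [run_extraction_stage()].
#' @export
load_activation_cache <- function(config) {
  cache_dir <- file.path(config$out_dir, "cache")
  files <- list.files(cache_dir, pattern = "\\.rds$", full.names = TRUE)
  out <- lapply(files, readRDS)
  names(out) <- tools::file_path_sans_ext(basename(files))
  out
}

# layers used for trajectory statistics: first through penultimate
.trajectory_idx <- function(n_layers) seq_len(max(n_layers - 1L, 2L))

#' Stage 3: the full metric/statistics suite on extracted activations
#'
#' Per network: layer-wise mean between-object color-space correlation,
#' within-object normalized color distances, slope regression of every
#' object pair's correlation over layer_fraction (first through penultimate
#' layers) with a one-sample t test, the color-label shuffle null per layer,
#' cross-layer profiles anchored at the first and penultimate layers, and the
#' layer-wise stability of the between-object similarity structure. Tables
#' are written as CSV under `<out_dir>/analysis/`.
#'
#' @param config a [run_config()].
#' @param cache activation cache from [run_extraction_stage()] or
#'   [load_activation_cache()].
#' @return an `analysis_report` list.
#' @export
run_analysis_stage <- function(config, cache) {
  dir <- file.path(config$out_dir, "analysis")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  between_rows <- list(); within_rows <- list(); slope_rows <- list()
  null_rows <- list(); profile_rows <- list(); stability_rows <- list()
  for (net_id in names(cache)) {
    acts <- cache[[net_id]]
    n_layers <- length(acts)
    fractions <- vapply(acts, function(a) attr(a, "layer")$layer_fraction,
                        numeric(1))
    corr_mats <- list(); cs_by_layer <- list()
    for (li in seq_along(acts)) {
      pats <- patterns_by_object(acts[[li]])
      res <- between_object_colorspace(pats, metric = config$metric)
      corr_mats[[li]] <- res$matrix
      cs_by_layer[[li]] <- res$cs_vectors
      wd <- vapply(pats, function(p) within_object_color_distance(p)$value,
                   numeric(1))
      lab <- names(acts)[li]
      between_rows[[length(between_rows) + 1L]] <- data.frame(
        network_id = net_id, layer = lab, layer_fraction = fractions[li],
        mean_between_object_r = res$mean, stringsAsFactors = FALSE)
      within_rows[[length(within_rows) + 1L]] <- data.frame(
        network_id = net_id, layer = lab, layer_fraction = fractions[li],
        mean_within_object_distance = mean(wd), stringsAsFactors = FALSE)
      nul <- shuffle_color_null(pats, n_shuffles = config$n_shuffles,
                                seed = config$seed, metric = config$metric)
      null_rows[[length(null_rows) + 1L]] <- data.frame(
        network_id = net_id, layer = lab, mean_null = nul$mean_null,
        se_null = nul$se_null, n_shuffles = nul$n_shuffles,
        stringsAsFactors = FALSE)
    }
    # slope regression over first..penultimate layers
    idx <- .trajectory_idx(n_layers)
    st <- hierarchy_slope_test(corr_mats[idx], fractions[idx])
    slope_rows[[length(slope_rows) + 1L]] <- data.frame(
      network_id = net_id, n_pairs = length(st$slopes),
      mean_slope = mean(st$slopes), t = st$test$t, df = st$test$df,
      p = st$test$p, stringsAsFactors = FALSE)
    # cross-layer profiles per object, anchored at first and penultimate
    pen <- max(n_layers - 1L, 1L)
    for (anchor in unique(c(1L, pen))) {
      for (oi in seq_len(nrow(cs_by_layer[[1]]))) {
        vecs <- do.call(rbind, lapply(cs_by_layer, function(m) m[oi, ]))
        prof <- cross_layer_profile(vecs, anchor)
        profile_rows[[length(profile_rows) + 1L]] <- data.frame(
          network_id = net_id, anchor_layer = names(acts)[anchor],
          object_index = oi, layer = names(acts),
          layer_fraction = fractions, r = as.numeric(prof),
          stringsAsFactors = FALSE)
      }
    }
    # stability of the between-object similarity structure across layers
    sim_vecs <- do.call(rbind, lapply(corr_mats, rsm_offdiag_vector))
    for (anchor in unique(c(1L, pen))) {
      stab <- cross_layer_profile(sim_vecs, anchor)
      stability_rows[[length(stability_rows) + 1L]] <- data.frame(
        network_id = net_id, anchor_layer = names(acts)[anchor],
        layer = names(acts), layer_fraction = fractions,
        r = as.numeric(stab), stringsAsFactors = FALSE)
    }
  }
  # 2-D MDS of the layer-by-layer color-space dissimilarity per network:
  # correlations between layers' color-space vectors are averaged across
  # objects first, then converted to dissimilarity (1 - r)
  mds_rows <- list()
  for (net_id in names(cache)) {
    acts <- cache[[net_id]]
    cs <- lapply(acts, function(a) {
      do.call(rbind, lapply(patterns_by_object(a), color_space_vector,
                            metric = config$metric))
    })
    L <- length(cs)
    sim <- matrix(1, L, L)
    for (i in seq_len(L - 1)) for (j in (i + 1):L) {
      rs <- vapply(seq_len(nrow(cs[[1]])), function(o) {
        stats::cor(cs[[i]][o, ], cs[[j]][o, ])
      }, numeric(1))
      sim[i, j] <- sim[j, i] <- mean(rs)
    }
    emb <- mds_embed(1 - sim, dim = 2, seed = config$seed)
    mds_rows[[net_id]] <- data.frame(
      network_id = net_id, layer = names(acts),
      dim1 = emb$points[, 1], dim2 = emb$points[, 2],
      stress = emb$stress, stringsAsFactors = FALSE)
  }
  report <- list(
    mds_layers = do.call(rbind, mds_rows),
    between_object = do.call(rbind, between_rows),
    within_object = do.call(rbind, within_rows),
    slopes = do.call(rbind, slope_rows),
    shuffle_null = do.call(rbind, null_rows),
    cross_layer = do.call(rbind, profile_rows),
    similarity_stability = do.call(rbind, stability_rows),
    provenance = list(config_hash = config$config_hash, seed = config$seed,
                      metric = config$metric))
  for (nm in c("between_object", "within_object", "slopes", "shuffle_null",
               "cross_layer", "similarity_stability", "mds_layers")) {
    .write_table(report[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  jsonlite::write_json(
    list(provenance = report$provenance,
         slope_tests = report$slopes,
         shuffle_null = report$shuffle_null),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  class(report) <- "analysis_report"
  .stage_log("analyze", "tables written to %s", dir)
  invisible(report)
}

#' Stage 4: validation run on synthetic populations
#'
#' Runs the metric/statistic suite on a generated trajectory with known
#' interaction strengths and joins the ground truth to every row.
#'
#' @param config a [run_config()].
#' @param trajectory a [trajectory_spec()]; default: a 6-layer increasing
#'   lambda schedule with 20 objects.
#' @return an `analysis_report`-style list with ground-truth columns.
#' @export
run_simulation_stage <- function(config,
                                 trajectory = trajectory_spec(
                                   lambdas = seq(0, 1, length.out = 6),
                                   n_units = 4000, n_objects = 20,
                                   seed = config$seed)) {
  dir <- file.path(config$out_dir, "simulation")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layers <- generate_trajectory(trajectory)
  fractions <- attr(layers, "fractions")
  lambdas <- attr(layers, "lambdas")
  corr_mats <- list(); rows <- list()
  for (li in seq_along(layers)) {
    pats <- patterns_by_object(layers[[li]])
    res <- between_object_colorspace(pats, metric = config$metric)
    corr_mats[[li]] <- res$matrix
    rows[[li]] <- data.frame(
      layer = names(layers)[li], layer_fraction = fractions[li],
      lambda_true = lambdas[li], mean_between_object_r = res$mean,
      stringsAsFactors = FALSE)
  }
  idx <- .trajectory_idx(length(layers))
  st <- hierarchy_slope_test(corr_mats[idx], fractions[idx])
  tab <- do.call(rbind, rows)
  .write_table(tab, file.path(dir, "lambda_recovery.csv"))
  out <- list(lambda_recovery = tab,
              slope_test = data.frame(mean_slope = mean(st$slopes),
                                      t = st$test$t, df = st$test$df,
                                      p = st$test$p),
              provenance = list(config_hash = config$config_hash,
                                seed = config$seed))
  .write_table(out$slope_test, file.path(dir, "slope_test.csv"))
  .stage_log("simulate", "tables written to %s", dir)
  invisible(out)
}

#' Render an analysis report as a markdown bundle with figures
#'
#' Line plots follow the field's convention: fully-connected layers drawn as
#' hollow markers, all other layer types solid.
#'
#' @param report an `analysis_report` from [run_analysis_stage()].
#' @param config the matching [run_config()].
#' @return path of the written markdown file, invisibly.
#' @export
render_report <- function(report, config) {
  dir <- file.path(config$out_dir, "report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fig <- file.path(dir, "between_object.png")
  tab <- report$between_object
  if (!is.null(tab) && nrow(tab)) {
    lt <- utils::read.csv(file.path(config$out_dir, "cache", "layers.csv"))
    grDevices::png(fig, width = 700, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(tab$layer_fraction, tab$mean_between_object_r, type = "n",
         xlab = "layer fraction", ylab = "mean between-object color-space r",
         ylim = range(c(0, 1, tab$mean_between_object_r)))
    for (net in unique(tab$network_id)) {
      sub <- tab[tab$network_id == net, ]
      cls <- lt$layer_class[match(paste(net, sub$layer),
                                  paste(lt$network_id, lt$layer_label))]
      graphics::lines(sub$layer_fraction, sub$mean_between_object_r)
      graphics::points(sub$layer_fraction, sub$mean_between_object_r,
                       pch = ifelse(!is.na(cls) & cls == "fc", 1, 19))
    }
  }
  md <- file.path(dir, "report.md")
  lines <- c(
    "# Color/form representational similarity report",
    "",
    sprintf("config hash: `%s`; master seed: %d; metric: %s",
            report$provenance$config_hash, report$provenance$seed,
            report$provenance$metric),
    "",
    "## Mean between-object color-space correlation by layer", "",
    .md_table(report$between_object),
    "", "## Within-object normalized color distance by layer", "",
    .md_table(report$within_object),
    "", "## Pairwise slope test (first through penultimate layers)", "",
    .md_table(report$slopes),
    "", "## Color-label shuffle null", "",
    .md_table(report$shuffle_null),
    "", sprintf("![between-object correlations](%s)", basename(fig)))
  writeLines(lines, md)
  .stage_log("report", "bundle written to %s", dir)
  invisible(md)
}

.md_table <- function(df) {
  if (is.null(df) || !nrow(df)) return("(empty)")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 6, format = "g"))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Command-line entry point
#'
#' Subcommands: `make-stimuli`, `extract`, `analyze`, `simulate`, `report`,
#' `all`. Flags: `--out DIR` (required), `--seed N`, `--source
#' builtin_bars|image_dir`, `--image-dir DIR`, `--colorspace
#' cieluv|synthetic_hsv`, `--metric pearson|euclidean`, `--shuffles N`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return invisibly, the last stage's result.
#' @export
chromaform_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: <subcommand> --out DIR [flags]", call. = FALSE)
  cmd <- args[1]
  flag <- function(name, default = NULL) {
    i <- which(args == name)
    if (length(i)) args[i[1] + 1] else default
  }
  out <- flag("--out")
  if (is.null(out)) stop("--out is required", call. = FALSE)
  config <- run_config(
    out_dir = out,
    stimulus_source = flag("--source", "builtin_bars"),
    image_dir = flag("--image-dir"),
    colorspace = flag("--colorspace", "cieluv"),
    metric = flag("--metric", "pearson"),
    n_shuffles = as.integer(flag("--shuffles", "100")),
    seed = as.integer(flag("--seed", "1")))
  run_all <- cmd == "all"
  res <- NULL
  if (cmd == "make-stimuli" || run_all) res <- run_stimulus_stage(config)
  if (cmd == "extract" || run_all) {
    if (is.null(res)) res <- run_stimulus_stage(config)
    res <- run_extraction_stage(config, res)
  }
  if (cmd == "analyze" || run_all) {
    cache <- if (is.list(res) && !inherits(res, "chromaform_stimulus_set"))
      res else load_activation_cache(config)
    res <- run_analysis_stage(config, cache)
  }
  if (cmd == "simulate") res <- run_simulation_stage(config)
  if (cmd == "report" || run_all) {
    if (!inherits(res, "analysis_report")) {
      res <- run_analysis_stage(config, load_activation_cache(config))
    }
    res <- render_report(res, config)
  }
  invisible(res)
}
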