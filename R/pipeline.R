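## Batch orchestration: config handling, per-cell runs, and the synthetic
## end-to-end demonstration.

#' Default run configuration
#'
#' All pipeline parameters with their defaults: PSF sigmas (62, 190) nm,
#' alpha 0.9, transition-intensity fraction 1/3, sigmaL 60 nm, sigmaA
#' 900 nm, closing radius 2.7 voxels, sigmaG 3 voxels, sigmaW 7 voxels,
#' clip at 4 sigma. Shipped as \code{inst/config/paper_defaults.yaml} as
#' well; [runPipeline()] fills unset fields from here.
#'
#' @return Nested list of configuration blocks.
#' @export
defaultConfig <- function() {
  list(
    optics = list(lambda_nm = 509, na = 1.32, magnification = 63,
                  sigma_r_nm = 62, sigma_z_nm = 190),
    segmentation = list(sigma_l_nm = 60, sigma_a_nm = 900, alpha = 0.9,
                        ic_fraction = 1/3, closing_radius_vox = 2.7),
    measurement = list(clip_k = 4, sigma_g_vox = 3, sigma_w_vox = 7,
                       gradient_floor = 0.01),
    classification = list(model = "linear",
                          features = c("K_naaGc", "i_average")),
    seed = 1L,
    log_level = "info"
  )
}

.mergeConfig <- function(user, base) {
  for (k in names(base)) {
    if (is.null(user[[k]])) user[[k]] <- base[[k]]
    else if (is.list(base[[k]])) user[[k]] <- .mergeConfig(user[[k]], base[[k]])
  }
  user
}

.configObjects <- function(cfg) {
  list(optics = opticsConfig(lambda = cfg$optics$lambda_nm,
                             na = cfg$optics$na,
                             magnification = cfg$optics$magnification,
                             sigmaR = cfg$optics$sigma_r_nm,
                             sigmaZ = cfg$optics$sigma_z_nm),
       seg = segmentationParams(sigmaL = cfg$segmentation$sigma_l_nm,
                                sigmaA = cfg$segmentation$sigma_a_nm,
                                alpha = cfg$segmentation$alpha,
                                icFraction = cfg$segmentation$ic_fraction,
                                closingRadius = cfg$segmentation$closing_radius_vox),
       meas = measurementParams(clipK = cfg$measurement$clip_k,
                                sigmaG = cfg$measurement$sigma_g_vox,
                                sigmaW = cfg$measurement$sigma_w_vox,
                                gradientFloor = cfg$measurement$gradient_floor))
}

.logLine <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  rec <- list(...)
  rec$time <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  message(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
}

#' Run the full pipeline from a configuration
#'
#' Configuration may be a YAML file path or a nested list; unset fields are
#' filled from [defaultConfig()]. Input cells come either from
#' \code{stacks} -- a list of \code{list(path, spacing_nm, label)} entries
#' read via [readStack()] -- or from \code{phantom} mode
#' (\code{phantom: list(n_per_class, ...)}), which generates the two
#' synthetic populations. Per-cell failures are logged and skipped; the
#' summary counts usable cells. Outputs (features.csv, confusion.json,
#' boundary plot) are written to \code{out_dir} when set.
#'
#' @param config YAML path or list.
#' @return list: \code{features} (data.frame), \code{confusion} (or NULL),
#'   \code{summary}, \code{config} (the fully resolved configuration).
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(config, defaultConfig())
  obj <- .configObjects(cfg)
  cells <- list()
  if (!is.null(cfg$phantom)) {
    n <- cfg$phantom$n_per_class
    if (is.null(n)) stop("config field phantom$n_per_class is missing")
    .logLine(cfg, stage = "phantom", n_per_class = n, seed = cfg$seed)
    for (cls in c("control", "apoptotic")) {
      pop <- generatePopulation(n, cls, seed = cfg$seed +
                                  ifelse(cls == "control", 0L, 10000L))
      for (i in seq_along(pop))
        cells[[length(cells) + 1]] <- list(grid = pop[[i]]$stack,
                                           id = sprintf("%s_%02d", cls, i),
                                           label = cls)
    }
  } else if (!is.null(cfg$stacks)) {
    for (s in cfg$stacks) {
      if (is.null(s$path)) stop("config field stacks[[i]]$path is missing")
      cells[[length(cells) + 1]] <- list(
        grid = readStack(s$path, s$spacing_nm),
        id = if (!is.null(s$id)) s$id else basename(s$path),
        label = if (!is.null(s$label)) s$label else NA_character_)
    }
  } else stop("config needs either a 'stacks' list or a 'phantom' block")

  rows <- list()
  failed <- 0L
  for (cell in cells) {
    row <- tryCatch({
      r <- measureCell(cell$grid, obj$optics, obj$seg, obj$meas, cell$id)
      r$label <- cell$label
      .logLine(cfg, stage = "measure", cell = cell$id,
               mask_voxels = r$mask_voxels, usable = r$usable)
      r
    }, error = function(e) {
      .logLine(cfg, stage = "measure", cell = cell$id,
               error = conditionMessage(e))
      NULL
    })
    if (is.null(row)) failed <- failed + 1L else rows[[length(rows) + 1]] <- row
  }
  if (!length(rows)) stop("no cell could be measured")
  feats <- do.call(rbind, rows)

  if (!is.null(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  confusion <- NULL
  plotPath <- NULL
  if (!anyNA(feats$label) && length(unique(feats$label)) == 2) {
    fcols <- cfg$classification$features
    model <- if (identical(cfg$classification$model, "quadratic"))
      fitQuadratic(feats, fcols) else fitFisherLinear(feats, fcols)
    confusion <- evaluateClassifier(model, feats)
    if (!is.null(cfg$out_dir) && model$kind == "fisher_linear" &&
        length(fcols) == 2) {
      plotPath <- file.path(cfg$out_dir, "boundary.png")
      scatterWithBoundary(feats, model, plotPath)
    }
  }
  summary <- list(n_cells = length(cells), n_measured = nrow(feats),
                  n_failed = failed, usable_fraction = mean(feats$usable))
  .logLine(cfg, stage = "summary", n_measured = summary$n_measured,
           n_failed = failed, usable_fraction = summary$usable_fraction)
  if (!is.null(cfg$out_dir)) {
    utils::write.csv(feats, file.path(cfg$out_dir, "features.csv"),
                     row.names = FALSE)
    if (!is.null(confusion))
      jsonlite::write_json(
        list(counts = confusion$counts,
             per_class = confusion$per_class, mode = confusion$mode),
        file.path(cfg$out_dir, "confusion.json"),
        auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(cfg, file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(features = feats, confusion = confusion, summary = summary,
       config = cfg)
}

#' Synthetic end-to-end demonstration
#'
#' Generates the two phantom populations (default 20 cells per class), runs
#' segmentation and measurement on every cell, fits the two-feature Fisher
#' linear classifier (normalized curvature vs average normalized
#' intensity), and writes features.csv, confusion.json and the decision-
#' boundary scatter plot.
#'
#' @param seed master seed.
#' @param outDir output directory.
#' @param nPerClass cells per class.
#' @return The [runPipeline()] result, invisibly.
#' @export
demoSynthetic <- function(seed = 1L, outDir = tempfile("lamina3d_demo"),
                          nPerClass = 20L) {
  res <- runPipeline(list(phantom = list(n_per_class = nPerClass),
                          seed = as.integer(seed), out_dir = outDir))
  invisible(res)
}
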