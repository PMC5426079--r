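#' Pipeline configuration
#'
#' Bundles the stage configurations.  The defaults reproduce every
#' published constant of the method: 200 particles, 200 generations,
#' c1 = c2 = 0.5, inertia 1 -> 0.2, k in \[100, 4000\], alpha in
#' \[0.001, 4\], objective weights 0.3/0.3/0.4, 5x5 elliptical kernel,
#' 180 evaluation rays, stagnation patience 4.
#'
#' @param preprocess a [preprocess_config()].
#' @param pso a [swarm_config()].
#' @param weights an [objective_weights()].
#' @param connectivity pixel connectivity for the segmenter (4 or 8).
#' @param keep_central apply the central-component guard after morphology.
#' @param p_form within-class variance form, `"divide"` or `"multiply"`.
#' @param n_rays rays for the radial-error metric.
#' @param verbose print progress messages.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(preprocess = preprocess_config(),
                            pso = swarm_config(),
                            weights = objective_weights(),
                            connectivity = 4, keep_central = TRUE,
                            p_form = "divide", n_rays = 180,
                            verbose = FALSE) {
  structure(list(preprocess = preprocess, pso = pso, weights = weights,
                 connectivity = as.integer(connectivity),
                 keep_central = isTRUE(keep_central), p_form = p_form,
                 n_rays = as.integer(n_rays), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Parse a pipeline configuration from JSON
#'
#' Reads a JSON file whose top-level blocks `preprocess`, `pso`, `weights`
#' and scalar options override the defaults of [pipeline_config()].
#'
#' @param path JSON file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to read config files", call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(raw$preprocess))
    args$preprocess <- do.call(preprocess_config, as.list(raw$preprocess))
  if (!is.null(raw$pso)) args$pso <- do.call(swarm_config, as.list(raw$pso))
  if (!is.null(raw$weights))
    args$weights <- do.call(objective_weights, as.list(raw$weights))
  for (nm in c("connectivity", "keep_central", "p_form", "n_rays",
               "verbose"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  do.call(pipeline_config, args)
}

#' Run the full segmentation pipeline on one image
#'
#' Crop and preprocess the TCI, initialize the swarm on the uniform grid,
#' evaluate the raw objective terms once per initial particle to fix the
#' normalization factors, optimize (k, alpha) by PSO maximizing the
#' combined fitness, segment at the global best, extract the reference
#' region, refine it morphologically, and trace the final contour.  When a
#' truth mask is supplied, metrics are attached (computed in TCI
#' coordinates: the truth is cropped by the same ROI).
#'
#' @param image grayscale matrix or path readable by [read_image()].
#' @param roi an [roi_rect()] (or `c(x0, y0, x1, y1)`), covering the full
#'   frame when `NULL`.
#' @param cfg a [pipeline_config()].
#' @param truth optional truth mask (matrix or path).
#' @return an object of class `moorgb_result`: list with `optimal`
#'   (`c(k, alpha)`), `mask` and `contour` in TCI coordinates,
#'   `contour_frame` in full-frame coordinates, `objective`
#'   (breakdown at the optimum), `factors`, `trace`, `tci`
#'   (preprocessed), `roi`, and `metrics` (when truth given).
#' @export
run_moorgb <- function(image, roi = NULL, cfg = pipeline_config(),
                       truth = NULL) {
  if (is.character(image)) image <- read_image(image)
  assert_gray_image(image, "image")
  if (is.null(roi)) roi <- roi_rect(0, 0, ncol(image), nrow(image))
  if (!inherits(roi, "roi_rect")) roi <- do.call(roi_rect, as.list(roi))
  if (!is.null(truth) && is.character(truth)) truth <- read_mask(truth)

  say <- function(...) if (cfg$verbose) message(sprintf(...))
  tci <- preprocess_pipeline(image, roi, cfg$preprocess)
  say("TCI %dx%d preprocessed", nrow(tci), ncol(tci))

  sobel <- cpp_sobel(tci)
  breakdown_of <- function(k, alpha)
    evaluate_candidate(tci, rgb_params(k, alpha, cfg$connectivity),
                       factors = NULL, weights = cfg$weights,
                       sobel = sobel, p_form = cfg$p_form)

  # normalization pass: raw terms over the uniformly initialized swarm
  init <- initialize_swarm(cfg$pso)
  init_terms <- do.call(rbind, lapply(seq_len(nrow(init)), function(i) {
    b <- breakdown_of(init$k[i], init$alpha[i])
    data.frame(v_b = b$v_b, v_w = b$v_w, g_a = b$g_a)
  }))
  factors <- normalization_factors(init_terms)
  say("normalization factors f_B=%.4g f_W=%.4g f_A=%.4g",
      factors$f_b, factors$f_w, factors$f_a)

  fitness <- function(k, alpha) {
    b <- breakdown_of(k, alpha)
    combined_objective(b$v_b, b$v_w, b$g_a, factors, cfg$weights)
  }
  opt <- pso_optimize(fitness, cfg$pso)
  say("optimum k=%.1f alpha=%.4f F_O=%.4f after %d generations",
      opt$best["k"], opt$best["alpha"], opt$best_fit,
      max(opt$trace$generation))

  params <- rgb_params(opt$best["k"], opt$best["alpha"], cfg$connectivity)
  part <- segment(tci, params)
  ref <- extract_reference_region(part)
  post <- postprocess_mask(part, ref, cfg$keep_central)
  if (!any(post$mask == 1))
    stop("degenerate convergence: final mask is empty", call. = FALSE)
  breakdown <- evaluate_candidate(tci, params, factors, cfg$weights,
                                  sobel = sobel, p_form = cfg$p_form)

  contour_frame <- post$contour
  if (!is.null(contour_frame)) {
    contour_frame[, "row"] <- contour_frame[, "row"] + roi$y0
    contour_frame[, "col"] <- contour_frame[, "col"] + roi$x0
  }
  metrics <- NULL
  if (!is.null(truth)) {
    truth_tci <- crop_tci(truth * 255, roi) / 255
    metrics <- metrics_report(truth_tci, post$mask, cfg$n_rays)
  }
  structure(list(optimal = opt$best, mask = post$mask,
                 contour = post$contour, contour_frame = contour_frame,
                 objective = breakdown, factors = factors,
                 trace = opt$trace, tci = tci, roi = roi,
                 metrics = metrics),
            class = "moorgb_result")
}

#' @export
print.moorgb_result <- function(x, ...) {
  cat(sprintf("moorgb: optimal k=%.1f alpha=%.4f, mask %d px, %d generations\n",
              x$optimal["k"], x$optimal["alpha"], sum(x$mask),
              max(x$trace$generation)))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Weight-sensitivity sweep
#'
#' Runs the full pipeline on each (image, truth) pair for every weight
#' triple of the grid and tabulates the mean metrics, mirroring the
#' published sensitivity experiment.  The grid defaults to the balanced
#' triples plus the three degenerate single-objective triples.
#'
#' @param images list of items with `image` and `truth` (e.g. from
#'   [phantom_suite()]).
#' @param weight_grid data frame or matrix with columns `a`, `b`, `c`.
#' @param cfg a [pipeline_config()]; its `weights` entry is overridden per
#'   triple.
#' @return data frame: one row per triple with mean `are`, `tpvf`, `fpvf`,
#'   `fnvf` over the images.
#' @export
weight_sweep <- function(images,
                         weight_grid = rbind(
                           c(0.4, 0.3, 0.3), c(0.3, 0.4, 0.3),
                           c(0.3, 0.3, 0.4), c(1, 0, 0), c(0, 1, 0),
                           c(0, 0, 1)),
                         cfg = pipeline_config()) {
  wg <- as.data.frame(weight_grid)
  names(wg) <- c("a", "b", "c")
  res <- lapply(seq_len(nrow(wg)), function(j) {
    cfg$weights <- objective_weights(wg$a[j], wg$b[j], wg$c[j])
    m <- vapply(images, function(it) {
      r <- tryCatch(run_moorgb(it$image, cfg = cfg, truth = it$truth),
                    error = function(e) NULL)
      if (is.null(r)) # collapsed run (empty mask): segments nothing
        return(c(NA_real_, 0, 0, 100))
      c(r$metrics$are, r$metrics$tpvf, r$metrics$fpvf, r$metrics$fnvf)
    }, numeric(4))
    data.frame(a = wg$a[j], b = wg$b[j], c = wg$c[j],
               are = mean(m[1, ], na.rm = TRUE), tpvf = mean(m[2, ]),
               fpvf = mean(m[3, ]), fnvf = mean(m[4, ]),
               n_collapsed = sum(is.na(m[1, ])))
  })
  do.call(rbind, res)
}
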