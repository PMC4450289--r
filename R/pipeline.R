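#' Pipeline configuration
#'
#' Collects every stage parameter of the segmentation pipeline. All
#' defaults follow the validated operating point: smoothing window
#' `M = 9` (an 81 x 81 system), `lambda = 1` (insensitive over
#' \code{[0.1, 1]}), 256 gray levels for thresholding, a length-5
#' horizontal dilation and the iterated majority cleanup.
#'
#' @param roi `"auto"` (near-extreme row/column cut), `"none"`, or a list
#'   `(top, left, height, width)` with 0-based `top`/`left`.
#' @param norm_window Local normalization box side (odd).
#' @param eps Normalization stabilizer.
#' @param M Smoothing window side (odd).
#' @param lambda Data-fidelity weight.
#' @param levels Quantization levels for entropy thresholding.
#' @param threshold_override Optional fixed threshold (bypasses entropy
#'   selection; used by ROC sweeps).
#' @param Y Line dilation length (odd).
#' @param majority_max_iter Majority filter iteration cap.
#' @param postprocess Apply dilation + majority cleanup? High-quality
#'   images can skip it.
#' @param enhance_method `"fast"` or `"per_window"` (see [residual_map()]).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(roi = "none", norm_window = 15L, eps = 1e-6,
                            M = 9L, lambda = 1, levels = 256L,
                            threshold_override = NULL,
                            Y = 5L, majority_max_iter = 100L,
                            postprocess = TRUE,
                            enhance_method = "fast") {
  structure(list(roi = roi, norm_window = as.integer(norm_window), eps = eps,
                 M = as.integer(M), lambda = lambda,
                 levels = as.integer(levels),
                 threshold_override = threshold_override,
                 Y = as.integer(Y),
                 majority_max_iter = as.integer(majority_max_iter),
                 postprocess = isTRUE(postprocess),
                 enhance_method = enhance_method),
            class = "pipeline_config")
}

#' Segment the vein network of one image
#'
#' Runs the full deterministic pipeline: ROI localization, local
#' brightness normalization, separable Mumford-Shah enhancement of concave
#' regions, co-occurrence entropy thresholding, and morphological cleanup
#' (line dilation then iterated majority filter).
#'
#' @param img Numeric matrix: raw 8-bit intensities in \code{[0, 255]} or
#'   a \code{[0, 1]} field (auto-detected by range).
#' @param cfg A [pipeline_config()].
#' @param keep_intermediates Keep normalized/enhanced/raw-mask stages in
#'   the result?
#' @return List of class `segmentation` with `mask` (0/1, ROI-sized),
#'   `roi` (`NULL` unless ROI cropping was applied), `t_star`, and — when
#'   requested — `normalized`, `enhanced`, `mask_raw`.
#' @export
segment <- function(img, cfg = pipeline_config(), keep_intermediates = FALSE) {
  check_matrix(img)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  roi <- NULL
  if (identical(cfg$roi, "auto")) {
    r <- stage("roi", extract_roi(img, min_size = cfg$M))
    img <- r$img; roi <- r$roi
  } else if (is.list(cfg$roi)) {
    roi <- cfg$roi
    img <- img[roi$top + seq_len(roi$height),
               roi$left + seq_len(roi$width), drop = FALSE]
  }
  norm <- stage("normalize",
                local_normalize(img, cfg$norm_window, cfg$eps))
  op <- stage("operator", build_window_operator(cfg$M, cfg$lambda))
  enh <- stage("enhance", separable_enhance(norm, op, cfg$enhance_method))
  if (is.null(cfg$threshold_override)) {
    q <- quantize(enh$values, cfg$levels)
    thr <- stage("threshold", select_threshold(cooccurrence(q, cfg$levels)))
    t_star <- thr$t_star
  } else {
    t_star <- as.integer(cfg$threshold_override)
  }
  mask_raw <- stage("binarize", binarize(enh$values, t_star, cfg$levels))
  mask <- mask_raw
  if (cfg$postprocess) {
    mask <- stage("dilate", dilate_line_x(mask, cfg$Y))
    mask <- stage("majority", majority_fixpoint(mask, cfg$majority_max_iter))
  }
  out <- list(mask = mask, roi = roi, t_star = t_star)
  if (keep_intermediates) {
    out$normalized <- norm
    out$enhanced <- enh$values
    out$mask_raw <- mask_raw
  }
  structure(out, class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation: %d x %d mask, vein fraction %.3f, t* = %d\n",
              nrow(x$mask), ncol(x$mask), mean(x$mask), x$t_star))
  invisible(x)
}

#' Evaluate the pipeline on a database with ground truth
#'
#' Segments every sample, scores it against its truth mask, and runs the
#' template matcher between the extracted pattern and the truth using
#' [scale_match_params()] for the sample's frame size.
#'
#' @param db List of `synth_sample` objects (see [gen_database()]), or a
#'   directory containing `sample_NN.png` / `sample_NN_truth.png` pairs
#'   and a `manifest.json`.
#' @param cfg A [pipeline_config()].
#' @param match Also compute the mismatch ratio per sample?
#' @return List of class `benchmark_report` with `per_image` (data frame:
#'   sensitivity, specificity, accuracy, t_star, and `R_m` when matched)
#'   and `summary` (means and standard deviations).
#' @export
run_benchmark <- function(db, cfg = pipeline_config(), match = TRUE) {
  if (is.character(db)) db <- load_database(db)
  rows <- lapply(seq_along(db), function(i) {
    s <- db[[i]]
    seg <- segment(s$image, cfg)
    truth <- s$truth
    if (!is.null(seg$roi))
      truth <- truth[seg$roi$top + seq_len(seg$roi$height),
                     seg$roi$left + seq_len(seg$roi$width), drop = FALSE]
    sc <- scores(confusion(seg$mask, truth))
    row <- data.frame(sample = i,
                      sensitivity = sc[["sensitivity"]],
                      specificity = sc[["specificity"]],
                      accuracy = sc[["accuracy"]],
                      t_star = seg$t_star)
    if (match) {
      mp <- scale_match_params(ncol(truth), nrow(truth))
      row$R_m <- match_masks(truth, seg$mask, mp)$R_m
    }
    row
  })
  per_image <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_image), "sample")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(per_image[metric_cols], mean, numeric(1)),
    sd = vapply(per_image[metric_cols], sd, numeric(1)),
    row.names = NULL)
  structure(list(per_image = per_image, summary = summary, config = cfg),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark over %d images:\n", nrow(x$per_image)))
  print(x$summary, digits = 4)
  invisible(x)
}

load_database <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf)
  missing <- character(0)
  db <- lapply(manifest$samples, function(s) {
    ip <- file.path(dir, paste0(s$id, ".png"))
    tp <- file.path(dir, paste0(s$id, "_truth.png"))
    if (!file.exists(tp)) { missing <<- c(missing, s$id); return(NULL) }
    list(image = load_gray(ip) / 255,
         truth = (load_gray(tp) > 127) * 1L)
  })
  if (length(missing) > 0)
    stop("missing truth masks for: ", paste(missing, collapse = ", "))
  db
}

#' Sensitivity of the evaluation rates to lambda
#'
#' Re-runs the pipeline on a database for each value of `lambda` and
#' reports, per lambda, the mean absolute accuracy difference from the
#' reference run (`lambda = ref_lambda`), in percentage points.
#'
#' @param db Database as in [run_benchmark()].
#' @param lambdas Values to test (default `c(0.1, 0.25, 0.5, 0.75, 1)`).
#' @param cfg Base configuration.
#' @param ref_lambda Reference value (default 1).
#' @return Data frame with columns `lambda`, `mean_accuracy`,
#'   `divergence_pp` (mean |accuracy - reference accuracy| in points).
#' @export
lambda_sensitivity <- function(db, lambdas = c(0.1, 0.25, 0.5, 0.75, 1),
                               cfg = pipeline_config(), ref_lambda = 1) {
  if (is.character(db)) db <- load_database(db)
  run_acc <- function(lam) {
    c2 <- cfg; c2$lambda <- lam
    run_benchmark(db, c2, match = FALSE)$per_image$accuracy
  }
  ref <- run_acc(ref_lambda)
  rows <- lapply(lambdas, function(lam) {
    acc <- if (identical(lam, ref_lambda)) ref else run_acc(lam)
    data.frame(lambda = lam,
               mean_accuracy = mean(acc),
               divergence_pp = 100 * mean(abs(acc - ref)))
  })
  do.call(rbind, rows)
}
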