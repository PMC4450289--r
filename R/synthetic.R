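#' Configuration for the synthetic infrared finger image generator
#'
#' The generator emulates the structure of transillumination finger
#' images: a vein-like network of connected lines with junctions,
#' bifurcations and variable widths, rendered dark on a light field with
#' blurred edges (repeated Gaussian low-pass), combined by weighted sum
#' with a smooth nonuniform background (iteratively smoothed noise), and
#' optionally distorted by noise.
#'
#' @param height,width Image size in pixels; the default 87 x 212 frame
#'   mirrors the reference finger geometry used by the template matcher.
#' @param n_seeds Number of primary vessel paths started at the left edge.
#' @param branch_prob Per-step probability that a path spawns a branch.
#' @param width_range Min/max stroke width of a vessel, in pixels.
#' @param blur_sigma,blur_iters Gaussian blur applied to the rendered vein
#'   image (`blur_iters` repetitions of sigma `blur_sigma`), emulating the
#'   edge blurriness caused by scattering and blood flow.
#' @param bg_window,bg_iters Background field: uniform noise smoothed
#'   `bg_iters` times with a Gaussian kernel of side `bg_window`.
#' @param mix_alpha Weight of the vein image in the final weighted sum.
#' @param noise_kind One of `"none"`, `"gaussian"`, `"salt_pepper"`,
#'   `"speckle"`.
#' @param noise_level Noise strength (sd, flip fraction, or multiplicative
#'   sd, depending on `noise_kind`).
#' @param seed RNG seed for this sample.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(height = 87L, width = 212L,
                         n_seeds = 2L, branch_prob = 0.005,
                         width_range = c(2, 5),
                         blur_sigma = 1.5, blur_iters = 3L,
                         bg_window = 31L, bg_iters = 10L,
                         mix_alpha = 0.6,
                         noise_kind = "none", noise_level = 0,
                         seed = 1L) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              n_seeds = as.integer(n_seeds), branch_prob = branch_prob,
              width_range = width_range,
              blur_sigma = blur_sigma, blur_iters = as.integer(blur_iters),
              bg_window = as.integer(bg_window), bg_iters = as.integer(bg_iters),
              mix_alpha = mix_alpha,
              noise_kind = noise_kind, noise_level = noise_level,
              seed = as.integer(seed))
  if (cfg$mix_alpha < 0 || cfg$mix_alpha > 1)
    stop_validation("mix_alpha must lie in [0, 1]")
  if (any(c(cfg$height, cfg$width, cfg$n_seeds) < 1))
    stop_validation("counts must be positive")
  if (width_range[1] < 1 || width_range[2] > min(height, width) / 8)
    stop_validation("width_range must lie within [1, min(height, width)/8]")
  if (!noise_kind %in% c("none", "gaussian", "salt_pepper", "speckle"))
    stop_validation("unknown noise kind: ", noise_kind)
  structure(cfg, class = "synth_config")
}

#' Generate a vein-like network mask
#'
#' Primary paths start at the left image edge at uniformly drawn heights
#' (central 70% of the frame) and
#' random-walk across the image with a persistent vertical drift; each
#' step may spawn a branch — a new path starting at the current point with
#' a deflected drift, a width no larger than its parent's, and a finite
#' length (side branches fade within a fraction of the frame, unlike the
#' principal veins, which cross it). Every path is rasterized as a
#' disk-stamped stroke of its half-width, so the union mask is connected
#' per seed tree and shows junctions and variable widths.
#'
#' If the resulting vein fraction leaves the plausible range
#' \code{(0.02, 0.40)} the sample is regenerated (up to 10 attempts).
#'
#' @param cfg A [synth_config()].
#' @return List with `mask` (0/1 ground truth) and `paths` (list of
#'   step-point data frames with columns `r`, `c`, `width`).
#' @export
gen_vein_network <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  for (attempt in 1:10) {
    paths <- list()
    queue <- lapply(seq_len(cfg$n_seeds), function(i) {
      list(r = runif(1, 0.15 * cfg$height, 0.85 * cfg$height),
           c = 1,
           drift = runif(1, -0.35, 0.35),
           width = runif(1, cfg$width_range[1], cfg$width_range[2]),
           len = Inf)
    })
    while (length(queue) > 0) {
      st <- queue[[1]]; queue <- queue[-1]
      r <- st$r; c <- st$c; drift <- st$drift
      pts <- matrix(NA_real_, nrow = cfg$width - floor(c) + 1L, ncol = 2)
      n_pts <- 0L
      while (c <= cfg$width && n_pts < st$len) {
        n_pts <- n_pts + 1L
        pts[n_pts, ] <- c(r, c)
        # persistent drift with small jitter, reflected at a margin
        drift <- drift * 0.92 + rnorm(1, 0, 0.18)
        drift <- max(min(drift, 1.2), -1.2)
        r <- r + drift
        margin <- cfg$height * 0.08
        if (r < margin) { r <- margin; drift <- abs(drift) }
        if (r > cfg$height - margin) { r <- cfg$height - margin; drift <- -abs(drift) }
        c <- c + 1
        if (runif(1) < cfg$branch_prob && c < cfg$width * 0.9) {
          queue <- c(queue, list(list(
            r = r, c = c,
            drift = drift + sample(c(-1, 1), 1) * runif(1, 0.4, 0.9),
            width = runif(1, cfg$width_range[1], st$width),
            len = round(runif(1, 0.1, 0.4) * cfg$width))))
        }
      }
      paths <- c(paths, list(data.frame(r = pts[seq_len(n_pts), 1],
                                        c = pts[seq_len(n_pts), 2],
                                        width = st$width)))
    }
    mask <- rasterize_paths(paths, cfg$height, cfg$width)
    frac <- mean(mask)
    if (frac > 0.02 && frac < 0.40)
      return(list(mask = mask, paths = paths))
  }
  stop("vein fraction out of (0.02, 0.40) after 10 attempts; ",
       "adjust n_seeds/width_range")
}

# Stamp a disk of radius `width` (the vessel half-width) at every path point.
rasterize_paths <- function(paths, height, width) {
  mask <- matrix(0L, height, width)
  for (p in paths) {
    rad <- p$width[1]
    ir <- floor(rad)
    offs <- expand.grid(dr = -ir:ir, dc = -ir:ir)
    offs <- offs[offs$dr^2 + offs$dc^2 <= rad^2 + 1e-9, , drop = FALSE]
    for (k in seq_len(nrow(p))) {
      rr <- round(p$r[k]) + offs$dr
      cc <- round(p$c[k]) + offs$dc
      ok <- rr >= 1 & rr <= height & cc >= 1 & cc <= width
      mask[cbind(rr[ok], cc[ok])] <- 1L
    }
  }
  mask
}

#' Render a vein mask as a blurred intensity image
#'
#' Veins are dark (0) on a light (1) field; `blur_iters` passes of a
#' Gaussian blur of `blur_sigma` give the Gaussian-like cross profile that
#' scattering produces in real transillumination images.
#'
#' @param mask 0/1 vein mask.
#' @param cfg A [synth_config()].
#' @return Numeric matrix in \code{[0, 1]}.
#' @export
render_veins <- function(mask, cfg) {
  check_binary(mask)
  img <- 1 - mask
  if (cfg$blur_iters > 0) {
    side <- 2L * ceiling(3 * cfg$blur_sigma) + 1L
    kern <- EBImage::makeBrush(side, shape = "Gaussian", sigma = cfg$blur_sigma)
    for (i in seq_len(cfg$blur_iters)) img <- box_filter(img, kern)
  }
  pmin(pmax(img, 0), 1)
}

#' Generate a smooth nonuniform background field
#'
#' Starts from seeded uniform noise in \code{[0.3, 0.9]} and applies
#' `bg_iters` Gaussian smoothings with a kernel of side `bg_window`. The
#' result is a smooth illumination-like field standing in for the
#' low-pass-filtered real infrared background the original construction
#' used (no real image is available).
#'
#' @param cfg A [synth_config()].
#' @return Numeric matrix in \code{[0.3, 0.9]} (approximately), smooth:
#'   max abs gradient < 0.02 per pixel for the default config.
#' @export
gen_background <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 7919L)   # decouple from the vein-network stream
  bg <- matrix(runif(cfg$height * cfg$width, 0.3, 0.9),
               cfg$height, cfg$width)
  kern <- EBImage::makeBrush(cfg$bg_window, shape = "Gaussian",
                             sigma = cfg$bg_window / 6)
  for (i in seq_len(cfg$bg_iters)) bg <- box_filter(bg, kern)
  bg
}

#' Weighted sum of vein image and background
#'
#' @param vein_img,bg Equal-dimension matrices in \code{[0, 1]}.
#' @param mix_alpha Weight of the vein image.
#' @return `mix_alpha * vein_img + (1 - mix_alpha) * bg`, clipped to [0, 1].
#' @export
compose <- function(vein_img, bg, mix_alpha = 0.6) {
  check_matrix(vein_img); check_matrix(bg)
  if (!all(dim(vein_img) == dim(bg)))
    stop_validation("vein image and background dims differ")
  pmin(pmax(mix_alpha * vein_img + (1 - mix_alpha) * bg, 0), 1)
}

#' Distort an image with noise
#'
#' @param img Matrix in \code{[0, 1]}.
#' @param noise_kind `"none"`, `"gaussian"` (additive, sd = level),
#'   `"salt_pepper"` (a `level` fraction of pixels forced to 0 or 1), or
#'   `"speckle"` (multiplicative `1 + level * N(0,1)`).
#' @param noise_level Noise strength.
#' @param seed Optional RNG seed.
#' @return Distorted matrix, clipped to \code{[0, 1]}.
#' @export
distort <- function(img, noise_kind, noise_level, seed = NULL) {
  check_matrix(img)
  if (!is.null(seed)) set.seed(seed)
  if (noise_level == 0 || noise_kind == "none") return(img)
  n <- length(img)
  out <- switch(noise_kind,
    gaussian = img + rnorm(n, 0, noise_level),
    salt_pepper = {
      o <- img
      hit <- which(runif(n) < noise_level)
      o[hit] <- sample(c(0, 1), length(hit), replace = TRUE)
      o
    },
    speckle = img * (1 + noise_level * rnorm(n)),
    stop_validation("unknown noise kind: ", noise_kind)
  )
  pmin(pmax(out, 0), 1)
}

#' Generate one synthetic sample
#'
#' @param cfg A [synth_config()].
#' @return List of class `synth_sample` with `image` (matrix in [0, 1]),
#'   `truth` (0/1 mask) and `config`.
#' @export
gen_sample <- function(cfg) {
  net <- gen_vein_network(cfg)
  veins <- render_veins(net$mask, cfg)
  bg <- gen_background(cfg)
  img <- compose(veins, bg, cfg$mix_alpha)
  if (cfg$noise_kind != "none" && cfg$noise_level > 0)
    img <- distort(img, cfg$noise_kind, cfg$noise_level,
                   seed = cfg$seed + 104729L)
  structure(list(image = img, truth = net$mask, config = cfg),
            class = "synth_sample")
}

#' Generate a synthetic image database with ground truth
#'
#' Draws `n` samples from `base_cfg` with per-sample seeds derived from
#' `master_seed`, optionally writing PNG images, 0/255 PNG truth masks and
#' a JSON manifest to `out_dir`.
#'
#' @param n Number of samples (the reference benchmark uses 20).
#' @param base_cfg A [synth_config()]; its `seed` field is overridden.
#' @param master_seed Integer master seed (default 42).
#' @param out_dir Optional output directory.
#' @return List of `synth_sample` objects, invisibly carrying the manifest
#'   as attribute `manifest`.
#' @export
gen_database <- function(n = 20L, base_cfg = synth_config(),
                         master_seed = 42L, out_dir = NULL) {
  if (n < 1) stop_validation("n must be >= 1")
  samples <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg <- base_cfg
    cfg$seed <- as.integer(master_seed * 1000L + i)
    samples[[i]] <- gen_sample(cfg)
    rows[[i]] <- list(
      id = sprintf("sample_%02d", i),
      seed = cfg$seed,
      vein_fraction = round(mean(samples[[i]]$truth), 6),
      mean_intensity = round(mean(samples[[i]]$image), 6))
  }
  manifest <- list(n = n, master_seed = master_seed,
                   config = unclass(base_cfg)[setdiff(names(base_cfg), "seed")],
                   samples = rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_gray(samples[[i]]$image, file.path(out_dir, sprintf("sample_%02d.png", i)))
      write_mask(samples[[i]]$truth, file.path(out_dir, sprintf("sample_%02d_truth.png", i)))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  attr(samples, "manifest") <- manifest
  invisible(samples)
}
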