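#' Locate the effective finger region
#'
#' Transillumination images are shaded at the borders where the finger does
#' not cover the sensor. Rows and columns dominated by near-extreme
#' intensities (below 10 or above 245 on the 8-bit scale) are cut away and
#' the maximal contiguous block of surviving rows/columns containing the
#' image centre is kept. This is a reproducible stand-in for
#' histogram-based finger localization; an explicit rectangle can be
#' passed downstream instead via [segment()]'s `roi` argument.
#'
#' @param img Matrix in \code{[0, 255]} (a \code{[0, 1]} matrix is scaled up).
#' @param dark_fraction_threshold Maximum tolerated fraction of
#'   near-extreme pixels per row/column (default 0.5).
#' @param min_size Minimum allowed ROI height/width (default 9, one
#'   smoothing window).
#' @return List with `img` (the crop) and `roi`, a list
#'   `(top, left, height, width)` with 0-based `top`/`left`.
#' @export
extract_roi <- function(img, dark_fraction_threshold = 0.5, min_size = 9L) {
  check_matrix(img)
  if (max(img) <= 1) img <- img * 255
  extreme <- img < 10 | img > 245
  row_ok <- rowMeans(extreme) <= dark_fraction_threshold
  col_ok <- colMeans(extreme) <= dark_fraction_threshold
  rr <- central_run(row_ok)
  cc <- central_run(col_ok)
  if (is.null(rr) || is.null(cc) ||
      length(rr) < min_size || length(cc) < min_size)
    stop_validation(
      "no usable region: ", sum(row_ok), "/", nrow(img), " rows and ",
      sum(col_ok), "/", ncol(img), " columns survive the near-extreme cut")
  list(
    img = img[rr, cc, drop = FALSE],
    roi = list(top = rr[1] - 1L, left = cc[1] - 1L,
               height = length(rr), width = length(cc))
  )
}

# Longest contiguous TRUE run; ties broken by proximity to the centre.
central_run <- function(ok) {
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lens <- r$lengths[idx]
  centre <- (length(ok) + 1) / 2
  mid <- (starts[idx] + ends[idx]) / 2
  best <- idx[order(-lens, abs(mid - centre))][1]
  seq.int(starts[best], ends[best])
}

#' Local mean and standard deviation over a sliding box
#'
#' Box statistics with replicate padding at the borders; the standard
#' deviation is the population form (divisor \eqn{n}).
#'
#' @param img Numeric matrix.
#' @param window Odd box side, >= 3.
#' @return List with `mean_img`, `std_img` (same dims as `img`) and `window`.
#' @export
local_stats <- function(img, window = 15L) {
  check_matrix(img)
  window <- check_odd_window(window)
  box <- matrix(1 / window^2, window, window)
  m1 <- box_filter(img, box)
  m2 <- box_filter(img * img, box)
  list(mean_img = m1,
       std_img = sqrt(pmax(m2 - m1 * m1, 0)),
       window = window)
}

# Replicate-padded correlation with a small kernel via EBImage. EBImage
# stores images x-major; a plain matrix passes through with dims intact
# and the box kernel is symmetric, so no transposition is needed.
box_filter <- function(img, kernel) {
  out <- EBImage::filter2(img, kernel, boundary = "replicate")
  matrix(as.numeric(out), nrow(img), ncol(img))
}

#' Normalize local brightness
#'
#' Unifies local mean and variance by the pixelwise z-score
#' \deqn{u_0(x, y) = \frac{r(x, y) - m_r(x, y)}{\sigma_r(x, y) + \epsilon},}
#' where \eqn{m_r} and \eqn{\sigma_r} are the box mean and standard
#' deviation of [local_stats()]. This flattens shading and nonuniform
#' illumination. The z-score field is then min-max rescaled to
#' \code{[0, 1]} so downstream stages see a bounded nonnegative range; a
#' constant input maps to the all-0.5 image.
#'
#' @inheritParams local_stats
#' @param eps Stabilizer added to \eqn{\sigma_r} so flat regions do not
#'   divide by zero (default 1e-6).
#' @param rescale If `FALSE`, return the raw z-score field.
#' @return Numeric matrix; in \code{[0, 1]} when `rescale = TRUE`.
#' @export
local_normalize <- function(img, window = 15L, eps = 1e-6, rescale = TRUE) {
  if (eps <= 0) stop_validation("eps must be positive")
  st <- local_stats(img, window)
  z <- (img - st$mean_img) / (st$std_img + eps)
  if (!rescale) return(z)
  rescale01(z, flat_value = 0.5)
}
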