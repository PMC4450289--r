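#' Template matching parameters
#'
#' `w`, `h` are the width and height of both matching data sets; `c_w`,
#' `c_h` are the maximum horizontal and vertical displacement allowances.
#' The template is the central region of the registered data, rows
#' `c_h .. h - c_h - 1` and columns `c_w .. w - c_w - 1` (0-based,
#' half-open), and is slid over all `2 c_w x 2 c_h` displacements of the
#' input. Defaults are the reference values for a 212 x 87 finger frame,
#' allowing about 1 cm of finger displacement.
#'
#' @param w,h Data width and height in pixels.
#' @param c_w,c_h Maximum horizontal/vertical displacement.
#' @return List of class `match_params`.
#' @export
match_params <- function(w = 212L, h = 87L, c_w = 57L, c_h = 38L) {
  p <- list(w = as.integer(w), h = as.integer(h),
            c_w = as.integer(c_w), c_h = as.integer(c_h))
  if (p$c_w <= 0 || 2L * p$c_w >= p$w || p$c_h <= 0 || 2L * p$c_h >= p$h)
    stop_validation("need 0 < 2*c_w < w and 0 < 2*c_h < h")
  structure(p, class = "match_params")
}

#' Scale matching parameters to another frame size
#'
#' Scales the reference geometry (212, 87, 57, 38) proportionally to an
#' `h x w` frame, keeping the displacement allowances at the same fraction
#' of the frame.
#'
#' @param width,height Target frame size.
#' @param ref Reference [match_params()].
#' @return A [match_params()] for the target size.
#' @export
scale_match_params <- function(width, height, ref = match_params()) {
  match_params(
    w = width, h = height,
    c_w = max(1L, round(ref$c_w / ref$w * width)),
    c_h = max(1L, round(ref$c_h / ref$h * height)))
}

#' Pixel disagreement indicator
#'
#' 1 iff exactly one of the two binary labels marks a vein — i.e. a
#' background pixel and a vein pixel overlap.
#'
#' @param p1,p2 Values in \{0, 1\} (vectorized).
#' @return 0/1 vector.
#' @export
phi <- function(p1, p2) {
  if (!all(p1 %in% c(0, 1)) || !all(p2 %in% c(0, 1)))
    stop_validation("phi expects binary labels")
  (p1 != p2) * 1L
}

#' Mismatch count at one displacement
#'
#' Number of label disagreements between the template region of the
#' registered data `R` and the window of the input data `I` at
#' displacement `(s, t)` (0-based):
#' \deqn{N_m(s, t) = \sum_{y=0}^{h-2c_h-1} \sum_{x=0}^{w-2c_w-1}
#'   \phi\big(I(s+x,\, t+y),\, R(c_w+x,\, c_h+y)\big).}
#'
#' @param R,I 0/1 matrices of dimensions `h x w` (rows x cols).
#' @param s,t Horizontal/vertical displacement, `0 <= s < 2 c_w`,
#'   `0 <= t < 2 c_h`.
#' @param params A [match_params()].
#' @return Integer mismatch count.
#' @export
mismatch_count <- function(R, I, s, t, params) {
  check_binary(R); check_binary(I)
  if (nrow(R) != params$h || ncol(R) != params$w ||
      nrow(I) != params$h || ncol(I) != params$w)
    stop_validation("masks must be ", params$h, " x ", params$w)
  if (s < 0 || s >= 2 * params$c_w || t < 0 || t >= 2 * params$c_h)
    stop_validation("displacement out of range")
  tpl <- template_region(R, params)
  win <- input_window(I, s, t, params)
  sum(win != tpl)
}

template_region <- function(R, params) {
  R[(params$c_h + 1):(params$h - params$c_h),
    (params$c_w + 1):(params$w - params$c_w), drop = FALSE]
}

input_window <- function(I, s, t, params) {
  th <- params$h - 2L * params$c_h
  tw <- params$w - 2L * params$c_w
  I[(t + 1):(t + th), (s + 1):(s + tw), drop = FALSE]
}

#' Template matching with mismatch ratio
#'
#' Exhaustively searches all displacements `(s, t)` in
#' `[0, 2 c_w) x [0, 2 c_h)` for the minimum mismatch count `N_m` (ties
#' resolved toward the smallest `(t, s)` lexicographically) and reports
#' the mismatch ratio
#' \deqn{R_m = \frac{N_m}{|\,\mathrm{veins}(I) \cap \mathrm{best\ window}\,| +
#'   |\,\mathrm{veins}(R) \cap \mathrm{template}\,|},}
#' the disagreement count normalized by the vein totals of the two
#' compared regions. Masks larger than `(h, w)` are center-cropped first;
#' smaller masks are an error.
#'
#' @param R,I Registered and input 0/1 masks.
#' @param params A [match_params()]; defaults to the reference geometry.
#' @return List of class `match_result` with `N_m`, `s0`, `t0`, `R_m`.
#' @export
match_masks <- function(R, I, params = match_params()) {
  check_binary(R); check_binary(I)
  R <- center_crop(R, params$h, params$w)
  I <- center_crop(I, params$h, params$w)
  tpl <- template_region(R, params)
  best <- list(N_m = Inf, s0 = NA_integer_, t0 = NA_integer_)
  for (t in 0:(2L * params$c_h - 1L)) {
    for (s in 0:(2L * params$c_w - 1L)) {
      n <- sum(input_window(I, s, t, params) != tpl)
      if (n < best$N_m) best <- list(N_m = n, s0 = s, t0 = t)
    }
  }
  denom <- sum(input_window(I, best$s0, best$t0, params)) + sum(tpl)
  r_m <- if (denom == 0) {
    if (best$N_m == 0) 0
    else stop("degenerate patterns: no vein pixels but nonzero mismatch")
  } else best$N_m / denom
  structure(list(N_m = as.integer(best$N_m), s0 = best$s0, t0 = best$t0,
                 R_m = r_m),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: N_m = %d at (s0 = %d, t0 = %d), R_m = %.4f\n",
              x$N_m, x$s0, x$t0, x$R_m))
  invisible(x)
}

center_crop <- function(m, h, w) {
  if (nrow(m) < h || ncol(m) < w)
    stop_validation("mask ", nrow(m), "x", ncol(m),
                    " smaller than matching frame ", h, "x", w)
  r0 <- (nrow(m) - h) %/% 2L
  c0 <- (ncol(m) - w) %/% 2L
  m[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w), drop = FALSE]
}
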