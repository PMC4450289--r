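#' Dilate a mask with a horizontal line element
#'
#' Binary dilation with a centered `1 x Y` structuring element along the
#' x-axis (image columns). Veins run predominantly along the finger, so a
#' short horizontal line reconnects fragmented vein runs before the
#' majority cleanup. Pixels outside the border count as 0.
#'
#' @param mask 0/1 matrix.
#' @param Y Odd element length >= 1 (default 5).
#' @return 0/1 integer matrix.
#' @export
dilate_line_x <- function(mask, Y = 5L) {
  check_binary(mask)
  if (length(Y) != 1L || Y < 1 || Y %% 2 != 1)
    stop_validation("Y must be an odd integer >= 1, got ", Y)
  half <- (Y - 1L) / 2L
  out <- mask
  for (d in seq_len(half)) {
    out <- out | shift_mat(mask, 0, d) | shift_mat(mask, 0, -d)
  }
  out <- out * 1L
  storage.mode(out) <- "integer"
  out
}

#' One pass of the 3x3 majority filter
#'
#' Sets a pixel to 1 iff five or more of the nine cells in its 3x3
#' neighborhood (center included) are 1; cells beyond the border count
#' as 0, so the filter shrinks toward background at the image edge.
#'
#' @param mask 0/1 matrix.
#' @return 0/1 integer matrix.
#' @export
majority_once <- function(mask) {
  check_binary(mask)
  s <- matrix(0, nrow(mask), ncol(mask))
  for (dr in -1:1)
    for (dc in -1:1)
      s <- s + shift_mat(mask, dr, dc)
  out <- (s >= 5) * 1L
  storage.mode(out) <- "integer"
  out
}

#' Iterate the majority filter to a fixpoint
#'
#' Applies [majority_once()] until the mask stops changing. This clears
#' small misclassified specks and smooths contours; convergence is fast in
#' practice because each pass only removes weakly supported pixels.
#'
#' @param mask 0/1 matrix.
#' @param max_iter Iteration cap (default 100).
#' @return 0/1 integer matrix, a fixpoint of the filter. The number of
#'   passes performed is attached as attribute `iterations`.
#' @export
majority_fixpoint <- function(mask, max_iter = 100L) {
  if (max_iter < 1) stop_validation("max_iter must be >= 1")
  cur <- mask
  for (i in seq_len(max_iter)) {
    nxt <- majority_once(cur)
    if (all(nxt == cur)) {
      attr(nxt, "iterations") <- i
      return(nxt)
    }
    cur <- nxt
  }
  stop("majority filter did not converge within ", max_iter, " iterations")
}
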