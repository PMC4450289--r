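#' Quantize a [0, 1] field to L gray levels
#'
#' @param enh Numeric matrix with values in \code{[0, 1]}.
#' @param L Number of levels (default 256).
#' @return Integer matrix with levels in \code{0 .. L-1}.
#' @export
quantize <- function(enh, L = 256L) {
  check_matrix(enh)
  if (L < 2) stop_validation("L must be >= 2")
  if (min(enh) < 0 || max(enh) > 1)
    stop_validation("values must lie in [0, 1]; range is [",
                    min(enh), ", ", max(enh), "]")
  q <- floor(enh * (L - 1) + 0.5)
  storage.mode(q) <- "integer"
  q
}

#' Gray-level co-occurrence matrix of adjacent pixels
#'
#' Counts intensity transitions to the right neighbor and to the neighbor
#' below, asymmetrically (the transpose is not added). Unlike a histogram
#' this captures the spatial arrangement of intensities: two images with
#' identical histograms but different layouts have different co-occurrence
#' matrices and hence different entropy curves.
#'
#' @param qimg Integer matrix of levels in \code{0 .. L-1}.
#' @param L Number of gray levels.
#' @return Object of class `cooc_matrix`: an `L x L` count matrix with
#'   attribute `total` equal to `rows*(cols-1) + (rows-1)*cols`.
#' @export
cooccurrence <- function(qimg, L = 256L) {
  check_matrix(qimg)
  if (min(qimg) < 0 || max(qimg) > L - 1)
    stop_validation("levels out of range 0..", L - 1)
  nr <- nrow(qimg); nc <- ncol(qimg)
  if (nr * (nc - 1L) + (nr - 1L) * nc == 0L)
    stop_validation("image too small for adjacent-pixel transitions")
  from <- c(if (nc > 1) qimg[, -nc], if (nr > 1) qimg[-nr, ])
  to   <- c(if (nc > 1) qimg[, -1],  if (nr > 1) qimg[-1, ])
  counts <- matrix(tabulate(from * L + to + 1L, nbins = L * L),
                   L, L, byrow = TRUE)
  structure(counts, total = sum(counts), class = "cooc_matrix")
}

#' Quadrant entropies of a co-occurrence matrix
#'
#' Splitting the co-occurrence matrix at candidate threshold `t` yields
#' four quadrants; the background-background quadrant covers transitions
#' with both levels \code{<= t} and the foreground-foreground quadrant
#' both levels \code{> t}. Each quadrant is normalized by its own mass and
#' its Shannon entropy (base 2, with \eqn{0 \log 0 := 0}) is returned; an
#' empty quadrant has entropy 0. The off-diagonal (edge) quadrants are
#' deliberately excluded — see [select_threshold()].
#'
#' @param cooc A [cooccurrence()] matrix.
#' @param t Candidate threshold in \code{0 .. L-2}.
#' @return Named numeric vector `c(H_BB =, H_FF =)`, in bits.
#' @export
quadrant_entropies <- function(cooc, t) {
  L <- nrow(cooc)
  if (t < 0 || t > L - 2) stop_validation("t must lie in 0..", L - 2)
  bb <- seq_len(t + 1)
  ff <- (t + 2):L
  c(H_BB = quad_entropy(cooc[bb, bb]),
    H_FF = quad_entropy(cooc[ff, ff]))
}

quad_entropy <- function(block) {
  s <- sum(block)
  if (s <= 0) return(0)
  c <- block[block > 0]
  # -sum(p log2 p) with p = c/s, rearranged for stability
  log2(s) - sum(c * log2(c)) / s
}

#' Entropy-maximizing segmentation threshold
#'
#' Selects the gray level `t*` maximizing the total local entropy
#' \eqn{H(t) = H_{BB}(t) + H_{FF}(t)} of the two within-class quadrants of
#' the co-occurrence matrix, ties broken toward the smallest `t`. The two
#' quadrants are normalized within themselves and the cross-class
#' (edge) quadrants are excluded; both choices are this package's
#' reconstruction of the second-order local entropy criterion, isolated
#' here so an alternate variant can be swapped in.
#'
#' @param cooc A [cooccurrence()] matrix.
#' @return List of class `threshold_result` with `t_star` and
#'   `entropy_curve` (H at each t in \code{0 .. L-2}).
#' @export
select_threshold <- function(cooc) {
  L <- nrow(cooc)
  total <- sum(cooc)
  if (total <= 0) stop_validation("empty co-occurrence matrix")
  counts <- unclass(cooc)
  clog <- counts * log2(pmax(counts, 1))        # c*log2(c), 0 for c in {0,1}
  cum2d <- function(m) t(apply(apply(m, 2, cumsum), 1, cumsum))
  P  <- cum2d(counts)                           # P[i,j] = sum counts[1:i,1:j]
  Pl <- cum2d(clog)
  ts <- 0:(L - 2)
  k <- ts + 1                                   # BB block side
  s_bb <- diag(P)[k]
  e_bb <- diag(Pl)[k]
  # FF block = total minus the top row-strip and left column-strip,
  # adding back the doubly removed BB block
  s_ff <- P[L, L]  - P[k, L]  - P[L, ][k]  + s_bb
  e_ff <- Pl[L, L] - Pl[k, L] - Pl[L, ][k] + e_bb
  h <- function(s, e) ifelse(s > 0, log2(pmax(s, 1)) - e / s, 0)
  curve <- h(s_bb, e_bb) + h(s_ff, e_ff)
  t_star <- ts[which.max(curve)]                # which.max takes first tie
  if (sum(counts > 0) == 1L) {
    warning("degenerate single-level image; threshold set to 0")
    t_star <- 0L
  }
  structure(list(t_star = as.integer(t_star), entropy_curve = curve),
            class = "threshold_result")
}

#' Binarize an enhanced image at a threshold
#'
#' Vein pixels carry high values in the accumulated residual, so levels
#' strictly above `t_star` are labeled vein (1).
#'
#' @param enh Numeric matrix in \code{[0, 1]}.
#' @param t_star Threshold level in \code{0 .. L-2}.
#' @param L Number of gray levels.
#' @return 0/1 integer matrix.
#' @export
binarize <- function(enh, t_star, L = 256L) {
  q <- quantize(enh, L)
  mask <- (q > t_star) * 1L
  storage.mode(mask) <- "integer"
  mask
}
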