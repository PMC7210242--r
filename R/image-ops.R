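## Low-level raster operations used by rendering and detection.
##
## EBImage supplies the Gaussian halo convolution. The 3x3 median and the
## connected-component labelling are implemented here because the detection
## rule needs an exact (unquantized) median and 8-connectivity.

#' Exact 3x3 median smoothing
#'
#' Median-of-nine smoothing with replicate padding at the matrix border.
#' Pixels outside \code{mask} (e.g. outside the circular field of view) are
#' treated as missing: before filtering they are filled with the median of
#' the in-mask pixels, and the output is \code{NA} outside the mask, so the
#' invalid region can neither leak extreme values into the field nor acquire
#' signal.
#'
#' The median of nine is computed with a vectorized sorting network, so
#' results are exact for any dynamic range (no rescaling or quantization).
#'
#' @param mat numeric matrix.
#' @param mask optional logical matrix of valid pixels; default all valid.
#' @return numeric matrix of the same dimensions; \code{NA} outside the mask.
#' @examples
#' m <- matrix(1, 5, 5); m[3, 3] <- 100
#' medianSmooth(m)[3, 3]  # isolated speckle removed
#' @export
medianSmooth <- function(mat, mask = NULL) {
  stopifnot(is.matrix(mat))
  nr <- nrow(mat); nc <- ncol(mat)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(mat)))
    fill <- stats::median(mat[mask])
    mat[!mask] <- fill
  }
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mat
  p[1L, ] <- p[2L, ]; p[nr + 2L, ] <- p[nr + 1L, ]
  p[, 1L] <- p[, 2L]; p[, nc + 2L] <- p[, nc + 1L]
  a <- vector("list", 9L)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    a[[k]] <- p[(1L + di):(nr + di), (1L + dj):(nc + dj)]
  }
  # Paeth's 19-comparator median-of-9 network, vectorized over pixels
  cs <- function(i, j) {
    lo <- pmin(a[[i]], a[[j]]); hi <- pmax(a[[i]], a[[j]])
    a[[i]] <<- lo; a[[j]] <<- hi
  }
  cs(2, 3); cs(5, 6); cs(8, 9)
  cs(1, 2); cs(4, 5); cs(7, 8)
  cs(2, 3); cs(5, 6); cs(8, 9)
  cs(1, 4); cs(6, 9); cs(5, 8)
  cs(4, 7); cs(2, 5); cs(3, 6)
  cs(5, 8); cs(5, 3); cs(7, 5)
  cs(5, 3)
  out <- a[[5]]
  if (!is.null(mask)) out[!mask] <- NA_real_
  out
}

#' Label 8-connected components of a binary mask
#'
#' @param mask logical matrix.
#' @return integer matrix; 0 for background, components numbered 1..k in
#'   order of their smallest linear index (column-major), so labelling is
#'   deterministic.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[4, 4] <- TRUE
#' max(labelComponents(m))  # diagonal pixels connect: 2 components
#' @export
labelComponents <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  if (!any(mask)) return(out)
  L <- matrix(Inf, nr, nc)
  L[mask] <- which(mask)
  idx <- which(mask)
  repeat {
    p <- matrix(Inf, nr + 2L, nc + 2L)
    p[2:(nr + 1L), 2:(nc + 1L)] <- L
    nb <- pmin(
      p[1:nr, 1:nc], p[1:nr, 2:(nc + 1L)], p[1:nr, 3:(nc + 2L)],
      p[2:(nr + 1L), 1:nc], p[2:(nr + 1L), 3:(nc + 2L)],
      p[3:(nr + 2L), 1:nc], p[3:(nr + 2L), 2:(nc + 1L)],
      p[3:(nr + 2L), 3:(nc + 2L)])
    Lnew <- pmin(L[idx], nb[idx])
    if (identical(Lnew, L[idx])) break
    L[idx] <- Lnew
  }
  out[idx] <- as.integer(match(L[idx], sort(unique(L[idx]))))
  out
}

#' Gaussian halo of a tumor indicator
#'
#' Convolves a binary tumor indicator with a normalized Gaussian kernel
#' (zero boundary) and takes the pixelwise maximum with the indicator
#' itself: inside the tumor the relative signal stays at its full value,
#' while outside the border the protease-activated signal decays smoothly --
#' the halo that extends beyond the tumor margin.
#'
#' @param indicator numeric or logical matrix (1 inside the tumor).
#' @param sigmaPx Gaussian sigma in pixels; 0 returns the indicator.
#' @return numeric matrix in [0, 1].
#' @export
haloProfile <- function(indicator, sigmaPx) {
  ind <- matrix(as.numeric(indicator), nrow(indicator), ncol(indicator))
  if (sigmaPx <= 0) return(ind)
  size <- 2L * as.integer(ceiling(3 * sigmaPx)) + 1L
  brush <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigmaPx)
  blurred <- EBImage::filter2(ind, brush, boundary = 0)
  # the kernel has finite support; clip the FFT residue so the far field
  # is exactly zero
  blurred[abs(blurred) < 1e-6] <- 0
  pmin(pmax(pmax(ind, blurred), 0), 1)
}

#' Circular field-of-view mask
#'
#' @param sizePx side length of the square pixel grid.
#' @return logical matrix, \code{TRUE} inside the inscribed circle.
#' @export
circularFieldMask <- function(sizePx) {
  ctr <- (sizePx + 1) / 2
  r <- sizePx / 2
  d2 <- outer((seq_len(sizePx) - ctr)^2, (seq_len(sizePx) - ctr)^2, "+")
  d2 <= r^2
}

#' Disc indicator on a pixel grid
#'
#' @param sizePx grid side length.
#' @param cx,cy disc centre (pixels).
#' @param rPx disc radius (pixels).
#' @return logical matrix.
#' @export
discMask <- function(sizePx, cx, cy, rPx) {
  d2 <- outer((seq_len(sizePx) - cx)^2, (seq_len(sizePx) - cy)^2, "+")
  d2 <= rPx^2
}
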