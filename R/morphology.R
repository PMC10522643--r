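# Binary morphology with disk structuring elements, connected components,
# and Otsu thresholding. These primitives back the dye-mask post-processing;
# no image-morphology package is available in this R stack, so they are
# implemented here (vectorized shift-and-combine; BFS labeling).

#' Offsets of a rasterized disk structuring element
#' @keywords internal
#' @noRd
disk_offsets <- function(radius) {
  r <- as.integer(radius)
  if (r < 0L) stop("radius must be >= 0", call. = FALSE)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius^2 + 1e-9, , drop = FALSE]
}

#' Shift a logical matrix by (dy, dx), padding with `fill`
#' @keywords internal
#' @noRd
shift_mat <- function(m, dy, dx, fill = FALSE) {
  h <- nrow(m)
  w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- seq_len(h) - dy
  xs <- seq_len(w) - dx
  ok_y <- ys >= 1 & ys <= h
  ok_x <- xs >= 1 & xs <= w
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

#' Binary dilation, erosion, opening and closing with a disk
#'
#' @param mask logical matrix.
#' @param radius disk radius in pixels; `0` is the identity.
#' @return logical matrix of the same size.
#' @export
binary_dilate <- function(mask, radius) {
  mask <- as_mask(mask)
  if (radius <= 0) return(mask)
  offs <- disk_offsets(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs))) {
    out <- out | shift_mat(mask, offs$dy[i], offs$dx[i], fill = FALSE)
  }
  out
}

#' @rdname binary_dilate
#' @export
binary_erode <- function(mask, radius) {
  mask <- as_mask(mask)
  if (radius <= 0) return(mask)
  !binary_dilate(!mask, radius)
}

#' @rdname binary_dilate
#' @export
binary_open <- function(mask, radius) {
  binary_dilate(binary_erode(mask, radius), radius)
}

#' @rdname binary_dilate
#' @export
binary_close <- function(mask, radius) {
  binary_erode(binary_dilate(mask, radius), radius)
}

as_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  if (!is.logical(mask)) {
    storage.mode(mask) <- "logical"
  }
  mask[is.na(mask)] <- FALSE
  mask
}

#' Label connected components of a binary mask
#'
#' Breadth-first flood fill. 8-connectivity by default, matching the usual
#' convention for bright blobs on dark background.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix; 0 is background, components numbered from 1 in
#'   raster order of their first pixel.
#' @export
label_components <- function(mask, connectivity = 8) {
  mask <- as_mask(mask)
  h <- nrow(mask)
  w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (!any(mask)) return(lab)
  if (connectivity == 4) {
    offs <- cbind(dy = c(-1L, 1L, 0L, 0L), dx = c(0L, 0L, -1L, 1L))
  } else if (connectivity == 8) {
    offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1))
    offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
  } else {
    stop("connectivity must be 4 or 8", call. = FALSE)
  }
  todo <- which(mask)  # column-major linear indices, raster-ish order
  current <- 0L
  for (start in todo) {
    if (lab[start] != 0L) next
    current <- current + 1L
    frontier <- start
    lab[start] <- current
    while (length(frontier)) {
      fy <- ((frontier - 1L) %% h) + 1L
      fx <- ((frontier - 1L) %/% h) + 1L
      nxt <- integer(0)
      for (k in seq_len(nrow(offs))) {
        ny <- fy + offs[k, 1]
        nx <- fx + offs[k, 2]
        ok <- ny >= 1L & ny <= h & nx >= 1L & nx <= w
        if (!any(ok)) next
        ni <- (nx[ok] - 1L) * h + ny[ok]
        ni <- ni[mask[ni] & lab[ni] == 0L]
        if (length(ni)) {
          lab[ni] <- current
          nxt <- c(nxt, ni)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

#' Otsu's threshold on a [0, 1] intensity image
#'
#' Maximizes between-class variance over a 256-bin histogram; returns the
#' threshold intensity (lower bin edge of the foreground class).
#'
#' @param img numeric matrix in [0, 1].
#' @param n_bins histogram resolution.
#' @return scalar threshold in [0, 1].
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  check_image(img)
  v <- as.vector(img)
  edges <- seq(0, 1, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, n_bins)
  between[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(between)
  edges[k + 1L]
}
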