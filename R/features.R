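# Visual-barcode features: scale-space blob keypoints with gradient-histogram
# descriptors, nearest-neighbor matching, and the delta/epsilon spatial
# coherency filter.
#
# A "visual barcode" is a locally distinctive patch of the fluorescent
# speckle pattern, operationalized as a scale-invariant keypoint plus a
# 128-vector descriptor. No SIFT binding exists in this R stack, so the
# detector is implemented here in the classical form: difference-of-Gaussians
# scale-space extrema, edge-response rejection, 3-d quadratic sub-pixel
# refinement, dominant-gradient orientation, and a 4x4x8
# gradient-orientation-histogram descriptor. The detector sits behind a
# pluggable seam: everything downstream consumes only `feature_set` objects.

#' Construct a feature set
#'
#' @param keypoints data frame with columns `x`, `y` (0-based pixel
#'   coordinates), `scale`, `orientation` (radians), `response`.
#' @param descriptors numeric matrix, one row per keypoint.
#' @param image_id identifier of the source image.
#' @return a `feature_set` object.
#' @export
feature_set <- function(keypoints, descriptors, image_id = NA_character_) {
  stopifnot(is.data.frame(keypoints), nrow(keypoints) == nrow(descriptors))
  structure(list(image_id = image_id, keypoints = keypoints,
                 descriptors = as.matrix(descriptors)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set '%s': %d keypoints, %d-d descriptors>\n",
              x$image_id, nrow(x$keypoints),
              if (nrow(x$keypoints)) ncol(x$descriptors) else 0L))
  invisible(x)
}

#' @export
length.feature_set <- function(x) nrow(x$keypoints)

empty_feature_set <- function(image_id = NA_character_, dims = 128L) {
  feature_set(data.frame(x = numeric(0), y = numeric(0), scale = numeric(0),
                         orientation = numeric(0), response = numeric(0)),
              matrix(numeric(0), 0, dims), image_id)
}

# 3x3 neighborhood maximum / minimum via shifts (replicated borders would
# create spurious border extrema, so borders are padded with -Inf / Inf and
# a margin is excluded downstream)
neigh_extreme <- function(m, op) {
  pad <- if (identical(op, pmax)) -Inf else Inf
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- op(out, shift_num(m, dy, dx, pad))
  }
  out
}

shift_num <- function(m, dy, dx, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- seq_len(h) - dy
  xs <- seq_len(w) - dx
  ok_y <- ys >= 1 & ys <= h
  ok_x <- xs >= 1 & xs <= w
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

#' Detect scale-invariant barcode keypoints
#'
#' Difference-of-Gaussians extrema over a seeded-free, fully deterministic
#' scale space. Keypoints weaker than `contrast_threshold` (on the [0, 1]
#' intensity scale, after sub-pixel interpolation) are discarded, as are
#' edge-like responses.
#'
#' @param image single-channel numeric matrix in [0, 1].
#' @param contrast_threshold minimum absolute interpolated DoG response
#'   (reference value 0.01).
#' @param n_octaves number of dyadic octaves; default fits the image size.
#' @param n_scales DoG intervals per octave.
#' @param sigma0 base blur of the first scale level.
#' @param edge_ratio maximum principal-curvature ratio (edge rejection).
#' @param upsample start from a 2x bilinearly upsampled base octave so blobs
#'   near one pixel in radius are still interior scale-space extrema (the
#'   classical choice).
#' @param image_id identifier stored on the result.
#' @return a `feature_set`. A blank image yields an empty set.
#' @export
detect_features <- function(image, contrast_threshold = 0.01,
                            n_octaves = NULL, n_scales = 3L, sigma0 = 1.6,
                            edge_ratio = 10, upsample = TRUE,
                            image_id = NA_character_) {
  check_image(image)
  h <- nrow(image); w <- ncol(image)
  if (is.null(n_octaves)) {
    n_octaves <- max(1L, min(4L, floor(log2(min(h, w))) - 4L)) +
      as.integer(upsample)
  }
  s <- as.integer(n_scales)
  k <- 2^(1 / s)
  sig <- sigma0 * k^(0:(s + 2))            # per-octave absolute blur levels
  margin <- 5L

  kp_rows <- list()
  desc_rows <- list()
  if (upsample) {
    ys <- (seq_len(2L * h) - 1) / 2
    xs <- (seq_len(2L * w) - 1) / 2
    base <- outer(ys, xs, function(y, x) bilinear_sample(image, x, y,
                                                         outside = NA))
    oct_shift <- -1L
  } else {
    base <- image
    oct_shift <- 0L
  }
  for (oct0 in 0:(n_octaves - 1L)) {
    oct <- oct0 + oct_shift
    if (nrow(base) < 2 * margin + 3 || ncol(base) < 2 * margin + 3) break
    # incremental Gaussian stack
    G <- vector("list", s + 3L)
    G[[1]] <- gauss_blur(base, sig[1])
    for (i in 2:(s + 3L)) {
      G[[i]] <- gauss_blur(G[[i - 1]], sqrt(sig[i]^2 - sig[i - 1]^2))
    }
    D <- lapply(1:(s + 2L), function(i) G[[i + 1]] - G[[i]])
    # gradients per Gaussian level (central differences)
    GX <- lapply(G, function(g) (shift_num(g, 0, -1, NA) - shift_num(g, 0, 1, NA)) / 2)
    GY <- lapply(G, function(g) (shift_num(g, -1, 0, NA) - shift_num(g, 1, 0, NA)) / 2)
    for (g in seq_along(GX)) {
      GX[[g]][is.na(GX[[g]])] <- 0
      GY[[g]][is.na(GY[[g]])] <- 0
    }
    hh <- nrow(base); ww <- ncol(base)
    inner <- matrix(FALSE, hh, ww)
    inner[(margin + 1):(hh - margin), (margin + 1):(ww - margin)] <- TRUE
    nmax <- lapply(D, neigh_extreme, op = pmax)
    nmin <- lapply(D, neigh_extreme, op = pmin)
    for (li in 2:(s + 1L)) {
      cur <- D[[li]]
      # non-strict comparisons: exact ties occur on synthetic imagery (e.g.
      # after bilinear upsampling); duplicates are collapsed afterwards
      is_max <- cur >= nmax[[li]] &
        cur >= nmax[[li - 1]] & cur >= D[[li - 1]] &
        cur >= nmax[[li + 1]] & cur >= D[[li + 1]]
      is_min <- cur <= nmin[[li]] &
        cur <= nmin[[li - 1]] & cur <= D[[li - 1]] &
        cur <= nmin[[li + 1]] & cur <= D[[li + 1]]
      cand <- which((is_max | is_min) & inner &
                      abs(cur) >= 0.8 * contrast_threshold, arr.ind = TRUE)
      if (nrow(cand) == 0L) next
      for (ci in seq_len(nrow(cand))) {
        r <- unname(cand[ci, 1]); c <- unname(cand[ci, 2])
        # gradient and Hessian of D at (r, c, li) by central differences
        dx <- (cur[r, c + 1] - cur[r, c - 1]) / 2
        dy <- (cur[r + 1, c] - cur[r - 1, c]) / 2
        ds <- (D[[li + 1]][r, c] - D[[li - 1]][r, c]) / 2
        dxx <- cur[r, c + 1] + cur[r, c - 1] - 2 * cur[r, c]
        dyy <- cur[r + 1, c] + cur[r - 1, c] - 2 * cur[r, c]
        dss <- D[[li + 1]][r, c] + D[[li - 1]][r, c] - 2 * cur[r, c]
        dxy <- (cur[r + 1, c + 1] - cur[r + 1, c - 1] -
                  cur[r - 1, c + 1] + cur[r - 1, c - 1]) / 4
        dxs <- (D[[li + 1]][r, c + 1] - D[[li + 1]][r, c - 1] -
                  D[[li - 1]][r, c + 1] + D[[li - 1]][r, c - 1]) / 4
        dys <- (D[[li + 1]][r + 1, c] - D[[li + 1]][r - 1, c] -
                  D[[li - 1]][r + 1, c] + D[[li - 1]][r - 1, c]) / 4
        # edge rejection on the 2x2 spatial Hessian
        tr <- dxx + dyy
        det2 <- dxx * dyy - dxy^2
        if (det2 <= 0 || tr^2 / det2 >= (edge_ratio + 1)^2 / edge_ratio) next
        H <- matrix(c(dxx, dxy, dxs, dxy, dyy, dys, dxs, dys, dss), 3, 3)
        g3 <- c(dx, dy, ds)
        off <- tryCatch(-solve(H, g3), error = function(e) c(0, 0, 0))
        if (any(!is.finite(off)) || any(abs(off) > 1.5)) off <- c(0, 0, 0)
        off <- clamp(off, -0.75, 0.75)
        peak <- cur[r, c] + 0.5 * sum(g3 * off)
        if (abs(peak) < contrast_threshold) next
        x0 <- (c - 1) + off[1]
        y0 <- (r - 1) + off[2]
        sc_rel <- sigma0 * k^((li - 1) + off[3])  # blur at octave sampling
        theta <- assign_orientation(GX[[li]], GY[[li]], x0, y0, sc_rel)
        desc <- descriptor_patch(GX[[li]], GY[[li]], x0, y0, sc_rel, theta)
        if (is.null(desc)) next
        kp_rows[[length(kp_rows) + 1L]] <- c(
          x = x0 * 2^oct, y = y0 * 2^oct, scale = sc_rel * 2^oct,
          orientation = theta, response = peak)
        desc_rows[[length(desc_rows) + 1L]] <- desc
      }
    }
    # next octave: subsample the level with doubled blur
    nb <- G[[s + 1L]]
    base <- nb[seq(1, nrow(nb), by = 2), seq(1, ncol(nb), by = 2)]
  }
  if (!length(kp_rows)) return(empty_feature_set(image_id))
  kps <- as.data.frame(do.call(rbind, kp_rows))
  # clip to image bounds (sub-pixel refinement can nudge outside) and
  # collapse duplicates arising from tied extrema
  keep <- kps$x >= 0 & kps$x <= w - 1 & kps$y >= 0 & kps$y <= h - 1
  kps <- kps[keep, , drop = FALSE]
  descs <- do.call(rbind, desc_rows)[keep, , drop = FALSE]
  dup <- duplicated(data.frame(round(kps$x), round(kps$y),
                               round(log2(kps$scale) * 6)))
  kps <- kps[!dup, , drop = FALSE]
  rownames(kps) <- NULL
  feature_set(kps, descs[!dup, , drop = FALSE], image_id)
}

# precomputed unit grids (scale-free parts of the orientation and
# descriptor samplers)
.ori_grid <- local({
  u <- seq(-4.5, 4.5, by = 0.75)
  g <- expand.grid(u = u, v = u)
  g$w <- exp(-(g$u^2 + g$v^2) / (2 * 1.5^2))
  g
})

.desc_grid <- local({
  # 16x16 samples covering the 4x4 spatial bins; bin coordinates and spatial
  # weights depend only on the unit grid
  off <- (0:15 - 7.5) / 4            # in units of the spatial bin width
  g <- expand.grid(u = off, v = off)
  g$w <- exp(-(g$u^2 + g$v^2) * 16 / (2 * 8^2))
  g$ub <- g$u + 1.5
  g$vb <- g$v + 1.5
  g$u0 <- floor(g$ub); g$v0 <- floor(g$vb)
  g$fu <- g$ub - g$u0; g$fv <- g$vb - g$v0
  g
})

# dominant gradient orientation from a 36-bin weighted histogram over a
# scale-adapted sample grid, with parabolic peak interpolation
assign_orientation <- function(gx, gy, x0, y0, sc_rel) {
  g <- .ori_grid
  px <- x0 + g$u * sc_rel
  py <- y0 + g$v * sc_rel
  vx <- bilinear_sample(gx, px, py, outside = 0)
  vy <- bilinear_sample(gy, px, py, outside = 0)
  mag <- sqrt(vx^2 + vy^2) * g$w
  ang <- atan2(vy, vx) %% (2 * pi)
  bin <- as.integer(floor(ang / (2 * pi) * 36)) %% 36L
  hist <- numeric(36)
  rs <- rowsum(mag, bin)
  hist[as.integer(rownames(rs)) + 1L] <- rs
  for (pass in 1:2) {
    hist <- (hist + c(hist[-1], hist[1]) + c(hist[36], hist[-36])) / 3
  }
  p <- which.max(hist) - 1L
  l <- hist[(p - 1L) %% 36 + 1L]; cc <- hist[p + 1L]; r <- hist[(p + 1L) %% 36 + 1L]
  denom <- l - 2 * cc + r
  dp <- if (abs(denom) > 1e-12) 0.5 * (l - r) / denom else 0
  ((p + dp) / 36 * 2 * pi) %% (2 * pi)
}

# 4x4 spatial x 8 orientation gradient histogram sampled on a rotated 16x16
# grid; trilinear soft assignment, normalized / clamped at 0.2 / renormalized
descriptor_patch <- function(gx, gy, x0, y0, sc_rel, theta) {
  d <- 4L; n_or <- 8L
  bin_w <- 3 * sc_rel
  g <- .desc_grid
  ct <- cos(theta); st <- sin(theta)
  gu <- g$u * bin_w  # grid is in bin-width units; back to pixels
  gv <- g$v * bin_w
  px <- x0 + gu * ct - gv * st
  py <- y0 + gu * st + gv * ct
  vx <- bilinear_sample(gx, px, py, outside = 0)
  vy <- bilinear_sample(gy, px, py, outside = 0)
  # rotate gradients into the keypoint frame
  rx <- vx * ct + vy * st
  ry <- -vx * st + vy * ct
  mag <- sqrt(rx^2 + ry^2)
  wgt <- g$w * mag
  ang <- atan2(ry, rx) %% (2 * pi)
  ob <- ang / (2 * pi) * n_or
  o0 <- floor(ob)
  fo <- ob - o0
  idx_all <- integer(0)
  w_all <- numeric(0)
  for (du in 0:1) for (dv in 0:1) for (dor in 0:1) {
    ui <- g$u0 + du; vi <- g$v0 + dv; oi <- (o0 + dor) %% n_or
    wq <- wgt * (if (du) g$fu else 1 - g$fu) * (if (dv) g$fv else 1 - g$fv) *
      (if (dor) fo else 1 - fo)
    ok <- ui >= 0 & ui < d & vi >= 0 & vi < d & wq > 0
    if (!any(ok)) next
    idx_all <- c(idx_all, (oi[ok] * d + vi[ok]) * d + ui[ok] + 1L)
    w_all <- c(w_all, wq[ok])
  }
  v <- numeric(d * d * n_or)
  if (length(idx_all)) {
    rs <- rowsum(w_all, idx_all)
    v[as.integer(rownames(rs))] <- rs
  }
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-12) return(NULL)
  v <- pmin(v / nrm, 0.2)
  nrm <- sqrt(sum(v^2))
  v / nrm
}

#' Match features between two sets
#'
#' Nearest-descriptor search with a Lowe ratio test and (by default) a
#' mutual-consistency check. Each left keypoint appears in at most one
#' match. The downstream coherency filter makes the pipeline robust to the
#' exact acceptance rule, so both knobs are configurable.
#'
#' @param a,b `feature_set` objects with equal descriptor length.
#' @param ratio Lowe ratio; a left feature is accepted when its best
#'   descriptor distance is at most `ratio` times its second best.
#' @param mutual require the right feature's nearest neighbor to be the left
#'   feature.
#' @return data frame of class `match_set`: `left_index`, `right_index`
#'   (1-based into the feature sets), `left_x`, `left_y`, `right_x`,
#'   `right_y`, `distance`.
#' @export
match_features <- function(a, b, ratio = 0.75, mutual = TRUE) {
  stopifnot(inherits(a, "feature_set"), inherits(b, "feature_set"))
  empty <- structure(
    data.frame(left_index = integer(0), right_index = integer(0),
               left_x = numeric(0), left_y = numeric(0),
               right_x = numeric(0), right_y = numeric(0),
               distance = numeric(0)),
    class = c("match_set", "data.frame"))
  na <- nrow(a$keypoints); nb <- nrow(b$keypoints)
  if (na == 0L || nb == 0L) return(empty)
  if (ncol(a$descriptors) != ncol(b$descriptors)) {
    stop("descriptor lengths differ", call. = FALSE)
  }
  A <- a$descriptors; B <- b$descriptors
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  nn1 <- max.col(-d2, ties.method = "first")
  best <- d2[cbind(seq_len(na), nn1)]
  d2b <- d2
  d2b[cbind(seq_len(na), nn1)] <- Inf
  second <- d2b[cbind(seq_len(na), max.col(-d2b, ties.method = "first"))]
  accept <- sqrt(best) <= ratio * sqrt(second)
  if (mutual) {
    rev_nn <- max.col(-t(d2), ties.method = "first")
    accept <- accept & rev_nn[nn1] == seq_len(na)
  }
  li <- which(accept)
  if (!length(li)) return(empty)
  structure(
    data.frame(left_index = li, right_index = nn1[li],
               left_x = a$keypoints$x[li], left_y = a$keypoints$y[li],
               right_x = b$keypoints$x[nn1[li]],
               right_y = b$keypoints$y[nn1[li]],
               distance = sqrt(best[li])),
    class = c("match_set", "data.frame"))
}

#' Spatial coherency filter for putative matches
#'
#' A match `(a, b)` survives iff some *different* match `(c, d)` has
#' `|a - c| <= delta_px` and `|b - d| <= epsilon_px` (Euclidean, boundaries
#' inclusive). Exact neighbor search on a uniform grid index; order is
#' preserved, and the operation is idempotent.
#'
#' @param matches a match data frame (as from [match_features()]).
#' @param delta_px left-endpoint radius (reference value 50 px).
#' @param epsilon_px right-endpoint radius (reference value 50 px).
#' @return the surviving subset of `matches`, original order.
#' @export
coherency_filter <- function(matches, delta_px = 50, epsilon_px = 50) {
  stopifnot(is.data.frame(matches))
  if (delta_px <= 0 || epsilon_px <= 0) {
    stop("delta_px and epsilon_px must be positive", call. = FALSE)
  }
  n <- nrow(matches)
  if (n <= 1L) return(matches[integer(0), , drop = FALSE])
  lx <- matches$left_x; ly <- matches$left_y
  rx <- matches$right_x; ry <- matches$right_y
  cell <- delta_px
  cx <- floor(lx / cell); cy <- floor(ly / cell)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  keep <- logical(n)
  d2 <- delta_px^2; e2 <- epsilon_px^2
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1) {
      b <- buckets[[paste(cx[i] + dx, cy[i] + dy)]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- cand[cand != i]
    if (!length(cand)) next
    ok <- (lx[cand] - lx[i])^2 + (ly[cand] - ly[i])^2 <= d2 &
      (rx[cand] - rx[i])^2 + (ry[cand] - ry[i])^2 <= e2
    keep[i] <- any(ok)
  }
  matches[keep, , drop = FALSE]
}

#' Count filtered matches per template region
#'
#' @param matches match data frame whose left endpoints live on the template
#'   image carrying the region mask.
#' @param region_mask integer matrix; pixel value is the region id, 0 is
#'   background.
#' @param template_dim optional `c(height, width)` to validate against.
#' @return data frame `region`, `count`, covering every region id present in
#'   the mask, plus one row with `region = NA` counting endpoints that fall
#'   outside all regions (or outside the mask).
#' @export
count_matches_by_region <- function(matches, region_mask,
                                    template_dim = NULL) {
  if (!is.matrix(region_mask)) stop("region_mask must be a matrix",
                                    call. = FALSE)
  if (!is.null(template_dim) &&
      !all(dim(region_mask) == template_dim[1:2])) {
    stop("region mask size does not match template image", call. = FALSE)
  }
  ids <- sort(unique(as.integer(region_mask[region_mask > 0])))
  counts <- stats::setNames(integer(length(ids)), ids)
  unassigned <- 0L
  if (nrow(matches)) {
    r <- round(matches$left_y) + 1
    c <- round(matches$left_x) + 1
    inside <- r >= 1 & r <= nrow(region_mask) & c >= 1 & c <= ncol(region_mask)
    reg <- rep(0L, nrow(matches))
    reg[inside] <- as.integer(region_mask[cbind(r[inside], c[inside])])
    tab <- table(reg[reg > 0L])
    counts[names(tab)] <- as.integer(tab)
    unassigned <- sum(reg == 0L)
  }
  rbind(data.frame(region = ids, count = as.integer(counts)),
        data.frame(region = NA_integer_, count = unassigned))
}
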