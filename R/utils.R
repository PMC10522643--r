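# Internal utilities: seeded evaluation, image arithmetic, interpolation,
# separable Gaussian filtering, multi-scale value noise, text PGM i/o.
#
# Image convention used throughout the package: a numeric matrix with rows
# indexing y (downward) and columns indexing x (rightward), intensities in
# [0, 1]. Public coordinates are 0-based pixel centers, so pixel (row r,
# col c) sits at (x, y) = (c - 1, r - 1).

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded operations do not perturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Stable 31-bit hash of a string, for deriving per-stage seeds
#' @keywords internal
#' @noRd
stable_string_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Derive a child seed from a master seed and a label
#' @keywords internal
#' @noRd
derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) * 7919 + stable_string_hash(label)) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Check an image matrix
#' @keywords internal
#' @noRd
check_image <- function(img, name = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop(name, " must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(img))) {
    stop(name, " contains non-finite pixels", call. = FALSE)
  }
  invisible(img)
}

#' Bilinear sampling at continuous 0-based coordinates
#'
#' @param img numeric matrix.
#' @param x,y vectors of 0-based coordinates (x along columns, y along rows).
#' @param outside value returned for samples outside the image; `NA` clamps
#'   to the border instead.
#' @keywords internal
#' @noRd
bilinear_sample <- function(img, x, y, outside = 0) {
  h <- nrow(img)
  w <- ncol(img)
  clamp_border <- is.na(outside)
  if (clamp_border) {
    x <- clamp(x, 0, w - 1)
    y <- clamp(y, 0, h - 1)
  }
  x0 <- floor(x)
  y0 <- floor(y)
  fx <- x - x0
  fy <- y - y0
  inside <- x0 >= 0 & y0 >= 0 & x0 <= w - 1 & y0 <= h - 1
  # clamp the +1 neighbor so border pixels sample themselves
  xi0 <- clamp(x0, 0, w - 1)
  yi0 <- clamp(y0, 0, h - 1)
  xi1 <- clamp(x0 + 1, 0, w - 1)
  yi1 <- clamp(y0 + 1, 0, h - 1)
  idx <- function(r, c) img[cbind(r + 1, c + 1)]
  v <- (1 - fx) * (1 - fy) * idx(yi0, xi0) +
    fx * (1 - fy) * idx(yi0, xi1) +
    (1 - fx) * fy * idx(yi1, xi0) +
    fx * fy * idx(yi1, xi1)
  if (!clamp_border) v[!inside] <- outside
  v
}

#' 1-D Gaussian kernel, normalized
#' @keywords internal
#' @noRd
gauss_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) return(1)
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian blur with replicated borders
#'
#' Implemented as two banded-matrix multiplications; fast for the image sizes
#' used here and exactly deterministic.
#'
#' @keywords internal
#' @noRd
gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  conv_mat <- function(n) {
    m <- matrix(0, n, n)
    for (j in seq_len(n)) {
      src <- clamp(seq(j - r, j + r), 1, n)
      for (t in seq_along(src)) m[j, src[t]] <- m[j, src[t]] + k[t]
    }
    m
  }
  rows_m <- conv_mat(nrow(img))
  cols_m <- if (ncol(img) == nrow(img)) rows_m else conv_mat(ncol(img))
  rows_m %*% img %*% t(cols_m)
}

#' Multi-scale seeded value noise in [0, 1]
#'
#' Sum of bilinearly upsampled uniform grids at dyadic scales; the standard
#' cheap stand-in for natural-image backgrounds.
#'
#' @param h,w output size.
#' @param seed integer seed.
#' @param scales grid cell sizes in pixels, coarse to fine.
#' @keywords internal
#' @noRd
value_noise <- function(h, w, seed, scales = c(64, 32, 16, 8, 4)) {
  with_seed(seed, {
    acc <- matrix(0, h, w)
    amp <- 1
    total <- 0
    ys <- seq_len(h) - 1
    xs <- seq_len(w) - 1
    for (s in scales) {
      gh <- ceiling(h / s) + 1L
      gw <- ceiling(w / s) + 1L
      g <- matrix(stats::runif(gh * gw), gh, gw)
      acc <- acc + amp * outer(ys / s, xs / s, function(y, x) {
        bilinear_sample(g, x, y, outside = NA)
      })
      total <- total + amp
      amp <- amp * 0.55
    }
    acc / total
  })
}

#' Read and write portable graymap (PGM, plain "P2") images
#'
#' Text-based single-channel image format used for on-disk frames and masks.
#' Values are scaled to/from [0, 1] via the stated maxval.
#'
#' @param path file path.
#' @return `read_pgm()` returns a numeric matrix in [0, 1].
#' @export
read_pgm <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  toks <- scan(text = paste(txt, collapse = " "), what = character(),
               quiet = TRUE)
  if (length(toks) < 4L || toks[1] != "P2") {
    stop("not a plain PGM (P2) file: ", path, call. = FALSE)
  }
  w <- as.integer(toks[2])
  h <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("PGM pixel count mismatch", call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' @param img numeric matrix in [0, 1].
#' @param maxval integer maximum gray value written.
#' @rdname read_pgm
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  check_image(img)
  q <- round(clamp(img, 0, 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  writeLines(apply(q, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read or write a grayscale image by extension (.pgm, or .png if available)
#' @keywords internal
#' @noRd
read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(read_pgm(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the 'png' package", call. = FALSE)
    }
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1]
    return(a)
  }
  stop("unsupported image format: ", path, call. = FALSE)
}

write_image_file <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pgm") return(write_pgm(img, path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("writing PNG requires the 'png' package", call. = FALSE)
    }
    png::writePNG(clamp(img, 0, 1), path)
    return(invisible(path))
  }
  stop("unsupported image format: ", path, call. = FALSE)
}
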