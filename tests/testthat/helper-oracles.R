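# Independent oracles and shared fixture builders. Oracles deliberately use
# a different implementation route than the code under test (dense outer
# products, recursive flood fill, literal re-implementation of printed
# definitions).

# O(n^2) brute-force coherency filter: the literal definition
brute_coherency <- function(matches, delta, epsilon) {
  n <- nrow(matches)
  if (n <= 1L) return(matches[integer(0), , drop = FALSE])
  dl <- as.matrix(stats::dist(cbind(matches$left_x, matches$left_y)))
  dr <- as.matrix(stats::dist(cbind(matches$right_x, matches$right_y)))
  keep <- vapply(seq_len(n), function(i) {
    any(dl[i, -i] <= delta & dr[i, -i] <= epsilon)
  }, logical(1))
  matches[keep, , drop = FALSE]
}

# recursive flood-fill component areas (independent of label_components)
flood_areas <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    ll <- list()
    for (dy in -1:1) for (dx in -1:1) if (dy || dx) ll <- c(ll, list(c(dy, dx)))
    ll
  }
  areas <- integer(0)
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE; area <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      area <- area + 1L
      for (o in offs) {
        r <- p[1] + o[1]; c <- p[2] + o[2]
        if (r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c] &&
            !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
    areas <- c(areas, area)
  }
  areas
}

# literal re-implementation of the three on-target conditions and the PR
# sweep, loop-based
brute_pr <- function(preds, truths, width, frac = 0.05) {
  truths <- truths[match(preds$frame_index, truths$frame_index), ]
  ths <- sort(unique(preds$confidence), decreasing = TRUE)
  out <- data.frame(threshold = ths, recall = NA_real_, precision = NA_real_)
  n_vis <- sum(truths$present)
  for (k in seq_along(ths)) {
    on_t <- 0L; n_above <- 0L
    for (i in seq_len(nrow(preds))) {
      above <- preds$confidence[i] >= ths[k]
      if (above) n_above <- n_above + 1L
      err <- sqrt((preds$x[i] - truths$x[i])^2 + (preds$y[i] - truths$y[i])^2)
      if (above && truths$present[i] && !is.na(err) && err < frac * width) {
        on_t <- on_t + 1L
      }
    }
    out$recall[k] <- on_t / n_vis
    out$precision[k] <- on_t / n_above
  }
  out
}

# random match configuration, with optional exact-boundary pairs planted at
# distance exactly delta / epsilon
random_matches <- function(n, size = 600, n_boundary = 0, delta = 50,
                           epsilon = 50) {
  m <- data.frame(
    left_index = seq_len(n), right_index = seq_len(n),
    left_x = stats::runif(n, 0, size), left_y = stats::runif(n, 0, size),
    right_x = stats::runif(n, 0, size), right_y = stats::runif(n, 0, size),
    distance = 0)
  if (n_boundary > 0 && n >= 2 * n_boundary) {
    for (b in seq_len(n_boundary)) {
      i <- 2 * b - 1; j <- 2 * b
      m$left_x[j] <- m$left_x[i] + delta   # exactly delta apart on the left
      m$left_y[j] <- m$left_y[i]
      m$right_x[j] <- m$right_x[i]
      m$right_y[j] <- m$right_y[i] + epsilon  # exactly epsilon on the right
    }
  }
  m
}

# synthetic descriptor corpus: each image draws features near a subset of
# well-separated cluster centers (no imagery involved)
make_descriptor_corpus <- function(n_images = 20, n_centers = 40,
                                   feats_per_image = 30, dim = 8,
                                   noise = 0.02, seed = 0) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(n_centers * dim, sd = 3), n_centers, dim)
  lapply(seq_len(n_images), function(i) {
    # a subset of distinct centers per image (an image's barcodes are
    # distinct local patches; duplicates would inflate the weight heuristic)
    picks <- sample.int(n_centers, min(feats_per_image, n_centers))
    X <- centers[picks, , drop = FALSE] +
      matrix(stats::rnorm(feats_per_image * dim, sd = noise),
             feats_per_image, dim)
    feature_set(data.frame(x = stats::runif(feats_per_image, 0, 100),
                           y = stats::runif(feats_per_image, 0, 100),
                           scale = 1, orientation = 0, response = 0.05),
                X, image_id = paste0("img", i))
  })
}

# memoized expensive fixtures shared across test files
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

get_speckle_base <- function() {
  cached("speckle_base", {
    sc <- gen_speckle_scene(speckle_fixture_spec(seed = 0, n_frames = 1,
                                                 warp_type = "translation"))
    fs <- detect_features(sc$base_uv, 0.01, image_id = "base")
    list(scene = sc, features = fs)
  })
}
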