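# Template atlas: rank template images by greedy estimated coverage of
# unmatched corpus features. Each corpus feature is assigned to a descriptor
# cluster; a feature's weight is the number of not-yet-covered corpus
# features in its cluster, an image's weight is the sum of its features'
# weights, and the greedy pick covers every cluster it touches. At fixture
# scale exact Lloyd k-means replaces the original approximate
# 500,000-cluster vocabulary scheme; the weighting/decrement contract is
# unchanged.

#' Cluster corpus descriptors
#'
#' @param corpus list of `feature_set` objects (the candidate template
#'   images).
#' @param n_clusters number of k-means clusters; default
#'   `min(2000, floor(total features / 10))` at fixture scale.
#' @param seed RNG seed (deterministic given seed).
#' @param iter_max Lloyd iteration cap.
#' @return a `cluster_model`: `n_clusters`, `assignment` (cluster id per
#'   corpus feature, in corpus order), `cluster_sizes`, `image_index`
#'   (which corpus image each feature came from), `seed`.
#' @export
cluster_features <- function(corpus, n_clusters = NULL, seed = 0L,
                             iter_max = 50L) {
  stopifnot(is.list(corpus), all(vapply(corpus, inherits, TRUE, "feature_set")))
  counts <- vapply(corpus, length, integer(1))
  total <- sum(counts)
  if (total == 0L) stop("corpus has no features", call. = FALSE)
  if (is.null(n_clusters)) n_clusters <- max(1L, min(2000L, total %/% 10L))
  n_clusters <- as.integer(n_clusters)
  if (n_clusters < 1L || n_clusters > total) {
    stop("n_clusters must be between 1 and the total feature count",
         call. = FALSE)
  }
  X <- do.call(rbind, lapply(corpus, function(fs) fs$descriptors))
  uniq <- X[!duplicated(X), , drop = FALSE]
  if (n_clusters > nrow(uniq)) n_clusters <- nrow(uniq)
  assignment <- with_seed(seed, {
    if (n_clusters == total) {
      seq_len(total)
    } else {
      # farthest-first (maximin) initialization: a random draw of initial
      # centers routinely lands two seeds in one descriptor mode and none
      # in another, and Lloyd cannot recover; maximin spreads the seeds
      # across modes deterministically given the first pick
      centers <- matrix(0, n_clusters, ncol(X))
      centers[1, ] <- uniq[sample.int(nrow(uniq), 1), ]
      d2min <- rowSums(sweep(uniq, 2, centers[1, ])^2)
      if (n_clusters > 1L) {
        for (j in 2:n_clusters) {
          centers[j, ] <- uniq[which.max(d2min), ]
          d2min <- pmin(d2min, rowSums(sweep(uniq, 2, centers[j, ])^2))
        }
      }
      km <- suppressWarnings(stats::kmeans(X, centers = centers,
                                           iter.max = iter_max,
                                           algorithm = "Lloyd"))
      km$cluster
    }
  })
  structure(list(n_clusters = n_clusters, assignment = as.integer(assignment),
                 cluster_sizes = tabulate(assignment, nbins = n_clusters),
                 image_index = rep(seq_along(corpus), counts),
                 seed = as.integer(seed)),
            class = "cluster_model")
}

#' Greedy template ranking by estimated coverage
#'
#' Iteratively picks the image whose features carry the greatest total
#' weight, where a feature's weight is the number of not-yet-covered corpus
#' features in its cluster. After a pick, all features in every cluster the
#' picked image touches are marked covered. Ties break toward the lowest
#' image index.
#'
#' @param corpus list of `feature_set` objects.
#' @param model `cluster_model` built over this corpus.
#' @param n_select number of templates to rank; truncated with a warning if
#'   it exceeds the corpus size.
#' @param per_feature_decrement if `TRUE`, a picked image covers only its
#'   own features' multiplicity rather than whole clusters (the alternative
#'   reading of the decrement step; default covers whole touched clusters).
#' @return a `template_atlas`: `template_ids` (indices into the corpus, in
#'   pick order), `trace` (data frame `image`, `weight`, `covered_total` at
#'   each pick), `model`.
#' @export
rank_templates_greedy <- function(corpus, model, n_select,
                                  per_feature_decrement = FALSE) {
  stopifnot(inherits(model, "cluster_model"))
  n_img <- length(corpus)
  if (n_select > n_img) {
    warning("n_select exceeds corpus size; truncated")
    n_select <- n_img
  }
  covered <- rep(FALSE, length(model$assignment))
  picked <- integer(0)
  trace <- list()
  for (step in seq_len(n_select)) {
    cl_weight <- tabulate(model$assignment[!covered],
                          nbins = model$n_clusters)
    img_weight <- vapply(seq_len(n_img), function(i) {
      if (i %in% picked) return(-Inf)
      feats <- which(model$image_index == i)
      if (!length(feats)) return(0)
      sum(cl_weight[model$assignment[feats]])
    }, numeric(1))
    best <- which.max(img_weight)   # lowest index on ties
    picked <- c(picked, best)
    feats <- which(model$image_index == best)
    if (per_feature_decrement) {
      # cover one corpus feature per picked-image feature, per cluster
      for (cl in model$assignment[feats]) {
        hit <- which(!covered & model$assignment == cl)
        if (length(hit)) covered[hit[1]] <- TRUE
      }
      covered[feats] <- TRUE
    } else {
      covered[model$assignment %in% unique(model$assignment[feats])] <- TRUE
    }
    trace[[step]] <- data.frame(image = best, weight = img_weight[best],
                                covered_total = sum(covered))
  }
  structure(list(template_ids = picked,
                 trace = do.call(rbind, trace), model = model),
            class = "template_atlas")
}

#' @export
print.template_atlas <- function(x, ...) {
  cat("<template_atlas:", length(x$template_ids), "templates; pick order",
      paste(x$template_ids, collapse = ", "), ">\n")
  invisible(x)
}

#' Cluster-space coverage curve of an arbitrary template selection
#'
#' Counts corpus features covered (same whole-cluster covering rule as the
#' greedy ranking) by the first t selected images, for t = 1..length. This
#' is the estimate the greedy algorithm optimizes and the cheap baseline
#' for greedy-vs-random comparisons.
#'
#' @param selection integer vector of corpus image indices.
#' @param model `cluster_model` over the corpus.
#' @return integer vector of cumulative covered-feature counts.
#' @export
cluster_coverage_curve <- function(selection, model) {
  covered <- rep(FALSE, length(model$assignment))
  out <- integer(length(selection))
  for (t in seq_along(selection)) {
    feats <- which(model$image_index == selection[t])
    covered[model$assignment %in% unique(model$assignment[feats])] <- TRUE
    out[t] <- sum(covered)
  }
  out
}

#' Match-based coverage curve of a template atlas
#'
#' For t = 1..n templates, the number of distinct corpus features matched
#' (after coherency filtering) by at least one of the first t templates.
#' Exact but quadratic in corpus size; intended for fixture-scale corpora.
#'
#' @param atlas `template_atlas` (or integer vector of template indices).
#' @param corpus list of `feature_set` objects the atlas indexes into.
#' @param ratio,mutual passed to [match_features()].
#' @param delta_px,epsilon_px passed to [coherency_filter()].
#' @return integer vector of cumulative distinct matched-feature counts.
#' @export
coverage_curve <- function(atlas, corpus, ratio = 0.75, mutual = TRUE,
                           delta_px = 50, epsilon_px = 50) {
  ids <- if (inherits(atlas, "template_atlas")) atlas$template_ids else atlas
  counts <- vapply(corpus, length, integer(1))
  offsets <- cumsum(c(0L, counts))
  covered <- rep(FALSE, sum(counts))
  out <- integer(length(ids))
  for (t in seq_along(ids)) {
    tmpl <- corpus[[ids[t]]]
    for (j in seq_along(corpus)) {
      m <- match_features(tmpl, corpus[[j]], ratio = ratio, mutual = mutual)
      m <- coherency_filter(m, delta_px, epsilon_px)
      if (nrow(m)) covered[offsets[j] + m$right_index] <- TRUE
    }
    out[t] <- sum(covered)
  }
  out
}
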