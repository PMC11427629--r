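# Model attribution: grouped feature-permutation importance and Grad-CAM
# spatial attribution over the mesh.

#' Grouped feature-permutation importance
#'
#' Permutes the columns of a feature group along the vertex dimension (one
#' shared random permutation per mesh per round, so within-group spatial
#' covariation is preserved), recomputes the performance metric, and reports
#' `importance = permuted - baseline` averaged over rounds. Negative values
#' mean the group is important (performance dropped).
#'
#' @param model `NetworkParams` (or a `CalibratedModel`).
#' @param dataset Dataset items with `X` and `y` (see [train()]).
#' @param group Character vector of feature column names to permute jointly.
#' @param metric Metric name from [metrics()] used for scoring (default
#'   `"AUROC"`).
#' @param n_rounds Number of permutation rounds (default 5).
#' @param seed Integer seed.
#' @return List of class `ImportanceResult`: `group`, `baseline`,
#'   `permuted` (per-round values), `importance`.
#' @export
permutation_importance <- function(model, dataset, group, metric = "AUROC",
                                   n_rounds = 5, seed = 0L) {
  params <- if (inherits(model, "CalibratedModel")) model$params else model
  dataset <- .with_hierarchies(dataset, params$config, params$seed)
  feat_names <- colnames(dataset[[1]]$X)
  unknown <- setdiff(group, feat_names)
  if (length(unknown) && length(group)) {
    # a model may deliberately ignore columns absent at training time, but a
    # name not present in the data at all is an error
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  }
  labs <- if (params$task == "classification") {
    vapply(dataset, function(it) it$y, numeric(1))
  } else unlist(lapply(dataset, function(it) it$y))
  score <- function(items) {
    metrics(.model_scores(params, items), labs)[[metric]]
  }
  baseline <- score(dataset)
  usable <- intersect(group, params$feature_names)
  perm_vals <- vapply(seq_len(n_rounds), function(r) {
    if (!length(usable)) return(baseline)  # empty group: identity
    set.seed(as.integer(seed) + r)
    permuted <- lapply(dataset, function(it) {
      pm <- sample(nrow(it$X))
      it$X[, usable] <- it$X[pm, usable, drop = FALSE]
      it
    })
    score(permuted)
  }, numeric(1))
  structure(list(group = group, metric = metric, baseline = baseline,
                 permuted = perm_vals,
                 importance = mean(perm_vals) - baseline),
            class = "ImportanceResult")
}

#' Grad-CAM spatial attribution
#'
#' Gradients of the target-class probability are taken with respect to the
#' activations of a chosen convolutional level, average-pooled along the
#' feature-map dimension, rectified, interpolated back to full mesh
#' resolution by KNN unpooling, and min-max normalized to `[0, 1]`. The
#' high-attribution mask keeps scores at or above the chosen percentile.
#'
#' @param model `NetworkParams` (classification) or `CalibratedModel`.
#' @param mesh A `SurfaceMesh` or prebuilt `MeshHierarchy`.
#' @param features Vertex feature matrix.
#' @param target_class 1 for the positive class (default), 0 for the
#'   negative class.
#' @param layer Convolutional level to attribute at: `"final_conv"` (the
#'   last encoder level, default) or an integer level index.
#' @param percentile High-attribution percentile (default 75).
#' @param weighted Use the classic gradient-times-activation weighting
#'   instead of the plain pooled gradient (default FALSE).
#' @return List of class `AttributionResult`: `scores` (per-vertex, in
#'   `[0, 1]`), `mask` (logical high-attribution mask), `target_class`,
#'   `layer`, `raw` (per-centroid pooled gradients).
#' @export
grad_cam <- function(model, mesh, features, target_class = 1,
                     layer = "final_conv", percentile = 75,
                     weighted = FALSE) {
  params <- if (inherits(model, "CalibratedModel")) model$params else model
  stopifnot(params$task == "classification")
  hier <- if (inherits(mesh, "MeshHierarchy")) mesh else
    build_hierarchy(mesh, params$config, seed = params$seed)
  d <- length(hier$levels)
  L <- if (identical(layer, "final_conv")) d else as.integer(layer)
  stopifnot(L >= 1, L <= d)
  fwd <- .network_forward(params, hier, features, keep_cache = TRUE)
  probs <- as.numeric(fwd$probs)
  tcol <- if (target_class == 1) 2L else 1L
  # the two-class probability gradient is p(1-p) times the logit-difference
  # gradient; since scores are min-max normalized, the positive scalar is
  # irrelevant and the difference form stays finite at saturated outputs
  gl <- ifelse(seq_len(2) == tcol, 1, -1)
  hb <- .mlp2_backward(fwd$head, params$par$head, matrix(gl, 1))
  ab <- .att_pool_backward(fwd$att, params$par$att,
                           as.numeric(hb$grad_X) / fwd$att$n)
  grad_acts <- rep(list(NULL), d + 1)
  grad_acts[[d + 1]] <- ab$grad_X
  if (L == d) {
    gH <- ab$grad_X
  } else {
    encb <- .encoder_backward(params$par, hier, fwd$enc, grad_acts,
                              to_level = L + 1L)
    gH <- encb$grad_H
  }
  act <- fwd$enc$acts[[L + 1]]
  raw <- if (weighted) {
    w <- colMeans(gH)
    as.numeric(act %*% w)
  } else {
    rowMeans(gH)
  }
  sc <- pmax(raw, 0)  # rectify
  if (max(sc) <= 0) sc <- raw  # all-negative field: fall back to signed scores
  # interpolate back to the full mesh through the stored unpooling maps
  sc <- matrix(sc, ncol = 1)
  for (l in rev(seq_len(L))) {
    sc <- apply_unpool(hier$levels[[l]]$unpool, sc)
  }
  sc <- as.numeric(sc)
  rng <- range(sc)
  if (diff(rng) < 1e-12) {
    warning("zero gradient everywhere: attribution scores are all zero")
    scores <- rep(0, length(sc))
  } else {
    scores <- (sc - rng[1]) / diff(rng)
  }
  thr <- stats::quantile(scores, percentile / 100)
  structure(list(scores = scores, mask = scores >= thr,
                 target_class = target_class, layer = L,
                 percentile = percentile, raw = raw),
            class = "AttributionResult")
}

#' Feature distributions inside high-attribution regions
#'
#' @param attribution An `AttributionResult` from [grad_cam()].
#' @param features Vertex feature matrix.
#' @return data.frame, one row per feature: mean and quartiles inside the
#'   high-attribution mask and outside it, and their mean difference.
#' @export
high_attribution_features <- function(attribution, features) {
  X <- as.matrix(features)
  m <- attribution$mask
  if (!any(m)) stop("empty high-attribution mask")
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75))
  inside <- X[m, , drop = FALSE]
  outside <- X[!m, , drop = FALSE]
  out <- data.frame(
    feature = colnames(X),
    mean_in = colMeans(inside),
    q25_in = apply(inside, 2, function(v) qs(v)[1]),
    q50_in = apply(inside, 2, function(v) qs(v)[2]),
    q75_in = apply(inside, 2, function(v) qs(v)[3]),
    mean_out = if (nrow(outside)) colMeans(outside) else NA_real_,
    row.names = NULL)
  out$mean_diff <- out$mean_in - out$mean_out
  out
}
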