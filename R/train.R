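# Training, cross-validation, calibration, thresholding, pooling, labeling
# and metrics: the probabilistic binding model around the networks.

#' Binary cross-entropy
#'
#' Mean negative log-likelihood of binary labels under predicted Bernoulli
#' probabilities, with probabilities clamped to `[eps, 1 - eps]`.
#'
#' @param q Predicted probabilities of the positive class.
#' @param p Binary labels (0/1), same length as `q`.
#' @param eps Clamping constant (default 1e-7).
#' @return Scalar mean cross-entropy.
#' @export
cross_entropy <- function(q, p, eps = 1e-7) {
  if (length(q) != length(p)) stop("shape mismatch between q and p")
  q <- pmin(pmax(q, eps), 1 - eps)
  -mean(p * log(q) + (1 - p) * log(1 - q))
}

#' Label binding residues and vertices by distance to nucleic-acid atoms
#'
#' A residue is positive iff any of its atoms lies within `cutoff` of any
#' nucleic-acid atom; vertices inherit the label of their residue.
#'
#' @param structure An `AtomicStructure` (the protein).
#' @param na_atoms Matrix (n x 3) of nucleic-acid atom coordinates; may be
#'   empty (all labels 0).
#' @param cutoff Distance threshold in A (default 5.0).
#' @param mesh Optional `SurfaceMesh` with `vertex_residue`; when given,
#'   per-vertex labels are included.
#' @return List of class `LabelSet` with `residue` (0/1 per residue),
#'   `vertex` (0/1 per vertex or NULL), `positive_fraction`.
#' @export
label_binding <- function(structure, na_atoms, cutoff = 5.0, mesh = NULL) {
  stopifnot(cutoff > 0)
  nres <- n_residues(structure)
  res_lab <- integer(nres)
  na_atoms <- as.matrix(na_atoms)
  if (length(na_atoms) && nrow(na_atoms) > 0) {
    xyz <- atom_xyz(structure)
    D2 <- outer(rowSums(xyz^2), rowSums(na_atoms^2), "+") -
      2 * xyz %*% t(na_atoms)
    near <- apply(D2, 1, min) <= cutoff^2
    hit <- unique(structure$residue[near])
    res_lab[hit] <- 1L
  }
  vert <- if (!is.null(mesh)) res_lab[mesh$vertex_residue] else NULL
  structure(list(residue = res_lab, vertex = vert,
                 positive_fraction = mean(res_lab)),
            class = "LabelSet")
}

# ---- optimization ----------------------------------------------------------

.flatten <- function(p) unlist(p, use.names = FALSE)

.adam_state <- function(n) list(m = numeric(n), v = numeric(n), t = 0)

.adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

.item_loss_grad <- function(params, item, want_grad = TRUE) {
  fwd <- .network_forward(params, item$hier, item$X, keep_cache = want_grad)
  if (params$task == "classification") {
    y <- item$y
    p1 <- fwd$probs[1, 2]
    loss <- cross_entropy(p1, y)
    n <- 1L
  } else {
    y <- item$y
    loss <- cross_entropy(fwd$probs[, 2], y)
    n <- length(y)
  }
  if (!want_grad) return(list(loss = loss))
  onehot <- cbind(1 - y, y)
  grad_logits <- (if (params$task == "classification")
    matrix(fwd$probs - onehot, 1) else (fwd$probs - onehot)) / n
  grads <- .network_backward(params, item$hier, fwd, grad_logits)
  grads$grad_X <- NULL
  list(loss = loss, grads = grads)
}

.dataset_loss <- function(params, items) {
  mean(vapply(items, function(it)
    .item_loss_grad(params, it, want_grad = FALSE)$loss, numeric(1)))
}

# ensure every dataset item carries a hierarchy
.with_hierarchies <- function(dataset, config, seed) {
  lapply(dataset, function(it) {
    if (is.null(it$hier)) it$hier <- build_hierarchy(it$mesh, config, seed = seed)
    it
  })
}

#' Train a network
#'
#' Gradient-based minimization of the cross-entropy with the Adam optimizer,
#' iterating items in a seeded shuffled order, with early stopping on
#' validation loss. Input features are standardized with statistics from the
#' training split (stored in the returned parameters). Deterministic given
#' the seed.
#'
#' @param dataset List of items, each a list with `mesh` (a `SurfaceMesh` or
#'   prebuilt `MeshHierarchy` under `hier`), `X` (feature matrix) and `y`
#'   (per-vertex 0/1 labels for segmentation; a single 0/1 label for
#'   classification).
#' @param config A [layer_config()].
#' @param task `"segmentation"` or `"classification"`.
#' @param lr Adam learning rate (default 0.01).
#' @param epochs Maximum epochs (default 40).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param seed Integer seed (initialization, shuffling, FPS).
#' @param val_items Optional validation items; by default `val_frac` of the
#'   dataset is held out (stratified for classification).
#' @param val_frac Fraction held out for validation when `val_items` is NULL.
#' @param verbose Print per-epoch losses.
#' @return `NetworkParams` at the best validation epoch, with `history`
#'   (data.frame of train/validation loss per epoch) attached.
#' @export
train <- function(dataset, config = layer_config(),
                  task = c("segmentation", "classification"),
                  lr = 0.01, epochs = 40, patience = 10, seed = 0L,
                  val_items = NULL, val_frac = 0.2, verbose = FALSE) {
  task <- match.arg(task)
  if (length(dataset) == 0L) stop("empty dataset")
  labs <- unlist(lapply(dataset, function(it) it$y))
  if (length(unique(labs)) < 2L) stop("dataset contains a single class")
  dataset <- .with_hierarchies(dataset, config, seed)
  if (is.null(val_items)) {
    set.seed(as.integer(seed) + 1L)
    n <- length(dataset)
    if (task == "classification") {
      yv <- vapply(dataset, function(it) it$y, numeric(1))
      vidx <- unlist(lapply(split(seq_len(n), yv), function(ix)
        sample(ix, max(1L, round(val_frac * length(ix))))))
    } else {
      vidx <- sample(n, max(1L, round(val_frac * n)))
    }
    val_items <- dataset[vidx]
    tr_items <- dataset[-vidx]
  } else {
    val_items <- .with_hierarchies(val_items, config, seed)
    tr_items <- dataset
  }

  nf <- ncol(tr_items[[1]]$X)
  fn <- colnames(tr_items[[1]]$X)
  params <- init_network_params(nf, config, task, seed = seed,
                                feature_names = fn)
  Xall <- do.call(rbind, lapply(tr_items, function(it) as.matrix(it$X)))
  params$feat_mean <- colMeans(Xall)
  params$feat_sd <- apply(Xall, 2, stats::sd)
  params$feat_sd[params$feat_sd < 1e-8] <- 1

  theta <- .flatten(params$par)
  st <- .adam_state(length(theta))
  best <- list(loss = Inf, theta = theta, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  wait <- 0L
  for (ep in seq_len(epochs)) {
    set.seed(as.integer(seed) + 1000L + ep)
    ord <- sample(length(tr_items))
    tot <- 0
    for (i in ord) {
      params$par <- utils::relist(theta, params$par)
      lg <- .item_loss_grad(params, tr_items[[i]])
      tot <- tot + lg$loss
      upd <- .adam_step(st, theta, .flatten(lg$grads), lr)
      theta <- upd$theta; st <- upd$state
    }
    params$par <- utils::relist(theta, params$par)
    vl <- .dataset_loss(params, val_items)
    hist <- rbind(hist, data.frame(epoch = ep, train = tot / length(tr_items),
                                   val = vl))
    if (verbose) message(sprintf("epoch %3d  train %.4f  val %.4f", ep,
                                 tot / length(tr_items), vl))
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, theta = theta, epoch = ep)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  params$par <- utils::relist(best$theta, params$par)
  params$history <- hist
  params$best_epoch <- best$epoch
  params$val_loss <- best$loss
  params
}

# ---- calibration and thresholds -------------------------------------------

#' Platt scaling
#'
#' Fits `p = sigmoid(a * s + b)` to scores by regularized maximum likelihood
#' using Platt's smoothed targets `(N+ + 1)/(N+ + 2)` and `1/(N- + 2)`,
#' constrained order-preserving (`a > 0`).
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (0/1).
#' @return Numeric `c(a, b)`.
#' @export
platt_scale <- function(scores, labels) {
  if (length(unique(labels)) < 2L) stop("both classes required")
  np <- sum(labels == 1); nn <- sum(labels == 0)
  t <- ifelse(labels == 1, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(ab) {
    p <- .sigmoid(ab[1] * scores + ab[2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(t * log(p) + (1 - t) * log(1 - p))
  }
  gr <- function(ab) {
    p <- .sigmoid(ab[1] * scores + ab[2])
    d <- p - t
    c(sum(d * scores), sum(d))
  }
  fit <- stats::optim(c(1, 0), nll, gr, method = "L-BFGS-B",
                      lower = c(1e-6, -Inf))
  stats::setNames(fit$par, c("a", "b"))
}

#' Apply Platt calibration
#' @param scores Raw scores.
#' @param ab `c(a, b)` from [platt_scale()].
#' @return Calibrated probabilities.
#' @export
platt_apply <- function(scores, ab) .sigmoid(ab[1] * scores + ab[2])

#' Decision threshold maximizing F1
#'
#' Scans the unique predicted probabilities as candidate thresholds and
#' returns the one maximizing F1 of `y_hat = (p >= tau)`; ties resolved
#' towards the largest threshold.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary labels.
#' @return The selected threshold.
#' @export
select_threshold_max_f1 <- function(probs, labels) {
  cand <- sort(unique(probs))
  f1 <- vapply(cand, function(tau) {
    yh <- as.integer(probs >= tau)
    tp <- sum(yh == 1 & labels == 1)
    fp <- sum(yh == 1 & labels == 0)
    fn <- sum(yh == 0 & labels == 1)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  max(cand[f1 == max(f1)])
}

#' Max-pool vertex probabilities to residues
#'
#' Residue probability = max over the vertices mapped to that residue.
#' Residues with no surface vertices are flagged buried and excluded.
#'
#' @param vertex_probs Per-vertex probabilities.
#' @param vertex_residue Vertex -> residue index map.
#' @param n_res Total residue count (default: max of the map).
#' @return data.frame (residue, prob) for surface residues, with attribute
#'   `buried` listing residues that have no vertices.
#' @export
residue_pool <- function(vertex_probs, vertex_residue,
                         n_res = max(vertex_residue)) {
  agg <- tapply(vertex_probs, vertex_residue, max)
  res <- as.integer(names(agg))
  out <- data.frame(residue = res, prob = as.numeric(agg))
  attr(out, "buried") <- setdiff(seq_len(n_res), res)
  out
}

#' Binary classification metrics
#'
#' AUROC by the midrank (Mann-Whitney) statistic, AUPRC by step integration
#' of the precision-recall curve, and threshold metrics at `tau`.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary labels.
#' @param tau Decision threshold (default 0.5).
#' @return Named list: AUROC, AUPRC, recall, precision, specificity, BA,
#'   MCC, FPR. Rank metrics are NA when only one class is present.
#' @export
metrics <- function(probs, labels, tau = 0.5) {
  pos <- labels == 1; neg <- !pos
  np <- sum(pos); nn <- sum(neg)
  if (np > 0 && nn > 0) {
    r <- rank(probs)  # midranks for ties
    auroc <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
    o <- order(-probs)
    tp <- cumsum(labels[o] == 1)
    prec <- tp / seq_along(tp)
    rec <- tp / np
    auprc <- sum(diff(c(0, rec)) * prec)
  } else {
    auroc <- NA_real_; auprc <- NA_real_
  }
  yh <- as.integer(probs >= tau)
  TP <- sum(yh == 1 & pos); FP <- sum(yh == 1 & neg)
  FN <- sum(yh == 0 & pos); TN <- sum(yh == 0 & neg)
  recall <- if (np > 0) TP / np else NA_real_
  precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  specificity <- if (nn > 0) TN / nn else NA_real_
  ba <- mean(c(recall, specificity))
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (den > 0) (TP * TN - FP * FN) / den else 0
  fpr <- if (nn > 0) FP / nn else NA_real_
  list(AUROC = auroc, AUPRC = auprc, recall = recall, precision = precision,
       specificity = specificity, BA = ba, MCC = mcc, FPR = fpr)
}

# ---- cross-validation ensembles -------------------------------------------

# stratified k folds; guarantees both classes in every training split
.make_folds <- function(y, k, seed) {
  set.seed(as.integer(seed))
  n <- length(y)
  fold <- integer(n)
  for (cls in unique(y)) {
    ix <- sample(which(y == cls))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

# positive-class scores of one model on dataset items
.model_scores <- function(params, items) {
  items <- .with_hierarchies(items, params$config, params$seed)
  if (params$task == "classification") {
    vapply(items, function(it)
      .network_forward(params, it$hier, it$X)$probs[1, 2], numeric(1))
  } else {
    unlist(lapply(items, function(it)
      .network_forward(params, it$hier, it$X)$probs[, 2]))
  }
}

#' Cross-validated ensemble with per-model calibration
#'
#' Splits the dataset into `k` stratified folds; for each fold, trains
#' `replicates` models with different random initializations on the
#' remaining folds (the held-out fold is the validation set for early
#' stopping) and keeps the replicate with the best validation loss. Each
#' kept model receives Platt parameters fit on its validation fold and an
#' independent decision threshold: max-F1 over its training-set predictions
#' for segmentation, fixed 0.5 for classification.
#'
#' @param dataset As in [train()].
#' @param config A [layer_config()].
#' @param task `"segmentation"` or `"classification"`.
#' @param k Number of folds (default 5).
#' @param replicates Models trained per fold (default 1).
#' @param seed Integer seed.
#' @param ... Passed to [train()] (lr, epochs, patience, ...).
#' @return List of `CalibratedModel` objects: each has `params`, `platt`,
#'   `tau`, `fold`.
#' @export
crossval_ensemble <- function(dataset, config = layer_config(),
                              task = c("segmentation", "classification"),
                              k = 5, replicates = 1, seed = 0L, ...) {
  task <- match.arg(task)
  stopifnot(k >= 2)
  dataset <- .with_hierarchies(dataset, config, seed)
  ymesh <- vapply(dataset, function(it)
    if (task == "classification") it$y else as.numeric(any(it$y == 1)),
    numeric(1))
  fold <- .make_folds(ymesh, k, seed)
  models <- list()
  for (f in seq_len(k)) {
    tr <- dataset[fold != f]; va <- dataset[fold == f]
    best <- NULL
    for (rep_i in seq_len(replicates)) {
      m <- train(tr, config, task, seed = as.integer(seed) + 97L * f + rep_i,
                 val_items = va, ...)
      if (is.null(best) || m$val_loss < best$val_loss) best <- m
    }
    vscores <- .model_scores(best, va)
    vlabs <- if (task == "classification") {
      vapply(va, function(it) it$y, numeric(1))
    } else unlist(lapply(va, function(it) it$y))
    ab <- if (length(unique(vlabs)) >= 2) platt_scale(vscores, vlabs)
          else c(a = 1, b = 0)
    if (task == "classification") {
      tau <- 0.5
    } else {
      tscores <- platt_apply(.model_scores(best, tr), ab)
      tlabs <- unlist(lapply(tr, function(it) it$y))
      tau <- select_threshold_max_f1(tscores, tlabs)
    }
    models[[f]] <- structure(list(params = best, platt = ab, tau = tau,
                                  fold = f), class = "CalibratedModel")
  }
  models
}

#' Ensemble prediction
#'
#' Mean of the members' calibrated probabilities; labels by majority vote of
#' the per-member thresholded calls (ties -> positive).
#'
#' @param models List of `CalibratedModel` from [crossval_ensemble()].
#' @param items Dataset items to score.
#' @return List with `prob` (mean calibrated probability), `label`
#'   (majority-vote call) and `member_probs` (matrix, one column per model).
#' @export
ensemble_predict <- function(models, items) {
  member <- sapply(models, function(m)
    platt_apply(.model_scores(m$params, items), m$platt))
  member <- as.matrix(member)
  calls <- sapply(seq_along(models), function(j)
    as.integer(member[, j] >= models[[j]]$tau))
  calls <- as.matrix(calls)
  list(prob = rowMeans(member),
       label = as.integer(rowMeans(calls) >= 0.5),
       member_probs = member)
}

#' Export residue-level predictions
#'
#' @param structure An `AtomicStructure`.
#' @param pooled data.frame from [residue_pool()].
#' @param tau Decision threshold used for the label column.
#' @param path Optional TSV output path.
#' @return data.frame with chain, resno, resname, prob, label.
#' @export
export_residue_predictions <- function(structure, pooled, tau = 0.5,
                                       path = NULL) {
  rt <- residue_table(structure)
  out <- merge(rt, pooled, by = "residue")
  out$label <- as.integer(out$prob >= tau)
  out <- out[order(out$residue), c("chain", "resno", "resname", "prob", "label")]
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
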