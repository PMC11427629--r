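# Crystal-graph convolution networks on mesh hierarchies, with manual
# forward/backward passes in plain matrix code.
#
# A level applies two CG convolutions: the first aggregates fine-level
# neighbours into the FPS centroids (fine -> coarse), the second operates
# between centroids. A CG convolution computes, per directed edge (j -> i),
#   z_ij = [x_i, x_j, e_ij]
#   m_ij = sigmoid(z W_g + b_g) * softplus(z W_f + b_f)
# and updates x_i <- x_i + a1 min + a2 max + a3 mean + a4 stdev of its
# incoming messages (learned combination weights a, population stdev;
# centroids with no neighbours pass through unchanged).

.sigmoid <- function(x) 1 / (1 + exp(-x))
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

.rand_mat <- function(nr, nc) {
  matrix(rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
}

#' Initialize network parameters
#'
#' @param n_features Number of input feature columns.
#' @param config A [layer_config()].
#' @param task `"segmentation"` or `"classification"`.
#' @param seed Integer initialization seed.
#' @param feature_names Optional column names enforced at prediction time.
#' @return List of class `NetworkParams` holding all learnable arrays plus
#'   the architecture config, task, seed and (after training) feature
#'   standardization statistics.
#' @export
init_network_params <- function(n_features, config = layer_config(),
                                task = c("segmentation", "classification"),
                                seed = 0L, feature_names = NULL) {
  task <- match.arg(task)
  set.seed(as.integer(seed))
  W <- config$width; H <- config$head_hidden; zc <- 2 * W + 4
  conv_init <- function() list(Wg = .rand_mat(zc, W), bg = numeric(W),
                               Wf = .rand_mat(zc, W), bf = numeric(W),
                               a = c(0, 0, 1, 0) + rnorm(4, sd = 0.01))
  levels <- lapply(seq_len(config$depth), function(l) {
    list(conv1 = conv_init(), conv2 = conv_init())
  })
  p <- list(lift = list(W = .rand_mat(n_features, W), b = numeric(W)),
            levels = levels)
  if (task == "classification") {
    p$att <- list(w = .rand_mat(W, 1), b = 0)
    p$head <- list(W1 = .rand_mat(W, H), b1 = numeric(H),
                   W2 = .rand_mat(H, 2), b2 = numeric(2))
  } else {
    p$dec <- lapply(seq_len(config$depth - 1), function(l) {
      list(W = .rand_mat(2 * W, W), b = numeric(W))
    })
    p$head <- list(W1 = .rand_mat(2 * W, H), b1 = numeric(H),
                   W2 = .rand_mat(H, 2), b2 = numeric(2))
  }
  structure(list(par = p, config = config, task = task, seed = as.integer(seed),
                 n_features = n_features, feature_names = feature_names,
                 feat_mean = rep(0, n_features), feat_sd = rep(1, n_features)),
            class = "NetworkParams")
}

# ---- grouped aggregation helpers ------------------------------------------

.rowsum_full <- function(m, idx, n) {
  out <- matrix(0, n, ncol(m))
  if (length(idx)) {
    acc <- rowsum(m, idx)
    out[as.integer(rownames(acc)), ] <- acc
  }
  out
}

# grouped min/max via padded gather over the precomputed IDX matrix
.group_extreme <- function(m, g, what) {
  pad <- if (what == "max") -Inf else Inf
  W <- ncol(m)
  mp <- rbind(m, rep(pad, W))
  out <- matrix(pad, g$n_cent, W)
  for (j in seq_len(ncol(g$IDX))) {
    cand <- mp[g$IDX[, j], , drop = FALSE]
    out <- if (what == "max") pmax(out, cand) else pmin(out, cand)
  }
  out[g$cnt == 0, ] <- 0
  out
}

# ---- CG convolution --------------------------------------------------------

cg_conv_forward <- function(Xs, Xc, g, p) {
  E <- length(g$from)
  W <- ncol(Xs)
  if (E == 0L) {
    return(list(out = Xc,
                cache = list(empty = TRUE, g = g, W = W, n_src = nrow(Xs))))
  }
  z <- cbind(Xc[g$to, , drop = FALSE], Xs[g$from, , drop = FALSE], g$ef)
  ug <- sweep(z %*% p$Wg, 2, p$bg, "+")
  uf <- sweep(z %*% p$Wf, 2, p$bf, "+")
  gate <- .sigmoid(ug)
  filt <- .softplus(uf)
  m <- gate * filt
  cnt <- pmax(g$cnt, 1L)
  s_sum <- .rowsum_full(m, g$to, g$n_cent)
  s_mean <- s_sum / cnt
  s_sq <- .rowsum_full(m * m, g$to, g$n_cent)
  s_var <- pmax(s_sq / cnt - s_mean^2, 0)
  s_sd <- sqrt(s_var)
  s_min <- .group_extreme(m, g, "min")
  s_max <- .group_extreme(m, g, "max")
  agg <- p$a[1] * s_min + p$a[2] * s_max + p$a[3] * s_mean + p$a[4] * s_sd
  agg[g$cnt == 0, ] <- 0
  out <- Xc + agg
  list(out = out,
       cache = list(empty = FALSE, g = g, z = z, ug = ug, uf = uf,
                    gate = gate, filt = filt, m = m, s_min = s_min,
                    s_max = s_max, s_mean = s_mean, s_sd = s_sd,
                    n_src = nrow(Xs), W = W))
}

cg_conv_backward <- function(cache, p, grad_out) {
  g <- cache$g
  W <- cache$W
  if (cache$empty) {
    zg <- list(Wg = p$Wg * 0, bg = p$bg * 0, Wf = p$Wf * 0, bf = p$bf * 0,
               a = p$a * 0)
    return(list(grad_Xs = matrix(0, cache$n_src, W),
                grad_Xc = grad_out, grads = zg))
  }
  live <- g$cnt > 0
  gml <- grad_out
  gml[!live, ] <- 0
  grad_a <- c(sum(gml * cache$s_min), sum(gml * cache$s_max),
              sum(gml * cache$s_mean), sum(gml * cache$s_sd))
  cnt <- pmax(g$cnt, 1L)
  exp_idx <- g$to
  grad_m <- (p$a[3] * gml / cnt)[exp_idx, , drop = FALSE]
  # min/max: gradient shared equally among ties
  for (what in c("min", "max")) {
    stat <- if (what == "min") cache$s_min else cache$s_max
    aw <- if (what == "min") p$a[1] else p$a[2]
    mask <- abs(cache$m - stat[exp_idx, , drop = FALSE]) < 1e-12
    ties <- .rowsum_full(mask * 1, g$to, g$n_cent)
    ties[ties == 0] <- 1
    grad_m <- grad_m + mask * ((aw * gml / ties)[exp_idx, , drop = FALSE])
  }
  # stdev: d sd / d m_e = (m_e - mean) / (n * sd); 0 at sd ~ 0
  sd_safe <- cache$s_sd
  zero_sd <- sd_safe < 1e-8
  sd_safe[zero_sd] <- 1
  coef <- p$a[4] * gml / (cnt * sd_safe)
  coef[zero_sd] <- 0
  grad_m <- grad_m + coef[exp_idx, , drop = FALSE] *
    (cache$m - cache$s_mean[exp_idx, , drop = FALSE])

  grad_ug <- grad_m * cache$filt * cache$gate * (1 - cache$gate)
  grad_uf <- grad_m * cache$gate * .sigmoid(cache$uf)
  grads <- list(Wg = crossprod(cache$z, grad_ug), bg = colSums(grad_ug),
                Wf = crossprod(cache$z, grad_uf), bf = colSums(grad_uf),
                a = grad_a)
  grad_z <- grad_ug %*% t(p$Wg) + grad_uf %*% t(p$Wf)
  grad_Xc <- grad_out + .rowsum_full(grad_z[, seq_len(W), drop = FALSE],
                                     g$to, g$n_cent)
  grad_Xs <- .rowsum_full(grad_z[, W + seq_len(W), drop = FALSE],
                          g$from, cache$n_src)
  list(grad_Xs = grad_Xs, grad_Xc = grad_Xc, grads = grads)
}

# ---- global attention pooling ---------------------------------------------

#' Global attention pooling
#'
#' Pools node features as `sum_i sigmoid(f(x_i)) x_i` with a learned scoring map `f`;
#' permutation invariant by construction.
#'
#' @param feats Node feature matrix (n x W).
#' @param params List with `w` (W x 1) and `b` (scalar) defining
#'   `f(x) = x w + b`.
#' @return Pooled feature vector of length W.
#' @export
global_attention_pool <- function(feats, params) {
  .att_pool_forward(as.matrix(feats), params)$r
}

.att_pool_forward <- function(X, p) {
  u <- as.numeric(X %*% p$w) + p$b
  s <- .sigmoid(u)
  list(r = colSums(X * s), X = X, s = s, u = u)
}

.att_pool_backward <- function(cache, p, grad_r) {
  cvec <- as.numeric(cache$X %*% grad_r)
  grad_u <- cvec * cache$s * (1 - cache$s)
  grad_X <- outer(cache$s, grad_r) + outer(grad_u, as.numeric(p$w))
  list(grad_X = grad_X,
       grads = list(w = matrix(crossprod(cache$X, grad_u), ncol = 1),
                    b = sum(grad_u)))
}

# ---- dense layers ----------------------------------------------------------

.linear_forward <- function(X, W, b) sweep(X %*% W, 2, b, "+")

.mlp2_forward <- function(X, h) {
  u1 <- .linear_forward(X, h$W1, h$b1)
  a1 <- .softplus(u1)
  logits <- .linear_forward(a1, h$W2, h$b2)
  list(logits = logits, X = X, u1 = u1, a1 = a1)
}

.mlp2_backward <- function(cache, h, grad_logits) {
  grad_a1 <- grad_logits %*% t(h$W2)
  grad_u1 <- grad_a1 * .sigmoid(cache$u1)
  list(grad_X = grad_u1 %*% t(h$W1),
       grads = list(W1 = crossprod(cache$X, grad_u1), b1 = colSums(grad_u1),
                    W2 = crossprod(cache$a1, grad_logits),
                    b2 = colSums(grad_logits)))
}

.softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- full network ----------------------------------------------------------

.encoder_forward <- function(par, hier, X) {
  H <- .linear_forward(X, par$lift$W, par$lift$b)
  acts <- list(H)  # acts[[l + 1]] = output of level l
  caches <- list()
  for (l in seq_along(hier$levels)) {
    lv <- hier$levels[[l]]
    pc <- par$levels[[l]]
    Xc <- H[lv$cidx, , drop = FALSE]
    c1 <- cg_conv_forward(H, Xc, lv$gA, pc$conv1)
    c2 <- cg_conv_forward(c1$out, c1$out, lv$gB, pc$conv2)
    caches[[l]] <- list(c1 = c1$cache, c2 = c2$cache)
    H <- c2$out
    acts[[l + 1]] <- H
  }
  list(acts = acts, caches = caches, X = X)
}

# backward through encoder levels down to (and including) `to_level` + lift;
# grad_acts must hold one gradient per entry of acts (zeros allowed)
.encoder_backward <- function(par, hier, enc, grad_acts, to_level = 0L) {
  d <- length(hier$levels)
  glevels <- vector("list", d)
  gH <- grad_acts[[d + 1]]
  for (l in rev(seq_len(d))) {
    lv <- hier$levels[[l]]
    pc <- par$levels[[l]]
    b2 <- cg_conv_backward(enc$caches[[l]]$c2, pc$conv2, gH)
    g_c1out <- b2$grad_Xc + b2$grad_Xs  # conv2 is centroid-to-centroid
    b1 <- cg_conv_backward(enc$caches[[l]]$c1, pc$conv1, g_c1out)
    gH <- b1$grad_Xs
    gH[lv$cidx, ] <- gH[lv$cidx, , drop = FALSE] + b1$grad_Xc
    glevels[[l]] <- list(conv1 = b1$grads, conv2 = b2$grads)
    if (!is.null(grad_acts[[l]])) gH <- gH + grad_acts[[l]]
    if (l - 1L < to_level) {
      return(list(glevels = glevels, grad_H = gH, level = l - 1L))
    }
  }
  glift <- list(W = crossprod(enc$X, gH), b = colSums(gH))
  list(glevels = glevels, glift = glift, grad_X = gH %*% t(par$lift$W),
       grad_H0 = gH)
}

.standardize <- function(params, X) {
  X <- as.matrix(X)
  if (!is.null(params$feature_names)) {
    if (is.null(colnames(X)) || !identical(colnames(X), params$feature_names)) {
      have <- if (is.null(colnames(X))) "<unnamed>" else
        paste(colnames(X), collapse = ", ")
      if (!is.null(colnames(X)) &&
          all(params$feature_names %in% colnames(X))) {
        # columns the model was not trained on are ignored
        X <- X[, params$feature_names, drop = FALSE]
      } else {
        stop("feature columns do not match the model: expected [",
             paste(params$feature_names, collapse = ", "), "], got [", have, "]")
      }
    }
  } else if (ncol(X) != params$n_features) {
    stop(sprintf("feature count mismatch: model expects %d columns, got %d",
                 params$n_features, ncol(X)))
  }
  sweep(sweep(X, 2, params$feat_mean), 2, pmax(params$feat_sd, 1e-8), "/")
}

.network_forward <- function(params, hier, X, keep_cache = FALSE) {
  X <- .standardize(params, X)
  par <- params$par
  enc <- .encoder_forward(par, hier, X)
  d <- length(hier$levels)
  if (params$task == "classification") {
    att <- .att_pool_forward(enc$acts[[d + 1]], par$att)
    # fixed 1/n rescaling between pool and head: keeps the head input on a
    # size-independent scale (absorbable into the head weights)
    att$n <- nrow(enc$acts[[d + 1]])
    head <- .mlp2_forward(matrix(att$r / att$n, 1), par$head)
    probs <- .softmax(head$logits)
    out <- list(probs = probs)
    if (keep_cache) out <- c(out, list(enc = enc, att = att, head = head))
    return(out)
  }
  # decoder with skip connections
  Hdec <- enc$acts[[d + 1]]
  dec_caches <- list()
  for (l in rev(seq_len(d))) {
    lv <- hier$levels[[l]]
    U <- apply_unpool(lv$unpool, Hdec)
    skip <- enc$acts[[l]]
    Z <- cbind(U, skip)
    if (l > 1) {
      pdl <- par$dec[[l - 1]]
      u <- .linear_forward(Z, pdl$W, pdl$b)
      Hnew <- .softplus(u)
      dec_caches[[l]] <- list(Z = Z, u = u, n_coarse = nrow(Hdec))
      Hdec <- Hnew
    } else {
      dec_caches[[l]] <- list(Z = Z, n_coarse = nrow(Hdec))
      Hdec <- Z
    }
  }
  head <- .mlp2_forward(Hdec, par$head)
  probs <- .softmax(head$logits)
  out <- list(probs = probs)
  if (keep_cache) out <- c(out, list(enc = enc, dec = dec_caches, head = head))
  out
}

# full backward from the per-row logit gradients; returns nested grads
.network_backward <- function(params, hier, fwd, grad_logits) {
  par <- params$par
  d <- length(hier$levels)
  hb <- .mlp2_backward(fwd$head, par$head, grad_logits)
  grad_acts <- rep(list(NULL), d + 1)
  gdec <- NULL
  if (params$task == "classification") {
    ab <- .att_pool_backward(fwd$att, par$att, as.numeric(hb$grad_X) / fwd$att$n)
    grad_acts[[d + 1]] <- ab$grad_X
    gatt <- ab$grads
  } else {
    gatt <- NULL
    gdec <- vector("list", d - 1)
    gZ <- hb$grad_X  # gradient wrt final concat [U0, H0-skip]
    W <- params$config$width
    for (l in seq_len(d)) {
      lv <- hier$levels[[l]]
      cache <- fwd$dec[[l]]
      if (l > 1) {
        grad_u <- gZnext * .sigmoid(cache$u)
        gdec[[l - 1]] <- list(W = crossprod(cache$Z, grad_u),
                              b = colSums(grad_u))
        gZ <- grad_u %*% t(par$dec[[l - 1]]$W)
      }
      gU <- gZ[, seq_len(W), drop = FALSE]
      gskip <- gZ[, W + seq_len(W), drop = FALSE]
      grad_acts[[l]] <- gskip
      gZnext <- apply_unpool_t(lv$unpool, gU, cache$n_coarse)
    }
    grad_acts[[d + 1]] <- gZnext
  }
  encb <- .encoder_backward(par, hier, fwd$enc, grad_acts)
  list(lift = encb$glift, levels = encb$glevels, att = gatt, dec = gdec,
       head = hb$grads, grad_X = encb$grad_X)
}

#' Segmentation forward pass
#'
#' Runs the graph U-Net: an encoder of FPS pooling + two CG convolutions per
#' level, a KNN-unpooling decoder with concatenated skip connections, and a
#' two-layer MLP head with softmax, giving a two-class Bernoulli
#' distribution per vertex.
#'
#' @param mesh A `SurfaceMesh` (or a prebuilt `MeshHierarchy`).
#' @param features Vertices x features matrix.
#' @param params `NetworkParams` with `task = "segmentation"`.
#' @return Matrix (vertices x 2) of class probabilities; column 2 is the
#'   binding probability.
#' @export
segmentation_forward <- function(mesh, features, params) {
  stopifnot(params$task == "segmentation")
  hier <- if (inherits(mesh, "MeshHierarchy")) mesh else
    build_hierarchy(mesh, params$config, seed = params$seed)
  .network_forward(params, hier, features)$probs
}

#' Classification forward pass
#'
#' Encoder as in [segmentation_forward()], then global attention pooling and
#' an MLP head with softmax over two classes.
#'
#' @inheritParams segmentation_forward
#' @param params `NetworkParams` with `task = "classification"`.
#' @return Length-2 probability vector; element 2 is the positive-class
#'   probability.
#' @export
classification_forward <- function(mesh, features, params) {
  stopifnot(params$task == "classification")
  hier <- if (inherits(mesh, "MeshHierarchy")) mesh else
    build_hierarchy(mesh, params$config, seed = params$seed)
  as.numeric(.network_forward(params, hier, features)$probs)
}

#' Crystal-graph convolution over a radial graph
#'
#' One gated message-passing update of centroid features (see the file
#' header for the formula). Exposed mainly for testing and reuse; the
#' networks call it internally.
#'
#' @param node_feats Feature matrix of the source nodes.
#' @param graph A `RadialGraph` prepared with edge features (as produced
#'   inside [build_hierarchy()]); `to` must index rows of `centroid_feats`.
#' @param params Conv parameter list (`Wg`, `bg`, `Wf`, `bf`, `a`).
#' @param centroid_feats Features of the centroid nodes; defaults to
#'   `node_feats` rows at the graph centroids.
#' @return Updated centroid feature matrix.
#' @export
cg_convolution <- function(node_feats, graph, params, centroid_feats = NULL) {
  node_feats <- as.matrix(node_feats)
  if (is.null(centroid_feats))
    centroid_feats <- node_feats[graph$centroids, , drop = FALSE]
  if (is.null(graph$IDX)) stop("graph lacks prepared edge features")
  cg_conv_forward(node_feats, as.matrix(centroid_feats), graph, params)$out
}

# ---- checkpoints -----------------------------------------------------------

#' Save network parameters to a JSON checkpoint
#'
#' Writes all tensors (named, with dimensions), the architecture config and
#' the standardization statistics at full double precision.
#'
#' @param params A `NetworkParams` (or `CalibratedModel`).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(params, path) {
  ser <- function(x) {
    if (is.list(x)) lapply(unclass(x), ser)
    else if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
    else x
  }
  obj <- ser(unclass(params))
  obj$.class <- class(params)
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a JSON checkpoint
#' @param path Checkpoint file from [save_checkpoint()].
#' @return The restored object.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  cls <- obj$.class
  obj$.class <- NULL
  de <- function(x) {
    if (is.list(x)) {
      if (!is.null(x$dim) && !is.null(x$data) && length(x) == 2)
        matrix(x$data, x$dim[1], x$dim[2])
      else lapply(x, de)
    } else x
  }
  out <- de(obj)
  if (!is.null(out$config)) class(out$config) <- "LayerConfig"
  class(out) <- cls
  out
}
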