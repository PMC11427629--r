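# Graph primitives and network forward passes: FPS, radial graphs,
# convolution, unpooling, pooling, invariances and oracle equivalence.

test_that("farthest point sampling matches the greedy definition", {
  V <- cbind(0:7, 0, 0)
  expect_equal(farthest_point_sample(V, 0.5, start = 1), c(1, 8, 4, 6))
  expect_equal(fps_exhaustive(V, 0.5, start = 1), c(1, 8, 4, 6))
  # ratio 1 returns everything
  expect_setequal(farthest_point_sample(V, 1), 1:8)
  # coincident pair, ratio 0.5: single point, no crash
  W <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_equal(length(farthest_point_sample(W, 0.5)), 1)
  expect_error(farthest_point_sample(V[0, , drop = FALSE], 0.5), "empty")
})

test_that("FPS and radial graphs match exhaustive oracles on random clouds", {
  for (trial in 1:20) {
    set.seed(trial)
    n <- sample(50:500, 1)
    V <- matrix(runif(3 * n, 0, 10), ncol = 3)
    start <- sample(n, 1)
    expect_identical(farthest_point_sample(V, 0.4, start = start),
                     as.integer(fps_exhaustive(V, 0.4, start = start)))
    cent <- sample(n, max(2, n %/% 8))
    r <- runif(1, 1, 4)
    g <- build_radial_graph(V, cent, r)
    o <- radial_graph_bruteforce(V, cent, r)
    got <- paste(g$from, g$to_vertex)
    want <- paste(o$from, o$to_vertex)
    expect_identical(sort(got), sort(want))
  }
})

test_that("radial graph edge counts at the extremes", {
  set.seed(2)
  V <- matrix(runif(30, 0, 100), ncol = 3)
  expect_equal(length(build_radial_graph(V, 1:10, 1e-3)$from), 0)
  gfull <- build_radial_graph(V, 1:10, 1000)
  expect_equal(as.vector(table(gfull$to)), rep(9L, 10))
})

test_that("CG convolution honours its pooled-statistics contract", {
  # tiny graph: 2 source nodes -> 1 centroid, explicit edge features
  W <- 4
  Xs <- matrix(rnorm(2 * W), 2)
  Xc <- matrix(rnorm(W), 1)
  g <- list(from = c(1L, 2L), to = c(1L, 1L), to_vertex = c(1L, 1L),
            centroids = 1L, radius = 5,
            ef = matrix(0.5, 2, 4), n_cent = 1L, cnt = 2L,
            IDX = matrix(c(1L, 2L), 1))
  mkp <- function(a) {
    set.seed(1)
    list(Wg = matrix(rnorm((2 * W + 4) * W, sd = 0.3), 2 * W + 4),
         bg = rnorm(W), Wf = matrix(rnorm((2 * W + 4) * W, sd = 0.3), 2 * W + 4),
         bf = rnorm(W), a = a)
  }
  # zero aggregation weights -> residual identity
  out0 <- cg_convolution(Xs, g, mkp(c(0, 0, 0, 0)), Xc)
  expect_equal(out0, Xc)
  # single neighbour: min = max = mean message, stdev = 0
  g1 <- g; g1$from <- 1L; g1$to <- 1L; g1$ef <- g$ef[1, , drop = FALSE]
  g1$cnt <- 1L; g1$IDX <- matrix(1L, 1)
  p <- mkp(c(1, 0, 0, 0))
  o_min <- cg_convolution(Xs, g1, p, Xc)
  o_max <- cg_convolution(Xs, g1, mkp(c(0, 1, 0, 0)), Xc)
  o_mean <- cg_convolution(Xs, g1, mkp(c(0, 0, 1, 0)), Xc)
  o_sd <- cg_convolution(Xs, g1, mkp(c(0, 0, 0, 1)), Xc)
  expect_equal(o_min, o_max)
  expect_equal(o_min, o_mean)
  expect_equal(o_sd, Xc)  # population stdev of one message is 0
  # centroid with no neighbours passes through unchanged
  gempty <- g; gempty$from <- integer(0); gempty$to <- integer(0)
  gempty$ef <- g$ef[0, , drop = FALSE]; gempty$cnt <- 0L
  gempty$IDX <- matrix(integer(0) + 1L, 1, 1)
  expect_equal(cg_convolution(Xs, gempty, mkp(c(1, 1, 1, 1)), Xc), Xc)
})

test_that("pooled statistics of opposite messages follow hand evaluation", {
  # engineer two edges whose messages are m and -m is not reachable through
  # the positive filter, so check the statistics layer directly instead
  m <- rbind(c(2, -3), c(-2, 3))
  g <- list(to = c(1L, 1L), n_cent = 1L, cnt = 2L, IDX = matrix(1:2, 1))
  s_mean <- surfbind:::.rowsum_full(m, g$to, 1) / 2
  s_min <- surfbind:::.group_extreme(m, g, "min")
  s_max <- surfbind:::.group_extreme(m, g, "max")
  s_sd <- sqrt(surfbind:::.rowsum_full(m^2, g$to, 1) / 2 - s_mean^2)
  expect_equal(as.numeric(s_mean), c(0, 0))
  expect_equal(as.numeric(s_min), c(-2, -3))
  expect_equal(as.numeric(s_max), c(2, 3))
  expect_equal(as.numeric(s_sd), c(2, 3))  # elementwise |m|
})

test_that("KNN unpooling interpolates by inverse distance", {
  coarse <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0))
  cf <- rbind(c(0), c(4), c(8))
  # coincident fine vertex copies the centroid exactly
  expect_equal(knn_unpool(coarse, cf, matrix(c(3, 0, 0), 1), k = 2)[1, 1], 4)
  # equidistant from all three -> arithmetic mean
  ctr <- matrix(c(1, 1, 0) * 3 / 3, 1)  # not equidistant; use symmetry point
  eq <- matrix(c(1, 1, sqrt(2)) , 1)    # equidistant from the two axis points
  # simple hand case: distances 1 and 3, feats 0 and 4, k = 2 -> 1.0
  c2 <- rbind(c(1, 0, 0), c(-3, 0, 0))
  f2 <- rbind(c(0), c(4))
  expect_equal(knn_unpool(c2, f2, matrix(c(0, 0, 0), 1), k = 2)[1, 1], 1.0)
  # equidistant triple -> mean
  tri <- rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0))
  f3 <- rbind(c(0), c(3), c(9))
  expect_equal(knn_unpool(tri, f3, matrix(c(0, 0, 0), 1), k = 3)[1, 1], 4)
})

test_that("global attention pooling follows its formula", {
  set.seed(3)
  X <- matrix(rnorm(40), 10)
  # f = 0 -> r = 0.5 * colSums(X)
  p0 <- list(w = matrix(0, 4, 1), b = 0)
  expect_equal(global_attention_pool(X, p0), 0.5 * colSums(X))
  # f -> -Inf closes the gate
  pneg <- list(w = matrix(0, 4, 1), b = -1e4)
  expect_lt(max(abs(global_attention_pool(X, pneg))), 1e-10)
  # permutation invariance
  pr <- list(w = matrix(rnorm(4), 4, 1), b = 0.3)
  r1 <- global_attention_pool(X, pr)
  r2 <- global_attention_pool(X[sample(10), ], pr)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("forward passes produce distributions and respect symmetries", {
  it <- tiny_planted(1, seed = 6)[[1]]
  cfg <- test_config()
  ps <- init_network_params(6, cfg, "segmentation", seed = 2,
                            feature_names = colnames(it$X))
  pc <- init_network_params(6, cfg, "classification", seed = 2,
                            feature_names = colnames(it$X))
  pr <- segmentation_forward(it$mesh, it$X, ps)
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-6)
  pcl <- classification_forward(it$mesh, it$X, pc)
  expect_equal(sum(pcl), 1, tolerance = 1e-6)

  # rigid motion: identical outputs within 1e-4
  R <- random_rotation(8)
  m2 <- compute_normals(surface_mesh(
    sweep(it$mesh$V %*% t(R), 2, -c(3, -5, 11)), it$mesh$F),
    fix_orientation = FALSE)
  pr2 <- segmentation_forward(m2, it$X, ps)
  expect_lt(max(abs(pr2 - pr)), 1e-4)
  pcl2 <- classification_forward(m2, it$X, pc)
  expect_lt(max(abs(pcl2 - pcl)), 1e-4)

  # vertex permutation: identical within 1e-6 (classification), rows permuted
  # (segmentation)
  set.seed(10)
  perm <- sample(nrow(it$mesh$V))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  mp <- compute_normals(surface_mesh(it$mesh$V[perm, ],
                                     matrix(inv[it$mesh$F], ncol = 3)),
                        fix_orientation = FALSE)
  Xp <- it$X[perm, ]
  pclp <- classification_forward(mp, Xp, pc)
  expect_lt(max(abs(pclp - pcl)), 1e-6)
  prp <- segmentation_forward(mp, Xp, ps)
  expect_lt(max(abs(prp - pr[perm, ])), 1e-6)

  # feature-name mismatch names the columns
  Xbad <- it$X; colnames(Xbad) <- paste0("Q", 1:6)
  expect_error(segmentation_forward(it$mesh, Xbad, ps), "feature columns")
})

test_that("gradients flow to the input layer through skip connections", {
  it <- tiny_planted(1, seed = 12)[[1]]
  cfg <- test_config()
  for (task in c("segmentation", "classification")) {
    p <- init_network_params(6, cfg, task, seed = 5,
                             feature_names = colnames(it$X))
    hier <- build_hierarchy(it$mesh, cfg, seed = p$seed)
    item <- list(hier = hier, X = it$X,
                 y = if (task == "classification") 1 else it$y)
    lg <- surfbind:::.item_loss_grad(p, item)
    expect_gt(sqrt(sum(lg$grads$lift$W^2)), 0)
  }
})

test_that("analytic gradients match numerical differentiation", {
  it <- tiny_planted(1, seed = 13)[[1]]
  cfg <- layer_config(width = 5, head_hidden = 4, radii = c(6, 9, 12))
  for (task in c("segmentation", "classification")) {
    p <- init_network_params(6, cfg, task, seed = 7,
                             feature_names = colnames(it$X))
    hier <- build_hierarchy(it$mesh, cfg, seed = p$seed)
    item <- list(hier = hier, X = it$X,
                 y = if (task == "classification") 1 else it$y)
    lg <- surfbind:::.item_loss_grad(p, item)
    ga <- unlist(lg$grads)
    th <- unlist(p$par)
    set.seed(20)
    idx <- sample(length(th), 25)
    eps <- 1e-5
    gn <- vapply(idx, function(i) {
      pp <- p; tt <- th
      tt[i] <- tt[i] + eps
      pp$par <- utils::relist(tt, p$par)
      l1 <- surfbind:::.item_loss_grad(pp, item, want_grad = FALSE)$loss
      tt[i] <- th[i] - eps
      pp$par <- utils::relist(tt, p$par)
      l2 <- surfbind:::.item_loss_grad(pp, item, want_grad = FALSE)$loss
      (l1 - l2) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(gn - ga[idx]) / pmax(abs(gn), 1e-4)), 1e-4)
  }
})

test_that("checkpoints round-trip bit-stably", {
  cfg <- test_config()
  p <- init_network_params(6, cfg, "classification", seed = 4,
                           feature_names = paste0("S", 1:6))
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(p, path)
  q <- load_checkpoint(path)
  expect_identical(unlist(q$par), unlist(p$par))
  expect_equal(q$feature_names, p$feature_names)
  expect_equal(q$task, p$task)
  it <- tiny_planted(1, seed = 3)[[1]]
  expect_identical(classification_forward(it$mesh, it$X, q),
                   classification_forward(it$mesh, it$X, p))
})
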