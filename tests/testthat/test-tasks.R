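test_that("1-NN picks the minimum-distance label with lowest-index ties", {
  cross <- rbind(c(0, 5), c(3, 1), c(1, 1))
  rownames(cross) <- c("t1", "t2", "t3")
  pred <- knn1_classify(cross, c("A", "B"))
  expect_equal(pred$pred_label, c("A", "B", "A"))
  pred2 <- knn1_classify(rbind(c(3, 1, 2)), c("A", "B", "A"))
  expect_equal(pred2$pred_label, "B")
  expect_error(knn1_classify(matrix(numeric(0), 1, 0), character(0)),
               class = "gwtau_input_error")
})

test_that("hierarchical clustering recovers separated blocks", {
  ids <- paste0("x", 1:6)
  D <- matrix(10, 6, 6, dimnames = list(ids, ids))
  D[1:3, 1:3] <- 0.1; D[4:6, 4:6] <- 0.1
  diag(D) <- 0
  dm <- dist_matrix(D, metric = "gwtau")
  for (linkage in c("single", "complete")) {
    cl <- hierarchical_cluster(dm, k = 2, linkage = linkage)
    expect_equal(length(unique(cl$cluster[1:3])), 1L)
    expect_equal(length(unique(cl$cluster[4:6])), 1L)
    expect_false(cl$cluster[1] == cl$cluster[4])
  }
  expect_equal(dplyr::n_distinct(hierarchical_cluster(dm, k = 6)$cluster), 6L)
  expect_equal(dplyr::n_distinct(hierarchical_cluster(dm, k = 1)$cluster), 1L)
  expect_error(hierarchical_cluster(dm, k = 0), class = "gwtau_input_error")
})

test_that("k-medoids recovers separated blocks for any seed", {
  ids <- paste0("x", 1:6)
  D <- matrix(10, 6, 6, dimnames = list(ids, ids))
  D[1:3, 1:3] <- 0; D[4:6, 4:6] <- 0
  diag(D) <- 0
  dm <- dist_matrix(D, metric = "gwtau")
  for (seed in c(0, 1, 42)) {
    cl <- kmedoids_cluster(dm, k = 2, seed = seed)
    expect_equal(clustering_quality(cl$cluster,
                                    rep(c("a", "b"), each = 3))$error_count, 0L)
  }
  expect_equal(dplyr::n_distinct(kmedoids_cluster(dm, k = 6)$cluster), 6L)
})

test_that("classical MDS reproduces Euclidean-realizable distances", {
  pts <- c(0, 1, 3)
  D <- abs(outer(pts, pts, "-"))
  dimnames(D) <- list(paste0("p", 1:3), paste0("p", 1:3))
  emb <- mds_embed(dist_matrix(D, metric = "euclidean"), dim = 2)
  X <- as.matrix(emb$coords[, c("mds_1", "mds_2")])
  recon <- as.matrix(stats::dist(X))
  expect_lt(max(abs(recon - D)), 1e-9)
  # zero matrix embeds at the origin
  Z <- matrix(0, 3, 3, dimnames = list(paste0("p", 1:3), paste0("p", 1:3)))
  embz <- mds_embed(dist_matrix(Z), dim = 2)
  expect_lt(max(abs(as.matrix(embz$coords[, -1]))), 1e-12)
  expect_error(mds_embed(dist_matrix(Z), dim = 3), class = "gwtau_input_error")
})

test_that("k-means on the embedding separates tight distant blobs", {
  set.seed(2)
  coords <- tibble::tibble(
    trajectory_id = paste0("x", 1:10),
    mds_1 = c(rnorm(5, 0, 0.01), rnorm(5, 10, 0.01)),
    mds_2 = c(rnorm(5, 0, 0.01), rnorm(5, 0, 0.01)))
  emb <- structure(list(coords = coords, eigenvalues = rep(NA_real_, 10),
                        metric = "gwtau", labels = NULL, flavor = "classical"),
                   class = "trj_embedding")
  cl <- kmeans_on_embedding(emb, k = 2, seed = 0)
  expect_equal(clustering_quality(cl$cluster,
                                  rep(1:2, each = 5))$error_count, 0L)
  expect_equal(dplyr::n_distinct(kmeans_on_embedding(emb, k = 1,
                                                     seed = 0)$cluster), 1L)
  # determinism: same seed, same labels
  expect_identical(cl, kmeans_on_embedding(emb, k = 2, seed = 0))
})

test_that("clustering quality counts permutation-minimal mistakes and ARI", {
  truth <- rep(c("a", "b"), each = 10)
  q <- clustering_quality(truth, truth)
  expect_equal(q$error_count, 0L); expect_equal(q$ari, 1)
  # constant prediction on two balanced classes: best matching leaves 10
  q2 <- clustering_quality(rep(1, 20), truth)
  expect_equal(q2$error_count, 10L)
  # label names are arbitrary
  q3 <- clustering_quality(rep(c("b", "a"), each = 10), truth)
  expect_equal(q3$error_count, 0L); expect_equal(q3$ari, 1)
  expect_error(clustering_quality(1:3, 1:4), class = "gwtau_input_error")
})

test_that("mean trajectory averages pointwise and damps phase shifts", {
  t <- seq(0, 2 * pi, length.out = 50)
  d <- trajectory_tbl(list(a = matrix(sin(t), ncol = 1),
                           b = matrix(sin(t), ncol = 1)),
                      times = list(t, t))
  m <- mean_trajectory(d)
  expect_equal(m$dim_1, sin(t))
  d2 <- trajectory_tbl(list(a = matrix(sin(t), ncol = 1),
                            b = matrix(-sin(t), ncol = 1)),
                       times = list(t, t))
  expect_equal(max(abs(mean_trajectory(d2)$dim_1)), 0)
  # sin(t) and sin(t + pi/2) average to a sqrt(2)/2-amplitude sinusoid
  d3 <- trajectory_tbl(list(a = matrix(sin(t), ncol = 1),
                            b = matrix(sin(t + pi / 2), ncol = 1)),
                       times = list(t, t))
  m3 <- mean_trajectory(d3)
  expect_equal(m3$dim_1, sqrt(2) / 2 * sin(t + pi / 4), tolerance = 1e-12)
  # mismatched grids rejected
  d4 <- trajectory_tbl(list(a = matrix(sin(t), ncol = 1),
                            b = matrix(sin(t), ncol = 1)),
                       times = list(t, t + 1))
  expect_error(mean_trajectory(d4), class = "gwtau_input_error")
})

test_that("averaging assessment places a group member in its own group", {
  set.seed(14)
  t <- seq(0, 1, length.out = 30)
  flat <- lapply(1:4, function(i) cbind(t, 0.01 * rnorm(30)))
  steep <- lapply(1:4, function(i) cbind(t, 5 * t + 0.01 * rnorm(30)))
  names(flat) <- paste0("flat_", 1:4); names(steep) <- paste0("steep_", 1:4)
  d <- trajectory_tbl(c(flat, steep), times = rep(list(t), 8),
                      labels = rep(c("flat", "steep"), each = 4))
  avg <- trajectory_tbl(list(member_copy = flat[[1]]), times = list(t))
  res <- averaging_assessment(d, avg)
  rep_row <- dplyr::filter(tidy(res), .data$nearest)
  expect_equal(rep_row$group, "flat")
  expect_error(averaging_assessment(d, dplyr::mutate(
    trajectory_tbl(list(flat_1 = flat[[1]]), times = list(t)))),
    class = "gwtau_input_error")
})
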