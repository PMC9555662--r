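test_that("spearman_per_marker identities and rank oracle", {
  set.seed(1)
  truth <- matrix(runif(6 * 3), 6, 3,
                  dimnames = list(paste0("c", 1:6), c("A", "B", "C")))
  sp <- spearman_per_marker(truth, truth)
  expect_equal(unname(sp$per_marker), rep(1, 3))
  expect_equal(sp$var_all, 0)
  sp_neg <- spearman_per_marker(truth, -truth)
  expect_equal(unname(sp_neg$per_marker), rep(-1, 3))
  # 6-cell toy vs a hand rank computation
  pred <- truth
  pred[, "A"] <- c(0.2, 0.9, 0.1, 0.5, 0.4, 0.8)
  sp2 <- spearman_per_marker(truth, pred, withheld = "A")
  expect_equal(sp2$per_marker[["A"]],
               cor(rank(truth[, "A"]), rank(pred[, "A"])))
  expect_equal(sp2$mean_withheld, sp2$per_marker[["A"]])
  # constant column warns and records 0
  pred[, "B"] <- 0.5
  expect_warning(sp3 <- spearman_per_marker(truth, pred), "constant")
  expect_equal(sp3$per_marker[["B"]], 0)
})

test_that("ssim identities, symmetry and the constant-image closed form", {
  set.seed(2)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_equal(ssim(x, x), 1)
  y <- matrix(runif(32 * 32), 32, 32)
  expect_equal(ssim(x, y), ssim(y, x))
  # constant images: variances vanish, closed form remains
  a <- 0.3; b <- 0.7
  C1 <- 0.01^2
  expected <- (2 * a * b + C1) / (a^2 + b^2 + C1)
  expect_equal(ssim(matrix(a, 20, 20), matrix(b, 20, 20)), expected)
  # decreasing in noise amplitude (fixed seed ladder)
  set.seed(3)
  eps <- matrix(rnorm(32 * 32), 32, 32)
  vals <- vapply(c(0.02, 0.05, 0.1, 0.2), function(s)
    ssim(x, pmin(pmax(x + s * eps, 0), 1)), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_warning(ssim(matrix(a, 6, 6), matrix(b, 6, 6)), "window")
})

test_that("nmi matches the brute-force contingency oracle on small labelings", {
  U <- c(0, 0, 1, 1)
  expect_equal(nmi(U, U), 1)
  expect_equal(nmi(U, c(0, 1, 0, 1)), 0)
  expect_equal(nmi(U, c(0, 0, 0, 1)), oracle_nmi(U, c(0, 0, 0, 1)))
  # exhaustive: all pairs of labelings of 5 items over 3 labels
  labelings <- as.matrix(expand.grid(rep(list(0:2), 5)))
  set.seed(4)
  pick <- sample(nrow(labelings), 40)
  for (i in pick) for (j in sample(nrow(labelings), 3)) {
    u <- labelings[i, ]; v <- labelings[j, ]
    expect_equal(suppressWarnings(nmi(u, v)),
                 max(0, min(1, oracle_nmi(u, v))), tolerance = 1e-12)
  }
  # symmetry
  expect_equal(nmi(U, c(0, 0, 0, 1)), nmi(c(0, 0, 0, 1), U))
  # degenerate constant labeling -> 0 with warning
  expect_warning(z <- nmi(c(1, 1, 1), c(0, 1, 2)), "constant")
  expect_equal(z, 0)
  # outliers excluded pairwise
  expect_equal(nmi(c(-1, 0, 0, 1, 1), c(5, 0, 0, 1, -1)),
               nmi(c(0, 0, 1), c(0, 0, 1)))
})

test_that("kmeans clustering separates blobs and is seeded", {
  set.seed(5)
  blob <- function(cx, cy, n) cbind(rnorm(n, cx, 0.05), rnorm(n, cy, 0.05))
  tab <- rbind(blob(0, 0, 40), blob(1, 0, 40), blob(0, 1, 40))
  dimnames(tab) <- list(paste0("c", 1:120), c("M1", "M2"))
  truth_lab <- rep(0:2, each = 40)
  cl <- kmeans_cluster(tab, 3, seed = 7)
  expect_equal(nmi(cl$labels, truth_lab), 1)
  expect_identical(cl$labels, kmeans_cluster(tab, 3, seed = 7)$labels)
  expect_true(all(cl$labels %in% 0:2))
  expect_error(kmeans_cluster(tab, 200), "exceeds")
})

test_that("silhouette elbow picks k = 3 on 3-blob data and matches a direct silhouette", {
  set.seed(6)
  blob <- function(cx, cy, n) cbind(rnorm(n, cx, 0.06), rnorm(n, cy, 0.06))
  tab <- rbind(blob(0, 0, 30), blob(2, 0, 30), blob(0, 2, 30))
  dimnames(tab) <- list(paste0("c", 1:90), c("M1", "M2"))
  k <- choose_k_silhouette(tab, k_range = 2:8, seed = 3)
  expect_equal(as.integer(k), 3)
  # direct silhouette formula oracle at k = 3 on the z-scored table
  z <- scale(tab)
  km <- panelreduce::kmeans_cluster(tab, 3, seed = 3)
  lab <- km$labels
  d <- as.matrix(dist(z))
  sil <- vapply(seq_len(nrow(z)), function(i) {
    a <- mean(d[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- min(vapply(setdiff(unique(lab), lab[i]), function(g)
      mean(d[i, lab == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(unname(attr(k, "silhouette")["3"]), mean(sil),
               tolerance = 1e-10)
})

test_that("graph clustering recovers separable blobs and flags small communities", {
  set.seed(7)
  blob <- function(cx, cy, n) cbind(rnorm(n, cx, 0.05), rnorm(n, cy, 0.05))
  tab <- rbind(blob(0, 0, 60), blob(2, 0, 60), blob(0, 2, 60))
  dimnames(tab) <- list(paste0("c", 1:180), c("M1", "M2"))
  truth_lab <- rep(0:2, each = 60)
  cl <- graph_cluster(tab, n_neighbors = 15, min_cluster_size = 50, seed = 2)
  expect_equal(nmi(cl$labels, truth_lab), 1)
  expect_setequal(unique(cl$labels), 0:2)
  # min size above every community: everything an outlier, with warning
  expect_warning(cl2 <- graph_cluster(tab, n_neighbors = 15,
                                      min_cluster_size = 1000, seed = 2),
                 "outlier")
  expect_true(all(cl2$labels == -1))
  expect_error(graph_cluster(tab, n_neighbors = 500), "n_neighbors")
})

test_that("cluster matching recovers permutations and agrees with brute force", {
  set.seed(8)
  U <- sample(0:3, 200, replace = TRUE)
  perm <- c(2L, 3L, 0L, 1L)
  V <- perm[U + 1]
  mp <- match_clusters(U, V)
  expect_identical(unname(mp[as.character(0:3)]), perm)
  # invariance to renumbering
  mp2 <- match_clusters(U + 10L, V)
  expect_identical(unname(mp2[as.character(10:13)]), perm)
  # 3x3 contingency vs brute force over all 6 permutations
  U3 <- c(rep(0, 30), rep(1, 30), rep(2, 30))
  V3 <- U3
  swap <- sample(90, 25)
  V3[swap] <- (V3[swap] + 1) %% 3
  tab <- table(U3, V3)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  best <- NULL; best_tot <- -1
  for (p in perms) {
    tot <- sum(vapply(1:3, function(i) tab[i, p[i]], numeric(1)))
    if (tot > best_tot) { best_tot <- tot; best <- p }
  }
  mp3 <- match_clusters(U3, V3)
  expect_identical(unname(mp3[rownames(tab)]),
                   as.integer(colnames(tab)[best]))
  # unequal cluster counts: surplus labels left unmatched
  U4 <- c(0, 0, 1, 1, 2, 2)
  V4 <- c(0, 0, 1, 1, 1, 1)
  mp4 <- match_clusters(U4, V4)
  expect_lte(length(mp4), 2)
})

test_that("shuffled baseline sits near chance and below genuine association", {
  set.seed(9)
  U <- rep(0:9, each = 500)
  V <- U
  sb <- shuffled_baseline(U, V, seed = 1, reps = 10)
  expect_lt(sb$mean, 0.01)
  expect_lt(sb$mean, nmi(U, V))
  expect_error(shuffled_baseline(U, V, reps = 0), "reps")
})

test_that("embedding is deterministic with one 2-D row per cell", {
  set.seed(10)
  tab <- matrix(runif(50 * 4), 50, 4,
                dimnames = list(paste0("c", 1:50), paste0("M", 1:4)))
  e1 <- embed_cells(tab)
  expect_identical(dim(e1), c(50L, 2L))
  expect_identical(e1, embed_cells(tab))
  expect_error(embed_cells(tab[1:5, ]), "10 cells")
  f <- file.path(withr::local_tempdir(), "umap.png")
  plot_embedding(e1, c(rep(0:1, 24), -1, -1), file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("evaluation of baseline predictions equals the partner correlation exactly", {
  spec <- synthetic_spec(n_cells = 300, seed = 17)
  ds <- generate_dataset(spec, render = FALSE)
  cm <- correlation_matrix(ds$truth)
  sel <- select_panel_corr(cm, 5, required = "Hoechst", mode = "exhaustive")
  bs <- baseline_substitute(ds$truth, cm, sel$panel)
  rep_ <- evaluate_panel(ds$truth, bs$predicted, sel)
  for (w in sel$withheld)
    expect_equal(rep_$per_marker_spearman[[w]], cm[w, bs$partners[[w]]],
                 tolerance = 1e-12)
})
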