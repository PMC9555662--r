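#' Per-marker Spearman correlation between truth and prediction
#'
#' Rank correlation per marker column, plus means and across-marker variances
#' reported separately for the withheld markers and for all markers —
#' the variance indicates whether prediction quality is consistent across
#' stains rather than concentrated in a few.
#'
#' @param truth,pred cells x markers matrices over the same cells and
#'   markers.
#' @param withheld optional character vector of withheld marker names.
#' @return list: `per_marker` (named vector; constant columns give 0 with a
#'   warning), `mean_all`, `var_all`, and if `withheld` is given,
#'   `mean_withheld`, `var_withheld`.
#' @export
spearman_per_marker <- function(truth, pred, withheld = NULL) {
  stopifnot(identical(dim(truth), dim(pred)),
            identical(colnames(truth), colnames(pred)))
  rho <- vapply(seq_len(ncol(truth)), function(j) {
    if (max(truth[, j]) == min(truth[, j]) ||
        max(pred[, j]) == min(pred[, j])) {
      warning("constant column '", colnames(truth)[j],
              "'; Spearman recorded as 0")
      return(0)
    }
    cor(truth[, j], pred[, j], method = "spearman")
  }, numeric(1))
  names(rho) <- colnames(truth)
  out <- list(per_marker = rho, mean_all = mean(rho), var_all = var(rho))
  if (!is.null(withheld)) {
    stopifnot(all(withheld %in% colnames(truth)))
    out$mean_withheld <- mean(rho[withheld])
    out$var_withheld <- if (length(withheld) > 1) var(rho[withheld]) else 0
  }
  out
}

# 2-D valid convolution by kernel-element accumulation (kernels are small)
conv_valid <- function(m, k) {
  kr <- nrow(k); kc <- ncol(k)
  or_ <- nrow(m) - kr + 1; oc <- ncol(m) - kc + 1
  out <- matrix(0, or_, oc)
  for (i in seq_len(kr)) for (j in seq_len(kc))
    out <- out + k[i, j] * m[i:(i + or_ - 1), j:(j + oc - 1)]
  out
}

gaussian_kernel <- function(size, sigma) {
  h <- (size - 1) / 2
  g <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Structural similarity (SSIM) between two images
#'
#' Windowed SSIM with the standard Gaussian window (11 x 11, sigma 1.5) and
#' stability constants `C1 = (0.01 * data_range)^2`,
#' `C2 = (0.03 * data_range)^2`; the reported value is the mean of the local
#' SSIM map over the valid (fully-windowed) region. If the window exceeds the
#' image, it is shrunk to the largest odd size that fits, with a warning.
#'
#' @param x,y numeric matrices of identical shape, values within
#'   `data_range`.
#' @param data_range dynamic range of the data (1 for \[0,1\] images).
#' @param window_size odd window side.
#' @param sigma Gaussian window sd.
#' @return scalar SSIM in \[-1, 1\]; exactly 1 when `x` and `y` are
#'   identical.
#' @export
ssim <- function(x, y, data_range = 1, window_size = 11, sigma = 1.5) {
  stopifnot(identical(dim(x), dim(y)))
  mn <- min(dim(x))
  if (window_size > mn) {
    window_size <- if (mn %% 2 == 1) mn else mn - 1
    warning("window larger than image; reduced to ", window_size)
  }
  w <- gaussian_kernel(window_size, sigma)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mu_x <- conv_valid(x, w); mu_y <- conv_valid(y, w)
  xx <- conv_valid(x * x, w); yy <- conv_valid(y * y, w)
  xy <- conv_valid(x * y, w)
  vx <- xx - mu_x^2; vy <- yy - mu_y^2; cxy <- xy - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + C1) * (2 * cxy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Per-channel SSIM between paired single-cell images
#'
#' @param cells_true,cells_pred lists of `single_cell_image` over the same
#'   cells; channels are matched by the true cells' marker names.
#' @param data_range dynamic range (1 for \[0,1\] images).
#' @return list: `per_channel` (named mean SSIM per marker across cells) and
#'   `mean` (mean over cells and channels).
#' @export
ssim_per_channel <- function(cells_true, cells_pred, data_range = 1) {
  stopifnot(length(cells_true) == length(cells_pred),
            length(cells_true) > 0)
  mk <- cells_true[[1]]$marker_names
  idx_pred <- match(mk, cells_pred[[1]]$marker_names)
  if (anyNA(idx_pred)) stop("predicted cells lack channels of the true cells")
  acc <- matrix(0, length(cells_true), length(mk),
                dimnames = list(NULL, mk))
  for (i in seq_along(cells_true))
    for (j in seq_along(mk))
      acc[i, j] <- ssim(cells_true[[i]]$pixels[j, , ],
                        cells_pred[[i]]$pixels[idx_pred[j], , ],
                        data_range = data_range)
  list(per_channel = colMeans(acc), mean = mean(acc))
}

#' Normalized mutual information between two labelings
#'
#' `NMI(U, V) = MI(U, V) / mean(H(U), H(V))` with natural logarithms (the
#' value is base-invariant). Cells labeled `-1` (outliers) in either vector
#' are excluded pairwise before computation. If either remaining labeling is
#' constant (zero entropy) the value is 0, with a warning.
#'
#' @param U,V integer label vectors of equal length.
#' @return scalar in \[0,1\]; 1 when the labelings are identical up to
#'   renaming (and nonconstant).
#' @export
nmi <- function(U, V) {
  stopifnot(length(U) == length(V), length(U) >= 1)
  keep <- U != -1 & V != -1
  U <- U[keep]; V <- V[keep]
  if (!length(U)) { warning("no non-outlier cells; NMI undefined, returning 0"); return(0) }
  tab <- table(U, V)
  n <- sum(tab)
  pu <- rowSums(tab) / n
  pv <- colSums(tab) / n
  hu <- -sum(pu[pu > 0] * log(pu[pu > 0]))
  hv <- -sum(pv[pv > 0] * log(pv[pv > 0]))
  if (hu == 0 || hv == 0) {
    warning("constant labeling (zero entropy); NMI recorded as 0")
    return(0)
  }
  p <- tab / n
  mi <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0)
      mi <- mi + p[i, j] * log(p[i, j] / (pu[i] * pv[j]))
  max(0, min(1, mi / mean(c(hu, hv))))
}

zscore_cols <- function(table) {
  s <- apply(table, 2, sd)
  s[s == 0] <- 1
  scale(table, center = TRUE, scale = s)
}

#' k-means clustering of an intensity table
#'
#' Seeded k-means on per-marker z-scored mean intensities. The same
#' standardization is applied to ground-truth and predicted tables so cluster
#' comparisons are fair.
#'
#' @param table cells x markers matrix.
#' @param k number of clusters (<= cells).
#' @param seed integer seed.
#' @param nstart k-means restarts.
#' @return object of class `cluster_assignment`: `labels` (0-based integers),
#'   `method = "kmeans"`, `params`.
#' @export
kmeans_cluster <- function(table, k, seed = 1, nstart = 10) {
  if (k > nrow(table)) stop("k exceeds the number of cells")
  z <- zscore_cols(table)
  km <- with_local_seed(seed, kmeans(z, centers = k, nstart = nstart,
                                     iter.max = 100))
  structure(list(labels = as.integer(km$cluster) - 1L, method = "kmeans",
                 params = list(k = k, seed = seed)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  tb <- table(x$labels)
  cat("cluster_assignment (", x$method, "): ",
      sum(names(tb) != "-1"), " clusters, ",
      sum(x$labels == -1), " outliers\n", sep = "")
  invisible(x)
}

#' Choose k by the elbow of the silhouette-vs-k curve
#'
#' Computes the mean silhouette width of seeded k-means for each `k` in
#' `k_range` and returns the elbow, located automatically as the `k` with the
#' maximum second difference (greatest downward curvature) of the curve; ties
#' go to the smaller `k`.
#'
#' @param table cells x markers matrix.
#' @param k_range integer vector of candidate k (length >= 3 for a proper
#'   elbow; otherwise the silhouette maximum is returned).
#' @param seed integer seed.
#' @return chosen integer k, with the silhouette curve as attribute
#'   `"silhouette"`.
#' @export
choose_k_silhouette <- function(table, k_range = 2:8, seed = 1) {
  z <- zscore_cols(table)
  d <- stats::dist(z)
  sil <- vapply(k_range, function(k) {
    km <- with_local_seed(seed, kmeans(z, centers = k, nstart = 10,
                                       iter.max = 100))
    mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
  }, numeric(1))
  if (length(k_range) < 3) {
    k <- k_range[which.max(sil)]
  } else {
    inner <- 2:(length(k_range) - 1)
    curv <- 2 * sil[inner] - sil[inner - 1] - sil[inner + 1]
    k <- k_range[inner][which.max(curv)]   # which.max: ties -> smaller k
  }
  structure(k, silhouette = stats::setNames(sil, k_range))
}

#' kNN-graph community clustering (PhenoGraph-style)
#'
#' Builds a k-nearest-neighbour graph on per-marker z-scored intensities and
#' partitions it with Louvain community detection; communities smaller than
#' `min_cluster_size` are relabeled `-1` (outliers), which downstream
#' [nmi()] excludes. The two parameters mirror the PhenoGraph settings used
#' for large datasets (500 neighbours, minimum size 2000) and should be
#' scaled down proportionally for small runs. Optional Jaccard edge weighting
#' reproduces PhenoGraph's shared-neighbour weights.
#'
#' @param table cells x markers matrix; must have more cells than
#'   `n_neighbors`.
#' @param n_neighbors neighbours per cell.
#' @param min_cluster_size communities below this size become outliers.
#' @param seed integer seed (Louvain is randomized).
#' @param weighting `"none"` or `"jaccard"`.
#' @return a `cluster_assignment` with `method = "graph"`; non-outlier labels
#'   are contiguous from 0, ordered by decreasing cluster size.
#' @export
graph_cluster <- function(table, n_neighbors = 500, min_cluster_size = 2000,
                          seed = 1, weighting = c("none", "jaccard")) {
  weighting <- match.arg(weighting)
  n <- nrow(table)
  if (n <= n_neighbors)
    stop("cells <= n_neighbors; lower n_neighbors for this dataset")
  z <- zscore_cols(table)
  d <- as.matrix(stats::dist(z))
  nn <- t(apply(d, 1, function(r) order(r)[2:(n_neighbors + 1)]))
  edges <- cbind(rep(seq_len(n), each = n_neighbors), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  if (weighting == "jaccard") {
    el <- igraph::as_edgelist(g)
    nbr <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
    wts <- vapply(seq_len(nrow(el)), function(e) {
      a <- nbr[[el[e, 1]]]; b <- nbr[[el[e, 2]]]
      length(intersect(a, b)) / length(union(a, b))
    }, numeric(1))
    igraph::E(g)$weight <- wts
  }
  comm <- with_local_seed(seed, igraph::cluster_louvain(g))
  memb <- igraph::membership(comm)
  sizes <- table(memb)
  keep <- names(sizes)[sizes >= min_cluster_size]
  if (!length(keep))
    warning("all communities below min_cluster_size; every cell is an outlier")
  labels <- rep(-1L, n)
  keep <- keep[order(-sizes[keep])]
  for (i in seq_along(keep))
    labels[memb == as.integer(keep[i])] <- i - 1L
  structure(list(labels = labels, method = "graph",
                 params = list(n_neighbors = n_neighbors,
                               min_cluster_size = min_cluster_size,
                               seed = seed, weighting = weighting)),
            class = "cluster_assignment")
}

# Hungarian algorithm (Jonker-Volgenant style shortest augmenting paths)
# for square min-cost assignment; returns col assigned to each row
hungarian_solve <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0
      for (j in 2:(n + 1)) if (!used[j]) {
        cur <- cost[i0, j - 1] - u[i0 + 0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1) break
    }
  }
  ans <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) ans[p[j]] <- j - 1
  ans
}

#' Match cluster labels between two labelings
#'
#' Optimal one-to-one pairing of `U` clusters to `V` clusters maximizing the
#' total number of shared cells on the contingency table (Hungarian
#' algorithm). When the two labelings have different cluster counts, surplus
#' labels are left unmatched rather than forced into a pairing. Outliers
#' (`-1`) are excluded. The mapping is invariant to renumbering of either
#' side.
#'
#' @param U,V integer label vectors of equal length.
#' @return named integer vector: for each `U` label (names), the matched `V`
#'   label; unmatched `U` labels are absent.
#' @export
match_clusters <- function(U, V) {
  stopifnot(length(U) == length(V))
  keep <- U != -1 & V != -1
  tab <- table(U[keep], V[keep])
  ru <- rownames(tab); cv <- colnames(tab)
  n <- max(dim(tab))
  cost <- matrix(0, n, n)   # pad with zero overlap
  cost[seq_along(ru), seq_along(cv)] <- -tab   # maximize overlap
  assign_col <- hungarian_solve(cost)
  out <- integer(0)
  for (i in seq_along(ru)) {
    j <- assign_col[i]
    if (j <= length(cv) && tab[i, j] > 0)
      out[ru[i]] <- as.integer(cv[j])
  }
  out
}

#' Shuffled-label NMI baseline
#'
#' Mean NMI between `V` and `reps` seeded random permutations of `U`; the
#' chance level against which observed cluster-overlap NMI is judged.
#'
#' @param U,V integer label vectors.
#' @param seed integer seed.
#' @param reps number of permutations (>= 1).
#' @return list: `mean`, `values`.
#' @export
shuffled_baseline <- function(U, V, seed = 1, reps = 20) {
  if (reps < 1) stop("reps must be >= 1")
  vals <- with_local_seed(seed, vapply(seq_len(reps), function(r)
    suppressWarnings(nmi(sample(U), V)), numeric(1)))
  list(mean = mean(vals), values = vals)
}

#' Deterministic 2-D embedding of an intensity table
#'
#' Principal-component projection of the z-scored table onto its first two
#' axes, with a fixed sign convention (the largest-magnitude loading of each
#' axis is positive) so the output is fully deterministic. Intended for
#' visualizing cluster structure.
#'
#' @param table cells x markers matrix (>= 10 cells).
#' @param seed accepted for interface uniformity; the embedding is
#'   deterministic and ignores it.
#' @return cells x 2 matrix of coordinates.
#' @export
embed_cells <- function(table, seed = NULL) {
  if (nrow(table) < 10) stop("need at least 10 cells to embed")
  pc <- prcomp(zscore_cols(table), rank. = 2)
  rot <- pc$rotation
  for (j in 1:2)
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  coords <- pc$x[, 1:2, drop = FALSE]
  colnames(coords) <- c("dim1", "dim2")
  coords
}

#' Plot a 2-D embedding colored by cluster labels
#'
#' Outliers (`-1`) are drawn grey.
#'
#' @param coords cells x 2 coordinates from [embed_cells()].
#' @param labels integer cluster labels (`-1` = outlier).
#' @param file optional PNG path; if given, the plot is written there.
#' @param main plot title.
#' @return invisibly, `file` (or `NULL` if plotted to the active device).
#' @export
plot_embedding <- function(coords, labels, file = NULL,
                           main = "cell embedding") {
  stopifnot(nrow(coords) == length(labels))
  if (!is.null(file)) { png(file, width = 700, height = 700); on.exit(dev.off()) }
  lev <- sort(unique(labels[labels != -1]))
  pal <- hcl.colors(max(3, length(lev)), "Dark 3")
  col <- rep("grey70", length(labels))
  for (i in seq_along(lev)) col[labels == lev[i]] <- pal[i]
  plot(coords, col = col, pch = 16, cex = 0.5, main = main,
       xlab = "dim 1", ylab = "dim 2")
  invisible(file)
}

#' Full evaluation report for a reduced panel
#'
#' Bundles the retention metrics for one reduced panel: per-marker Spearman
#' (split into withheld / all markers), per-channel SSIM if image pairs are
#' supplied, and clustering concordance (NMI of k-means labels on the
#' predicted table vs the truth table, with a shuffled-label baseline and
#' matched cluster labels).
#'
#' @param truth,pred cells x markers intensity matrices (same cells/markers).
#' @param panel a `reduced_panel` or character vector of included markers.
#' @param cells_true,cells_pred optional paired image lists for SSIM.
#' @param kmeans_k clusters for k-means (`NULL` skips clustering;
#'   `"auto"` chooses k by [choose_k_silhouette()]).
#' @param graph_params optional list(n_neighbors, min_cluster_size) to add
#'   graph-based clustering NMI.
#' @param seed integer seed for clustering and the shuffled baseline.
#' @param shuffle_reps permutations for the baseline.
#' @return object of class `evaluation_report`.
#' @export
evaluate_panel <- function(truth, pred, panel, cells_true = NULL,
                           cells_pred = NULL, kmeans_k = NULL,
                           graph_params = NULL, seed = 1,
                           shuffle_reps = 20) {
  panel_mk <- if (inherits(panel, "reduced_panel")) panel$panel else panel
  withheld <- setdiff(colnames(truth), panel_mk)
  sp <- spearman_per_marker(truth, pred, withheld = withheld)
  rep_ <- list(panel = panel_mk, withheld = withheld,
               per_marker_spearman = sp$per_marker,
               mean_withheld = sp$mean_withheld, mean_all = sp$mean_all,
               variance_withheld = sp$var_withheld,
               variance_all = sp$var_all)
  if (!is.null(cells_true) && !is.null(cells_pred)) {
    ss <- ssim_per_channel(cells_true, cells_pred)
    rep_$per_channel_ssim <- ss$per_channel
    rep_$mean_ssim <- ss$mean
  }
  if (!is.null(kmeans_k)) {
    if (identical(kmeans_k, "auto"))
      kmeans_k <- as.integer(choose_k_silhouette(truth, seed = seed))
    cl_true <- kmeans_cluster(truth, kmeans_k, seed = seed)
    cl_pred <- kmeans_cluster(pred, kmeans_k, seed = seed)
    rep_$kmeans_k <- kmeans_k
    rep_$clusters_true <- cl_true$labels
    rep_$clusters_pred <- cl_pred$labels
    rep_$nmi_kmeans <- nmi(cl_pred$labels, cl_true$labels)
    rep_$cluster_matching <- match_clusters(cl_pred$labels, cl_true$labels)
    rep_$nmi_shuffled_baseline <-
      shuffled_baseline(cl_pred$labels, cl_true$labels, seed = seed,
                        reps = shuffle_reps)$mean
  }
  if (!is.null(graph_params)) {
    gt <- do.call(graph_cluster,
                  c(list(table = truth, seed = seed), graph_params))
    gp <- do.call(graph_cluster,
                  c(list(table = pred, seed = seed), graph_params))
    rep_$nmi_graph <- nmi(gp$labels, gt$labels)
  }
  structure(rep_, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report\n")
  cat(sprintf("  panel (%d markers): %s\n", length(x$panel),
              paste(x$panel, collapse = ", ")))
  cat(sprintf("  Spearman: withheld %.3f (var %.4f), all %.3f (var %.4f)\n",
              x$mean_withheld, x$variance_withheld, x$mean_all,
              x$variance_all))
  if (!is.null(x$mean_ssim))
    cat(sprintf("  SSIM: %.3f\n", x$mean_ssim))
  if (!is.null(x$nmi_kmeans))
    cat(sprintf("  NMI (k-means, k=%d): %.3f (shuffled baseline %.4f)\n",
                x$kmeans_k, x$nmi_kmeans, x$nmi_shuffled_baseline))
  if (!is.null(x$nmi_graph))
    cat(sprintf("  NMI (graph): %.3f\n", x$nmi_graph))
  invisible(x)
}
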