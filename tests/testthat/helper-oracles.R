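# Independent oracles used across test files. These are deliberately plain
# loop-based implementations, kept separate from the package's vectorized
# code paths.

# panel score by direct looping over withheld markers (signed max)
oracle_score_corr <- function(panel, corr) {
  W <- setdiff(colnames(corr), panel)
  if (!length(W)) return(1)
  tot <- 0
  for (w in W) {
    best <- -Inf
    for (r in panel) best <- max(best, corr[w, r])
    tot <- tot + best
  }
  tot / length(W)
}

oracle_score_ssc <- function(panel, C) {
  W <- setdiff(colnames(C), panel)
  int_ms <- function(m, S) {
    s <- 0
    for (x in setdiff(S, m)) s <- s + abs(C[m, x]) + abs(C[x, m])
    s
  }
  t1 <- if (length(W))
    mean(vapply(W, int_ms, numeric(1), S = panel)) else 0
  t2 <- mean(vapply(panel, function(r)
    int_ms(r, setdiff(panel, r)), numeric(1)))
  t1 - t2
}

# naive full enumeration of size-n panels containing `required`
oracle_best_panel <- function(markers, n, required, score_fn) {
  free <- setdiff(markers, required)
  best <- NULL; best_s <- -Inf; best_key <- NULL
  for (combo in utils::combn(free, n - length(required), simplify = FALSE)) {
    p <- c(required, combo)
    s <- score_fn(p)
    key <- paste(sort(p), collapse = "\r")
    if (s > best_s || (s == best_s && key < best_key)) {
      best <- p; best_s <- s; best_key <- key
    }
  }
  list(panel = sort(best), score = best_s)
}

# contingency-table mutual information / entropies from first principles
oracle_nmi <- function(U, V) {
  keep <- U != -1 & V != -1
  U <- U[keep]; V <- V[keep]
  n <- length(U)
  us <- unique(U); vs <- unique(V)
  hu <- 0
  for (u in us) { p <- sum(U == u) / n; hu <- hu - p * log(p) }
  hv <- 0
  for (v in vs) { p <- sum(V == v) / n; hv <- hv - p * log(p) }
  if (hu == 0 || hv == 0) return(0)
  mi <- 0
  for (u in us) for (v in vs) {
    p <- sum(U == u & V == v) / n
    if (p > 0) mi <- mi + p * log(p / ((sum(U == u) / n) * (sum(V == v) / n)))
  }
  mi / mean(c(hu, hv))
}

# brute-force binary morphology with a disk of the given radius
oracle_disk <- function(radius) {
  d <- 2 * radius + 1
  outer(seq_len(d), seq_len(d), function(i, j)
    (i - radius - 1)^2 + (j - radius - 1)^2 <= radius^2 + 1e-9) * 1L
}

oracle_dilate <- function(mask, radius) {
  out <- mask * 0L
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    for (di in -radius:radius) for (dj in -radius:radius) {
      if (di^2 + dj^2 > radius^2 + 1e-9) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) out[ii, jj] <- 1L
    }
  }
  out
}

oracle_erode <- function(mask, radius) {
  out <- mask * 0L
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    keep <- TRUE
    for (di in -radius:radius) for (dj in -radius:radius) {
      if (di^2 + dj^2 > radius^2 + 1e-9) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || !mask[ii, jj])
        keep <- FALSE
    }
    if (keep) out[i, j] <- 1L
  }
  out
}

# orientation of a mask recomputed from raw image moments
oracle_orientation <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  x <- idx[, 2] - mean(idx[, 2]); y <- idx[, 1] - mean(idx[, 1])
  0.5 * atan2(2 * mean(x * y), mean(x^2) - mean(y^2))
}

# rasterized centered disk mask
disk_mask <- function(size, radius, center = (size + 1) / 2) {
  outer(seq_len(size), seq_len(size), function(i, j)
    (i - center)^2 + (j - center)^2 <= radius^2 + 1e-9) * 1L
}

# small deterministic cell for image-op tests
toy_cell <- function(crop = 24, seed = 1) {
  panelreduce::render_cell(
    c(Hoechst = 0.8, CK = 0.6, CD = 0.4),
    c("nuclear", "cytoplasmic", "membrane"),
    crop, shape_seed = seed)
}
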