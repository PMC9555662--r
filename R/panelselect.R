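#' Marker-marker correlation matrix of mean intensities
#'
#' @param table cells x markers numeric matrix (mean intensities).
#' @param method `"spearman"` (default, matching how results are typically
#'   reported) or `"pearson"`.
#' @return object of class `correlation_matrix`: symmetric matrix with unit
#'   diagonal and a `method` attribute. Constant columns correlate 0 with
#'   everything (with a warning).
#' @export
correlation_matrix <- function(table, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(is.matrix(table))
  if (nrow(table) < 3) stop("need at least 3 cells")
  const <- apply(table, 2, function(x) max(x) == min(x))
  cm <- suppressWarnings(cor(table, method = method))
  if (any(const)) {
    warning("constant column(s): ", paste(colnames(table)[const], collapse = ", "),
            "; their correlations set to 0")
    cm[const, ] <- 0
    cm[, const] <- 0
  }
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  cm <- (cm + t(cm)) / 2
  structure(cm, method = method, class = c("correlation_matrix", "matrix"))
}

#' Score a candidate reduced panel by withheld-marker correlation
#'
#' The panel score is the mean, over withheld markers, of each withheld
#' marker's maximum correlation to any panel member:
#' `score = mean_w max_{r in R} corr(w, r)`.
#'
#' @param panel character vector of panel marker names (nonempty).
#' @param corr a [correlation_matrix()] over the full panel.
#' @param use_abs if `TRUE`, maximize absolute correlations (an
#'   anticorrelated marker is also predictive); default uses signed values.
#' @return scalar score. If the panel is the full panel (no withheld
#'   markers), the score is 1 by convention.
#' @export
score_panel_corr <- function(panel, corr, use_abs = FALSE) {
  mk <- colnames(corr)
  stopifnot(length(panel) > 0, all(panel %in% mk))
  withheld <- setdiff(mk, panel)
  if (!length(withheld)) {
    message("panel equals the full panel; score is 1 by convention")
    return(1)
  }
  cm <- corr[withheld, panel, drop = FALSE]
  if (use_abs) cm <- abs(cm)
  mean(apply(cm, 1, max))
}

#' Fit the self-expressive marker interaction map
#'
#' Learns a zero-diagonal coefficient matrix `C` such that `C %*% I`
#' reconstructs each cell's marker intensity vector `I`: row `j` of `C` is
#' the ridge regression of marker `j` on all other markers (no intercept),
#' minimizing `mean_cells ||I - C I||^2 + (lambda_scale / n_markers) ||C||_F^2`
#' with `C_ii = 0`. The data term is the mean over cells so `lambda_scale`
#' is sample-size independent. Entries with `|C_ij| < threshold` are then
#' set to 0.
#'
#' @param table cells x markers matrix of (normalized) mean intensities.
#' @param lambda_scale ridge penalty scale (>= 0).
#' @param threshold absolute values below this are dropped (default 0.05).
#' @param solver `"closed_form"` (row-wise exact solve) or `"gradient"`
#'   (projected gradient descent on the same objective; must match the
#'   closed form).
#' @param penalty `"l2"` (the objective above) or `"l1"` (sparse
#'   alternative via glmnet, if installed).
#' @param max_iter,tol gradient-solver controls.
#' @return object of class `interaction_map`: the thresholded matrix `C`
#'   with attributes `threshold`, `lambda_scale` and `C_raw` (unthresholded).
#' @export
fit_interaction_map <- function(table, lambda_scale = 0.1, threshold = 0.05,
                                solver = c("closed_form", "gradient"),
                                penalty = c("l2", "l1"),
                                max_iter = 5000, tol = 1e-10) {
  solver <- match.arg(solver)
  penalty <- match.arg(penalty)
  stopifnot(is.matrix(table))
  n <- ncol(table); m <- nrow(table)
  if (m < n + 1) stop("need at least markers + 1 cells")
  X <- table
  lam <- lambda_scale / n
  if (penalty == "l1") {
    if (!requireNamespace("glmnet", quietly = TRUE))
      stop("penalty = 'l1' requires the glmnet package")
    C <- matrix(0, n, n)
    for (j in seq_len(n)) {
      fit <- glmnet::glmnet(X[, -j, drop = FALSE], X[, j], alpha = 1,
                            lambda = lam, intercept = FALSE,
                            standardize = FALSE)
      C[j, -j] <- as.numeric(fit$beta)
    }
  } else if (solver == "closed_form") {
    S <- crossprod(X) / m                   # X'X / m
    C <- matrix(0, n, n)
    for (j in seq_len(n)) {
      A <- S[-j, -j, drop = FALSE]
      diag(A) <- diag(A) + lam
      cj <- tryCatch(solve(A, S[-j, j]),
                     error = function(e)
                       stop("singular normal equations; use lambda_scale > 0"))
      C[j, -j] <- cj
    }
  } else {
    # projected gradient descent with diag(C) = 0 enforced every step
    S <- crossprod(X) / m
    L <- 2 * max(eigen(S, symmetric = TRUE, only.values = TRUE)$values) +
      2 * lam
    C <- matrix(0, n, n)
    f_prev <- Inf
    for (it in seq_len(max_iter)) {
      G <- 2 * (C %*% S - S) + 2 * lam * C
      diag(G) <- 0
      C <- C - G / L
      diag(C) <- 0
      if (it %% 25 == 0) {
        R <- diag(n) - C
        f <- sum(diag(R %*% S %*% t(R))) + lam * sum(C^2)
        if (abs(f_prev - f) < tol * max(1, abs(f))) break
        f_prev <- f
      }
    }
  }
  dimnames(C) <- list(colnames(table), colnames(table))
  C_raw <- C
  C[abs(C) < threshold] <- 0
  diag(C) <- 0
  structure(C, threshold = threshold, lambda_scale = lambda_scale,
            C_raw = C_raw, class = c("interaction_map", "matrix"))
}

# total |C| interaction linking marker m to set S, both directions
interaction_strength <- function(C, m, S) {
  S <- setdiff(S, m)
  if (!length(S)) return(0)
  sum(abs(C[m, S])) + sum(abs(C[S, m]))
}

#' Score a candidate panel on the interaction map
#'
#' Rewards panels whose members interact strongly with the withheld markers
#' (so the withheld markers are reconstructible) and weakly with each other
#' (so no panel slot is wasted on a redundant marker):
#' `score = mean_w Int(w, R) - mean_r Int(r, R \ {r})`, where `Int(m, S)`
#' sums `|C_ij| + |C_ji|` over pairs linking `m` to `S` (both directions,
#' preventing cancellation since `C` is not symmetric).
#'
#' @param panel character vector of panel marker names (nonempty).
#' @param interactions a thresholded [fit_interaction_map()].
#' @return scalar score; 0 for every panel when `C` is all zero.
#' @export
score_panel_ssc <- function(panel, interactions) {
  mk <- colnames(interactions)
  stopifnot(length(panel) > 0, all(panel %in% mk))
  withheld <- setdiff(mk, panel)
  Cmat <- unclass(interactions)
  to_w <- if (length(withheld))
    mean(vapply(withheld, function(w)
      interaction_strength(Cmat, w, panel), numeric(1)))
  else 0
  within <- mean(vapply(panel, function(r)
    interaction_strength(Cmat, r, setdiff(panel, r)), numeric(1)))
  to_w - within
}

# shared combinatorial engine: enumerate (or greedily grow) size-n panels
# containing `required`, maximize score_fn(panel), ties -> lexicographically
# smallest sorted panel
select_panel_engine <- function(marker_names, n, required, score_fn,
                                mode = c("auto", "exhaustive", "greedy"),
                                enum_budget = 2.5e5) {
  mode <- match.arg(mode)
  stopifnot(all(required %in% marker_names),
            n >= length(required), n <= length(marker_names))
  free <- sort(setdiff(marker_names, required))
  k <- n - length(required)
  if (n == length(marker_names)) {
    panel <- c(required, free)
    return(list(panel = panel, score = score_fn(panel)))
  }
  n_panels <- choose(length(free), k)
  if (mode == "auto")
    mode <- if (n_panels <= enum_budget) "exhaustive" else "greedy"
  if (mode == "exhaustive") {
    best <- NULL; best_score <- -Inf; best_key <- NULL
    combos <- combn(free, k)
    for (i in seq_len(ncol(combos))) {
      panel <- c(required, combos[, i])
      s <- score_fn(panel)
      key <- paste(sort(panel), collapse = "\r")
      if (s > best_score ||
          (s == best_score && !is.null(best_key) && key < best_key)) {
        best <- panel; best_score <- s; best_key <- key
      }
    }
    list(panel = best, score = best_score)
  } else {
    panel <- required
    while (length(panel) < n) {
      cand <- sort(setdiff(free, panel))
      scores <- vapply(cand, function(mk)
        score_fn(c(panel, mk)), numeric(1))
      panel <- c(panel, cand[which.max(scores)])  # ties -> first = lexicographic
    }
    list(panel = panel, score = score_fn(panel))
  }
}

reduced_panel_result <- function(panel, marker_names, method, score,
                                 required) {
  structure(list(panel = panel, withheld = setdiff(marker_names, panel),
                 method = method, size = length(panel), score = score,
                 required = required, full_panel = marker_names),
            class = "reduced_panel")
}

#' @export
print.reduced_panel <- function(x, ...) {
  cat(sprintf("reduced_panel (%s, n = %d, score = %.4f)\n",
              x$method, x$size, x$score))
  cat("  panel:   ", paste(x$panel, collapse = ", "), "\n")
  cat("  withheld:", paste(x$withheld, collapse = ", "), "\n")
  invisible(x)
}

#' Select a reduced panel by combinatorial correlation scoring
#'
#' Enumerates all size-`n` supersets of `required` and returns the panel with
#' the highest [score_panel_corr()] (ties broken by lexicographically
#' smallest sorted panel). Above `enum_budget` candidate panels in `"auto"`
#' mode, a greedy forward selection is used instead. Panels are re-selected
#' independently for each size.
#'
#' @param corr a [correlation_matrix()].
#' @param n panel size, `length(required) <= n <=` full panel size.
#' @param required markers forced into the panel (typically the nuclear
#'   stain, which segmentation needs).
#' @param mode `"auto"`, `"exhaustive"` or `"greedy"`.
#' @param use_abs passed to [score_panel_corr()].
#' @param enum_budget candidate-panel count above which `"auto"` falls back
#'   to greedy.
#' @return a `reduced_panel` result.
#' @export
select_panel_corr <- function(corr, n, required = character(0),
                              mode = c("auto", "exhaustive", "greedy"),
                              use_abs = FALSE, enum_budget = 2.5e5) {
  mk <- colnames(corr)
  res <- select_panel_engine(mk, n, required,
                             function(p) score_panel_corr(p, corr, use_abs),
                             mode, enum_budget)
  reduced_panel_result(res$panel, mk, "correlation", res$score, required)
}

#' Select a reduced panel by interaction-map scoring
#'
#' As [select_panel_corr()] but maximizing [score_panel_ssc()] on a
#' thresholded interaction map.
#'
#' @param interactions a [fit_interaction_map()].
#' @inheritParams select_panel_corr
#' @return a `reduced_panel` result.
#' @export
select_panel_ssc <- function(interactions, n, required = character(0),
                             mode = c("auto", "exhaustive", "greedy"),
                             enum_budget = 2.5e5) {
  mk <- colnames(interactions)
  res <- select_panel_engine(mk, n, required,
                             function(p) score_panel_ssc(p, interactions),
                             mode, enum_budget)
  reduced_panel_result(res$panel, mk, "subspace", res$score, required)
}

#' Seeded random marker ordering for nested random panels
#'
#' Returns a seeded permutation of the markers with `required` markers placed
#' first, so the size-`n` random panel is the first `n` entries and panels
#' are nested across sizes.
#'
#' @param marker_names full panel.
#' @param seed integer seed.
#' @param required markers placed at the head of the sequence.
#' @return character vector: a permutation of `marker_names`.
#' @export
random_panel_sequence <- function(marker_names, seed = 1,
                                  required = character(0)) {
  stopifnot(all(required %in% marker_names))
  rest <- setdiff(marker_names, required)
  with_local_seed(seed, c(required, sample(rest)))
}

#' Random reduced panel of a given size
#'
#' @inheritParams random_panel_sequence
#' @param n panel size.
#' @return a `reduced_panel` (first `n` entries of the random sequence; its
#'   `score` is `NA`).
#' @export
select_panel_random <- function(marker_names, n, seed = 1,
                                required = character(0)) {
  seqn <- random_panel_sequence(marker_names, seed, required)
  stopifnot(n >= length(required), n <= length(marker_names))
  reduced_panel_result(seqn[seq_len(n)], marker_names, "random", NA_real_,
                       required)
}

#' Reduced panel from per-marker gradient importances
#'
#' Takes the top-`n` markers ranked by descending importance (required
#' markers first; importance ties broken by marker name). Because the ranking
#' is static, panels are nested: the size-`n` panel is always a subset of the
#' size-`n+1` panel.
#'
#' @param importances named nonnegative numeric vector, one per marker (e.g.
#'   from [encoding_gradients()]).
#' @param n panel size.
#' @param required markers forced in.
#' @return a `reduced_panel`; `score` is the mean importance of the panel.
#' @export
select_panel_gradient <- function(importances, n, required = character(0)) {
  stopifnot(!is.null(names(importances)))
  if (any(importances < 0)) stop("importances must be nonnegative")
  mk <- names(importances)
  stopifnot(all(required %in% mk), n >= length(required), n <= length(mk))
  rest <- setdiff(mk, required)
  ord <- rest[order(-importances[rest], rest)]
  panel <- c(required, ord)[seq_len(n)]
  reduced_panel_result(panel, mk, "gradient", mean(importances[panel]),
                       required)
}

#' 1-to-1 intensity substitution baseline
#'
#' Predicts each withheld marker's intensities by copying the column of its
#' most-correlated marker inside the reduced panel (its "matched partner");
#' panel markers pass through unchanged. This is the no-computation baseline
#' a reduced panel achieves without any predictive model.
#'
#' @param table cells x markers matrix over the full panel.
#' @param corr a [correlation_matrix()] computed on the full panel.
#' @param panel character vector: the reduced panel (nonempty).
#' @param use_abs maximize absolute correlation when pairing.
#' @return list: `predicted` (full-panel matrix), `partners` (named character
#'   vector mapping each withheld marker to its in-panel partner).
#' @export
baseline_substitute <- function(table, corr, panel, use_abs = FALSE) {
  mk <- colnames(table)
  stopifnot(length(panel) > 0, all(panel %in% mk),
            identical(sort(colnames(corr)), sort(mk)))
  withheld <- setdiff(mk, panel)
  pred <- table
  partners <- character(0)
  panel_sorted <- sort(panel)     # tie-break: lexicographically smallest
  for (w in withheld) {
    v <- corr[w, panel_sorted]
    if (use_abs) v <- abs(v)
    partner <- panel_sorted[which.max(v)]
    pred[, w] <- table[, partner]
    partners[w] <- partner
  }
  list(predicted = pred, partners = partners)
}
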