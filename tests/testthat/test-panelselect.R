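make_corr <- function(m, names_ = LETTERS[seq_len(ncol(m))]) {
  dimnames(m) <- list(names_, names_)
  structure(m, method = "spearman",
            class = c("correlation_matrix", "matrix"))
}

test_that("correlation_matrix handles duplicates, negations and a rank oracle", {
  set.seed(2)
  x <- runif(20)
  tab <- cbind(A = x, B = x, C = -x, D = runif(20))
  rownames(tab) <- paste0("c", 1:20)
  cm <- correlation_matrix(tab, "spearman")
  expect_equal(cm["A", "B"], 1)
  expect_equal(cm["A", "C"], -1)
  expect_equal(diag(unclass(cm)), rep(1, 4), ignore_attr = TRUE)
  expect_equal(unclass(cm), t(unclass(cm)), ignore_attr = TRUE)
  # 5-cell toy: spearman = pearson on ranks
  t5 <- cbind(A = c(1, 4, 2, 5, 3), B = c(10, 2, 8, 1, 9))
  rownames(t5) <- paste0("c", 1:5)
  cm5 <- correlation_matrix(t5, "spearman")
  expect_equal(cm5["A", "B"], cor(rank(t5[, "A"]), rank(t5[, "B"])))
  # constant column warns and gets 0
  t0 <- cbind(A = runif(5), B = rep(0.3, 5))
  rownames(t0) <- paste0("c", 1:5)
  expect_warning(cm0 <- correlation_matrix(t0), "constant")
  expect_equal(cm0["A", "B"], 0)
  expect_error(correlation_matrix(tab[1:2, ]), "3 cells")
})

test_that("score_panel_corr matches hand evaluation and is order-invariant", {
  m <- make_corr(matrix(c(1, .8, .2, .8, 1, .4, .2, .4, 1), 3, 3))
  expect_equal(score_panel_corr("A", m), (0.8 + 0.2) / 2)
  expect_equal(score_panel_corr(c("B", "A"), m),
               score_panel_corr(c("A", "B"), m))
  # perfect duplicates in panel give score 1
  dup <- make_corr(matrix(c(1, 1, 1, 1, 1, 1, 1, 1, 1), 3, 3))
  expect_equal(score_panel_corr("A", dup), 1)
  # full panel scores 1 by convention
  expect_message(s <- score_panel_corr(c("A", "B", "C"), m), "full panel")
  expect_equal(s, 1)
})

test_that("exhaustive correlation selection agrees with the naive enumeration oracle", {
  set.seed(5)
  for (rep in 1:3) {
    R <- matrix(runif(64, -1, 1), 8, 8)
    R <- (R + t(R)) / 2; diag(R) <- 1
    cm <- make_corr(R, paste0("M", 1:8))
    for (n in c(2, 4, 6)) {
      got <- select_panel_corr(cm, n, required = "M1", mode = "exhaustive")
      want <- oracle_best_panel(colnames(cm), n, "M1",
                                function(p) oracle_score_corr(p, cm))
      expect_identical(sort(got$panel), want$panel)
      expect_equal(got$score, want$score)
    }
  }
  # n = full size returns everything at score 1
  cm <- make_corr(diag(4), paste0("M", 1:4))
  full <- select_panel_corr(cm, 4)
  expect_setequal(full$panel, colnames(cm))
  expect_equal(full$score, 1)
  expect_error(select_panel_corr(cm, 5), "n <=")
})

test_that("max-correlation panel score is monotone as the panel grows", {
  set.seed(8)
  R <- matrix(runif(100, -1, 1), 10, 10)
  R <- (R + t(R)) / 2; diag(R) <- 1
  cm <- make_corr(R, paste0("M", 1:10))
  w <- "M10"
  panels <- lapply(1:9, function(n) paste0("M", 1:n))
  best <- vapply(panels, function(p) max(cm[w, p]), numeric(1))
  expect_true(all(diff(best) >= 0))
})

test_that("fit_interaction_map recovers a planted linear dependency (ridge oracle)", {
  set.seed(3)
  n <- 500
  A <- runif(n)
  B <- 0.9 * A + rnorm(n, sd = 0.01)
  C_ <- runif(n); D <- runif(n)
  tab <- cbind(A = A, B = B, C = C_, D = D)
  rownames(tab) <- paste0("c", seq_len(n))
  im <- fit_interaction_map(tab, lambda_scale = 0.01, threshold = 0.05)
  # closed-form ridge oracle for row B: (X'X/m + lam I)^-1 X'y/m
  X <- tab[, c("A", "C", "D")]; y <- tab[, "B"]
  lam <- 0.01 / 4
  beta <- solve(crossprod(X) / n + lam * diag(3), crossprod(X, y) / n)
  expect_equal(attr(im, "C_raw")["B", c("A", "C", "D")], beta[, 1],
               tolerance = 1e-10)
  expect_gt(im["B", "A"], 0.8)
  # diagonal exactly zero; sub-threshold entries dropped
  expect_true(all(diag(unclass(im)) == 0))
  expect_true(all(abs(unclass(im)[unclass(im) != 0]) >= 0.05))
  expect_error(fit_interaction_map(tab[1:3, ]), "cells")
})

test_that("gradient solver matches the closed form", {
  set.seed(4)
  tab <- matrix(runif(300 * 6), 300, 6,
                dimnames = list(paste0("c", 1:300), paste0("M", 1:6)))
  tab[, 2] <- 0.8 * tab[, 1] + rnorm(300, sd = 0.02)
  a <- fit_interaction_map(tab, lambda_scale = 0.1, solver = "closed_form")
  b <- fit_interaction_map(tab, lambda_scale = 0.1, solver = "gradient")
  rel <- norm(attr(a, "C_raw") - attr(b, "C_raw"), "F") /
    norm(attr(a, "C_raw"), "F")
  expect_lt(rel, 1e-3)
})

test_that("independent markers give a (near-)all-zero thresholded map", {
  set.seed(6)
  tab <- matrix(runif(2000 * 5), 2000, 5,
                dimnames = list(paste0("c", 1:2000), paste0("M", 1:5)))
  im <- fit_interaction_map(tab, lambda_scale = 0.1, threshold = 0.05)
  # oracle on the same draw: count closed-form entries >= threshold
  X <- tab; lam <- 0.1 / 5
  n_big <- 0
  for (j in 1:5) {
    Xj <- X[, -j]; yj <- X[, j]
    beta <- solve(crossprod(Xj) / 2000 + lam * diag(4),
                  crossprod(Xj, yj) / 2000)
    n_big <- n_big + sum(abs(beta) >= 0.05)
  }
  expect_equal(sum(unclass(im) != 0), n_big)
})

test_that("score_panel_ssc matches hand evaluation on a 3-marker toy", {
  C <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  C["B", "A"] <- 0.9
  im <- structure(C, threshold = 0.05, lambda_scale = 0.1,
                  class = c("interaction_map", "matrix"))
  # R = {A}: Int(B,{A}) = 0.9, Int(C,{A}) = 0 -> mean 0.45; within-term 0
  expect_equal(score_panel_ssc("A", im), 0.45)
  # all-zero C scores 0 for every panel
  C0 <- structure(C * 0, threshold = 0.05, lambda_scale = 0.1,
                  class = c("interaction_map", "matrix"))
  expect_equal(score_panel_ssc(c("A", "B"), C0), 0)
  # moving the zero-interaction marker C into the panel leaves the
  # within-panel term at 0 and the withheld mean becomes Int(B,{A,C}) = 0.9
  expect_equal(score_panel_ssc(c("A", "C"), im), 0.9)
})

test_that("exhaustive subspace selection agrees with the naive oracle", {
  set.seed(9)
  for (rep in 1:3) {
    C <- matrix(runif(49, -0.5, 0.5), 7, 7)
    diag(C) <- 0
    C[abs(C) < 0.05] <- 0
    dimnames(C) <- list(paste0("M", 1:7), paste0("M", 1:7))
    im <- structure(C, threshold = 0.05, lambda_scale = 0.1,
                    class = c("interaction_map", "matrix"))
    for (n in c(2, 4)) {
      got <- select_panel_ssc(im, n, required = "M1", mode = "exhaustive")
      want <- oracle_best_panel(colnames(C), n, "M1",
                                function(p) oracle_score_ssc(p, C))
      expect_identical(sort(got$panel), want$panel)
      expect_equal(got$score, want$score)
    }
  }
})

test_that("selection is deterministic and invariant to marker column order", {
  set.seed(10)
  tab <- matrix(runif(200 * 6), 200, 6,
                dimnames = list(paste0("c", 1:200), paste0("M", 1:6)))
  tab[, 4] <- tab[, 2] * 0.95 + rnorm(200, sd = 0.02)
  cm1 <- correlation_matrix(tab)
  perm <- c(3, 1, 6, 2, 5, 4)
  cm2 <- correlation_matrix(tab[, perm])
  s1 <- select_panel_corr(cm1, 3, required = "M1", mode = "exhaustive")
  s2 <- select_panel_corr(cm2, 3, required = "M1", mode = "exhaustive")
  expect_identical(sort(s1$panel), sort(s2$panel))
  expect_equal(s1$score, s2$score)
})

test_that("planted-redundancy blocks are each represented once at n = blocks", {
  spec <- synthetic_spec(n_cells = 1500, seed = 21)
  ds <- generate_dataset(spec, render = FALSE)
  cm <- correlation_matrix(ds$truth)
  sel <- select_panel_corr(cm, 4, required = "Hoechst", mode = "exhaustive")
  per_block <- vapply(spec$redundancy_blocks, function(blk)
    sum(spec$marker_names[blk] %in% sel$panel), numeric(1))
  expect_identical(unname(per_block), rep(1, 4))
  im <- fit_interaction_map(ds$truth, lambda_scale = 0.1)
  sel2 <- select_panel_ssc(im, 4, required = "Hoechst", mode = "exhaustive")
  per_block2 <- vapply(spec$redundancy_blocks, function(blk)
    sum(spec$marker_names[blk] %in% sel2$panel), numeric(1))
  expect_identical(unname(per_block2), rep(1, 4))
})

test_that("random_panel_sequence is a seeded nested permutation", {
  mk <- paste0("M", 1:9)
  s1 <- random_panel_sequence(mk, seed = 3, required = "M5")
  expect_identical(s1, random_panel_sequence(mk, seed = 3, required = "M5"))
  expect_identical(s1[1], "M5")
  expect_setequal(s1, mk)
  # panels nested across sizes by construction
  p4 <- select_panel_random(mk, 4, seed = 3, required = "M5")
  p6 <- select_panel_random(mk, 6, seed = 3, required = "M5")
  expect_true(all(p4$panel %in% p6$panel))
})

test_that("gradient selection ranks by importance with required markers first", {
  imp <- c(A = 3, B = 1, C = 2)
  sel <- select_panel_gradient(imp, 2, required = "A")
  expect_identical(sel$panel, c("A", "C"))
  expect_identical(select_panel_gradient(imp, 3)$panel, c("A", "C", "B"))
  # invariant under positive rescaling
  expect_identical(select_panel_gradient(imp * 7.3, 2, required = "A")$panel,
                   sel$panel)
  expect_error(select_panel_gradient(c(A = -1, B = 2), 1), "nonnegative")
})

test_that("baseline substitution copies the max-correlation partner column", {
  set.seed(11)
  x <- runif(30)
  tab <- cbind(CK19 = x, PanCK = x * 0.9 + rnorm(30, sd = 0.01),
               CD3 = runif(30), Hoechst = runif(30))
  rownames(tab) <- paste0("c", 1:30)
  cm <- correlation_matrix(tab)
  bs <- baseline_substitute(tab, cm, panel = c("CK19", "Hoechst"))
  # PanCK predicted by verbatim copy of CK19 (its top in-panel correlate)
  expect_identical(bs$partners[["PanCK"]], "CK19")
  expect_identical(bs$predicted[, "PanCK"], tab[, "CK19"])
  # included markers pass through unchanged
  expect_identical(bs$predicted[, "CK19"], tab[, "CK19"])
  # partner = argmax over the panel, exhaustive scan oracle
  for (w in c("PanCK", "CD3")) {
    best <- NULL; best_v <- -Inf
    for (r in sort(c("CK19", "Hoechst")))
      if (cm[w, r] > best_v) { best <- r; best_v <- cm[w, r] }
    expect_identical(bs$partners[[w]], best)
  }
  # empty withheld set: identity
  bs_full <- baseline_substitute(tab, cm, panel = colnames(tab))
  expect_identical(bs_full$predicted, tab)
  expect_error(baseline_substitute(tab, cm, panel = character(0)))
})
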