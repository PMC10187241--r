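make_em <- function(values, tp = tgrid()) {
  expression_matrix(matrix(values, ncol = length(tp), byrow = TRUE,
                           dimnames = list(paste0("g", seq_len(length(values) / length(tp))),
                                           paste0("t", tp))))
}

test_that("background threshold is the grand mean over the panel", {
  tp <- tgrid()
  em <- make_em(c(rep(1, 24), rep(3, 24), rep(10, 24)), tp)
  expect_equal(background_threshold(em, c("g1", "g2")), 2)
  em0 <- make_em(c(rep(0, 24), rep(5, 24)), tp)
  expect_equal(background_threshold(em0, "g1"), 0)
  expect_error(background_threshold(em, c("g1", "nope")), "nope")
  expect_error(background_threshold(em, character()), "empty")

  # arbitrary fixture: direct summation oracle
  set.seed(1)
  vals <- runif(5 * 24, 0, 4)
  em5 <- make_em(vals, tp)
  panel <- c("g2", "g4")
  expect_equal(background_threshold(em5, panel),
               sum(unclass(em5)[panel, ]) / (2 * 24))
})

test_that("expression filtering keeps genes above threshold, in order", {
  tp <- tgrid()
  set.seed(2)
  X <- matrix(runif(10 * 24, 1, 2), 10, 24,
              dimnames = list(paste0("g", 1:10), paste0("t", tp)))
  X[c(2, 5, 7, 9), ] <- X[c(2, 5, 7, 9), ] * 0.1
  em <- expression_matrix(X)
  thr <- 0.5
  kept <- filter_expressed(em, thr)
  expect_identical(rownames(kept), paste0("g", c(1, 3, 4, 6, 8, 10)))
  # brute-force comparison
  expect_setequal(rownames(kept), rownames(X)[rowMeans(X) > thr])
  # identity at 0, empty above max
  expect_identical(nrow(filter_expressed(em, 0)), 10L)
  expect_identical(nrow(filter_expressed(em, max(rowMeans(X)) + 1)), 0L)
  # idempotence
  expect_identical(unclass(filter_expressed(kept, thr)), unclass(kept))
})

test_that("linear detrend removes lines exactly and is a projection", {
  tp <- tgrid()
  expect_equal(linear_detrend(3 + 0.25 * tp, tp), rep(0, 24),
               tolerance = 1e-12)
  # cosine even about the grid midpoint is orthogonal to the line
  y <- cos(2 * pi * (tp - mean(tp)) / 12)
  expect_equal(linear_detrend(y, tp), y, tolerance = 1e-9)
  # arbitrary series: residual slope is 0 (refit oracle)
  set.seed(3)
  z <- linear_detrend(runif(24, 0, 5), tp)
  refit <- stats::lm(z ~ tp)
  expect_lt(abs(stats::coef(refit)[2]), 1e-12)
  expect_lt(abs(mean(z)), 1e-12)
  # projection
  expect_equal(linear_detrend(z, tp), z, tolerance = 1e-10)
  expect_error(linear_detrend(c(1, 2, 3), c(2, 2, 2)), "degenerate")
})

test_that("polynomial detrend handles degree correctly", {
  tp <- tgrid()
  y <- 1 + 0.3 * tp - 0.01 * tp^2
  expect_equal(polynomial_detrend(y, tp, 2L), rep(0, 24), tolerance = 1e-9)
  set.seed(4)
  w <- runif(24)
  expect_equal(polynomial_detrend(w, tp, 0L), w - mean(w), tolerance = 1e-12)
  # refit oracle: quadratic fit of the residual is flat
  z <- polynomial_detrend(w, tp, 2L)
  cf <- stats::coef(stats::lm(z ~ tp + I(tp^2)))
  expect_true(all(abs(cf) < 1e-10))
  expect_error(polynomial_detrend(w[1:4], tp[1:4], 3L), "degree")
})

test_that("folding 48h data yields day replicates", {
  tp <- tgrid()
  set.seed(5)
  X <- matrix(runif(3 * 24, 1, 5), 3, 24,
              dimnames = list(paste0("g", 1:3), paste0("t", tp)))
  em <- expression_matrix(X)
  f <- fold_duplicates(em)
  expect_identical(dim(f), c(3L, 24L))
  expect_identical(unique(time_points(f)), seq(0, 22, 2))
  expect_identical(as.numeric(table(time_points(f))), rep(2, 12))
  # replicate 2 of phase t is the original t + 24 sample
  for (t0 in seq(0, 22, 2)) {
    cols <- which(time_points(f) == t0)
    expect_equal(unname(f[, cols[1]]), unname(X[, tp == t0]))
    expect_equal(unname(f[, cols[2]]), unname(X[, tp == t0 + 24]))
  }
  # identical days give equal replicate pairs
  X2 <- cbind(X[, 1:12], X[, 1:12])
  colnames(X2) <- paste0("t", tp)
  f2 <- fold_duplicates(expression_matrix(X2))
  expect_equal(f2[, seq(1, 24, 2)], f2[, seq(2, 24, 2)], ignore_attr = TRUE)
  expect_error(fold_duplicates(expression_matrix(X[, 1:12])), "two full days")
})

test_that("interval subsampling selects the right phases", {
  tp <- tgrid()
  em <- make_em(seq_len(24), tp)
  s4 <- subsample_interval(em, 4)
  expect_identical(time_points(s4), seq(0, 44, 4))
  expect_identical(time_points(subsample_interval(em, 4, offset = 2)),
                   seq(2, 46, 4))
  expect_identical(unclass(subsample_interval(em, 2)), unclass(em))
  expect_error(subsample_interval(em, 3), "multiple")
  expect_error(subsample_interval(em, 4, offset = 1), "grid")
})
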