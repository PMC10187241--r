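test_that("independence test builds the right table and chi-square", {
  uni <- sprintf("u%03d", 1:200)
  # perfectly independent 2x2: [[50,50],[50,50]]
  A <- uni[1:100]
  B <- uni[c(1:50, 101:150)]
  r <- independence_test(A, B, uni)
  expect_equal(unname(as.vector(r$table)), c(50, 50, 50, 50))
  expect_equal(r$chisq, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$expected, 50)
  expect_true(sum(r$table) == r$N)

  # expected overlap formula
  uni2 <- sprintf("v%04d", 1:1000)
  r2 <- independence_test(uni2[1:100], uni2[51:250], uni2)
  expect_equal(r2$expected, 100 * 200 / 1000)
  expect_equal(r2$observed, 50)

  expect_error(independence_test("a", "a", character()), "empty")
  expect_error(independence_test("zz", uni[1], uni), "subsets")
  # degenerate margins
  expect_equal(independence_test(character(), uni[1:10], uni)$p_value, 1)
})

test_that("chi-square p agrees with the hypergeometric oracle on big cells", {
  set.seed(40)
  for (i in 1:10) {
    N <- 800; nA <- sample(150:300, 1); nB <- sample(150:300, 1)
    shift <- sample(-10:25, 1)
    obs <- max(0, round(nA * nB / N) + shift)
    obs <- min(obs, nA, nB)
    uni <- sprintf("g%04d", 1:N)
    A <- uni[1:nA]
    B <- uni[c(seq_len(obs), nA + seq_len(nB - obs))]
    r <- suppressMessages(independence_test(A, B, uni))
    emin <- min(outer(c(nA, N - nA), c(nB, N - nB)) / N)
    p_h <- oracle_hyper_p(obs, nA, nB, N)
    if (emin >= 5 && p_h >= 0.01)
      expect_lt(abs(r$p_value - p_h) / p_h, 0.15)
  }
})

test_that("conservation overlap maps ids and recovers planted overlaps", {
  uni <- sprintf("h%03d", 1:100)
  idmap <- data.frame(other = uni, human = uni)
  r <- conservation_overlap(uni[1:20], uni[1:20], idmap, uni)
  expect_equal(r$observed, 20)
  r2 <- conservation_overlap(uni[1:20], uni[21:40], idmap, uni)
  expect_equal(r2$observed, 0)

  cs <- simulate_conserved_sets(600, 500, 80, 90, 25, seed = 9)
  r3 <- conservation_overlap(cs$set_a, cs$set_b, cs$ortholog_map,
                             cs$universe_a)
  expect_equal(r3$observed, 25)
  # unmapped foreign ids are excluded with a message
  extra <- c(cs$set_b, "OGXXXXX")
  expect_message(r4 <- conservation_overlap(cs$set_a, extra, cs$ortholog_map,
                                            cs$universe_a), "no ortholog")
  expect_equal(r4$observed, 25)
  expect_equal(r4$n_unmapped, 1L)
})

test_that("three-way overlap partitions the union and matches set algebra", {
  uni <- sprintf("g%03d", 1:300)
  set.seed(41)
  A <- sample(uni, 90); B <- sample(uni, 120); C <- sample(uni, 70)
  r <- three_way_overlap(A, B, C, uni)
  expect_equal(sum(r$regions), length(union(union(A, B), C)))
  expect_equal(unname(r$regions["ABC"]),
               length(intersect(intersect(A, B), C)))
  expect_equal(unname(r$regions["A_only"]),
               length(setdiff(setdiff(A, B), C)))
  expect_equal(unname(r$regions["AB"]),
               length(setdiff(intersect(A, B), C)))
  expect_equal(r$expected_triple, 90 * 120 * 70 / 300^2)
  expect_gte(r$chisq, 0)

  same <- three_way_overlap(A, A, A, uni)
  expect_equal(unname(same$regions["ABC"]), 90)
  expect_lt(same$p_value, 1e-10)

  w <- sprintf("w%04d", 1:1000)
  expect_equal(three_way_overlap(w[1:100], w[101:200], w[201:300],
                                 w)$expected_triple, 1)
})

test_that("preranked enrichment statistic behaves like weighted KS", {
  set.seed(42)
  N <- 200
  genes <- sprintf("g%03d", 1:N)
  scores <- sort(rnorm(N, 0, 2), decreasing = TRUE)
  # set = top of the ranking: maximal positive ES
  top <- genes[1:20]
  r <- preranked_enrichment(genes, scores, top, n_permutations = 200, seed = 1)
  expect_equal(r$ES, 1)
  expect_identical(r$direction, "positive")
  expect_lt(r$p_value, 0.01)

  # weight 0 equals the ECDF-difference statistic
  rnd <- sample(genes, 30)
  r0 <- preranked_enrichment(genes, scores, rnd, n_permutations = 50,
                             seed = 2, weight = 0)
  hits <- genes %in% rnd
  ecdf_diff <- cumsum(hits) / sum(hits) - cumsum(!hits) / sum(!hits)
  expect_equal(r0$ES, ecdf_diff[which.max(abs(ecdf_diff))], tolerance = 1e-12)

  # reversing the ranking flips the KS-type ES sign
  rrev <- preranked_enrichment(rev(genes), rev(scores), rnd,
                               n_permutations = 50, seed = 2, weight = 0)
  expect_equal(rrev$ES, -r0$ES, tolerance = 1e-12)

  # permutation p of random sets is roughly uniform
  ps <- vapply(1:30, function(i) {
    s <- sample(genes, 25)
    preranked_enrichment(genes, scores, s, n_permutations = 99,
                         seed = i)$p_value
  }, 0)
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps < 0.1), 0.35)

  expect_error(preranked_enrichment(genes, scores, "nope"), "intersect")
})

test_that("harmonic control returns coherent sets and curves on noise", {
  out <- simulate_expression(sim_config(n_genes = 120, frac_circadian = 0,
                                        frac_ultradian12 = 0,
                                        n_participants = 1,
                                        n_background_genes = 0, seed = 50))
  hc <- harmonic_control(out$matrices[[1]], B = 999)
  expect_s3_class(hc$overlap, "overlap_result")
  expect_identical(hc$overlap$N, 120L)
  # near-empty sets on pure noise at a 5% threshold
  expect_lt(length(hc$set_circadian), 0.15 * 120)
  expect_lt(length(hc$set_ultradian), 0.15 * 120)
  expect_true(all(diff(hc$curves$n_ultradian12) >= 0))
  # pencil membership route runs and reports the same universe
  hp <- harmonic_control(out$matrices[[1]], membership = "pencil")
  expect_identical(hp$overlap$N, 120L)
})
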