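test_that("simulation is deterministic and class counts are exact", {
  cfg <- sim_config(n_genes = 100, seed = 42)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$matrices, b$matrices)
  expect_identical(a$truth, b$truth)

  cfg2 <- sim_config(n_genes = 1000, frac_ultradian12 = 0.2, seed = 1)
  tr <- simulate_expression(cfg2)$truth
  expect_identical(sum(tr$label == "ultradian12"), 200L)
  expect_identical(sum(tr$label == "circadian"), 150L)
  expect_identical(sum(tr$label == "background"), 62L)

  # different seed changes the data
  c2 <- simulate_expression(sim_config(n_genes = 100, seed = 43))
  expect_false(identical(unclass(a$matrices[[1]]), unclass(c2$matrices[[1]])))
})

test_that("noiseless simulation matches the closed-form signal model", {
  cfg <- sim_config(n_genes = 30, frac_circadian = 0.3, frac_ultradian12 = 0.3,
                    frac_both = 0.2, noise_rel_sd = 0, decay_range = c(0.9, 1.1),
                    n_background_genes = 0, seed = 7)
  out <- simulate_expression(cfg)
  tr <- out$truth
  tp <- cfg$timepoints
  offs <- cfg$phase_offsets_per_participant
  for (p in seq_along(out$matrices)) {
    m <- out$matrices[[p]]
    for (g in seq_len(nrow(tr))) {
      comps <- data.frame(period = numeric(), amplitude = numeric(),
                          phase = numeric(), decay = numeric())
      if (!is.na(tr$period24[g]))
        comps <- rbind(comps, data.frame(period = tr$period24[g],
                                         amplitude = tr$amp24[g],
                                         phase = tr$phase24[g] + offs[p],
                                         decay = tr$decay24[g]))
      if (!is.na(tr$period12[g]))
        comps <- rbind(comps, data.frame(period = tr$period12[g],
                                         amplitude = tr$amp12[g],
                                         phase = tr$phase12[g] + offs[p],
                                         decay = tr$decay12[g]))
      expect_equal(as.numeric(m[tr$gene[g], ]),
                   pmax(damped_signal(tp, tr$baseline[g], tr$slope[g], comps), 0),
                   tolerance = 1e-12)
    }
  }
})

test_that("arrhythmic genes without noise or drift are constant", {
  cfg <- sim_config(n_genes = 20, frac_circadian = 0, frac_ultradian12 = 0,
                    noise_rel_sd = 0, trend_rel_slope_range = c(0, 0),
                    n_background_genes = 0, seed = 3)
  m <- simulate_expression(cfg)$matrices[[1]]
  expect_true(all(apply(m, 1L, function(r) max(r) - min(r)) == 0))
})

test_that("temporal mean equals baseline plus trend midpoint (decay 1, no noise)", {
  cfg <- sim_config(n_genes = 50, frac_circadian = 0.3, frac_ultradian12 = 0.3,
                    decay_range = c(1, 1), noise_rel_sd = 0,
                    n_background_genes = 0, seed = 5)
  out <- simulate_expression(cfg)
  m <- out$matrices[[1]]
  tr <- out$truth
  expected <- tr$baseline + tr$slope * mean(cfg$timepoints)
  expect_equal(unname(rowMeans(m)[tr$gene]), expected, tolerance = 1e-9)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(frac_circadian = 0.7, frac_ultradian12 = 0.4),
               "proportions")
  expect_error(sim_config(timepoints = c(0, 2, 3, 8)), "evenly spaced")
  expect_error(sim_config(timepoints = c(4, 2, 0)), "increasing")
  expect_error(sim_config(n_genes = 0), "positive count")
})

test_that("background panel genes are lowly expressed and usable as panel", {
  out <- simulate_expression(sim_config(n_genes = 50, seed = 2))
  expect_length(out$panel, 62L)
  expect_true(all(out$panel %in% rownames(out$matrices[[1]])))
  thr <- background_threshold(out$matrices[[1]], out$panel)
  expect_lt(thr, 1)
  # all foreground baselines clear the threshold comfortably
  kept <- filter_expressed(out$matrices[[1]], thr)
  expect_true(all(sprintf("G%05d", 1:50) %in% rownames(kept)))
  # the threshold is the panel *average*, so roughly half the panel
  # genes sit above it; all of them stay far below the foreground
  expect_lt(sum(out$panel %in% rownames(kept)), 45)
  expect_lt(max(rowMeans(out$matrices[[1]])[out$panel]), 1)
})

test_that("IR table simulation is seeded and phase-locked", {
  cfg <- sim_config(seed = 4)
  a <- simulate_ir_table(cfg, splicing_phase = 2, n_introns = 150)
  b <- simulate_ir_table(cfg, splicing_phase = 2, n_introns = 150)
  expect_identical(a, b)
  expect_error(simulate_ir_table(cfg, n_introns = 0), "positive")
  expect_error(simulate_ir_table(cfg, splicing_phase = 14), "splicing_phase")

  # strong rhythm, peak of retained counts at the planted phase mod 12
  big <- simulate_ir_table(cfg, splicing_phase = 4, n_introns = 500,
                           base_rate = 0.5, amplitude = 0.48)
  kept <- filter_retained(big)
  cnt <- tapply(rep(1, nrow(kept)), kept$time_h, sum)
  tph <- as.numeric(names(cnt)) %% 12
  folded <- tapply(as.numeric(cnt), tph, mean)
  expect_equal(as.numeric(names(which.max(folded))), 4)

  # amplitude 0: counts stay within binomial noise of a constant level
  flat <- simulate_ir_table(cfg, splicing_phase = 0, n_introns = 400,
                            amplitude = 0)
  kc <- tapply(rep(1, nrow(filter_retained(flat))),
               filter_retained(flat)$time_h, sum)
  expect_true(all(abs(kc - 200) < 4 * sqrt(400 * 0.25)))
})

test_that("conserved-set generator plants exact overlaps", {
  cs <- simulate_conserved_sets(1000, 800, 100, 120, 30, seed = 6)
  mapped <- cs$ortholog_map$human[match(cs$set_b, cs$ortholog_map$other)]
  ov <- intersect(intersect(mapped[!is.na(mapped)], cs$universe_a), cs$set_a)
  expect_length(ov, 30L)

  nest <- simulate_conserved_sets(500, 500, 40, 40, 40, seed = 1)
  mapped <- nest$ortholog_map$human[match(nest$set_b, nest$ortholog_map$other)]
  expect_setequal(mapped, nest$set_a)

  none <- simulate_conserved_sets(500, 500, 40, 40, 0, seed = 1)
  mapped <- none$ortholog_map$human[match(none$set_b, none$ortholog_map$other)]
  expect_length(intersect(mapped, none$set_a), 0L)

  expect_error(simulate_conserved_sets(100, 100, 10, 20, 15), "planted_overlap")
  expect_error(simulate_conserved_sets(100, 100, 90, 95, 0), "cannot place")
})
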