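test_that("tbp_statistic agrees with the brute-force Pearson oracle", {
  # a 10-transformed-value worked pair: t = r * sqrt(8) / sqrt(1 - r^2)
  a <- random_series(14L, 1600L, seed = 21)
  b <- random_series(14L, 1600L, seed = 22)
  got <- tbp_statistic(a, b)
  exp_ <- oracle_tbp(oracle_bp(a$widths), oracle_bp(b$widths))
  expect_equal(got$overlap, 10L)
  expect_equal(got$r, exp_$r, tolerance = 1e-12)
  expect_equal(got$t, exp_$r * sqrt(8) / sqrt(1 - exp_$r^2),
               tolerance = 1e-12)
})

test_that("tbp_statistic is symmetric and capped at self-match", {
  a <- random_series(50L, 1600L, seed = 31)
  b <- random_series(60L, 1610L, seed = 32)
  ab <- tbp_statistic(a, b); ba <- tbp_statistic(b, a)
  expect_equal(ab$r, ba$r); expect_equal(ab$t, ba$t)
  expect_equal(ab$overlap, ba$overlap)
  self <- tbp_statistic(a, a)
  expect_equal(self$r, 1)
  expect_equal(self$t, 9999)
})

test_that("tbp_statistic errors on tiny overlap and zero variance", {
  a <- random_series(20L, 1600L, seed = 41)
  b <- random_series(20L, 1700L, seed = 42)
  expect_error(tbp_statistic(a, b), "overlap")
  flat <- ring_series(rep(1, 20), 1600L)
  expect_error(tbp_statistic(flat, a), "zero variance")
})

test_that("glk_statistic matches the explicit sign-agreement oracle", {
  set.seed(55)
  for (i in 1:8) {
    n <- sample(20:120, 1)
    a <- random_series(n, 1600L)
    b <- random_series(n, 1600L)
    got <- glk_statistic(a, b)
    exp_ <- oracle_glk(sign(diff(a$widths)), sign(diff(b$widths)))
    expect_equal(got$glk, exp_$glk, tolerance = 1e-12)
    expect_equal(got$p, exp_$p, tolerance = 1e-12)
    expect_gte(got$glk, 0); expect_lte(got$glk, 100)
  }
})

test_that("glk handles the boundary cases and the printed approximation", {
  a <- ring_series(c(1, 2, 1, 3, 1, 4, 2, 5), 1600L)  # no tied intervals
  expect_equal(glk_statistic(a, a)$glk, 100)
  # a series against its difference-sign negation scores 0
  flipped <- ring_series(cumsum(c(2, -diff(a$widths))) + 3, 1600L)
  expect_equal(sign(diff(flipped$widths)), -sign(diff(a$widths)))
  expect_equal(glk_statistic(a, flipped)$glk, 0)
  # 63 agreements in 100 untied intervals: p = 1 - pnorm(2 * 0.13 * 10)
  up <- rep(c(1, -1), 50)
  agree <- c(rep(1, 63), rep(0, 37))
  sb <- ifelse(agree == 1, up, -up)
  wa <- cumsum(c(0, up * 0.1)) + 5
  wb <- cumsum(c(0, sb * 0.1)) + 5
  got <- glk_statistic(ring_series(wa, 1600L), ring_series(wb, 1600L))
  expect_equal(got$glk, 63)
  expect_equal(got$p, 1 - pnorm(2 * 0.13 * sqrt(100)), tolerance = 1e-12)
  expect_equal(got$significance_class, "p01")
})

test_that("ties score one half against a moving partner", {
  a <- ring_series(c(1, 1, 1, 1), 1600L)        # all ties
  b <- ring_series(c(1, 2, 3, 4), 1600L)        # all up
  expect_equal(glk_statistic(a, b)$glk, 50)
  expect_equal(glk_statistic(a, a)$glk, 0)      # both tied scores 0
})

test_that("a sample embedded verbatim in the reference dates itself", {
  set.seed(77)
  for (i in 1:5) {
    ref <- random_series(400L, 1650L, id = "REF")
    start <- sample(1:250, 1)
    cut <- ring_series(ref$widths[start:(start + 99L)],
                       last_year = 2000L, series_id = "CUT")
    true_end <- first_year(ref) + start + 98L
    res <- scan_offsets(cut, ref)
    expect_equal(res$end_year[1L], true_end)
    expect_equal(res$r[1L], 1)
    expect_equal(res$t_bp[1L], 9999)
    expect_equal(res$match_class[1L], "accepted")
  }
})

test_that("scan results are ranked and classified per policy", {
  sc <- synthetic_scenario(seed = 12)
  ref <- generate_master(sc)
  b <- generate_boards(sc)$boards[[1L]]
  pol <- match_policy()
  res <- scan_offsets(b, ref, pol)
  expect_gt(nrow(res), 500)
  expect_true(all(res$overlap >= pol$min_overlap_scan))
  expect_true(all(diff(res$t_bp) <= 1e-12))      # t descending
  expect_true(all(res$glk >= 0 & res$glk <= 100))
  expect_true(all(res$glk_p > 0 & res$glk_p <= 1))
  # classification consistent with the policy thresholds on every row
  acc <- res$t_bp >= pol$t_accepted & res$glk >= pol$glk_min &
    res$glk_p <= pol$glk_p_max
  pot <- !acc & res$t_bp >= pol$t_potential &
    res$overlap >= pol$min_overlap_potential
  expect_identical(res$match_class,
                   ifelse(acc, "accepted",
                          ifelse(pot, "potential", "no_match")))
  # a 4.49-strength match over >= 100 rings is "potential", not "accepted"
  mid <- res[res$t_bp >= 3.5 & res$t_bp < 5 &
             res$overlap >= 100 & res$glk_p > pol$glk_p_max, ]
  if (nrow(mid) > 0L)
    expect_true(all(mid$match_class == "potential"))
  # the crossdate() wrapper carries the same table
  fit <- crossdate(b, ref, pol)
  expect_s3_class(fit, "crossdate")
  expect_identical(fit$results, res)
  expect_output(print(fit), "accepted")
  expect_output(print(summary(fit)), "best: end year")
})

test_that("an empty scan is a zero-row table, not an error", {
  a <- random_series(60L, 1600L, seed = 91)
  short_ref <- random_series(40L, 1600L, seed = 92)
  expect_identical(nrow(scan_offsets(a, short_ref)), 0L)
})

test_that("same-tree boards are flagged; a disregard window is honoured", {
  pair <- same_tree_pair(101)
  res <- assess_same_tree(pair$clean, pair$reference)
  expect_true(res$same_tree)
  expect_equal(res$match_class, "same_tree_candidate")
  expect_gt(res$t_bp, 10)
  expect_equal(res$significance_class, "p001")
  # excluding an early span changes the overlap entering the statistics
  res2 <- assess_same_tree(pair$clean, pair$reference,
                          disregard = c(1397, 1427))
  expect_equal(res2$overlap_t, res$overlap_t - 29L)
  expect_true(res2$same_tree)
  # a series against itself is a trivially positive same-tree candidate
  self <- assess_same_tree(pair$clean, pair$clean)
  expect_equal(self$r, 1)
  expect_true(self$same_tree)
})

test_that("boards sharing only the master signal are not called same-tree", {
  wrong <- 0L
  for (i in 1:200) {
    sc <- synthetic_scenario(
      seed = 5000L + i,
      boards = data.frame(tree = c(1L, 2L), length = 210L,
                          end_year = 1606L, n_sapwood = 0L))
    gb <- generate_boards(sc)
    res <- assess_same_tree(gb$boards[[1L]], gb$boards[[2L]])
    if (res$same_tree) wrong <- wrong + 1L
  }
  expect_lte(wrong / 200, 0.05)
})
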