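poland <- sapwood_stats()  # 9/15/24 rings, 90% CI

test_that("sapwood statistics and seasoning presets validate their fields", {
  expect_equal(poland$sw_min, 9L)
  expect_equal(poland$sw_median, 15L)
  expect_equal(poland$sw_max, 24L)
  expect_equal(poland$confidence, 0.90)
  expect_error(sapwood_stats(sw_min = 10, sw_median = 9, sw_max = 24),
               "sw_min")
  expect_error(sapwood_stats(confidence = 1.2), "confidence")
  expect_equal(unclass(seasoning_policy(preset = "klein_1990s")),
               list(s_min = 2L, s_max = 2L))
  expect_equal(unclass(seasoning_policy(preset = "replication")),
               list(s_min = 2L, s_max = 5L))
  expect_error(seasoning_policy(4, 2), "s_min")
})

test_that("the heartwood/sapwood border year is the last ring minus sapwood", {
  expect_equal(hw_sw_border_year(1614, 8), 1606L)
  expect_equal(hw_sw_border_year(1700, 15), 1685L)
  expect_equal(hw_sw_border_year(1650, 0), 1650L)
  expect_error(hw_sw_border_year(1650, -1), "non-negative")
})

test_that("a dated heartwood/sapwood border gives the felling interval", {
  f <- estimate_felling(1606, "hw_sw_border", poland)
  expect_equal(f$kind, "interval")
  expect_equal(f$lower, 1615L)
  expect_equal(f$upper, 1630L)
  expect_equal(f$median_year, 1621L)
  expect_equal(f$confidence, 0.90)
})

test_that("heartwood-only boards get a terminus post quem", {
  f2 <- estimate_felling(1602, "heartwood_only", poland)
  expect_equal(f2$kind, "terminus_post_quem")
  expect_equal(f2$lower, 1611L)
  expect_true(is.na(f2$upper))
  f3 <- estimate_felling(1601, "heartwood_only", poland)
  expect_equal(f3$lower, 1610L)
})

test_that("bark edge fixes the felling year exactly", {
  f <- estimate_felling(1624, "bark_edge", poland)
  expect_equal(f$kind, "exact")
  expect_equal(f$lower, 1624L)
  expect_equal(f$upper, 1624L)
})

test_that("partial sapwood counts from the border, clamped to existing rings", {
  # 8 preserved sapwood rings ending 1614: border 1606, interval as hw/sw
  f <- estimate_felling(1614, "partial_sapwood", poland, n_sapwood = 8)
  expect_equal(c(f$lower, f$upper), c(1615L, 1630L))
  # 20 preserved sapwood rings: lower bound would predate the last measured
  # ring; clamp to last + 1
  g <- estimate_felling(1614, "partial_sapwood", poland, n_sapwood = 20)
  expect_equal(g$lower, 1615L)            # max(1614 + 1, 1594 + 9)
  expect_equal(g$upper, 1594L + 24L)
  expect_error(estimate_felling(1614, "partial_sapwood", poland),
               "positive n_sapwood")
})

test_that("production windows add the seasoning allowance", {
  f <- estimate_felling(1606, "hw_sw_border", poland)
  p <- estimate_production(f, seasoning_policy(2, 5))
  expect_equal(p$earliest_window, c(1617L, 1620L))
  expect_equal(p$likely_kind, "interval")
  expect_equal(c(p$likely_lower, p$likely_upper), c(1617L, 1635L))
  # the fixed 2-year 1990s allowance degenerates the earliest window
  p2 <- estimate_production(f, seasoning_policy(preset = "klein_1990s"))
  expect_equal(p2$earliest_window, c(1617L, 1617L))
  expect_equal(c(p2$likely_lower, p2$likely_upper), c(1617L, 1632L))
  # terminus post quem stays open above
  tpq <- estimate_production(estimate_felling(1601, "heartwood_only", poland),
                             seasoning_policy(2, 5))
  expect_equal(tpq$earliest_window, c(1612L, 1615L))
  expect_equal(tpq$likely_kind, "terminus_post_quem")
  expect_equal(tpq$likely_lower, 1612L)
  expect_true(is.na(tpq$likely_upper))
})

test_that("interval width always equals the sapwood range width", {
  for (y in c(1500L, 1606L, 1750L))
    for (st in list(poland, sapwood_stats("X", 5, 10, 30, 0.95))) {
      f <- estimate_felling(y, "hw_sw_border", st)
      expect_equal(f$upper - f$lower, st$sw_max - st$sw_min)
    }
})

test_that("all estimates shift equivariantly with the last ring year", {
  for (d in c(-120L, 1L, 37L)) {
    a <- estimate_felling(1606L, "hw_sw_border", poland)
    b <- estimate_felling(1606L + d, "hw_sw_border", poland)
    expect_equal(b$lower - a$lower, d)
    expect_equal(b$upper - a$upper, d)
    expect_equal(b$median_year - a$median_year, d)
    pa <- estimate_production(a, seasoning_policy(2, 5))
    pb <- estimate_production(b, seasoning_policy(2, 5))
    expect_equal(pb$earliest_window - pa$earliest_window, c(d, d))
    expect_equal(pb$likely_upper - pa$likely_upper, d)
  }
})

test_that("same-tree boards sharing a border year date identically", {
  # two boards of one tree: one ends at the border, the other carries 8
  # sapwood rings up to 1614; both imply border 1606 and identical estimates
  f_border <- estimate_felling(1606, "hw_sw_border", poland)
  f_partial <- estimate_felling(1614, "partial_sapwood", poland,
                                n_sapwood = 8)
  expect_equal(c(f_border$lower, f_border$upper),
               c(f_partial$lower, f_partial$upper))
  expect_equal(hw_sw_border_year(1614, 8), 1606L)
})
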