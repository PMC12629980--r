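test_that("scenario construction validates its parameters", {
  expect_error(synthetic_scenario(master_span = c(1600, 1650)), "100 years")
  expect_error(synthetic_scenario(ar1_phi = 1), "ar1_phi")
  expect_error(synthetic_scenario(tree_signal_share = 1.5), "share")
  expect_error(synthetic_scenario(
    boards = data.frame(tree = 1L, length = 600L, end_year = 1606L)),
    "inside the master span")
})

test_that("the generator is deterministic under its seed", {
  sc <- synthetic_scenario(seed = 99)
  expect_identical(generate_master(sc)$widths, generate_master(sc)$widths)
  a <- generate_boards(sc); b <- generate_boards(sc)
  expect_identical(lapply(a$boards, `[[`, "widths"),
                   lapply(b$boards, `[[`, "widths"))
  expect_identical(a$truth, b$truth)
  # a different seed gives different draws
  expect_false(identical(generate_master(synthetic_scenario(seed = 98))$widths,
                         generate_master(sc)$widths))
})

test_that("master persistence matches the requested AR(1) coefficient", {
  lag1 <- function(x) cor(x[-1], x[-length(x)])
  m0 <- generate_master(synthetic_scenario(seed = 5, ar1_phi = 0,
                                           master_span = c(1100L, 1599L)))
  expect_lt(abs(lag1(log(m0$widths))), 0.1)
  m5 <- generate_master(synthetic_scenario(seed = 6, ar1_phi = 0.5,
                                           master_span = c(1L, 5000L)))
  expect_lt(abs(lag1(log(m5$widths)) - 0.5), 0.05)
})

test_that("boards of one tree coincide when measurement noise is zero", {
  sc <- synthetic_scenario(
    seed = 8, measurement_sd = 0,
    boards = data.frame(tree = c(1L, 1L), length = 150L, end_year = 1600L,
                        n_sapwood = 0L))
  gb <- generate_boards(sc)
  expect_identical(gb$boards[[1L]]$widths, gb$boards[[2L]]$widths)
})

test_that("same-tree boards correlate above different-tree boards", {
  same_r <- diff_r <- numeric(100)
  for (i in 1:100) {
    sc <- synthetic_scenario(
      seed = 9000L + i,
      boards = data.frame(tree = c(1L, 1L, 2L), length = 150L,
                          end_year = 1600L, n_sapwood = 0L))
    gb <- generate_boards(sc)
    same_r[i] <- tbp_statistic(gb$boards[[1L]], gb$boards[[2L]])$r
    diff_r[i] <- tbp_statistic(gb$boards[[1L]], gb$boards[[3L]])$r
  }
  expect_gt(mean(same_r), mean(diff_r))
  expect_gt(mean(same_r), 0.9)
})

test_that("inter-board correlation rises with the master's variance share", {
  shares <- c(0.15, 0.45, 0.8)
  mean_r <- vapply(shares, function(sh) {
    r <- numeric(100)
    for (i in 1:100) {
      sc <- synthetic_scenario(
        seed = 20000L + i, tree_signal_share = sh,
        boards = data.frame(tree = c(1L, 2L), length = 150L,
                            end_year = 1600L, n_sapwood = 0L))
      gb <- generate_boards(sc)
      r[i] <- tbp_statistic(gb$boards[[1L]], gb$boards[[2L]])$r
    }
    mean(r)
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})

test_that("the study-like default scenario reproduces the panel structure", {
  gb <- generate_boards(synthetic_scenario(seed = 1))
  tr <- gb$truth
  expect_equal(tr$length, c(210L, 231L, 99L))
  expect_equal(tr$end_year, c(1606L, 1614L, 1601L))
  expect_equal(tr$first_year, c(1397L, 1384L, 1503L))
  expect_equal(tr$tree, c(1L, 1L, 2L))
  expect_equal(tr$n_sapwood, c(0L, 8L, 0L))
  expect_equal(tr$hw_sw_border_year[1:2], c(1606L, 1606L))
  expect_true(gb$boards[[1L]]$hw_sw_border_is_last_ring)
  expect_equal(gb$boards[[2L]]$n_sapwood, 8L)
  expect_true(all(vapply(gb$boards, function(b) all(b$widths > 0), TRUE)))
})

test_that("drawn sapwood counts honour the regional range", {
  counts <- integer(40)
  for (i in 1:40) {
    sc <- synthetic_scenario(
      seed = 31000L + i,
      boards = data.frame(tree = 1L, length = 120L, end_year = 1600L,
                          n_sapwood = NA_integer_))
    counts[i] <- generate_boards(sc)$truth$n_sapwood
  }
  expect_true(all(counts >= 9L & counts <= 24L))
  expect_gt(length(unique(counts)), 5L)   # actually a draw, not a constant
})

test_that("inject_errors implements the two slips start-anchored", {
  s <- random_series(100L, 1600L, seed = 17)
  expect_identical(inject_errors(s, data.frame(kind = character(0),
                                               year = integer(0))), s)
  d <- inject_errors(s, data.frame(kind = "doubled", year = 1550L))
  expect_equal(n_rings(d), 101L)
  expect_equal(d$last_year, 1601L)
  expect_equal(first_year(d), first_year(s))
  expect_equal(sum(d$widths), sum(s$widths))
  m <- inject_errors(s, data.frame(kind = "missing", year = 1550L))
  expect_equal(n_rings(m), 99L)
  expect_equal(m$last_year, 1599L)
  # the classic offsetting configuration: one ring too many and one too few
  both <- inject_errors(s, data.frame(kind = c("missing", "doubled"),
                                      year = c(1520L, 1570L)))
  expect_equal(n_rings(both), 100L)
  expect_equal(both$last_year, 1600L)
  expect_error(inject_errors(s, data.frame(kind = c("missing", "missing"),
                                           year = c(1550L, 1550L))),
               "distinct")
  expect_error(inject_errors(s, data.frame(kind = "missing", year = 1700L)),
               "outside")
})
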