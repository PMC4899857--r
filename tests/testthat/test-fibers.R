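test_that("micrometre conversion and fork speed arithmetic", {
  cfg <- fiber_config()
  expect_equal(um_to_kb(23.55, cfg), 47.1)
  expect_equal(um_to_kb(0, cfg), 0)
  expect_equal(um_to_kb(5, fiber_config(scale_kb_per_um = 1)), 5)
  expect_error(um_to_kb(-1, cfg), "negative")
  expect_equal(fork_speed(23.55, cfg), 1.570)
  expect_equal(fork_speed(0, cfg), 0)
  expect_equal(fork_speed(15, cfg), 1.0)
})

test_that("fork-pair classification uses the strict 33% rule", {
  expect_identical(classify_fork(10, 10), "symmetric")
  expect_identical(classify_fork(13.4, 10), "asymmetric")
  expect_identical(classify_fork(13.3, 10), "symmetric")  # ratio exactly 1.33
  expect_identical(classify_fork(0, 5), "asymmetric")
  expect_error(classify_fork(0, 0), "both sides zero")
  # symmetry in the two arguments, property-checked
  set.seed(5)
  l <- runif(50, 0.1, 30); r <- runif(50, 0.1, 30)
  expect_identical(classify_fork(l, r), classify_fork(r, l))
})

test_that("inter-origin distances come from initiating-segment centres", {
  # two origins centred at 10 kb and 112.6 kb (5 um and 56.3 um)
  tab <- data.frame(
    fiber_id = "f1", condition = "WT", segment_index = 1:5,
    label = c("none", "IdU", "none", "IdU", "none"),
    kind = c("gap", "initiating", "gap", "initiating", "gap"),
    length_um = c(4, 2, 49.3, 2, 10),
    stringsAsFactors = FALSE)
  expect_equal(inter_origin_distances(tab), 102.6)
  # single origin -> empty
  expect_length(inter_origin_distances(tab[1:2, ]), 0L)
  # three equally spaced origins at 0/50/100 kb (centres)
  tab3 <- data.frame(
    fiber_id = "f2", condition = "WT", segment_index = 1:5,
    label = c("IdU", "none", "IdU", "none", "IdU"),
    kind = c("initiating", "gap", "initiating", "gap", "initiating"),
    length_um = c(2, 23, 2, 23, 2),
    stringsAsFactors = FALSE)
  expect_equal(inter_origin_distances(tab3), c(50, 50))
  # sided initiating rows place the origin at the fork-divergence junction
  tabs <- data.frame(
    fiber_id = "f3", condition = "WT", segment_index = 1:5,
    label = c("IdU", "IdU", "none", "IdU", "IdU"),
    kind = rep(c("initiating", "gap", "initiating"), c(2, 1, 2)),
    length_um = c(3, 1, 16, 2, 4),
    origin_id = c("o1", "o1", NA, "o2", "o2"),
    side = c("left", "right", NA, "left", "right"),
    stringsAsFactors = FALSE)
  # junctions at 3 um and 22 um -> 19 um = 38 kb
  expect_equal(inter_origin_distances(tabs), 38)
})

test_that("mw_test matches exact enumeration and wilcox.test", {
  set.seed(61)
  for (i in 1:25) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- sample(1:10, n1, replace = TRUE)   # ties likely
    y <- sample(1:10, n2, replace = TRUE)
    expect_equal(mw_test(x, y)$p_value, oracle_mw_exact(x, y))
  }
  # tie-free small samples also agree with wilcox.test's exact p
  for (i in 1:10) {
    x <- sample(1:1000, 6); y <- sample(2000:3000, 5) + 0.5  # tie-free
    expect_equal(mw_test(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
  # large-sample path agrees with wilcox.test's corrected approximation
  x <- rnorm(40); y <- rnorm(35, 0.5)
  expect_equal(mw_test(x, y)$p_value,
               stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
  # identical samples are maximally insignificant
  expect_gte(mw_test(1:10, 1:10)$p_value, 0.99)
  expect_gte(mw_test(rep(1, 20), rep(1, 20))$p_value, 0.99)
})

test_that("summarize_conditions computes the toy asymmetry percentage", {
  mk <- function(fid, left, right) data.frame(
    fiber_id = fid, condition = "WT", segment_index = 1:3,
    label = c("CldU", "IdU", "CldU"),
    kind = c("elongating", "initiating", "elongating"),
    length_um = c(left, 1, right) / 2,   # kb -> um at 2 kb/um
    origin_id = paste0(fid, "_o1"), side = c("left", NA, "right"),
    stringsAsFactors = FALSE)
  tab <- rbind(mk("f1", 10, 10), mk("f2", 10, 10),
               mk("f3", 20, 10), mk("f4", 10, 10))
  s <- summarize_conditions(tab)
  expect_equal(s$per_condition$pct_asymmetric, 25)
  expect_equal(s$per_condition$n_fork_pairs, 4L)
  expect_equal(s$per_condition$pct_fibers_signal, 100)
  # identical conditions give non-significant rank tests
  tab2 <- tab; tab2$condition <- "KO"
  tab2$fiber_id <- sub("^f", "g", tab2$fiber_id)
  s2 <- summarize_conditions(rbind(tab, tab2), condition_a = "WT",
                             condition_b = "KO")
  expect_gte(s2$p_speed, 0.99)
  expect_error(summarize_conditions(tab, condition_a = "XX",
                                    condition_b = "WT"),
               "unknown condition")
})

test_that("rank statistics are invariant to the stretching constant", {
  tab <- simulate_fibers(fiber_sim_spec(n_fibers = 60, seed = 3),
                         condition = "WT")
  tab2 <- simulate_fibers(fiber_sim_spec(n_fibers = 60, speed_mean = 1.9,
                                         seed = 4), condition = "KO")
  both <- rbind(tab, tab2)
  s1 <- summarize_conditions(both, fiber_config(scale_kb_per_um = 2),
                             condition_a = "WT", condition_b = "KO")
  s4 <- summarize_conditions(both, fiber_config(scale_kb_per_um = 4),
                             condition_a = "WT", condition_b = "KO")
  expect_equal(s4$per_condition$median_speed_kb_min,
               2 * s1$per_condition$median_speed_kb_min)
  expect_equal(s4$per_condition$median_interorigin_kb,
               2 * s1$per_condition$median_interorigin_kb)
  expect_equal(s4$per_condition$pct_asymmetric,
               s1$per_condition$pct_asymmetric)
  expect_equal(s4$p_speed, s1$p_speed)
  expect_equal(s4$p_distance, s1$p_distance)
})

test_that("read/write fibre table round-trips and validates", {
  tab <- simulate_fibers(fiber_sim_spec(n_fibers = 10, seed = 12))
  f <- withr_local_tempfile()
  write_fiber_table(tab, f)
  back <- read_fiber_table(f)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$length_um, tab[order(tab$fiber_id, tab$segment_index),
                                   "length_um"])
  bad <- tab; bad$label[1] <- "EdU"
  write_fiber_table(bad, f)
  expect_error(read_fiber_table(f), "label")
})
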