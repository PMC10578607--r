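test_that("per-unit normalization divides by unit sums", {
  df <- data.frame(unit_id = "u1", instance_id = c("a", "b", "c"),
                   value = c(2, 3, 5))
  expect_equal(normalize_per_unit(df)$norm_value, c(0.2, 0.3, 0.5))
  one <- data.frame(unit_id = "u", instance_id = "a", value = 7)
  expect_equal(normalize_per_unit(one)$norm_value, 1)
  # random positive table: every unit sums to 1 within 1e-9, order preserved
  set.seed(1)
  big <- data.frame(unit_id = rep(sprintf("u%d", 1:20), each = 15),
                    instance_id = rep(sprintf("i%d", 1:15), 20),
                    value = runif(300, 0.1, 2))
  nb <- normalize_per_unit(big)
  sums <- tapply(nb$norm_value, nb$unit_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  for (u in c("u1", "u13")) {
    sub <- nb[nb$unit_id == u, ]
    expect_identical(order(sub$value), order(sub$norm_value))
  }
  df$value[2] <- 0
  expect_error(normalize_per_unit(df), "positive")
})

test_that("spearman_cor matches Pearson-on-midranks on all small inputs", {
  expect_equal(spearman_cor(1:5, 1:5)$rho, 1)
  expect_equal(spearman_cor(1:5, 5:1)$rho, -1)
  set.seed(2)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    x <- sample(1:4, n, replace = TRUE) + runif(n) * sample(0:1, 1)  # ties
    y <- rnorm(n)
    if (sd(x) == 0) next
    expect_equal(spearman_cor(x, y)$rho, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }
  expect_true(spearman_cor(rep(1, 5), 1:5)$undefined)
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
  expect_error(spearman_cor(1:4, 1:5), "equal length")
})

test_that("spearman_cor is invariant under monotone transforms", {
  set.seed(3)
  x <- rnorm(20); y <- rnorm(20)
  base <- spearman_cor(x, y)$rho
  expect_equal(spearman_cor(exp(x), y)$rho, base, tolerance = 1e-12)
  expect_equal(spearman_cor(x, 3 * y + 10)$rho, base, tolerance = 1e-12)
  # entropy base change is such a transform
  expect_equal(spearman_cor(x / log(2), y)$rho, base, tolerance = 1e-12)
})

test_that("correlation_report handles single nets and self-correlation", {
  rts <- normalize_per_unit(data.frame(
    unit_id = rep(c("p1", "p2"), each = 5),
    instance_id = rep(sprintf("i%d", 1:5), 2),
    value = c(0.3, 0.5, 0.4, 0.8, 0.6, 0.35, 0.45, 0.5, 0.75, 0.55)))
  mean_rt <- tapply(rts$norm_value, rts$instance_id, mean)
  conf <- data.frame(net_id = 1L, instance_id = names(mean_rt),
                     entropy = as.numeric(mean_rt))
  rep1 <- correlation_report(conf, rts)
  expect_equal(rep1$rho_of_means, 1)               # self-correlation
  expect_equal(rep1$per_net$rho, rep1$rho_of_means) # single net collapses
  expect_equal(rep1$n_items, 5)
  none <- data.frame(net_id = 1L, instance_id = "zz", entropy = 0.5)
  expect_error(correlation_report(none, rts), "no common instances")
})

test_that("comparison of correlation sets uses Fisher z and Welch t", {
  same <- compare_correlation_sets(c(0.4, 0.5, 0.45), c(0.45, 0.4, 0.5))
  expect_gt(same$p_value, 0.5)
  expect_identical(same$tier, "n.s.")
  set.seed(4)
  a <- rnorm(100, 0.4, 0.1); b <- rnorm(100, -0.2, 0.1)
  strong <- compare_correlation_sets(a, b, labels = c("hi", "lo"))
  expect_lt(strong$p_value, 0.001)
  expect_identical(strong$tier, "***")
  expect_identical(strong$condition_a, "hi")
  # agreement with a direct computation
  tt <- t.test(atanh(a), atanh(b))
  expect_equal(strong$t, unname(tt$statistic), tolerance = 1e-12)
  expect_error(compare_correlation_sets(0.5, c(0.1, 0.2)), "at least 2")
  clamped <- compare_correlation_sets(c(1, 0.5), c(0.2, 0.3))
  expect_true(clamped$clamped)
})

test_that("accuracy-set comparison is a plain Welch t-test with tiers", {
  same <- compare_accuracy_sets(c(0.8, 0.82, 0.81), c(0.81, 0.8, 0.82))
  expect_identical(same$tier, "n.s.")
  apart <- compare_accuracy_sets(c(0.9, 0.91, 0.92, 0.93),
                                 c(0.5, 0.51, 0.52, 0.53))
  expect_identical(apart$tier, "***")
  tt <- t.test(c(0.9, 0.91, 0.92, 0.93), c(0.5, 0.51, 0.52, 0.53))
  expect_equal(apart$p_value, tt$p.value)
  expect_error(compare_accuracy_sets(0.5, c(0.4, 0.6)), "at least 2")
})

test_that("significance tiers follow the caption convention exactly", {
  expect_identical(exemplaRT:::significance_tier(0.0005), "***")
  expect_identical(exemplaRT:::significance_tier(0.005), "**")
  expect_identical(exemplaRT:::significance_tier(0.03), "*")
  expect_identical(exemplaRT:::significance_tier(0.05), "n.s.")
  expect_identical(exemplaRT:::significance_tier(0.5), "n.s.")
})

test_that("crossed grids label cells by both factors", {
  set.seed(5)
  items <- sprintf("i%d", 1:8)
  mk_rts <- function(seed) {
    set.seed(seed)
    normalize_per_unit(data.frame(unit_id = rep(c("pa", "pb"), each = 8),
                                  instance_id = rep(items, 2),
                                  value = runif(16, 0.2, 1)))
  }
  mk_conf <- function(seed) {
    set.seed(seed)
    data.frame(net_id = rep(1:2, each = 8), instance_id = rep(items, 2),
               entropy = runif(16, 0.1, 1))
  }
  grid <- crossed_grid(list(good = mk_conf(1), bad = mk_conf(2)),
                       list(good = mk_rts(3), bad = mk_rts(4)))
  expect_setequal(names(grid), c("good/good", "good/bad", "bad/good", "bad/bad"))
  expect_s3_class(grid[["good/bad"]], "correlation_report")
  # 1x1 grid is equivalent to a direct correlation_report
  g1 <- crossed_grid(list(only = mk_conf(1)), list(only = mk_rts(3)))
  direct <- correlation_report(mk_conf(1), mk_rts(3))
  expect_equal(g1[["only/only"]]$rho_of_means, direct$rho_of_means)
  # empty cell inputs flag the cell but return the grid
  empty_rts <- data.frame(unit_id = character(), instance_id = character(),
                          norm_value = numeric())
  expect_warning(g2 <- crossed_grid(list(good = mk_conf(1)),
                                    list(good = mk_rts(3), none = empty_rts)),
                 "flagged")
  expect_null(g2[["good/none"]])
  expect_s3_class(g2[["good/good"]], "correlation_report")
})
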