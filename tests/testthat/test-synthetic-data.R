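test_that("prototype library is valid and bounded", {
  protos <- glyph_prototypes(4, 28, 28)
  expect_length(protos, 4)
  for (p in protos) {
    expect_true(all(p$coords[, 1] >= 1 & p$coords[, 1] <= 28))
    expect_true(all(p$coords[, 2] >= 1 & p$coords[, 2] <= 28))
  }
  # templates of distinct classes differ
  keys <- vapply(protos, function(p)
    paste(sort(paste(p$coords[, 1], p$coords[, 2])), collapse = ";"), "")
  expect_length(unique(keys), 4)
  expect_error(glyph_prototypes(5), "2..4", fixed = TRUE)
  expect_error(glyph_prototypes(2, 4, 4), "too small")
})

test_that("generate_instances returns K x n_per_class instances", {
  protos <- glyph_prototypes(4, 28, 28)
  gs <- generate_instances(protos, 20, 10, 8, seed = 1)
  expect_length(gs$instance_id, 80)
  expect_equal(as.integer(table(gs$class_label)), rep(20L, 4))
  expect_equal(dim(gs$pixels), c(28, 28, 80))
  expect_false(any(duplicated(gs$instance_id)))
})

test_that("zero deformation reproduces prototypes with tau = 1", {
  protos <- glyph_prototypes(4, 28, 28)
  gs <- generate_instances(protos, 3, deform_scale = 0, seed = 1)
  expect_true(all(gs$tau == 1))
  for (k in seq_along(gs$instance_id)) {
    proto <- protos[[gs$class_label[k]]]
    img <- matrix(0, 28, 28); img[proto$coords] <- 1
    expect_identical(gs$pixels[, , k], img)
  }
})

test_that("tau equals exp(-d/sigma) with d the realized flip count", {
  # independent re-implementation of the typicality rule: recompute d as the
  # Hamming distance between instance and prototype
  protos <- glyph_prototypes(4, 28, 28)
  sigma <- 7
  gs <- generate_instances(protos, 10, deform_scale = 3, sigma_tau = sigma,
                           seed = 42)
  d_oracle <- vapply(seq_along(gs$instance_id), function(k) {
    proto <- protos[[gs$class_label[k]]]
    img <- matrix(0, 28, 28); img[proto$coords] <- 1
    sum(img != gs$pixels[, , k])
  }, 0)
  expect_equal(gs$tau, exp(-d_oracle / sigma), tolerance = 1e-12)
  # per-class tau mean within tolerance of a direct re-simulation of the rule
  big <- generate_instances(protos, 200, deform_scale = 3, sigma_tau = sigma,
                            deform_shape = Inf, seed = 7)
  set.seed(123)
  expect_equal(mean(big$tau), mean(exp(-rpois(20000, 3) / sigma)),
               tolerance = 0.05)
})

test_that("generate_instances is deterministic under seed and validates input", {
  protos <- glyph_prototypes(3, 28, 28)
  a <- generate_instances(protos, 4, 10, 8, seed = 9)
  b <- generate_instances(protos, 4, 10, 8, seed = 9)
  expect_identical(a, b)
  expect_error(generate_instances(list(), 5), "empty prototype")
  expect_error(generate_instances(protos, 0), "n_per_class")
  expect_error(generate_instances(protos, 2, -1), "deform_scale")
  expect_error(generate_instances(protos, 2, 3, 5, deform_shape = 0),
               "deform_shape")
})

test_that("schedules contain every instance exactly `repeats` times", {
  gs <- tiny_world(20)
  s <- make_schedule(gs, repeats = 2, seed = 1)
  expect_length(s$instance_id, 160)
  s2 <- make_schedule(gs$instance_id[1:20], repeats = 2, seed = 1)
  expect_length(s2$instance_id, 40)
  s3 <- make_schedule("only_one", repeats = 1, seed = 1)
  expect_identical(s3$instance_id, "only_one")
  expect_error(make_schedule(character(0)), "empty")
  expect_error(make_schedule("x", repeats = 0), "repeats")
  expect_identical(make_schedule(gs, 2, seed = 3), make_schedule(gs, 2, seed = 3))
})

test_that("schedule multiset property holds up to n = 1000", {
  ids <- sprintf("i%04d", 1:1000)
  s <- make_schedule(ids, repeats = 3, seed = 11)
  expect_length(s$instance_id, 3000)
  expect_true(all(table(s$instance_id) == 3L))
  expect_setequal(unique(s$instance_id), ids)
})

test_that("simulated RTs respect the non-decision floor", {
  gs <- tiny_world(5)
  part <- sim_participant("p1", a = 0.1, ter = 0.3, beta = 2, lambda = 0)
  tr <- simulate_trials(make_schedule(gs, 2, seed = 1), part, gs, seed = 2)
  expect_equal(nrow(tr), 40)
  expect_true(all(tr$rt_sec >= 0.3))
  expect_true(all(tr$correct == (tr$response_class == tr$true_class)))
})

test_that("zero drift gives chance accuracy on the two-boundary diffusion", {
  gs <- tiny_world(5)
  part <- sim_participant("p1", a = 0.1, ter = 0.3, beta = 0, lambda = 0)
  sched <- make_schedule(rep(gs$instance_id, length.out = 4000), 1, seed = 1)
  tr <- simulate_trials(sched, part, gs, seed = 3)
  # upper-boundary hits should be Binomial(4000, 0.5)
  n_upper <- sum(tr$correct)
  expect_gt(binom.test(n_upper, 4000, 0.5)$p.value, 0.01)
})

test_that("simulated accuracy matches the closed-form hit probability", {
  protos <- glyph_prototypes(4, 28, 28)
  gs <- generate_instances(protos, 2, deform_scale = 0, seed = 1)  # tau == 1
  part <- sim_participant("p1", a = 0.1, ter = 0.3, beta = 3, lambda = 0)
  sched <- make_schedule(rep(gs$instance_id[1], 5000), 1, seed = 1)
  tr <- simulate_trials(sched, part, gs, seed = 4)
  expect_equal(mean(tr$correct), ddm_hit_probability(3, 0.1), tolerance = 0.03)
})

test_that("simulate_trials validates parameters and is deterministic", {
  gs <- tiny_world(3)
  sched <- make_schedule(gs, 1, seed = 1)
  expect_error(sim_participant("p", a = 0), "positive")
  bad_sched <- structure(list(instance_id = "nope", repeats = 1L),
                         class = "trial_schedule")
  expect_error(simulate_trials(bad_sched, sim_participant("p"), gs),
               "unknown instance")
  p <- sim_participant("p", a = 0.1, ter = 0.3, beta = 2, lambda = 0.1)
  expect_identical(simulate_trials(sched, p, gs, seed = 7),
                   simulate_trials(sched, p, gs, seed = 7))
})

test_that("cohort simulation is sized, sane, and deterministic", {
  gs <- tiny_world(20)
  rec <- simulate_cohort(3, default_participant_dists(), gs, 2, seed = 1)
  expect_equal(nrow(rec), 480)
  dists <- list(a = 0.1, ter = 0.3, beta = 10, lambda = 0)
  rec2 <- simulate_cohort(4, dists, gs, 2, seed = 2)
  expect_gt(mean(rec2$correct), 0.9)
  expect_identical(simulate_cohort(2, dists, gs, 1, seed = 5),
                   simulate_cohort(2, dists, gs, 1, seed = 5))
  expect_error(simulate_cohort(0, dists, gs), "n_participants")
})

test_that("accuracy increases and RT decreases with typicality", {
  protos <- glyph_prototypes(4, 28, 28)
  gs <- generate_instances(protos, 5, 30, 20, seed = 3)  # 20 instances
  rec <- simulate_cohort(50, default_participant_dists(), gs, 2, seed = 4)
  acc <- tapply(rec$correct, rec$instance_id, mean)[gs$instance_id]
  rt <- tapply(rec$rt_sec, rec$instance_id, mean)[gs$instance_id]
  expect_gt(cor(as.numeric(acc), gs$tau, method = "spearman"), 0.5)
  expect_lt(cor(as.numeric(rt), gs$tau, method = "spearman"), -0.5)
})

test_that("glyph_subset selects by id or index and preserves order", {
  gs <- tiny_world(3)
  ids <- gs$instance_id[c(5, 2, 9)]
  sub <- glyph_subset(gs, ids)
  expect_identical(sub$instance_id, ids)
  expect_identical(sub$pixels[, , 2], gs$pixels[, , 2])
  expect_error(glyph_subset(gs, "missing_id"), "unknown instance")
})
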