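make_scores <- function(n_per_class = 10, classes = 1:4, n_participants = 30,
                        seed = 1) {
  set.seed(seed)
  rows <- lapply(classes, function(cl) {
    data.frame(instance_id = sprintf("c%d_i%03d", cl, seq_len(n_per_class)),
               class_label = cl,
               mean_rank = seq_len(n_per_class),
               t_stat = seq(-3, 3, length.out = n_per_class),
               p_value = runif(n_per_class, 0.001, 0.9),
               direction = rep(c("easy", "hard"), each = n_per_class / 2),
               mean_correct = 2, n_zero_correct = 0L, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_participants") <- n_participants
  class(out) <- c("instance_scores", "data.frame")
  out
}

test_that("curate_extreme picks k most significant per class in direction", {
  sc <- make_scores()
  good <- curate_extreme(sc, 5, "good")
  expect_length(curated_members(good), 20)
  expect_true(all(vapply(good$members, length, 1L) == 5))
  # members must be easy-direction and the smallest p-values among them
  for (cl in 1:4) {
    cand <- sc[sc$class_label == cl & sc$direction == "easy", ]
    expect_setequal(good$members[[as.character(cl)]],
                    cand$instance_id[order(cand$p_value)][1:5])
  }
  # k = 1 -> argmin p per class
  bad1 <- curate_extreme(sc, 1, "bad")
  for (cl in 1:4) {
    cand <- sc[sc$class_label == cl & sc$direction == "hard", ]
    expect_identical(bad1$members[[as.character(cl)]],
                     cand$instance_id[which.min(cand$p_value)])
  }
  expect_error(curate_extreme(sc, 6, "good"), "curation error")
})

test_that("never-correct candidates are excluded from the good set", {
  sc <- make_scores(n_per_class = 12)  # 6 easy / 6 hard per class
  # the most significant easy candidate in class 1 was never answered correctly
  cand <- sc[sc$class_label == 1 & sc$direction == "easy", ]
  top <- cand$instance_id[which.min(cand$p_value)]
  sc$n_zero_correct[sc$instance_id == top] <- attr(sc, "n_participants")
  good <- curate_extreme(sc, 5, "good")
  expect_false(top %in% curated_members(good))
  expect_length(curated_members(good), 20)  # replaced, size unchanged
  # the bad set applies no such rule
  sc2 <- make_scores(n_per_class = 12)
  candh <- sc2[sc2$class_label == 1 & sc2$direction == "hard", ]
  toph <- candh$instance_id[which.min(candh$p_value)]
  sc2$n_zero_correct[sc2$instance_id == toph] <- attr(sc2, "n_participants")
  expect_true(toph %in% curated_members(curate_extreme(sc2, 5, "bad")))
})

test_that("random curation is uniform, seeded, and sized", {
  gs <- tiny_world(8)
  r1 <- curate_random(gs, 5, seed = 3)
  expect_length(curated_members(r1), 20)
  expect_identical(r1, curate_random(gs, 5, seed = 3))
  # k = all instances in a class -> the full class roster
  rall <- curate_random(gs, 8, seed = 1)
  expect_setequal(rall$members[["2"]], gs$instance_id[gs$class_label == 2])
  expect_error(curate_random(gs, 9), "curation error")
  # full set contains everything
  expect_setequal(curated_members(curate_full(gs)), gs$instance_id)
})

test_that("response entropy matches the direct definition", {
  expect_equal(response_entropy(c(12, 0, 0, 0)), 0)
  expect_equal(response_entropy(c(3, 3, 3, 3)), log(4), tolerance = 1e-12)
  expect_equal(response_entropy(c(6, 2, 1, 1)), oracle_entropy(c(6, 2, 1, 1)),
               tolerance = 1e-12)
  expect_error(response_entropy(c(-1, 2)), "negative")
  expect_error(response_entropy(c(0, 0)), "total")
  # bounds [0, ln K] over random tallies
  set.seed(9)
  for (i in 1:200) {
    K <- sample(2:10, 1)
    counts <- rpois(K, 3); counts[1] <- counts[1] + 1
    H <- response_entropy(counts)
    expect_gte(H, 0); expect_lte(H, log(K) + 1e-12)
  }
})

test_that("confidence selection equals independent sort-then-slice", {
  set.seed(4)
  n_cl <- 10; per_cl <- 120
  ids <- sprintf("it%04d", seq_len(n_cl * per_cl))
  labels <- setNames(rep(seq_len(n_cl), each = per_cl), ids)
  counts <- matrix(rpois(length(ids) * n_cl, 2) + 1, ncol = n_cl)
  dists <- data.frame(item_id = ids, counts)
  high <- select_by_confidence(dists, labels, 100, "high")
  expect_length(curated_members(high), 1000)
  H <- apply(counts, 1, oracle_entropy)
  for (cl in seq_len(n_cl)) {
    in_cl <- which(labels[ids] == cl)
    pick <- in_cl[order(H[in_cl])][1:100]
    expect_setequal(high$members[[as.character(cl)]], ids[pick])
  }
  low <- select_by_confidence(dists, labels, 3, "low")
  for (cl in seq_len(n_cl)) {
    in_cl <- which(labels[ids] == cl)
    expect_setequal(low$members[[as.character(cl)]],
                    ids[in_cl[order(-H[in_cl])][1:3]])
  }
})

test_that("zero-entropy items are selected first for high confidence", {
  ids <- c("a", "b", "c", "d")
  dists <- data.frame(item_id = ids,
                      k1 = c(10, 5, 9, 2), k2 = c(0, 5, 1, 8))
  labels <- setNames(rep(1L, 4), ids)
  sel <- select_by_confidence(dists, labels, 2, "high")
  expect_true("a" %in% curated_members(sel))  # H = 0 item always in
  expect_error(select_by_confidence(dists, labels, 5), "curation error")
})

test_that("augmentation yields exactly 27 variants per source", {
  gs <- tiny_world(5)  # 20 instances
  aug <- augment_images(gs)
  expect_length(aug$labels, 540)
  expect_equal(dim(aug$pixels)[3], 540)
  # identity variant is pixel-equal to the (binarized) source
  for (i in c(1, 7, 20)) {
    idx <- which(aug$parent_id == gs$instance_id[i] & aug$dx == 0 &
                   aug$dy == 0 & aug$theta == 0)
    expect_length(idx, 1)
    expect_equal(aug$pixels[, , idx], (gs$pixels[, , i] >= 0.5) + 0)
  }
})

test_that("320 sources augment to 8640 items", {
  protos <- glyph_prototypes(4, 28, 28)
  gs <- generate_instances(protos, 80, 10, 8, seed = 2)  # 320 instances
  aug <- augment_images(gs)
  expect_length(aug$labels, 8640)
})

test_that("an all-background image is invariant under all 27 transforms", {
  store <- list(instance_id = "z", class_label = 1L,
                pixels = array(0, dim = c(28, 28, 1)),
                n_classes = 4L, H = 28L, W = 28L)
  class(store) <- "glyph_set"
  aug <- augment_images(store)
  expect_equal(dim(aug$pixels)[3], 27)
  expect_true(all(aug$pixels == 0))
})

test_that("shift translates the foreground set with border cropping", {
  img <- matrix(0, 28, 28); img[1, 1] <- 1; img[15, 15] <- 1
  # shift up-left: the corner pixel falls off, the middle one moves
  out <- exemplaRT:::shift_binary(img, -1, -1)
  expect_equal(sum(out), 1)
  expect_equal(out[14, 14], 1)
  # zero rotation is the identity
  expect_identical(exemplaRT:::rotate_binary(img, 0), img)
  # rotation by +10 then -10 keeps the pixel count approximately (NN resample)
  rot <- exemplaRT:::rotate_binary(img, 10)
  expect_true(all(rot %in% c(0, 1)))
})
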