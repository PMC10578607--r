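new_curated_set <- function(label, members, provenance, k_per_class) {
  structure(list(label = label, members = members, provenance = provenance,
                 k_per_class = k_per_class), class = "curated_set")
}

#' @export
print.curated_set <- function(x, ...) {
  cat(sprintf("curated_set '%s': %d members (%s per class)\n", x$label,
              length(unlist(x$members)),
              paste(vapply(x$members, length, 1L), collapse = "/")))
  invisible(x)
}

#' All member ids of a curated set
#' @param set a `curated_set`.
#' @return character vector of instance ids.
#' @export
curated_members <- function(set) unname(unlist(set$members))

#' Curate the good or bad training set from instance scores
#'
#' Per class, takes the `k_per_class` instances with the smallest t-test
#' p-value among those ranked in the requested direction (`"good"` = easy,
#' mean rank below the class average; `"bad"` = hard). For the good set, any
#' candidate that was never answered correctly by any participant is
#' disqualified (its fast responses cannot reflect ease of correct
#' identification) and replaced by the next most significant candidate.
#'
#' @param scores an `instance_scores` data.frame from [score_instances()].
#' @param k_per_class members per class.
#' @param which `"good"` or `"bad"`.
#' @return a `curated_set` with per-member p-values as provenance.
#' @export
curate_extreme <- function(scores, k_per_class, which = c("good", "bad")) {
  which <- match.arg(which)
  n_part <- attr(scores, "n_participants")
  dir_wanted <- if (which == "good") "easy" else "hard"
  members <- list(); prov <- list()
  for (cl in sort(unique(scores$class_label))) {
    cand <- scores[scores$class_label == cl & scores$direction == dir_wanted &
                     !scores$degenerate, , drop = FALSE]
    if (which == "good" && !is.null(n_part))
      cand <- cand[cand$n_zero_correct < n_part, , drop = FALSE]
    cand <- cand[order(cand$p_value), , drop = FALSE]
    if (nrow(cand) < k_per_class)
      stopf("curation error: class %s has only %d %s candidate(s), need %d",
            cl, nrow(cand), which, k_per_class)
    sel <- cand[seq_len(k_per_class), ]
    members[[as.character(cl)]] <- sel$instance_id
    prov[[as.character(cl)]] <- sel$p_value
  }
  new_curated_set(which, members,
                  data.frame(instance_id = unlist(members),
                             p_value = unlist(prov), row.names = NULL),
                  k_per_class)
}

#' Curate a random training set
#'
#' Uniform without-replacement draw of `k_per_class` instances per class.
#'
#' @param instances a `glyph_set`.
#' @param k_per_class members per class.
#' @param seed integer seed or `NULL`.
#' @return a `curated_set` labeled `"random"`.
#' @export
curate_random <- function(instances, k_per_class, seed = NULL) {
  with_seed(seed, {
    members <- list()
    for (cl in sort(unique(instances$class_label))) {
      ids <- instances$instance_id[instances$class_label == cl]
      if (length(ids) < k_per_class)
        stopf("curation error: class %s has only %d instance(s), need %d",
              cl, length(ids), k_per_class)
      members[[as.character(cl)]] <- sample(ids, k_per_class)
    }
    new_curated_set("random", members,
                    data.frame(instance_id = unlist(members), row.names = NULL),
                    k_per_class)
  })
}

#' The full training set (all instances)
#' @param instances a `glyph_set`.
#' @return a `curated_set` labeled `"full"` containing every instance.
#' @export
curate_full <- function(instances) {
  members <- split(instances$instance_id, instances$class_label)
  new_curated_set("full", members,
                  data.frame(instance_id = unlist(members), row.names = NULL),
                  NA_integer_)
}

#' Shannon entropy of a response-count vector
#'
#' `H = -sum p_k log p_k` in nats with `p_k = count_k / total` and
#' `0 * log 0 = 0`. Bounded by `[0, log K]`.
#'
#' @param counts non-negative per-class tallies, total >= 1.
#' @return entropy in nats.
#' @export
response_entropy <- function(counts) {
  if (any(counts < 0)) stopf("negative counts")
  total <- sum(counts)
  if (total <= 0) stopf("total count must be >= 1")
  p <- counts / total
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Select items by response-distribution confidence
#'
#' Per class, picks the `k_per_class` items with the lowest entropy
#' (`which = "high"`, confident responses) or the highest entropy
#' (`which = "low"`). Ties are broken by item order.
#'
#' @param dists data.frame with `item_id` and per-class count columns, or a
#'   list of `list(item_id=, counts=)`.
#' @param labels named vector mapping `item_id` to class.
#' @param k_per_class members per class.
#' @param which `"high"` or `"low"`.
#' @return a `curated_set` with per-member entropies as provenance.
#' @export
select_by_confidence <- function(dists, labels, k_per_class,
                                 which = c("high", "low")) {
  which <- match.arg(which)
  if (is.data.frame(dists)) {
    ids <- dists$item_id
    cnt <- as.matrix(dists[setdiff(names(dists), "item_id")])
    H <- apply(cnt, 1L, response_entropy)
  } else {
    ids <- vapply(dists, `[[`, "", "item_id")
    H <- vapply(dists, function(d) response_entropy(d$counts), 0)
  }
  cls <- labels[ids]
  if (anyNA(cls)) stopf("item(s) without a class label: %s",
                        paste(ids[is.na(cls)][1], collapse = ", "))
  members <- list(); prov <- list()
  for (cl in sort(unique(cls))) {
    in_cl <- base::which(cls == cl)
    if (length(in_cl) < k_per_class)
      stopf("curation error: class %s has only %d item(s), need %d",
            cl, length(in_cl), k_per_class)
    # stable sort: ties broken by item order
    o <- in_cl[order(if (which == "high") H[in_cl] else -H[in_cl])]
    sel <- o[seq_len(k_per_class)]
    members[[as.character(cl)]] <- ids[sel]
    prov[[as.character(cl)]] <- H[sel]
  }
  new_curated_set(paste0(which, "_conf"), members,
                  data.frame(item_id = unlist(members),
                             entropy = unlist(prov), row.names = NULL),
                  k_per_class)
}

# nearest-neighbour rotation about the image centre, rebinarized at 0.5
rotate_binary <- function(img, degrees) {
  if (degrees == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  th <- degrees * pi / 180
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  r <- matrix(seq_len(H), H, W) - cr
  c <- matrix(rep(seq_len(W), each = H), H, W) - cc
  # inverse mapping: target (r,c) samples source rotated by -theta
  sr <- round(cos(th) * r - sin(th) * c + cr)
  sc <- round(sin(th) * r + cos(th) * c + cc)
  out <- matrix(0, H, W)
  ok <- sr >= 1 & sr <= H & sc >= 1 & sc <= W
  out[ok] <- img[cbind(sr[ok], sc[ok])]
  (out >= 0.5) + 0
}

# translate the foreground-pixel set; content shifted past the border is
# dropped, vacated pixels become background
shift_binary <- function(img, dy, dx) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  src_r <- max(1, 1 - dy):min(H, H - dy)
  src_c <- max(1, 1 - dx):min(W, W - dx)
  out[src_r + dy, src_c + dx] <- img[src_r, src_c]
  out
}

#' Shift-and-rotation augmentation
#'
#' For every source image, produces all 27 combinations of a one-pixel shift
#' (`dx, dy` in -1/0/+1, nine shifts) and a rotation by -10, 0, or +10 degrees
#' (rotation applied first, nearest-neighbour resampling, rebinarized at 0.5).
#' The identity transform is always included, so `|augment(S)| = 27 |S|`.
#' Images are binarized at 0.5 before transforming.
#'
#' @param images a `glyph_set` (typically a curated subset via [glyph_subset()]).
#' @return an `augmented_set`: list with `pixels` (`H x W x 27n`), `labels`,
#'   `parent_id`, `dx`, `dy`, `theta`.
#' @export
augment_images <- function(images) {
  n <- length(images$instance_id)
  H <- images$H; W <- images$W
  grid <- expand.grid(theta = c(-10, 0, 10), dx = -1:1, dy = -1:1)
  out <- array(0, dim = c(H, W, 27L * n))
  labels <- integer(27L * n); parent <- character(27L * n)
  k <- 0L
  for (i in seq_len(n)) {
    img <- (images$pixels[, , i] >= 0.5) + 0
    for (g in seq_len(nrow(grid))) {
      k <- k + 1L
      rot <- rotate_binary(img, grid$theta[g])
      out[, , k] <- shift_binary(rot, grid$dy[g], grid$dx[g])
      labels[k] <- images$class_label[i]
      parent[k] <- images$instance_id[i]
    }
  }
  structure(list(pixels = out, labels = labels, parent_id = parent,
                 dx = rep(grid$dx, n), dy = rep(grid$dy, n),
                 theta = rep(grid$theta, n), H = H, W = W,
                 n_classes = images$n_classes),
            class = "augmented_set")
}

#' @export
print.augmented_set <- function(x, ...) {
  cat(sprintf("augmented_set: %d items (27 x %d sources), %dx%d px\n",
              length(x$labels), length(x$labels) / 27L, x$H, x$W))
  invisible(x)
}
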