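#' Built-in glyph prototypes
#'
#' Returns simple stroke templates ("bar", "cross", "ell", "ring") on an
#' `H` x `W` binary grid. Each prototype is the canonical, undeformed shape of
#' one stimulus class; instances are produced by [generate_instances()], which
#' flips pixels near the stroke to create graded typicality.
#'
#' @param n_classes number of classes (2 to 4; the built-in library has 4).
#' @param H,W grid dimensions in pixels.
#' @return A list of prototypes, each a list with `class_label` (integer) and
#'   `coords` (two-column matrix of row/column stroke pixels, 1-based).
#' @export
glyph_prototypes <- function(n_classes = 4L, H = 28L, W = 28L) {
  if (n_classes < 2L || n_classes > 4L)
    stopf("built-in prototype library supports 2..4 classes, got %d", n_classes)
  if (H < 12L || W < 12L) stopf("grid too small for glyph strokes (min 12x12)")
  m <- function() matrix(0L, H, W)
  top <- max(3L, round(0.18 * H)); bot <- min(H - 2L, round(0.82 * H))
  lef <- max(3L, round(0.18 * W)); rig <- min(W - 2L, round(0.82 * W))
  midr <- round(H / 2); midc <- round(W / 2)
  as_coords <- function(img) which(img == 1L, arr.ind = TRUE)

  # stroke sizes are deliberately balanced (~70 px each) so that equal-weight
  # deletion deforms all classes at a comparable rate
  bar <- m(); bar[top:bot, midc + (-1:2)] <- 1L
  cross <- m(); cross[top:bot, midc + (0:1)] <- 1L; cross[midr + (0:1), lef:rig] <- 1L
  ell <- m(); ell[top:bot, lef + (0:1)] <- 1L; ell[bot - (0:1), lef:rig] <- 1L
  ring <- m()
  ring[top, lef:rig] <- 1L; ring[bot, lef:rig] <- 1L
  ring[top:bot, lef] <- 1L; ring[top:bot, rig] <- 1L

  shapes <- list(bar, cross, ell, ring)[seq_len(n_classes)]
  protos <- lapply(seq_along(shapes), function(i) {
    structure(list(class_label = i, coords = as_coords(shapes[[i]]), H = H, W = W),
              class = "glyph_prototype")
  })
  protos
}

# deformation pool: the own stroke (flips here erase class evidence) and the
# union of the other classes' strokes excluding shared pixels (flips here add
# spurious evidence). Each deformation event is a deletion with probability
# 1/2 and a spurious addition with probability 1/2, implemented as weights in
# a without-replacement draw, so heavy deformation erases the glyph while
# scattering fragments of the alternatives - genuinely ambiguous, not merely
# noisy, which is what makes some exemplars hard for humans and classifiers
# alike.
deform_candidates <- function(coords, H, W, other_coords = NULL) {
  own <- unique(coords)
  pool <- own; w <- rep(1 / nrow(own), nrow(own))
  if (!is.null(other_coords) && nrow(other_coords)) {
    oth <- unique(other_coords)
    shared <- paste(oth[, 1], oth[, 2]) %in% paste(own[, 1], own[, 2])
    oth <- oth[!shared, , drop = FALSE]
    if (nrow(oth)) {
      pool <- rbind(own, oth)
      w <- c(rep(0.5 / nrow(own), nrow(own)), rep(0.5 / nrow(oth), nrow(oth)))
    }
  }
  list(pix = pool, w = w)
}

#' Generate glyph instances with graded typicality
#'
#' Each instance starts from its class prototype and has `d` pixels flipped
#' (0 <-> 1), drawn without replacement from the deformation
#' pool: the own stroke pixels (a flip here erases class evidence) and the
#' stroke pixels of the other classes (a flip here adds spurious evidence).
#' Deletions and spurious additions are equally weighted regardless of pool
#' sizes, so heavy deformation erases the glyph while scattering fragments of
#' the alternatives - heavily deformed instances are genuinely ambiguous
#' rather than merely noisy. Typicality is `tau = exp(-d / sigma_tau)`
#' with `d` the realized number of flipped pixels, so `tau = 1` iff the instance
#' equals its prototype and `tau` decreases strictly with deformation.
#'
#' The flip count is overdispersed: `d ~ Poisson(rate)` with
#' `rate ~ Gamma(deform_shape, mean = deform_scale)` (a negative binomial),
#' because exemplar quality in handwriting-like material varies far more than
#' a Poisson allows - most exemplars are clean while some are badly deformed.
#' `deform_shape = Inf` recovers the pure Poisson.
#'
#' @param prototypes list from [glyph_prototypes()].
#' @param n_per_class instances per class (>= 1).
#' @param deform_scale mean pixel-flip count (>= 0).
#' @param sigma_tau scale (pixels) of the typicality decay; default 5.
#' @param deform_shape Gamma shape of the flip-rate mixture (> 0, or `Inf`
#'   for Poisson); smaller = more overdispersed.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return A `glyph_set`: list with `instance_id`, `class_label`, `tau`
#'   (numeric vectors of length n), `pixels` (`H x W x n` array in `[0,1]`),
#'   `n_classes`, `H`, `W`.
#' @export
generate_instances <- function(prototypes, n_per_class, deform_scale = 3,
                               sigma_tau = 5, deform_shape = 2, seed = NULL) {
  if (length(prototypes) == 0L) stopf("empty prototype list")
  if (n_per_class < 1L) stopf("n_per_class must be >= 1")
  if (deform_scale < 0) stopf("deform_scale must be >= 0")
  if (deform_shape <= 0) stopf("deform_shape must be positive")
  H <- prototypes[[1]]$H; W <- prototypes[[1]]$W
  K <- length(prototypes)
  with_seed(seed, {
    n <- K * n_per_class
    pix <- array(0, dim = c(H, W, n))
    id <- character(n); lab <- integer(n); tau <- numeric(n)
    k <- 0L
    for (p in prototypes) {
      base <- matrix(0, H, W)
      base[p$coords] <- 1
      others <- do.call(rbind, lapply(prototypes, function(q)
        if (q$class_label == p$class_label) NULL else q$coords))
      cand <- deform_candidates(p$coords, H, W, others)
      for (i in seq_len(n_per_class)) {
        k <- k + 1L
        rate <- if (is.finite(deform_shape) && deform_scale > 0)
          rgamma(1L, shape = deform_shape,
                 scale = deform_scale / deform_shape)
        else deform_scale
        d <- rpois(1L, rate)
        d <- min(d, nrow(cand$pix))
        img <- base
        if (d > 0L) {
          sel <- cand$pix[sample.int(nrow(cand$pix), d, prob = cand$w), ,
                          drop = FALSE]
          img[sel] <- 1 - img[sel]
        }
        pix[, , k] <- img
        id[k] <- sprintf("c%d_i%03d", p$class_label, i)
        lab[k] <- p$class_label
        tau[k] <- exp(-d / sigma_tau)
      }
    }
    structure(list(instance_id = id, class_label = lab, tau = tau,
                   pixels = pix, n_classes = K, H = H, W = W),
              class = "glyph_set")
  })
}

#' @export
print.glyph_set <- function(x, ...) {
  cat(sprintf("glyph_set: %d instances, %d classes, %dx%d px, mean tau %.3f\n",
              length(x$instance_id), x$n_classes, x$H, x$W, mean(x$tau)))
  invisible(x)
}

#' Subset a glyph set by instance id or index
#' @param x a `glyph_set`.
#' @param ids character instance ids or integer indices.
#' @return A `glyph_set` restricted to the selected instances, in the given order.
#' @export
glyph_subset <- function(x, ids) {
  idx <- if (is.character(ids)) match(ids, x$instance_id) else as.integer(ids)
  if (anyNA(idx)) stopf("unknown instance id(s): %s",
                        paste(ids[is.na(idx)], collapse = ", "))
  structure(list(instance_id = x$instance_id[idx], class_label = x$class_label[idx],
                 tau = x$tau[idx], pixels = x$pixels[, , idx, drop = FALSE],
                 n_classes = x$n_classes, H = x$H, W = x$W),
            class = "glyph_set")
}

#' Build a randomized trial schedule
#'
#' Every instance appears exactly `repeats` times, in a seeded random order —
#' the within-participant schedule of the behavioral task (80 instances x 2
#' presentations = 160 trials at the defaults).
#'
#' @param instances a `glyph_set` or a character vector of instance ids.
#' @param repeats presentations per instance (>= 1).
#' @param seed integer seed or `NULL`.
#' @return A `trial_schedule`: list with `instance_id` (ordered) and `repeats`.
#' @export
make_schedule <- function(instances, repeats = 2L, seed = NULL) {
  ids <- if (inherits(instances, "glyph_set")) instances$instance_id else instances
  if (length(ids) == 0L) stopf("empty instance list")
  if (repeats < 1L) stopf("repeats must be >= 1")
  with_seed(seed, {
    sched <- sample(rep(ids, times = repeats))
    structure(list(instance_id = sched, repeats = as.integer(repeats)),
              class = "trial_schedule")
  })
}

#' Construct a simulated participant
#'
#' @param participant_id identifier string.
#' @param a boundary separation (evidence units, > 0).
#' @param ter non-decision time in seconds (>= 0).
#' @param beta drift gain: drift for instance i is `v_i = beta * tau_i` (1/s per
#'   unit typicality).
#' @param lambda lapse rate in `[0, 1)`: probability the response is replaced by
#'   a uniformly random class label (the diffusion RT is kept).
#' @return A `sim_participant` list.
#' @export
sim_participant <- function(participant_id, a = 0.1, ter = 0.3, beta = 3,
                            lambda = 0) {
  if (a <= 0) stopf("boundary separation must be positive")
  if (ter < 0) stopf("non-decision time must be non-negative")
  if (lambda < 0 || lambda >= 1) stopf("lapse rate must be in [0, 1)")
  structure(list(participant_id = participant_id, a = a, ter = ter,
                 beta = beta, lambda = lambda), class = "sim_participant")
}

#' Simulate one participant's trials
#'
#' Reaction times and choices come from a two-boundary drift-diffusion process:
#' start point `a/2`, diffusion coefficient `s = 0.1`, Euler step `dt` = 1 ms.
#' Only the drift varies by stimulus, `v_i = beta * tau_i`; the upper boundary
#' is the correct response and lower-boundary errors pick uniformly among the
#' K - 1 wrong labels. With probability `lambda` the response class is replaced
#' by a uniform random label (RT unchanged). RT = first-passage time + `ter`.
#'
#' @param schedule a `trial_schedule`.
#' @param participant a `sim_participant`.
#' @param instances the `glyph_set` the schedule ids refer to.
#' @param seed integer seed or `NULL`.
#' @param dt,s Euler step (s) and diffusion coefficient.
#' @param drift_by_instance optional named numeric vector of per-instance
#'   drifts overriding `beta * tau` (used when drift reflects learned
#'   similarity rather than typicality).
#' @return data.frame with columns `participant_id`, `trial_index`,
#'   `instance_id`, `true_class`, `response_class`, `rt_sec`, `correct`.
#' @export
simulate_trials <- function(schedule, participant, instances, seed = NULL,
                            dt = 1e-3, s = 0.1, drift_by_instance = NULL) {
  idx <- match(schedule$instance_id, instances$instance_id)
  if (anyNA(idx)) stopf("schedule contains unknown instance id(s)")
  if (participant$a <= 0) stopf("boundary separation must be positive")
  K <- instances$n_classes
  with_seed(seed, {
    v <- if (is.null(drift_by_instance)) participant$beta * instances$tau[idx]
         else {
           dv <- drift_by_instance[schedule$instance_id]
           if (anyNA(dv)) stopf("drift_by_instance missing some scheduled ids")
           unname(dv)
         }
    fp <- ddm_first_passage_cpp(v, participant$a, participant$ter, s, dt, 30)
    true_class <- instances$class_label[idx]
    n <- length(idx)
    resp <- true_class
    err <- which(!fp$upper)
    if (length(err)) {
      # uniform draw among the K-1 wrong labels
      shift <- sample.int(K - 1L, length(err), replace = TRUE)
      resp[err] <- ((true_class[err] - 1L + shift) %% K) + 1L
    }
    lapse <- which(runif(n) < participant$lambda)
    if (length(lapse)) resp[lapse] <- sample.int(K, length(lapse), replace = TRUE)
    data.frame(participant_id = participant$participant_id,
               trial_index = seq_len(n),
               instance_id = schedule$instance_id,
               true_class = true_class,
               response_class = resp,
               rt_sec = fp$rt,
               correct = resp == true_class,
               stringsAsFactors = FALSE)
  })
}

#' Default cohort parameter distributions
#'
#' Uniform ranges (length-2 elements) or fixed values (length-1) for the
#' diffusion participants. With the default stimulus conditions (typicality
#' centered near 0.2) these ranges put simulated accuracy mostly in 0.7-0.97
#' and mean RTs near 0.4-0.6 s - the regime a difficult speeded categorization
#' task produces in practice - so the 75% accuracy filter excludes a realistic
#' minority of participants.
#' @return named list with `a`, `ter`, `beta`, `lambda`.
#' @export
default_participant_dists <- function() {
  list(a = c(0.08, 0.12), ter = c(0.25, 0.35), beta = c(0.3, 2), lambda = 0.02)
}

draw_param <- function(spec) {
  if (length(spec) == 1L) spec else runif(1L, spec[1], spec[2])
}

#' Simulate a cohort of diffusion participants
#'
#' Samples each participant's parameters from `param_dists`, builds an
#' independently shuffled schedule per participant (each instance exactly
#' `repeats` times), and simulates all trials. Fully deterministic under `seed`.
#'
#' @param n_participants number of participants (>= 1).
#' @param param_dists see [default_participant_dists()].
#' @param instances a `glyph_set`.
#' @param repeats presentations per instance.
#' @param seed integer seed or `NULL`.
#' @return data.frame of trial records (see [simulate_trials()]).
#' @export
simulate_cohort <- function(n_participants, param_dists = default_participant_dists(),
                            instances = NULL, repeats = 2L, seed = NULL) {
  if (n_participants < 1L) stopf("n_participants must be >= 1")
  if (is.null(instances)) stopf("instances must be supplied")
  with_seed(seed, {
    out <- vector("list", n_participants)
    for (i in seq_len(n_participants)) {
      part <- sim_participant(sprintf("p%03d", i),
                              a = draw_param(param_dists$a),
                              ter = draw_param(param_dists$ter),
                              beta = draw_param(param_dists$beta),
                              lambda = draw_param(param_dists$lambda))
      sched <- make_schedule(instances, repeats = repeats, seed = NULL)
      out[[i]] <- simulate_trials(sched, part, instances, seed = NULL)
    }
    do.call(rbind, out)
  })
}

#' Closed-form hit probability of the two-boundary diffusion
#'
#' Probability of absorption at the upper (correct) boundary for drift `v`,
#' boundary `a`, start `a/2`, diffusion coefficient `s`:
#' `1 / (1 + exp(-a v / s^2))`.
#' @param v drift rate.
#' @param a boundary separation.
#' @param s diffusion coefficient.
#' @export
ddm_hit_probability <- function(v, a, s = 0.1) 1 / (1 + exp(-a * v / s^2))
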