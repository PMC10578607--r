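#' Pool per-item moments for EZ-style drift fitting
#'
#' Pools trials across participants per instance and computes the fraction
#' correct `Pc`, the mean `MRT` and variance `VRT` of correct-trial RTs, and
#' the trial count. Edge rules: `Pc = 1` is corrected to `1 - 1/(2n)`;
#' items at or below chance accuracy, with zero correct trials, or with fewer
#' than two correct trials (variance undefined) are flagged and excluded from
#' fitting.
#'
#' @param records trial data.frame.
#' @param chance chance accuracy used for the at-or-below-chance flag
#'   (default 0.5, the two-boundary convention).
#' @return data.frame (`ez_moments_table`) with `instance_id`, `pc`, `mrt`,
#'   `vrt`, `n_trials`, `n_correct`, `flag` (`"ok"` or a reason).
#' @export
pool_moments <- function(records, chance = 0.5) {
  rows <- lapply(split(records, records$instance_id), function(tr) {
    n <- nrow(tr); nc <- sum(tr$correct)
    pc <- nc / n
    flag <- "ok"
    if (nc == 0L) flag <- "zero_correct"
    else if (nc < 2L) flag <- "single_correct"
    else if (pc <= chance) flag <- "at_or_below_chance"
    if (pc == 1) pc <- 1 - 1 / (2 * n)
    crt <- tr$rt_sec[tr$correct]
    data.frame(instance_id = tr$instance_id[1], pc = pc,
               mrt = if (nc >= 1L) mean(crt) else NA_real_,
               vrt = if (nc >= 2L) var(crt) else NA_real_,
               n_trials = n, n_correct = nc, flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ez_moments_table", "data.frame")
  out
}

#' EZ-diffusion closed-form parameter estimates
#'
#' Maps accuracy and correct-RT moments to diffusion parameters under the
#' scaling convention `s = 0.1`, with `L = logit(Pc)`:
#' \deqn{v = sign(Pc - 1/2) \, s \, [L (L Pc^2 - L Pc + Pc - 1/2) / VRT]^{1/4}}
#' \deqn{a = s^2 L / v}
#' \deqn{Ter = MRT - (a / 2v) (1 - e^{-va/s^2}) / (1 + e^{-va/s^2})}
#' `Pc = 0.5` returns `v = 0` directly with `a` flagged undefined.
#'
#' @param pc fraction correct (edge-corrected, in (0,1)).
#' @param mrt,vrt mean and variance of correct-trial RTs (seconds, seconds^2).
#' @param s diffusion coefficient (default 0.1).
#' @return list with `v`, `a`, `ter`, `flag`.
#' @export
ez_fit <- function(pc, mrt, vrt, s = 0.1) {
  if (is.na(pc) || pc <= 0 || pc >= 1) stopf("pc must be in (0,1) after edge correction")
  if (pc == 0.5)
    return(list(v = 0, a = NA_real_, ter = NA_real_, flag = "pc_at_chance"))
  if (is.na(vrt) || vrt <= 0) stopf("vrt must be positive")
  L <- qlogis(pc)
  x <- L * (L * pc^2 - L * pc + pc - 0.5) / vrt
  v <- sign(pc - 0.5) * s * x^(1 / 4)
  a <- s^2 * L / v
  y <- exp(-v * a / s^2)
  mdt <- (a / (2 * v)) * (1 - y) / (1 + y)
  list(v = v, a = a, ter = mrt - mdt, flag = "ok")
}

#' Closed-form EZ moments for given diffusion parameters
#'
#' Forward model of [ez_fit()]: for drift `v`, boundary `a`, non-decision time
#' `ter`, start point `a/2`, returns the accuracy and the correct-RT mean and
#' variance that the EZ equations invert exactly. Used for round-trip checks
#' and as the analytic reference for simulation-based recovery.
#'
#' @param v,a,ter diffusion parameters (`v != 0`).
#' @param s diffusion coefficient.
#' @return list with `pc`, `mrt`, `vrt`.
#' @export
ez_moments <- function(v, a, ter, s = 0.1) {
  if (v == 0) stopf("forward moments need v != 0")
  y <- exp(-v * a / s^2)
  pc <- 1 / (1 + y)
  L <- qlogis(pc)  # = v a / s^2
  mdt <- (a / (2 * v)) * (1 - y) / (1 + y)
  vrt <- s^4 * L * (L * pc^2 - L * pc + pc - 0.5) / v^4
  list(pc = pc, mrt = ter + mdt, vrt = vrt)
}

#' Fit per-item drifts with shared boundary and non-decision time
#'
#' Three stages: (1) independent EZ fits per unflagged item; (2) shared
#' `a*` and `Ter*` taken as the medians of the per-item fits (only drift is
#' assumed to vary by stimulus); (3) per-item drifts re-estimated from the EZ
#' accuracy relation inverted at the fixed boundary,
#' `v_i = s^2 logit(Pc_i) / a*`, which is strictly increasing in `Pc_i`.
#'
#' @param moments an `ez_moments_table` from [pool_moments()].
#' @param s diffusion coefficient.
#' @return data.frame (`drift_table`) with `instance_id`, `v`, `v_stage1`,
#'   `a_shared`, `ter_shared`, `flag`; fit method in `attr(, "method")`.
#' @export
fit_drifts_shared <- function(moments, s = 0.1) {
  ok <- moments[moments$flag == "ok", , drop = FALSE]
  if (nrow(ok) < 2L) stopf("fit error: fewer than 2 fittable items")
  fits <- lapply(seq_len(nrow(ok)), function(i)
    ez_fit(ok$pc[i], ok$mrt[i], ok$vrt[i], s))
  a_star <- median(vapply(fits, `[[`, 0, "a"))
  ter_star <- median(vapply(fits, `[[`, 0, "ter"))
  v_i <- s^2 * qlogis(ok$pc) / a_star
  out <- data.frame(instance_id = ok$instance_id, v = v_i,
                    v_stage1 = vapply(fits, `[[`, 0, "v"),
                    a_shared = a_star, ter_shared = ter_star,
                    flag = "ok", stringsAsFactors = FALSE)
  flagged <- moments[moments$flag != "ok", , drop = FALSE]
  if (nrow(flagged)) {
    out <- rbind(out, data.frame(instance_id = flagged$instance_id,
                                 v = NA_real_, v_stage1 = NA_real_,
                                 a_shared = a_star, ter_shared = ter_star,
                                 flag = flagged$flag, stringsAsFactors = FALSE))
  }
  attr(out, "method") <- "ez_shared_boundary"
  class(out) <- c("drift_table", "data.frame")
  out
}

#' Correlate fitted drift rates with network confidence
#'
#' Spearman correlation between per-item fitted drifts and per-item mean
#' output entropy. High drift should co-occur with low entropy, so the
#' expected sign is negative for networks that account for the behavior.
#'
#' @param drifts a `drift_table`.
#' @param confidence data.frame `net_id`, `instance_id`, `entropy`.
#' @return list with `rho`, `p_value`, `n`, `undefined`.
#' @export
drift_confidence_correlation <- function(drifts, confidence) {
  mh <- mean_confidence(confidence)
  ok <- drifts[drifts$flag == "ok", c("instance_id", "v")]
  m <- merge(ok, mh, by = "instance_id")
  if (nrow(m) < 3L) stopf("analysis error: fewer than 3 overlapping items")
  spearman_cor(m$v, m$mean_entropy)
}
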