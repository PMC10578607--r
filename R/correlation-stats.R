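#' Normalize values within each unit to sum to one
#'
#' Applied to per-participant per-exemplar mean RTs (and, symmetrically, to
#' each network's per-exemplar entropies) so that every unit's values sum to 1.
#' The scaling is strictly positive, so within-unit rank order is preserved
#' exactly.
#'
#' @param df data.frame with columns `unit_id`, `instance_id`, `value`
#'   (all values > 0).
#' @return the data.frame with an added `norm_value` column.
#' @export
normalize_per_unit <- function(df) {
  stopifnot(all(c("unit_id", "instance_id", "value") %in% names(df)))
  if (any(!is.finite(df$value) | df$value <= 0))
    stopf("normalization error: all values must be positive")
  sums <- tapply(df$value, df$unit_id, sum)
  if (any(sums == 0)) stopf("normalization error: zero-sum unit")
  df$norm_value <- df$value / as.numeric(sums[as.character(df$unit_id)])
  df
}

#' Spearman rank correlation
#'
#' Midrank-based rho with a two-sided p-value (t approximation, as required in
#' the presence of ties). Constant input yields an `undefined` flag rather than
#' an error.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p_value`, `n`, `undefined`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3L) stopf("need at least 3 items")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                undefined = TRUE))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       undefined = FALSE)
}

#' Confidence--reaction-time correlation report
#'
#' Restricts both sides to their common instances, normalizes each network's
#' entropies over those instances (mirroring the participants' per-unit RT
#' normalization), and reports (a) the Spearman correlation between per-item
#' mean normalized confidence and per-item mean normalized RT, and (b) one
#' correlation per network against the mean normalized RTs.
#'
#' @param confidence data.frame `net_id`, `instance_id`, `entropy`.
#' @param rts normalized RT series from [normalize_per_unit()] (columns
#'   `unit_id`, `instance_id`, `norm_value`).
#' @param normalize_confidence set `FALSE` to correlate raw entropies instead.
#' @return a `correlation_report`: list with `rho_of_means`, `p_of_means`,
#'   `per_net` (data.frame `net_id`, `rho`, `p_value`), `mean_rho`, `se_rho`,
#'   `n_items`.
#' @export
correlation_report <- function(confidence, rts, normalize_confidence = TRUE) {
  items <- intersect(unique(confidence$instance_id), unique(rts$instance_id))
  if (!length(items)) stopf("analysis error: no common instances")
  conf <- confidence[confidence$instance_id %in% items, , drop = FALSE]
  rt <- rts[rts$instance_id %in% items, , drop = FALSE]
  if (normalize_confidence) {
    cdf <- data.frame(unit_id = conf$net_id, instance_id = conf$instance_id,
                      value = conf$entropy)
    # entropies can be exactly 0 for a saturated softmax; shift into the
    # positive domain required by the sum-to-1 normalization
    if (any(cdf$value <= 0)) cdf$value <- cdf$value + 1e-12
    conf$entropy <- normalize_per_unit(cdf)$norm_value
  }
  mean_rt <- tapply(rt$norm_value, rt$instance_id, mean)[items]
  mean_cf <- tapply(conf$entropy, conf$instance_id, mean)[items]
  of_means <- spearman_cor(as.numeric(mean_cf), as.numeric(mean_rt))
  per_net <- do.call(rbind, lapply(split(conf, conf$net_id), function(cn) {
    v <- tapply(cn$entropy, cn$instance_id, mean)[items]
    sc <- spearman_cor(as.numeric(v), as.numeric(mean_rt))
    data.frame(net_id = cn$net_id[1], rho = sc$rho, p_value = sc$p_value)
  }))
  rownames(per_net) <- NULL
  rhos <- per_net$rho[!is.na(per_net$rho)]
  structure(list(rho_of_means = of_means$rho, p_of_means = of_means$p_value,
                 per_net = per_net, mean_rho = mean(rhos),
                 se_rho = if (length(rhos) > 1L) sd(rhos) / sqrt(length(rhos))
                          else NA_real_,
                 n_items = length(items)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report: rho(means) = %.3f (p = %.3g), mean per-net rho = %.3f (n = %d nets, %d items)\n",
              x$rho_of_means, x$p_of_means, x$mean_rho, nrow(x$per_net),
              x$n_items))
  invisible(x)
}

fisher_z <- function(r) {
  lim <- 1 - 1e-7
  atanh(pmin(pmax(r, -lim), lim))
}

pairwise_result <- function(label_a, label_b, tt, clamped = FALSE) {
  structure(list(condition_a = label_a, condition_b = label_b,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, tier = significance_tier(tt$p.value),
                 clamped = clamped),
            class = "pairwise_comparison")
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: t = %.3f, p = %.3g  [%s]\n", x$condition_a,
              x$condition_b, x$t, x$p_value, x$tier))
  invisible(x)
}

#' Compare two sets of correlations
#'
#' Fisher z-transforms both sets (values at |rho| = 1 are clamped to
#' 1 - 1e-7 and flagged) and applies a two-sided Welch t-test. Significance
#' tiers follow the figure-caption convention: `***` p < .001, `**` p < .01,
#' `*` p < .05, else `n.s.`.
#'
#' @param rhos_a,rhos_b numeric vectors of correlations, each length >= 2.
#' @param labels length-2 character vector naming the conditions.
#' @return a `pairwise_comparison`.
#' @export
compare_correlation_sets <- function(rhos_a, rhos_b, labels = c("A", "B")) {
  if (length(rhos_a) < 2L || length(rhos_b) < 2L)
    stopf("need at least 2 correlations per set")
  clamped <- any(abs(c(rhos_a, rhos_b)) >= 1)
  tt <- t.test(fisher_z(rhos_a), fisher_z(rhos_b))
  pairwise_result(labels[1], labels[2], tt, clamped)
}

#' Compare two sets of accuracies
#'
#' Two-sided Welch t-test on raw accuracies (no transform).
#'
#' @param acc_a,acc_b numeric vectors, each length >= 2.
#' @param labels condition names.
#' @return a `pairwise_comparison`.
#' @export
compare_accuracy_sets <- function(acc_a, acc_b, labels = c("A", "B")) {
  if (length(acc_a) < 2L || length(acc_b) < 2L)
    stopf("need at least 2 accuracies per set")
  pairwise_result(labels[1], labels[2], t.test(acc_a, acc_b))
}

#' Crossed network-training x participant-training correlation grid
#'
#' One [correlation_report()] per combination of network-training condition
#' (a named list of confidence tables) and participant-training condition (a
#' named list of normalized RT series). Cells whose inputs are empty are
#' flagged but the grid is still returned.
#'
#' @param confidence_tables named list of confidence data.frames.
#' @param rts_by_condition named list of normalized RT data.frames.
#' @param normalize_confidence passed through to [correlation_report()].
#' @return a named list (`"<net>/<participant>"`) of `correlation_report`s or
#'   `NULL` for flagged cells, with class `correlation_grid`.
#' @export
crossed_grid <- function(confidence_tables, rts_by_condition,
                         normalize_confidence = TRUE) {
  if (!length(confidence_tables) || !length(rts_by_condition))
    stopf("both factors need at least one condition")
  out <- list()
  for (nc in names(confidence_tables)) {
    for (pc in names(rts_by_condition)) {
      cell <- paste(nc, pc, sep = "/")
      out[[cell]] <- tryCatch(
        correlation_report(confidence_tables[[nc]], rts_by_condition[[pc]],
                           normalize_confidence),
        error = function(e) { warning(sprintf("cell %s flagged: %s", cell,
                                              conditionMessage(e))); NULL })
    }
  }
  class(out) <- "correlation_grid"
  out
}

#' @export
print.correlation_grid <- function(x, ...) {
  for (cell in names(x)) {
    if (is.null(x[[cell]])) cat(sprintf("%-12s  [flagged: empty]\n", cell))
    else cat(sprintf("%-12s  rho(means) = %+.3f  mean per-net rho = %+.3f\n",
                     cell, x[[cell]]$rho_of_means, x[[cell]]$mean_rho))
  }
  invisible(x)
}
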