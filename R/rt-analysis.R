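#' Filter participants by overall accuracy
#'
#' A participant is retained iff their fraction of correct trials is at least
#' `min_accuracy` (the behavioral analyses use 0.75). Participants with zero
#' trials are excluded with a warning.
#'
#' @param records trial data.frame.
#' @param min_accuracy threshold in `[0, 1]`.
#' @return character vector of retained participant ids.
#' @export
filter_participants <- function(records, min_accuracy = 0.75) {
  if (min_accuracy < 0 || min_accuracy > 1) stopf("min_accuracy must be in [0,1]")
  n <- tapply(records$correct, records$participant_id, length)
  if (any(n == 0L)) warning("participant(s) with zero trials excluded")
  acc <- tapply(records$correct, records$participant_id, mean)
  names(acc)[!is.na(acc) & acc >= min_accuracy]
}

#' Per-participant within-class reaction-time ranks
#'
#' For each retained participant, averages the RTs over all presentations of
#' each instance (error trials included) and ranks instances within each class
#' using midranks for ties, so each (participant, class) group of `n` instances
#' has rank sum `n (n + 1) / 2`. Also tallies per-(participant, instance)
#' correct responses, used downstream for the accuracy--RT correlation and the
#' never-correct exclusion rule.
#'
#' @param records trial data.frame.
#' @param participants ids to retain (e.g. from [filter_participants()]).
#' @param instances optional `glyph_set` or id vector; when given, every
#'   retained participant must have seen every instance at least once.
#' @return data.frame (`rank_table`) with `participant_id`, `instance_id`,
#'   `class_label`, `mean_rt`, `n_correct`, `rank`.
#' @export
rank_within_class <- function(records, participants, instances = NULL) {
  rec <- records[records$participant_id %in% participants, , drop = FALSE]
  if (!nrow(rec)) stopf("no trials for the retained participants")
  if (!is.null(instances)) {
    ids <- if (inherits(instances, "glyph_set")) instances$instance_id else instances
    seen <- table(rec$participant_id, rec$instance_id)
    missing_ids <- setdiff(ids, colnames(seen))
    if (length(missing_ids) || any(seen[, ids[ids %in% colnames(seen)]] == 0)) {
      if (length(missing_ids)) {
        stopf("instance %s seen by no retained participant", missing_ids[1])
      }
      w <- which(seen[, ids] == 0, arr.ind = TRUE)[1, ]
      stopf("participant %s never saw instance %s",
            rownames(seen)[w[1]], ids[w[2]])
    }
  }
  key <- interaction(rec$participant_id, rec$instance_id, drop = TRUE)
  agg <- data.frame(
    participant_id = tapply(rec$participant_id, key, `[`, 1L),
    instance_id = tapply(rec$instance_id, key, `[`, 1L),
    class_label = tapply(rec$true_class, key, `[`, 1L),
    mean_rt = as.numeric(tapply(rec$rt_sec, key, mean)),
    n_correct = as.integer(tapply(rec$correct, key, sum)),
    stringsAsFactors = FALSE, row.names = NULL)
  agg$rank <- stats::ave(agg$mean_rt, agg$participant_id, agg$class_label,
                         FUN = rank)
  class(agg) <- c("rank_table", "data.frame")
  agg
}

#' Score instances by reaction-time rank extremity
#'
#' For each instance, compares its ranks (one per participant who saw it) to
#' the pooled ranks of all other same-class instances with a two-sided Welch
#' t-test. `direction` is `"easy"` when the instance's mean rank is below the
#' peer mean (fast responses), `"hard"` when above. Instances with fewer than
#' two ranks, or zero variance in both groups, are flagged degenerate with
#' `p_value = NA`.
#'
#' @param ranks a `rank_table` from [rank_within_class()].
#' @return data.frame (`instance_scores`) with `instance_id`, `class_label`,
#'   `mean_rank`, `t_stat`, `p_value`, `direction`, `mean_correct`,
#'   `n_zero_correct`, `degenerate`; the number of contributing participants is
#'   stored in `attr(, "n_participants")`.
#' @export
score_instances <- function(ranks) {
  if (length(unique(ranks$participant_id)) < 2L)
    stopf("need ranks from at least 2 participants")
  out <- lapply(split(ranks, ranks$class_label), function(cls) {
    if (length(unique(cls$instance_id)) < 2L)
      stopf("need at least 2 instances in class %s", cls$class_label[1])
    ids <- unique(cls$instance_id)
    rows <- lapply(ids, function(id) {
      x <- cls$rank[cls$instance_id == id]
      y <- cls$rank[cls$instance_id != id]
      nc <- cls$n_correct[cls$instance_id == id]
      degenerate <- length(x) < 2L || (var(x) == 0 && var(y) == 0)
      if (!degenerate) {
        tt <- t.test(x, y)        # Welch, two-sided
        tstat <- unname(tt$statistic); pval <- tt$p.value
      } else {
        tstat <- NA_real_; pval <- NA_real_
      }
      dmean <- mean(x) - mean(y)
      data.frame(instance_id = id, class_label = cls$class_label[1],
                 mean_rank = mean(x), t_stat = tstat, p_value = pval,
                 direction = if (dmean < 0) "easy" else if (dmean > 0) "hard"
                             else "neither",
                 mean_correct = mean(nc),
                 n_zero_correct = sum(nc == 0L),
                 degenerate = degenerate,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_participants") <- length(unique(ranks$participant_id))
  class(res) <- c("instance_scores", "data.frame")
  res
}

#' Correlation between per-instance accuracy and RT rank
#'
#' Spearman rank correlation between the average number of correct responses
#' to an instance (per-participant correct counts, averaged across
#' participants) and the instance's average reaction-time rank. Negative
#' values mean faster responses to instances that are classified more
#' accurately.
#'
#' @param ranks a `rank_table` (carries both the ranks and the correct tallies).
#' @return list with `rho`, `p_value`, `n_instances`, `undefined` (TRUE when a
#'   side is constant and the correlation does not exist).
#' @export
accuracy_rt_correlation <- function(ranks) {
  mean_corr <- tapply(ranks$n_correct, ranks$instance_id, mean)
  mean_rank <- tapply(ranks$rank, ranks$instance_id, mean)
  stopifnot(identical(names(mean_corr), names(mean_rank)))
  x <- as.numeric(mean_corr); y <- as.numeric(mean_rank)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n_instances = length(x),
                undefined = TRUE))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_instances = length(x), undefined = FALSE)
}
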