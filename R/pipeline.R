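#' @title Full synthetic-replication pipeline
#' @description
#' `run_exp1_analog()` executes the complete first-experiment analysis chain
#' on synthetic data: generate glyph instances -> simulate a diffusion cohort
#' -> accuracy filter -> within-class RT ranking -> instance scoring ->
#' good/bad/random/full curation -> 27-fold augmentation -> ensemble training
#' -> test accuracies, confidence--RT correlation reports, and the EZ drift
#' stage. `run_exp3_analog()` simulates transfer cohorts "trained" on the good
#' or bad set and produces the 2x2 crossed correlation grid.
#' `run_all()` chains both. All stages are deterministic given `config$seed`.
#' @name pipeline
NULL

stage_seeds <- function(seed) {
  list(instances = seed, cohort = seed + 1L, random_set = seed + 2L,
       test_set = seed + 3L, ensembles = seed * 1000L,
       exp3_good = seed + 4L, exp3_bad = seed + 5L)
}

# max Jaccard overlap between a binarized image and the same-class members of
# a curated set: the "match quality" a learner of that set assigns an item
set_similarity <- function(img, class_label, set, member_store) {
  ids <- set$members[[as.character(class_label)]]
  if (is.null(ids) || !length(ids)) return(0)
  a <- img >= 0.5
  best <- 0
  for (id in ids) {
    k <- match(id, member_store$instance_id)
    if (is.na(k)) stopf("curated member %s not found in the instance store", id)
    b <- member_store$pixels[, , k] >= 0.5
    j <- sum(a & b) / sum(a | b)
    if (j > best) best <- j
  }
  best
}

#' Per-participant normalized mean reaction times
#'
#' Collapses a trial table to one mean RT per participant x instance and
#' normalizes each participant's means to sum to 1 (see
#' [normalize_per_unit()]), the form expected by [correlation_report()].
#' @param records trial table as produced by [simulate_cohort()].
#' @param participants optional character vector restricting to a retained
#'   subset of participant ids.
#' @return a normalized unit table with columns `unit_id`, `instance_id`,
#'   `value`, `norm_value`.
#' @export
normalized_rts <- function(records, participants = NULL) {
  rec <- if (is.null(participants)) records
         else records[records$participant_id %in% participants, , drop = FALSE]
  key <- interaction(rec$participant_id, rec$instance_id, drop = TRUE)
  df <- data.frame(
    unit_id = as.character(tapply(rec$participant_id, key, `[`, 1L)),
    instance_id = as.character(tapply(rec$instance_id, key, `[`, 1L)),
    value = as.numeric(tapply(rec$rt_sec, key, mean)),
    stringsAsFactors = FALSE, row.names = NULL)
  normalize_per_unit(df)
}

#' @rdname pipeline
#' @param config configuration list (see [default_config()]).
#' @return `run_exp1_analog()`: a manifest list with the curated sets, per-set
#'   ensemble accuracies and confidence tables, pairwise accuracy comparisons,
#'   correlation reports, the accuracy--RT correlation, and the drift-fitting
#'   stage.
#' @export
run_exp1_analog <- function(config = default_config()) {
  cfg <- validate_config(config)
  sd <- stage_seeds(cfg$seed)
  protos <- glyph_prototypes(cfg$n_classes, cfg$H, cfg$W)
  instances <- generate_instances(protos, cfg$n_per_class, cfg$deform_scale,
                                  cfg$sigma_tau, cfg$deform_shape,
                                  seed = sd$instances)
  records <- simulate_cohort(cfg$n_participants, cfg$participant_dists,
                             instances, cfg$repeats, seed = sd$cohort)
  retained <- filter_participants(records, cfg$min_accuracy)
  if (length(retained) < 2L)
    stopf("stage 'filter': only %d participant(s) retained", length(retained))
  ranks <- rank_within_class(records, retained, instances)
  scores <- score_instances(ranks)
  acc_rt <- accuracy_rt_correlation(ranks)

  sets <- list(
    good = curate_extreme(scores, cfg$k_per_class, "good"),
    bad = curate_extreme(scores, cfg$k_per_class, "bad"),
    random = curate_random(instances, cfg$k_per_class, seed = sd$random_set),
    full = curate_full(instances))

  test_set <- generate_instances(protos, cfg$test_per_class, cfg$deform_scale,
                                 cfg$sigma_tau, cfg$deform_shape,
                                 seed = sd$test_set)
  spec <- net_spec(cfg$n_classes, cfg$H, cfg$W, cfg$epochs, cfg$batch_size,
                   cfg$alpha, cfg$dropout)
  rts <- normalized_rts(records, retained)

  ensembles <- list(); reports <- list()
  for (i in seq_along(sets)) {
    nm <- names(sets)[i]
    train <- glyph_subset(instances, curated_members(sets[[nm]]))
    if (cfg$augment) train <- augment_images(train)
    ens <- train_ensemble(spec, train, cfg$ensemble_size,
                          base_seed = sd$ensembles + 100L * i,
                          test_images = test_set, conf_images = instances)
    ensembles[[nm]] <- ens
    reports[[nm]] <- correlation_report(ens$confidence, rts)
  }

  pairs <- utils::combn(names(sets), 2L, simplify = FALSE)
  acc_comparisons <- lapply(pairs, function(p)
    compare_accuracy_sets(ensembles[[p[1]]]$accuracies,
                          ensembles[[p[2]]]$accuracies, labels = p))
  names(acc_comparisons) <- vapply(pairs, paste, "", collapse = "_vs_")

  moments <- pool_moments(records[records$participant_id %in% retained, ])
  drifts <- fit_drifts_shared(moments)
  drift_rho <- drift_confidence_correlation(drifts, ensembles$good$confidence)

  manifest <- list(
    experiment = "exp1_analog", config = cfg,
    instances = instances, records = records, retained = retained,
    ranks = ranks, scores = scores, acc_rt = acc_rt,
    sets = sets, test_set = test_set, rts = rts,
    ensembles = ensembles, reports = reports,
    acc_comparisons = acc_comparisons,
    moments = moments, drifts = drifts, drift_rho = drift_rho,
    mean_accuracy = vapply(ensembles, function(e) mean(e$accuracies), 0))
  if (!is.null(cfg$out_dir)) manifest$files <- write_exp1(manifest, cfg$out_dir)
  manifest
}

write_exp1 <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(trials = file.path(dir, "trials.csv"),
             scores = file.path(dir, "instance_scores.csv"),
             accuracies = file.path(dir, "ensemble_accuracies.csv"),
             confidence = file.path(dir, "confidence.csv"),
             drifts = file.path(dir, "drift_table.csv"),
             summary = file.path(dir, "summary.json"))
  write_trials(m$records, paths["trials"])
  write.csv(m$scores, paths["scores"], row.names = FALSE)
  acc <- do.call(rbind, lapply(names(m$ensembles), function(nm)
    data.frame(set = nm, net_id = seq_along(m$ensembles[[nm]]$accuracies),
               accuracy = m$ensembles[[nm]]$accuracies)))
  write.csv(acc, paths["accuracies"], row.names = FALSE)
  conf <- do.call(rbind, lapply(names(m$ensembles), function(nm)
    cbind(set = nm, m$ensembles[[nm]]$confidence)))
  write.csv(conf, paths["confidence"], row.names = FALSE)
  write.csv(as.data.frame(m$drifts), paths["drifts"], row.names = FALSE)
  summary <- list(mean_accuracy = as.list(m$mean_accuracy),
                  acc_rt_rho = m$acc_rt$rho,
                  rho_of_means = lapply(m$reports, `[[`, "rho_of_means"),
                  drift_confidence_rho = m$drift_rho$rho)
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE, digits = NA)
  data.frame(name = names(paths), path = unname(paths),
             md5 = unname(tools::md5sum(unname(paths))), row.names = NULL)
}

# simulate one transfer cohort whose drift for each test item is
# gain * max(0, similarity-to-trained-set - sim_floor)
simulate_transfer_cohort <- function(prefix, n, trained_set, test_pool, cfg,
                                     seed, member_store) {
  with_seed(seed, {
    sim <- vapply(seq_along(test_pool$instance_id), function(i)
      set_similarity(test_pool$pixels[, , i], test_pool$class_label[i],
                     trained_set, member_store), 0)
    # match quality below the floor contributes no usable evidence
    base <- pmax(0, sim - cfg$exp3_sim_floor)
    out <- vector("list", n)
    for (p in seq_len(n)) {
      part <- sim_participant(sprintf("%s%03d", prefix, p),
                              a = draw_param(cfg$participant_dists$a),
                              ter = draw_param(cfg$participant_dists$ter),
                              beta = 1,
                              lambda = draw_param(cfg$participant_dists$lambda))
      gain <- runif(1, cfg$exp3_drift_gain[1], cfg$exp3_drift_gain[2])
      drift <- setNames(gain * base, test_pool$instance_id)
      sched <- make_schedule(test_pool, repeats = cfg$repeats, seed = NULL)
      out[[p]] <- simulate_trials(sched, part, test_pool, seed = NULL,
                                  drift_by_instance = drift)
    }
    do.call(rbind, out)
  })
}

#' @rdname pipeline
#' @param exp1 result of `run_exp1_analog()` (supplies the curated sets and
#'   the good/bad-trained network confidence tables).
#' @return `run_exp3_analog()`: a manifest with both cohorts' trial records,
#'   the good-vs-bad accuracy comparison (no accuracy filter), and the 2x2
#'   crossed grid of correlation reports (participants filtered at the
#'   transfer-phase 50% accuracy threshold).
#' @export
run_exp3_analog <- function(config = default_config(), exp1 = NULL) {
  cfg <- validate_config(config)
  if (is.null(exp1)) exp1 <- run_exp1_analog(cfg)
  if (is.null(exp1$sets$good) || is.null(exp1$sets$bad))
    stopf("configuration error: exp1 result lacks good/bad curated sets")
  sd <- stage_seeds(cfg$seed)

  # test items exclude members of either curated training set
  excluded <- union(curated_members(exp1$sets$good),
                    curated_members(exp1$sets$bad))
  pool_ids <- setdiff(exp1$instances$instance_id, excluded)
  test_pool <- glyph_subset(exp1$instances, pool_ids)

  cohorts <- list(
    good = simulate_transfer_cohort("g", cfg$exp3_n_per_cohort,
                                    exp1$sets$good, test_pool, cfg,
                                    sd$exp3_good, exp1$instances),
    bad = simulate_transfer_cohort("b", cfg$exp3_n_per_cohort,
                                   exp1$sets$bad, test_pool, cfg,
                                   sd$exp3_bad, exp1$instances))

  # accuracy comparison uses every participant (no filter)
  acc_by <- lapply(cohorts, function(rec)
    as.numeric(tapply(rec$correct, rec$participant_id, mean)))
  acc_comparison <- compare_accuracy_sets(acc_by$good, acc_by$bad,
                                          labels = c("good", "bad"))

  # correlation analyses use the 50%-accuracy subset
  retained <- lapply(cohorts, function(rec)
    filter_participants(rec, cfg$exp3_min_accuracy))
  rts_by <- list()
  for (nm in names(cohorts)) {
    if (length(retained[[nm]]))
      rts_by[[nm]] <- normalized_rts(cohorts[[nm]], retained[[nm]])
  }
  conf_by <- list(good = exp1$ensembles$good$confidence,
                  bad = exp1$ensembles$bad$confidence)
  grid <- crossed_grid(conf_by, rts_by)

  list(experiment = "exp3_analog", config = cfg, test_pool = test_pool,
       cohorts = cohorts, cohort_accuracy = vapply(acc_by, mean, 0),
       acc_comparison = acc_comparison, retained = retained,
       rts_by_condition = rts_by, grid = grid)
}

#' @rdname pipeline
#' @param dry_run if `TRUE`, print the stage plan and return it without
#'   computing or writing anything.
#' @return `run_all()`: list with `exp1` and `exp3` manifests.
#' @export
run_all <- function(config = default_config(), dry_run = FALSE) {
  cfg <- validate_config(config)
  plan <- c("generate instances", "simulate cohort", "filter participants",
            "rank within class", "score instances", "curate sets",
            "augment", "train ensembles", "correlation reports",
            "ez drift stage", "transfer cohorts", "crossed grid")
  if (dry_run) {
    cat("stage plan:\n"); cat(paste0("  - ", plan, "\n"), sep = "")
    return(invisible(list(plan = plan)))
  }
  exp1 <- run_exp1_analog(cfg)
  exp3 <- run_exp3_analog(cfg, exp1)
  list(plan = plan, exp1 = exp1, exp3 = exp3)
}
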