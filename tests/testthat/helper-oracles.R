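# Independent brute-force oracles used across test files. These deliberately
# avoid the package's own code paths.

# Spearman rho as Pearson on midranks
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# entropy in nats by direct evaluation
oracle_entropy <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

# small deterministic glyph world for structural tests
tiny_world <- function(n_per_class = 5, deform_scale = 10, sigma_tau = 8,
                       seed = 1) {
  protos <- glyph_prototypes(4, 28, 28)
  generate_instances(protos, n_per_class, deform_scale, sigma_tau, seed = seed)
}

# hand-built rank table: one row per participant x instance
make_rank_table <- function(ranks_by_participant, class_label = 1L,
                            n_correct = NULL) {
  n_inst <- length(ranks_by_participant[[1]])
  ids <- sprintf("c%d_i%03d", class_label, seq_len(n_inst))
  rows <- lapply(names(ranks_by_participant), function(p) {
    data.frame(participant_id = p, instance_id = ids,
               class_label = class_label, mean_rt = NA_real_,
               n_correct = if (is.null(n_correct)) 2L else n_correct,
               rank = ranks_by_participant[[p]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rank_table", "data.frame")
  out
}

# smoke-scale pipeline configuration (fast enough for CI-style runs)
smoke_config <- function(seed = 5) {
  cfg <- default_config()
  cfg$n_per_class <- 8L
  cfg$n_participants <- 8L
  cfg$min_accuracy <- 0.5
  cfg$k_per_class <- 2L
  cfg$test_per_class <- 10L
  cfg$epochs <- 4L
  cfg$ensemble_size <- 2L
  cfg$exp3_n_per_cohort <- 5L
  cfg$seed <- seed
  cfg
}
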