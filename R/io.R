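TRIAL_COLS <- c("participant_id", "trial_index", "instance_id", "true_class",
                "response_class", "rt_sec", "correct")

#' Write / read behavioral trial tables
#'
#' Comma-separated UTF-8 with a mandatory header
#' `participant_id,trial_index,instance_id,true_class,response_class,rt_sec,correct`.
#' Reading validates each row (`rt_sec > 0`, `correct` consistent with the
#' response) and reports the offending line on failure.
#'
#' @param records trial data.frame as produced by [simulate_trials()].
#' @param path file path.
#' @return `read_trials()` returns the validated data.frame; `write_trials()`
#'   returns `path` invisibly.
#' @export
write_trials <- function(records, path) {
  missing_cols <- setdiff(TRIAL_COLS, names(records))
  if (length(missing_cols)) stopf("records missing column(s): %s",
                                  paste(missing_cols, collapse = ", "))
  write.csv(records[TRIAL_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRIAL_COLS, names(df))
  if (length(missing_cols)) stopf("malformed trial table %s: missing column(s) %s",
                                  path, paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) return(df[TRIAL_COLS])
  bad <- function(cond, what) {
    i <- which(cond)
    # +1 for the header line
    if (length(i)) stopf("invalid trial row (line %d): %s", i[1] + 1L, what)
  }
  bad(!is.finite(df$rt_sec) | df$rt_sec <= 0, "rt_sec must be positive")
  bad(is.na(df$true_class) | is.na(df$response_class), "missing class label")
  df$correct <- as.logical(df$correct)
  bad(is.na(df$correct), "correct must be logical")
  bad(df$correct != (df$true_class == df$response_class),
      "correct flag inconsistent with response")
  df[TRIAL_COLS]
}

# ---- IDX (MNIST-dialect) image/label files ----------------------------------

write_idx_int32 <- function(con, x) writeBin(as.integer(x), con, size = 4L,
                                            endian = "big")

#' Write / read image stores
#'
#' Two dialects. `"idx"`: a pair of MNIST-style big-endian files
#' (`<stem>-images-idx3-ubyte`, magic 2051; `<stem>-labels-idx1-ubyte`, magic
#' 2049), unsigned-byte pixels, row-major, origin top-left, 0-based instance
#' order. `"png_dirs"`: one grayscale PNG per instance in per-class
#' subdirectories `class_<k>/<instance_id>.png` (requires the `png` package).
#' Round-trips are pixel-exact for 8-bit data.
#'
#' @param store a `glyph_set` (or any list with `pixels`, `instance_id`,
#'   `class_label`, `H`, `W`, `n_classes`).
#' @param path file stem (idx) or directory (png_dirs).
#' @param dialect `"idx"` or `"png_dirs"`.
#' @return `read_images()` returns a `glyph_set` (with `tau = NA`, unknown for
#'   externally supplied images); `write_images()` returns `path` invisibly.
#' @export
write_images <- function(store, path, dialect = c("idx", "png_dirs")) {
  dialect <- match.arg(dialect)
  n <- length(store$instance_id)
  H <- store$H; W <- store$W
  if (!all(dim(store$pixels)[1:2] == c(H, W))) stopf("inconsistent image sizes")
  if (dialect == "idx") {
    con <- file(paste0(path, "-images-idx3-ubyte"), "wb")
    on.exit(close(con), add = TRUE)
    write_idx_int32(con, c(2051L, n, H, W))
    for (i in seq_len(n)) {
      img <- round(store$pixels[, , i] * 255)
      writeBin(as.raw(t(img)), con)  # row-major
    }
    lcon <- file(paste0(path, "-labels-idx1-ubyte"), "wb")
    on.exit(close(lcon), add = TRUE)
    write_idx_int32(lcon, c(2049L, n))
    writeBin(as.raw(store$class_label), lcon)
  } else {
    if (!requireNamespace("png", quietly = TRUE))
      stopf("the png_dirs dialect needs the 'png' package")
    for (i in seq_len(n)) {
      d <- file.path(path, sprintf("class_%d", store$class_label[i]))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      png::writePNG(store$pixels[, , i],
                    file.path(d, paste0(store$instance_id[i], ".png")))
    }
  }
  invisible(path)
}

#' @rdname write_images
#' @export
read_images <- function(path, dialect = c("idx", "png_dirs")) {
  dialect <- match.arg(dialect)
  if (dialect == "idx") {
    ipath <- paste0(path, "-images-idx3-ubyte")
    if (!file.exists(ipath)) stopf("no such file: %s", ipath)
    con <- file(ipath, "rb"); on.exit(close(con), add = TRUE)
    hdr <- readBin(con, "integer", 4L, size = 4L, endian = "big")
    if (hdr[1] != 2051L) stopf("%s: bad IDX image magic %d", ipath, hdr[1])
    n <- hdr[2]; H <- hdr[3]; W <- hdr[4]
    pix <- array(0, dim = c(H, W, n))
    for (i in seq_len(n)) {
      raw <- readBin(con, "raw", H * W)
      pix[, , i] <- t(matrix(as.integer(raw), W, H)) / 255
    }
    lcon <- file(paste0(path, "-labels-idx1-ubyte"), "rb")
    on.exit(close(lcon), add = TRUE)
    lhdr <- readBin(lcon, "integer", 2L, size = 4L, endian = "big")
    if (lhdr[1] != 2049L) stopf("bad IDX label magic %d", lhdr[1])
    lab <- as.integer(readBin(lcon, "raw", lhdr[2]))
    structure(list(instance_id = sprintf("idx_%04d", seq_len(n) - 1L),
                   class_label = lab, tau = rep(NA_real_, n), pixels = pix,
                   n_classes = length(unique(lab)), H = H, W = W),
              class = "glyph_set")
  } else {
    if (!requireNamespace("png", quietly = TRUE))
      stopf("the png_dirs dialect needs the 'png' package")
    dirs <- sort(list.dirs(path, recursive = FALSE))
    dirs <- dirs[grepl("^class_[0-9]+$", basename(dirs))]
    if (!length(dirs)) stopf("no class_<k> directories under %s", path)
    ids <- character(); lab <- integer(); imgs <- list()
    for (d in dirs) {
      k <- as.integer(sub("class_", "", basename(d)))
      files <- sort(list.files(d, pattern = "\\.png$", full.names = TRUE))
      for (f in files) {
        img <- png::readPNG(f)
        if (length(dim(img)) == 3L) img <- img[, , 1]
        imgs[[length(imgs) + 1L]] <- img
        ids <- c(ids, sub("\\.png$", "", basename(f)))
        lab <- c(lab, k)
      }
    }
    dims <- vapply(imgs, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stopf("inconsistent image sizes under %s", path)
    H <- dims[1, 1]; W <- dims[2, 1]
    pix <- array(unlist(imgs), dim = c(H, W, length(imgs)))
    structure(list(instance_id = ids, class_label = lab,
                   tau = rep(NA_real_, length(ids)), pixels = pix,
                   n_classes = length(unique(lab)), H = H, W = W),
              class = "glyph_set")
  }
}

# ---- run configuration ------------------------------------------------------

#' Default run configuration
#'
#' The defaults encode the benchmark's study conditions: 4 classes x 20
#' instances each on a 28x28 grid, 50 diffusion participants seeing every
#' instance exactly twice, a 75% accuracy filter, curated sets of 5 instances
#' per class, the 27-fold shift/rotation augmentation, and the standard
#' network hyperparameters (64 epochs, batch 64, step size 0.005, dropout 0.5,
#' ensembles of 10 networks).
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    n_classes = 4L, n_per_class = 20L, H = 28L, W = 28L,
    deform_scale = 60, sigma_tau = 38, deform_shape = 2,
    n_participants = 50L, repeats = 2L,
    participant_dists = default_participant_dists(),
    min_accuracy = 0.75,
    k_per_class = 5L,
    augment = TRUE,
    test_per_class = 50L,
    epochs = 64L, batch_size = 64L, alpha = 0.005, dropout = 0.5,
    ensemble_size = 10L,
    exp3_n_per_cohort = 30L,
    exp3_drift_gain = c(0.5, 1),
    exp3_sim_floor = 0.25,
    exp3_min_accuracy = 0.5,
    seed = 1L,
    out_dir = NULL
  )
}

#' Load a run configuration from YAML or JSON
#'
#' Unspecified fields are filled from [default_config()]; invariants (positive
#' counts, thresholds in `[0,1]`) are validated, with the failing field named.
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(utils::modifyList(default_config(), as.list(cfg)))
}

validate_config <- function(cfg) {
  pos <- c("n_classes", "n_per_class", "H", "W", "n_participants", "repeats",
           "k_per_class", "test_per_class", "epochs", "batch_size", "alpha",
           "ensemble_size", "exp3_n_per_cohort")
  for (f in pos) {
    if (is.null(cfg[[f]]) || any(cfg[[f]] <= 0))
      stopf("configuration error: '%s' must be positive", f)
  }
  for (f in c("min_accuracy", "exp3_min_accuracy", "dropout")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stopf("configuration error: '%s' must be in [0,1]", f)
  }
  if (cfg$deform_scale < 0) stopf("configuration error: 'deform_scale' must be >= 0")
  if (is.null(cfg$deform_shape) || cfg$deform_shape <= 0)
    stopf("configuration error: 'deform_shape' must be positive")
  cfg
}

#' Curated-set size implied by a configuration
#' @param cfg configuration list.
#' @return `n_classes * k_per_class`.
#' @export
curated_set_size <- function(cfg) as.integer(cfg$n_classes) * as.integer(cfg$k_per_class)
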