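#' Network architecture and training hyperparameters
#'
#' The classifier is a small convolutional network: a convolutional layer with
#' 6 filters of size 5x5 (stride 1, ReLU), 2x2 max pooling, a second
#' convolutional layer with 16 filters of size 5x5 (stride 1, ReLU), 2x2 max
#' pooling, dense layers of 128 and 64 ReLU units, and `K` softmax outputs.
#' All layers but the output use 50% dropout during training. Weights are
#' He-normal initialized except the output layer (Glorot uniform). Training
#' uses Adam on categorical cross-entropy for 64 epochs with batch size 64 and
#' step size 0.005. Convolutions are unpadded; pooling stride is 2, so `H - 4`
#' and `(H - 4)/2 - 4` must be positive and even (28x28 and 20x20 both work).
#'
#' @param K number of classes (>= 2).
#' @param H,W input image size in pixels.
#' @param epochs,batch_size,alpha,dropout training hyperparameters.
#' @return a `net_spec` list.
#' @export
net_spec <- function(K = 4L, H = 28L, W = 28L, epochs = 64L, batch_size = 64L,
                     alpha = 0.005, dropout = 0.5) {
  if (K < 2L) stopf("K must be >= 2")
  if (epochs < 1L || batch_size < 1L || alpha <= 0)
    stopf("hyperparameters must be positive")
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  h1 <- H - 4L; w1 <- W - 4L
  if (h1 < 2L || w1 < 2L || h1 %% 2L || w1 %% 2L ||
      (h1 %/% 2L - 4L) < 2L || (w1 %/% 2L - 4L) < 2L ||
      (h1 %/% 2L - 4L) %% 2L || (w1 %/% 2L - 4L) %% 2L)
    stopf("image size %dx%d incompatible with the two conv/pool stages", H, W)
  structure(list(K = as.integer(K), H = as.integer(H), W = as.integer(W),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 alpha = alpha, dropout = dropout), class = "net_spec")
}

# flatten an image array (H x W x n) to the H*W x n column layout the C++
# backend expects
images_to_matrix <- function(pixels) {
  d <- dim(pixels)
  matrix(pixels, nrow = d[1] * d[2], ncol = d[3])
}

train_inputs <- function(train) {
  if (inherits(train, "augmented_set"))
    list(x = images_to_matrix(train$pixels), y = train$labels,
         H = train$H, W = train$W)
  else if (inherits(train, "glyph_set"))
    list(x = images_to_matrix(train$pixels), y = train$class_label,
         H = train$H, W = train$W)
  else stopf("train set must be an augmented_set or glyph_set")
}

#' Train one network
#'
#' @param spec a [net_spec()].
#' @param train an `augmented_set` or `glyph_set` with labels in `1..K`.
#' @param seed integer seed (controls initialization, shuffling, dropout);
#'   identical seeds give identical parameters.
#' @return a `trained_net` (opaque parameter list plus the spec and seed).
#' @export
train_network <- function(spec, train, seed = NULL) {
  inp <- train_inputs(train)
  if (length(inp$y) == 0L) stopf("empty training set")
  if (any(inp$y < 1L | inp$y > spec$K)) stopf("label outside 1..K")
  if (inp$H != spec$H || inp$W != spec$W)
    stopf("image size %dx%d incompatible with spec %dx%d",
          inp$H, inp$W, spec$H, spec$W)
  with_seed(seed, {
    w <- cnn_init_cpp(spec$H, spec$W, spec$K)
    w <- cnn_train_cpp(w, inp$x, as.integer(inp$y) - 1L, spec$epochs,
                       spec$batch_size, spec$alpha, spec$dropout)
    structure(list(weights = w, spec = spec, seed = seed), class = "trained_net")
  })
}

#' @export
print.trained_net <- function(x, ...) {
  cat(sprintf("trained_net: %d-class conv net on %dx%d input (seed %s)\n",
              x$spec$K, x$spec$H, x$spec$W, x$seed %||% "ambient"))
  invisible(x)
}

#' Class-probability predictions (dropout disabled)
#'
#' @param net a `trained_net`.
#' @param images a `glyph_set` or `augmented_set`.
#' @return matrix `n x K` of softmax probabilities (rows sum to 1).
#' @export
net_predict <- function(net, images) {
  inp <- train_inputs(images)
  cnn_predict_cpp(net$weights, inp$x)
}

#' Argmax test-set accuracy
#'
#' Probability ties are broken toward the lowest class index.
#'
#' @param net a `trained_net`.
#' @param images a labeled `glyph_set`/`augmented_set`.
#' @return fraction correct in `[0, 1]`.
#' @export
evaluate_accuracy <- function(net, images) {
  inp <- train_inputs(images)
  if (length(inp$y) == 0L) stopf("empty test set")
  probs <- net_predict(net, images)
  pred <- apply(probs, 1L, which.max)
  mean(pred == inp$y)
}

#' Softmax-entropy confidence
#'
#' Entropy (nats, `0 log 0 = 0`) of each output distribution; low entropy is
#' high confidence.
#'
#' @param net a `trained_net`.
#' @param images instances to evaluate.
#' @return data.frame with `instance_id`, per-class probabilities `p1..pK`,
#'   and `entropy`.
#' @export
net_confidence <- function(net, images) {
  probs <- net_predict(net, images)
  H <- apply(probs, 1L, response_entropy)
  ids <- if (!is.null(images$instance_id)) images$instance_id
         else sprintf("item_%04d", seq_len(nrow(probs)))
  out <- data.frame(instance_id = ids, probs, entropy = H,
                    stringsAsFactors = FALSE)
  names(out)[1 + seq_len(ncol(probs))] <- paste0("p", seq_len(ncol(probs)))
  out
}

#' Train an ensemble of randomly initialized networks
#'
#' Network `i` is trained with seed `base_seed + i - 1`. Returns per-net test
#' accuracies and a confidence table of per-(net, instance) output entropies
#' over `conf_images`.
#'
#' @param spec a [net_spec()].
#' @param train training set (`augmented_set`/`glyph_set`).
#' @param n_nets ensemble size (>= 1).
#' @param base_seed integer; seeds the members deterministically.
#' @param test_images labeled set for accuracy (optional).
#' @param conf_images instances for the confidence table (optional).
#' @param keep_nets keep the trained parameter lists (default FALSE to save
#'   memory).
#' @return an `ensemble_result`: list with `accuracies` (numeric, one per
#'   net), `confidence` (data.frame `net_id`, `instance_id`, `entropy`), and
#'   optionally `nets`.
#' @export
train_ensemble <- function(spec, train, n_nets, base_seed = 1L,
                           test_images = NULL, conf_images = NULL,
                           keep_nets = FALSE) {
  if (n_nets < 1L) stopf("n_nets must be >= 1")
  acc <- rep(NA_real_, n_nets)
  conf <- vector("list", n_nets)
  nets <- if (keep_nets) vector("list", n_nets) else NULL
  for (i in seq_len(n_nets)) {
    net <- tryCatch(train_network(spec, train, seed = base_seed + i - 1L),
                    error = function(e) stopf("ensemble member %d failed: %s",
                                              i, conditionMessage(e)))
    if (!is.null(test_images)) acc[i] <- evaluate_accuracy(net, test_images)
    if (!is.null(conf_images)) {
      cf <- net_confidence(net, conf_images)
      conf[[i]] <- data.frame(net_id = i, instance_id = cf$instance_id,
                              entropy = cf$entropy, stringsAsFactors = FALSE)
    }
    if (keep_nets) nets[[i]] <- net
  }
  structure(list(accuracies = acc,
                 confidence = if (!is.null(conf_images)) do.call(rbind, conf),
                 nets = nets, label = attr(train, "label")),
            class = "ensemble_result")
}

#' Per-instance mean entropy of a confidence table
#' @param confidence data.frame with `net_id`, `instance_id`, `entropy`.
#' @return data.frame with `instance_id` and `mean_entropy`.
#' @export
mean_confidence <- function(confidence) {
  m <- tapply(confidence$entropy, confidence$instance_id, mean)
  data.frame(instance_id = names(m), mean_entropy = as.numeric(m),
             stringsAsFactors = FALSE, row.names = NULL)
}
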