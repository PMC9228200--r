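#' Attribute normalization ranges
#'
#' Min-max ranges mapping each attribute (medium component concentration or
#' response) onto `[0, 1]` for neural-network training. The default spec uses
#' the instrument/formulation limits of the cultivation study: cellulose
#' 0-50, urea 0-10, ammonium sulfate 0-10, dipotassium phosphate 0-10 g/L,
#' and both inhibition-zone responses 10-40 mm.
#'
#' @param name,range_min,range_max Equal-length vectors defining the ranges.
#' @return Data frame of class `normalization_spec`.
#' @export
normalization_spec <- function(name, range_min, range_max) {
  stopifnot(length(name) == length(range_min), length(name) == length(range_max))
  if (anyDuplicated(name)) stop("duplicate attribute names")
  if (any(range_min >= range_max)) stop("range_min must be < range_max for every attribute")
  structure(data.frame(name = name, range_min = range_min, range_max = range_max),
            class = c("normalization_spec", "data.frame"))
}

#' @rdname normalization_spec
#' @export
default_normalization <- function() {
  normalization_spec(
    name = c("cellulose", "urea", "ammonium_sulfate", "dipotassium_phosphate",
             "SA2BSS", "PA2DSS"),
    range_min = c(0, 0, 0, 0, 10, 10),
    range_max = c(50, 10, 10, 10, 40, 40))
}

#' Min-max rescaling of attributes
#'
#' Affine map between original units and the unit interval according to a
#' [normalization_spec()]; the round trip is the identity.
#'
#' @param x Matrix or data frame whose column names appear in `spec`.
#' @param spec A `normalization_spec`.
#' @param direction `"to_unit"` (original units to `[0,1]`) or
#'   `"to_original"`.
#' @return Matrix of the same shape.
#' @examples
#' rescale(cbind(cellulose = 50), default_normalization())  # 1
#' @export
rescale <- function(x, spec, direction = c("to_unit", "to_original")) {
  direction <- match.arg(direction)
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("x must have column names matching the spec")
  unknown <- setdiff(colnames(x), spec$name)
  if (length(unknown)) stop("attribute(s) not in normalization spec: ",
                            paste(unknown, collapse = ", "))
  out <- x
  for (j in seq_len(ncol(x))) {
    s <- spec[match(colnames(x)[j], spec$name), ]
    if (direction == "to_unit") {
      bad <- which(x[, j] < s$range_min - 1e-9 | x[, j] > s$range_max + 1e-9)
      if (length(bad)) stop("out of range: attribute '", s$name, "', row ", bad[1],
                            " value ", x[bad[1], j], " outside [", s$range_min, ", ", s$range_max, "]")
      out[, j] <- (x[, j] - s$range_min) / (s$range_max - s$range_min)
    } else {
      bad <- which(x[, j] < -1e-9 | x[, j] > 1 + 1e-9)
      if (length(bad)) stop("out of range: attribute '", s$name, "', row ", bad[1],
                            " value ", x[bad[1], j], " outside [0, 1]")
      out[, j] <- s$range_min + x[, j] * (s$range_max - s$range_min)
    }
  }
  out
}

#' Autoencoder configuration
#'
#' @param hidden Encoder hidden-layer widths (mirrored in the decoder).
#' @param embedding_dim Width of the bottleneck embedding layer (default 4).
#' @param activation Activation for all hidden layers including the
#'   embedding: `"elu"`, `"relu"` or `"sigmoid"`. The output layer is always
#'   sigmoid, keeping reconstructions inside the unit hypercube; with the
#'   default elu the embedding is bounded below by -1, consistent with the
#'   `[-1, 2.5]` sampling interval of [augment()].
#' @param learning_rate,decay Initial learning rate and its decay factor
#'   (applied once per 1000 epochs).
#' @param max_epochs Epoch cap (training usually stops earlier on the
#'   relative-improvement rule).
#' @param tol,patience Early stop when the relative loss improvement over
#'   `patience` consecutive epochs drops below `tol`.
#' @param seed Seed for initialization.
#' @return List of class `autoencoder_config`.
#' @export
autoencoder_config <- function(hidden = 16, embedding_dim = 4,
                               activation = c("elu", "relu", "sigmoid"),
                               learning_rate = 0.03, decay = 0.8,
                               max_epochs = 50000, tol = 1e-8, patience = 500,
                               seed = 1) {
  activation <- match.arg(activation)
  if (embedding_dim < 1) stop("embedding_dim must be >= 1")
  structure(list(hidden = hidden, embedding_dim = embedding_dim,
                 activation = activation, learning_rate = learning_rate,
                 decay = decay, max_epochs = max_epochs, tol = tol,
                 patience = patience, seed = seed),
            class = "autoencoder_config")
}

#' Train an autoencoder on normalized tabular data
#'
#' The encoder compresses each row through a low-dimensional embedding and
#' the decoder reconstructs it; both are trained jointly against mean
#' squared reconstruction error. The trained decoder is the generative half
#' used by [augment()] to synthesize new rows with the statistical structure
#' of the training set.
#'
#' @param data Numeric matrix with entries in `[0, 1]`, at least 8 rows.
#' @param config An [autoencoder_config()].
#' @return Object of class `autoencoder` with the network, the encoder
#'   depth, and a training `report` (reconstruction `mse`, `r2`, `epochs`).
#' @export
train_autoencoder <- function(data, config = autoencoder_config()) {
  data <- as.matrix(data)
  if (nrow(data) < 8) stop("need at least 8 rows to train an autoencoder")
  if (any(data < -1e-9 | data > 1 + 1e-9)) stop("data must be normalized to [0, 1]")
  d <- ncol(data)
  sizes <- c(d, config$hidden, config$embedding_dim, rev(config$hidden), d)
  # the embedding layer uses the hidden activation too (only the output is
  # sigmoid); with elu this bounds embeddings below by -1, matching the
  # default [-1, 2.5] sampling interval of augment()
  acts <- c(rep(config$activation, length(config$hidden) + 1L),
            rep(config$activation, length(config$hidden)), "sigmoid")
  net <- mlp_new(sizes, acts, seed = config$seed)
  tr <- mlp_train(net, data, data, epochs = config$max_epochs,
                  learning_rate = config$learning_rate, decay = config$decay,
                  tol = config$tol, patience = config$patience, seed = config$seed)
  # Standardize the reported embedding so the training rows span [-0.75,
  # 2.25] per dimension (an exact affine reparameterization, inverted inside
  # decode(), so the autoencoder function is unchanged). The default
  # sampling interval [-1, 2.5] of augment() is then exactly the "slightly
  # expanded" version of the range the embedding takes on the training set.
  raw <- encode_raw(tr$net, length(config$hidden) + 1L, data)
  lo <- apply(raw, 2, min); hi <- apply(raw, 2, max)
  span <- pmax(hi - lo, 1e-8)
  structure(list(net = tr$net,
                 n_encoder_layers = length(config$hidden) + 1L,
                 embedding_dim = config$embedding_dim,
                 emb_shift = lo, emb_scale = 3 / span,  # lo -> -0.75, hi -> 2.25
                 attributes = colnames(data),
                 config = config,
                 report = list(mse = tr$mse,
                               r2 = r_squared(data, mlp_predict(tr$net, data)),
                               epochs = tr$epochs)),
            class = "autoencoder")
}

#' @export
print.autoencoder <- function(x, ...) {
  cat(sprintf("autoencoder: %s -> %d -> %s (hidden %s), recon MSE %.2e, R2 %.3f\n",
              x$net$sizes[1], x$embedding_dim, x$net$sizes[length(x$net$sizes)],
              x$config$activation, x$report$mse, x$report$r2))
  invisible(x)
}

#' Encode rows to the embedding / decode embeddings to attribute space
#'
#' @param ae A trained `autoencoder`.
#' @param x Rows in attribute space (`encode`) or embedding space (`decode`).
#' @return Matrix of embeddings, or of decoded attributes in `[0, 1]`.
#' @export
encode <- function(ae, x) {
  raw <- encode_raw(ae$net, ae$n_encoder_layers, x)
  sweep(sweep(raw, 2, ae$emb_shift, `-`), 2, ae$emb_scale, `*`) - 0.75
}

encode_raw <- function(net, n_enc, x) {
  sub <- list(sizes = net$sizes[1:(n_enc + 1)], act = net$act[1:n_enc],
              W = net$W[1:n_enc], b = net$b[1:n_enc])
  mlp_predict(sub, as.matrix(x))
}

#' @rdname encode
#' @export
decode <- function(ae, x) {
  net <- ae$net
  idx <- (ae$n_encoder_layers + 1):length(net$W)
  sub <- list(sizes = net$sizes[c(idx, length(net$sizes))],
              act = net$act[idx], W = net$W[idx], b = net$b[idx])
  raw <- sweep(sweep(as.matrix(x) + 0.75, 2, ae$emb_scale, `/`), 2, ae$emb_shift, `+`)
  out <- mlp_predict(sub, raw)
  colnames(out) <- ae$attributes
  out
}

#' Grid search over autoencoder hyperparameters
#'
#' Trains one autoencoder per grid row and returns the configuration with
#' the lowest reconstruction MSE. Deterministic given the seed and the row
#' order of the grid.
#'
#' @param data Normalized training matrix.
#' @param grid Data frame with columns `hidden` (single hidden width),
#'   `activation`, `learning_rate`, `decay`; optional `embedding_dim`.
#' @param seed Base seed (row i trains with `seed + i - 1`).
#' @param max_epochs,tol,patience Passed to every candidate.
#' @return List: `best` (an `autoencoder_config`), `best_model` (the trained
#'   `autoencoder`) and `results` (grid with reconstruction `mse` appended).
#' @export
search_autoencoder <- function(data, grid, seed, max_epochs = 5000,
                               tol = 1e-6, patience = 100) {
  if (!is.data.frame(grid) || nrow(grid) == 0) stop("invalid argument: empty search grid")
  need <- c("hidden", "activation", "learning_rate", "decay")
  if (!all(need %in% names(grid))) stop("grid needs columns ", paste(need, collapse = ", "))
  mses <- numeric(nrow(grid))
  models <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- autoencoder_config(
      hidden = grid$hidden[i],
      embedding_dim = if ("embedding_dim" %in% names(grid)) grid$embedding_dim[i] else 4,
      activation = as.character(grid$activation[i]),
      learning_rate = grid$learning_rate[i], decay = grid$decay[i],
      max_epochs = max_epochs, tol = tol, patience = patience,
      seed = seed + i - 1)
    models[[i]] <- train_autoencoder(data, cfg)
    mses[i] <- models[[i]]$report$mse
  }
  best <- which.min(mses)
  res <- grid
  res$mse <- mses
  list(best = models[[best]]$config, best_model = models[[best]], results = res)
}

#' Generate synthetic rows from a trained decoder
#'
#' Samples embedding vectors i.i.d. uniformly over `interval` in every
#' embedding dimension (default `[-1, 2.5]`, a slightly expanded version of
#' the embedding range seen on real data) and decodes them, producing an
#' arbitrary number of new normalized rows that follow the statistical
#' trends of the training set.
#'
#' @param ae A trained `autoencoder`.
#' @param n_samples Number of rows to generate (default 10000).
#' @param interval Length-2 sampling interval for every embedding dimension.
#' @param seed Sampling seed.
#' @return Matrix of class `augmented_dataset` (`n_samples` x attributes,
#'   entries in `[0, 1]`) with provenance attributes `interval` and `seed`.
#' @export
augment <- function(ae, n_samples = 10000, interval = c(-1, 2.5), seed) {
  if (!is.numeric(n_samples) || n_samples < 1) stop("invalid argument: n_samples must be >= 1")
  if (interval[1] >= interval[2]) stop("invalid argument: interval low must be < high")
  if (missing(seed)) stop("a seed is required for augmentation sampling")
  set.seed(seed)
  Z <- matrix(stats::runif(n_samples * ae$embedding_dim, interval[1], interval[2]),
              nrow = n_samples)
  out <- decode(ae, Z)
  structure(out, class = c("augmented_dataset", class(out)),
            interval = interval, seed = seed)
}

#' Predictor (MLP) configuration
#'
#' The predictor is a multilayer perceptron with exactly three hidden
#' layers, elu-family hidden activations and a sigmoid output, regularized
#' by dropout and an l2 weight penalty.
#'
#' @param neurons Hidden width: a single number (replicated over the three
#'   hidden layers) or a length-3 vector.
#' @param activation Hidden activation (`"elu"`, `"relu"`, `"sigmoid"`).
#' @param learning_rate,decay Initial learning rate and decay factor per
#'   1000 epochs.
#' @param dropout Hidden-unit dropout probability (default 0.05).
#' @param l2 Weight-penalty coefficient (default 0.01).
#' @param max_epochs,tol,patience Training budget and early-stop rule.
#' @param seed Seed for initialization and dropout.
#' @return List of class `predictor_config`.
#' @export
predictor_config <- function(neurons = 7, activation = c("elu", "relu", "sigmoid"),
                             learning_rate = 0.02, decay = 0.85,
                             dropout = 0.05, l2 = 0.01,
                             max_epochs = 10000, tol = 1e-8, patience = 1000,
                             seed = 1) {
  activation <- match.arg(activation)
  if (length(neurons) == 1) neurons <- rep(neurons, 3)
  if (length(neurons) != 3) stop("the predictor has exactly three hidden layers")
  structure(list(neurons = neurons, activation = activation,
                 learning_rate = learning_rate, decay = decay,
                 dropout = dropout, l2 = l2, max_epochs = max_epochs,
                 tol = tol, patience = patience, seed = seed),
            class = "predictor_config")
}

#' Train the MLP response predictor
#'
#' @param x Matrix of normalized inputs (factor settings in `[0, 1]`),
#'   typically the factor columns of an [augment()]ed dataset.
#' @param y Normalized target response in `[0, 1]`.
#' @param config A [predictor_config()].
#' @return Object of class `mlp_predictor` with a training report; use
#'   [predict()] for new inputs and [validate_on_original()] for evaluation.
#' @export
train_predictor <- function(x, y, config = predictor_config()) {
  x <- as.matrix(x)
  Y <- matrix(y, ncol = 1)
  sizes <- c(ncol(x), config$neurons, 1)
  acts <- c(rep(config$activation, 3), "sigmoid")
  net <- mlp_new(sizes, acts, seed = config$seed)
  tr <- mlp_train(net, x, Y, epochs = config$max_epochs,
                  learning_rate = config$learning_rate, decay = config$decay,
                  l2 = config$l2, dropout = config$dropout,
                  tol = config$tol, patience = config$patience, seed = config$seed)
  structure(list(net = tr$net, config = config,
                 report = list(mse = tr$mse,
                               r2 = r_squared(Y, mlp_predict(tr$net, x)),
                               epochs = tr$epochs)),
            class = "mlp_predictor")
}

#' @export
predict.mlp_predictor <- function(object, newdata, ...) {
  drop(mlp_predict(object$net, as.matrix(newdata)))
}

#' @export
print.mlp_predictor <- function(x, ...) {
  cat(sprintf("MLP predictor %s, training MSE %.2e (R2 %.3f, %d epochs)\n",
              paste(x$net$sizes, collapse = "-"), x$report$mse, x$report$r2,
              x$report$epochs))
  invisible(x)
}

#' Five-fold cross-validated hyperparameter selection for the predictor
#'
#' Rows are partitioned into `folds` disjoint seeded folds; every grid row
#' is trained on each training split and scored on the held-out fold. The
#' configuration with the lowest mean validation MSE wins; ties go to the
#' network with fewer total hidden neurons.
#'
#' @param x,y Normalized inputs and target.
#' @param grid Data frame with columns `neurons`, `activation`,
#'   `learning_rate`, `decay` (optional `dropout`, `l2`).
#' @param folds Number of folds (default 5, >= 2).
#' @param seed Seed for the fold assignment and per-candidate training.
#' @param max_epochs,tol,patience Training budget per candidate fit.
#' @return List: `best` (`predictor_config`), `results` (grid with mean
#'   validation `mse` and `r2`), `fold_mse` (configs x folds matrix),
#'   `fold_id` (the row assignment).
#' @export
cross_validate_predictor <- function(x, y, grid, folds = 5, seed,
                                     max_epochs = 3000, tol = 1e-6, patience = 100) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (!is.data.frame(grid) || nrow(grid) == 0) stop("invalid argument: empty search grid")
  if (folds < 2) stop("invalid argument: folds must be >= 2")
  if (n / folds < 2) stop("invalid argument: fold size below 2 rows")
  set.seed(seed)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  fold_mse <- matrix(NA_real_, nrow(grid), folds)
  for (i in seq_len(nrow(grid))) {
    cfg <- predictor_config(
      neurons = grid$neurons[i], activation = as.character(grid$activation[i]),
      learning_rate = grid$learning_rate[i], decay = grid$decay[i],
      dropout = if ("dropout" %in% names(grid)) grid$dropout[i] else 0.05,
      l2 = if ("l2" %in% names(grid)) grid$l2[i] else 0.01,
      max_epochs = max_epochs, tol = tol, patience = patience,
      seed = seed + i)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      p <- train_predictor(x[tr, , drop = FALSE], y[tr], cfg)
      fold_mse[i, f] <- mean((predict(p, x[!tr, , drop = FALSE]) - y[!tr])^2)
    }
  }
  mean_mse <- rowMeans(fold_mse)
  total_neurons <- 3 * grid$neurons
  best <- order(mean_mse, total_neurons)[1]
  res <- grid
  res$mse <- mean_mse
  best_cfg <- predictor_config(
    neurons = grid$neurons[best], activation = as.character(grid$activation[best]),
    learning_rate = grid$learning_rate[best], decay = grid$decay[best],
    dropout = if ("dropout" %in% names(grid)) grid$dropout[best] else 0.05,
    l2 = if ("l2" %in% names(grid)) grid$l2[best] else 0.01,
    max_epochs = max_epochs, tol = tol, patience = patience, seed = seed + best)
  list(best = best_cfg, results = res, fold_mse = fold_mse, fold_id = fold_id)
}

#' Validate a predictor on the original experimental rows
#'
#' The augmentation-success check: the predictor is trained on decoder
#' output only, so scoring it on the held-out original design rows measures
#' how faithfully the augmented cloud carries the original factor-response
#' relationship.
#'
#' @param predictor An `mlp_predictor`, any object with a `predict` method,
#'   or a plain function of the input matrix returning normalized responses.
#' @param x,y Normalized original inputs and responses (never used in
#'   training).
#' @return List with `mse` and `r2` (computed against the validation set's
#'   own mean).
#' @export
validate_on_original <- function(predictor, x, y) {
  pred <- if (is.function(predictor)) predictor(as.matrix(x))
          else predict(predictor, as.matrix(x))
  list(mse = mean((pred - y)^2), r2 = r_squared(matrix(y), matrix(pred)))
}
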