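#' Bi-LSTM model specification
#'
#' The regressor reads a sequence of `seq_len` cardiac cycles with
#' `n_features` features each through a bidirectional LSTM with `hidden`
#' units per direction (tanh activations), concatenates both directions at
#' each timestep (`2 * hidden` wide), flattens across time
#' (`seq_len * 2 * hidden` wide), optionally appends five demographic
#' inputs (gender, age, height, weight, BMI), and maps through a ReLU
#' fully connected layer of `fc1_units` to a linear 2-unit output
#' (SBP, DBP). Dropout acts variationally on the LSTM input and recurrent
#' connections.
#'
#' @param seq_len cycles per sequence.
#' @param n_features features per cycle.
#' @param hidden LSTM hidden units per direction.
#' @param fc1_units first fully connected layer width.
#' @param dropout dropout fraction on LSTM connections.
#' @param use_demographics append demographic inputs to the first fully
#'   connected layer.
#' @return a `model_spec` list; `flat_width` gives the flattened pre-FC
#'   width.
#' @export
model_spec <- function(seq_len = 10L, n_features = 7L, hidden = 128L,
                       fc1_units = 64L, dropout = 0.10,
                       use_demographics = FALSE) {
  stopifnot(seq_len >= 1, n_features >= 1, hidden >= 1, fc1_units >= 1,
            dropout >= 0, dropout < 1)
  structure(list(seq_len = as.integer(seq_len),
                 n_features = as.integer(n_features),
                 hidden = as.integer(hidden),
                 fc1_units = as.integer(fc1_units),
                 dropout = dropout,
                 use_demographics = isTRUE(use_demographics),
                 step_width = 2L * as.integer(hidden),
                 flat_width = as.integer(seq_len) * 2L * as.integer(hidden)),
            class = "model_spec")
}

#' Training configuration
#'
#' Defaults: Adam with learning rate 1e-3, MSE loss on (SBP, DBP) jointly,
#' batch size 64, at most 100 epochs with early stopping at patience 10,
#' 60/20/20 train/validation/test split, and 3 independently seeded runs
#' whose predictions are averaged.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param n_runs independently initialized runs to average.
#' @param split train/validation/test fractions (sum to 1).
#' @param seed master seed; all run/shuffle/dropout seeds derive from it.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64L,
                         max_epochs = 100L, patience = 10L, n_runs = 3L,
                         split = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(abs(sum(split) - 1) < 1e-9, n_runs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 n_runs = as.integer(n_runs), split = split,
                 seed = as.integer(seed)), class = "train_config")
}

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build (initialize) a Bi-LSTM model
#'
#' Weights use scaled-uniform (Glorot) initialization with forget-gate
#' biases at 1; `init = "zero"` gives an all-zero parameter store (useful
#' for structural checks: the linear head then outputs exactly 0).
#'
#' @param spec a [model_spec()].
#' @param seed integer seed for the initialization.
#' @param init `"glorot"` or `"zero"`.
#' @return a `bp_model`: `spec`, `params` (named matrices, partitioned into
#'   a recurrent block `Wx_f, Wh_f, b_f, Wx_b, Wh_b, b_b` and a fully
#'   connected block `W1, b1, W2, b2`), empty `history`.
#' @export
build_model <- function(spec, seed = 1L, init = c("glorot", "zero")) {
  init <- match.arg(init)
  H <- spec$hidden; F <- spec$n_features
  D <- spec$flat_width + if (spec$use_demographics) 5L else 0L
  params <- with_seed(seed, {
    if (init == "zero") {
      list(Wx_f = matrix(0, 4 * H, F), Wh_f = matrix(0, 4 * H, H),
           b_f = numeric(4 * H),
           Wx_b = matrix(0, 4 * H, F), Wh_b = matrix(0, 4 * H, H),
           b_b = numeric(4 * H),
           W1 = matrix(0, spec$fc1_units, D), b1 = numeric(spec$fc1_units),
           W2 = matrix(0, 2, spec$fc1_units), b2 = numeric(2))
    } else {
      bias <- numeric(4 * H)
      bias[(H + 1):(2 * H)] <- 1 # forget gate
      list(Wx_f = .glorot(4 * H, F), Wh_f = .glorot(4 * H, H), b_f = bias,
           Wx_b = .glorot(4 * H, F), Wh_b = .glorot(4 * H, H), b_b = bias,
           W1 = .glorot(spec$fc1_units, D), b1 = numeric(spec$fc1_units),
           W2 = .glorot(2, spec$fc1_units), b2 = numeric(2))
    }
  })
  structure(list(spec = spec, params = params, history = NULL,
                 stats = NULL, demo_stats = NULL, provenance = list()),
            class = "bp_model")
}

#' Parameter counts by block
#'
#' @param model a `bp_model`.
#' @return list with `recurrent`, `fc` and `total` parameter counts. For
#'   hidden size H and F input features the recurrent block holds
#'   `2 * 4 * (H*(F+H) + H)` parameters.
#' @export
count_params <- function(model) {
  sizes <- vapply(model$params, length, numeric(1))
  rec <- sum(sizes[c("Wx_f", "Wh_f", "b_f", "Wx_b", "Wh_b", "b_b")])
  fc <- sum(sizes[c("W1", "b1", "W2", "b2")])
  list(recurrent = unname(rec), fc = unname(fc), total = unname(rec + fc))
}

RECURRENT_BLOCK <- c("Wx_f", "Wh_f", "b_f", "Wx_b", "Wh_b", "b_b")
FC_BLOCK <- c("W1", "b1", "W2", "b2")

# sequences array [n, L, F] -> cube (n, F, L) expected by the C++ core
.to_cube <- function(x) aperm(x, c(1, 3, 2))

.ones_masks <- function(n, spec) {
  list(xf = matrix(1, n, spec$n_features), hf = matrix(1, n, spec$hidden),
       xb = matrix(1, n, spec$n_features), hb = matrix(1, n, spec$hidden))
}

.drop_masks <- function(n, spec) {
  p <- spec$dropout
  if (p <= 0) return(.ones_masks(n, spec))
  rb <- function(nr, nc)
    matrix(rbinom(nr * nc, 1, 1 - p), nr, nc) / (1 - p)
  list(xf = rb(n, spec$n_features), hf = rb(n, spec$hidden),
       xb = rb(n, spec$n_features), hb = rb(n, spec$hidden))
}

#' Forward pass: predict SBP/DBP for sequences
#'
#' @param model a trained `bp_model`.
#' @param x array `[n, L, F]` of (already standardized) sequences, or a
#'   `feature_sequences` object.
#' @param demo optional `n x 5` demographics matrix (required when the
#'   spec uses demographics).
#' @param batch_size forward-pass batch size.
#' @return `n x 2` matrix of predictions (`sbp`, `dbp`) in mmHg.
#' @export
predict_bp <- function(model, x, demo = NULL, batch_size = 512L) {
  if (inherits(x, "feature_sequences")) x <- x$x
  spec <- model$spec
  n <- dim(x)[1]
  if (spec$use_demographics && is.null(demo))
    stop("model requires demographics", call. = FALSE)
  if (!spec$use_demographics) demo <- matrix(numeric(0), n, 0)
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("sbp", "dbp")))
  for (at in seq(1L, n, by = batch_size)) {
    i <- at:min(n, at + batch_size - 1L)
    m <- .ones_masks(length(i), spec)
    r <- cpp_bilstm_pass(model$params, .to_cube(x[i, , , drop = FALSE]),
                         demo[i, , drop = FALSE],
                         matrix(numeric(0), 0, 2),
                         m$xf, m$hf, m$xb, m$hb, FALSE)
    out[i, ] <- r$pred
  }
  out
}

.mse_loss <- function(model, x, y, demo) {
  p <- predict_bp(model, x, demo)
  mean((p - y)^2)
}

#' Train (or fine-tune) a Bi-LSTM model
#'
#' Minimizes the joint MSE on (SBP, DBP) with Adam and minibatches,
#' monitors the validation loss each epoch, stops after `patience` epochs
#' without improvement and restores the best-validation parameters.
#' Reproducible for a fixed `config$seed` (single-threaded BLAS assumed).
#'
#' @param model a `bp_model` from [build_model()].
#' @param train,val lists with `x` (`[n, L, F]` array), `y` (`n x 2`
#'   matrix) and optionally `demo` (`n x 5`).
#' @param config a [train_config()]; `n_runs` is ignored here (averaging
#'   is handled by the protocol wrappers).
#' @param trainable `"all"`, or `"fc"` to freeze the recurrent block
#'   (fine-tuning).
#' @return the trained `bp_model` with `history` (per-epoch train/val
#'   loss and the restored epoch).
#' @export
train_model <- function(model, train, val, config = train_config(),
                        trainable = c("all", "fc")) {
  trainable <- match.arg(trainable)
  n <- dim(train$x)[1]
  if (!n || !dim(val$x)[1]) stop("empty train or validation split",
                                 call. = FALSE)
  spec <- model$spec
  upd <- if (trainable == "fc") FC_BLOCK else c(RECURRENT_BLOCK, FC_BLOCK)
  demo_tr <- if (spec$use_demographics) train$demo else
    matrix(numeric(0), n, 0)
  demo_val <- if (spec$use_demographics) val$demo else NULL
  if (spec$use_demographics && (is.null(train$demo) || is.null(val$demo)))
    stop("spec uses demographics but none supplied", call. = FALSE)

  # start the linear head at the training-label mean so optimization
  # spends its budget on the mapping, not on the intercept
  if (trainable == "all" && all(model$params$b2 == 0))
    model$params$b2 <- colMeans(train$y)

  adam_m <- lapply(model$params[upd], function(p) p * 0)
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  with_seed(config$seed, {
    wait <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      tot <- 0; nb <- 0L
      for (at in seq(1L, n, by = config$batch_size)) {
        i <- ord[at:min(n, at + config$batch_size - 1L)]
        masks <- .drop_masks(length(i), spec)
        r <- cpp_bilstm_pass(model$params,
                             .to_cube(train$x[i, , , drop = FALSE]),
                             demo_tr[i, , drop = FALSE],
                             train$y[i, , drop = FALSE],
                             masks$xf, masks$hf, masks$xb, masks$hb, TRUE)
        step <- step + 1L
        g <- r$grads
        corr <- sqrt(1 - b2^step) / (1 - b1^step)
        for (k in upd) {
          adam_m[[k]] <- b1 * adam_m[[k]] + (1 - b1) * g[[k]]
          adam_v[[k]] <- b2 * adam_v[[k]] + (1 - b2) * g[[k]]^2
          model$params[[k]] <- model$params[[k]] -
            config$learning_rate * corr * adam_m[[k]] /
            (sqrt(adam_v[[k]]) + eps)
        }
        tot <- tot + r$loss; nb <- nb + 1L
      }
      vl <- .mse_loss(model, val$x, val$y, demo_val)
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tot / nb,
                                     val_loss = vl))
      if (vl < best$loss - 1e-12) {
        best <- list(loss = vl, params = model$params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  model$params <- best$params
  model$history <- hist
  model$provenance$restored_epoch <- best$epoch
  model$provenance$val_loss <- best$loss
  model
}

#' Fine-tune the fully connected head of a trained model
#'
#' The recurrent block is frozen (bit-identical before and after); only
#' the fully connected layers are updated on the tuning sequences. A 25%
#' slice of the tuning set is held out as the early-stopping monitor.
#'
#' @param model a trained `bp_model`.
#' @param tune list with `x`, `y` and optionally `demo`: the tuning subset
#'   (typically 20% of the held-out subject's sequences).
#' @param config a [train_config()]; defaults here cap epochs at 50.
#' @return the fine-tuned `bp_model`.
#' @export
fine_tune_model <- function(model, tune,
                            config = train_config(max_epochs = 50L)) {
  n <- dim(tune$x)[1]
  if (!n) stop("tuning set is empty", call. = FALSE)
  n_val <- max(1L, floor(0.25 * n))
  idx <- with_seed(derive_seed(config$seed, 77L), sample.int(n))
  vi <- idx[seq_len(n_val)]
  ti <- idx[-seq_len(n_val)]
  if (!length(ti)) { ti <- vi } # degenerate tiny tuning sets
  pick <- function(i) list(
    x = tune$x[i, , , drop = FALSE], y = tune$y[i, , drop = FALSE],
    demo = if (!is.null(tune$demo)) tune$demo[i, , drop = FALSE])
  train_model(model, pick(ti), pick(vi), config, trainable = "fc")
}
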