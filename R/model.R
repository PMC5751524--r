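# The three-channel bidirectional peephole-LSTM relation classifier:
# parameter containers, a pure-R reference implementation of the LSTM block,
# and the forward pass used for prediction. The training loop drives the
# compiled kernel in src/.

#' Model and training configuration
#'
#' Defaults follow the published hyperparameter table: word-embedding
#' dimension `dw = 100`, distance-code dimension `dp = 10` (fixed by the
#' 10-bit encoding), `num = 300` hidden units, dropout ratio `rho = 0.7`
#' read as the keep probability, L2 coefficient `l2 = 0.001`, Adam learning
#' rate `la = 0.01`, undersampling ratio `alpha = 0.5`, oversampling ratio
#' `beta = 0.5` with `K = 6` rounds. Batch size, epoch budget, clipping
#' norm, dev fraction and early-stopping patience are this package's own
#' desk-scale choices.
#'
#' @param dw Word-embedding dimension.
#' @param num Hidden units per LSTM direction.
#' @param rho Dropout keep probability on the tanh layer before softmax
#'   (an alternative reading as the drop probability can be obtained by
#'   passing `rho = 0.3`).
#' @param l2 L2 regularization coefficient (weights only, biases excluded).
#' @param la Adam learning rate.
#' @param alpha Per-epoch undersampling ratio for Negative instances.
#' @param beta Oversampling ratio for Int instances.
#' @param K Number of oversampling rounds.
#' @param channels Channels to build: subset of `c("linear","dfs","bfs")`.
#' @param batch_size Minibatch size.
#' @param epochs Maximum training epochs.
#' @param clip Global gradient-norm clipping threshold.
#' @param dev_fraction Fraction of training sentences held out for early
#'   stopping.
#' @param patience Early-stopping patience in epochs (on dev micro-F).
#' @param average Keep a running (Polyak) average of the parameters and use
#'   it at evaluation time.
#' @param seed Integer seed controlling initialization, sampling, dropout.
#' @return A `ddi_config` list.
#' @export
ddi_config <- function(dw = 100L, num = 300L, rho = 0.7, l2 = 0.001,
                       la = 0.01, alpha = 0.5, beta = 0.5, K = 6L,
                       channels = c("linear", "dfs", "bfs"),
                       batch_size = 64L, epochs = 30L, clip = 5,
                       dev_fraction = 0.1, patience = 5L,
                       average = TRUE, seed = 1L) {
  stopifnot(
    dw >= 1, num >= 1, rho > 0, rho <= 1, l2 >= 0, la >= 0,
    alpha > 0, alpha <= 1, beta > 0, beta <= 1, K >= 1,
    all(channels %in% c("linear", "dfs", "bfs")), length(channels) >= 1
  )
  structure(
    list(
      dw = as.integer(dw), dp = 10L, num = as.integer(num), rho = rho,
      l2 = l2, la = la, alpha = alpha, beta = beta, K = as.integer(K),
      channels = channels, batch_size = as.integer(batch_size),
      epochs = as.integer(epochs), clip = clip,
      dev_fraction = dev_fraction, patience = as.integer(patience),
      average = isTRUE(average), seed = as.integer(seed)
    ),
    class = "ddi_config"
  )
}

# Uniform fan-in-scaled initialization for one LSTM direction. The forget
# bias starts at 1 (standard practice for trainability). Peepholes are
# diagonal, initialized small.
init_lstm_params <- function(d_in, num) {
  lim <- 1 / sqrt(d_in + num)
  b <- numeric(4 * num)
  b[(num + 1):(2 * num)] <- 1
  list(
    Wx = matrix(runif(4 * num * d_in, -lim, lim), 4 * num, d_in),
    Wh = matrix(runif(4 * num * num, -lim, lim), 4 * num, num),
    b = b,
    pi = runif(num, -lim, lim),
    pf = runif(num, -lim, lim),
    po = runif(num, -lim, lim)
  )
}

# Full parameter set: embeddings, per-channel forward/backward LSTMs, and
# the softmax head over the concatenated pooled channel outputs (dimension
# length(channels) * num -- averaging the two directions, rather than
# concatenating them, keeps the head at C*num instead of 2*C*num).
init_ddi_params <- function(vocab, config, embeddings = NULL) {
  d_in <- config$dw + 2L * config$dp
  if (is.null(embeddings)) {
    embeddings <- init_embeddings(vocab, config$dw)
  }
  stopifnot(nrow(embeddings) == length(vocab), ncol(embeddings) == config$dw)
  channels <- lapply(config$channels, function(ch) {
    list(fwd = init_lstm_params(d_in, config$num), bwd = init_lstm_params(d_in, config$num))
  })
  names(channels) <- config$channels
  hdim <- length(config$channels) * config$num
  lim <- 1 / sqrt(hdim)
  list(
    emb = embeddings,
    channels = channels,
    Ws = matrix(runif(5 * hdim, -lim, lim), 5, hdim),
    bs = numeric(5)
  )
}

#' One step of the peephole LSTM block (reference implementation)
#'
#' Computes the input and forget gates from the current input, previous
#' hidden state and previous cell state; the candidate activation; the new
#' cell; the output gate (whose peephole reads the *current* cell); and the
#' new hidden state `h = o * tanh(c)`. Peepholes are diagonal. This pure-R
#' version is the reference the compiled training kernel is tested against.
#'
#' @param x Input vector (length `dw + 2 dp`).
#' @param state List with `h` and `c` vectors (the previous state).
#' @param params One direction's parameter list (`Wx`, `Wh`, `b`, `pi`,
#'   `pf`, `po`) as produced inside [train_ddi_dlstm()].
#' @return List with the new `h` and `c`.
#' @export
lstm_step <- function(x, state, params) {
  if (!all(is.finite(x))) stop("non-finite input to lstm_step", call. = FALSE)
  num <- length(state$h)
  a <- as.vector(params$Wx %*% x + params$Wh %*% state$h + params$b)
  sigm <- function(u) 1 / (1 + exp(-u))
  i <- sigm(a[1:num] + params$pi * state$c)
  f <- sigm(a[(num + 1):(2 * num)] + params$pf * state$c)
  g <- tanh(a[(2 * num + 1):(3 * num)])
  c2 <- f * state$c + i * g
  o <- sigm(a[(3 * num + 1):(4 * num)] + params$po * c2)
  list(h = o * tanh(c2), c = c2)
}

#' Run one bidirectional channel
#'
#' Forward LSTM over the sequence, backward LSTM over the reversed
#' sequence with outputs re-reversed so both align by token, element-wise
#' averaging `z_t = (h^f_t + h^b_t) / 2`, and max pooling over time.
#'
#' @param X `m x (dw + 2 dp)` input matrix, rows in run order (`m >= 1`).
#' @param fwd,bwd Parameter lists for the two directions.
#' @param engine `"cpp"` (compiled) or `"r"` (reference loop over
#'   [lstm_step()]); both produce the same output.
#' @return List with `h_f`, `h_b` (token-aligned `m x num` matrices), `z`,
#'   `pooled` (length-`num` component-wise maximum of the rows of `z`) and
#'   `argmax` (the pooling row index per component).
#' @export
run_channel <- function(X, fwd, bwd, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  m <- nrow(X)
  if (is.null(m) || m < 1) stop("run_channel requires m >= 1", call. = FALSE)
  if (engine == "cpp") {
    return(cpp_channel_forward(X, fwd, bwd))
  }
  num <- ncol(fwd$Wh)
  run_dir <- function(Xd, p) {
    st <- list(h = numeric(num), c = numeric(num))
    H <- matrix(0, nrow(Xd), num)
    for (t in seq_len(nrow(Xd))) {
      st <- lstm_step(Xd[t, ], st, p)
      H[t, ] <- st$h
    }
    H
  }
  h_f <- run_dir(X, fwd)
  h_b <- run_dir(X[m:1, , drop = FALSE], bwd)[m:1, , drop = FALSE]
  z <- (h_f + h_b) / 2
  list(
    h_f = h_f, h_b = h_b, z = z,
    pooled = apply(z, 2, max),
    argmax = apply(z, 2, which.max)
  )
}

#' Forward pass of the full classifier
#'
#' Pools each channel, concatenates in the fixed order given by the
#' parameter set (linear, DFS, BFS by default), applies tanh, dropout (in
#' training mode only) and the softmax head.
#'
#' @param channel_mats Named list of channel input matrices (as from
#'   [build_channels()]), in the parameter set's channel order.
#' @param params Full parameter set (`channels`, `Ws`, `bs`).
#' @param train Apply dropout.
#' @param rho Keep probability when `train = TRUE`.
#' @return Named probability vector over [ddi_classes()], summing to 1.
#' @export
ddi_forward <- function(channel_mats, params, train = FALSE, rho = 0.7) {
  stopifnot(length(channel_mats) == length(params$channels))
  pooled <- unlist(lapply(seq_along(channel_mats), function(c) {
    run_channel(
      channel_mats[[c]], params$channels[[c]]$fwd, params$channels[[c]]$bwd
    )$pooled
  }))
  if (length(pooled) != ncol(params$Ws)) {
    stop("channel dimension mismatch: head expects ", ncol(params$Ws),
      ", got ", length(pooled),
      call. = FALSE
    )
  }
  hs <- tanh(pooled)
  if (train) {
    hs <- hs * (rbinom(length(hs), 1, rho) / rho)
  }
  logits <- as.vector(params$Ws %*% hs + params$bs)
  logits <- logits - max(logits)
  p <- exp(logits) / sum(exp(logits))
  setNames(p, ddi_classes())
}

#' Argmax label from a probability vector
#'
#' Ties are broken by the fixed class order Advice, Effect, Mechanism, Int,
#' Negative.
#'
#' @param p Probability vector of length 5 (in [ddi_classes()] order).
#' @return A single class label.
#' @export
predict_label <- function(p) {
  ddi_classes()[which.max(p)]
}

# Serialize a fitted model (or raw parameter set) to a portable JSON-backed
# checkpoint: a JSON header with dimensions and config plus flattened
# parameter values.
#' Save / load a model checkpoint
#'
#' The checkpoint is a single JSON file holding a header (dimensions,
#' channel set, config, vocabulary) and all parameter values; it is
#' text-only and portable.
#'
#' @param fit A `ddi_dlstm` object.
#' @param path Checkpoint file path.
#' @return `path` invisibly for save; a `ddi_dlstm` object for load.
#' @export
save_checkpoint <- function(fit, path) {
  obj <- list(
    header = list(
      package = "ddilstm", version = "0.1.0",
      classes = ddi_classes(), channels = fit$config$channels,
      dw = fit$config$dw, num = fit$config$num,
      vocab = names(fit$vocab)
    ),
    config = unclass(fit$config),
    params = fit$params,
    avg_params = fit$avg_params,
    history = fit$history
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vocab <- setNames(seq_along(obj$header$vocab), obj$header$vocab)
  class(vocab) <- "ddi_vocab"
  relist_params <- function(p) {
    p$emb <- as.matrix(p$emb)
    p$Ws <- as.matrix(p$Ws)
    p$channels <- lapply(p$channels, function(ch) {
      lapply(ch, function(dir) {
        dir$Wx <- as.matrix(dir$Wx)
        dir$Wh <- as.matrix(dir$Wh)
        dir
      })
    })
    p
  }
  cfg <- do.call(ddi_config, obj$config[setdiff(names(obj$config), "dp")])
  fit <- list(
    params = relist_params(obj$params),
    avg_params = if (!is.null(obj$avg_params)) relist_params(obj$avg_params),
    vocab = vocab, config = cfg,
    history = tibble::as_tibble(obj$history),
    classes = ddi_classes()
  )
  class(fit) <- "ddi_dlstm"
  fit
}
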