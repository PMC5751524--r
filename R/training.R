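# Imbalance-aware training loop: per-epoch negative undersampling, K-round
# Int oversampling, Adam with global-norm gradient clipping, L2 on weights,
# and a running (Polyak) parameter average used at evaluation time.

# ---- flat parameter vector helpers --------------------------------------

flatten_params <- function(p) unlist(p, use.names = FALSE)

relist_like <- function(x, skel) {
  i <- 0L
  rec <- function(s) {
    if (is.list(s)) {
      return(lapply(s, rec))
    }
    n <- length(s)
    out <- x[(i + 1L):(i + n)]
    i <<- i + n
    if (!is.null(dim(s))) dim(out) <- dim(s)
    out
  }
  rec(skel)
}

# 1 for weight leaves (LSTM matrices, peepholes, softmax matrix), 0 for
# biases and the embedding table: the L2 penalty covers weights only.
l2_mask_params <- function(params) {
  mask_dir <- function(d) {
    list(
      Wx = d$Wx * 0 + 1, Wh = d$Wh * 0 + 1, b = d$b * 0,
      pi = d$pi * 0 + 1, pf = d$pf * 0 + 1, po = d$po * 0 + 1
    )
  }
  list(
    emb = params$emb * 0,
    channels = lapply(params$channels, function(ch) {
      list(fwd = mask_dir(ch$fwd), bwd = mask_dir(ch$bwd))
    }),
    Ws = params$Ws * 0 + 1,
    bs = params$bs * 0
  )
}

# ---- sampling ------------------------------------------------------------

sample_epoch_indices <- function(labels, alpha, beta, K) {
  neg <- which(labels == "Negative")
  int <- which(labels == "Int")
  rest <- which(!labels %in% c("Negative", "Int"))
  idx <- rest
  if (length(neg) > 0) {
    idx <- c(idx, sample(neg, floor(alpha * length(neg))))
  }
  if (length(int) > 0) {
    n_draw <- floor(beta * length(int))
    for (k in seq_len(K)) {
      idx <- c(idx, sample(int, n_draw))
    }
  }
  sample(idx)
}

#' Resample the training set for one epoch
#'
#' Negative instances are undersampled: one fresh draw of
#' `floor(alpha * |Neg|)` without replacement per epoch, so different epochs
#' see different negative subsets and, over epochs, all negatives are
#' covered. Int instances are oversampled: `K` independent draws of
#' `floor(beta * |Int|)` without replacement are concatenated (duplicates
#' across draws are intended). Advice, Effect and Mechanism pass through
#' unchanged. The result is shuffled. Instance contents are never altered,
#' only multiplicity and order.
#'
#' @param instances Instance tibble (the filtered training set).
#' @param alpha,beta,K Sampling parameters (see [ddi_config()]).
#' @param seed Optional base seed; the epoch number is added so every epoch
#'   draws a different, reproducible subset.
#' @param epoch Epoch number (used only with `seed`).
#' @return The resampled instance tibble.
#' @export
sample_epoch <- function(instances, alpha = 0.5, beta = 0.5, K = 6L,
                         seed = NULL, epoch = 0L) {
  if (!is.null(seed)) set.seed(as.integer(seed) + as.integer(epoch))
  instances[sample_epoch_indices(instances$label, alpha, beta, K), ]
}

# ---- loss ----------------------------------------------------------------

#' Cross-entropy loss with optional L2 penalty
#'
#' Mean cross-entropy over the batch, with the probability at the true
#' label clamped at 1e-12, plus `l2` times the squared norm of the weight
#' parameters (biases and embeddings excluded).
#'
#' @param probs `n x 5` matrix of class probabilities (columns in
#'   [ddi_classes()] order) or a single probability vector.
#' @param labels Character labels (or integer indices into [ddi_classes()]).
#' @param l2 L2 coefficient.
#' @param params Optional full parameter set for the penalty term.
#' @return A single number.
#' @export
ddi_loss <- function(probs, labels, l2 = 0, params = NULL) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  y <- if (is.character(labels)) match(labels, ddi_classes()) else as.integer(labels)
  stopifnot(length(y) == nrow(probs), !anyNA(y))
  p_true <- probs[cbind(seq_len(nrow(probs)), y)]
  ce <- -mean(log(pmax(p_true, 1e-12)))
  pen <- 0
  if (!is.null(params) && l2 > 0) {
    flat <- flatten_params(params)
    mask <- flatten_params(l2_mask_params(params))
    pen <- l2 * sum((flat * mask)^2)
  }
  ce + pen
}

# ---- prediction over instance tibbles ------------------------------------

# Precompute the per-channel integer data (ids + distance codes) for every
# valid instance; returns a list parallel to the rows, NULL where invalid.
precompute_channels <- function(instances, vocab, channels) {
  lapply(seq_len(nrow(instances)), function(i) {
    if (!isTRUE(instances$valid[i])) {
      return(NULL)
    }
    dat <- instance_channel_data(
      instances$tokens[[i]], instances$drug1_index[i], instances$drug2_index[i],
      head = instances$head[[i]], deprel = instances$deprel[[i]],
      vocab = vocab, channels = channels,
      sentence_id = instances$sentence_id[i]
    )
    lapply(dat, function(ch) list(ids = ch$ids, codes = ch$codes))
  })
}

predict_probs <- function(params, chan_data, chunk = 256L) {
  ok <- !vapply(chan_data, is.null, TRUE)
  n <- length(chan_data)
  probs <- matrix(NA_real_, n, 5, dimnames = list(NULL, ddi_classes()))
  idx <- which(ok)
  for (start in seq(1, length(idx), by = chunk)) {
    sl <- idx[start:min(start + chunk - 1L, length(idx))]
    res <- cpp_batch(
      chan_data[sl], params$emb, unname(params$channels),
      params$Ws, params$bs, integer(length(sl)), NULL, FALSE
    )
    probs[sl, ] <- res$probs
  }
  probs
}

#' Predict DDI labels for candidate instances
#'
#' @param object A fitted `ddi_dlstm` model.
#' @param instances Instance tibble from [candidate_instances()].
#' @param use_average Use the Polyak-averaged parameters (when available).
#' @param ... Unused.
#' @return The input tibble with columns `.pred` (class label) and
#'   `.prob_<class>` appended. Invalid instances (and any row without the
#'   parse needed by a dependency channel) are predicted `"Negative"` with
#'   `NA` probabilities, so a filtered or unparseable instance stays in the
#'   evaluation universe as a non-interaction.
#' @export
predict.ddi_dlstm <- function(object, instances, use_average = TRUE, ...) {
  params <- if (use_average && !is.null(object$avg_params)) object$avg_params else object$params
  chan <- precompute_channels(instances, object$vocab, object$config$channels)
  probs <- predict_probs(params, chan)
  pred <- apply(probs, 1, function(p) {
    if (anyNA(p)) "Negative" else predict_label(p)
  })
  out <- instances
  out$.pred <- pred
  colnames(probs) <- paste0(".prob_", ddi_classes())
  dplyr::bind_cols(out, tibble::as_tibble(probs))
}

# ---- training ------------------------------------------------------------

#' Train the three-channel Bi-LSTM DDI classifier
#'
#' Runs the full training loop: per-epoch resampling ([sample_epoch()]),
#' shuffled minibatches, the compiled forward/backward pass, Adam updates
#' with global-norm gradient clipping and L2 on the weights, a running
#' arithmetic average of the parameters, and early stopping on held-out
#' micro-F over the positive classes.
#'
#' @param instances Training instance tibble (already blinded and,
#'   typically, negative-filtered).
#' @param config A [ddi_config()].
#' @param embeddings Optional pretrained embedding matrix over the built
#'   vocabulary (as from [load_word_vectors()]); by default embeddings are
#'   initialized uniformly in [-1, 1].
#' @param dev Optional instance tibble for early stopping; by default
#'   `dev_fraction` of the training *sentences* are held out.
#' @param verbose Print one line per epoch.
#' @return A `ddi_dlstm` object: parameter sets (`params`, `avg_params`),
#'   `vocab`, `config`, a `history` tibble (epoch, loss, dev micro-F,
#'   sampled class counts) and the best epoch.
#' @export
train_ddi_dlstm <- function(instances, config = ddi_config(),
                            embeddings = NULL, dev = NULL, verbose = FALSE) {
  stopifnot(nrow(instances) > 0)
  set.seed(config$seed)
  instances <- instances[instances$valid, ]

  if (is.null(dev) && config$dev_fraction > 0) {
    sids <- unique(instances$sentence_id)
    n_dev <- floor(config$dev_fraction * length(sids))
    if (n_dev >= 1) {
      dev_sids <- sample(sids, n_dev)
      dev <- instances[instances$sentence_id %in% dev_sids, ]
      instances <- instances[!instances$sentence_id %in% dev_sids, ]
    }
  }

  vocab <- build_vocab(instances$tokens)
  if (is.null(embeddings)) {
    emb0 <- NULL
  } else {
    emb0 <- embeddings
  }
  params <- init_ddi_params(vocab, config, embeddings = emb0)
  chan <- precompute_channels(instances, vocab, config$channels)
  keep_row <- !vapply(chan, is.null, TRUE)
  instances <- instances[keep_row, ]
  chan <- chan[keep_row]
  labels_int <- match(instances$label, ddi_classes())

  dev_chan <- NULL
  if (!is.null(dev) && nrow(dev) > 0) {
    dev_chan <- precompute_channels(dev, vocab, config$channels)
  }

  flat <- flatten_params(params)
  skel <- params
  mask_l2 <- flatten_params(l2_mask_params(params))
  m_state <- numeric(length(flat))
  v_state <- numeric(length(flat))
  avg <- flat
  n_upd <- 0L
  t_adam <- 0L
  beta1 <- 0.9
  beta2 <- 0.999
  eps <- 1e-8
  hdim <- length(config$channels) * config$num

  history <- list()
  best_f <- -Inf
  best_epoch <- 0L
  wait <- 0L

  for (epoch in seq_len(config$epochs)) {
    set.seed(config$seed + epoch)
    idx <- sample_epoch_indices(instances$label, config$alpha, config$beta, config$K)
    epoch_labels <- instances$label[idx]
    n_batches <- ceiling(length(idx) / config$batch_size)
    epoch_loss <- 0
    for (bi in seq_len(n_batches)) {
      sl <- idx[((bi - 1) * config$batch_size + 1):min(bi * config$batch_size, length(idx))]
      B <- length(sl)
      masks <- NULL
      if (config$rho < 1) {
        masks <- matrix(rbinom(B * hdim, 1, config$rho) / config$rho, B, hdim)
      }
      params_cur <- relist_like(flat, skel)
      res <- cpp_batch(
        chan[sl], params_cur$emb, unname(params_cur$channels),
        params_cur$Ws, params_cur$bs, labels_int[sl], masks, TRUE
      )
      g <- flatten_params(list(
        emb = res$grads$emb, channels = res$grads$channels,
        Ws = res$grads$Ws, bs = res$grads$bs
      )) / B
      if (config$l2 > 0) g <- g + 2 * config$l2 * mask_l2 * flat
      loss_b <- res$loss / B + config$l2 * sum((mask_l2 * flat)^2)
      epoch_loss <- epoch_loss + loss_b * B
      if (!is.finite(loss_b)) {
        stop("training diverged: non-finite loss at epoch ", epoch, call. = FALSE)
      }
      gn <- sqrt(sum(g^2))
      if (is.finite(config$clip) && gn > config$clip) g <- g * (config$clip / gn)
      t_adam <- t_adam + 1L
      m_state <- beta1 * m_state + (1 - beta1) * g
      v_state <- beta2 * v_state + (1 - beta2) * g^2
      mhat <- m_state / (1 - beta1^t_adam)
      vhat <- v_state / (1 - beta2^t_adam)
      flat <- flat - config$la * mhat / (sqrt(vhat) + eps)
      n_upd <- n_upd + 1L
      if (config$average) avg <- avg + (flat - avg) / n_upd
    }
    epoch_loss <- epoch_loss / length(idx)

    dev_f <- NA_real_
    if (!is.null(dev_chan)) {
      eval_params <- relist_like(if (config$average) avg else flat, skel)
      probs <- predict_probs(eval_params, dev_chan)
      pred <- apply(probs, 1, function(p) if (anyNA(p)) "Negative" else predict_label(p))
      dev_f <- micro_prf(dev$label, pred)$f
    }
    counts <- table(factor(epoch_labels, levels = ddi_classes()))
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, loss = epoch_loss, dev_micro_f = dev_f,
      n_advice = as.integer(counts["Advice"]), n_effect = as.integer(counts["Effect"]),
      n_mechanism = as.integer(counts["Mechanism"]), n_int = as.integer(counts["Int"]),
      n_negative = as.integer(counts["Negative"])
    )
    if (verbose) {
      message(sprintf(
        "epoch %d  loss %.4f  dev micro-F %s", epoch, epoch_loss,
        ifelse(is.na(dev_f), "-", sprintf("%.3f", dev_f))
      ))
    }
    if (!is.na(dev_f)) {
      if (dev_f > best_f + 1e-9) {
        best_f <- dev_f
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  }

  fit <- list(
    params = relist_like(flat, skel),
    avg_params = if (config$average) relist_like(avg, skel) else NULL,
    vocab = vocab, config = config,
    history = dplyr::bind_rows(history),
    best_epoch = best_epoch,
    classes = ddi_classes()
  )
  class(fit) <- "ddi_dlstm"
  fit
}

#' @export
print.ddi_dlstm <- function(x, ...) {
  cat("<ddi_dlstm> channels:", paste(x$config$channels, collapse = "+"),
    " num:", x$config$num, " vocab:", length(x$vocab), "\n",
    sep = ""
  )
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(
      "  epochs run:", last$epoch, " final loss:", round(last$loss, 4),
      " best dev micro-F:", round(max(x$history$dev_micro_f, na.rm = TRUE), 3), "\n"
    )
  }
  invisible(x)
}

#' @export
tidy.ddi_dlstm <- function(x, ...) {
  x$history
}

#' @export
glance.ddi_dlstm <- function(x, ...) {
  n_par <- length(flatten_params(x$params))
  tibble::tibble(
    channels = paste(x$config$channels, collapse = "+"),
    num = x$config$num,
    vocab_size = length(x$vocab),
    n_parameters = n_par,
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_dev_micro_f = if (all(is.na(x$history$dev_micro_f))) NA_real_ else max(x$history$dev_micro_f, na.rm = TRUE)
  )
}

#' @export
autoplot.ddi_dlstm <- function(object, ...) {
  h <- tidyr::pivot_longer(
    object$history[, c("epoch", "loss", "dev_micro_f")],
    cols = c("loss", "dev_micro_f"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training history")
}
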