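# DDIExtraction-2013-style scoring: class-wise and micro/macro P/R/F over
# the four positive classes, confusion matrices, and length-binned F.

prf <- function(tp, fp, fn) {
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(p = p, r = r, f = f)
}

# Micro P/R/F pooled over the positive classes: Negative is not scored, so
# a Negative instance predicted Negative contributes nothing, and a
# positive instance predicted Negative is a pooled false negative.
micro_prf <- function(gold, pred) {
  pos <- ddi_positive_classes()
  tp <- sum(gold == pred & gold %in% pos)
  fp <- sum(pred %in% pos & pred != gold)
  fn <- sum(gold %in% pos & pred != gold)
  c(prf(tp, fp, fn), list(tp = tp, fp = fp, fn = fn))
}

#' Score predictions with the DDIExtraction-2013 protocol
#'
#' Computes per-class precision, recall and F over the four positive
#' classes, the micro-averaged scores from pooled TP/FP/FN (Negative is not
#' a scored class), the macro-average F (MAVG, the arithmetic mean of the
#' four class F-scores), and the 5x5 confusion matrix. `gold` and `pred`
#' must cover the full evaluation universe: instances removed by test-set
#' filtering are entered by the caller as predicted-Negative, so a wrongly
#' filtered positive counts as a false negative.
#'
#' @param gold,pred Aligned character vectors of class labels.
#' @return A `ddi_eval` object with elements `per_class` (tibble),
#'   `micro` (list with `p`, `r`, `f`), `macro_f`, `confusion` (counts,
#'   gold in rows), `confusion_norm` (row-normalized) and `n`.
#' @export
ddi_score <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop("gold and pred must have the same length", call. = FALSE)
  }
  stopifnot(all(gold %in% ddi_classes()), all(pred %in% ddi_classes()))
  per_class <- dplyr::bind_rows(lapply(ddi_positive_classes(), function(cls) {
    tp <- sum(gold == cls & pred == cls)
    fp <- sum(pred == cls & gold != cls)
    fn <- sum(gold == cls & pred != cls)
    s <- prf(tp, fp, fn)
    tibble::tibble(
      class = cls, tp = tp, fp = fp, fn = fn,
      precision = s$p, recall = s$r, f = s$f
    )
  }))
  structure(
    list(
      per_class = per_class,
      micro = micro_prf(gold, pred),
      macro_f = macro_average_f(per_class$f),
      confusion = confusion_matrix(gold, pred),
      confusion_norm = confusion_matrix(gold, pred, normalize = TRUE),
      n = length(gold)
    ),
    class = "ddi_eval"
  )
}

#' Macro-average F-score (MAVG)
#'
#' The arithmetic mean of the per-class F-scores of the four positive DDI
#' classes.
#'
#' @param f Numeric vector of class F-scores.
#' @return A single number.
#' @export
macro_average_f <- function(f) {
  mean(f)
}

#' Confusion matrix over the five DDI classes
#'
#' Rows are the targeted (gold) classes, columns the predicted classes.
#' With `normalize = TRUE` each row is divided by its total so it sums to 1
#' (empty rows stay 0).
#'
#' @param gold,pred Aligned label vectors.
#' @param normalize Row-normalize.
#' @return A 5x5 matrix in [ddi_classes()] order.
#' @export
confusion_matrix <- function(gold, pred, normalize = FALSE) {
  lv <- ddi_classes()
  m <- table(
    factor(gold, levels = lv), factor(pred, levels = lv)
  )
  m <- unclass(m)
  dimnames(m) <- list(gold = lv, pred = lv)
  if (normalize) {
    rs <- rowSums(m)
    rs[rs == 0] <- 1
    m <- m / rs
  }
  m
}

#' Micro F-score by instance length
#'
#' Instances are binned by token count into bins of `bin_width` tokens
#' ((0,10], (10,20], ... by default: length 10 falls in the first bin,
#' length 11 in the second) and the micro F over the positive classes is
#' computed within each occupied bin. An empty bin has no F (`NA`).
#'
#' @param gold,pred Aligned label vectors.
#' @param lengths Integer token counts of the (blinded) instances.
#' @param bin_width Bin width in tokens.
#' @return A tibble with `bin` (label), `bin_start`, `bin_end`, `n`, `f`.
#' @export
length_binned_f <- function(gold, pred, lengths, bin_width = 10L) {
  stopifnot(length(gold) == length(pred), length(gold) == length(lengths))
  bin <- ceiling(lengths / bin_width)
  max_bin <- max(bin, 1L)
  out <- lapply(seq_len(max_bin), function(b) {
    sel <- bin == b
    tibble::tibble(
      bin = paste0(((b - 1L) * bin_width) + 1L, "-", b * bin_width),
      bin_start = ((b - 1L) * bin_width) + 1L,
      bin_end = b * bin_width,
      n = sum(sel),
      f = if (any(sel)) micro_prf(gold[sel], pred[sel])$f else NA_real_
    )
  })
  dplyr::bind_rows(out)
}

#' @export
print.ddi_eval <- function(x, ...) {
  cat("<ddi_eval> n = ", x$n, "\n", sep = "")
  print(x$per_class)
  cat(sprintf(
    "micro  P %.4f  R %.4f  F %.4f   MAVG %.4f\n",
    x$micro$p, x$micro$r, x$micro$f, x$macro_f
  ))
  invisible(x)
}

#' @export
tidy.ddi_eval <- function(x, ...) {
  x$per_class
}

#' @export
glance.ddi_eval <- function(x, ...) {
  tibble::tibble(
    micro_p = x$micro$p, micro_r = x$micro$r, micro_f = x$micro$f,
    macro_f = x$macro_f, n = x$n
  )
}

#' @export
autoplot.ddi_eval <- function(object, normalize = TRUE, ...) {
  m <- if (normalize) object$confusion_norm else object$confusion
  df <- tibble::as_tibble(as.table(m))
  names(df) <- c("gold", "pred", "value")
  df$gold <- factor(df$gold, levels = rev(ddi_classes()))
  df$pred <- factor(df$pred, levels = ddi_classes())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$gold, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$value, 3)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      x = "predicted type", y = "targeted type",
      fill = if (normalize) "row ratio" else "count",
      title = "Confusion matrix"
    )
}

#' Write an evaluation report as JSON
#'
#' @param eval A `ddi_eval` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(eval, path) {
  obj <- list(
    per_class = eval$per_class,
    micro = eval$micro[c("p", "r", "f")],
    macro_f = eval$macro_f,
    confusion = unname(apply(eval$confusion, 1, as.integer, simplify = FALSE)),
    classes = ddi_classes(),
    n = eval$n
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
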