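# Independent oracles and fixture builders shared across the test files.
# Every oracle here is deliberately written in the most naive style
# (scalar loops, recursion, explicit tallies) so it shares no code path
# with the package implementation it checks.

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- sentence fixture builder -------------------------------------------

# Locate the occ-th occurrence of a word in a sentence as 0-based
# inclusive character offsets.
char_span <- function(text, word, occ = 1L) {
  m <- gregexpr(word, text, fixed = TRUE)[[1]]
  c(start = m[occ] - 1L, end = m[occ] - 1L + nchar(word) - 1L)
}

# Build a one-row sentence tibble from mention words and labelled pairs.
# mentions: list of list(text=, occ=); pairs: list of list(i, j, label).
make_sentence <- function(text, mentions, pairs, sid = "s1") {
  men <- dplyr::bind_rows(lapply(seq_along(mentions), function(i) {
    sp <- char_span(text, mentions[[i]]$text, mentions[[i]]$occ %||% 1L)
    tibble::tibble(
      id = paste0(sid, ".e", i), char_start = unname(sp["start"]),
      char_end = unname(sp["end"]), text = mentions[[i]]$text, type = "drug"
    )
  }))
  prs <- dplyr::bind_rows(lapply(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    tibble::tibble(
      pair_id = paste0(sid, ".p", k),
      e1 = paste0(sid, ".e", p[[1]]), e2 = paste0(sid, ".e", p[[2]]),
      label = p[[3]]
    )
  }))
  tibble::tibble(sentence_id = sid, text = text, mentions = list(men), pairs = list(prs))
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "ddilstm", mustWork = TRUE)
}

# ---- random trees and traversal oracles ---------------------------------

# Random rooted tree on n nodes: each non-root node picks a parent among
# already-attached nodes (random labelling, guaranteed acyclic).
random_tree <- function(n) {
  ord <- sample(n)
  head <- integer(n)
  head[ord[1]] <- 0L
  for (k in seq_len(n)[-1]) {
    head[ord[k]] <- ord[sample(k - 1L, 1)]
  }
  head
}

# Depths by naive parent-chasing, one node at a time.
depth_oracle <- function(head) {
  vapply(seq_along(head), function(i) {
    d <- 0L
    while (head[i] != 0L) {
      i <- head[i]
      d <- d + 1L
    }
    d
  }, 1L)
}

# Recursive preorder with children in ascending token order.
preorder_oracle <- function(head) {
  rec <- function(node) {
    kids <- which(head == node)
    c(node, unlist(lapply(sort(kids), rec)))
  }
  as.integer(rec(which(head == 0L)))
}

# Level-order via repeated level scans.
levelorder_oracle <- function(head) {
  out <- which(head == 0L)
  level <- out
  while (length(out) < length(head)) {
    nxt <- integer(0)
    for (node in level) nxt <- c(nxt, sort(which(head == node)))
    out <- c(out, nxt)
    level <- nxt
  }
  as.integer(out)
}

# A tree drawn over a linearly ordered sentence is projective iff no two
# arcs cross: arcs (min,max) must nest or be disjoint, and no arc may
# "cover" a node whose parent is outside the covered span (planarity +
# single-head suffices for the crossing check used here).
is_projective <- function(head) {
  arcs <- cbind(pmin(seq_along(head), head), pmax(seq_along(head), head))
  arcs <- arcs[head != 0L, , drop = FALSE]
  n <- nrow(arcs)
  if (n < 2) {
    return(TRUE)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- arcs[i, ]
      b <- arcs[j, ]
      if (a[1] < b[1] && b[1] < a[2] && a[2] < b[2]) {
        return(FALSE)
      }
      if (b[1] < a[1] && a[1] < b[2] && b[2] < a[2]) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# ---- scalar-loop LSTM oracle --------------------------------------------

# One peephole-LSTM step computed unit by unit with explicit loops.
scalar_lstm_step <- function(x, h, c, p) {
  num <- length(h)
  d <- length(x)
  sig <- function(u) 1 / (1 + exp(-u))
  h2 <- numeric(num)
  c2 <- numeric(num)
  for (j in seq_len(num)) {
    ai <- p$b[j]
    af <- p$b[num + j]
    ag <- p$b[2 * num + j]
    ao <- p$b[3 * num + j]
    for (k in seq_len(d)) {
      ai <- ai + p$Wx[j, k] * x[k]
      af <- af + p$Wx[num + j, k] * x[k]
      ag <- ag + p$Wx[2 * num + j, k] * x[k]
      ao <- ao + p$Wx[3 * num + j, k] * x[k]
    }
    for (k in seq_len(num)) {
      ai <- ai + p$Wh[j, k] * h[k]
      af <- af + p$Wh[num + j, k] * h[k]
      ag <- ag + p$Wh[2 * num + j, k] * h[k]
      ao <- ao + p$Wh[3 * num + j, k] * h[k]
    }
    i_g <- sig(ai + p$pi[j] * c[j])
    f_g <- sig(af + p$pf[j] * c[j])
    g_g <- tanh(ag)
    c2[j] <- f_g * c[j] + i_g * g_g
    o_g <- sig(ao + p$po[j] * c2[j])
    h2[j] <- o_g * tanh(c2[j])
  }
  list(h = h2, c = c2)
}

random_lstm_params <- function(d, num, scale = 0.5) {
  list(
    Wx = matrix(runif(4 * num * d, -scale, scale), 4 * num, d),
    Wh = matrix(runif(4 * num * num, -scale, scale), 4 * num, num),
    b = runif(4 * num, -scale, scale),
    pi = runif(num, -scale, scale),
    pf = runif(num, -scale, scale),
    po = runif(num, -scale, scale)
  )
}

# ---- contingency-table scoring oracle -----------------------------------

# Brute-force per-class and micro scores from explicit tallies.
score_oracle <- function(gold, pred) {
  pos <- c("Advice", "Effect", "Mechanism", "Int")
  per <- list()
  tp_all <- fp_all <- fn_all <- 0
  for (cls in pos) {
    tp <- 0
    fp <- 0
    fn <- 0
    for (i in seq_along(gold)) {
      if (gold[i] == cls && pred[i] == cls) tp <- tp + 1
      if (pred[i] == cls && gold[i] != cls) fp <- fp + 1
      if (gold[i] == cls && pred[i] != cls) fn <- fn + 1
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    per[[cls]] <- c(p = p, r = r, f = f)
    tp_all <- tp_all + tp
    fp_all <- fp_all + fp
    fn_all <- fn_all + fn
  }
  mp <- if (tp_all + fp_all > 0) tp_all / (tp_all + fp_all) else 0
  mr <- if (tp_all + fn_all > 0) tp_all / (tp_all + fn_all) else 0
  mf <- if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
  list(
    per_class = per,
    micro = c(p = mp, r = mr, f = mf),
    macro_f = mean(vapply(per, function(x) x[["f"]], 1))
  )
}

random_labels <- function(n) {
  sample(ddi_classes(), n, replace = TRUE, prob = c(.1, .15, .1, .05, .6))
}
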