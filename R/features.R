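# Channel features: relative token distances (linear channel), dependency
# trees with depth differences (DFS/BFS channels), and the 10-bit binary
# distance encoding shared by all channels.

#' Relative-distance features for the linear channel
#'
#' Each token at position `p` gets two signed distances to the candidate
#' drugs: `d1 = pos(DRUG_1) - p` and `d2 = pos(DRUG_2) - p`, so a word to
#' the left of both drugs has two positive distances and each placeholder
#' has a zero self-distance.
#'
#' @param tokens Blinded token vector.
#' @param drug1_index,drug2_index 1-based positions of `DRUG_1` / `DRUG_2`.
#' @return A tibble with `position`, `token`, `d1`, `d2`.
#' @export
distance_features <- function(tokens, drug1_index, drug2_index) {
  stopifnot(
    tokens[drug1_index] == DRUG1_TOKEN,
    tokens[drug2_index] == DRUG2_TOKEN
  )
  p <- seq_along(tokens)
  tibble::tibble(
    position = p, token = tokens,
    d1 = as.integer(drug1_index - p),
    d2 = as.integer(drug2_index - p)
  )
}

#' Build a validated dependency tree
#'
#' Heads use the CoNLL-U convention: 1-based parent indices with 0 for the
#' root. A parse with several roots is repaired by attaching the extra roots
#' to the first root with the synthetic relation `"dep"` (parser output on
#' biomedical text is imperfect and instances must not be dropped silently);
#' a cyclic parse is an error.
#'
#' @param head Integer vector of parent indices (0 = root).
#' @param deprel Optional character vector of relation labels.
#' @param sentence_id Used in error messages.
#' @return A `ddi_dep_tree`: list with `head`, `deprel`, `root`, `depth`
#'   (edges to the root; root depth 0) and `children` (list of integer
#'   vectors, each in ascending token order).
#' @export
build_tree <- function(head, deprel = NULL, sentence_id = NULL) {
  n <- length(head)
  stopifnot(n >= 1)
  head <- as.integer(head)
  if (is.null(deprel)) deprel <- rep("dep", n)
  where <- if (is.null(sentence_id)) "" else paste0(" in sentence '", sentence_id, "'")
  if (any(head < 0L | head > n)) {
    stop("head index out of range", where, call. = FALSE)
  }
  roots <- which(head == 0L)
  if (length(roots) == 0) {
    stop("no root", where, call. = FALSE)
  }
  if (length(roots) > 1) {
    head[roots[-1]] <- roots[1]
    deprel[roots[-1]] <- "dep"
  }
  depth <- rep(NA_integer_, n)
  depth[roots[1]] <- 0L
  frontier <- roots[1]
  while (length(frontier) > 0) {
    nxt <- which(head %in% frontier & is.na(depth))
    if (length(nxt) == 0) break
    depth[nxt] <- depth[head[nxt]] + 1L
    frontier <- nxt
  }
  if (anyNA(depth)) {
    stop("cyclic parse: tokens unreachable from the root", where, call. = FALSE)
  }
  children <- lapply(seq_len(n), function(i) which(head == i))
  structure(
    list(
      head = head, deprel = deprel, root = roots[1],
      depth = depth, children = children
    ),
    class = "ddi_dep_tree"
  )
}

#' @export
print.ddi_dep_tree <- function(x, ...) {
  cat("<ddi_dep_tree> ", length(x$head), " nodes, root ", x$root, "\n", sep = "")
  invisible(x)
}

#' Depth-difference features for the dependency channels
#'
#' Each token gets `(L - L1, L - L2)`, where `L` is its depth in the
#' dependency tree (edge count to the root) and `L1`, `L2` are the depths of
#' the two candidate drugs.
#'
#' @param tree A `ddi_dep_tree` from [build_tree()].
#' @param drug1_index,drug2_index 1-based positions of the drug tokens.
#' @return A tibble with `position`, `l`, `d1`, `d2`.
#' @export
depth_features <- function(tree, drug1_index, drug2_index) {
  l <- tree$depth
  tibble::tibble(
    position = seq_along(l), l = l,
    d1 = as.integer(l - l[drug1_index]),
    d2 = as.integer(l - l[drug2_index])
  )
}

#' Depth-first linearization of a dependency tree
#'
#' Preorder traversal from the root, visiting the children of each node in
#' ascending token order.
#'
#' @param tree A `ddi_dep_tree`.
#' @return An integer permutation of `1..n` starting at the root.
#' @export
dfs_order <- function(tree) {
  n <- length(tree$head)
  out <- integer(n)
  k <- 0L
  stack <- tree$root
  while (length(stack) > 0) {
    node <- stack[1]
    stack <- stack[-1]
    k <- k + 1L
    out[k] <- node
    stack <- c(tree$children[[node]], stack)
  }
  out
}

#' Breadth-first linearization of a dependency tree
#'
#' Level-order traversal from the root; within a level, nodes are visited in
#' the order their parents were visited, children in ascending token order.
#'
#' @param tree A `ddi_dep_tree`.
#' @return An integer permutation of `1..n` starting at the root.
#' @export
bfs_order <- function(tree) {
  n <- length(tree$head)
  out <- integer(n)
  out[1] <- tree$root
  k <- 1L
  q <- 1L
  while (q <= k && k < n) {
    kids <- tree$children[[out[q]]]
    if (length(kids) > 0) {
      out[(k + 1L):(k + length(kids))] <- kids
      k <- k + length(kids)
    }
    q <- q + 1L
  }
  out
}

#' Encode a signed distance as a 10-bit binary vector
#'
#' Sign-magnitude encoding: the first component is 1 for a negative value;
#' the remaining nine components are the binary expansion (most-significant
#' bit first) of the absolute value, clamped to 511. Zero maps to the
#' all-zero vector.
#'
#' @param v Integer vector of distances.
#' @return A `length(v) x 10` 0/1 matrix.
#' @export
encode_distance <- function(v) {
  v <- as.integer(v)
  mag <- pmin(abs(v), 511L)
  bits <- matrix(0, nrow = length(v), ncol = 10L)
  bits[, 1] <- as.numeric(v < 0L)
  for (b in 1:9) {
    bits[, 1L + b] <- bitwAnd(mag, bitwShiftL(1L, 9L - b)) > 0L
  }
  bits
}

# Per-channel integer data for one instance: token ids in traversal order
# plus the 20-column matrix of encoded distance pairs. Embeddings are
# resolved later (inside the model), so this is what gets cached and dumped.
instance_channel_data <- function(tokens, drug1_index, drug2_index,
                                  head = NULL, deprel = NULL, vocab = NULL,
                                  channels = c("linear", "dfs", "bfs"),
                                  sentence_id = NULL) {
  ids <- if (is.null(vocab)) NULL else vocab_ids(vocab, tokens)
  out <- list()
  if ("linear" %in% channels) {
    df <- distance_features(tokens, drug1_index, drug2_index)
    out$linear <- list(
      order = df$position, ids = ids,
      codes = cbind(encode_distance(df$d1), encode_distance(df$d2))
    )
  }
  if (any(c("dfs", "bfs") %in% channels)) {
    if (is.null(head)) {
      stop("dependency channels requested but instance has no parse",
        call. = FALSE
      )
    }
    tree <- build_tree(head, deprel, sentence_id)
    pf <- depth_features(tree, drug1_index, drug2_index)
    codes <- cbind(encode_distance(pf$d1), encode_distance(pf$d2))
    if ("dfs" %in% channels) {
      ord <- dfs_order(tree)
      out$dfs <- list(
        order = ord, ids = if (is.null(ids)) NULL else ids[ord],
        codes = codes[ord, , drop = FALSE]
      )
    }
    if ("bfs" %in% channels) {
      ord <- bfs_order(tree)
      out$bfs <- list(
        order = ord, ids = if (is.null(ids)) NULL else ids[ord],
        codes = codes[ord, , drop = FALSE]
      )
    }
  }
  out[channels]
}

#' Build the three channel sequences for one instance
#'
#' The linear channel carries the tokens in sentence order with
#' relative-distance features; the DFS and BFS channels carry the
#' dependency-tree linearizations with depth-difference features. Each
#' token vector is the word embedding concatenated with the two 10-bit
#' distance codes. Out-of-vocabulary tokens use the UNK embedding.
#'
#' @param instance One-row instance tibble from [candidate_instances()].
#' @param embeddings Embedding matrix over `vocab` (rows = vocabulary ids).
#' @param vocab A `ddi_vocab`.
#' @param channels Subset of `c("linear", "dfs", "bfs")`.
#' @return Named list of `m x (dw + 20)` matrices, one per channel, each
#'   with attribute `"order"` (the token positions in traversal order).
#' @export
build_channels <- function(instance, embeddings, vocab,
                           channels = c("linear", "dfs", "bfs")) {
  stopifnot(nrow(instance) == 1)
  dat <- instance_channel_data(
    instance$tokens[[1]], instance$drug1_index, instance$drug2_index,
    head = instance$head[[1]], deprel = instance$deprel[[1]],
    vocab = vocab, channels = channels, sentence_id = instance$sentence_id
  )
  lapply(dat, function(ch) {
    X <- cbind(embeddings[ch$ids, , drop = FALSE], ch$codes)
    rownames(X) <- NULL
    attr(X, "order") <- ch$order
    X
  })
}

#' Dump per-instance channel features as JSON lines
#'
#' One JSON record per instance with the traversal orders and the integer
#' distance/depth feature pairs; embeddings are resolved only inside the
#' model, so the dump is vocabulary-free.
#'
#' @param instances Instance tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_dump <- function(instances, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(instances))) {
    if (!isTRUE(instances$valid[i])) next
    tokens <- instances$tokens[[i]]
    df <- distance_features(tokens, instances$drug1_index[i], instances$drug2_index[i])
    rec <- list(
      sentence_id = instances$sentence_id[i],
      pair_id = instances$pair_id[i],
      label = instances$label[i],
      tokens = tokens,
      linear = list(d1 = df$d1, d2 = df$d2)
    )
    if (!is.null(instances$head[[i]])) {
      tree <- build_tree(instances$head[[i]], instances$deprel[[i]])
      pf <- depth_features(tree, instances$drug1_index[i], instances$drug2_index[i])
      rec$dfs <- list(order = dfs_order(tree))
      rec$bfs <- list(order = bfs_order(tree))
      rec$depth <- list(d1 = pf$d1, d2 = pf$d2)
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}
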