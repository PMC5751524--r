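fig2_instance <- function() {
  s <- read_ddi_xml(fixture_path("distance-example.xml"))
  p <- read_conllu(fixture_path("distance-example.conllu"))
  candidate_instances(s, p)
}

test_that("distance features reproduce the worked example", {
  inst <- fig2_instance()
  df <- distance_features(inst$tokens[[1]], inst$drug1_index, inst$drug2_index)
  expect_equal(unlist(df[df$token == "suggest", c("d1", "d2")]), c(d1 = 5L, d2 = 12L))
  expect_equal(unlist(df[df$token == "DRUG_1", c("d1", "d2")]), c(d1 = 0L, d2 = 7L))
  # zero self-distance at each placeholder, and only there
  expect_equal(which(df$d1 == 0L), inst$drug1_index)
  expect_equal(which(df$d2 == 0L), inst$drug2_index)
})

test_that("distance features are translation-covariant", {
  inst <- fig2_instance()
  toks <- inst$tokens[[1]]
  df0 <- distance_features(toks, inst$drug1_index, inst$drug2_index)
  k <- 4L
  df1 <- distance_features(
    c(rep("pad", k), toks), inst$drug1_index + k, inst$drug2_index + k
  )
  expect_equal(df1$d1[-seq_len(k)], df0$d1)
  expect_equal(df1$d2[-seq_len(k)], df0$d2)
})

test_that("tree building validates structure and orients edges correctly", {
  inst <- fig2_instance()
  tree <- build_tree(inst$head[[1]], inst$deprel[[1]])
  # nsubj(suggest-3, findings-2): the parent of node 2 is node 3
  expect_equal(tree$head[2], 3L)
  expect_equal(tree$root, 3L)
  # chain 1 <- 2 <- 3: root 3, depths (2, 1, 0)
  chain <- build_tree(c(2L, 3L, 0L))
  expect_equal(chain$root, 3L)
  expect_equal(chain$depth, c(2L, 1L, 0L))
  expect_error(build_tree(c(2L, 1L), sentence_id = "cyc"), "no root")
  expect_error(build_tree(c(0L, 1L, 2L, 3L, 6L, 5L)), "cyclic")
  # a two-root parse is repaired by attaching the extra root to the first
  repaired <- build_tree(c(0L, 1L, 0L, 3L))
  expect_equal(repaired$head[3], 1L)
  expect_equal(repaired$deprel[3], "dep")
})

test_that("tree depths agree with a parent-chasing oracle on random trees", {
  set.seed(502)
  for (rep in 1:1000) {
    n <- sample(2:30, 1)
    head <- random_tree(n)
    tree <- build_tree(head)
    expect_equal(tree$depth, depth_oracle(head))
  }
})

test_that("depth features difference the drug depths", {
  inst <- fig2_instance()
  tree <- build_tree(inst$head[[1]])
  pf <- depth_features(tree, inst$drug1_index, inst$drug2_index)
  # hand-derived depths for the fixture parse: DRUG_1 at depth 3, DRUG_2 at 4
  expect_equal(pf$l, c(2L, 1L, 0L, 2L, 3L, 2L, 4L, 3L, 2L, 2L, 1L, 3L, 2L, 3L, 4L))
  expect_equal(unlist(pf[pf$position == tree$root, c("d1", "d2")]), c(d1 = -3L, d2 = -4L))
  expect_equal(pf$d1[inst$drug1_index], 0L)
  expect_equal(pf$d2[inst$drug2_index], 0L)
  expect_equal(pf$d1, pf$l - 3L)
  expect_equal(pf$d2, pf$l - 4L)
})

test_that("DFS and BFS orders match traversal oracles and are permutations", {
  # single node
  one <- build_tree(0L)
  expect_equal(dfs_order(one), 1L)
  expect_equal(bfs_order(one), 1L)
  # root with children a < b, b has child c: both traversals coincide
  t2 <- build_tree(c(0L, 1L, 1L, 3L))
  expect_equal(dfs_order(t2), c(1L, 2L, 3L, 4L))
  expect_equal(bfs_order(t2), c(1L, 2L, 3L, 4L))
  # deep-left chain vs right leaf: DFS dives, BFS sweeps
  t3 <- build_tree(c(0L, 1L, 2L, 1L)) # 1 -> {2 -> 3, 4}
  expect_equal(dfs_order(t3), c(1L, 2L, 3L, 4L))
  expect_equal(bfs_order(t3), c(1L, 2L, 4L, 3L))
  set.seed(503)
  for (rep in 1:1000) {
    n <- sample(2:30, 1)
    head <- random_tree(n)
    tree <- build_tree(head)
    d <- dfs_order(tree)
    b <- bfs_order(tree)
    expect_equal(d, preorder_oracle(head))
    expect_equal(b, levelorder_oracle(head))
    expect_equal(sort(d), seq_len(n))
    expect_equal(sort(b), seq_len(n))
    expect_equal(d[1], tree$root)
    expect_equal(b[1], tree$root)
  }
})

test_that("the worked parse linearizes to the hand-derived DFS and BFS orders", {
  inst <- fig2_instance()
  tree <- build_tree(inst$head[[1]])
  expect_equal(
    dfs_order(tree),
    c(3L, 2L, 1L, 11L, 4L, 6L, 5L, 8L, 7L, 9L, 10L, 13L, 12L, 14L, 15L)
  )
  expect_equal(
    bfs_order(tree),
    c(3L, 2L, 11L, 1L, 4L, 6L, 9L, 10L, 13L, 5L, 8L, 12L, 14L, 7L, 15L)
  )
})

test_that("distance encoding is 10-bit sign-magnitude with clamping", {
  expect_equal(encode_distance(0L)[1, ], rep(0, 10))
  expect_equal(encode_distance(5L)[1, ], c(0, 0, 0, 0, 0, 0, 0, 1, 0, 1))
  expect_equal(encode_distance(-600L)[1, ], c(1, rep(1, 9))) # sign + clamp at 511
  # binary-expansion oracle over a wide range of values
  decode <- function(bits) {
    mag <- sum(bits[2:10] * 2^(8:0))
    if (bits[1] == 1) -mag else mag
  }
  v <- c(-520:-500, -63:63, 500:520)
  enc <- encode_distance(v)
  expect_equal(
    apply(enc, 1, decode),
    pmax(pmin(v, 511), -511)
  )
  expect_true(all(enc %in% c(0, 1)))
})

test_that("channel matrices concatenate embedding and distance codes", {
  inst <- fig2_instance()
  vocab <- build_vocab(inst$tokens)
  set.seed(77)
  emb <- init_embeddings(vocab, dw = 8L)
  ch <- build_channels(inst, emb, vocab)
  m <- inst$n_tokens
  expect_named(ch, c("linear", "dfs", "bfs"))
  expect_true(all(vapply(ch, nrow, 1L) == m))
  expect_true(all(vapply(ch, ncol, 1L) == 8L + 20L))
  # index-arithmetic check of the layout: word part then two 10-bit codes
  ids <- vocab_ids(vocab, inst$tokens[[1]])
  df <- distance_features(inst$tokens[[1]], inst$drug1_index, inst$drug2_index)
  expect_equal(ch$linear[, 1:8], emb[ids, ], ignore_attr = TRUE)
  expect_equal(ch$linear[, 9:18], encode_distance(df$d1), ignore_attr = TRUE)
  expect_equal(ch$linear[, 19:28], encode_distance(df$d2), ignore_attr = TRUE)
  # linear channel's first distance code is all-zero at the DRUG_1 row
  expect_equal(ch$linear[inst$drug1_index, 9:18], rep(0, 10), ignore_attr = TRUE)
  # DFS rows are the depth-coded vectors in traversal order
  tree <- build_tree(inst$head[[1]])
  ord <- dfs_order(tree)
  pf <- depth_features(tree, inst$drug1_index, inst$drug2_index)
  expect_equal(ch$dfs[, 1:8], emb[ids[ord], ], ignore_attr = TRUE)
  expect_equal(ch$dfs[, 9:18], encode_distance(pf$d1)[ord, ], ignore_attr = TRUE)
  # out-of-vocabulary tokens take the UNK row, never an error
  vocab_small <- build_vocab(list(c("suggest")))
  emb_small <- init_embeddings(vocab_small, dw = 8L)
  ch2 <- build_channels(inst, emb_small, vocab_small)
  unk <- unclass(vocab_small)[["UNK"]]
  expect_equal(ch2$linear[1, 1:8], emb_small[unk, ], ignore_attr = TRUE)
})
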