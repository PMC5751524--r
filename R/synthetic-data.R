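# Desk-scale synthetic DDI corpora: sentences with 2-4 drug mentions, a
# projective dependency tree rooted at the main verb, and a planted,
# learnable class signal -- the designated pair's label is determined by a
# class-specific trigger token that is the tree-parent of both drugs.
# Decoy triggers elsewhere in the sentence make the linear surface
# ambiguous, so the dependency channels carry signal the linear channel
# lacks. A configurable fraction of negative sentences instantiate the
# apposition/coordination surface patterns targeted by the filtering rules.

#' Default trigger lexicons for the synthetic generator
#'
#' One small lexicon per positive class; a trigger token determines the
#' class of the pair it governs in the generated dependency tree.
#'
#' @return Named list of character vectors.
#' @export
ddi_sim_triggers <- function() {
  list(
    Advice = c("recommended", "avoided", "discontinued"),
    Effect = c("enhances", "potentiates", "attenuates"),
    Mechanism = c("inhibits", "induces", "displaces"),
    Int = c("interacts", "interferes", "coadministered")
  )
}

sim_fillers <- function() {
  c(
    "patients", "dosage", "treatment", "therapy", "plasma", "levels",
    "concomitant", "administration", "clinical", "studies", "may", "be",
    "with", "of", "the", "in", "reduced", "increased", "observed",
    "receiving", "oral", "daily", "dose", "response", "renal", "hepatic",
    "serum", "concentrations", "monitoring", "caution", "risk", "severe",
    "moderate", "during", "chronic", "acute", "elderly", "adult", "use",
    "reported", "single", "repeated", "prior", "following", "therapeutic"
  )
}

sim_verbs <- function() {
  c("suggest", "indicate", "show", "report", "describe")
}

sim_drug_names <- function(n = 60L) {
  pre <- c("alfa", "beta", "gama", "delta", "zeta", "kappa", "mido", "nor", "pro", "tri")
  suf <- c("zine", "olol", "micin", "statin", "prazole", "cillin")
  grid <- expand.grid(pre = pre, suf = suf, stringsAsFactors = FALSE)
  paste0(grid$pre, grid$suf)[seq_len(n)]
}

#' Configuration for the synthetic corpus generator
#'
#' The defaults emulate the DDI corpus study conditions: the designated
#' pair's class distribution is Negative-heavy with Int rarest, chosen so
#' that with 2-4 mentions per sentence the instance-level positive:negative
#' ratio lands near the corpus's 1:5.8; a quarter of negative sentences
#' instantiate the filterable apposition/coordination patterns (the corpus
#' filtering removes about 26% of negatives).
#'
#' @param n_sentences Number of sentences.
#' @param class_probs Designated-pair label distribution over
#'   [ddi_classes()]; must sum to 1.
#' @param mention_probs Distribution of the number of drug mentions per
#'   sentence (names "2", "3", "4").
#' @param filterable_frac Probability that a Negative-designated sentence
#'   is built as a Rule-2/Rule-3 surface pattern.
#' @param decoy_frac Probability of inserting a decoy trigger token (class
#'   word not governing the pair) into a sentence.
#' @param triggers Trigger lexicons per positive class.
#' @param seed Integer seed; the same seed gives byte-identical output.
#' @return A `ddi_sim_config` list.
#' @export
ddi_sim_config <- function(n_sentences = 1000L,
                           class_probs = c(
                             Negative = 0.690, Advice = 0.101,
                             Effect = 0.130, Mechanism = 0.064, Int = 0.015
                           ),
                           mention_probs = c(`2` = 0.6, `3` = 0.3, `4` = 0.1),
                           filterable_frac = 0.25,
                           decoy_frac = 0.5,
                           triggers = ddi_sim_triggers(),
                           seed = 1L) {
  stopifnot(
    n_sentences >= 0,
    abs(sum(class_probs) - 1) < 1e-8,
    all(ddi_classes() %in% names(class_probs)),
    abs(sum(mention_probs) - 1) < 1e-8,
    filterable_frac >= 0, filterable_frac <= 1,
    decoy_frac >= 0, decoy_frac <= 1
  )
  structure(
    list(
      n_sentences = as.integer(n_sentences),
      class_probs = class_probs[ddi_classes()],
      mention_probs = mention_probs,
      filterable_frac = filterable_frac,
      decoy_frac = decoy_frac,
      triggers = triggers,
      seed = as.integer(seed)
    ),
    class = "ddi_sim_config"
  )
}

# Build one sentence: token vector, 0-root head vector, deprels, mention
# token positions, designated pair and its label, bookkeeping flags.
sim_sentence <- function(cfg, sid) {
  fillers <- sim_fillers()
  label <- sample(ddi_classes(), 1, prob = cfg$class_probs)
  n_mentions <- as.integer(sample(names(cfg$mention_probs), 1, prob = cfg$mention_probs))
  drugs <- sample(sim_drug_names(), n_mentions)
  filterable <- label == "Negative" && runif(1) < cfg$filterable_frac
  decoy <- !filterable && runif(1) < cfg$decoy_frac

  tok <- character(0) # tokens
  hd <- integer(0) # parent slot index (0 = root), resolved to positions later
  rl <- character(0)
  role <- character(0) # "verb","drugA","drugB","trig","extra","filler"
  push <- function(t, h, r, ro) {
    tok <<- c(tok, t)
    hd <<- c(hd, h)
    rl <<- c(rl, r)
    role <<- c(role, ro)
    length(tok)
  }
  n_fill <- function(max_n) sample(0:max_n, 1)
  add_fillers <- function(n, head_slot, extra_pool = character(0)) {
    pool <- c(sample(fillers, n, replace = TRUE), extra_pool)
    for (w in pool) push(w, head_slot, "dep", "filler")
  }

  if (filterable) {
    rule <- sample(c(2L, 2L, 3L), 1) # both Rule-2 shapes plus Rule 3
    shape <- if (rule == 2L) sample(c("paren", "suchas"), 1) else "coord"
    for (w in sample(fillers, n_fill(2), replace = TRUE)) push(w, NA, "dep", "pre")
    v <- push(sample(sim_verbs(), 1), 0L, "root", "verb")
    for (w in sample(fillers, n_fill(2), replace = TRUE)) push(w, v, "dep", "filler")
    a <- push(drugs[1], v, "obj", "drugA")
    extra_in <- n_mentions > 2
    if (shape == "paren") {
      push("(", a, "punct", "filler")
      if (extra_in) {
        push(drugs[3], a, "conj", "extra")
        push(",", a, "punct", "filler")
      }
      b <- push(drugs[2], a, "appos", "drugB")
      push(")", b, "punct", "filler")
    } else if (shape == "suchas") {
      push("such", a, "case", "filler")
      push("as", a, "case", "filler")
      if (extra_in) {
        push(drugs[3], a, "conj", "extra")
        push(",", a, "punct", "filler")
      }
      b <- push(drugs[2], a, "conj", "drugB")
    } else {
      push(",", a, "punct", "filler")
      if (extra_in) {
        push(drugs[3], a, "conj", "extra")
        push(",", a, "punct", "filler")
        push("and", a, "cc", "filler")
      } else {
        push(sample(c("and", "or"), 1), a, "cc", "filler")
      }
      b <- push(drugs[2], a, "conj", "drugB")
    }
    if (n_mentions > 3) push(drugs[4], v, "obj", "extra")
    for (w in sample(fillers, n_fill(3), replace = TRUE)) push(w, v, "dep", "filler")
    planted_rule <- rule
  } else {
    planted_rule <- NA_integer_
    trig_word <- if (label != "Negative") sample(cfg$triggers[[label]], 1) else NA_character_
    decoy_word <- if (decoy) sample(unlist(cfg$triggers), 1) else NA_character_
    # layout: pre VERB mid DRUG_A gap1 [TRIG] gap2 DRUG_B post (+ extras)
    n_extra_pre <- if (n_mentions > 2) sample(0:(n_mentions - 2), 1) else 0L
    n_extra_post <- n_mentions - 2L - n_extra_pre
    for (w in sample(fillers, n_fill(2), replace = TRUE)) push(w, NA, "dep", "pre")
    v <- push(sample(sim_verbs(), 1), 0L, "root", "verb")
    for (k in seq_len(n_extra_pre)) push(drugs[2 + k], v, "obj", "extra")
    for (w in sample(fillers, n_fill(2), replace = TRUE)) push(w, v, "dep", "filler")
    if (label == "Negative") {
      a <- push(drugs[1], v, "obj", "drugA")
      gap <- sample(1:3, 1) # keep the pair non-adjacent
      slot <- if (decoy) sample(gap, 1) else 0L
      for (g in seq_len(gap)) {
        w <- if (g == slot) decoy_word else sample(fillers, 1)
        push(w, NA, "dep", "gapN") # resolved to drugB below
      }
      b <- push(drugs[2], v, "obj", "drugB")
      hd[role == "gapN"] <- b
    } else {
      a <- push(drugs[1], NA, "obj", "drugA") # resolved to trig below
      for (w in sample(fillers, n_fill(2), replace = TRUE)) push(w, NA, "dep", "gap1")
      tr <- push(trig_word, v, "advcl", "trig")
      hd[role == "drugA"] <- tr
      hd[role == "gap1"] <- tr
      for (w in sample(fillers, n_fill(2), replace = TRUE)) push(w, tr, "dep", "filler")
      b <- push(drugs[2], tr, "obj", "drugB")
      if (decoy) {
        # decoy goes before the verb or to the tail, attached to the verb
        push(decoy_word, v, "dep", "filler")
      }
    }
    for (k in seq_len(n_extra_post)) push(drugs[2 + n_extra_pre + k], v, "obj", "extra")
    for (w in sample(fillers, n_fill(3), replace = TRUE)) push(w, v, "dep", "filler")
    v_pos <- which(role == "verb")
    hd[role == "pre"] <- v_pos
  }
  hd[role == "pre"] <- which(role == "verb")
  stopifnot(!anyNA(hd))

  mention_pos <- c(which(role == "drugA"), which(role == "drugB"), which(role == "extra"))
  mention_pos <- sort(mention_pos)
  pair_pos <- sort(c(which(role == "drugA"), which(role == "drugB")))
  list(
    tokens = tok, head = hd, deprel = rl,
    mention_pos = mention_pos, pair_pos = pair_pos,
    label = label, filterable = filterable, planted_rule = planted_rule,
    decoy = decoy
  )
}

#' Generate a synthetic annotated corpus in memory
#'
#' @param cfg A [ddi_sim_config()].
#' @return A list with `sentences` (tibble in [read_ddi_xml()] shape),
#'   `parses` (tibble in [read_conllu()] shape), `gold` (tibble with
#'   `sentence_id`, `pair_id`, `label`) and `meta` (per-sentence planted
#'   label, filterable flag and rule, decoy flag).
#' @export
ddi_simulate <- function(cfg) {
  set.seed(cfg$seed)
  sent_rows <- vector("list", cfg$n_sentences)
  parse_rows <- vector("list", cfg$n_sentences)
  gold_rows <- vector("list", cfg$n_sentences)
  meta_rows <- vector("list", cfg$n_sentences)
  for (i in seq_len(cfg$n_sentences)) {
    s <- sim_sentence(cfg, i)
    sid <- paste0("s", i)
    text <- paste(s$tokens, collapse = " ")
    starts <- c(0L, head(cumsum(nchar(s$tokens) + 1L), -1L))
    mention_ids <- paste0(sid, ".e", seq_along(s$mention_pos))
    mentions <- tibble::tibble(
      id = mention_ids,
      char_start = starts[s$mention_pos],
      char_end = starts[s$mention_pos] + nchar(s$tokens[s$mention_pos]) - 1L,
      text = s$tokens[s$mention_pos],
      type = "drug"
    )
    combos <- utils::combn(seq_along(s$mention_pos), 2)
    pair_labels <- character(ncol(combos))
    for (p in seq_len(ncol(combos))) {
      pp <- sort(s$mention_pos[combos[, p]])
      pair_labels[p] <- if (identical(pp, s$pair_pos)) s$label else "Negative"
    }
    pairs <- tibble::tibble(
      pair_id = paste0(sid, ".p", seq_len(ncol(combos))),
      e1 = mention_ids[combos[1, ]],
      e2 = mention_ids[combos[2, ]],
      label = pair_labels
    )
    sent_rows[[i]] <- tibble::tibble(
      sentence_id = sid, text = text,
      mentions = list(mentions), pairs = list(pairs)
    )
    parse_rows[[i]] <- tibble::tibble(
      sentence_id = sid, form = list(s$tokens),
      head = list(s$head), deprel = list(s$deprel)
    )
    gold_rows[[i]] <- tibble::tibble(
      sentence_id = sid, pair_id = pairs$pair_id, label = pairs$label
    )
    meta_rows[[i]] <- tibble::tibble(
      sentence_id = sid, label = s$label, filterable = s$filterable,
      planted_rule = s$planted_rule, decoy = s$decoy,
      n_mentions = length(s$mention_pos), n_tokens = length(s$tokens)
    )
  }
  empty_sent <- tibble::tibble(
    sentence_id = character(), text = character(), mentions = list(), pairs = list()
  )
  empty_parse <- tibble::tibble(
    sentence_id = character(), form = list(), head = list(), deprel = list()
  )
  list(
    sentences = if (cfg$n_sentences > 0) dplyr::bind_rows(sent_rows) else empty_sent,
    parses = if (cfg$n_sentences > 0) dplyr::bind_rows(parse_rows) else empty_parse,
    gold = dplyr::bind_rows(gold_rows),
    meta = dplyr::bind_rows(meta_rows)
  )
}

#' Generate a synthetic corpus on disk
#'
#' Writes three cross-referenced files to `dir`: `corpus.xml` (DDI-XML
#' dialect), `corpus.conllu` (dependency parses over the collapsed
#' tokenization) and `gold.tsv` (sentence id, pair id, label). The same
#' seed produces byte-identical files.
#'
#' @param cfg A [ddi_sim_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the [ddi_simulate()] list with an added `paths`
#'   element.
#' @export
generate_ddi_corpus <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- ddi_simulate(cfg)
  paths <- list(
    xml = file.path(dir, "corpus.xml"),
    conllu = file.path(dir, "corpus.conllu"),
    gold = file.path(dir, "gold.tsv")
  )
  write_ddi_xml(sim$sentences, paths$xml)
  write_conllu(sim$parses, paths$conllu)
  gold <- sim$gold
  lines <- c(
    "sentence_id\tpair_id\tlabel",
    if (nrow(gold) > 0) paste(gold$sentence_id, gold$pair_id, gold$label, sep = "\t")
  )
  writeLines(lines, paths$gold)
  sim$paths <- paths
  invisible(sim)
}

#' Recompute a generated pair's label from its planted trigger
#'
#' Self-consistency oracle for the generator: a pair is positive iff both
#' drug tokens share the same tree parent and that parent is a trigger
#' token, in which case the label is the trigger's class; otherwise the
#' pair is Negative.
#'
#' @param tokens Token vector of the generated sentence.
#' @param head 0-rooted parent indices.
#' @param pos1,pos2 Token positions of the two drugs of the pair.
#' @param triggers Trigger lexicons (as in the generating config).
#' @return A class label.
#' @export
oracle_label <- function(tokens, head, pos1, pos2, triggers = ddi_sim_triggers()) {
  if (head[pos1] != head[pos2] || head[pos1] == 0L) {
    return("Negative")
  }
  parent <- tokens[head[pos1]]
  for (cls in names(triggers)) {
    if (parent %in% triggers[[cls]]) {
      return(cls)
    }
  }
  "Negative"
}
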