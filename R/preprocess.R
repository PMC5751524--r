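# Candidate-instance construction: drug blinding and rule-based
# negative-instance filtering.

# Tokenize a sentence and collapse every annotated mention span to a single
# token. Returns the collapsed tokens, the mention row index owning each
# token (NA for plain words), and per-mention token positions. This collapsed
# tokenization is the canonical one: dependency parses must align with it.
canonical_tokens <- function(text, mentions) {
  spans <- tokenize_spans(text)
  n <- nrow(spans)
  owner <- rep(NA_integer_, n)
  overlapping <- integer(0)
  for (j in seq_len(nrow(mentions))) {
    cov <- which(spans$start <= mentions$char_end[j] & spans$end >= mentions$char_start[j])
    if (length(cov) == 0) {
      stop("mention '", mentions$id[j], "' covers no token", call. = FALSE)
    }
    cov <- seq(min(cov), max(cov))
    clash <- cov[!is.na(owner[cov])]
    if (length(clash) > 0) {
      overlapping <- union(overlapping, c(j, owner[clash]))
    }
    owner[cov] <- j
  }
  # collapse runs of tokens sharing an owner into one token
  tokens <- character(0)
  tok_owner <- integer(0)
  i <- 1L
  while (i <= n) {
    if (is.na(owner[i])) {
      tokens <- c(tokens, spans$token[i])
      tok_owner <- c(tok_owner, NA_integer_)
      i <- i + 1L
    } else {
      j <- owner[i]
      k <- i
      while (k < n && !is.na(owner[k + 1L]) && owner[k + 1L] == j) k <- k + 1L
      tokens <- c(tokens, mentions$text[j])
      tok_owner <- c(tok_owner, j)
      i <- k + 1L
    }
  }
  mention_pos <- match(seq_len(nrow(mentions)), tok_owner)
  list(
    tokens = tokens, owner = tok_owner,
    mention_pos = mention_pos, overlapping = overlapping
  )
}

# Blind one candidate pair given the canonical tokenization: pair mentions
# become DRUG_1 / DRUG_2 (sentence order), all other mentions DRUG_N, and
# every remaining token is lowercased.
blind_tokens <- function(canon, mentions, e1, e2) {
  j1 <- match(e1, mentions$id)
  j2 <- match(e2, mentions$id)
  # DRUG_1 is the mention appearing first in the sentence
  if (mentions$char_start[j2] < mentions$char_start[j1]) {
    tmp <- j1
    j1 <- j2
    j2 <- tmp
  }
  tokens <- tolower(canon$tokens)
  tokens[!is.na(canon$owner)] <- DRUGN_TOKEN
  tokens[canon$mention_pos[j1]] <- DRUG1_TOKEN
  tokens[canon$mention_pos[j2]] <- DRUG2_TOKEN
  list(
    tokens = tokens,
    drug1_index = canon$mention_pos[j1],
    drug2_index = canon$mention_pos[j2],
    mention1 = mentions$text[j1],
    mention2 = mentions$text[j2]
  )
}

#' Build blinded candidate instances from annotated sentences
#'
#' Every annotated pair yields one instance: the two candidate mentions are
#' replaced by the placeholder tokens `DRUG_1` and `DRUG_2` in sentence
#' order, all other drug mentions by `DRUG_N`, multi-token mentions are
#' collapsed to a single token, and remaining tokens are lowercased. The
#' placeholders keep their uppercase so they stay distinct vocabulary items.
#'
#' When `parses` are supplied, each parse must have exactly one token per
#' collapsed sentence token; any mismatch is an alignment error (never a
#' silent truncation). Parses with several roots are repaired by attaching
#' the extra roots to the first root with relation `"dep"`.
#'
#' @param sentences Sentence tibble from [read_ddi_xml()].
#' @param parses Optional parse tibble from [read_conllu()], keyed by
#'   `sentence_id`.
#' @return A tibble with one row per annotated pair: `sentence_id`,
#'   `pair_id`, `e1`, `e2`, `label`, list-column `tokens`, `drug1_index`,
#'   `drug2_index` (1-based token positions, `drug1_index < drug2_index`),
#'   original `mention1`/`mention2` texts, `n_tokens`, list-columns `head`
#'   and `deprel` (NULL when no parse), and `valid` (FALSE for pairs with
#'   overlapping mention spans, which are skipped with a warning).
#' @export
candidate_instances <- function(sentences, parses = NULL) {
  out <- vector("list", nrow(sentences))
  for (i in seq_len(nrow(sentences))) {
    sid <- sentences$sentence_id[i]
    mentions <- sentences$mentions[[i]]
    prs <- sentences$pairs[[i]]
    if (nrow(prs) == 0) next
    canon <- canonical_tokens(sentences$text[i], mentions)
    head_ <- NULL
    rel <- NULL
    if (!is.null(parses)) {
      k <- match(sid, parses$sentence_id)
      if (!is.na(k)) {
        head_ <- parses$head[[k]]
        rel <- parses$deprel[[k]]
        if (length(head_) != length(canon$tokens)) {
          stop(
            "parse/token alignment error in sentence '", sid, "': ",
            length(head_), " parse tokens vs ", length(canon$tokens),
            " sentence tokens",
            call. = FALSE
          )
        }
      }
    }
    rows <- vector("list", nrow(prs))
    for (p in seq_len(nrow(prs))) {
      j1 <- match(prs$e1[p], mentions$id)
      j2 <- match(prs$e2[p], mentions$id)
      valid <- !(j1 %in% canon$overlapping || j2 %in% canon$overlapping)
      if (!valid) {
        warning("overlapping mention spans for pair '", prs$pair_id[p],
          "' in sentence '", sid, "'; instance marked invalid",
          call. = FALSE
        )
        rows[[p]] <- tibble::tibble(
          sentence_id = sid, pair_id = prs$pair_id[p],
          e1 = prs$e1[p], e2 = prs$e2[p], label = prs$label[p],
          tokens = list(character()), drug1_index = NA_integer_,
          drug2_index = NA_integer_, mention1 = NA_character_,
          mention2 = NA_character_, n_tokens = 0L,
          head = list(NULL), deprel = list(NULL), valid = FALSE
        )
        next
      }
      b <- blind_tokens(canon, mentions, prs$e1[p], prs$e2[p])
      rows[[p]] <- tibble::tibble(
        sentence_id = sid, pair_id = prs$pair_id[p],
        e1 = prs$e1[p], e2 = prs$e2[p], label = prs$label[p],
        tokens = list(b$tokens),
        drug1_index = as.integer(b$drug1_index),
        drug2_index = as.integer(b$drug2_index),
        mention1 = b$mention1, mention2 = b$mention2,
        n_tokens = length(b$tokens),
        head = list(head_), deprel = list(rel), valid = TRUE
      )
    }
    out[[i]] <- dplyr::bind_rows(rows)
  }
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      sentence_id = character(), pair_id = character(), e1 = character(),
      e2 = character(), label = character(), tokens = list(),
      drug1_index = integer(), drug2_index = integer(),
      mention1 = character(), mention2 = character(), n_tokens = integer(),
      head = list(), deprel = list(), valid = logical()
    ))
  }
  out
}

#' Blind one drug pair of one sentence
#'
#' Convenience wrapper around [candidate_instances()] for a single pair.
#'
#' @param sentence One-row sentence tibble.
#' @param pair_id Id of the pair to blind.
#' @return A one-row instance tibble.
#' @export
blind_drugs <- function(sentence, pair_id) {
  stopifnot(nrow(sentence) == 1)
  inst <- candidate_instances(sentence)
  out <- inst[inst$pair_id == pair_id, ]
  if (nrow(out) == 0) stop("pair '", pair_id, "' not found", call. = FALSE)
  out
}

# Which filtering rule (1, 2, 3) removes this instance, or 0L for none.
# Rules read only the blinded token stream and the original mention texts,
# never the label. First-matching-rule attribution: 1, then 2, then 3.
match_filter_rule <- function(tokens, d1, d2, mention1, mention2) {
  norm <- function(x) tolower(gsub("\\s+", " ", trimws(x)))
  # Rule 1: the two targeted drugs share the same name
  if (norm(mention1) == norm(mention2)) {
    return(1L)
  }
  between <- if (d2 - d1 > 1) tokens[(d1 + 1):(d2 - 1)] else character(0)
  filler_ok <- function(x) all(x %in% c(DRUGN_TOKEN, ","))
  # Rule 2a: DRUG_1 ( DRUG_N* DRUG_2 )
  if (length(between) >= 1 && between[1] == "(" &&
    filler_ok(between[-1]) &&
    d2 < length(tokens) && tokens[d2 + 1] == ")") {
    return(2L)
  }
  # Rule 2b: DRUG_1 such as DRUG_N* DRUG_2 (optional commas)
  if (length(between) >= 2) {
    b <- between
    if (b[1] == ",") b <- b[-1]
    if (length(b) >= 2 && b[1] == "such" && b[2] == "as" && filler_ok(b[-(1:2)])) {
      return(2L)
    }
  }
  # Rule 3: both drugs inside one coordinate structure -- everything between
  # them is commas, conjunctions or other (blinded) drugs
  if (length(between) >= 1 && all(between %in% c(",", "and", "or", DRUGN_TOKEN))) {
    return(3L)
  }
  0L
}

#' Filter likely-negative candidate instances
#'
#' Applies the three removal rules to every instance, label-blind:
#' \describe{
#'   \item{Rule 1}{the two targeted drugs share the same name (exact
#'     case-insensitive match of the original mention texts after whitespace
#'     normalization);}
#'   \item{Rule 2}{apposition/exemplification: `DRUG_1 ( DRUG_N* DRUG_2 )`
#'     or `DRUG_1 such as DRUG_N* DRUG_2`, with optional commas;}
#'   \item{Rule 3}{coordination: the two drugs appear in the same coordinate
#'     structure, i.e. every token between them is a comma, `and`, `or`, or
#'     another (blinded) drug.}
#' }
#' Rules are attributed in order 1, 2, 3 for reporting; the removal outcome
#' is order-independent.
#'
#' @param instances Instance tibble from [candidate_instances()].
#' @param keep If `TRUE`, no rows are dropped; instead columns `filtered`
#'   and `filter_rule` are added (useful for test-set scoring, where removed
#'   instances stay in the evaluation universe as predicted-Negative).
#' @return The retained (or annotated) instance tibble, with the removal
#'   tally attached as attribute `"filter_report"` (see [filter_report()]).
#' @export
filter_negatives <- function(instances, keep = FALSE) {
  n <- nrow(instances)
  rule <- integer(n)
  for (i in seq_len(n)) {
    if (!isTRUE(instances$valid[i])) next
    rule[i] <- match_filter_rule(
      instances$tokens[[i]], instances$drug1_index[i], instances$drug2_index[i],
      instances$mention1[i], instances$mention2[i]
    )
  }
  report <- build_filter_report(instances$label, rule)
  if (keep) {
    out <- instances
    out$filtered <- rule > 0L
    out$filter_rule <- ifelse(rule > 0L, rule, NA_integer_)
  } else {
    out <- instances[rule == 0L, ]
  }
  attr(out, "filter_report") <- report
  out
}

build_filter_report <- function(labels, rule) {
  by_rule_label <- tibble::tibble(label = labels, rule = rule) |>
    dplyr::filter(.data$rule > 0L) |>
    dplyr::count(.data$rule, .data$label, name = "n")
  structure(
    list(
      by_rule_label = by_rule_label,
      total = length(labels),
      removed = sum(rule > 0L),
      retained = sum(rule == 0L)
    ),
    class = "ddi_filter_report"
  )
}

#' Retrieve the filtering report
#'
#' @param x Output of [filter_negatives()].
#' @return A `ddi_filter_report`: removal counts per rule and per class plus
#'   totals, satisfying `removed + retained == total`.
#' @export
filter_report <- function(x) {
  attr(x, "filter_report")
}

#' @export
print.ddi_filter_report <- function(x, ...) {
  cat("<ddi_filter_report> total ", x$total, ", removed ", x$removed,
    ", retained ", x$retained, "\n",
    sep = ""
  )
  print(x$by_rule_label)
  invisible(x)
}
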