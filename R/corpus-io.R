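# Readers and writers for the corpus formats: the DDIExtraction-2013 XML
# dialect, CoNLL-U dependency parses, and word2vec text embeddings.

# Token pattern: runs of word characters joined by internal hyphens, slashes,
# apostrophes or dots (so "S-ketamine", "2.5" and "DRUG_1" stay whole), or a
# single non-word, non-space character (so "a," yields "a" ",").
TOKEN_REGEX <- "[[:alnum:]_]+(?:[-'/.][[:alnum:]_]+)*|[^[:alnum:]_[:space:]]"

#' Tokenize a sentence
#'
#' Deterministic whitespace-and-punctuation tokenizer. Punctuation characters
#' become single-character tokens, while internal hyphens, slashes,
#' apostrophes and dots are kept inside a token, so multiword-style drug
#' names such as "S-ketamine" survive as one token.
#'
#' @param text A single string.
#' @return Character vector of tokens (empty for an empty string).
#' @examples
#' ddi_tokenize("a, b")
#' @export
ddi_tokenize <- function(text) {
  tokenize_spans(text)$token
}

# Tokenize with 0-based inclusive character offsets, needed to map entity
# charOffsets onto token ranges.
tokenize_spans <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(token = character(), start = integer(), end = integer()))
  }
  m <- gregexpr(TOKEN_REGEX, text)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(token = character(), start = integer(), end = integer()))
  }
  len <- attr(m, "match.length")
  tibble::tibble(
    token = substring(text, m, m + len - 1),
    start = as.integer(m - 1L),
    end = as.integer(m + len - 2L)
  )
}

#' Read a corpus file in the DDIExtraction-2013 XML dialect
#'
#' Parses `document`/`sentence`/`entity`/`pair` elements. Entity character
#' offsets are 0-based with inclusive ends (the corpus convention). Pair
#' labels are mapped to the fixed class set: `ddi="false"` becomes
#' `"Negative"`; `ddi="true"` takes its (case-normalized) `type` attribute,
#' with the corpus spelling "advise" normalized to "Advice".
#'
#' @param path Path to an XML file whose root is a `document` element or a
#'   container of `document` elements.
#' @return A tibble with one row per sentence: `sentence_id`, `text`, and
#'   list-columns `mentions` (tibbles with `id`, `char_start`, `char_end`,
#'   `text`, `type`) and `pairs` (tibbles with `pair_id`, `e1`, `e2`,
#'   `label`).
#' @export
read_ddi_xml <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop("malformed XML in '", path, "': ", conditionMessage(e), call. = FALSE)
  )
  sents <- xml2::xml_find_all(doc, ".//sentence")
  rows <- lapply(sents, parse_sentence_node)
  if (length(rows) == 0) {
    return(tibble::tibble(
      sentence_id = character(), text = character(),
      mentions = list(), pairs = list()
    ))
  }
  dplyr::bind_rows(rows)
}

parse_sentence_node <- function(node) {
  sid <- xml2::xml_attr(node, "id")
  text <- xml2::xml_attr(node, "text")
  ents <- xml2::xml_find_all(node, "./entity")
  mentions <- tibble::tibble(
    id = xml2::xml_attr(ents, "id"),
    char_offset = xml2::xml_attr(ents, "charOffset"),
    text = xml2::xml_attr(ents, "text"),
    type = xml2::xml_attr(ents, "type")
  )
  off <- parse_char_offsets(mentions$char_offset)
  mentions$char_start <- off$start
  mentions$char_end <- off$end
  mentions$char_offset <- NULL
  mentions <- mentions[, c("id", "char_start", "char_end", "text", "type")]
  bad <- which(
    mentions$char_start > mentions$char_end |
      mentions$char_start < 0 | mentions$char_end >= nchar(text)
  )
  if (length(bad) > 0) {
    stop("invalid charOffset for entity '", mentions$id[bad[1]],
      "' in sentence '", sid, "'",
      call. = FALSE
    )
  }
  prs <- xml2::xml_find_all(node, "./pair")
  pairs <- tibble::tibble(
    pair_id = xml2::xml_attr(prs, "id"),
    e1 = xml2::xml_attr(prs, "e1"),
    e2 = xml2::xml_attr(prs, "e2"),
    label = map_pair_label(xml2::xml_attr(prs, "ddi"), xml2::xml_attr(prs, "type"))
  )
  unknown <- setdiff(c(pairs$e1, pairs$e2), mentions$id)
  if (length(unknown) > 0) {
    stop("pair references unknown entity id '", unknown[1],
      "' in sentence '", sid, "'",
      call. = FALSE
    )
  }
  if (nrow(pairs) > 0 && any(pairs$e1 == pairs$e2)) {
    stop("pair references the same entity twice in sentence '", sid, "'", call. = FALSE)
  }
  tibble::tibble(
    sentence_id = sid, text = text,
    mentions = list(mentions), pairs = list(pairs)
  )
}

# charOffset is "start-end"; discontinuous annotations "s1-e1;s2-e2" are
# reduced to their first span.
parse_char_offsets <- function(x) {
  first <- sub(";.*$", "", x)
  parts <- regmatches(first, regexec("^([0-9]+)-([0-9]+)$", first))
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad)) {
    stop("cannot parse charOffset '", x[which(bad)[1]], "'", call. = FALSE)
  }
  list(
    start = vapply(parts, function(p) as.integer(p[2]), 1L),
    end = vapply(parts, function(p) as.integer(p[3]), 1L)
  )
}

map_pair_label <- function(ddi, type) {
  if (length(ddi) == 0) {
    return(character())
  }
  out <- ifelse(tolower(ddi) == "false", "Negative", NA_character_)
  pos <- which(is.na(out))
  if (length(pos) > 0) {
    ty <- tolower(type[pos])
    canon <- c(
      advice = "Advice", advise = "Advice", effect = "Effect",
      mechanism = "Mechanism", int = "Int"
    )
    mapped <- canon[ty]
    if (anyNA(mapped)) {
      stop("unknown DDI type '", ty[which(is.na(mapped))[1]], "'", call. = FALSE)
    }
    out[pos] <- mapped
  }
  out
}

#' Write sentences to the DDIExtraction-2013 XML dialect
#'
#' Inverse of [read_ddi_xml()]; used by the synthetic-corpus generator and
#' for round-trip testing.
#'
#' @param sentences Sentence tibble as returned by [read_ddi_xml()].
#' @param path Output file path.
#' @param document_id `id` attribute for the enclosing `document` element.
#' @return `path`, invisibly.
#' @export
write_ddi_xml <- function(sentences, path, document_id = "d0") {
  doc <- xml2::xml_new_root("document", id = document_id)
  for (i in seq_len(nrow(sentences))) {
    sn <- xml2::xml_add_child(doc, "sentence",
      id = sentences$sentence_id[i], text = sentences$text[i]
    )
    men <- sentences$mentions[[i]]
    for (j in seq_len(nrow(men))) {
      xml2::xml_add_child(sn, "entity",
        id = men$id[j],
        charOffset = paste0(men$char_start[j], "-", men$char_end[j]),
        type = men$type[j], text = men$text[j]
      )
    }
    prs <- sentences$pairs[[i]]
    for (j in seq_len(nrow(prs))) {
      lab <- prs$label[j]
      if (lab == "Negative") {
        xml2::xml_add_child(sn, "pair",
          id = prs$pair_id[j], e1 = prs$e1[j], e2 = prs$e2[j], ddi = "false"
        )
      } else {
        xml2::xml_add_child(sn, "pair",
          id = prs$pair_id[j], e1 = prs$e1[j], e2 = prs$e2[j],
          ddi = "true", type = tolower(lab)
        )
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read dependency parses from a CoNLL-U file
#'
#' Only the ID, FORM, HEAD and DEPREL columns are used; sentences are keyed
#' by their `# sent_id = ...` metadata line. Multiword-token ranges and
#' empty-node lines are skipped.
#'
#' @param path Path to a CoNLL-U file.
#' @return A tibble with one row per sentence: `sentence_id` and
#'   list-columns `form` (character), `head` (integer, 0 = root) and
#'   `deprel` (character).
#' @export
read_conllu <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sent_id <- NA_character_
  forms <- heads <- rels <- list()
  cur <- NULL
  out <- list()
  flush <- function() {
    if (!is.null(cur) && nrow(cur) > 0) {
      if (is.na(sent_id)) stop("CoNLL-U block without sent_id in '", path, "'", call. = FALSE)
      out[[length(out) + 1L]] <<- tibble::tibble(
        sentence_id = sent_id,
        form = list(cur$form), head = list(cur$head), deprel = list(cur$deprel)
      )
    }
    cur <<- NULL
    sent_id <<- NA_character_
  }
  for (ln in lines) {
    if (!nzchar(ln)) {
      flush()
      next
    }
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*sent_id\\s*=\\s*(\\S+)", ln))[[1]]
      if (length(m) == 2) sent_id <- m[2]
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) stop("malformed CoNLL-U line: '", ln, "'", call. = FALSE)
    if (grepl("[-.]", f[1])) next # multiword range or empty node
    row <- tibble::tibble(
      id = as.integer(f[1]), form = f[2],
      head = as.integer(f[7]), deprel = f[8]
    )
    cur <- if (is.null(cur)) row else dplyr::bind_rows(cur, row)
  }
  flush()
  if (length(out) == 0) {
    return(tibble::tibble(
      sentence_id = character(), form = list(), head = list(), deprel = list()
    ))
  }
  dplyr::bind_rows(out)
}

#' Write dependency parses to a CoNLL-U file
#'
#' @param parses Parse tibble as returned by [read_conllu()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_conllu <- function(parses, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(parses))) {
    writeLines(paste0("# sent_id = ", parses$sentence_id[i]), con)
    form <- parses$form[[i]]
    head_ <- parses$head[[i]]
    rel <- parses$deprel[[i]]
    for (t in seq_along(form)) {
      writeLines(paste(t, form[t], "_", "_", "_", "_", head_[t], rel[t], "_", "_",
        sep = "\t"
      ), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Build a token vocabulary
#'
#' Ids are dense, 1-based, with the special tokens PAD, UNK and the three
#' drug-blinding placeholders always present and first. Remaining tokens are
#' ordered by decreasing frequency, then alphabetically.
#'
#' @param token_lists A list of character vectors (or a single character
#'   vector) of tokens.
#' @param min_count Minimum frequency for a token to enter the vocabulary.
#' @return A `ddi_vocab` object: a named integer vector mapping token to id.
#' @export
build_vocab <- function(token_lists, min_count = 1L) {
  if (is.character(token_lists)) token_lists <- list(token_lists)
  specials <- c("PAD", "UNK", DRUG1_TOKEN, DRUG2_TOKEN, DRUGN_TOKEN)
  tokens <- unlist(token_lists, use.names = FALSE)
  tokens <- tokens[!tokens %in% specials]
  tab <- table(tokens)
  tab <- tab[tab >= min_count]
  ord <- order(-as.integer(tab), names(tab))
  words <- c(specials, names(tab)[ord])
  v <- setNames(seq_along(words), words)
  class(v) <- "ddi_vocab"
  v
}

#' @export
print.ddi_vocab <- function(x, ...) {
  cat("<ddi_vocab> ", length(x), " tokens (5 specials)\n", sep = "")
  invisible(x)
}

#' Map tokens to vocabulary ids
#'
#' @param vocab A `ddi_vocab` object.
#' @param tokens Character vector of tokens.
#' @return Integer ids; out-of-vocabulary tokens map to the UNK id.
#' @export
vocab_ids <- function(vocab, tokens) {
  ids <- unclass(vocab)[tokens]
  ids[is.na(ids)] <- unclass(vocab)[["UNK"]]
  as.integer(ids)
}

#' Load word vectors in word2vec text format
#'
#' Known vocabulary words are copied from the file; unknown words (and the
#' specials) are initialized uniformly in [-1, 1]. A leading "count dim"
#' header line is accepted but not required.
#'
#' @param path Path to a word2vec text-format file.
#' @param vocab A `ddi_vocab` object.
#' @param dw Expected word-embedding dimension; a file with a different
#'   dimension is a configuration error.
#' @return A `|vocab| x dw` matrix with attribute `n_unknown`, the number of
#'   vocabulary words not present in the file.
#' @export
load_word_vectors <- function(path, vocab, dw = 100L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0 && grepl("^[0-9]+\\s+[0-9]+\\s*$", lines[1])) {
    lines <- lines[-1]
  }
  emb <- init_embeddings(vocab, dw)
  known <- 0L
  words <- names(vocab)
  hit <- logical(length(vocab))
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 2) next
    vals <- as.numeric(f[-1])
    if (length(vals) != dw) {
      stop("word-vector dimension ", length(vals), " does not match dw = ", dw,
        call. = FALSE
      )
    }
    id <- unclass(vocab)[f[1]]
    if (!is.na(id)) {
      emb[id, ] <- vals
      hit[id] <- TRUE
    }
  }
  n_unknown <- sum(!hit[-match(c("PAD", "UNK", DRUG1_TOKEN, DRUG2_TOKEN, DRUGN_TOKEN), words)])
  attr(emb, "n_unknown") <- as.integer(n_unknown)
  emb
}

#' Randomly initialize an embedding matrix
#'
#' Entries are drawn uniformly in [-1, 1] from the current RNG state, so a
#' run seed makes the matrix reproducible.
#'
#' @param vocab A `ddi_vocab` object.
#' @param dw Word-embedding dimension.
#' @return A `|vocab| x dw` numeric matrix.
#' @export
init_embeddings <- function(vocab, dw = 100L) {
  matrix(runif(length(vocab) * dw, -1, 1),
    nrow = length(vocab), ncol = dw,
    dimnames = list(names(vocab), NULL)
  )
}
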