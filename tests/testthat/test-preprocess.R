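blinding_fixture <- function() {
  read_ddi_xml(fixture_path("blinding-example.xml"))
}

test_that("drug blinding reproduces the three worked candidates token-for-token", {
  s <- blinding_fixture()
  inst <- candidate_instances(s)
  expect_equal(nrow(inst), 3)
  stem <- c("the", "cns-depressant", "effect", "of")
  tail_ <- c("is", "additive", "with", "that", "of", "other")
  expect_equal(
    inst$tokens[[1]], # (propoxyphene, CNS depressants)
    c(stem, "DRUG_1", tail_, "DRUG_2", ",", "including", "DRUG_N")
  )
  expect_equal(
    inst$tokens[[2]], # (propoxyphene, alcohol)
    c(stem, "DRUG_1", tail_, "DRUG_N", ",", "including", "DRUG_2")
  )
  expect_equal(
    inst$tokens[[3]], # (CNS depressants, alcohol)
    c(stem, "DRUG_N", tail_, "DRUG_1", ",", "including", "DRUG_2")
  )
  expect_true(all(inst$drug1_index < inst$drug2_index))
})

test_that("blind_drugs extracts a single pair and a two-mention sentence has no DRUG_N", {
  s <- make_sentence(
    "alfazine may increase the effects of betaolol",
    list(list(text = "alfazine"), list(text = "betaolol")),
    list(list(1, 2, "Effect"))
  )
  inst <- blind_drugs(s, "s1.p1")
  expect_equal(nrow(inst), 1)
  toks <- inst$tokens[[1]]
  expect_equal(sum(toks == "DRUG_1"), 1)
  expect_equal(sum(toks == "DRUG_2"), 1)
  expect_false("DRUG_N" %in% toks)
  # everything else is lowercased
  expect_equal(toks[1], "DRUG_1")
  expect_equal(toks[2], "may")
})

test_that("all annotated pairs become instances: n(n-1)/2 for a fully paired sentence", {
  text <- "alfazine betaolol gamazine deltazine react"
  men <- lapply(c("alfazine", "betaolol", "gamazine", "deltazine"), function(w) list(text = w))
  combos <- utils::combn(4, 2)
  pairs <- lapply(seq_len(ncol(combos)), function(k) {
    list(combos[1, k], combos[2, k], "Negative")
  })
  s <- make_sentence(text, men, pairs)
  inst <- candidate_instances(s)
  expect_equal(nrow(inst), 4 * 3 / 2)
  expect_equal(candidate_instances(s[0, ]) |> nrow(), 0)
})

test_that("instance count equals the generator's planted pair count", {
  sim <- ddi_simulate(ddi_sim_config(n_sentences = 100, seed = 21))
  inst <- candidate_instances(sim$sentences, sim$parses)
  expect_equal(nrow(inst), nrow(sim$gold))
  expect_equal(inst$label, sim$gold$label)
})

test_that("parse/token misalignment raises an error naming the sentence", {
  s <- make_sentence(
    "alfazine inhibits betaolol",
    list(list(text = "alfazine"), list(text = "betaolol")),
    list(list(1, 2, "Mechanism"))
  )
  bad_parse <- tibble::tibble(
    sentence_id = "s1", form = list(c("alfazine", "inhibits")),
    head = list(c(2L, 0L)), deprel = list(c("nsubj", "root"))
  )
  expect_error(candidate_instances(s, bad_parse), "alignment error.*'s1'")
})

test_that("overlapping mention spans invalidate the pair with a warning", {
  text <- "oral hypoglycemic agents interact badly"
  s <- make_sentence(
    text,
    list(
      list(text = "oral hypoglycemic agents"),
      list(text = "hypoglycemic agents")
    ),
    list(list(1, 2, "Negative"))
  )
  expect_warning(inst <- candidate_instances(s), "overlapping")
  expect_false(inst$valid[1])
})

test_that("the three worked filtering sentences fall to rules 1, 2 and 3", {
  sents <- dplyr::bind_rows(
    make_sentence(
      "aspirin should not be taken with aspirin",
      list(list(text = "aspirin", occ = 1), list(text = "aspirin", occ = 2)),
      list(list(1, 2, "Negative")),
      sid = "a"
    ),
    make_sentence(
      paste(
        "A variety of antiarrhythmics such as quinidine or propranolol were",
        "also added, sometimes with improved control of ventricular ectopy."
      ),
      list(
        list(text = "antiarrhythmics"), list(text = "quinidine"),
        list(text = "propranolol")
      ),
      list(list(1, 2, "Negative")),
      sid = "b"
    ),
    make_sentence(
      "Sulfamethizole may increase the effects of barbiturates, tolbutamide, and uricosurics.",
      list(
        list(text = "Sulfamethizole"), list(text = "barbiturates"),
        list(text = "tolbutamide"), list(text = "uricosurics")
      ),
      list(list(2, 3, "Negative")),
      sid = "c"
    )
  )
  flagged <- filter_negatives(candidate_instances(sents), keep = TRUE)
  expect_equal(flagged$filter_rule, c(1L, 2L, 3L))
  expect_true(all(flagged$filtered))
})

test_that("a positive instance matching no pattern is retained", {
  s <- make_sentence(
    "alfazine strongly potentiates the effect of betaolol",
    list(list(text = "alfazine"), list(text = "betaolol")),
    list(list(1, 2, "Effect"))
  )
  inst <- candidate_instances(s)
  kept <- filter_negatives(inst)
  expect_equal(nrow(kept), 1)
  expect_equal(filter_report(kept)$removed, 0)
})

test_that("filtering is label-blind, idempotent, and its report adds up", {
  sim <- ddi_simulate(ddi_sim_config(n_sentences = 300, seed = 31))
  inst <- candidate_instances(sim$sentences, sim$parses)
  kept <- filter_negatives(inst)
  rep_ <- filter_report(kept)
  expect_equal(rep_$removed + rep_$retained, rep_$total)
  expect_equal(sum(rep_$by_rule_label$n), rep_$removed)
  # label-blind: relabelling every instance Advice removes the same rows
  relab <- inst
  relab$label <- "Advice"
  kept2 <- filter_negatives(relab)
  expect_equal(kept2$pair_id, kept$pair_id)
  # idempotent: filtering the retained set removes nothing
  again <- filter_negatives(kept)
  expect_equal(nrow(again), nrow(kept))
  expect_equal(filter_report(again)$removed, 0)
})

test_that("planted filterable negatives are all removed and no positive is lost", {
  sim <- ddi_simulate(ddi_sim_config(n_sentences = 400, filterable_frac = 0.3, seed = 41))
  inst <- candidate_instances(sim$sentences, sim$parses)
  flagged <- filter_negatives(inst, keep = TRUE)
  planted_sids <- sim$meta$sentence_id[sim$meta$filterable]
  # the designated pair of every planted sentence is removed
  planted <- flagged[flagged$sentence_id %in% planted_sids, ]
  expect_true(all(vapply(split(planted$filtered, planted$sentence_id), any, TRUE)))
  # no positive instance is ever removed on the synthetic corpus
  expect_false(any(flagged$filtered & flagged$label != "Negative"))
})
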