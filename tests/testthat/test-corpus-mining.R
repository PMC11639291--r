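test_that("dictionary construction validates and truncates codes", {
  d <- disease_dictionary(c("Hypertension", "renal failure"),
                          c("I10.9", "N17"))
  expect_equal(sort(unique(d$code)), c("I10", "N17"))
  expect_equal(attr(d, "n_names"), 2L)
  expect_error(disease_dictionary("", "I10"), "empty")
  expect_error(disease_dictionary("x", "1A0"), "invalid")
  # one name, two codes is ambiguous
  expect_error(disease_dictionary(c("pain", "Pain"), c("R52", "G89")),
               "ambiguous")
})

test_that("mention matching finds exact names at word boundaries", {
  d <- disease_dictionary("hypertension", "I10")
  m <- match_mentions("hypertension worsens outcomes", d)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 1L)
  expect_equal(m$end, 12L)
  expect_equal(m$code, "I10")
  # no partial-token matches
  expect_equal(nrow(match_mentions("pseudohypertensionlike state", d)), 0L)
  expect_equal(nrow(match_mentions("no disease terms here", d)), 0L)
})

test_that("longest dictionary match wins and offsets index the text", {
  d <- disease_dictionary(c("kidney disease", "chronic kidney disease"),
                          c("N18", "N18"))
  text <- "chronic kidney disease"
  m <- match_mentions(text, d)
  expect_equal(nrow(m), 1L)
  expect_equal(nchar(m$surface), 22L)
  # brute-force oracle: the longest dictionary name present in the text
  hits <- d$name[vapply(d$name, function(nm) grepl(nm, tolower(text),
                                                   fixed = TRUE), TRUE)]
  expect_equal(tolower(m$surface), hits[which.max(nchar(hits))])
  # offsets round-trip through substring
  expect_equal(tolower(substring(text, m$start, m$end)), tolower(m$surface))
})

test_that("mention matching is case-insensitive and left-to-right greedy", {
  d <- disease_dictionary(c("diabetes", "diabetic retinopathy"),
                          c("E11", "H35"))
  m <- match_mentions("DIABETES then Diabetic Retinopathy", d)
  expect_equal(m$code, c("E11", "H35"))
  expect_true(all(m$start == sort(m$start)))
  expect_true(all(m$end[-nrow(m)] < m$start[-1]))  # non-overlapping
})

test_that("pattern extraction orients pairs by slot names", {
  d <- disease_dictionary(c("diabetes", "retinopathy"), c("E11", "H35"))
  p <- causal_patterns(c("{CAUSE} can cause {EFFECT}",
                         "{EFFECT} caused by {CAUSE}"))
  fwd <- "diabetes can cause retinopathy"
  expect_equal(extract_pairs(fwd, match_mentions(fwd, d), p),
               data.frame(cause = "E11", effect = "H35",
                          stringsAsFactors = FALSE))
  rev <- "retinopathy caused by diabetes"
  expect_equal(extract_pairs(rev, match_mentions(rev, d), p),
               data.frame(cause = "E11", effect = "H35",
                          stringsAsFactors = FALSE))
  none <- "diabetes and retinopathy were measured"
  expect_equal(nrow(extract_pairs(none, match_mentions(none, d), p)), 0L)
})

test_that("pattern extraction tolerates case, whitespace and short gaps", {
  d <- disease_dictionary(c("cirrhosis", "portal hypertension"),
                          c("K74", "K76"))
  p <- causal_patterns("{CAUSE} leads to {EFFECT}")
  base <- extract_pairs("cirrhosis leads to portal hypertension",
                        match_mentions("cirrhosis leads to portal hypertension", d), p)
  spaced <- "   Cirrhosis  LEADS TO portal hypertension   "
  expect_equal(extract_pairs(spaced, match_mentions(spaced, d), p), base)
  gap <- "cirrhosis frequently leads to overt portal hypertension"
  expect_equal(extract_pairs(gap, match_mentions(gap, d), p), base)
})

test_that("a slot binds the mention nearest the cue", {
  d <- disease_dictionary(c("obesity", "diabetes", "nephropathy"),
                          c("E66", "E11", "N08"))
  p <- causal_patterns("{CAUSE} causes {EFFECT}")
  txt <- "obesity and diabetes causes nephropathy"
  pr <- extract_pairs(txt, match_mentions(txt, d), p)
  expect_equal(pr$cause, "E11")  # diabetes, adjacent to the cue
  expect_equal(pr$effect, "N08")
})

test_that("malformed templates fail at load time", {
  expect_error(causal_patterns("{CAUSE} causes trouble"), "malformed")
  expect_error(causal_patterns("{CAUSE} and {CAUSE} cause {EFFECT}"),
               "malformed")
})

test_that("same-category filtering keeps exactly the cross-category pairs", {
  pairs <- data.frame(
    cause = c("E11", "I25", "I10", "N17", "N18"),
    effect = c("E11", "I21", "I10", "N18", "N17"),
    stringsAsFactors = FALSE)
  kept <- filter_same_category(pairs)
  # enumeration oracle
  expect_equal(nrow(kept),
               sum(substr(pairs$cause, 1, 3) != substr(pairs$effect, 1, 3)))
  expect_equal(kept$cause, c("I25", "N17", "N18"))
  expect_equal(nrow(filter_same_category(
    data.frame(cause = "E11", effect = "E11"))), 0L)
})

test_that("aggregation counts distinct sentences and keeps direction", {
  pairs <- data.frame(
    cause = c("I10", "I10", "I10", "N17"),
    effect = c("N17", "N17", "N17", "I10"),
    doc_id = c("d1", "d2", "d2", "d3"),
    sent_id = c("s1", "s1", "s1", "s1"),
    stringsAsFactors = FALSE)
  rel <- aggregate_relations(pairs)
  expect_equal(nrow(rel), 2L)
  expect_equal(rel$n_annot[rel$cause == "I10"], 2L)  # d2:s1 deduplicated
  expect_equal(rel$n_annot[rel$cause == "N17"], 1L)
  expect_equal(rel$sentence_ids[rel$cause == "I10"], "d1:s1;d2:s1")
})

test_that("mining a planted corpus recovers the truth relations", {
  w <- gen_world(world_config(n_codes = 25, n_edges = 40,
                              n_individuals = 100), seed = 42)
  corp <- gen_corpus(w)
  res <- mine_corpus(corp$corpus, corp$dictionary)
  truth_key <- paste0(corp$truth$cause, "->", corp$truth$effect)
  mined_key <- paste0(res$relations$cause, "->", res$relations$effect)
  expect_setequal(mined_key, truth_key)
  expect_equal(res$relations$n_annot[match(truth_key, mined_key)],
               corp$truth$n_annot)
  # no same-category pair survives
  expect_true(all(substr(res$relations$cause, 1, 3) !=
                    substr(res$relations$effect, 1, 3)))
})

test_that("dictionary and corpus round-trip through their file formats", {
  tmp <- withr::local_tempdir()
  d <- disease_dictionary(c("angina pectoris", "heart failure"),
                          c("I20", "I50"))
  write_dictionary(d, file.path(tmp, "dict.tsv"))
  expect_equal(read_dictionary(file.path(tmp, "dict.tsv"))$name, d$name)
  corp <- data.frame(doc_id = "d1", sent_id = "s1",
                     text = "angina pectoris due to heart failure",
                     stringsAsFactors = FALSE)
  write_corpus(corp, file.path(tmp, "c.jsonl"))
  expect_equal(read_corpus(file.path(tmp, "c.jsonl")), corp)
})
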