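test_that("contingency tables count joint disease status over everyone", {
  rec <- make_records(list(
    I10 = data.frame(idx = c(1, 2), year = 2000),
    N17 = data.frame(idx = c(1, 3), year = 2005)), n = 4)
  tb <- contingency_table(rec, "I10", "N17")
  expect_equal(unclass(tb)[c("n11", "n10", "n01", "n00")],
               list(n11 = 1L, n10 = 1L, n01 = 1L, n00 = 1L))
  expect_equal(tb$n, 4L)
  # empty diagnoses: everyone has neither
  empty <- make_records(list(), n = 10)
  tb0 <- contingency_table(empty, "I10", "N17")
  expect_equal(tb0$n00, 10L)
  expect_equal(tb0$n11 + tb0$n10 + tb0$n01, 0L)
  # unknown code: zero margin, no error
  tbu <- contingency_table(rec, "Z99", "N17")
  expect_equal(tbu$n11 + tbu$n10, 0L)
})

test_that("contingency counts match generator tallies on simulated data", {
  w <- gen_world(world_config(n_codes = 10, n_edges = 8,
                              n_individuals = 500), seed = 5)
  rec <- gen_patients(w)
  truth <- attr(rec, "truth")
  for (code in names(truth$case_counts)[1:4]) {
    other <- setdiff(w$codes, code)[1]
    tb <- contingency_table(rec, code, other)
    expect_equal(tb$n11 + tb$n10, unname(truth$case_counts[code]))
  }
})

test_that("phi matches its closed form and the zero-margin rule", {
  expect_identical(phi_coefficient(contingency_2x2(0, 0, 0, 0)), 0)
  expect_identical(phi_coefficient(contingency_2x2(50, 0, 0, 50)), 1)
  expect_identical(phi_coefficient(contingency_2x2(7, 0, 3, 0)), 0)
  expect_equal(phi_coefficient(contingency_2x2(10, 5, 3, 82)),
               0.670362150538242, tolerance = 1e-12)
})

test_that("phi equals the Pearson correlation of the binary indicators", {
  set.seed(101)
  for (i in 1:200) {
    counts <- rmultinom(1, sample(20:200, 1), prob = runif(4, 0.05, 1))
    x <- rep(c(1, 1, 0, 0), counts)
    y <- rep(c(1, 0, 1, 0), counts)
    tb <- contingency_2x2(counts[1], counts[2], counts[3], counts[4])
    if (sd(x) > 0 && sd(y) > 0) {
      expect_equal(phi_coefficient(tb), cor(x, y), tolerance = 1e-12)
    } else {
      expect_identical(phi_coefficient(tb), 0)
    }
  }
})

test_that("dependence screen flags strong association and small samples", {
  tabs <- list(strong = contingency_2x2(500, 10, 10, 500),
               tiny = contingency_2x2(2, 1, 1, 2),
               null1 = contingency_2x2(50, 50, 50, 50),
               null2 = contingency_2x2(40, 60, 42, 58))
  res <- dependence_screen(tabs)
  expect_equal(res$dep[res$relation == "strong"], 1L)
  expect_false(res$testable[res$relation == "tiny"])
  expect_equal(res$dep[res$relation == "tiny"], 0L)
  expect_true(is.na(res$p_value[res$relation == "tiny"]))
})

test_that("a single-relation screen reduces to an unadjusted chi-square", {
  tb <- contingency_2x2(30, 20, 15, 35)
  res <- dependence_screen(list(r = tb))
  ref <- chisq.test(matrix(c(30, 20, 15, 35), 2, 2), correct = FALSE)
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$p_adj, ref$p.value)  # BH of one p-value is itself
})

test_that("adding null relations never increases the significant count", {
  set.seed(7)
  strong <- list(s1 = contingency_2x2(400, 30, 30, 400),
                 s2 = contingency_2x2(200, 80, 60, 300))
  nulls <- lapply(1:30, function(i) {
    x <- rbinom(400, 1, 0.3); y <- rbinom(400, 1, 0.3)
    contingency_2x2(sum(x & y), sum(x & !y), sum(!x & y), sum(!x & !y))
  })
  names(nulls) <- paste0("n", 1:30)
  small <- dependence_screen(strong)
  big <- dependence_screen(c(strong, nulls))
  expect_lte(sum(big$dep[1:2]), sum(small$dep))
})

test_that("ddate counts cause-not-after-effect years among co-occurrences", {
  rec <- make_records(list(
    A10 = data.frame(idx = 1:4, year = c(2000, 2001, 2003, 2010)),
    B20 = data.frame(idx = 1:4, year = c(2005, 2001, 2004, 2002))),
    n = 5)
  expect_equal(ddate(rec, "A10", "B20"), 0.75)
  expect_equal(ddate(rec, "B20", "A10"), 0.5)  # ties count for the cause
  # no co-occurring individuals
  rec2 <- make_records(list(A10 = data.frame(idx = 1, year = 2000),
                            B20 = data.frame(idx = 2, year = 2001)), n = 2)
  expect_equal(ddate(rec2, "A10", "B20"), 0)
  # all causes strictly earlier
  rec3 <- make_records(list(A10 = data.frame(idx = 1:3, year = 2000),
                            B20 = data.frame(idx = 1:3, year = 2005)), n = 3)
  expect_equal(ddate(rec3, "A10", "B20"), 1)
})

test_that("ddate is invariant to shifting all years by a constant", {
  set.seed(11)
  yx <- sample(1990:2010, 20, replace = TRUE)
  yy <- sample(1990:2010, 20, replace = TRUE)
  r1 <- make_records(list(A10 = data.frame(idx = 1:20, year = yx),
                          B20 = data.frame(idx = 1:20, year = yy)), n = 20)
  r2 <- make_records(list(A10 = data.frame(idx = 1:20, year = yx + 7),
                          B20 = data.frame(idx = 1:20, year = yy + 7)), n = 20)
  expect_equal(ddate(r1, "A10", "B20"), ddate(r2, "A10", "B20"))
})

test_that("annotation support binarizes against the run-wide median", {
  expect_equal(binarize_nannot(c(A = 1, B = 1, C = 2)),
               c(A = 0L, B = 0L, C = 1L))
  expect_equal(unname(binarize_nannot(c(3, 3, 3))), c(0L, 0L, 0L))
  # the mined-corpus regime: median 1, two-sentence support scores 1
  counts <- c(rep(1L, 10), 2L, 5L)
  expect_equal(unname(binarize_nannot(counts)),
               as.integer(counts > 1))
})

test_that("combined score averages the five measures with the phi clamp", {
  expect_equal(combined_score(1, 1, 1, 1, 1), 1)
  expect_equal(combined_score(0, 0, 0, 0, 0), 0)
  expect_equal(combined_score(0.5, 1, 0.75, 1, 0), 0.65)
  expect_equal(combined_score(-0.4, 1, 0, 0, 0), 0.2)  # clamped, in [0,1]
  # monotone non-decreasing in each measure
  set.seed(3)
  for (i in 1:50) {
    m <- list(phi = runif(1, -1, 1), dep = rbinom(1, 1, 0.5),
              dd = runif(1), nb = rbinom(1, 1, 0.5), g = rbinom(1, 1, 0.5))
    base <- combined_score(m$phi, m$dep, m$dd, m$nb, m$g)
    expect_gte(combined_score(min(m$phi + 0.1, 1), m$dep, m$dd, m$nb, m$g),
               base)
    expect_gte(combined_score(m$phi, 1, m$dd, m$nb, m$g), base)
    expect_gte(combined_score(m$phi, m$dep, min(m$dd + 0.1, 1), m$nb, m$g),
               base)
  }
})

test_that("judges parse affirmative responses and replay transcripts", {
  j <- llm_judge_stub(c("hypertension|acute kidney failure" = "Yes",
                        "gout|asthma" = "No"))
  expect_equal(judge_confirm(j, "Hypertension", "acute kidney failure"), 1L)
  expect_equal(judge_confirm(j, "gout", "asthma"), 0L)
  expect_equal(judge_confirm(j, "unknown", "pair"), 0L)  # default "No"
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"cause":"a","effect":"b","response":"Yes"}',
               '{"cause":"c","effect":"d","response":"no, unlikely"}',
               '{"cause":"e","effect":"f","response":"yes - established"}'),
             tmp)
  r <- llm_judge_replay(tmp)
  expect_equal(vapply(list(c("a", "b"), c("c", "d"), c("e", "f")),
                      function(p) judge_confirm(r, p[1], p[2]), 0L),
               c(1L, 0L, 1L))
})

test_that("group comparison reproduces the transformed t-test and Cohen's d", {
  a <- c(0.30, 0.10, 0.25, 0.40, 0.05)
  b <- c(0.02, -0.05, 0.10, 0.00, 0.08)
  v <- validation_stats(a, b)
  expect_equal(v$t_statistic, 2.683959307866, tolerance = 1e-9)
  expect_equal(v$cohens_d, 1.697484912013, tolerance = 1e-9)
  # identical groups: no effect
  same <- validation_stats(a, a)
  expect_equal(same$cohens_d, 0)
  expect_equal(same$p_value, 1)
  expect_error(validation_stats(rep(0.2, 5), rep(0.2, 5)), "variance")
})

test_that("Cohen's d recovers a planted standardized separation", {
  set.seed(21)
  delta <- 0.8
  a <- tanh(rnorm(20000, delta, 1))
  b <- tanh(rnorm(20000, 0, 1))
  v <- validation_stats(a, b)
  expect_equal(v$cohens_d, delta, tolerance = 0.05)
})

test_that("random pair sampling is exhaustive, seeded and exclusion-aware", {
  pairs <- random_pair_sampler(c("A01", "B02", "C03"), 6, seed = 9)
  expect_equal(nrow(pairs), 6L)
  expect_equal(anyDuplicated(paste(pairs$cause, pairs$effect)), 0L)
  expect_identical(random_pair_sampler(c("A01", "B02", "C03"), 6, seed = 9),
                   pairs)
  excl <- data.frame(cause = "A01", effect = "B02")
  p2 <- random_pair_sampler(c("A01", "B02", "C03"), 5, exclude = excl,
                            seed = 1)
  expect_false("A01->B02" %in% paste0(p2$cause, "->", p2$effect))
  expect_error(random_pair_sampler(c("A01", "B02"), 5), "eligible")
})

test_that("random pair sampling is uniform over eligible pairs", {
  codes <- c("A01", "B02", "C03", "D04")
  draws <- table(unlist(lapply(1:3000, function(i) {
    p <- random_pair_sampler(codes, 1, seed = i)
    paste0(p$cause, "->", p$effect)
  })))
  expect_equal(length(draws), 12L)
  expect_gt(chisq.test(draws)$p.value, 0.01)
})

test_that("scored edges combine the measures and sort by score", {
  w <- gen_world(world_config(n_codes = 12, n_edges = 15,
                              n_individuals = 800), seed = 31)
  corp <- gen_corpus(w)
  res <- mine_corpus(corp$corpus, corp$dictionary)
  rec <- gen_patients(w)
  sc <- score_relations(res$relations, rec)
  expect_true(all(sc$score >= 0 & sc$score <= 1))
  expect_true(!is.unsorted(rev(sc$score)))
  expect_equal(sc$score,
               combined_score(sc$phi, sc$dep, sc$ddate, sc$nannot_bin,
                              sc$gpt))
})
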