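toy_genotypes <- function() {
  G <- matrix(c(0, 1, 2, 2,
                1, 1, 0, 2,
                2, 0, 1, 1), nrow = 4,
              dimnames = list(NULL, c("rs1", "rs2", "rs3")))
  genotype_matrix(G, data.frame(
    variant_id = c("rs1", "rs2", "rs3"),
    allele1 = c("A", "T", "C"), allele2 = c("C", "G", "T"),
    info = c(1, 1, 1), stringsAsFactors = FALSE))
}

test_that("harmonization aligns, flips and excludes with reasons", {
  g <- toy_genotypes()
  s <- scoring_file(c("rs1", "rs2", "rs3"), "1", 1:3,
                    effect_allele = c("A", "G", "C"),
                    other_allele = c("C", "T", "T"),
                    effect_weight = c(0.5, -0.2, 0.1))
  h <- harmonize_variants(s, g)
  expect_equal(names(h$weights), c("rs1", "rs2", "rs3"))
  expect_equal(h$dosages[, "rs1"], g$dosages[, "rs1"])   # as-is
  expect_equal(h$dosages[, "rs2"], 2 - g$dosages[, "rs2"])  # flipped
  expect_equal(nrow(h$exclusions), 0L)
  # ambiguous, duplicate, missing, low-info exclusions
  g2 <- toy_genotypes()
  g2$variants$info[3] <- 0.1
  s2 <- scoring_file(c("rs1", "rs1", "rsX", "rs3", "rs4"), "1", 1:5,
                     effect_allele = c("A", "A", "G", "C", "A"),
                     other_allele = c("C", "C", "T", "T", "T"),
                     effect_weight = c(0.5, 0.5, 0.2, 0.1, 0.3))
  h2 <- harmonize_variants(s2, g2)
  reasons <- setNames(h2$exclusions$reason, h2$exclusions$variant_id)
  expect_equal(unname(reasons["rs4"]), "ambiguous")
  expect_equal(unname(reasons["rsX"]), "not_in_genotypes")
  expect_equal(unname(reasons["rs3"]), "low_imputation_quality")
  expect_true("duplicate" %in% reasons)
  expect_equal(names(h2$weights), "rs1")
  expect_error(harmonize_variants(
    scoring_file("rsQ", "1", 1, "A", "C", 1), g), "overlap")
})

test_that("scores are invariant to the scoring file's allele orientation", {
  g <- toy_genotypes()
  fwd <- scoring_file(c("rs1", "rs2"), "1", 1:2,
                      effect_allele = c("A", "T"),
                      other_allele = c("C", "G"),
                      effect_weight = c(0.4, -0.3))
  # swapped orientation: effect/other exchanged, weight negated and the
  # baseline shifts by 2w per variant; the induced risk ordering is equal
  rev <- scoring_file(c("rs1", "rs2"), "1", 1:2,
                      effect_allele = c("C", "G"),
                      other_allele = c("A", "T"),
                      effect_weight = c(-0.4, 0.3))
  p_fwd <- compute_prs(harmonize_variants(fwd, g))
  p_rev <- compute_prs(harmonize_variants(rev, g))
  expect_equal(p_rev, p_fwd - 2 * 0.4 - 2 * (-0.3), tolerance = 1e-12)
  expect_equal(rank(p_rev), rank(p_fwd))
})

test_that("the PRS is the weighted dosage sum, with mean imputation", {
  h <- list(weights = c(rs1 = 0.5),
            dosages = matrix(2, 1, 1, dimnames = list(NULL, "rs1")))
  expect_equal(compute_prs(h), 1.0)
  g <- toy_genotypes()
  s <- scoring_file(c("rs1", "rs2", "rs3"), "1", 1:3,
                    effect_allele = c("A", "T", "C"),
                    other_allele = c("C", "G", "T"),
                    effect_weight = c(0.25, -0.5, 1))
  h2 <- harmonize_variants(s, g)
  expect_equal(compute_prs(h2), drop(g$dosages %*% c(0.25, -0.5, 1)))
  # all-zero weights
  s0 <- scoring_file("rs1", "1", 1, "A", "C", 0)
  expect_equal(unname(compute_prs(harmonize_variants(s0, g))),
               rep(0, 4))
  # missing dosage replaced by the variant mean
  h3 <- h2
  h3$dosages[1, "rs1"] <- NA
  mu <- mean(h3$dosages[-1, "rs1"])
  expect_equal(unname(compute_prs(h3)[1]),
               unname(mu * 0.25 + h3$dosages[1, "rs2"] * -0.5 +
                        h3$dosages[1, "rs3"] * 1))
})

test_that("the PRS is linear in the weights", {
  set.seed(53)
  G <- matrix(rbinom(500, 2, 0.3), 100, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  w1 <- setNames(rnorm(5), colnames(G))
  w2 <- setNames(rnorm(5), colnames(G))
  p1 <- compute_prs(list(weights = w1, dosages = G))
  p2 <- compute_prs(list(weights = w2, dosages = G))
  p12 <- compute_prs(list(weights = w1 + w2, dosages = G))
  expect_equal(p12, p1 + p2, tolerance = 1e-9)
})

test_that("AUC matches exhaustive pairwise comparison and its invariances", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  scores <- c(1, 2, 2, 3, 3, 5)
  labels <- c(0, 0, 1, 0, 1, 1)
  expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  expect_equal(roc_auc(exp(scores), labels), roc_auc(scores, labels))
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  set.seed(59)
  big <- rnorm(20000)
  expect_equal(roc_auc(big, rbinom(20000, 1, 0.5)), 0.5, tolerance = 0.02)
})

test_that("the modified PRS recovers a planted combination coefficient", {
  set.seed(61)
  n <- 20000
  prs <- rnorm(n)
  alpha_true <- 0.8
  y <- rbinom(n, 1, plogis(-1 + alpha_true * prs))
  fit <- fit_modified_prs(list(p = prs), y, split_fraction = 0.5, seed = 2)
  # recovery within 3 standard errors at this n
  se <- sqrt(diag(vcov(glm(y ~ prs, family = binomial(),
                           subset = seq_len(n) %in% fit$fit_idx))))[2]
  expect_lt(abs(fit$alphas[["p"]] - alpha_true), 3 * se)
  expect_equal(fit$beta, 0)  # no outcome PRS supplied
  expect_false(fit$has_outcome_prs)
})

test_that("uninformative scores give chance-level held-out discrimination", {
  set.seed(67)
  n <- 20000
  prs <- rnorm(n)
  y <- rbinom(n, 1, 0.3)  # independent of the score
  fit <- fit_modified_prs(list(p = prs), y, split_fraction = 0.1, seed = 3)
  ev <- fit$eval_idx
  auc <- roc_auc(predict(fit, list(prs[ev])), y[ev])
  expect_equal(auc, 0.5, tolerance = 0.02)
})

test_that("degenerate fitting splits are refused", {
  y <- c(rep(0, 99), 1)
  expect_error(fit_modified_prs(list(p = rnorm(100)), y,
                                split_fraction = 0.02, seed = 4),
               "single class")
})

test_that("the association scan flags perfect signals and monomorphs", {
  set.seed(71)
  n <- 2000
  y <- rbinom(n, 1, 0.5)
  G <- cbind(perfect = 2 * y, mono = rep(1, n),
             null = rbinom(n, 2, 0.3))
  res <- association_scan(G, y, p_threshold = 1e-8)
  expect_true(res$significant[res$variant_id == "perfect"])
  expect_true(res$monomorphic[res$variant_id == "mono"])
  expect_equal(res$p_value[res$variant_id == "mono"], 1)
  expect_false(res$significant[res$variant_id == "null"])
})

test_that("association-scan p-values are uniform under the null", {
  set.seed(73)
  n <- 500
  y <- rbinom(n, 1, 0.4)
  G <- matrix(rbinom(n * 2000, 2, 0.3), n, 2000,
              dimnames = list(NULL, paste0("v", 1:2000)))
  res <- association_scan(G, y)
  # discrete genotype tables duplicate some p-values; the KS tie warning
  # is expected and harmless at this resolution
  expect_gt(suppressWarnings(ks.test(res$p_value, "punif"))$p.value, 0.01)
})

test_that("the conditional-independence test handles degenerate layouts", {
  # outcome constant within every cause stratum
  n <- 400
  cause <- rep(0:1, each = n / 2)
  outcome <- cause  # constant given cause
  variant <- rbinom(n, 2, 0.4)
  res <- conditional_independence_test(variant, cause, outcome)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 0)
  # single cause stratum falls back with a warning
  expect_warning(
    conditional_independence_test(variant, rep(1, n), rbinom(n, 1, 0.5)),
    "one cause stratum")
})

test_that("mediated chains pass and direct effects fail the CI test", {
  set.seed(79)
  n <- 30000
  g <- rbinom(n, 2, 0.3)
  cause <- rbinom(n, 1, plogis(-1 + 0.8 * g))
  mediated_out <- rbinom(n, 1, plogis(-1.5 + 1.5 * cause))
  direct_out <- rbinom(n, 1, plogis(-1.5 + 1.5 * cause + 0.5 * g))
  p_med <- conditional_independence_test(g, cause, mediated_out)$p_value
  p_dir <- conditional_independence_test(g, cause, direct_out)$p_value
  expect_gt(p_med, 0.001)   # should typically not reject
  expect_lt(p_dir, 1e-6)    # strong direct effect must reject
  expect_equal(classify_mediated(c(0.2, 0.01)),
               c("mediated-consistent", "not-independent"))
  # the CMH variant agrees directionally
  p_cmh <- conditional_independence_test(g, cause, direct_out,
                                         method = "cmh")$p_value
  expect_lt(p_cmh, 1e-6)
})

test_that("the panel screen reproduces per-variant tests and verdicts", {
  w <- gen_world(world_config(genetics = list(n_variants = 12,
                                              n_mediated = 6,
                                              n_horizontal = 3)), seed = 83)
  gen <- gen_genetics(w, 4000)
  res <- ci_screen(gen$genotypes, gen$labels$cause, gen$labels$outcome)
  expect_equal(nrow(res), 12L)
  one <- conditional_independence_test(gen$genotypes$dosages[, 5],
                                       gen$labels$cause,
                                       gen$labels$outcome)
  expect_equal(res$p_value[5], one$p_value)
  expect_equal(res$verdict, classify_mediated(res$p_value))
})

test_that("scoring files round-trip through the catalogue format", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  s <- scoring_file(c("rs1", "rs2"), c("1", "2"), c(100L, 200L),
                    c("A", "T"), c("G", "C"), c(0.12, -0.07))
  write_scoring_file(s, tmp, comment = "toy score")
  back <- read_scoring_file(tmp)
  expect_equal(back$variant_id, s$variant_id)
  expect_equal(back$effect_weight, s$effect_weight)
})
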