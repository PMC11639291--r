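#' Configuration for a synthetic ground-truth world
#'
#' Defines the conditions the generator emulates: a planted causal DAG over
#' synthetic disease codes, a literature corpus expressing its edges through
#' the shipped lexical patterns (plus same-category decoys and patternless
#' distractors), a patient population with temporal diagnosis structure, an
#' optional exactly-parameterised confounded treatment/outcome triple, and a
#' genetic architecture with mediated and horizontal pleiotropy.
#'
#' @param n_codes number of synthetic disease codes (default 80).
#' @param n_edges number of planted causal edges (default 200).
#' @param n_individuals population size for patient records (default 10000).
#' @param root_prevalence range of per-root disease prevalences
#'   (default `c(0.05, 0.15)`).
#' @param edge_transmission range of per-edge cause-to-effect transmission
#'   probabilities (default `c(0.3, 0.6)`).
#' @param background_rate baseline prevalence every disease also has
#'   independently of its causes (default 0.01), so contingency tables have
#'   mass in every cell.
#' @param temporal_q probability that, given both endpoint diseases, the
#'   cause's diagnosis year does not exceed the effect's (default 0.9).
#' @param mention_lambda Poisson rate for extra supporting sentences; each
#'   planted relation gets `1 + rpois(mention_lambda)` sentences
#'   (default 0.7, putting the median support at 1).
#' @param decoy_rate same-category decoy sentences as a fraction of planted
#'   sentences (default 0.2).
#' @param distractor_rate patternless co-mention sentences as a fraction of
#'   planted sentences (default 0.3).
#' @param confounder `NULL`, or a list describing an exactly-parameterised
#'   binary confounded triple: `prev_a` (confounder prevalence),
#'   `p_x_given_a` (length-2, treatment probability for A = 0, 1),
#'   `p_y_given_xa` (2x2 matrix, outcome probability indexed
#'   `[X + 1, A + 1]`), and optionally `codes` (length-3 named character
#'   vector `a`, `x`, `y`; defaults `Z80`, `Z81`, `Z82`).
#' @param genetics list of genetic-architecture parameters: `n_variants`
#'   (50), `n_mediated` (30), `n_horizontal` (10), `maf` range
#'   (`c(0.1, 0.5)`), `effect_mediated` (0.3, per-allele log-odds on the
#'   cause), `effect_horizontal_cause` (0.2), `effect_horizontal_outcome`
#'   (0.2, the direct per-allele log-odds on the outcome that makes a
#'   variant horizontally pleiotropic), `gamma` (2.0, log-odds of the cause
#'   disease on the outcome), `cause_intercept` (-1.5), `outcome_intercept`
#'   (-2.2).
#' @return A config list of class `world_config`.
#' @export
world_config <- function(n_codes = 80, n_edges = 200,
                         n_individuals = 10000,
                         root_prevalence = c(0.05, 0.15),
                         edge_transmission = c(0.3, 0.6),
                         background_rate = 0.01,
                         temporal_q = 0.9,
                         mention_lambda = 0.7,
                         decoy_rate = 0.2,
                         distractor_rate = 0.3,
                         confounder = NULL,
                         genetics = list()) {
  gdef <- list(n_variants = 50, n_mediated = 30, n_horizontal = 10,
               maf = c(0.1, 0.5), effect_mediated = 0.3,
               effect_horizontal_cause = 0.2,
               effect_horizontal_outcome = 0.2,
               gamma = 2.0, cause_intercept = -1.5,
               outcome_intercept = -2.2)
  gdef[names(genetics)] <- genetics
  if (gdef$n_mediated + gdef$n_horizontal > gdef$n_variants) {
    abort("more mediated + horizontal variants than variants")
  }
  if (!is.null(confounder)) {
    confounder$codes <- confounder$codes %||%
      c(a = "Z80", x = "Z81", y = "Z82")
    stopifnot(length(confounder$p_x_given_a) == 2,
              is.matrix(confounder$p_y_given_xa),
              all(dim(confounder$p_y_given_xa) == 2))
  }
  probs <- c(root_prevalence, edge_transmission, background_rate,
             temporal_q, decoy_rate, distractor_rate)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  structure(list(n_codes = n_codes, n_edges = n_edges,
                 n_individuals = n_individuals,
                 root_prevalence = root_prevalence,
                 edge_transmission = edge_transmission,
                 background_rate = background_rate,
                 temporal_q = temporal_q,
                 mention_lambda = mention_lambda,
                 decoy_rate = decoy_rate,
                 distractor_rate = distractor_rate,
                 confounder = confounder, genetics = gdef),
            class = "world_config")
}

#' Generate a synthetic ground-truth world
#'
#' Samples the disease codes and the acyclic truth DAG (edges drawn under a
#' random topological order, so acyclicity holds by construction), together
#' with per-root prevalences and per-edge transmission probabilities. All
#' downstream generators ([gen_corpus()], [gen_patients()],
#' [gen_genetics()]) derive their randomness from the world's seed, so a
#' fixed (config, seed) pair reproduces every output exactly.
#'
#' @param config a [world_config()].
#' @param seed integer seed.
#' @return An object of class `synthetic_world` with the codes, the truth
#'   edge table (`cause`, `effect`, `transmission`), root prevalences,
#'   background rates, the config and the seed.
#' @export
gen_world <- function(config = world_config(), seed = 1) {
  stopifnot(inherits(config, "world_config"))
  max_edges <- choose(config$n_codes, 2)
  if (config$n_edges > max_edges) {
    abort("n_edges (%d) exceeds the %d pairs available under a topological order",
          config$n_edges, max_edges)
  }
  with_seed(seed, {
    codes <- gen_codes(config$n_codes,
                       reserved = config$confounder$codes)
    topo <- sample(codes)  # position = topological rank
    pairs <- t(utils::combn(config$n_codes, 2))
    pick <- sample.int(nrow(pairs), config$n_edges)
    edges <- data.frame(
      cause = topo[pairs[pick, 1]], effect = topo[pairs[pick, 2]],
      transmission = stats::runif(config$n_edges,
                                  config$edge_transmission[1],
                                  config$edge_transmission[2]),
      stringsAsFactors = FALSE)
    edges <- edges[order(edges$cause, edges$effect), , drop = FALSE]
    rownames(edges) <- NULL
    structure(list(
      codes = codes,
      truth_edges = edges,
      root_prevalence = stats::setNames(
        stats::runif(config$n_codes, config$root_prevalence[1],
                     config$root_prevalence[2]), codes),
      config = config, seed = seed),
      class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d codes, %d truth edges, seed %s\n",
              length(x$codes), nrow(x$truth_edges), format(x$seed)))
  invisible(x)
}

# unique synthetic ICD-style codes (letter + two digits), avoiding any
# reserved codes (e.g. the confounder triple)
gen_codes <- function(n, reserved = NULL) {
  pool <- as.vector(outer(LETTERS[1:25], sprintf("%02d", 0:99), paste0))
  pool <- setdiff(pool, reserved)
  sort(sample(pool, n))
}

# pronounceable unique pseudoword; used for synthetic disease names
gen_pseudowords <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z", "th", "br", "cl", "st")
  vow <- c("a", "e", "i", "o", "u", "ai", "ou")
  out <- character(0)
  while (length(out) < n) {
    w <- paste0(sample(cons, 1), sample(vow, 1), sample(cons, 1),
                sample(vow, 1), sample(cons, 1), sample(vow, 1), "sis")
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

#' Generate the dictionary and pattern-bearing sentence corpus
#'
#' Every planted truth edge is expressed via a randomly chosen shipped
#' pattern in a planned number of sentences (`1 + rpois(mention_lambda)`).
#' Decoy sentences assert relations between two surface names of the same
#' three-character code (they must be removed by the same-category filter),
#' and distractor sentences co-mention two diseases with no causal cue.
#' Each code receives two single-token pseudoword names, and one code in
#' four also gets a two-word "chronic" alias so longest-match resolution is
#' exercised.
#'
#' @param world a [gen_world()] result.
#' @return A list with `dictionary` (a [disease_dictionary()]), `corpus`
#'   (sentence data frame), and `truth` (data frame `cause`, `effect`,
#'   `n_annot`: the planted relation multiset).
#' @export
gen_corpus <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  cfg <- world$config
  with_seed(world$seed + 1L, {
    codes <- world$codes
    n <- length(codes)
    words <- gen_pseudowords(2 * n)
    name1 <- words[seq_len(n)]
    name2 <- words[n + seq_len(n)]
    alias <- seq_len(n) %% 4 == 0
    dict <- disease_dictionary(
      c(name1, name2, paste("chronic", name1[alias])),
      c(codes, codes, codes[alias]))
    pats <- default_patterns()
    templates <- vapply(pats, `[[`, "", "template")
    templates <- gsub("\\{C\\}", "{CAUSE}", templates)
    templates <- gsub("\\{E\\}", "{EFFECT}", templates)
    pick_name <- function(code) {
      nm <- c(name1[match(code, codes)], name2[match(code, codes)])
      sample(nm, 1)
    }
    sentences <- list()
    emit <- function(text) {
      sentences[[length(sentences) + 1L]] <<- text
    }
    tr <- world$truth_edges
    n_annot <- 1L + stats::rpois(nrow(tr), cfg$mention_lambda)
    for (i in seq_len(nrow(tr))) {
      for (k in seq_len(n_annot[i])) {
        emit(realize_sentence(sample(templates, 1),
                              pick_name(tr$cause[i]),
                              pick_name(tr$effect[i])))
      }
    }
    n_planted <- length(sentences)
    n_decoy <- round(cfg$decoy_rate * n_planted)
    for (k in seq_len(n_decoy)) {
      j <- sample.int(n, 1)
      emit(realize_sentence(sample(templates, 1), name1[j], name2[j]))
    }
    n_distract <- round(cfg$distractor_rate * n_planted)
    neutral <- c("%s and %s were assessed in the cohort.",
                 "Prevalence of %s was compared with %s.",
                 "We measured %s alongside %s at baseline.")
    for (k in seq_len(n_distract)) {
      j <- sample.int(n, 2)
      emit(sprintf(sample(neutral, 1), pick_name(codes[j[1]]),
                   pick_name(codes[j[2]])))
    }
    corpus <- data.frame(
      doc_id = sprintf("d%05d", seq_along(sentences)),
      sent_id = "s1",
      text = unlist(sentences),
      stringsAsFactors = FALSE)
    corpus <- corpus[sample.int(nrow(corpus)), , drop = FALSE]
    rownames(corpus) <- NULL
    list(dictionary = dict, corpus = corpus,
         truth = data.frame(cause = tr$cause, effect = tr$effect,
                            n_annot = n_annot, stringsAsFactors = FALSE))
  })
}

# fill a template, optionally injecting an adverb after a slot when the
# junction is whitespace (the miner tolerates short gaps), and wrap in
# sentence context
realize_sentence <- function(template, cause_name, effect_name) {
  if (grepl("\\{CAUSE\\} ", template) && stats::runif(1) < 0.3) {
    template <- sub("\\{CAUSE\\} ",
                    paste0("{CAUSE} ", sample(c("often", "frequently",
                                                "reportedly"), 1), " "),
                    template)
  }
  body <- sub("{CAUSE}", cause_name, template, fixed = TRUE)
  body <- sub("{EFFECT}", effect_name, body, fixed = TRUE)
  prefix <- sample(c("", "We found that ", "Recent work suggests that ",
                     "In this registry, "), 1)
  suffix <- sample(c(".", " in adults.", " across both cohorts."), 1)
  paste0(prefix, body, suffix)
}

#' Generate patient first-diagnosis records from the truth DAG
#'
#' Root status is drawn from each disease's prevalence; effects propagate
#' along truth edges with the per-edge transmission probability, on top of
#' a small background rate for every disease. Diagnosis years are assigned
#' so that, for a truth edge with both endpoint diseases present, the
#' cause's year does not exceed the effect's with probability `temporal_q`
#' (enforced per parent in topological order, so it is exact for nodes with
#' a single present parent). Ages are uniform on 40-69. When the config
#' carries a confounder block, the triple (A, X, Y) is drawn from its exact
#' conditional tables and the analytic interventional truth is attached.
#'
#' @param world a [gen_world()] result.
#' @param n_individuals optional override of the config population size.
#' @return A [patient_records()] object, with attribute `truth` carrying
#'   generator bookkeeping (per-code case counts and, when a confounder is
#'   configured, `p_do1` / `p_naive1` analytic values).
#' @export
gen_patients <- function(world, n_individuals = NULL) {
  stopifnot(inherits(world, "synthetic_world"))
  cfg <- world$config
  n <- n_individuals %||% cfg$n_individuals
  stopifnot(n >= 1)
  with_seed(world$seed + 2L, {
    codes <- world$codes
    topo <- topo_order(codes, world$truth_edges)
    status <- matrix(FALSE, n, length(codes),
                     dimnames = list(NULL, codes))
    years <- matrix(NA_integer_, n, length(codes),
                    dimnames = list(NULL, codes))
    parents_of <- split(world$truth_edges$cause, world$truth_edges$effect)
    trans_of <- split(world$truth_edges$transmission,
                      world$truth_edges$effect)
    is_effect <- codes %in% world$truth_edges$effect
    for (v in topo) {
      base_p <- if (is_effect[match(v, codes)]) cfg$background_rate
                else world$root_prevalence[[v]]
      present <- stats::runif(n) < base_p
      yr <- sample(1995:2015, n, replace = TRUE)
      ps <- parents_of[[v]]
      if (!is.null(ps)) {
        for (k in seq_along(ps)) {
          u <- ps[k]
          caused <- status[, u] & stats::runif(n) < trans_of[[v]][k]
          present <- present | caused
          both <- status[, u] & present
          if (any(both)) {
            fwd <- stats::runif(n) < cfg$temporal_q
            lag_f <- sample(0:5, n, replace = TRUE)
            lag_b <- sample(1:5, n, replace = TRUE)
            yr[both & fwd] <- years[both & fwd, u] + lag_f[both & fwd]
            yr[both & !fwd] <- years[both & !fwd, u] - lag_b[both & !fwd]
          }
        }
      }
      status[, v] <- present
      years[present, v] <- pmin(pmax(yr[present], 1900L), 2100L)
    }
    ids <- sprintf("ind%06d", seq_len(n))
    demo <- data.frame(individual_id = ids,
                       age = sample(40:69, n, replace = TRUE),
                       sex = sample(c("F", "M"), n, replace = TRUE),
                       stringsAsFactors = FALSE)
    truth <- list(case_counts = colSums(status))
    if (!is.null(cfg$confounder)) {
      cf <- cfg$confounder
      a <- stats::runif(n) < cf$prev_a
      x <- stats::runif(n) < cf$p_x_given_a[a + 1L]
      y <- stats::runif(n) < cf$p_y_given_xa[cbind(x + 1L, a + 1L)]
      status <- cbind(status,
                      matrix(c(a, x, y), n, 3,
                             dimnames = list(NULL, unname(cf$codes))))
      yr3 <- matrix(2005L, n, 3, dimnames = list(NULL, unname(cf$codes)))
      yr3[!cbind(a, x, y)] <- NA_integer_
      years <- cbind(years, yr3)
      pa <- c(1 - cf$prev_a, cf$prev_a)
      truth$p_do1 <- sum(pa * cf$p_y_given_xa[2, ])
      # analytic naive conditional: weights P(A = a | X = 1)
      pa_x1 <- pa * cf$p_x_given_a / sum(pa * cf$p_x_given_a)
      truth$p_naive1 <- sum(pa_x1 * cf$p_y_given_xa[2, ])
      truth$confounder <- cf
    }
    idx <- which(status, arr.ind = TRUE)
    diagnoses <- data.frame(
      individual_id = ids[idx[, 1]],
      code = colnames(status)[idx[, 2]],
      year = years[idx],
      stringsAsFactors = FALSE)
    rec <- patient_records(diagnoses, demo)
    attr(rec, "truth") <- truth
    rec
  })
}

# topological order of the truth DAG (roots first)
topo_order <- function(codes, edges) {
  g <- igraph::graph_from_data_frame(
    edges[, c("cause", "effect"), drop = FALSE],
    directed = TRUE, vertices = codes)
  names(igraph::topo_sort(g, mode = "out"))
}

#' Generate genotypes, scoring files and disease labels
#'
#' Draws Hardy-Weinberg genotypes at per-variant allele frequencies and
#' simulates a causative disease and an outcome disease from liability
#' (logistic) models: mediated variants carry weight only on the cause,
#' horizontal variants on both, null variants on neither, and the cause
#' feeds the outcome's liability with log-odds `gamma`. The returned
#' scoring files contain each disease's true effect variants with their
#' generating weights.
#'
#' @param world a [gen_world()] result.
#' @param n_individuals optional override of the config population size.
#' @return A list with `genotypes` (a [genotype_matrix()]), `scoring`
#'   (list of [scoring_file()]s: `cause`, `outcome`), `labels` (list of
#'   binary vectors: `cause`, `outcome`) and `truth` (roles, weights,
#'   allele frequencies and model parameters).
#' @export
gen_genetics <- function(world, n_individuals = NULL) {
  stopifnot(inherits(world, "synthetic_world"))
  g <- world$config$genetics
  n <- n_individuals %||% world$config$n_individuals
  with_seed(world$seed + 3L, {
    m <- g$n_variants
    ids <- sprintf("rs%05d", seq_len(m))
    maf <- stats::runif(m, g$maf[1], g$maf[2])
    G <- vapply(maf, function(p) stats::rbinom(n, 2, p), numeric(n))
    colnames(G) <- ids
    roles <- rep("null", m)
    roles[seq_len(g$n_mediated)] <- "mediated"
    roles[g$n_mediated + seq_len(g$n_horizontal)] <- "horizontal"
    b_cause <- ifelse(roles == "mediated", g$effect_mediated,
                      ifelse(roles == "horizontal",
                             g$effect_horizontal_cause, 0))
    b_outcome <- ifelse(roles == "horizontal",
                        g$effect_horizontal_outcome, 0)
    # centred genetic contributions, so the intercepts set the baseline
    # disease prevalences regardless of allele frequencies
    eta_c <- g$cause_intercept + drop(G %*% b_cause) -
      sum(2 * maf * b_cause)
    cause <- as.integer(stats::runif(n) < stats::plogis(eta_c))
    eta_o <- g$outcome_intercept + g$gamma * cause + drop(G %*% b_outcome) -
      sum(2 * maf * b_outcome)
    outcome <- as.integer(stats::runif(n) < stats::plogis(eta_o))
    # unambiguous allele pairs only, so harmonization keeps every variant
    pairs <- rbind(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"))
    al <- pairs[sample.int(4, m, replace = TRUE), , drop = FALSE]
    meta <- data.frame(variant_id = ids, allele1 = al[, 1],
                       allele2 = al[, 2], info = 1,
                       stringsAsFactors = FALSE)
    sc <- function(keep, w) {
      scoring_file(ids[keep], chromosome = rep("1", sum(keep)),
                   position = 1000L * which(keep),
                   effect_allele = al[keep, 1], other_allele = al[keep, 2],
                   effect_weight = w[keep])
    }
    list(genotypes = genotype_matrix(G, meta),
         scoring = list(cause = sc(b_cause != 0, b_cause),
                        outcome = sc(b_outcome != 0, b_outcome)),
         labels = list(cause = cause, outcome = outcome),
         truth = list(roles = roles, b_cause = b_cause,
                      b_outcome = b_outcome, maf = maf,
                      gamma = g$gamma,
                      cause_intercept = g$cause_intercept,
                      outcome_intercept = g$outcome_intercept))
  })
}

#' Write every synthetic input to a directory
#'
#' Materialises a world as the files the pipeline consumes:
#' `dictionary.tsv`, `corpus.jsonl`, `records.tsv`, `demographics.tsv`,
#' `genotypes.tsv`, `variants.tsv`, `scoring/<disease>.tsv` and
#' `truth/truth.json`.
#'
#' @param world a [gen_world()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  corp <- gen_corpus(world)
  write_dictionary(corp$dictionary, file.path(dir, "dictionary.tsv"))
  write_corpus(corp$corpus, file.path(dir, "corpus.jsonl"))
  rec <- gen_patients(world)
  write_records(rec, file.path(dir, "records.tsv"),
                file.path(dir, "demographics.tsv"))
  gen <- gen_genetics(world)
  utils::write.table(gen$genotypes$dosages, file.path(dir, "genotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gen$genotypes$variants, file.path(dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dir.create(file.path(dir, "scoring"), showWarnings = FALSE)
  for (nm in names(gen$scoring)) {
    write_scoring_file(gen$scoring[[nm]],
                       file.path(dir, "scoring", paste0(nm, ".tsv")),
                       comment = sprintf("synthetic %s scoring file", nm))
  }
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  jsonlite::write_json(
    list(truth_edges = world$truth_edges,
         relation_multiset = corp$truth,
         patient_truth = attr(rec, "truth"),
         genetic_truth = gen$truth,
         seed = world$seed),
    file.path(dir, "truth", "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
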