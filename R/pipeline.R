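#' Run the full mine-score-DAG-applications pipeline
#'
#' Orchestrates an end-to-end run on a synthetic world: (1) `simulate`
#' writes every input file; (2) `mine` extracts relations from the corpus;
#' (3) `score` computes the five evidence measures and the combined score;
#' (4) `dag` builds the acyclic graph; (5) `causal` answers the configured
#' backdoor query; (6) `genetics` computes PRSs, fits the modified PRS and
#' runs the conditional-independence screen. Each stage records its
#' parameters, output files and their MD5 checksums in a JSON manifest, so
#' a rerun with the same config and seed reproduces identical outputs. A
#' failing stage aborts the run with the stage named and leaves a
#' `.partial` marker in the output directory.
#'
#' @param config a named list, or the path to a YAML file with the same
#'   structure. Recognised entries: `seed` (integer), `out_dir` (output
#'   directory), `simulate` (arguments for [world_config()]), `score`
#'   (`alpha`, `judge` = `"truth"`/`"none"`/`"replay"`, `replay_path`),
#'   `causal` (`treatment`, `outcome`, `adjustment`; defaults to the
#'   configured confounder triple when one exists), `genetics`
#'   (`split_fraction`, `info_threshold`, `ci_cutoff`, `gwas_threshold`).
#' @return The run manifest (a list), invisibly; it is also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is_string(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% abort("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  partial <- file.path(out_dir, ".partial")
  file.create(partial)
  manifest <- list(seed = seed, stages = list())
  record <- function(stage, params, files) {
    files <- files[file.exists(files)]
    manifest$stages[[stage]] <<- list(
      stage = stage, params = params,
      outputs = as.list(tools::md5sum(files)))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort("pipeline stage '%s' failed: %s (partial outputs kept in %s)",
            stage, conditionMessage(e), out_dir)
    })
  }
  sim_args <- config$simulate %||% list()
  world <- run_stage("simulate", {
    w <- gen_world(do.call(world_config, sim_args), seed = seed)
    write_world(w, out_dir)
    record("simulate", c(sim_args, list(seed = seed)),
           file.path(out_dir, c("dictionary.tsv", "corpus.jsonl",
                                "records.tsv", "demographics.tsv",
                                "genotypes.tsv", "variants.tsv",
                                "truth/truth.json")))
    w
  })
  mined <- run_stage("mine", {
    dict <- read_dictionary(file.path(out_dir, "dictionary.tsv"))
    corpus <- read_corpus(file.path(out_dir, "corpus.jsonl"))
    res <- mine_corpus(corpus, dict)
    write_relations(res$relations, file.path(out_dir, "relations.tsv"))
    record("mine", list(n_patterns = length(default_patterns())),
           file.path(out_dir, "relations.tsv"))
    res$dictionary <- dict
    res
  })
  scored <- run_stage("score", {
    sc_cfg <- config$score %||% list()
    rec <- read_records(file.path(out_dir, "records.tsv"),
                        file.path(out_dir, "demographics.tsv"))
    judge <- pipeline_judge(sc_cfg$judge %||% "truth", world,
                            mined$dictionary, sc_cfg$replay_path)
    edges <- score_relations(mined$relations, rec, judge = judge,
                             dictionary = mined$dictionary,
                             alpha = sc_cfg$alpha %||% 0.05)
    write_scored_edges(edges, file.path(out_dir, "scored_edges.tsv"))
    record("score", list(alpha = sc_cfg$alpha %||% 0.05,
                         judge = sc_cfg$judge %||% "truth"),
           file.path(out_dir, "scored_edges.tsv"))
    edges
  })
  dag <- run_stage("dag", {
    d <- build_dag(relation_graph(scored))
    write_dag(d, file.path(out_dir, "dag_edges.tsv"),
              file.path(out_dir, "dag_removed.tsv"))
    write_dot(d, file.path(out_dir, "dag.dot"))
    record("dag", list(n_kept = nrow(d$edges), n_removed = nrow(d$removed)),
           file.path(out_dir, c("dag_edges.tsv", "dag_removed.tsv",
                                "dag.dot")))
    d
  })
  run_stage("causal", {
    ca <- config$causal %||% list()
    cf <- world$config$confounder
    treatment <- ca$treatment %||% unname(cf$codes["x"])
    outcome <- ca$outcome %||% unname(cf$codes["y"])
    adjustment <- ca$adjustment %||%
      (if (!is.null(cf)) unname(cf$codes["a"]) else character(0))
    if (is.null(treatment) || is.null(outcome)) {
      res <- list(skipped = "no causal query configured")
    } else {
      rec <- read_records(file.path(out_dir, "records.tsv"),
                          file.path(out_dir, "demographics.tsv"))
      adj <- backdoor_adjust(rec, treatment, outcome, adjustment)
      res <- list(treatment = treatment, outcome = outcome,
                  adjustment = as.list(adjustment),
                  estimate = adj$estimate, n_treated = adj$n_treated,
                  uncovered_mass = adj$uncovered_mass,
                  naive = naive_conditional(rec, treatment, outcome))
    }
    jsonlite::write_json(res, file.path(out_dir, "causal_query.json"),
                         auto_unbox = TRUE, digits = NA)
    record("causal", res["adjustment"],
           file.path(out_dir, "causal_query.json"))
  })
  run_stage("genetics", {
    ge <- config$genetics %||% list()
    gen <- gen_genetics(world)
    harm_c <- harmonize_variants(gen$scoring$cause, gen$genotypes,
                                 ge$info_threshold %||% 0.3)
    harm_o <- harmonize_variants(gen$scoring$outcome, gen$genotypes,
                                 ge$info_threshold %||% 0.3)
    prs_c <- compute_prs(harm_c)
    prs_o <- compute_prs(harm_o)
    fit <- fit_modified_prs(list(cause = prs_c), gen$labels$outcome,
                            prs_outcome = prs_o,
                            split_fraction = ge$split_fraction %||% 0.10,
                            seed = seed + 10L)
    ev <- fit$eval_idx
    combined <- predict(fit, list(cause = prs_c[ev]), prs_o[ev])
    scan <- association_scan(gen$genotypes, gen$labels$outcome,
                             ge$gwas_threshold %||% 1e-8)
    ci <- ci_screen(gen$genotypes, gen$labels$cause, gen$labels$outcome,
                    cutoff = ge$ci_cutoff %||% 0.05)
    write_modified_prs(fit, file.path(out_dir, "modified_prs.json"))
    utils::write.table(ci, file.path(out_dir, "ci_screen.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(scan, file.path(out_dir, "association_scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    record("genetics",
           list(auc_outcome_prs = roc_auc(prs_o[ev], gen$labels$outcome[ev]),
                auc_modified = roc_auc(combined, gen$labels$outcome[ev]),
                n_mediated_consistent =
                  sum(ci$verdict == "mediated-consistent")),
           file.path(out_dir, c("modified_prs.json", "ci_screen.tsv",
                                "association_scan.tsv")))
  })
  manifest$config <- config
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unlink(partial)
  invisible(manifest)
}

# judge used in pipeline runs: a stub confirming the world's truth edges
# (emulating an accurate background-knowledge source), the all-"No"
# default stub, or a transcript replayer
pipeline_judge <- function(kind, world, dictionary, replay_path = NULL) {
  if (identical(kind, "none")) return(llm_judge_stub())
  if (identical(kind, "replay")) {
    if (is.null(replay_path)) abort("judge 'replay' needs replay_path")
    return(llm_judge_replay(replay_path))
  }
  tr <- world$truth_edges
  keys <- paste0(vapply(tr$cause, code_name, "", dictionary = dictionary),
                 "|",
                 vapply(tr$effect, code_name, "", dictionary = dictionary))
  llm_judge_stub(stats::setNames(rep("Yes", nrow(tr)), keys))
}
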