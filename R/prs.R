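#' Polygenic scoring files
#'
#' A scoring file lists variants with the allele whose dosage is counted
#' (effect allele), the other allele, and the per-allele effect weight, in
#' the layout used by public score catalogues.
#'
#' @param variant_id,chromosome,position,effect_allele,other_allele,effect_weight
#'   column vectors of equal length.
#' @return A data frame of class `scoring_file`.
#' @export
scoring_file <- function(variant_id, chromosome, position, effect_allele,
                         other_allele, effect_weight) {
  effect_allele <- toupper(effect_allele)
  other_allele <- toupper(other_allele)
  ok <- effect_allele %in% c("A", "C", "G", "T") &
    other_allele %in% c("A", "C", "G", "T")
  if (!all(ok)) abort("alleles must be single bases A/C/G/T")
  if (any(!is.finite(effect_weight))) abort("effect weights must be finite")
  structure(data.frame(
    variant_id = as.character(variant_id),
    chromosome = as.character(chromosome),
    position = as.integer(position),
    effect_allele = effect_allele, other_allele = other_allele,
    effect_weight = as.numeric(effect_weight),
    stringsAsFactors = FALSE), class = c("scoring_file", "data.frame"))
}

#' Read a catalogue-style scoring file
#'
#' TSV with `#`-prefixed header comments and columns `rsID`, `chr_name`,
#' `chr_position`, `effect_allele`, `other_allele`, `effect_weight`.
#'
#' @param path path to the scoring TSV.
#' @return A [scoring_file()] data frame.
#' @export
read_scoring_file <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                         comment.char = "#", stringsAsFactors = FALSE)
  need <- c("rsID", "chr_name", "chr_position", "effect_allele",
            "other_allele", "effect_weight")
  if (!all(need %in% names(d))) {
    abort("scoring file missing columns: %s",
          paste(setdiff(need, names(d)), collapse = ", "))
  }
  scoring_file(d$rsID, d$chr_name, d$chr_position, d$effect_allele,
               d$other_allele, d$effect_weight)
}

#' Write a scoring file to TSV
#' @param scoring a [scoring_file()].
#' @param path output path.
#' @param comment optional header comment lines (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_scoring_file <- function(scoring, path, comment = NULL) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  out <- data.frame(rsID = scoring$variant_id,
                    chr_name = scoring$chromosome,
                    chr_position = scoring$position,
                    effect_allele = scoring$effect_allele,
                    other_allele = scoring$other_allele,
                    effect_weight = scoring$effect_weight)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genotype dosage matrix with variant metadata
#'
#' @param dosages numeric matrix, individuals in rows and variants in
#'   columns (unique column names = variant ids); entries are effect-allele
#'   dosages in \eqn{[0, 2]} (fractional for imputed data), `NA` for missing.
#' @param variants data frame with one row per column of `dosages`:
#'   `variant_id`, `allele1` (the allele the dosage counts), `allele2`, and
#'   `info` (imputation quality in \eqn{[0, 1]}; 1 for directly typed).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants) {
  stopifnot(is.matrix(dosages), is.numeric(dosages),
            is.data.frame(variants),
            all(c("variant_id", "allele1", "allele2", "info") %in%
                  names(variants)),
            nrow(variants) == ncol(dosages))
  if (is.null(colnames(dosages))) colnames(dosages) <- variants$variant_id
  if (anyDuplicated(colnames(dosages))) abort("duplicate variant columns")
  if (!identical(colnames(dosages), as.character(variants$variant_id))) {
    abort("dosage column names must match variants$variant_id in order")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    abort("dosages must lie in [0, 2]")
  }
  variants$allele1 <- toupper(variants$allele1)
  variants$allele2 <- toupper(variants$allele2)
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

is_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize a scoring file against a genotype matrix
#'
#' Aligns scoring-file weights with genotype dosages: duplicated variant
#' ids beyond their first occurrence are dropped, strand-ambiguous (A/T or
#' C/G) variants are excluded, variants below the imputation-quality
#' threshold are excluded, and when the scoring effect allele equals the
#' genotype's other allele the dosage is flipped to \eqn{2 - G}. Variants
#' whose alleles cannot be reconciled, or that are absent from the
#' genotypes, are excluded with a reason.
#'
#' @param scoring a [scoring_file()].
#' @param genotypes a [genotype_matrix()].
#' @param info_threshold minimum imputation quality (default 0.3).
#' @return A list with `weights` (named numeric vector), `dosages`
#'   (aligned, flips applied), and `exclusions`
#'   (data frame `variant_id`, `reason`).
#' @export
harmonize_variants <- function(scoring, genotypes, info_threshold = 0.3) {
  stopifnot(inherits(scoring, "scoring_file"),
            inherits(genotypes, "genotype_matrix"))
  excl <- list()
  drop <- function(ids, reason) {
    if (length(ids)) {
      excl[[length(excl) + 1L]] <<- data.frame(
        variant_id = ids, reason = reason, stringsAsFactors = FALSE)
    }
  }
  s <- scoring
  dup <- duplicated(s$variant_id)
  drop(s$variant_id[dup], "duplicate")
  s <- s[!dup, , drop = FALSE]
  amb <- is_ambiguous(s$effect_allele, s$other_allele)
  drop(s$variant_id[amb], "ambiguous")
  s <- s[!amb, , drop = FALSE]
  meta <- genotypes$variants
  present <- s$variant_id %in% meta$variant_id
  drop(s$variant_id[!present], "not_in_genotypes")
  s <- s[present, , drop = FALSE]
  m <- meta[match(s$variant_id, meta$variant_id), , drop = FALSE]
  low <- m$info < info_threshold
  drop(s$variant_id[low], "low_imputation_quality")
  s <- s[!low, , drop = FALSE]; m <- m[!low, , drop = FALSE]
  same <- s$effect_allele == m$allele1 & s$other_allele == m$allele2
  flip <- s$effect_allele == m$allele2 & s$other_allele == m$allele1
  mismatch <- !(same | flip)
  drop(s$variant_id[mismatch], "allele_mismatch")
  s <- s[!mismatch, , drop = FALSE]
  flip <- flip[!mismatch]
  if (!nrow(s)) abort("no variants overlap between scoring file and genotypes")
  G <- genotypes$dosages[, s$variant_id, drop = FALSE]
  if (any(flip)) G[, flip] <- 2 - G[, flip, drop = FALSE]
  exclusions <- if (length(excl)) do.call(rbind, excl) else {
    data.frame(variant_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  list(weights = stats::setNames(s$effect_weight, s$variant_id),
       dosages = G, exclusions = exclusions)
}

#' Compute polygenic risk scores
#'
#' The weighted dosage sum \eqn{PRS = \sum_i w_i G_i} per individual.
#' Missing dosages are mean-imputed per variant (twice the observed
#' effect-allele frequency) before summation.
#'
#' @param harmonized output of [harmonize_variants()], or a list with
#'   `weights` (named numeric) and `dosages` (matrix with matching columns).
#' @return Named numeric vector of scores, one per individual.
#' @export
compute_prs <- function(harmonized) {
  w <- harmonized$weights
  G <- harmonized$dosages
  stopifnot(is.numeric(w), is.matrix(G),
            identical(names(w), colnames(G)))
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    for (j in which(colSums(is.na(G)) > 0)) {
      G[is.na(G[, j]), j] <- mu[j]
    }
  }
  drop(G %*% w)
}

#' ROC AUC by rank-sum
#'
#' The probability that a randomly chosen case outranks a randomly chosen
#' control, with ties counting one half — the Mann-Whitney form of the area
#' under the ROC curve.
#'
#' @param scores numeric risk scores.
#' @param labels binary case/control labels (0/1 or logical).
#' @return AUC in \eqn{[0, 1]}.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit a multi-parent modified polygenic risk score
#'
#' Combines the PRSs of an outcome disease's DAG parents with (optionally)
#' the outcome's own PRS via logistic regression,
#' \deqn{ModifiedPRS_Y = \sum_i \alpha_i PRS_{Pa(Y)_i} + \beta PRS_Y,}
#' with the coefficients fitted by maximum likelihood on a seeded random
#' `split_fraction` of the samples; the remainder is reserved for
#' evaluation. When `prs_outcome` is `NULL` the model runs in the
#' no-base-PRS mode with \eqn{\beta} fixed at 0, covering outcomes with no
#' available score of their own.
#'
#' @param prs_parents named list (or matrix with named columns) of parent
#'   PRS vectors; at least one unless `prs_outcome` is given.
#' @param labels binary outcome status per individual.
#' @param prs_outcome the outcome's own PRS vector, or `NULL` for the
#'   beta = 0 mode.
#' @param split_fraction fraction of samples used for coefficient fitting
#'   (default 0.10).
#' @param seed integer seed for the random split.
#' @return An object of class `modified_prs` with elements `alphas`,
#'   `beta`, `intercept`, `parent_names`, `fit_idx`, `eval_idx`, `seed`,
#'   and `split_fraction`.
#' @export
fit_modified_prs <- function(prs_parents, labels, prs_outcome = NULL,
                             split_fraction = 0.10, seed = NULL) {
  if (is.matrix(prs_parents)) {
    prs_parents <- as.list(as.data.frame(prs_parents))
  }
  stopifnot(is.list(prs_parents),
            split_fraction > 0, split_fraction < 1)
  if (!length(prs_parents) && is.null(prs_outcome)) {
    abort("need at least one parent PRS or an outcome PRS")
  }
  labels <- as.integer(labels)
  n <- length(labels)
  stopifnot(all(labels %in% 0:1),
            all(vapply(prs_parents, length, 0L) == n),
            is.null(prs_outcome) || length(prs_outcome) == n)
  pn <- names(prs_parents) %||% paste0("parent", seq_along(prs_parents))
  X <- do.call(cbind, prs_parents)
  colnames(X) <- pn
  if (!is.null(prs_outcome)) X <- cbind(X, .outcome = prs_outcome)
  fit_idx <- with_seed(seed, sort(sample.int(n, max(2, round(split_fraction * n)))))
  eval_idx <- setdiff(seq_len(n), fit_idx)
  if (length(unique(labels[fit_idx])) < 2) {
    abort("fitting split contains a single class; enlarge the split or reseed")
  }
  df <- data.frame(y = labels[fit_idx], X[fit_idx, , drop = FALSE])
  fit <- stats::glm(y ~ ., family = stats::binomial(), data = df)
  co <- stats::coef(fit)
  co[is.na(co)] <- 0
  structure(list(
    alphas = stats::setNames(co[make.names(pn)], pn),
    beta = if (is.null(prs_outcome)) 0 else unname(co[".outcome"]),
    intercept = unname(co["(Intercept)"]),
    parent_names = pn,
    has_outcome_prs = !is.null(prs_outcome),
    fit_idx = fit_idx, eval_idx = eval_idx,
    seed = seed, split_fraction = split_fraction),
    class = "modified_prs")
}

#' Combined risk score from a fitted modified PRS
#'
#' @param object a fitted `modified_prs`.
#' @param prs_parents named list (or matrix) of parent PRS vectors in the
#'   order used at fitting.
#' @param prs_outcome outcome PRS vector (required iff the model was fitted
#'   with one).
#' @param ... unused.
#' @return Numeric vector of linear risk scores
#'   (intercept + sum alpha_i PRS_i + beta PRS_Y).
#' @export
predict.modified_prs <- function(object, prs_parents, prs_outcome = NULL,
                                 ...) {
  if (is.matrix(prs_parents)) {
    prs_parents <- as.list(as.data.frame(prs_parents))
  }
  stopifnot(length(prs_parents) == length(object$parent_names))
  if (object$has_outcome_prs && is.null(prs_outcome)) {
    abort("model was fitted with an outcome PRS; supply prs_outcome")
  }
  s <- object$intercept
  for (i in seq_along(prs_parents)) {
    s <- s + object$alphas[[i]] * prs_parents[[i]]
  }
  if (object$has_outcome_prs) s <- s + object$beta * prs_outcome
  unname(s)
}

#' @export
print.modified_prs <- function(x, ...) {
  cat(sprintf("<modified_prs> %d parent scores%s; fitted on %d samples (%.0f%% split)\n",
              length(x$alphas),
              if (x$has_outcome_prs) " + outcome PRS" else " (beta = 0 mode)",
              length(x$fit_idx), 100 * x$split_fraction))
  print(round(c(x$alphas, beta = x$beta, intercept = x$intercept), 4))
  invisible(x)
}

#' Serialize a fitted modified PRS to JSON
#' @param object a `modified_prs`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_modified_prs <- function(object, path) {
  stopifnot(inherits(object, "modified_prs"))
  jsonlite::write_json(list(
    alphas = as.list(object$alphas), beta = object$beta,
    intercept = object$intercept, parent_names = object$parent_names,
    has_outcome_prs = object$has_outcome_prs,
    split_fraction = object$split_fraction, seed = object$seed,
    n_fit = length(object$fit_idx), n_eval = length(object$eval_idx)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
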