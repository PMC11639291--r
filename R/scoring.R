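#' 2x2 disease contingency table
#'
#' Counts individuals by joint status of a putative cause `x` and outcome
#' `y` over everyone in the demographics table; individuals without
#' diagnosis rows count as having neither disease. An unknown code simply
#' yields zero counts on its margin.
#'
#' @param records a [patient_records()] object.
#' @param x,y three-character disease codes.
#' @return A named list of class `contingency_2x2` with counts `n11`
#'   (both), `n10` (x only), `n01` (y only), `n00` (neither) and total `n`.
#' @export
contingency_table <- function(records, x, y) {
  stopifnot(inherits(records, "patient_records"),
            is_string(x), is_string(y))
  hx <- disease_status(records, truncate_code(x))
  hy <- disease_status(records, truncate_code(y))
  tab <- list(n11 = sum(hx & hy), n10 = sum(hx & !hy),
              n01 = sum(!hx & hy), n00 = sum(!hx & !hy))
  tab$n <- tab$n11 + tab$n10 + tab$n01 + tab$n00
  structure(tab, class = "contingency_2x2")
}

#' Construct a contingency table from raw counts
#' @param n11,n10,n01,n00 non-negative counts: both, x-only, y-only, neither.
#' @return A `contingency_2x2` object.
#' @export
contingency_2x2 <- function(n11, n10, n01, n00) {
  counts <- c(n11, n10, n01, n00)
  stopifnot(length(counts) == 4, all(counts >= 0), all(is.finite(counts)))
  structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                 n = sum(counts)),
            class = "contingency_2x2")
}

#' Phi coefficient of a 2x2 table
#'
#' The Pearson correlation of the two binary disease indicators:
#' \deqn{\phi = (n_{11} n_{00} - n_{10} n_{01}) /
#'   \sqrt{n_{1\cdot} n_{0\cdot} n_{\cdot 1} n_{\cdot 0}}}
#' When either disease has no cases or no non-cases (any zero margin) the
#' coefficient is undefined and set to 0.
#'
#' @param table a `contingency_2x2` object (or list with the four counts).
#' @return Phi in \eqn{[-1, 1]}.
#' @export
phi_coefficient <- function(table) {
  # double arithmetic: the margin product overflows integer range easily
  n11 <- as.numeric(table$n11); n10 <- as.numeric(table$n10)
  n01 <- as.numeric(table$n01); n00 <- as.numeric(table$n00)
  m1x <- n11 + n10; m0x <- n01 + n00  # x margins
  mx1 <- n11 + n01; mx0 <- n10 + n00  # y margins
  if (m1x == 0 || m0x == 0 || mx1 == 0 || mx0 == 0) return(0)
  (n11 * n00 - n10 * n01) / sqrt(m1x * m0x * mx1 * mx0)
}

# expected counts under independence; NULL when the total is zero
expected_counts <- function(table) {
  n <- table$n
  if (n == 0) return(NULL)
  rx <- c(table$n11 + table$n10, table$n01 + table$n00)
  cy <- c(table$n11 + table$n01, table$n10 + table$n00)
  outer(rx, cy) / n
}

#' Chi-square dependence screen with Benjamini-Hochberg control
#'
#' Runs a Pearson chi-square test of independence (no continuity
#' correction) on each relation's 2x2 table and adjusts the p-values
#' jointly across all testable relations by the Benjamini-Hochberg
#' procedure. A table is testable only when all four expected counts are at
#' least 5; untestable relations are flagged and never significant.
#'
#' @param tables named list of `contingency_2x2` tables, one per relation.
#' @param alpha significance threshold for the adjusted p-values
#'   (default 0.05).
#' @return Data frame (row per relation, in input order) with columns
#'   `relation`, `testable`, `p_value`, `p_adj` and `dep` (1 iff testable
#'   and adjusted p below `alpha`).
#' @export
dependence_screen <- function(tables, alpha = 0.05) {
  stopifnot(is.list(tables), length(tables) >= 1,
            is.numeric(alpha), alpha > 0, alpha < 1)
  nm <- names(tables) %||% as.character(seq_along(tables))
  testable <- vapply(tables, function(tb) {
    e <- expected_counts(tb)
    !is.null(e) && all(e >= 5)
  }, TRUE)
  p <- rep(NA_real_, length(tables))
  for (i in which(testable)) {
    tb <- tables[[i]]
    m <- matrix(c(tb$n11, tb$n10, tb$n01, tb$n00), 2, 2)
    p[i] <- suppressWarnings(
      stats::chisq.test(m, correct = FALSE)$p.value)
  }
  p_adj <- rep(NA_real_, length(tables))
  p_adj[testable] <- stats::p.adjust(p[testable], method = "BH")
  data.frame(relation = nm, testable = unname(testable),
             p_value = unname(p), p_adj = unname(p_adj),
             dep = as.integer(!is.na(p_adj) & p_adj < alpha),
             stringsAsFactors = FALSE)
}

#' Temporal correspondence of diagnosis years
#'
#' Among the N individuals diagnosed with both the cause `x` and the
#' outcome `y`, the fraction whose first diagnosis of `x` falls in the same
#' or an earlier calendar year than their first diagnosis of `y`
#' (ties count towards the cause-first direction). Returns 0 when no
#' individual exhibits both diseases.
#'
#' @param records a [patient_records()] object.
#' @param x,y cause and outcome disease codes.
#' @return A value in \eqn{[0, 1]}.
#' @export
ddate <- function(records, x, y) {
  stopifnot(inherits(records, "patient_records"))
  dg <- records$diagnoses
  x <- truncate_code(x); y <- truncate_code(y)
  dx <- dg[dg$code == x, c("individual_id", "year")]
  dy <- dg[dg$code == y, c("individual_id", "year")]
  both <- merge(dx, dy, by = "individual_id", suffixes = c("_x", "_y"))
  if (nrow(both) == 0) return(0)
  mean(both$year_x <= both$year_y)
}

#' Binarize annotation support against the corpus-wide median
#'
#' A relation's annotation measure is 1 iff the number of supporting
#' sentences strictly exceeds the median support over all relations in the
#' run (in the mined literature corpus this median is 1, so the measure
#' marks relations supported by more than one mention).
#'
#' @param counts named integer vector of `n_annot` per relation.
#' @return Named integer vector of 0/1 in the same order.
#' @export
binarize_nannot <- function(counts) {
  stopifnot(is.numeric(counts), length(counts) >= 1)
  med <- stats::median(counts)
  stats::setNames(as.integer(counts > med), names(counts))
}

#' Combined evidence score for a relation
#'
#' The equal-weight mean of the five measures,
#' \deqn{score = (\phi + dep + Ddate + nannot + GPT)/5,}
#' interpreted as a confidence in the causal relation and lying in
#' \eqn{[0, 1]}. A negative phi is clamped to 0 inside the combination (the
#' raw coefficient is kept in the measure vector) so the stated range holds.
#'
#' @param phi phi coefficient in \eqn{[-1, 1]}.
#' @param dep dependence indicator, 0 or 1.
#' @param ddate temporal correspondence in \eqn{[0, 1]}.
#' @param nannot_bin annotation-support indicator, 0 or 1.
#' @param gpt judge-confirmation indicator, 0 or 1.
#' @return Score in \eqn{[0, 1]}. Vectorised over its arguments.
#' @export
combined_score <- function(phi, dep, ddate, nannot_bin, gpt) {
  stopifnot(all(phi >= -1 & phi <= 1), all(dep %in% 0:1),
            all(ddate >= 0 & ddate <= 1), all(nannot_bin %in% 0:1),
            all(gpt %in% 0:1))
  (pmax(phi, 0) + dep + ddate + nannot_bin + gpt) / 5
}

#' Score mined relations with the five evidence measures
#'
#' For every relation computes phi, the BH-screened dependence indicator,
#' the diagnosis-year correspondence, the binarized annotation support and
#' the judge confirmation, and combines them into the equal-weight score.
#'
#' @param relations relation table with columns `cause`, `effect`,
#'   `n_annot` (from [mine_corpus()]).
#' @param records a [patient_records()] object.
#' @param judge an [llm_judge_stub()]/[llm_judge_replay()] judge, or `NULL`
#'   to set the judge measure to 0 for all relations.
#' @param dictionary optional [disease_dictionary()] used to phrase judge
#'   queries with a surface name per code; codes are used verbatim when
#'   absent.
#' @param alpha dependence-screen threshold (default 0.05).
#' @return Data frame of scored edges: `cause`, `effect`, `phi`, `dep`,
#'   `testable`, `p_adj`, `ddate`, `n_annot`, `nannot_bin`, `gpt`, `score`,
#'   sorted by descending score then (cause, effect).
#' @export
score_relations <- function(relations, records, judge = NULL,
                            dictionary = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(relations),
            all(c("cause", "effect", "n_annot") %in% names(relations)),
            inherits(records, "patient_records"))
  n <- nrow(relations)
  if (n == 0) abort("no relations to score")
  tables <- lapply(seq_len(n), function(i) {
    contingency_table(records, relations$cause[i], relations$effect[i])
  })
  names(tables) <- paste0(relations$cause, "->", relations$effect)
  phi <- vapply(tables, phi_coefficient, 0)
  dep_tab <- dependence_screen(tables, alpha = alpha)
  dd <- vapply(seq_len(n), function(i) {
    ddate(records, relations$cause[i], relations$effect[i])
  }, 0)
  nb <- binarize_nannot(relations$n_annot)
  gpt <- if (is.null(judge)) {
    rep(0L, n)
  } else {
    vapply(seq_len(n), function(i) {
      judge_confirm(judge,
                    code_name(relations$cause[i], dictionary),
                    code_name(relations$effect[i], dictionary))
    }, 0L)
  }
  out <- data.frame(
    cause = relations$cause, effect = relations$effect,
    phi = unname(phi), dep = dep_tab$dep, testable = dep_tab$testable,
    p_adj = dep_tab$p_adj, ddate = dd, n_annot = relations$n_annot,
    nannot_bin = unname(nb), gpt = gpt,
    stringsAsFactors = FALSE)
  out$score <- combined_score(out$phi, out$dep, out$ddate, out$nannot_bin,
                              out$gpt)
  out <- out[order(-out$score, out$cause, out$effect), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# preferred surface name for a code, falling back to the code itself
code_name <- function(code, dictionary = NULL) {
  if (is.null(dictionary)) return(code)
  hit <- dictionary$name[dictionary$code == code]
  if (length(hit)) hit[1] else code
}

#' Write scored edges to TSV
#' @param edges scored-edge data frame from [score_relations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scored_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read scored edges from TSV
#' @param path path written by [write_scored_edges()].
#' @return Scored-edge data frame.
#' @export
read_scored_edges <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}
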