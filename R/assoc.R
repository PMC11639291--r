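#' Per-variant association scan
#'
#' A desk-scale stand-in for an external genome-wide association step: for
#' each variant a score (Cochran-Armitage trend) test of dosage against
#' case status, \eqn{\chi^2 = n\,r^2} on one degree of freedom where `r` is
#' the dosage-phenotype correlation. It accepts fractional dosages and
#' applies no covariate adjustment, clumping, or relatedness correction, so
#' it does not reproduce the behaviour of full GWAS toolchains.
#'
#' @param genotypes a [genotype_matrix()] or bare dosage matrix
#'   (individuals x variants, named columns).
#' @param labels binary case/control labels.
#' @param p_threshold significance threshold on the raw p-value
#'   (default `1e-8`).
#' @return Data frame with one row per variant: `variant_id`, `chi2`,
#'   `p_value`, `significant`, `monomorphic` (monomorphic variants get
#'   p = 1 and are flagged).
#' @export
association_scan <- function(genotypes, labels, p_threshold = 1e-8) {
  G <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages
       else genotypes
  stopifnot(is.matrix(G), nrow(G) == length(labels))
  y <- as.integer(labels)
  stopifnot(all(y %in% 0:1))
  if (length(unique(y)) < 2) abort("labels contain a single class")
  n <- nrow(G)
  sds <- apply(G, 2, stats::sd, na.rm = TRUE)
  mono <- !is.finite(sds) | sds == 0
  chi2 <- rep(NA_real_, ncol(G))
  for (j in which(!mono)) {
    g <- G[, j]
    ok <- !is.na(g)
    r <- stats::cor(g[ok], y[ok])
    chi2[j] <- sum(ok) * r^2
  }
  p <- ifelse(mono, 1, stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  data.frame(variant_id = colnames(G) %||% as.character(seq_len(ncol(G))),
             chi2 = ifelse(mono, 0, chi2), p_value = p,
             significant = p < p_threshold, monomorphic = mono,
             stringsAsFactors = FALSE)
}

# Pearson chi-square statistic and df for a contingency matrix after
# collapsing zero-margin rows/columns; returns c(stat, df).
pearson_stat <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(c(0, 0))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  c(sum((tab - e)^2 / e), (nrow(tab) - 1) * (ncol(tab) - 1))
}

#' Conditional-independence test of a variant and an outcome given a cause
#'
#' Tests `outcome` \eqn{\perp\!\!\!\perp} `variant` | `cause`: within each
#' stratum of the (binary) cause disease, a Pearson chi-square statistic
#' for the genotype-by-outcome table is computed; stratum statistics and
#' degrees of freedom are summed and referred to the chi-square
#' distribution. Genotypes are categorized as carrier status
#' (dosage >= 1 versus 0) by default, or as three classes 0/1/2; strata or
#' genotype/outcome categories with zero margins are collapsed before
#' testing, and a stratum whose outcome (or genotype) is constant
#' contributes nothing. A high p-value is consistent with the variant's
#' effect on the outcome being entirely mediated by the cause.
#'
#' @param variant numeric dosage vector.
#' @param cause binary status vector of the causative disease.
#' @param outcome binary status vector of the outcome disease.
#' @param coding `"carrier"` (default) or `"additive3"`.
#' @param method `"sum"` (default; summed per-stratum Pearson statistics)
#'   or `"cmh"` (Cochran-Mantel-Haenszel via [stats::mantelhaen.test()],
#'   carrier coding only).
#' @return A list with `p_value`, `statistic`, `df`, and `method`.
#' @export
conditional_independence_test <- function(variant, cause, outcome,
                                          coding = c("carrier", "additive3"),
                                          method = c("sum", "cmh")) {
  coding <- match.arg(coding)
  method <- match.arg(method)
  stopifnot(length(variant) == length(cause),
            length(cause) == length(outcome))
  cause <- as.integer(cause); outcome <- as.integer(outcome)
  stopifnot(all(cause %in% 0:1), all(outcome %in% 0:1))
  g <- if (coding == "carrier") as.integer(variant >= 1)
       else pmin(pmax(round(variant), 0), 2)
  strata <- sort(unique(cause))
  if (length(strata) < 2) {
    warning("all individuals fall in one cause stratum; unstratified test")
  }
  if (method == "cmh") {
    if (coding != "carrier") abort("method 'cmh' requires carrier coding")
    if (length(strata) < 2) {
      st <- pearson_stat(table(g, outcome))
      return(list(p_value = if (st[2] == 0) 1 else
                    stats::pchisq(st[1], st[2], lower.tail = FALSE),
                  statistic = st[1], df = st[2], method = "sum"))
    }
    tab <- table(g, outcome, cause)
    # double storage: CMH internals overflow integer counts at large n
    tab <- array(as.numeric(tab), dim = dim(tab), dimnames = dimnames(tab))
    res <- tryCatch(stats::mantelhaen.test(tab, correct = FALSE),
                    error = function(e) NULL)
    if (is.null(res)) return(list(p_value = 1, statistic = 0, df = 0,
                                  method = "cmh"))
    return(list(p_value = res$p.value, statistic = unname(res$statistic),
                df = unname(res$parameter), method = "cmh"))
  }
  stat <- 0; df <- 0
  for (s in strata) {
    st <- pearson_stat(table(g[cause == s], outcome[cause == s]))
    stat <- stat + st[1]; df <- df + st[2]
  }
  list(p_value = if (df == 0) 1 else
         stats::pchisq(stat, df, lower.tail = FALSE),
       statistic = stat, df = df, method = "sum")
}

#' Classify variants as mediated-consistent or not
#'
#' Applies the raw `P > cutoff` rule to conditional-independence p-values:
#' a variant whose test does not reject is consistent with purely mediated
#' (vertical) pleiotropy; rejection indicates a direct (horizontal)
#' component. No multiple-testing correction is applied, matching the raw
#' screening rule; this is deliberately liberal.
#'
#' @param p_values numeric vector of p-values.
#' @param cutoff significance cutoff (default 0.05).
#' @return Character vector with values `"mediated-consistent"` (p >
#'   cutoff) or `"not-independent"`.
#' @export
classify_mediated <- function(p_values, cutoff = 0.05) {
  stopifnot(is.numeric(p_values), all(p_values >= 0 & p_values <= 1))
  ifelse(p_values > cutoff, "mediated-consistent", "not-independent")
}

#' Conditional-independence screen over a variant panel
#'
#' Runs [conditional_independence_test()] for every shared variant and
#' classifies each one.
#'
#' @param genotypes a [genotype_matrix()] or dosage matrix.
#' @param cause,outcome binary status vectors.
#' @param cutoff classification cutoff (default 0.05).
#' @inheritParams conditional_independence_test
#' @return Data frame: `variant_id`, `p_value`, `statistic`, `df`,
#'   `verdict`.
#' @export
ci_screen <- function(genotypes, cause, outcome, cutoff = 0.05,
                      coding = c("carrier", "additive3"),
                      method = c("sum", "cmh")) {
  G <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosages
       else genotypes
  coding <- match.arg(coding); method <- match.arg(method)
  res <- lapply(seq_len(ncol(G)), function(j) {
    conditional_independence_test(G[, j], cause, outcome,
                                  coding = coding, method = method)
  })
  data.frame(
    variant_id = colnames(G) %||% as.character(seq_len(ncol(G))),
    p_value = vapply(res, `[[`, 0, "p_value"),
    statistic = vapply(res, `[[`, 0, "statistic"),
    df = vapply(res, `[[`, 0, "df"),
    verdict = classify_mediated(vapply(res, `[[`, 0, "p_value"), cutoff),
    stringsAsFactors = FALSE)
}
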