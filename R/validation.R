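#' Compare phi coefficients of mined versus random disease pairs
#'
#' Applies Fisher's z-transformation (`atanh`) to both groups of phi
#' coefficients, runs an independent two-sample Student t-test on the
#' transformed values and reports Cohen's d, the difference of group means
#' over the pooled standard deviation. Coefficients are clipped to
#' \eqn{\pm(1 - 10^{-12})} before the transform.
#'
#' @param phi_mined,phi_random numeric vectors of phi coefficients
#'   (length at least 2 each).
#' @return A list with `t_statistic`, `p_value`, `cohens_d`, and the group
#'   means of the transformed coefficients.
#' @export
validation_stats <- function(phi_mined, phi_random) {
  stopifnot(is.numeric(phi_mined), is.numeric(phi_random),
            length(phi_mined) >= 2, length(phi_random) >= 2,
            all(abs(phi_mined) <= 1), all(abs(phi_random) <= 1))
  clip <- 1 - 1e-12
  z1 <- atanh(pmin(pmax(phi_mined, -clip), clip))
  z2 <- atanh(pmin(pmax(phi_random, -clip), clip))
  if (stats::sd(z1) == 0 && stats::sd(z2) == 0) {
    abort("zero variance in both groups: comparison is unusable")
  }
  tt <- stats::t.test(z1, z2, var.equal = TRUE)
  n1 <- length(z1); n2 <- length(z2)
  pooled_sd <- sqrt(((n1 - 1) * stats::var(z1) + (n2 - 1) * stats::var(z2)) /
                      (n1 + n2 - 2))
  list(t_statistic = unname(tt$statistic),
       p_value = tt$p.value,
       cohens_d = (mean(z1) - mean(z2)) / pooled_sd,
       mean_mined = mean(z1), mean_random = mean(z2))
}

#' Sample random directed disease pairs
#'
#' Draws `k` ordered pairs uniformly without replacement from all ordered
#' cross-category pairs of the eligible codes, excluding any pairs supplied
#' in `exclude` (typically the mined relations). Used as the null comparison
#' group for [validation_stats()]; eligibility (e.g. a minimum case count)
#' is decided by the caller.
#'
#' @param codes character vector of eligible disease codes (at least 2).
#' @param k number of pairs to draw.
#' @param exclude optional data frame with `cause`/`effect` columns of pairs
#'   to exclude.
#' @param seed integer seed for reproducibility (optional).
#' @return Data frame with `cause` and `effect` columns, `k` rows.
#' @export
random_pair_sampler <- function(codes, k, exclude = NULL, seed = NULL) {
  codes <- unique(codes)
  stopifnot(is.character(codes), length(codes) >= 2, k >= 1)
  grid <- expand.grid(cause = codes, effect = codes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[substr(grid$cause, 1, 3) != substr(grid$effect, 1, 3), ,
               drop = FALSE]
  if (!is.null(exclude) && nrow(exclude)) {
    bad <- paste0(exclude$cause, "->", exclude$effect)
    grid <- grid[!(paste0(grid$cause, "->", grid$effect) %in% bad), ,
                 drop = FALSE]
  }
  if (k > nrow(grid)) {
    abort("requested %d pairs but only %d eligible pairs exist",
          k, nrow(grid))
  }
  idx <- with_seed(seed, sample.int(nrow(grid), k))
  out <- grid[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Disease codes observed in at least a minimum number of individuals
#'
#' @param records a [patient_records()] object.
#' @param min_cases minimum number of distinct diagnosed individuals
#'   (default 1000, the eligibility rule used for the mined-vs-random
#'   comparison).
#' @return Character vector of eligible codes.
#' @export
eligible_codes <- function(records, min_cases = 1000) {
  stopifnot(inherits(records, "patient_records"))
  counts <- table(records$diagnoses$code)
  names(counts)[counts >= min_cases]
}
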