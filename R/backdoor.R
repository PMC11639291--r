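#' Backdoor-adjusted interventional probability
#'
#' Estimates \eqn{P(\mathrm{outcome}=1 \mid do(\mathrm{treatment}=v))} from
#' patient records by backdoor adjustment over the strata of the adjustment
#' covariates:
#' \deqn{\sum_a \hat P(Y = 1 \mid X = v, A = a)\,\hat P(A = a)}
#' with plain empirical frequencies. Strata containing no individual with
#' the requested treatment value contribute nothing; their total population
#' mass is reported as `uncovered_mass` rather than imputed.
#'
#' @param records a [patient_records()] object.
#' @param treatment,outcome disease codes (three-character categories).
#' @param adjustment character vector of adjustment covariates, possibly
#'   empty. Each element is a disease code (binary diagnosis indicator),
#'   `"age"` (ages grouped into `age_band`-year bands), `"sex"`, or a
#'   threshold expression such as `"age>=50"` / `"age<40"` (a two-level
#'   stratification).
#' @param treatment_value 0 or 1; the value set by the intervention
#'   (default 1, presence of the treatment disease).
#' @param age_band width in years of the age bands used for `"age"`
#'   (default 5).
#' @return A list with `estimate`, `n_treated` (individuals at the
#'   treatment value across used strata), `strata` (per-stratum weight,
#'   counts and conditional outcome frequency), and `uncovered_mass`.
#' @export
backdoor_adjust <- function(records, treatment, outcome,
                            adjustment = character(0),
                            treatment_value = 1, age_band = 5) {
  stopifnot(inherits(records, "patient_records"),
            is_string(treatment), is_string(outcome),
            treatment_value %in% 0:1)
  treatment <- truncate_code(treatment)
  outcome <- truncate_code(outcome)
  if (treatment == outcome) abort("treatment and outcome must differ")
  if (any(adjustment %in% c(treatment, outcome))) {
    abort("adjustment set must exclude treatment and outcome")
  }
  x <- as.integer(disease_status(records, treatment))
  y <- as.integer(disease_status(records, outcome))
  n <- length(x)
  if (!any(x == treatment_value)) {
    abort("no individuals with treatment value %d: query unidentifiable",
          treatment_value)
  }
  strata <- covariate_strata(records, adjustment, age_band)
  levs <- sort(unique(strata))
  rows <- lapply(levs, function(a) {
    in_a <- strata == a
    treated <- in_a & x == treatment_value
    data.frame(stratum = a,
               weight = sum(in_a) / n,
               n_in_stratum = sum(in_a),
               n_treated = sum(treated),
               p_outcome = if (any(treated)) mean(y[treated]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, rows)
  rep_df$used <- rep_df$n_treated > 0
  used <- rep_df[rep_df$used, , drop = FALSE]
  list(estimate = sum(used$weight * used$p_outcome),
       n_treated = sum(used$n_treated),
       strata = rep_df,
       uncovered_mass = sum(rep_df$weight[!rep_df$used]))
}

# one stratum label per individual from the adjustment covariates
covariate_strata <- function(records, adjustment, age_band = 5) {
  demo <- records$demographics
  n <- nrow(demo)
  if (!length(adjustment)) return(rep("(all)", n))
  cols <- lapply(adjustment, function(a) {
    if (grepl("^[A-Z][0-9]{2}", a)) {
      paste0(a, "=", as.integer(disease_status(records, truncate_code(a))))
    } else if (identical(a, "age")) {
      band <- floor(demo$age / age_band) * age_band
      sprintf("age[%d,%d)", band, band + age_band)
    } else if (identical(a, "sex")) {
      paste0("sex=", demo$sex)
    } else if (grepl("^age\\s*(>=|<=|>|<)\\s*[0-9]+$", a)) {
      m <- regmatches(a, regexec("^age\\s*(>=|<=|>|<)\\s*([0-9]+)$", a))[[1]]
      op <- match.fun(m[2])
      paste0(a, "=", op(demo$age, as.numeric(m[3])))
    } else {
      abort("unrecognised adjustment covariate: %s", a)
    }
  })
  do.call(paste, c(cols, sep = "|"))
}

#' Naive conditional outcome frequency
#'
#' The unadjusted \eqn{\hat P(\mathrm{outcome}=1\mid\mathrm{treatment}=v)},
#' i.e. [backdoor_adjust()] with an empty adjustment set. Useful as the
#' biased comparator on confounded data.
#'
#' @inheritParams backdoor_adjust
#' @return A probability.
#' @export
naive_conditional <- function(records, treatment, outcome,
                              treatment_value = 1) {
  backdoor_adjust(records, treatment, outcome, character(0),
                  treatment_value)$estimate
}
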