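#' Background-knowledge judges
#'
#' A judge answers, for a directed (cause, effect) disease-name pair, the
#' yes/no question of whether the cause can cause the effect. Two pure and
#' reproducible implementations ship with the package: a lookup-table stub
#' and a transcript replayer. A live language-model client can implement the
#' same contract but is outside the reproducible core, since live models
#' answer the same prompt inconsistently across calls.
#'
#' @name judges
NULL

#' Deterministic stub judge backed by a lookup table
#'
#' @param verdicts named character vector: names are `"cause|effect"` keys
#'   (lowercased), values are free-text responses such as `"Yes"` / `"No"`.
#' @param default response returned for pairs absent from the table
#'   (default `"No"`).
#' @return An object of class `llm_judge`.
#' @examples
#' j <- llm_judge_stub(c("hypertension|acute kidney failure" = "Yes"))
#' judge_confirm(j, "hypertension", "acute kidney failure")
#' @export
llm_judge_stub <- function(verdicts = character(), default = "No") {
  stopifnot(is.character(verdicts))
  names(verdicts) <- tolower(names(verdicts))
  structure(list(kind = "stub", verdicts = verdicts, default = default),
            class = "llm_judge")
}

#' Replay judge from a recorded transcript
#'
#' Reads a JSONL transcript with keys `cause`, `effect`, `response` and
#' answers queries from it, so a recorded interactive session can be
#' re-scored byte-identically.
#'
#' @param path path to the transcript JSONL.
#' @param default response for pairs absent from the transcript.
#' @return An object of class `llm_judge`.
#' @export
llm_judge_replay <- function(path, default = "No") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  verdicts <- character(0)
  for (ln in lines) {
    r <- jsonlite::fromJSON(ln)
    verdicts[tolower(paste0(r$cause, "|", r$effect))] <-
      as.character(r$response)
  }
  structure(list(kind = "replay", verdicts = verdicts, default = default),
            class = "llm_judge")
}

#' Query a judge about a directed disease pair
#'
#' Returns 1 iff the judge's response is affirmative, i.e. begins with
#' "yes" case-insensitively. A judge failure is recorded conservatively as
#' 0 with a warning.
#'
#' @param judge an `llm_judge`.
#' @param cause_name,effect_name surface names (or codes) of the pair.
#' @return Integer 0 or 1.
#' @export
judge_confirm <- function(judge, cause_name, effect_name) {
  stopifnot(inherits(judge, "llm_judge"),
            is_string(cause_name), is_string(effect_name))
  resp <- tryCatch({
    key <- tolower(paste0(cause_name, "|", effect_name))
    if (key %in% names(judge$verdicts)) judge$verdicts[[key]]
    else judge$default
  }, error = function(e) {
    warning(sprintf("judge failed for (%s, %s): %s; recording 0",
                    cause_name, effect_name, conditionMessage(e)))
    ""
  })
  as.integer(grepl("^\\s*yes", resp, ignore.case = TRUE))
}

#' @export
print.llm_judge <- function(x, ...) {
  cat(sprintf("<llm_judge:%s> %d recorded verdicts, default \"%s\"\n",
              x$kind, length(x$verdicts), x$default))
  invisible(x)
}
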