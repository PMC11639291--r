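#' Read a sentence corpus from JSONL
#'
#' One JSON object per line with keys `doc_id`, `sent_id` and `text`.
#'
#' @param path path to a JSONL file.
#' @return A data frame with character columns `doc_id`, `sent_id`, `text`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(doc_id = character(), sent_id = character(),
                      text = character(), stringsAsFactors = FALSE))
  }
  recs <- lapply(lines, jsonlite::fromJSON)
  out <- data.frame(
    doc_id  = vapply(recs, function(r) as.character(r$doc_id), ""),
    sent_id = vapply(recs, function(r) as.character(r$sent_id), ""),
    text    = vapply(recs, function(r) as.character(r$text), ""),
    stringsAsFactors = FALSE)
  if (any(!nzchar(out$text))) abort("corpus contains empty sentence text")
  out
}

#' Write a sentence corpus as JSONL
#' @param corpus data frame with columns `doc_id`, `sent_id`, `text`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    writeLines(jsonlite::toJSON(
      list(doc_id = corpus$doc_id[i], sent_id = corpus$sent_id[i],
           text = corpus$text[i]),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Causal lexical patterns
#'
#' A pattern is a template with one `{CAUSE}` and one `{EFFECT}` slot
#' (`{C}`/`{E}` abbreviations accepted), e.g. `"{CAUSE} can cause {EFFECT}"`
#' or `"{EFFECT} caused by {CAUSE}"`. The slot names carry the causal
#' direction, so passive constructions orient correctly. Templates are
#' matched case-insensitively against sentences in which disease mentions
#' have already been identified; up to three non-mention words may intervene
#' between a slot and its neighbouring cue text, which binds each slot to the
#' mention nearest the cue.
#'
#' @param templates character vector of templates.
#' @return An object of class `causal_patterns`.
#' @export
causal_patterns <- function(templates) {
  stopifnot(is.character(templates), length(templates) >= 1)
  templates <- trimws(templates)
  templates <- templates[nzchar(templates)]
  norm <- gsub("\\{C\\}", "{CAUSE}", templates)
  norm <- gsub("\\{E\\}", "{EFFECT}", norm)
  ok <- vapply(norm, function(t) {
    length(gregexpr("\\{CAUSE\\}", t, perl = TRUE)[[1]]) == 1 &&
      grepl("\\{CAUSE\\}", t) &&
      length(gregexpr("\\{EFFECT\\}", t, perl = TRUE)[[1]]) == 1 &&
      grepl("\\{EFFECT\\}", t)
  }, TRUE)
  if (!all(ok)) {
    abort("malformed pattern template(s): %s",
          paste(templates[!ok], collapse = "; "))
  }
  pats <- lapply(seq_along(norm), function(i) {
    compiled <- compile_pattern(norm[i])
    list(pattern_id = sprintf("p%02d", i), template = templates[i],
         regex = compiled$regex, cause_group = compiled$cause_group)
  })
  structure(pats, class = "causal_patterns")
}

#' Read causal patterns from a file
#'
#' One template per line; blank lines and lines starting with `#` ignored.
#'
#' @param path path to the pattern file, or `NULL` for the default set
#'   shipped with the package.
#' @return A [causal_patterns()] object.
#' @export
read_patterns <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_patterns.txt",
                        package = "causenet", mustWork = TRUE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  causal_patterns(lines)
}

#' Default causal pattern set
#' @return A [causal_patterns()] object with the shipped templates.
#' @export
default_patterns <- function() read_patterns(NULL)

# Compile "{CAUSE} cue {EFFECT}"-style template into a PCRE over
# mention-masked text. Mentions are masked as \x01<index>\x02; a slot matches
# exactly one mask token. At whitespace junctions between a slot and cue text
# up to three intervening non-mention words are tolerated.
compile_pattern <- function(template) {
  slot_re <- "\\{(CAUSE|EFFECT)\\}"
  m <- gregexpr(slot_re, template, perl = TRUE)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  slot_names <- substring(template, starts + 1, starts + lens - 2)
  # split into literal / slot pieces
  pieces <- list(); pos <- 1L
  for (k in seq_along(starts)) {
    if (starts[k] > pos) {
      pieces[[length(pieces) + 1L]] <-
        list(type = "lit", text = substring(template, pos, starts[k] - 1L))
    }
    pieces[[length(pieces) + 1L]] <- list(type = "slot", name = slot_names[k])
    pos <- starts[k] + lens[k]
  }
  if (pos <= nchar(template)) {
    pieces[[length(pieces) + 1L]] <-
      list(type = "lit", text = substring(template, pos, nchar(template)))
  }
  filler <- "(?:[^\x01\x02\\s]+\\s+){0,3}"
  mask <- "\x01(\\d+)\x02"
  out <- character(0)
  for (k in seq_along(pieces)) {
    p <- pieces[[k]]
    if (p$type == "slot") {
      out <- c(out, mask)
    } else {
      txt <- p$text
      lead_ws <- grepl("^\\s", txt)
      trail_ws <- grepl("\\s$", txt)
      core <- trimws(txt)
      core_re <- gsub("\\\\\\s+", "\\\\s+",
                      gsub("\\s+", " ", regex_escape(core)))
      core_re <- gsub(" ", "\\\\s+", core_re)
      left <- if (lead_ws && k > 1) paste0("\\s+", filler) else ""
      right <- if (trail_ws && k < length(pieces)) {
        paste0("\\s+", filler)
      } else ""
      out <- c(out, paste0(left, core_re, right))
    }
  }
  list(regex = paste0(out, collapse = ""),
       cause_group = which(slot_names == "CAUSE"))
}

#' @export
print.causal_patterns <- function(x, ...) {
  cat(sprintf("<causal_patterns> %d templates\n", length(x)))
  for (p in x) cat(sprintf("  %s: %s\n", p$pattern_id, p$template))
  invisible(x)
}
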