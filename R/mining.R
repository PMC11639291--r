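#' Find disease mentions in a sentence
#'
#' Dictionary matching is case-insensitive, anchored at word boundaries,
#' longest-match-first, and non-overlapping left-to-right: when two dictionary
#' names overlap in the text the longest one wins, and matching resumes after
#' the matched span.
#'
#' @param text a single sentence.
#' @param dictionary a [disease_dictionary()].
#' @return A data frame with one row per mention, sorted by `start`:
#'   `start`, `end` (1-based, inclusive character offsets), `surface`
#'   (matched text) and `code`. Zero rows when nothing matches.
#' @examples
#' d <- disease_dictionary("hypertension", "I10")
#' match_mentions("Hypertension worsens outcomes", d)
#' @export
match_mentions <- function(text, dictionary) {
  stopifnot(is_string(text), inherits(dictionary, "disease_dictionary"))
  if (nrow(dictionary) == 0) abort("dictionary is empty")
  names <- dictionary$name[order(-nchar(dictionary$name), dictionary$name)]
  alts <- gsub(" ", "\\\\s+", regex_escape(names))
  rx <- paste0("(?<![[:alnum:]])(?:", paste(alts, collapse = "|"),
               ")(?![[:alnum:]])")
  m <- gregexpr(rx, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(), end = integer(),
                      surface = character(), code = character(),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(m)
  end <- start + attr(m, "match.length") - 1L
  surface <- substring(text, start, end)
  key <- tolower(gsub("\\s+", " ", surface))
  code <- dictionary$code[match(key, dictionary$name)]
  data.frame(start = start, end = end, surface = surface, code = code,
             stringsAsFactors = FALSE)
}

#' Extract directed causal pairs from one sentence
#'
#' Applies each lexical pattern to the sentence with its disease mentions
#' masked, and emits a directed (cause, effect) pair for every pattern
#' instance whose slots align with two distinct mentions. A slot binds the
#' mention nearest the pattern's cue text. Sentences where diseases co-occur
#' without any causal cue yield no pairs.
#'
#' @param text the sentence.
#' @param mentions mention table from [match_mentions()].
#' @param patterns a [causal_patterns()] object.
#' @return Data frame with columns `cause` and `effect` (possibly zero rows).
#'   Same-code pairs arising from two surface forms of one category are kept
#'   here and removed by [filter_same_category()].
#' @export
extract_pairs <- function(text, mentions, patterns) {
  stopifnot(is_string(text), inherits(patterns, "causal_patterns"))
  out <- data.frame(cause = character(), effect = character(),
                    stringsAsFactors = FALSE)
  if (is.null(mentions) || nrow(mentions) < 2) return(out)
  masked <- mask_mentions(text, mentions)
  for (p in patterns) {
    mm <- gregexpr(p$regex, masked, perl = TRUE, ignore.case = TRUE)[[1]]
    if (mm[1] == -1L) next
    cstarts <- attr(mm, "capture.start")
    clens <- attr(mm, "capture.length")
    for (i in seq_along(mm)) {
      idx <- vapply(1:2, function(g) {
        as.integer(substring(masked, cstarts[i, g],
                             cstarts[i, g] + clens[i, g] - 1L))
      }, 0L)
      cause_i <- idx[p$cause_group]
      effect_i <- idx[if (p$cause_group == 1L) 2L else 1L]
      if (cause_i == effect_i) next
      out <- rbind(out, data.frame(cause = mentions$code[cause_i],
                                   effect = mentions$code[effect_i],
                                   stringsAsFactors = FALSE))
    }
  }
  unique(out)
}

# replace mention spans by \x01<row index>\x02 tokens (right-to-left so
# earlier offsets stay valid)
mask_mentions <- function(text, mentions) {
  ord <- order(mentions$start, decreasing = TRUE)
  for (i in ord) {
    text <- paste0(substring(text, 1, mentions$start[i] - 1L),
                   "\x01", i, "\x02",
                   substring(text, mentions$end[i] + 1L))
  }
  text
}

#' Drop pairs within the same three-character category
#'
#' Relations between codes sharing their ICD-10-CM three-character category
#' are considered spurious (two surface forms of the same disease family) and
#' removed. Input order is preserved.
#'
#' @param pairs data frame with `cause` and `effect` columns.
#' @return The subset with `cause` and `effect` in distinct categories.
#' @export
filter_same_category <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("cause", "effect") %in% names(pairs)))
  keep <- substr(pairs$cause, 1, 3) != substr(pairs$effect, 1, 3)
  pairs[keep, , drop = FALSE]
}

#' Aggregate sentence-level pairs into unique relations
#'
#' Collapses directed pairs (with sentence provenance) into one row per
#' unique (cause, effect), counting distinct supporting sentences.
#'
#' @param pairs data frame with columns `cause`, `effect`, `doc_id`,
#'   `sent_id`.
#' @return Data frame sorted by (cause, effect) with columns `cause`,
#'   `effect`, `n_annot`, and `sentence_ids` (semicolon-joined
#'   `doc_id:sent_id` keys).
#' @export
aggregate_relations <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("cause", "effect", "doc_id", "sent_id") %in% names(pairs)))
  if (nrow(pairs) == 0) {
    return(data.frame(cause = character(), effect = character(),
                      n_annot = integer(), sentence_ids = character(),
                      stringsAsFactors = FALSE))
  }
  sid <- paste0(pairs$doc_id, ":", pairs$sent_id)
  key <- paste0(pairs$cause, "\t", pairs$effect)
  sid_by_rel <- lapply(split(sid, key), function(s) sort(unique(s)))
  keys <- sort(names(sid_by_rel))
  parts <- strsplit(keys, "\t", fixed = TRUE)
  data.frame(
    cause = vapply(parts, `[`, "", 1L),
    effect = vapply(parts, `[`, "", 2L),
    n_annot = vapply(keys, function(k) length(sid_by_rel[[k]]), 0L,
                     USE.NAMES = FALSE),
    sentence_ids = vapply(keys, function(k) {
      paste(sid_by_rel[[k]], collapse = ";")
    }, "", USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' Mine causal disease relations from a corpus
#'
#' End-to-end miner: identifies mentions per sentence, extracts directed
#' pairs with the lexical patterns, removes same-category pairs and
#' aggregates the survivors into unique relations with support counts.
#'
#' @param corpus sentence data frame from [read_corpus()].
#' @param dictionary a [disease_dictionary()].
#' @param patterns a [causal_patterns()] object (default: shipped set).
#' @return A list with elements `relations` (see [aggregate_relations()])
#'   and `counts`, a named vector tracing the mining funnel (sentences,
#'   sentences with co-mentions, raw pairs, cross-category pairs, unique
#'   relations).
#' @export
mine_corpus <- function(corpus, dictionary, patterns = default_patterns()) {
  stopifnot(is.data.frame(corpus),
            all(c("doc_id", "sent_id", "text") %in% names(corpus)))
  all_pairs <- vector("list", nrow(corpus))
  n_comention <- 0L
  for (i in seq_len(nrow(corpus))) {
    men <- match_mentions(corpus$text[i], dictionary)
    if (nrow(men) < 2) next
    n_comention <- n_comention + 1L
    pr <- extract_pairs(corpus$text[i], men, patterns)
    if (nrow(pr)) {
      pr$doc_id <- corpus$doc_id[i]
      pr$sent_id <- corpus$sent_id[i]
      all_pairs[[i]] <- pr
    }
  }
  pairs <- do.call(rbind, all_pairs)
  if (is.null(pairs)) {
    pairs <- data.frame(cause = character(), effect = character(),
                        doc_id = character(), sent_id = character(),
                        stringsAsFactors = FALSE)
  }
  kept <- filter_same_category(pairs)
  relations <- aggregate_relations(kept)
  list(relations = relations,
       counts = c(sentences = nrow(corpus),
                  comention_sentences = n_comention,
                  raw_pairs = nrow(pairs),
                  cross_category_pairs = nrow(kept),
                  unique_relations = nrow(relations)))
}

#' Write mined relations to TSV
#' @param relations relation table from [mine_corpus()]/[aggregate_relations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_relations <- function(relations, path) {
  utils::write.table(relations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read mined relations from TSV
#' @param path path written by [write_relations()].
#' @return Relation data frame.
#' @export
read_relations <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", quote = "")
  if ("n_annot" %in% names(d)) d$n_annot <- as.integer(d$n_annot)
  d
}
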