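#' Disease codes and the surface-name dictionary
#'
#' Diseases are identified throughout by their ICD-10-CM three-character
#' category (one uppercase letter followed by two digits, e.g. `"I10"` for
#' essential hypertension). Longer codes such as `"I10.9"` or `"N210"` are
#' truncated to their category at load time, because the relation miner and
#' every downstream measure operate at category resolution.
#'
#' @name disease-codes
NULL

#' Normalise disease codes to their three-character category
#'
#' Strips punctuation, upper-cases, and truncates each code to its leading
#' letter-digit-digit category.
#'
#' @param code character vector of ICD-10-CM codes (any specificity).
#' @return Character vector of three-character category codes.
#' @examples
#' truncate_code(c("I10", "N21.0", "e119"))
#' @export
truncate_code <- function(code) {
  stopifnot(is.character(code))
  x <- toupper(gsub("[^A-Za-z0-9]", "", code))
  x <- substr(x, 1L, 3L)
  bad <- !grepl("^[A-Z][0-9]{2}$", x) & !is.na(x)
  if (any(bad)) {
    abort("invalid ICD-10-CM code(s) after truncation: %s",
          paste(unique(code[bad]), collapse = ", "))
  }
  x
}

#' Construct a disease-name dictionary
#'
#' A dictionary maps lowercased surface names to three-character disease
#' codes. Lookup during mention matching is case-insensitive; codes are
#' truncated to their category on construction.
#'
#' @param names character vector of surface names (non-empty strings).
#' @param codes character vector of ICD-10-CM codes, one per name.
#' @return An object of class `disease_dictionary`: a data frame with columns
#'   `name` (lowercased) and `code`, plus attributes `n_names` and `n_codes`.
#' @export
disease_dictionary <- function(names, codes) {
  stopifnot(is.character(names), is.character(codes),
            length(names) == length(codes))
  names <- trimws(tolower(names))
  if (any(!nzchar(names))) abort("dictionary contains empty surface names")
  codes <- truncate_code(codes)
  d <- unique(data.frame(name = names, code = codes,
                         stringsAsFactors = FALSE))
  dupes <- d$name[duplicated(d$name)]
  if (length(dupes)) {
    # a surface name must resolve to a single category
    abort("ambiguous dictionary names mapping to multiple codes: %s",
          paste(utils::head(unique(dupes), 5), collapse = ", "))
  }
  d <- d[order(d$name), , drop = FALSE]
  rownames(d) <- NULL
  structure(d, class = c("disease_dictionary", "data.frame"),
            n_names = nrow(d), n_codes = length(unique(d$code)))
}

#' Read a dictionary from a two-column TSV
#'
#' Expects a header row and two columns: surface name and ICD-10-CM code.
#'
#' @param path path to a UTF-8 TSV file.
#' @return A [disease_dictionary()].
#' @export
read_dictionary <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         colClasses = "character", quote = "",
                         fileEncoding = "UTF-8")
  if (ncol(d) < 2) abort("dictionary TSV must have two columns (name, code)")
  disease_dictionary(d[[1]], d[[2]])
}

#' Write a dictionary to TSV
#' @param dictionary a [disease_dictionary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "disease_dictionary"))
  utils::write.table(
    data.frame(name = dictionary$name, icd10cm_code = dictionary$code),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.disease_dictionary <- function(x, ...) {
  cat(sprintf("<disease_dictionary> %d names covering %d codes\n",
              attr(x, "n_names"), attr(x, "n_codes")))
  invisible(x)
}
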