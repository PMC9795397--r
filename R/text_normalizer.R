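#' PTSD mention lexicon
#'
#' A lexicon bundles the surface forms (acronyms, misspellings, multiword
#' phrases) that providers use to record PTSD in short diagnostic text,
#' the canonical token they are rewritten to, and the stop-word list used
#' during normalization.  The package ships a default variant list and a
#' small English function-word list; both are plain-text files (one entry
#' per line, `#` comments) so a site-specific list can be dropped in.
#'
#' @param variants Character vector of surface forms, or `NULL` to read the
#'   shipped default list.  When any variants are supplied the canonical
#'   token is always included; an explicitly empty vector yields an empty
#'   lexicon under which no text ever flags (useful to switch the text
#'   pathway off).
#' @param stop_words Character vector of stop words, or `NULL` for the
#'   shipped default list.
#' @param canonical Canonical replacement token.  Lower-case; defaults to
#'   `"ptsd"`.
#' @return An object of class `ptsd_lexicon`.
#' @examples
#' lex <- ptsd_lexicon()
#' contains_ptsd("P.T.S.D. follow-up", lex)
#' @export
ptsd_lexicon <- function(variants = NULL, stop_words = NULL,
                         canonical = "ptsd") {
  if (is.null(variants)) {
    variants <- read_word_file(
      system.file("extdata", "ptsd_lexicon.txt", package = "ptsdemr",
        mustWork = TRUE))
  }
  if (is.null(stop_words)) {
    stop_words <- read_word_file(
      system.file("extdata", "stop_words.txt", package = "ptsdemr",
        mustWork = TRUE))
  }
  canonical <- tolower(trimws(canonical))
  stopifnot(nzchar(canonical))
  variants <- unique(tolower(trimws(variants)))
  variants <- variants[nzchar(variants)]
  if (length(variants) > 0) variants <- unique(c(canonical, variants))
  stop_words <- unique(tolower(trimws(stop_words)))
  stop_words <- setdiff(stop_words[nzchar(stop_words)], canonical)
  structure(
    list(variants = variants, canonical = canonical, stop_words = stop_words),
    class = "ptsd_lexicon"
  )
}

#' @rdname ptsd_lexicon
#' @param path Path to a variant or stop-word file.
#' @export
read_lexicon <- function(path, stop_words = NULL) {
  ptsd_lexicon(variants = read_word_file(path), stop_words = stop_words)
}

read_word_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' @export
print.ptsd_lexicon <- function(x, ...) {
  cat("<ptsd_lexicon> canonical:", x$canonical,
      "| variants:", length(x$variants),
      "| stop words:", length(x$stop_words), "\n")
  invisible(x)
}

#' Normalize short diagnostic text and flag PTSD mentions
#'
#' `normalize_text()` applies the cleanup used before text-based case
#' definitions are evaluated: lower-case the field; rewrite every lexicon
#' variant (longest match first, at word boundaries, so dotted acronyms like
#' `"P.T.S.D."` are caught before punctuation is removed) to the canonical
#' token; strip characters outside `[a-z0-9 ]`; drop stop words; and
#' tokenize on whitespace.  `contains_ptsd()` is the vectorized predicate
#' equivalent to `normalize_text(x)$ptsd_flag`.
#'
#' @param text A single string (`normalize_text`) or character vector
#'   (`contains_ptsd`); `NA` and empty strings normalize to nothing.
#' @param lexicon A [ptsd_lexicon].
#' @return `normalize_text()` returns a list with `tokens` (character vector)
#'   and `ptsd_flag` (logical scalar, `TRUE` iff the canonical token is
#'   present).  `contains_ptsd()` returns a logical vector along `text`.
#' @details Negated mentions (`"no ptsd"`, `"ptsd ruled out"`) are not
#'   special-cased: the step is a pure string conversion, mirroring how the
#'   short diagnostic text field names a diagnosis rather than narrates one.
#' @examples
#' normalize_text("Anxiety NOS", ptsd_lexicon())
#' contains_ptsd(c("P.T.S.D. follow-up", "post traumatic stress disorder",
#'                 "anxiety"), ptsd_lexicon())
#' @export
normalize_text <- function(text, lexicon = ptsd_lexicon()) {
  stopifnot(length(text) <= 1)
  norm <- normalize_vec(if (length(text)) text else NA_character_, lexicon)
  tokens <- strsplit(norm, " ", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  list(tokens = tokens,
    ptsd_flag = length(lexicon$variants) > 0 && lexicon$canonical %in% tokens)
}

#' @rdname normalize_text
#' @export
contains_ptsd <- function(text, lexicon = ptsd_lexicon()) {
  if (!length(text)) return(logical(0))
  if (length(lexicon$variants) == 0) return(rep(FALSE, length(text)))
  norm <- normalize_vec(text, lexicon)
  grepl(paste0("(^| )", lexicon$canonical, "( |$)"), norm)
}

# Vectorized normalization pipeline; returns space-joined token strings.
normalize_vec <- function(text, lexicon) {
  stopifnot(inherits(lexicon, "ptsd_lexicon"))
  x <- tolower(as.character(text))
  x[is.na(x)] <- ""
  variants <- lexicon$variants[order(-nchar(lexicon$variants))]
  for (v in variants) {
    pat <- paste0("(?<![a-z0-9])", escape_regex(v), "(?![a-z0-9])")
    x <- gsub(pat, paste0(" ", lexicon$canonical, " "), x, perl = TRUE)
  }
  x <- gsub("[^a-z0-9 ]", " ", x)
  if (length(lexicon$stop_words)) {
    stop_pat <- paste0("(?<![a-z0-9])(",
      paste(escape_regex(lexicon$stop_words), collapse = "|"),
      ")(?![a-z0-9])")
    x <- gsub(stop_pat, " ", x, perl = TRUE)
  }
  trimws(gsub(" +", " ", x))
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)
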