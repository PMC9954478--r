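#' Tokenize a phonemic transcription
#'
#' Splits a raw transcription string into an ordered sequence of phoneme
#' symbols. Two schemes are supported: `"chars"`, where every character is
#' one phoneme symbol (suitable for one-symbol-per-phoneme encodings such
#' as Klattese), and `"delim"`, where symbols are separated by a delimiter
#' (suitable for multi-character symbol sets such as ARPABET).
#'
#' @param transcription Character scalar, the raw transcription.
#' @param scheme `"chars"` or `"delim"`.
#' @param delim Delimiter used when `scheme = "delim"` (default a space).
#' @param inventory Optional character vector of allowed phoneme symbols;
#'   when supplied, any symbol outside it raises an error naming the symbol.
#' @return Character vector of phoneme symbols.
#' @examples
#' tokenize_transcription("kat", "chars")
#' tokenize_transcription("s p ii ch", "delim")
#' @export
tokenize_transcription <- function(transcription, scheme = c("chars", "delim"),
                                   delim = " ", inventory = NULL) {
  scheme <- match.arg(scheme)
  if (!is.character(transcription) || length(transcription) != 1L ||
      is.na(transcription)) {
    stop("'transcription' must be a single character string")
  }
  if (!nzchar(transcription)) stop("empty transcription")
  phonemes <- if (scheme == "chars") {
    strsplit(transcription, "", fixed = TRUE)[[1L]]
  } else {
    out <- strsplit(transcription, delim, fixed = TRUE)[[1L]]
    out[nzchar(out)]
  }
  if (length(phonemes) == 0L) stop("empty transcription")
  if (!is.null(inventory)) {
    bad <- setdiff(phonemes, inventory)
    if (length(bad)) {
      stop(sprintf("phoneme symbol(s) outside inventory: %s",
                   paste(unique(bad), collapse = ", ")))
    }
  }
  phonemes
}

new_phon_lexicon <- function(entries, phonemes, scheme, delim = " ") {
  structure(
    list(entries = entries, phonemes = phonemes,
         scheme = scheme, delim = delim,
         inventory = sort(unique(unlist(phonemes, use.names = FALSE)))),
    class = "phon_lexicon"
  )
}

#' Construct a phonological lexicon from words and transcriptions
#'
#' @param word Character vector of orthographic word forms; used as node
#'   identifiers, so duplicates are disambiguated with a numeric suffix.
#' @param transcription Character vector of phonemic transcriptions, same
#'   length as `word`. Duplicate transcriptions (homophones) are retained
#'   as distinct entries.
#' @param scheme,delim,inventory Passed to [tokenize_transcription()].
#' @return A `phon_lexicon` object: a list with `entries` (data frame with
#'   columns `word_id`, `word`, `transcription`), `phonemes` (list of
#'   tokenized symbol sequences), the tokenization `scheme`, and the
#'   observed phoneme `inventory`.
#' @export
phon_lexicon <- function(word, transcription, scheme = c("chars", "delim"),
                         delim = " ", inventory = NULL) {
  scheme <- match.arg(scheme)
  if (length(word) != length(transcription)) {
    stop("'word' and 'transcription' must have the same length")
  }
  if (length(word) == 0L) stop("empty lexicon")
  word <- as.character(word)
  transcription <- as.character(transcription)
  word_id <- make.unique(word, sep = "#")
  phonemes <- vector("list", length(word))
  for (i in seq_along(word)) {
    phonemes[[i]] <- tryCatch(
      tokenize_transcription(transcription[i], scheme, delim, inventory),
      error = function(e) {
        stop(sprintf("row %d (word '%s'): %s", i, word[i],
                     conditionMessage(e)), call. = FALSE)
      }
    )
  }
  entries <- data.frame(word_id = word_id, word = word,
                        transcription = transcription,
                        stringsAsFactors = FALSE)
  new_phon_lexicon(entries, phonemes, scheme, delim)
}

#' Read a lexicon from a delimited text file
#'
#' Expects a header row. The default format is TSV with columns `word`
#' and `transcription`.
#'
#' @param path Path to the file.
#' @param word_col,transcription_col Column names holding the word form and
#'   the phonemic transcription.
#' @param sep Field separator (default tab).
#' @param scheme,delim,inventory Tokenization scheme, see
#'   [tokenize_transcription()].
#' @return A `phon_lexicon`; the number of rows read is reported via
#'   `message()`.
#' @export
read_lexicon <- function(path, word_col = "word",
                         transcription_col = "transcription",
                         sep = "\t", scheme = c("chars", "delim"),
                         delim = " ", inventory = NULL) {
  scheme <- match.arg(scheme)
  if (!file.exists(path)) stop(sprintf("lexicon file not found: %s", path))
  tab <- read.delim(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "#",
                    colClasses = "character")
  missing_cols <- setdiff(c(word_col, transcription_col), names(tab))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  lex <- phon_lexicon(tab[[word_col]], tab[[transcription_col]],
                      scheme = scheme, delim = delim, inventory = inventory)
  message(sprintf("read %d lexicon entries from %s", nrow(lex$entries), path))
  lex
}

#' Write a lexicon to a TSV file
#'
#' Writes columns `word` and `transcription` with a header, the format
#' [read_lexicon()] reads back.
#'
#' @param lexicon A `phon_lexicon`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "phon_lexicon"))
  out <- lexicon$entries[, c("word", "transcription")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.phon_lexicon <- function(x, ...) {
  cat(sprintf("phon_lexicon: %d entries, %d phoneme symbols, scheme '%s'\n",
              nrow(x$entries), length(x$inventory), x$scheme))
  lens <- lengths(x$phonemes)
  cat(sprintf("word length (phonemes): min %d, median %g, max %d\n",
              min(lens), stats::median(lens), max(lens)))
  invisible(x)
}

#' Resolve a target-word list against a lexicon
#'
#' Looks up each requested item among the lexicon's word identifiers and
#' word forms, preserving order. Items not found are reported, never
#' silently dropped.
#'
#' @param items Character vector of requested words.
#' @param lexicon A `phon_lexicon`.
#' @param provenance Free-text label recording where the list came from.
#' @return A `target_list`: list with `items` (resolved `word_id`s, in
#'   input order), `unresolved` (requested words not in the lexicon),
#'   `n_excluded`, and `provenance`.
#' @export
resolve_targets <- function(items, lexicon, provenance = "unspecified") {
  stopifnot(inherits(lexicon, "phon_lexicon"))
  items <- as.character(items)
  if (length(items) == 0L) stop("empty target list")
  ids <- lexicon$entries$word_id
  hit <- items %in% ids
  # fall back to orthographic form for items that are not ids themselves
  miss <- !hit
  if (any(miss)) {
    by_word <- match(items[miss], lexicon$entries$word)
    items[miss][!is.na(by_word)] <- ids[by_word[!is.na(by_word)]]
    hit[miss] <- !is.na(by_word)
  }
  res <- structure(
    list(items = items[hit], unresolved = items[!hit],
         n_excluded = sum(!hit), provenance = provenance),
    class = "target_list"
  )
  res
}

#' Read a target-word list from a text file
#'
#' One word per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the file.
#' @param lexicon A `phon_lexicon` the items must resolve against.
#' @return A `target_list`, see [resolve_targets()].
#' @export
read_target_list <- function(path, lexicon) {
  if (!file.exists(path)) stop(sprintf("target list not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop(sprintf("target list is empty: %s", path))
  res <- resolve_targets(lines, lexicon, provenance = path)
  message(sprintf("%d of %d target words resolved (%d excluded)",
                  length(res$items), length(lines), res$n_excluded))
  res
}

#' @export
print.target_list <- function(x, ...) {
  cat(sprintf("target_list (%s): %d resolved, %d excluded\n",
              x$provenance, length(x$items), x$n_excluded))
  invisible(x)
}
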