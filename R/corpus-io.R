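#' Default crisis keyword list
#'
#' The hashtag/keyword set used to harvest vaccine-era COVID-19 tweets
#' (lowercase, without the leading `#`). Used as the default keyword filter in
#' [filter_spec()] and as the hashtag pool of the synthetic generator.
#'
#' @return A character vector of keywords.
#' @export
covid_keywords <- function() {
  c("vaccine", "pfizer", "moderna", "astrazeneca", "sputnik", "sinopharm",
    "coronavirus", "coronavirusoutbreak", "coronaviruspandemic",
    "covid19", "covid_19", "epitwitter", "ihavecorona",
    "stayhomestaysafe", "testtraceisolate")
}

#' Default topic class names
#'
#' Human-readable names for the ten COVID-19 discussion classes used as the
#' default label-name table when `K = 10`; for other `K` generic
#' `"Topic k"` names are produced.
#'
#' @param K Number of topics.
#' @return Character vector of length `K`.
#' @export
covid_topic_names <- function(K = 10) {
  defaults <- c("Conspiracy Theory", "COVID-19 information",
                "COVID-19 statistics", "Economics", "Fake Treatment",
                "Governmental Measures", "Politics",
                "Public health measures", "Stocking Up", "Vaccine/Cure")
  if (K == length(defaults)) defaults else paste("Topic", seq_len(K))
}

tweet_cols <- c("id", "text", "lang", "country", "created_at", "hashtags",
                "retweet_count", "is_retweet", "is_reply", "is_quote")

new_tweet_row_defaults <- function() {
  list(lang = "", country = "", created_at = "", hashtags = list(character()),
       retweet_count = 0L, is_retweet = FALSE, is_reply = FALSE,
       is_quote = FALSE)
}

# normalize one parsed record (named list) into a 1-row tibble, or NULL if it
# has no usable text
coerce_tweet_record <- function(rec, fallback_id) {
  if (is.null(rec$text) || !nzchar(as.character(rec$text)[1])) return(NULL)
  defs <- new_tweet_row_defaults()
  hashtags <- rec$hashtags
  if (is.null(hashtags) || length(hashtags) == 0) {
    hashtags <- character()
  } else {
    hashtags <- tolower(sub("^#", "", as.character(unlist(hashtags))))
    hashtags <- hashtags[nzchar(hashtags) & !grepl("\\s", hashtags)]
  }
  tibble::tibble(
    id = as.character(rec$id %||% fallback_id),
    text = as.character(rec$text)[1],
    lang = as.character(rec$lang %||% defs$lang)[1],
    country = as.character(rec$country %||% defs$country)[1],
    created_at = as.character(rec$created_at %||% defs$created_at)[1],
    hashtags = list(hashtags),
    retweet_count = max(0L, as.integer(rec$retweet_count %||% 0L)[1],
                        na.rm = TRUE),
    is_retweet = isTRUE(as.logical(rec$is_retweet %||% FALSE)[1]),
    is_reply = isTRUE(as.logical(rec$is_reply %||% FALSE)[1]),
    is_quote = isTRUE(as.logical(rec$is_quote %||% FALSE)[1])
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read a tweet corpus from JSONL or CSV
#'
#' Reads tweet-like records into a tidy corpus tibble with one row per tweet.
#' Missing optional fields are defaulted (`country = ""`, flags `FALSE`,
#' `retweet_count = 0`); malformed records (unparseable, or lacking a
#' non-empty `text`) are skipped with a message. More than 50% malformed
#' records is treated as a fatal format error.
#'
#' @param path Path to the input file.
#' @param format `"jsonl"` (one JSON object per line) or `"csv"` (RFC 4180
#'   with a header row; the `hashtags` column holds space-separated tags).
#' @return A tibble with columns `id`, `text`, `lang`, `country`,
#'   `created_at`, `hashtags` (list column), `retweet_count`, `is_retweet`,
#'   `is_reply`, `is_quote`. The number of skipped records is attached as
#'   attribute `"skipped"`.
#' @export
read_tweets <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) tt_abort(paste0("cannot read tweet file: ", path))
  if (format == "jsonl") {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    n_total <- length(lines)
    rows <- vector("list", n_total)
    skipped <- 0L
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                      error = function(e) NULL)
      row <- if (is.null(rec)) NULL else coerce_tweet_record(rec, paste0("row", i))
      if (is.null(row)) {
        skipped <- skipped + 1L
        tt_inform("read_tweets: skipping malformed record at line ", i)
      } else {
        rows[[i]] <- row
      }
    }
    corpus <- dplyr::bind_rows(rows)
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    if (!"text" %in% names(df)) tt_abort("csv corpus must have a `text` column")
    n_total <- nrow(df)
    rows <- vector("list", n_total)
    skipped <- 0L
    for (i in seq_len(n_total)) {
      rec <- as.list(df[i, , drop = FALSE])
      rec <- lapply(rec, function(x) if (is.na(x)) NULL else x)
      if (!is.null(rec$hashtags)) {
        rec$hashtags <- strsplit(rec$hashtags, "\\s+")[[1]]
      }
      row <- coerce_tweet_record(rec, paste0("row", i))
      if (is.null(row)) {
        skipped <- skipped + 1L
        tt_inform("read_tweets: skipping malformed record at row ", i)
      } else {
        rows[[i]] <- row
      }
    }
    corpus <- dplyr::bind_rows(rows)
  }
  if (n_total > 0 && skipped > n_total / 2) {
    tt_abort(sprintf(
      "read_tweets: %d of %d records malformed (>50%%); wrong format?",
      skipped, n_total))
  }
  if (anyDuplicated(corpus$id)) {
    tt_abort("read_tweets: duplicate tweet ids in corpus")
  }
  attr(corpus, "skipped") <- skipped
  attr(corpus, "provenance") <- paste0(format, ":", path)
  corpus
}

#' Write a tweet corpus to JSONL or CSV
#'
#' Inverse of [read_tweets()]: read-write-read round-trips are the identity on
#' well-formed corpora.
#'
#' @param corpus A corpus tibble as returned by [read_tweets()].
#' @param path Output path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_tweets <- function(corpus, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      rec <- as.list(corpus[i, setdiff(names(corpus), "hashtags")])
      rec$hashtags <- corpus$hashtags[[i]]
      jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    flat <- corpus
    flat$hashtags <- vapply(corpus$hashtags, paste, character(1), collapse = " ")
    readr::write_csv(flat, path, progress = FALSE)
  }
  invisible(path)
}

#' Corpus filter specification
#'
#' Declares the corpus filtering rules: language restriction, exclusion of
#' retweets/replies/quotes, an optional keyword filter, and an optional date
#' range. Defaults mirror an English-only vaccine-era collection: keep
#' English originals only. The keyword list is typically applied at
#' collection time, so the keyword post-filter is off by default; pass e.g.
#' `keywords = covid_keywords()` to re-apply it.
#'
#' @param languages Character vector of ISO-639-1 codes to retain, or `NULL`
#'   to disable the language filter. Tweets with an empty `lang` are dropped
#'   while a language filter is active.
#' @param exclude_retweets,exclude_replies,exclude_quotes Drop flagged tweets.
#' @param keywords Character vector of keywords/hashtags (leading `#` and case
#'   are ignored); empty vector or `NULL` disables the keyword filter.
#' @param match_text If `TRUE` (default) a keyword also matches as a
#'   case-insensitive substring of the tweet text, not only against hashtags.
#' @param date_range Optional length-2 character vector `[start, end)` of
#'   ISO-8601 instants compared lexicographically against `created_at`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(languages = "en",
                        exclude_retweets = TRUE,
                        exclude_replies = TRUE,
                        exclude_quotes = TRUE,
                        keywords = NULL,
                        match_text = TRUE,
                        date_range = NULL) {
  if (!is.null(date_range) && length(date_range) != 2) {
    tt_abort("date_range must be NULL or length 2 (start, end)")
  }
  keywords <- tolower(sub("^#", "", keywords %||% character()))
  keywords <- keywords[nzchar(keywords)]
  structure(list(languages = languages, exclude_retweets = exclude_retweets,
                 exclude_replies = exclude_replies,
                 exclude_quotes = exclude_quotes, keywords = keywords,
                 match_text = match_text, date_range = date_range),
            class = "filter_spec")
}

#' Filter a corpus
#'
#' Applies a [filter_spec()] to a corpus, preserving the original tweet
#' order. Filtering is idempotent and an empty result is legal.
#'
#' @param corpus A corpus tibble.
#' @param spec A [filter_spec()].
#' @return The filtered corpus tibble.
#' @export
filter_corpus <- function(corpus, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  keep <- rep(TRUE, nrow(corpus))
  if (!is.null(spec$languages)) {
    keep <- keep & corpus$lang %in% spec$languages
  }
  if (spec$exclude_retweets) keep <- keep & !corpus$is_retweet
  if (spec$exclude_replies) keep <- keep & !corpus$is_reply
  if (spec$exclude_quotes) keep <- keep & !corpus$is_quote
  if (length(spec$keywords) > 0) {
    text_lc <- tolower(corpus$text)
    kw_hit <- vapply(seq_len(nrow(corpus)), function(i) {
      if (any(spec$keywords %in% corpus$hashtags[[i]])) return(TRUE)
      if (spec$match_text) {
        return(any(vapply(spec$keywords, grepl, logical(1),
                          x = text_lc[i], fixed = TRUE)))
      }
      FALSE
    }, logical(1))
    keep <- keep & kw_hit
  }
  if (!is.null(spec$date_range)) {
    keep <- keep & corpus$created_at >= spec$date_range[1] &
      corpus$created_at < spec$date_range[2]
  }
  out <- corpus[keep, , drop = FALSE]
  attr(out, "provenance") <- attr(corpus, "provenance")
  out
}

#' Write a labeled corpus to JSONL
#'
#' Writes tweets together with their dominant-topic annotation: integer
#' `label` in `1..K`, human-readable `label_name`, and the length-`K`
#' per-topic score vector `topic_scores`. Reading the file back with
#' [read_labeled()] reproduces the input.
#'
#' @param labeled A labeled corpus tibble as produced by [label_corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labeled <- function(labeled, path) {
  need <- c("id", "text", "label", "label_name", "topic_scores")
  missing <- setdiff(need, names(labeled))
  if (length(missing) > 0) {
    tt_abort(paste0("labeled corpus lacks column(s): ",
                    paste(missing, collapse = ", ")))
  }
  lens <- lengths(labeled$topic_scores)
  if (length(unique(lens)) > 1) {
    tt_abort("topic_scores rows have inconsistent lengths")
  }
  K <- lens[1]
  lab <- labeled$label[!is.na(labeled$label)]
  if (length(lab) > 0 && (min(lab) < 1 || max(lab) > K)) {
    tt_abort(sprintf("labels must lie in 1..K (K = %d)", K))
  }
  lines <- vapply(seq_len(nrow(labeled)), function(i) {
    rec <- as.list(labeled[i, setdiff(names(labeled),
                                      c("hashtags", "topic_scores"))])
    if ("hashtags" %in% names(labeled)) rec$hashtags <- labeled$hashtags[[i]]
    rec$topic_scores <- I(as.numeric(labeled$topic_scores[[i]]))
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a labeled corpus written by [write_labeled()]
#'
#' @param path Path to the labeled JSONL file.
#' @return A tibble with the tweet fields plus `label`, `label_name` and the
#'   `topic_scores` list column.
#' @export
read_labeled <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    rec <- jsonlite::fromJSON(lines[i], simplifyVector = TRUE)
    row <- coerce_tweet_record(rec, paste0("row", i))
    row$label <- if (is.null(rec$label)) NA_integer_ else as.integer(rec$label)
    row$label_name <- as.character(rec$label_name %||% NA_character_)
    row$topic_scores <- list(as.numeric(rec$topic_scores))
    if (!is.null(rec$unlabelable)) row$unlabelable <- isTRUE(rec$unlabelable)
    row
  })
  dplyr::bind_rows(rows)
}

#' Read a country population table
#'
#' @param path CSV with columns `country` (ISO-3166 alpha-2) and `population`.
#' @return A tibble with `country` and numeric `population`.
#' @export
read_population <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    country = readr::col_character(), population = readr::col_double()),
    progress = FALSE)
  tibble::as_tibble(df[, c("country", "population")])
}

#' Read a sentiment lexicon
#'
#' @param path CSV with columns `term` and `polarity` (`"pos"` or `"neg"`).
#' @return A lexicon tibble; a term mapped to both polarities is an error.
#' @export
read_lexicon <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    term = readr::col_character(), polarity = readr::col_character()),
    progress = FALSE)
  if (!all(df$polarity %in% c("pos", "neg"))) {
    tt_abort("lexicon polarity must be 'pos' or 'neg'")
  }
  dup <- unique(df$term[duplicated(df[, "term"])])
  both <- dup[vapply(dup, function(t)
    length(unique(df$polarity[df$term == t])) > 1, logical(1))]
  if (length(both) > 0) {
    tt_abort(paste0("lexicon terms with both polarities: ",
                    paste(both, collapse = ", ")))
  }
  tibble::as_tibble(unique(df[, c("term", "polarity")]))
}
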