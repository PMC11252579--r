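#' Bundled sentiment lexicon
#'
#' A small transparent polarity word list (positive/negative) used as the
#' default scorer and by the synthetic generator's sentiment injection.
#'
#' @return A lexicon tibble with columns `term`, `polarity`.
#' @export
default_sentiment_lexicon <- function() {
  pos <- c("hope", "hopeful", "good", "great", "safe", "effective",
           "recovery", "recover", "better", "relief", "grateful", "thankful",
           "optimistic", "success", "protect", "trust", "happy", "strong",
           "improve", "positive")
  neg <- c("fear", "afraid", "bad", "terrible", "dangerous", "death", "die",
           "worse", "crisis", "panic", "angry", "failure", "risk", "scam",
           "hoax", "sick", "weak", "decline", "negative", "sad")
  tibble::tibble(term = c(pos, neg),
                 polarity = rep(c("pos", "neg"), c(length(pos), length(neg))))
}

#' Score document sentiment with a polarity lexicon
#'
#' The raw score of a document is the mean polarity (+1/-1) of its
#' lexicon-matched tokens (`0` when nothing matches). Documents are
#' classified `positive` when `raw > neutral_band`, `negative` when
#' `raw < -neutral_band`, else `neutral`; the default band 0 is the sign
#' rule, and no match always means neutral. Swapping the lexicon's
#' polarities negates every raw score.
#'
#' @param docs A token-document tibble.
#' @param lexicon A lexicon tibble (default [default_sentiment_lexicon()]).
#' @param neutral_band Non-negative half-width of the neutral zone.
#' @return `docs` with added `sentiment` (`"positive"`, `"negative"`,
#'   `"neutral"`) and `sentiment_raw` columns.
#' @export
score_sentiment <- function(docs, lexicon = default_sentiment_lexicon(),
                            neutral_band = 0) {
  if (nrow(lexicon) == 0) tt_abort("score_sentiment: empty lexicon")
  pol <- setNames(ifelse(lexicon$polarity == "pos", 1, -1), lexicon$term)
  raw <- vapply(docs$tokens, function(tk) {
    p <- pol[tk]
    p <- p[!is.na(p)]
    sum(p) / max(1, length(p))
  }, numeric(1))
  docs$sentiment_raw <- raw
  docs$sentiment <- dplyr::case_when(
    raw > neutral_band ~ "positive",
    raw < -neutral_band ~ "negative",
    TRUE ~ "neutral")
  docs
}

#' Aggregate sentiment per country and topic with population normalization
#'
#' One row per observed (country, topic) cell with sentiment counts, the
#' per-capita tweet rate `(n_pos + n_neg + n_neu) / population`, and the
#' count-free net score `(n_pos - n_neg) / (n_pos + n_neg + n_neu)` bounded
#' in `[-1, 1]`. Tweets with an empty country are pooled under `"??"`;
#' countries missing from the population table are flagged and their
#' per-capita rate left `NA`. Cells with zero tweets are absent rather than
#' zero rows, and counts across rows conserve the input tweet count.
#'
#' @param labeled A tibble with columns `country`, `label` and `sentiment`.
#' @param populations A population tibble (`country`, `population`), e.g.
#'   from [read_population()].
#' @return A tibble with columns `country`, `label`, `n_pos`, `n_neg`,
#'   `n_neu`, `population`, `per_capita_rate`, `net_score`,
#'   `population_missing`.
#' @export
aggregate_by_country <- function(labeled, populations) {
  df <- labeled
  df$country <- ifelse(is.na(df$country) | df$country == "", "??",
                       df$country)
  out <- df |>
    dplyr::group_by(.data$country, .data$label) |>
    dplyr::summarise(
      n_pos = sum(.data$sentiment == "positive"),
      n_neg = sum(.data$sentiment == "negative"),
      n_neu = sum(.data$sentiment == "neutral"),
      .groups = "drop") |>
    dplyr::left_join(populations, by = "country") |>
    dplyr::mutate(
      total = .data$n_pos + .data$n_neg + .data$n_neu,
      population_missing = is.na(.data$population) | .data$population <= 0,
      per_capita_rate = ifelse(.data$population_missing, NA_real_,
                               .data$total / .data$population),
      net_score = ifelse(.data$total == 0, 0,
                         (.data$n_pos - .data$n_neg) / .data$total)) |>
    dplyr::select("country", "label", "n_pos", "n_neg", "n_neu",
                  "population", "per_capita_rate", "net_score",
                  "population_missing")
  out
}

#' Per-topic share table of a labeled corpus
#'
#' Shares are computed over labelable tweets and sum to 1 exactly before
#' rounding; `pct` is the share as a percentage.
#'
#' @param labeled A labeled corpus tibble (column `label`, `NA` allowed).
#' @param topic_names Optional length-`K` name table.
#' @return A tibble with `label`, `label_name`, `n`, `share`, `pct`.
#' @export
topic_shares <- function(labeled, topic_names = NULL) {
  lab <- labeled$label[!is.na(labeled$label)]
  K <- max(lab)
  counts <- tabulate(lab, nbins = K)
  present <- which(counts > 0)
  names <- if (is.null(topic_names)) covid_topic_names(K) else topic_names
  tibble::tibble(label = present,
                 label_name = names[present],
                 n = counts[present],
                 share = counts[present] / sum(counts),
                 pct = 100 * counts[present] / sum(counts))
}
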