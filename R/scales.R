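# Psychometric instrument scoring.
#
# Four instruments are scored: the 16-item Narcissistic Personality Inventory
# (NPI-16, binary items, total 0-16, grandiose/dominant narcissism), the
# 10-item Hypersensitive Narcissism Scale (HSNS, 5-point Likert, total 10-50,
# implicit/vulnerable narcissism), the 20-item Basic Needs Scale (5-point
# Likert with nine reverse-keyed items, total 20-100, higher = lower perceived
# threat after Cyberball), and the ambiguous-sentence interpretation task
# (12 ambiguous sentences, each rated 1-5 for its hostile and its non-hostile
# reading; summed per reading).

# 1-based positions of the reverse-keyed Basic Needs items
BN_REVERSE_ITEMS <- c(1L, 3L, 5L, 7L, 9L, 11L, 14L, 16L, 20L)

# Attainable range of the summed interpretation scores (12 sentences x 1..5)
HOSTILE_RANGE <- c(12L, 60L)
# Single cut separating low (<= 35) from high (>= 36) hostile interpretation
HOSTILE_BIN_CUT <- 36L

check_likert <- function(items, n_items, lo, hi, what) {
  if (length(items) != n_items)
    stop_invalid("%s requires exactly %d items, got %d", what, n_items, length(items))
  if (anyNA(items) || !is.numeric(items) || any(items != as.integer(items)) ||
      any(items < lo) || any(items > hi))
    stop_invalid("%s items must be integers in %d..%d", what, lo, hi)
  invisible(as.integer(items))
}

#' Score the NPI-16 (dominant/grandiose narcissism)
#'
#' Counts narcissistic-option endorsements over the 16 forced-choice items.
#'
#' @param items Numeric vector of exactly 16 binary indicators (1 =
#'   narcissistic option chosen).
#' @return Integer total in 0..16; higher scores indicate greater dominant
#'   narcissism.
#' @examples
#' score_npi16(rep(1, 16))
#' score_npi16(c(rep(1, 5), rep(0, 11)))
#' @export
score_npi16 <- function(items) {
  items <- check_likert(items, 16L, 0L, 1L, "NPI-16")
  sum(items)
}

#' Score the Hypersensitive Narcissism Scale (implicit narcissism)
#'
#' @param items Numeric vector of exactly 10 Likert responses in 1..5.
#' @return Integer total in 10..50.
#' @examples
#' score_hsns(rep(3, 10))
#' @export
score_hsns <- function(items) {
  items <- check_likert(items, 10L, 1L, 5L, "HSNS")
  sum(items)
}

#' Score the Basic Needs Scale
#'
#' Sums the 20 post-Cyberball items after reverse-keying items
#' 1, 3, 5, 7, 9, 11, 14, 16 and 20 (v -> 6 - v). Higher totals indicate
#' lower perceived threat to belonging, self-esteem, meaning and control.
#'
#' @param items Numeric vector of exactly 20 Likert responses in 1..5.
#' @return Integer total in 20..100.
#' @examples
#' score_basic_needs(rep(3, 20)) # 60: 3 is the reversal fixed point
#' @export
score_basic_needs <- function(items) {
  items <- check_likert(items, 20L, 1L, 5L, "Basic Needs Scale")
  items[BN_REVERSE_ITEMS] <- 6L - items[BN_REVERSE_ITEMS]
  sum(items)
}

#' Reverse-key Likert items (v -> 6 - v)
#'
#' Involution on 5-point Likert responses; applying it twice returns the
#' original vector.
#'
#' @param items Numeric vector of responses in 1..5.
#' @return Reverse-keyed integer vector.
#' @export
reverse_key <- function(items) {
  if (anyNA(items) || any(items < 1) || any(items > 5))
    stop_invalid("Likert items must be in 1..5")
  6L - as.integer(items)
}

#' Score the ambiguous-sentence interpretation task
#'
#' Each ambiguous sentence receives a likelihood rating (1-5) for its hostile
#' and its non-hostile interpretation; the two scores are the per-reading
#' rating sums.
#'
#' @param hostile_ratings,non_hostile_ratings Equal-length integer vectors of
#'   ratings in 1..5, one per ambiguous sentence.
#' @return Named list with `hostile_score` and `non_hostile_score`.
#' @examples
#' score_interpretations(rep(5, 12), rep(1, 12))
#' @export
score_interpretations <- function(hostile_ratings, non_hostile_ratings) {
  if (length(hostile_ratings) != length(non_hostile_ratings))
    stop_invalid("hostile and non-hostile rating vectors must have equal length")
  n <- length(hostile_ratings)
  hostile_ratings <- check_likert(hostile_ratings, n, 1L, 5L, "hostile interpretation")
  non_hostile_ratings <- check_likert(non_hostile_ratings, n, 1L, 5L, "non-hostile interpretation")
  list(hostile_score = sum(hostile_ratings),
       non_hostile_score = sum(non_hostile_ratings))
}

#' Bin hostile-interpretation scores into low/high
#'
#' Scores at or below 35 are "low-level hostile interpretation", scores of 36
#' or more are "high-level". The cut reflects the observed bimodal grouping of
#' summed scores; the instrument's attainable range is 12-60 (12 ambiguous
#' sentences rated 1-5).
#'
#' @param score Numeric vector of summed hostile-interpretation scores.
#' @return Factor with levels `low < high` (ordered).
#' @examples
#' bin_hostile(c(15, 35, 36, 55))
#' @export
bin_hostile <- function(score) {
  if (anyNA(score) || any(score < HOSTILE_RANGE[1]) || any(score > HOSTILE_RANGE[2]))
    stop_invalid("hostile score outside the attainable range [%d, %d]",
                 HOSTILE_RANGE[1], HOSTILE_RANGE[2])
  factor(ifelse(score >= HOSTILE_BIN_CUT, "high", "low"),
         levels = c("low", "high"), ordered = TRUE)
}

#' Questionnaire response rate
#'
#' @param returned,distributed Counts of returned and distributed copies.
#' @return Percentage, rounded to one decimal.
#' @examples
#' response_rate(258, 315) # 81.9
#' @export
response_rate <- function(returned, distributed) {
  if (distributed <= 0) stop_invalid("distributed count must be positive")
  if (returned < 0 || returned > distributed)
    stop_invalid("returned must be between 0 and distributed")
  round(100 * returned / distributed, 1)
}

#' Assign narcissistic trait groups by top-27% cutoffs
#'
#' The top 27% of HSNS totals form the implicit-narcissism group, the top 27%
#' of NPI-16 totals the dominant-narcissism group, and the remaining middle
#' 46% the neutral control group. Group sizes are `round(0.27 n)` each for the
#' narcissism groups with the remainder neutral. Ties are broken by ascending
#' participant index; a participant qualifying for both top sets is assigned
#' to the scale on which their percentile is higher (HSNS wins exact ties),
#' and the other set is back-filled from the next-ranked participant so the
#' group sizes are preserved.
#'
#' @param data Data frame with one row per participant containing the score
#'   columns, or `NULL` to pass scores directly.
#' @param hsns_score,npi16_score Column names (when `data` is given) or
#'   numeric vectors of scale totals.
#' @return A tibble with `participant_id`, `group` (factor
#'   dominant/implicit/neutral), `hsns_percentile`, `npi_percentile`.
#' @examples
#' assign_trait_groups(hsns_score = c(50, 40, 30, 20), npi16_score = c(2, 4, 16, 8))
#' @export
assign_trait_groups <- function(data = NULL, hsns_score = "hsns_score",
                                npi16_score = "npi16_score") {
  if (!is.null(data)) {
    hsns <- data[[hsns_score]]
    npi <- data[[npi16_score]]
  } else {
    hsns <- hsns_score
    npi <- npi16_score
  }
  n <- length(hsns)
  if (n == 0) stop_invalid("empty cohort")
  if (length(npi) != n) stop_invalid("score vectors must cover the same participants")
  if (n < 4) stop_invalid("need at least 4 participants to form three groups")

  n_imp <- round(0.27 * n)
  n_dom <- round(0.27 * n)

  idx <- seq_len(n)
  # descending score, ties broken by ascending participant index
  ord_h <- order(-hsns, idx)
  ord_n <- order(-npi, idx)
  rank_h <- match(idx, ord_h)
  rank_n <- match(idx, ord_n)
  pct_h <- (n - rank_h + 1) / n
  pct_n <- (n - rank_n + 1) / n

  group <- rep(NA_character_, n)
  top_h <- ord_h[seq_len(n_imp)]
  top_n <- ord_n[seq_len(n_dom)]
  both <- intersect(top_h, top_n)
  only_h <- setdiff(top_h, top_n)
  only_n <- setdiff(top_n, top_h)
  group[only_h] <- "implicit"
  group[only_n] <- "dominant"
  # dual qualifiers: scale with the higher percentile wins; HSNS on exact tie
  group[both] <- ifelse(pct_h[both] >= pct_n[both], "implicit", "dominant")

  backfill <- function(ordering, label, deficit) {
    pos <- which(is.na(group[ordering]))
    take <- ordering[pos][seq_len(min(deficit, length(pos)))]
    group[take] <<- label
  }
  backfill(ord_h, "implicit", n_imp - sum(group == "implicit", na.rm = TRUE))
  backfill(ord_n, "dominant", n_dom - sum(group == "dominant", na.rm = TRUE))
  group[is.na(group)] <- "neutral"

  tibble::tibble(
    participant_id = idx,
    group = factor(group, levels = c("dominant", "implicit", "neutral")),
    hsns_percentile = pct_h,
    npi_percentile = pct_n
  )
}

#' Score a raw item-level response table
#'
#' Takes one row per participant with item-level columns `npi_01..npi_16`,
#' `hsns_01..hsns_10`, `bn_01..bn_20`, `host_01..host_12`,
#' `nonhost_01..nonhost_12` and `est_catch_pct`, and returns scale totals plus
#' the hostile-interpretation bin.
#'
#' @param responses Data frame in the raw-response schema.
#' @return Tibble with one row per participant: `npi16_score`, `hsns_score`,
#'   `basic_needs_score`, `hostile_score`, `non_hostile_score`, `hostile_bin`,
#'   `est_catch_pct`, plus any identifier columns carried through.
#' @export
score_responses <- function(responses) {
  grab <- function(prefix, k) {
    cols <- sprintf("%s_%02d", prefix, seq_len(k))
    missing <- setdiff(cols, names(responses))
    if (length(missing))
      stop_invalid("missing response columns: %s", paste(missing, collapse = ", "))
    as.matrix(responses[cols])
  }
  npi <- grab("npi", 16)
  hsns <- grab("hsns", 10)
  bn <- grab("bn", 20)
  host <- grab("host", 12)
  nonhost <- grab("nonhost", 12)
  if (!("est_catch_pct" %in% names(responses)))
    stop_invalid("missing response columns: est_catch_pct")
  if (any(responses$est_catch_pct < 0 | responses$est_catch_pct > 100))
    stop_invalid("est_catch_pct must lie in [0, 100]")

  scored <- tibble::tibble(
    npi16_score = vapply(seq_len(nrow(npi)), function(i) score_npi16(npi[i, ]), integer(1)),
    hsns_score = vapply(seq_len(nrow(hsns)), function(i) score_hsns(hsns[i, ]), integer(1)),
    basic_needs_score = vapply(seq_len(nrow(bn)), function(i) score_basic_needs(bn[i, ]), integer(1)),
    hostile_score = as.integer(rowSums(host)),
    non_hostile_score = as.integer(rowSums(nonhost)),
    est_catch_pct = responses$est_catch_pct
  )
  scored$hostile_bin <- bin_hostile(scored$hostile_score)
  id_cols <- intersect(c("participant_id", "id"), names(responses))
  dplyr::bind_cols(responses[id_cols], scored)
}
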