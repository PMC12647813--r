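# Lexical consistency of recall: Jaccard overlap of the unique normalized
# words used to describe the same event, either by the same participant across
# sessions (within-participant consistency) or by different participants of
# the same age group within a session (between-participant consistency).

#' Tokenize text to a set of normalized word types
#'
#' Lowercase, replace every non-alphanumeric character (including apostrophes)
#' with a space, split on whitespace, drop empties, keep unique types. No
#' stopword removal and no stemming: the overlap measure is deliberately
#' sensitive to exact word repetition.
#'
#' @param text character scalar (possibly empty).
#' @return character vector of unique tokens (sorted, for determinism).
#' @examples
#' tokenize("It's a cat") # "a" "cat" "it" "s"
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(character(0))
  }
  sort(unique(.hash_tokens(text)))
}

#' Jaccard index of two token sets
#'
#' `|A intersect B| / |A union B|`; ranges from 0 (no shared words) to 1
#' (identical word sets). Two empty sets give 0 with a warning.
#'
#' @param a,b character vectors (treated as sets).
#' @return a number in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) {
    warning("jaccard of two empty sets defined as 0", call. = FALSE)
    return(0)
  }
  length(intersect(a, b)) / u
}

# Merged recall text per participant x video x session x event:
# event-segment texts mapped to the same event concatenate with one space, in
# transcript order (the data-model merge rule).
.event_texts <- function(transcripts) {
  rows <- lapply(transcripts, function(tr) {
    ev <- Filter(function(s) s$category == "event", tr$segments)
    if (!length(ev)) {
      return(NULL)
    }
    idx <- vapply(ev, function(s) s$event_index, integer(1))
    txt <- vapply(ev, function(s) s$text, character(1))
    agg <- tapply(txt, idx, paste, collapse = " ")
    data.frame(
      participant_id = tr$participant_id, group = tr$group %||% NA_character_,
      video_id = tr$video_id, session = tr$session,
      event_index = as.integer(names(agg)), text = unname(agg),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.session_pairs <- rbind(
  c("day1", "day2"), c("day2", "day8"), c("day1", "day8")
)

#' Within-participant recall consistency across sessions
#'
#' For every participant x video x event recalled in both sessions of a pair
#' (day1-day2, day2-day8, day1-day8), the Jaccard overlap of the two sessions'
#' merged event recall texts. Events not recalled in both sessions of a pair
#' contribute no row (rather than a zero).
#'
#' @param transcripts list of `narrec_transcript`.
#' @return data.frame with columns `scope, group, participant_id, video_id,
#'   event_index, comparison, jaccard` (zero rows if no event repeats).
#' @export
within_participant <- function(transcripts) {
  et <- .event_texts(transcripts)
  empty <- data.frame(
    scope = character(0), group = character(0), participant_id = character(0),
    video_id = character(0), event_index = integer(0),
    comparison = character(0), jaccard = numeric(0)
  )
  if (is.null(et)) {
    return(empty)
  }
  out <- list()
  for (p in unique(et$participant_id)) {
    ep <- et[et$participant_id == p, ]
    for (v in unique(ep$video_id)) {
      ev <- ep[ep$video_id == v, ]
      for (r in seq_len(nrow(.session_pairs))) {
        s1 <- ev[ev$session == .session_pairs[r, 1], ]
        s2 <- ev[ev$session == .session_pairs[r, 2], ]
        shared <- intersect(s1$event_index, s2$event_index)
        for (e in shared) {
          out[[length(out) + 1L]] <- data.frame(
            scope = "within", group = ev$group[1], participant_id = p,
            video_id = v, event_index = e,
            comparison = paste(.session_pairs[r, ], collapse = "-"),
            jaccard = jaccard(
              tokenize(s1$text[s1$event_index == e]),
              tokenize(s2$text[s2$event_index == e])
            ),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out)) {
    return(empty)
  }
  do.call(rbind, out)
}

#' Between-participant recall consistency within a session and age group
#'
#' For each event recalled by at least `min_recallers` participants of `group`
#' in `session`, the Jaccard overlap is computed over every unordered pair of
#' those participants' merged recall texts and averaged to one value per
#' event.
#'
#' @param transcripts list of `narrec_transcript` (their `group` field is
#'   used).
#' @param group,session the age group and session to analyse.
#' @param min_recallers minimum number of recallers for an event to enter
#'   (default 3).
#' @return data.frame with columns `scope, group, video_id, event_index,
#'   session, n_recallers, jaccard`.
#' @export
between_participant <- function(transcripts, group, session, min_recallers = 3L) {
  et <- .event_texts(transcripts)
  empty <- data.frame(
    scope = character(0), group = character(0), video_id = character(0),
    event_index = integer(0), session = character(0),
    n_recallers = integer(0), jaccard = numeric(0)
  )
  if (is.null(et)) {
    return(empty)
  }
  et <- et[et$group %in% group & et$session == session, ]
  out <- list()
  for (v in unique(et$video_id)) {
    ev <- et[et$video_id == v, ]
    for (e in unique(ev$event_index)) {
      ee <- ev[ev$event_index == e, ]
      if (nrow(ee) < min_recallers) next
      toks <- lapply(ee$text, tokenize)
      pairs <- utils::combn(length(toks), 2)
      js <- apply(pairs, 2, function(ij) jaccard(toks[[ij[1]]], toks[[ij[2]]]))
      out[[length(out) + 1L]] <- data.frame(
        scope = "between", group = group, video_id = v, event_index = e,
        session = session, n_recallers = nrow(ee), jaccard = mean(js),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(empty)
  }
  do.call(rbind, out)
}

#' Aggregate within-participant consistency for group-level modeling
#'
#' Averages the event-level within-participant Jaccard values to one value per
#' participant x video x session pair, the unit entering the linear mixed
#' model on narrative consistency.
#'
#' @param rows output of [within_participant()].
#' @export
aggregate_within <- function(rows) {
  if (!nrow(rows)) {
    return(rows[0, c("participant_id", "group", "video_id", "comparison", "jaccard")])
  }
  agg <- stats::aggregate(
    jaccard ~ participant_id + group + video_id + comparison, rows, mean
  )
  agg[order(agg$participant_id, agg$video_id, agg$comparison), ]
}
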