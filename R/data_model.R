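# Domain types and on-disk formats.
#
# The experiment's raw materials are (1) reference annotations of each video —
# an ordered set of events with onset/offset times and a free-text description
# each; (2) scored recall transcripts — per participant x video x session, the
# transcript is segmented, each segment categorized (event / error / comment /
# other), event segments mapped to a reference event and subdivided into
# central and peripheral details; (3) subjective ratings. Everything funnels
# into one long-format analysis table with a row per participant x video x
# event x session.

.sessions <- c("day1", "day2", "day8")
.groups <- c("young", "older")
.categories <- c("event", "error", "comment", "other")
.detail_categories <- c("central", "peripheral")
.recall_types <- c("multiple", "one")

#' Event annotation
#'
#' One annotated event of a video: its time span and the annotator's free-text
#' description (the input to semantic centrality), plus optional finer-grained
#' sub-event descriptions.
#'
#' @param video_id identifier of the parent video.
#' @param event_index 1-based position within the video.
#' @param onset_s,offset_s event time span in seconds, `0 <= onset < offset`.
#' @param description non-empty free text.
#' @param sub_event_descriptions character vector (possibly empty).
#' @export
event_annotation <- function(video_id, event_index, onset_s, offset_s,
                             description, sub_event_descriptions = character(0)) {
  if (!is.character(description) || !nzchar(trimws(description))) {
    stop("event description must be non-empty (video ", video_id,
      ", event ", event_index, ")",
      call. = FALSE
    )
  }
  if (onset_s < 0 || offset_s <= onset_s) {
    stop("invalid event times for video ", video_id, " event ", event_index,
      ": need 0 <= onset_s < offset_s, got [", onset_s, ", ", offset_s, "]",
      call. = FALSE
    )
  }
  structure(
    list(
      video_id = video_id, event_index = as.integer(event_index),
      onset_s = as.numeric(onset_s), offset_s = as.numeric(offset_s),
      description = description,
      sub_event_descriptions = as.character(sub_event_descriptions)
    ),
    class = "narrec_event"
  )
}

#' Video annotation
#'
#' @param video_id,title identifiers.
#' @param duration_s video duration in seconds.
#' @param events ordered list of [event_annotation()] objects; must have at
#'   least 2 non-overlapping events within the video duration.
#' @export
video_annotation <- function(video_id, title, duration_s, events) {
  if (length(events) < 2L) {
    stop("video ", video_id, " needs at least 2 events", call. = FALSE)
  }
  onsets <- vapply(events, function(e) e$onset_s, numeric(1))
  offsets <- vapply(events, function(e) e$offset_s, numeric(1))
  idx <- vapply(events, function(e) e$event_index, integer(1))
  if (!identical(idx, seq_along(events))) {
    stop("video ", video_id, ": event_index must run 1..n in order", call. = FALSE)
  }
  if (any(diff(onsets) <= 0) || any(offsets[-length(offsets)] > onsets[-1] + 1e-9)) {
    stop("video ", video_id, ": events must be ordered by onset and non-overlapping",
      call. = FALSE
    )
  }
  if (any(offsets > duration_s + 1e-9)) {
    stop("video ", video_id, ": event times exceed the video duration", call. = FALSE)
  }
  structure(
    list(
      video_id = video_id, title = title, duration_s = as.numeric(duration_s),
      events = events
    ),
    class = "narrec_video"
  )
}

#' Participant record
#'
#' @param participant_id identifier.
#' @param group `"young"` or `"older"`; `"young"` is the reference level in
#'   all models.
#' @param age,education_years optional numerics.
#' @export
participant <- function(participant_id, group, age = NA_real_,
                        education_years = NA_real_) {
  group <- match.arg(group, .groups)
  structure(
    list(
      participant_id = participant_id, group = group,
      age = as.numeric(age), education_years = as.numeric(education_years)
    ),
    class = "narrec_participant"
  )
}

#' Detail annotation
#'
#' A scored unit of recalled information inside an event segment: `"central"`
#' (essential to the unfolding of the story) or `"peripheral"` (descriptive
#' perceptual/contextual embellishment).
#'
#' @param category `"central"` or `"peripheral"`.
#' @param text free text of the detail.
#' @export
detail_annotation <- function(category, text = "") {
  category <- match.arg(category, .detail_categories)
  structure(list(category = category, text = text), class = "narrec_detail")
}

#' Recall segment
#'
#' One scored transcript segment. `event_index` must be given exactly when
#' `category == "event"`, and only event segments may carry details.
#'
#' @param text segment text.
#' @param category one of event, error, comment, other.
#' @param event_index 1-based reference event (event segments only).
#' @param details list of [detail_annotation()] (event segments only).
#' @export
recall_segment <- function(text, category, event_index = NULL, details = list()) {
  category <- match.arg(category, .categories)
  if (category == "event") {
    if (is.null(event_index) || is.na(event_index)) {
      stop("event segment requires an event_index", call. = FALSE)
    }
    event_index <- as.integer(event_index)
  } else {
    if (!is.null(event_index) && !is.na(event_index)) {
      stop("only event segments may carry an event_index", call. = FALSE)
    }
    if (length(details)) {
      stop("only event segments may carry details (got ", category, ")",
        call. = FALSE
      )
    }
    event_index <- NA_integer_
  }
  structure(
    list(
      text = text, category = category, event_index = event_index,
      details = details
    ),
    class = "narrec_segment"
  )
}

#' Recall transcript
#'
#' One participant's scored recall of one video in one session, with the
#' post-recall subjective ratings. Videos retrieved in all three sessions have
#' `recall_type = "multiple"`; videos retrieved for the first time at the
#' one-week session have `recall_type = "one"` (only valid with
#' `session = "day8"`). The rehearsal rating exists only from day 2 on.
#'
#' @param participant_id,video_id identifiers.
#' @param session one of day1, day2, day8.
#' @param recall_type `"multiple"` or `"one"`.
#' @param segments ordered list of [recall_segment()].
#' @param ratings named list/vector with optional `vividness`, `content`,
#'   `rehearsal`, each in 1..5 when present.
#' @param group optional age group carried along for convenience.
#' @export
recall_transcript <- function(participant_id, video_id, session, recall_type,
                              segments, ratings = list(), group = NULL) {
  session <- match.arg(session, .sessions)
  recall_type <- match.arg(recall_type, .recall_types)
  if (recall_type == "one" && session != "day8") {
    stop("recall_type 'one' is only defined for the day8 session", call. = FALSE)
  }
  ratings <- lapply(
    stats::setNames(
      lapply(c("vividness", "content", "rehearsal"), function(k) ratings[[k]] %||% NA_real_),
      c("vividness", "content", "rehearsal")
    ),
    as.numeric
  )
  bad <- vapply(ratings, function(r) !is.na(r) && (r < 1 || r > 5), logical(1))
  if (any(bad)) {
    stop("ratings must lie in [1, 5]: ", paste(names(ratings)[bad], collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.na(ratings$rehearsal) && session == "day1") {
    stop("rehearsal rating is only collected on day2/day8", call. = FALSE)
  }
  structure(
    list(
      participant_id = participant_id, video_id = video_id, session = session,
      recall_type = recall_type, segments = segments, ratings = ratings,
      group = group
    ),
    class = "narrec_transcript"
  )
}

# ---- annotation JSON ---------------------------------------------------------

#' Write video annotations to JSON
#'
#' Top level is a list of videos, each
#' `{video_id, title, duration_s, events: [{event_index, onset_s, offset_s,
#' description, sub_events: [...]}]}`. Serialization is deterministic, so a
#' read/write round trip is byte-identical.
#'
#' @param videos list of `narrec_video`.
#' @param path output file.
#' @export
write_annotations <- function(videos, path) {
  payload <- lapply(videos, function(v) {
    list(
      video_id = v$video_id, title = v$title, duration_s = v$duration_s,
      events = lapply(v$events, function(e) {
        list(
          event_index = e$event_index, onset_s = e$onset_s,
          offset_s = e$offset_s, description = e$description,
          sub_events = as.list(e$sub_event_descriptions)
        )
      })
    )
  })
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read video annotations from JSON
#'
#' Inverse of [write_annotations()]; every type invariant is re-validated on
#' read, and a malformed record errors with the offending video/event named.
#'
#' @param path annotation JSON file.
#' @return list of `narrec_video`.
#' @export
read_annotations <- function(path) {
  raw <- jsonlite::read_json(path)
  if (!is.list(raw)) stop("annotation file must contain a list of videos", call. = FALSE)
  lapply(raw, function(v) {
    need <- c("video_id", "title", "duration_s", "events")
    if (!all(need %in% names(v))) {
      stop(
        "malformed video record (id: ", v$video_id %||% "<missing>",
        "): needs fields ", paste(need, collapse = ", "),
        call. = FALSE
      )
    }
    events <- lapply(v$events, function(e) {
      need_e <- c("event_index", "onset_s", "offset_s", "description")
      if (!all(need_e %in% names(e))) {
        stop("malformed event record in video ", v$video_id, call. = FALSE)
      }
      event_annotation(
        video_id = v$video_id, event_index = e$event_index,
        onset_s = e$onset_s, offset_s = e$offset_s,
        description = e$description,
        sub_event_descriptions = unlist(e$sub_events) %||% character(0)
      )
    })
    video_annotation(v$video_id, v$title, v$duration_s, events)
  })
}

# ---- transcript CSV ----------------------------------------------------------

.recall_cols <- c(
  "participant_id", "group", "video_id", "session", "recall_type",
  "segment_order", "category", "event_index", "detail_category",
  "detail_text", "segment_text"
)

#' Write recall transcripts to a long-format CSV
#'
#' One row per detail, plus one row with empty detail fields for every
#' detail-less segment (RFC-4180 quoting, UTF-8).
#'
#' @param transcripts list of `narrec_transcript`.
#' @param path output file.
#' @export
write_recalls <- function(transcripts, path) {
  rows <- lapply(transcripts, function(tr) {
    seg_rows <- lapply(seq_along(tr$segments), function(i) {
      s <- tr$segments[[i]]
      base <- data.frame(
        participant_id = tr$participant_id, group = tr$group %||% "",
        video_id = tr$video_id, session = tr$session,
        recall_type = tr$recall_type, segment_order = i,
        category = s$category,
        event_index = if (is.na(s$event_index)) "" else s$event_index,
        stringsAsFactors = FALSE
      )
      if (length(s$details)) {
        do.call(rbind, lapply(s$details, function(d) {
          cbind(base,
            detail_category = d$category, detail_text = d$text,
            segment_text = s$text, stringsAsFactors = FALSE
          )
        }))
      } else {
        cbind(base,
          detail_category = "", detail_text = "", segment_text = s$text,
          stringsAsFactors = FALSE
        )
      }
    })
    do.call(rbind, seg_rows)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out[, .recall_cols], path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read recall transcripts from the long-format CSV
#'
#' Rows are regrouped into transcripts (participant x video x session) in file
#' order; multiple detail rows of one segment are reassembled. Unknown extra
#' columns are ignored with a warning; unknown category labels and event
#' segments with a missing event index are validation errors.
#'
#' @param path transcript CSV.
#' @return list of `narrec_transcript` (ratings left empty; see
#'   [read_ratings()]).
#' @export
read_recalls <- function(path) {
  df <- utils::read.csv(path,
    stringsAsFactors = FALSE, colClasses = "character",
    fileEncoding = "UTF-8"
  )
  extra <- setdiff(names(df), .recall_cols)
  if (length(extra)) {
    warning(
      "ignoring unknown column(s) in ", path, ": ",
      paste(extra, collapse = ", "),
      call. = FALSE
    )
    df <- df[, setdiff(names(df), extra)]
  }
  missing <- setdiff(.recall_cols, names(df))
  if (length(missing)) {
    stop("transcript file lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  bad_cat <- setdiff(unique(df$category), .categories)
  if (length(bad_cat)) {
    stop("unknown segment category label(s): ", paste(bad_cat, collapse = ", "),
      call. = FALSE
    )
  }
  key <- paste(df$participant_id, df$video_id, df$session, sep = "\r")
  out <- lapply(unique(key), function(k) {
    sub <- df[key == k, , drop = FALSE]
    seg_ids <- unique(as.integer(sub$segment_order))
    segments <- lapply(seg_ids, function(i) {
      sr <- sub[as.integer(sub$segment_order) == i, , drop = FALSE]
      cat <- sr$category[1]
      ei <- sr$event_index[1]
      if (cat == "event" && !nzchar(ei)) {
        stop(
          "event segment without event_index (participant ",
          sr$participant_id[1], ", video ", sr$video_id[1], ", segment ", i, ")",
          call. = FALSE
        )
      }
      has_detail <- nzchar(sr$detail_category)
      if (any(has_detail) && cat != "event") {
        stop("details attached to a non-event segment (category ", cat, ")",
          call. = FALSE
        )
      }
      details <- lapply(which(has_detail), function(r) {
        detail_annotation(sr$detail_category[r], sr$detail_text[r])
      })
      recall_segment(
        text = sr$segment_text[1], category = cat,
        event_index = if (nzchar(ei)) as.integer(ei) else NULL,
        details = details
      )
    })
    recall_transcript(
      participant_id = sub$participant_id[1], video_id = sub$video_id[1],
      session = sub$session[1], recall_type = sub$recall_type[1],
      segments = segments[order(seg_ids)],
      group = if (nzchar(sub$group[1])) sub$group[1] else NULL
    )
  })
  out
}

# ---- ratings & boundaries CSV ------------------------------------------------

#' Write subjective ratings to CSV
#'
#' Columns `participant_id, video_id, session, vividness, content, rehearsal`
#' (rehearsal empty on day 1).
#'
#' @param transcripts list of `narrec_transcript` whose ratings to export.
#' @param path output file.
#' @export
write_ratings <- function(transcripts, path) {
  rows <- do.call(rbind, lapply(transcripts, function(tr) {
    data.frame(
      participant_id = tr$participant_id, video_id = tr$video_id,
      session = tr$session, vividness = tr$ratings$vividness,
      content = tr$ratings$content, rehearsal = tr$ratings$rehearsal
    )
  }))
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read subjective ratings from CSV
#'
#' @param path ratings CSV (see [write_ratings()]).
#' @return data.frame with one row per participant x video x session.
#' @export
read_ratings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "video_id", "session", "vividness", "content", "rehearsal")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("ratings file lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("vividness", "content", "rehearsal")) {
    v <- df[[col]]
    if (any(!is.na(v) & (v < 1 | v > 5))) {
      stop("rating column ", col, " outside [1, 5]", call. = FALSE)
    }
  }
  df
}

#' Read/write rater boundary sets
#'
#' CSV columns `video_id, rater_id, time_s`; one [boundary_set()] per
#' video x rater.
#'
#' @param path CSV file.
#' @return list of `narrec_boundaries`.
#' @export
read_boundaries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("video_id", "rater_id", "time_s") %in% names(df)))
  key <- paste(df$video_id, df$rater_id, sep = "\r")
  lapply(unique(key), function(k) {
    sub <- df[key == k, ]
    boundary_set(sub$video_id[1], sub$rater_id[1], sort(sub$time_s))
  })
}

#' @rdname read_boundaries
#' @param boundaries list of `narrec_boundaries` to write.
#' @export
write_boundaries <- function(boundaries, path) {
  rows <- do.call(rbind, lapply(boundaries, function(b) {
    data.frame(video_id = b$video_id, rater_id = b$rater_id, time_s = b$times_s)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

# ---- analysis table ----------------------------------------------------------

#' Build the long-format analysis table
#'
#' One row per participant x cued video x annotated event x session:
#' `recalled` is 1 iff at least one event segment of the transcript maps to
#' that event; `n_central`/`n_peripheral` sum the detail counts over all such
#' segments (0 when not recalled); `centrality_z` is joined by (video_id,
#' event_index). Error, comment and other segments are retained in the
#' transcripts but contribute nothing here.
#'
#' @param transcripts list of `narrec_transcript`.
#' @param annotations list of `narrec_video` covering every cued video.
#' @param centrality data.frame with columns `video_id, event_index, z` (e.g.
#'   from [centrality_table()]).
#' @return data.frame with columns `participant_id, group, video_id,
#'   event_index, session, recall_type, recalled, n_central, n_peripheral,
#'   centrality_z`.
#' @export
build_analysis_table <- function(transcripts, annotations, centrality) {
  ann_ids <- vapply(annotations, function(v) v$video_id, character(1))
  stopifnot(is.data.frame(centrality), all(c("video_id", "event_index", "z") %in% names(centrality)))
  rows <- lapply(transcripts, function(tr) {
    vi <- match(tr$video_id, ann_ids)
    if (is.na(vi)) {
      stop("no annotations for video ", tr$video_id, call. = FALSE)
    }
    n_events <- length(annotations[[vi]]$events)
    recalled <- integer(n_events)
    n_c <- integer(n_events)
    n_p <- integer(n_events)
    for (s in tr$segments) {
      if (s$category != "event") next
      if (s$event_index < 1L || s$event_index > n_events) {
        stop(
          "event_index ", s$event_index, " outside 1..", n_events,
          " for video ", tr$video_id,
          call. = FALSE
        )
      }
      recalled[s$event_index] <- 1L
      for (d in s$details) {
        if (d$category == "central") {
          n_c[s$event_index] <- n_c[s$event_index] + 1L
        } else {
          n_p[s$event_index] <- n_p[s$event_index] + 1L
        }
      }
    }
    z <- centrality$z[centrality$video_id == tr$video_id][
      match(
        seq_len(n_events),
        centrality$event_index[centrality$video_id == tr$video_id]
      )
    ]
    data.frame(
      participant_id = tr$participant_id, group = tr$group %||% NA_character_,
      video_id = tr$video_id, event_index = seq_len(n_events),
      session = tr$session, recall_type = tr$recall_type,
      recalled = recalled, n_central = n_c, n_peripheral = n_p,
      centrality_z = z, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
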