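test_that("annotation JSON round-trip is byte-identical", {
  videos <- fixture_videos()
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_annotations(videos, p1)
  back <- read_annotations(p1)
  write_annotations(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))
  expect_equal(length(back), 2L)
  expect_equal(length(back[[1]]$events), 10L)
  expect_equal(
    vapply(back[[1]]$events, function(e) e$event_index, integer(1)),
    1:10
  )
})

test_that("annotation validation rejects malformed structures", {
  expect_error(event_annotation("v", 1, 10, 5, "desc"), "onset_s < offset_s")
  expect_error(event_annotation("v", 1, 0, 5, "  "), "non-empty")
  ok1 <- event_annotation("v", 1, 0, 5, "one")
  ok2 <- event_annotation("v", 2, 4, 9, "two") # overlaps ok1
  expect_error(video_annotation("v", "t", 20, list(ok1, ok2)), "non-overlapping")
  expect_error(video_annotation("v", "t", 20, list(ok1)), "at least 2")
  e2 <- event_annotation("v", 2, 5, 30, "two")
  expect_error(video_annotation("v", "t", 20, list(ok1, e2)), "duration")
  # malformed file contents name the offender
  p <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(video_id = "vX", title = "t")), p, auto_unbox = TRUE)
  expect_error(read_annotations(p), "vX")
})

test_that("segment and transcript invariants are enforced", {
  expect_error(recall_segment("text", "event"), "event_index")
  expect_error(recall_segment("text", "comment", event_index = 3), "event segments")
  expect_error(
    recall_segment("text", "comment",
      details = list(detail_annotation("central"))
    ),
    "details"
  )
  expect_error(
    recall_transcript("p", "v", "day1", "one", list()),
    "day8"
  )
  expect_error(
    recall_transcript("p", "v", "day1", "multiple", list(),
      ratings = list(vividness = 7)
    ),
    "\\[1, 5\\]"
  )
  expect_error(
    recall_transcript("p", "v", "day1", "multiple", list(),
      ratings = list(rehearsal = 3)
    ),
    "day2/day8"
  )
})

test_that("recall CSV round-trip preserves the transcript object graph", {
  trs <- list(
    fixture_transcript("p01"),
    fixture_transcript("p02",
      segments = list(recall_segment("nothing concrete", "comment"))
    ),
    fixture_transcript("p03", session = "day2")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_recalls(trs, path)
  back <- read_recalls(path)
  expect_equal(length(back), 3L)
  strip <- function(tr) tr[c("participant_id", "video_id", "session", "recall_type", "segments", "group")]
  expect_equal(lapply(back, strip), lapply(trs, strip))
})

test_that("recall CSV reader validates categories, indices and detail placement", {
  trs <- list(fixture_transcript())
  path <- withr::local_tempfile(fileext = ".csv")
  write_recalls(trs, path)
  df <- read.csv(path, colClasses = "character")

  bad1 <- df
  bad1$category[1] <- "evnt"
  p1 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad1, p1, row.names = FALSE)
  expect_error(read_recalls(p1), "unknown segment category")

  bad2 <- df
  bad2$event_index[bad2$category == "event"] <- ""
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad2, p2, row.names = FALSE)
  expect_error(read_recalls(p2), "without event_index")

  bad3 <- df
  bad3$detail_category[bad3$category == "other"] <- "central"
  p3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad3, p3, row.names = FALSE)
  expect_error(read_recalls(p3), "non-event")

  extra <- df
  extra$scratch_notes <- "x"
  p4 <- withr::local_tempfile(fileext = ".csv")
  write.csv(extra, p4, row.names = FALSE)
  expect_warning(back <- read_recalls(p4), "unknown column")
  expect_equal(length(back), 1L)
})

test_that("detail rows aggregate per event in the analysis table", {
  videos <- fixture_videos()
  cent <- centrality_table(videos)
  # two event segments both mapped to event 4, carrying 1 central + 1 peripheral
  tr <- fixture_transcript(segments = list(
    recall_segment("first mention", "event", 4,
      details = list(detail_annotation("central", "c1"))
    ),
    recall_segment("second mention", "event", 4,
      details = list(detail_annotation("peripheral", "p1"))
    )
  ))
  tab <- build_analysis_table(list(tr), videos, cent)
  row4 <- tab[tab$event_index == 4, ]
  expect_equal(row4$recalled, 1L)
  expect_equal(row4$n_central, 1L)
  expect_equal(row4$n_peripheral, 1L)

  # two segments on event 3 with 2 and 1 central details sum to 3
  tr2 <- fixture_transcript(segments = list(
    recall_segment("a", "event", 3, details = list(
      detail_annotation("central"), detail_annotation("central")
    )),
    recall_segment("b", "event", 3, details = list(detail_annotation("central")))
  ))
  tab2 <- build_analysis_table(list(tr2), videos, cent)
  expect_equal(tab2$n_central[tab2$event_index == 3], 3L)
  expect_equal(tab2$recalled[tab2$event_index == 3], 1L)
})

test_that("analysis table covers every annotated event of every cued video", {
  videos <- fixture_videos()
  cent <- centrality_table(videos)
  # transcript with no event segments: all 10 rows recalled = 0
  tr <- fixture_transcript(segments = list(recall_segment("hmm", "comment")))
  tab <- build_analysis_table(list(tr), videos, cent)
  expect_equal(nrow(tab), 10L)
  expect_equal(sum(tab$recalled), 0L)
  expect_true(all(tab$n_central == 0L & tab$n_peripheral == 0L))

  # recalled row count = number of distinct event indices among event segments
  tr2 <- fixture_transcript(segments = list(
    recall_segment("a", "event", 2),
    recall_segment("b", "event", 2),
    recall_segment("c", "event", 7),
    recall_segment("d", "error")
  ))
  tab2 <- build_analysis_table(list(tr2), videos, cent)
  expect_equal(sum(tab2$recalled), 2L)
  # centrality joined by (video_id, event_index)
  expect_equal(tab2$centrality_z, cent$z[cent$video_id == "vidA"])

  # out-of-range mapping errors
  tr3 <- fixture_transcript(segments = list(recall_segment("x", "event", 11)))
  expect_error(build_analysis_table(list(tr3), videos, cent), "outside")
  # unknown video errors
  tr4 <- fixture_transcript(video_id = "vidZ", segments = list())
  expect_error(build_analysis_table(list(tr4), videos, cent), "vidZ")
})

test_that("generator output survives the full read/write round trip (property)", {
  cfg <- small_config(seed = 5)
  sim <- generate_study(cfg)
  dir <- withr::local_tempdir()
  write_recalls(sim$transcripts, file.path(dir, "recalls.csv"))
  write_annotations(sim$videos, file.path(dir, "ann.json"))
  write_ratings(sim$transcripts, file.path(dir, "ratings.csv"))
  back_tr <- read_recalls(file.path(dir, "recalls.csv"))
  back_ann <- read_annotations(file.path(dir, "ann.json"))
  ratings <- read_ratings(file.path(dir, "ratings.csv"))

  tab <- build_analysis_table(back_tr, back_ann, sim$centrality)
  # same mask as the generator's ground truth, matched row by row
  key <- function(d) paste(d$participant_id, d$video_id, d$session, d$event_index)
  m <- match(key(sim$analysis), key(tab))
  expect_false(anyNA(m))
  expect_equal(tab$recalled[m], sim$analysis$recalled)
  expect_equal(tab$n_central[m], sim$analysis$n_central)
  expect_equal(tab$n_peripheral[m], sim$analysis$n_peripheral)
  expect_equal(tab$centrality_z[m], sim$analysis$centrality_z, tolerance = 1e-12)
  expect_equal(nrow(ratings), length(sim$transcripts))
})

test_that("ratings files reject out-of-range values", {
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(
    data.frame(
      participant_id = "p1", video_id = "v1", session = "day1",
      vividness = 9, content = 3, rehearsal = NA
    ),
    p,
    row.names = FALSE
  )
  expect_error(read_ratings(p), "vividness")
})
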