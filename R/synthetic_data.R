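# Synthetic study generator. Emulates the full experiment — annotated videos,
# rater boundary sets, scored multi-session recall transcripts with recall
# text, subjective ratings — from known ground-truth parameters that mirror
# the generative assumptions of the fitted models: recall is Bernoulli with a
# logistic link on semantic centrality plus participant and video random
# intercepts; detail counts are Poisson; recall text reproduces a controlled
# fraction of the annotator's description vocabulary.
#
# The default parameter set is the "paper-scale template": 2 age groups x 28
# participants, 8 videos of 10-25 events, and link-scale coefficients chosen
# so the marginal behaviour echoes the published design (overall event recall
# around 0.55-0.60 for repeatedly recalled videos, noticeably lower for
# videos first recalled after a week, roughly 2 central and 1.7 peripheral
# details per recalled event). Group and interaction effects default to zero,
# so null calibration is the generator's default state.

#' Configuration of a synthetic study
#'
#' All parameters of the generator, with the paper-scale template as
#' defaults. `seed` is mandatory: every dataset is a pure function of its
#' config.
#'
#' @param seed integer seed, `0 <= seed < 2^31 - 10^6` (sub-seeds are derived
#'   by small offsets).
#' @param n_per_group participants per age group (default 28).
#' @param n_videos number of videos (default 8); the first half are cued in
#'   every session (`recall_type = "multiple"`), the rest only on day 8
#'   (`"one"`).
#' @param events_per_video inclusive range of events per video, default
#'   `c(10, 25)`.
#' @param description_length words per event description (default 12).
#' @param topic_overlap in `[0, 1]`: mean fraction of description words drawn
#'   from the video's shared topic pool rather than the event's own pool;
#'   drives the spread of semantic centrality (0 = disjoint vocabularies,
#'   degenerate network).
#' @param hub_event optional event index whose description borrows words from
#'   every other event's pool, making it the semantic hub of each video.
#' @param beta0 recall intercept on the logit scale.
#' @param beta_centrality effect of the centrality z-score on recall.
#' @param beta_session named logit offsets per session
#'   (`c(day1 = , day2 = , day8 = )`).
#' @param beta_recall_one additional logit offset for videos first recalled on
#'   day 8.
#' @param beta_group logit offset for the older group.
#' @param beta_interaction group x centrality interaction on the logit scale.
#' @param sigma_participant,sigma_video random-intercept SDs on the link
#'   scale (defaults 0.5; the paper reports no variance components, so these
#'   are documented conventions).
#' @param gamma0,gamma_centrality log-scale intercept and centrality effect
#'   for central-detail counts of recalled events.
#' @param delta0 log-scale rate of peripheral details.
#' @param rho fraction of an event description's words reproduced verbatim in
#'   the recall text (drives Jaccard consistency).
#' @param noise_words_rate Poisson mean of extra non-description words per
#'   recall text.
#' @param comment_rate probability a transcript gains one non-event (comment)
#'   segment.
#' @param boundary_jitter_sd_s,boundary_miss_rate,boundary_fa_rate simulated
#'   rater imperfections: Gaussian jitter SD (s), per-boundary miss
#'   probability, false alarms per minute.
#' @param sessions sessions to simulate (subset of day1/day2/day8; simulation
#'   loops restrict to `"day1"` for speed).
#' @param make_text build transcripts, recall text and ratings (TRUE); FALSE
#'   produces only the analysis table and ground truth, for fitting loops.
#' @return a `narrec_config` list.
#' @export
synthetic_config <- function(seed,
                             n_per_group = 28L,
                             n_videos = 8L,
                             events_per_video = c(10L, 25L),
                             description_length = 12L,
                             topic_overlap = 0.5,
                             hub_event = NULL,
                             beta0 = 0.3,
                             beta_centrality = 0.3,
                             beta_session = c(day1 = 0, day2 = -0.05, day8 = -0.05),
                             beta_recall_one = -0.9,
                             beta_group = 0,
                             beta_interaction = 0,
                             sigma_participant = 0.5,
                             sigma_video = 0.5,
                             gamma0 = log(2),
                             gamma_centrality = 0.1,
                             delta0 = log(1.7),
                             rho = 0.7,
                             noise_words_rate = 2,
                             comment_rate = 0.3,
                             boundary_jitter_sd_s = 0.3,
                             boundary_miss_rate = 0.05,
                             boundary_fa_rate = 0.5,
                             sessions = c("day1", "day2", "day8"),
                             make_text = TRUE) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  seed <- as.integer(seed)
  stopifnot(
    seed >= 0L, seed < 2147483647L - 1000000L,
    n_per_group >= 1L, n_videos >= 1L,
    length(events_per_video) == 2L, events_per_video[1] >= 3L,
    events_per_video[1] <= events_per_video[2],
    topic_overlap >= 0, topic_overlap <= 1,
    rho >= 0, rho <= 1,
    sigma_participant >= 0, sigma_video >= 0,
    boundary_miss_rate >= 0, boundary_miss_rate <= 1,
    boundary_fa_rate >= 0, noise_words_rate >= 0,
    all(sessions %in% .sessions)
  )
  stopifnot(all(c("day1", "day2", "day8") %in% names(beta_session)))
  structure(
    list(
      seed = seed, n_per_group = as.integer(n_per_group),
      n_videos = as.integer(n_videos),
      events_per_video = as.integer(events_per_video),
      description_length = as.integer(description_length),
      topic_overlap = topic_overlap, hub_event = hub_event,
      beta0 = beta0, beta_centrality = beta_centrality,
      beta_session = beta_session, beta_recall_one = beta_recall_one,
      beta_group = beta_group, beta_interaction = beta_interaction,
      sigma_participant = sigma_participant, sigma_video = sigma_video,
      gamma0 = gamma0, gamma_centrality = gamma_centrality, delta0 = delta0,
      rho = rho, noise_words_rate = noise_words_rate,
      comment_rate = comment_rate,
      boundary_jitter_sd_s = boundary_jitter_sd_s,
      boundary_miss_rate = boundary_miss_rate,
      boundary_fa_rate = boundary_fa_rate,
      sessions = sessions, make_text = isTRUE(make_text)
    ),
    class = "narrec_config"
  )
}

# Deterministic pseudo-word vocabulary: word k is three consonant-vowel
# syllables read off the base-70 digits of k. Pools are slices of this global
# list, so shared pools, event pools and the noise pool are pairwise disjoint.
.make_words <- function(from, n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(cons, vow, paste0))
  vapply(from + seq_len(n) - 1L, function(k) {
    paste0(
      syl[k %% 70L + 1L],
      syl[(k %/% 70L) %% 70L + 1L],
      syl[(k %/% 4900L) %% 70L + 1L]
    )
  }, character(1))
}

.noise_pool <- function() .make_words(900000L, 60L)

#' Generate annotated videos
#'
#' Event descriptions are composed from word pools: each event draws a
#' fraction of its words (scaled by `topic_overlap`) from a pool shared
#' across the video's events and the rest from its private pool, so
#' `topic_overlap` controls how semantically interconnected — and hence how
#' spread in centrality — the events are under the hash embedder. Event
#' onsets/offsets tile the video duration.
#'
#' @param cfg a `narrec_config`.
#' @return list of `narrec_video`, deterministic in `cfg$seed`.
#' @export
generate_videos <- function(cfg) {
  stopifnot(inherits(cfg, "narrec_config"))
  if (cfg$description_length < 1L) stop("empty vocabulary budget", call. = FALSE)
  set.seed(cfg$seed)
  L <- cfg$description_length
  lapply(seq_len(cfg$n_videos), function(v) {
    n_e <- if (cfg$events_per_video[1] == cfg$events_per_video[2]) {
      cfg$events_per_video[1]
    } else {
      sample(seq(cfg$events_per_video[1], cfg$events_per_video[2]), 1L)
    }
    shared <- .make_words((v - 1L) * 10000L, 40L)
    pools <- lapply(seq_len(n_e), function(e) {
      .make_words((v - 1L) * 10000L + 100L * e, 25L)
    })
    durations <- stats::rgamma(n_e, shape = 4, scale = 3.3)
    onsets <- c(0, cumsum(durations)[-n_e])
    offsets <- cumsum(durations)
    # draw non-hub descriptions first; the hub event then borrows words from
    # the other events' realized descriptions, making it the network's hub
    words_by_event <- vector("list", n_e)
    for (e in seq_len(n_e)) {
      if (!is.null(cfg$hub_event) && e == cfg$hub_event) next
      f <- cfg$topic_overlap * stats::runif(1, 0.3, 1)
      n_sh <- max(0L, min(L, round(f * L)))
      words_by_event[[e]] <- c(
        if (n_sh > 0L) sample(shared, n_sh) else character(0),
        sample(pools[[e]], L - n_sh)
      )
    }
    if (!is.null(cfg$hub_event) && cfg$hub_event <= n_e) {
      donors <- setdiff(seq_len(n_e), cfg$hub_event)
      words_by_event[[cfg$hub_event]] <- unlist(lapply(donors, function(d) {
        sample(words_by_event[[d]], min(2L, length(words_by_event[[d]])))
      }))
    }
    events <- lapply(seq_len(n_e), function(e) {
      words <- words_by_event[[e]]
      n_sub <- sample(0:2, 1L)
      subs <- if (n_sub > 0L) {
        vapply(seq_len(n_sub), function(i) {
          paste(sample(pools[[e]], 4L), collapse = " ")
        }, character(1))
      } else {
        character(0)
      }
      event_annotation(
        video_id = sprintf("video%02d", v), event_index = e,
        onset_s = onsets[e], offset_s = offsets[e],
        description = paste(words, collapse = " "),
        sub_event_descriptions = subs
      )
    })
    video_annotation(
      video_id = sprintf("video%02d", v),
      title = sprintf("Synthetic story %d", v),
      duration_s = offsets[n_e], events = events
    )
  })
}

#' Reference boundary set of a video
#'
#' The internal event boundaries (onsets of events 2..n) as a ground-truth
#' [boundary_set()] for the agreement simulations.
#'
#' @param video a `narrec_video`.
#' @param rater_id label for the returned set.
#' @export
truth_boundaries <- function(video, rater_id = "truth") {
  onsets <- vapply(video$events[-1], function(e) e$onset_s, numeric(1))
  boundary_set(video$video_id, rater_id, onsets)
}

#' Simulate an imperfect rater from true boundaries
#'
#' Each true boundary survives with probability `1 - boundary_miss_rate` and
#' is jittered by Gaussian noise (`boundary_jitter_sd_s`); false alarms
#' arrive at `boundary_fa_rate` per minute, uniformly in time. Times that
#' collide after jitter are dropped to keep the set strictly increasing.
#'
#' @param truth a `narrec_boundaries` ground-truth set.
#' @param cfg a `narrec_config` (jitter/miss/false-alarm fields).
#' @param rater_id label for the simulated rater.
#' @param seed seed for this rater (default `cfg$seed + 13`).
#' @export
generate_rater <- function(truth, cfg, rater_id = "sim_rater",
                           seed = cfg$seed + 13L) {
  stopifnot(inherits(truth, "narrec_boundaries"), inherits(cfg, "narrec_config"))
  set.seed(seed)
  keep <- stats::runif(length(truth$times_s)) >= cfg$boundary_miss_rate
  times <- truth$times_s[keep] +
    stats::rnorm(sum(keep), 0, cfg$boundary_jitter_sd_s)
  span <- max(truth$times_s, 1)
  n_fa <- stats::rpois(1, cfg$boundary_fa_rate * span / 60)
  times <- c(times, stats::runif(n_fa, 0, span))
  times <- sort(pmax(times, 0))
  times <- times[c(TRUE, diff(times) > 1e-9)]
  boundary_set(truth$video_id, rater_id, times)
}

# recall text for one event: a rho-fraction of the description's words plus
# Poisson noise words (pre-drawn counts for vectorized generation upstream)
.recall_text <- function(desc_words, rho, n_noise, noise_pool) {
  n_keep <- ceiling(rho * length(desc_words))
  kept <- if (n_keep >= length(desc_words)) {
    desc_words
  } else {
    desc_words[sort(sample.int(length(desc_words), n_keep))]
  }
  paste(c(kept, if (n_noise > 0) sample(noise_pool, n_noise, replace = TRUE)),
    collapse = " "
  )
}

#' Generate a complete synthetic study
#'
#' Generates videos (via [generate_videos()]), computes their true semantic
#' centrality through the real embedding/network pipeline, then simulates
#' recall per participant x cued video x event x session:
#' `recalled ~ Bernoulli(plogis(beta0 + beta_centrality z + beta_group G +
#' beta_interaction G z + beta_session + beta_recall_one [day-8-only videos] +
#' u_p + w_v))` with `u_p ~ N(0, sigma_participant^2)`,
#' `w_v ~ N(0, sigma_video^2)`; for recalled events
#' `n_central ~ Poisson(exp(gamma0 + gamma_centrality z))` and
#' `n_peripheral ~ Poisson(exp(delta0))`. When `cfg$make_text` is TRUE the
#' recalled events also get recall text (a fraction `rho` of the description's
#' words plus noise words), detail texts, occasional comment segments, and
#' ordinal ratings; otherwise only the analysis table and ground truth are
#' produced.
#'
#' @param cfg a `narrec_config`.
#' @return list with elements `config`, `videos`, `centrality` (data.frame),
#'   `participants`, `analysis` (the long-format table with the true recall
#'   mask), `transcripts`, `ratings` (NULL unless `make_text`), and `truth`
#'   (realized `u_p`, `w_v`, per-row linear predictor and probability).
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "narrec_config"))
  videos <- generate_videos(cfg)
  centrality <- centrality_table(videos, hash_embedder())
  set.seed(cfg$seed + 1L)

  groups <- rep(c("young", "older"), each = cfg$n_per_group)
  pids <- c(
    sprintf("y%03d", seq_len(cfg$n_per_group)),
    sprintf("o%03d", seq_len(cfg$n_per_group))
  )
  participants <- Map(function(id, g) {
    participant(id, g,
      age = round(stats::runif(1, if (g == "young") 20 else 65, if (g == "young") 35 else 80)),
      education_years = round(stats::runif(1, 12, 20))
    )
  }, pids, groups)

  u_p <- stats::rnorm(length(pids), 0, cfg$sigma_participant)
  names(u_p) <- pids
  vids <- vapply(videos, function(v) v$video_id, character(1))
  w_v <- stats::rnorm(length(vids), 0, cfg$sigma_video)
  names(w_v) <- vids
  n_multiple <- ceiling(cfg$n_videos / 2)
  vtype <- ifelse(seq_along(vids) <= n_multiple, "multiple", "one")
  names(vtype) <- vids

  # design grid: multiple-type videos cued every session, one-type on day8
  per_video <- do.call(rbind, lapply(seq_along(vids), function(vi) {
    sess <- if (vtype[vi] == "multiple") cfg$sessions else intersect("day8", cfg$sessions)
    if (!length(sess)) {
      return(NULL)
    }
    n_e <- length(videos[[vi]]$events)
    expand.grid(
      video_id = vids[vi], event_index = seq_len(n_e), session = sess,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(per_video) || !nrow(per_video)) {
    stop("no session x video combinations to simulate under cfg$sessions", call. = FALSE)
  }
  grid <- merge(
    data.frame(participant_id = pids, group = groups, stringsAsFactors = FALSE),
    per_video
  )
  grid <- grid[order(
    grid$participant_id, grid$video_id,
    match(grid$session, .sessions), grid$event_index
  ), ]
  grid$recall_type <- vtype[grid$video_id]
  key <- paste(grid$video_id, grid$event_index)
  ckey <- paste(centrality$video_id, centrality$event_index)
  grid$centrality_z <- centrality$z[match(key, ckey)]

  G <- as.numeric(grid$group == "older")
  eta <- cfg$beta0 +
    cfg$beta_centrality * grid$centrality_z +
    cfg$beta_group * G +
    cfg$beta_interaction * G * grid$centrality_z +
    cfg$beta_session[grid$session] +
    cfg$beta_recall_one * (grid$recall_type == "one") +
    u_p[grid$participant_id] + w_v[grid$video_id]
  prob <- stats::plogis(eta)
  grid$recalled <- stats::rbinom(nrow(grid), 1L, prob)
  lambda_c <- exp(cfg$gamma0 + cfg$gamma_centrality * grid$centrality_z)
  grid$n_central <- ifelse(grid$recalled == 1L, stats::rpois(nrow(grid), lambda_c), 0L)
  grid$n_peripheral <- ifelse(
    grid$recalled == 1L, stats::rpois(nrow(grid), exp(cfg$delta0)), 0L
  )
  rownames(grid) <- NULL
  analysis <- grid[, c(
    "participant_id", "group", "video_id", "event_index", "session",
    "recall_type", "recalled", "n_central", "n_peripheral", "centrality_z"
  )]

  transcripts <- NULL
  ratings <- NULL
  if (cfg$make_text) {
    noise_pool <- .noise_pool()
    desc_words <- lapply(videos, function(v) {
      lapply(v$events, function(e) .hash_tokens(e$description))
    })
    names(desc_words) <- vids
    tkey <- paste(grid$participant_id, grid$video_id, grid$session, sep = "\r")
    grid_split <- split(seq_len(nrow(grid)), tkey)
    # deterministic transcript order
    grid_split <- grid_split[order(names(grid_split))]
    transcripts <- lapply(grid_split, function(ix) {
      rows <- grid[ix, ]
      rows <- rows[order(rows$event_index), ]
      segs <- list()
      for (r in which(rows$recalled == 1L)) {
        e <- rows$event_index[r]
        words <- desc_words[[rows$video_id[1]]][[e]]
        txt <- .recall_text(
          words, cfg$rho, stats::rpois(1, cfg$noise_words_rate), noise_pool
        )
        details <- c(
          lapply(seq_len(rows$n_central[r]), function(i) {
            detail_annotation("central", paste(sample(words, min(3L, length(words))), collapse = " "))
          }),
          lapply(seq_len(rows$n_peripheral[r]), function(i) {
            detail_annotation("peripheral", paste(sample(words, min(2L, length(words))), collapse = " "))
          })
        )
        segs[[length(segs) + 1L]] <- recall_segment(
          text = txt, category = "event", event_index = e, details = details
        )
      }
      # always at least one segment, so every cued video keeps a transcript
      # row on disk even when nothing was recalled
      if (!length(segs) || stats::runif(1) < cfg$comment_rate) {
        segs[[length(segs) + 1L]] <- recall_segment(
          text = paste(sample(noise_pool, 5L), collapse = " "),
          category = sample(c("comment", "other", "error"), 1L)
        )
      }
      sess <- rows$session[1]
      rt <- rows$recall_type[1]
      base_mu <- 3.5 - 0.3 * (sess != "day1") - 1.5 * (rt == "one")
      clamp15 <- function(x) pmin(5, pmax(1, round(x)))
      recall_transcript(
        participant_id = rows$participant_id[1], video_id = rows$video_id[1],
        session = sess, recall_type = rt, segments = segs,
        ratings = list(
          vividness = clamp15(stats::rnorm(1, base_mu, 1)),
          content = clamp15(stats::rnorm(1, base_mu, 1)),
          rehearsal = if (sess == "day1") NA_real_ else clamp15(stats::rnorm(1, 2.5, 1))
        ),
        group = rows$group[1]
      )
    })
    names(transcripts) <- NULL
    ratings <- do.call(rbind, lapply(transcripts, function(tr) {
      data.frame(
        participant_id = tr$participant_id, video_id = tr$video_id,
        session = tr$session, vividness = tr$ratings$vividness,
        content = tr$ratings$content, rehearsal = tr$ratings$rehearsal,
        stringsAsFactors = FALSE
      )
    }))
  }

  list(
    config = cfg, videos = videos, centrality = centrality,
    participants = participants, analysis = analysis,
    transcripts = transcripts, ratings = ratings,
    truth = list(u_p = u_p, w_v = w_v, eta = eta, prob = prob)
  )
}
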