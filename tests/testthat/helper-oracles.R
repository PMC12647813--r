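# Independent oracles and fixture builders. Each oracle recomputes a quantity
# by a route deliberately different from the package implementation (explicit
# loops, stats::aov, exhaustive search), so agreement is evidence rather than
# tautology.

# centrality by explicit loops: degree -> normalize -> population z-score
oracle_centrality <- function(S) {
  n <- nrow(S)
  raw <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) raw[i] <- raw[i] + S[i, j]
    }
  }
  norm <- raw / sum(raw)
  mu <- sum(norm) / n
  sdev <- sqrt(sum((norm - mu)^2) / n)
  list(raw = raw, norm = norm, z = (norm - mu) / sdev)
}

random_similarity <- function(n) {
  S <- matrix(stats::runif(n * n, -0.2, 1), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

as_similarity <- function(S, video_id = "vx") {
  structure(list(video_id = video_id, n = nrow(S), S = S),
    class = "narrec_similarity"
  )
}

# cosine by scalar loop
oracle_cosine <- function(u, v) {
  dot <- 0
  nu <- 0
  nv <- 0
  for (i in seq_along(u)) {
    dot <- dot + u[i] * v[i]
    nu <- nu + u[i]^2
    nv <- nv + v[i]^2
  }
  dot / sqrt(nu * nv)
}

# jaccard by element-wise membership loops
oracle_jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 && length(b) == 0) {
    return(0)
  }
  inter <- 0
  for (x in a) if (any(b == x)) inter <- inter + 1
  union_n <- length(b)
  for (x in a) if (!any(b == x)) union_n <- union_n + 1
  inter / union_n
}

# exhaustive maximum-cardinality matching under |dt| <= tol (recursive search
# over which obs each ref matches; feasible for <= ~10 boundaries)
oracle_max_matching <- function(ref, obs, tol) {
  recurse <- function(i, used) {
    if (i > length(ref)) {
      return(0L)
    }
    best <- recurse(i + 1L, used) # leave ref[i] unmatched
    for (j in seq_along(obs)) {
      if (!used[j] && abs(ref[i] - obs[j]) <= tol) {
        used[j] <- TRUE
        best <- max(best, 1L + recurse(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  recurse(1L, logical(length(obs)))
}

# ICC(2,1) via stats::aov mean squares
oracle_icc21 <- function(x) {
  n <- nrow(x)
  k <- ncol(x)
  long <- data.frame(
    y = as.vector(x),
    target = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ target + rater, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]
  msc <- ms[2]
  mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# ---- fixtures ----------------------------------------------------------------

fixture_videos <- function() {
  mk_events <- function(vid, descs) {
    lapply(seq_along(descs), function(i) {
      event_annotation(vid, i, (i - 1) * 10, i * 10 - 1, descs[i])
    })
  }
  list(
    video_annotation(
      "vidA", "The kitchen", 100,
      mk_events("vidA", c(
        "the dad drops the cup on the floor",
        "mum wipes the floor with a towel",
        "the dad picks up the broken cup",
        "the cat watches from the kitchen table",
        "mum pours coffee into a new cup",
        "the dad drinks the coffee smiling",
        "the cat jumps off the table",
        "mum laughs at the cat",
        "the dad opens the kitchen window",
        "a bird lands on the window sill"
      ))
    ),
    video_annotation(
      "vidB", "The park", 80,
      mk_events("vidB", c(
        "two sisters walk into the park",
        "the younger sister climbs a tree",
        "the older sister reads a book on a bench",
        "a dog chases a red ball past the bench",
        "the younger sister waves from the tree",
        "both sisters share a sandwich",
        "the dog returns the red ball",
        "the sisters leave the park at sunset"
      ))
    )
  )
}

fixture_transcript <- function(participant_id = "p01", video_id = "vidA",
                               session = "day1", group = "young",
                               segments = NULL) {
  if (is.null(segments)) {
    segments <- list(
      recall_segment("the dad drops the cup", "event", 1,
        details = list(
          detail_annotation("central", "drops the cup"),
          detail_annotation("peripheral", "on the floor")
        )
      ),
      recall_segment("mum cleans up", "event", 2,
        details = list(detail_annotation("central", "cleans"))
      ),
      recall_segment("I think there was music", "other")
    )
  }
  recall_transcript(participant_id, video_id, session, "multiple",
    segments,
    ratings = list(vividness = 4, content = 3), group = group
  )
}

# tiny study config for fast end-to-end tests (dots override the defaults)
small_config <- function(seed, ...) {
  args <- list(
    seed = seed, n_per_group = 4L, n_videos = 2L,
    events_per_video = c(8L, 10L)
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}

# paper-scale template used by the acceptance criteria (day1, no text)
paper_scale_config <- function(seed, ...) {
  args <- list(
    seed = seed, n_per_group = 28L, n_videos = 8L,
    events_per_video = c(15L, 15L), sessions = "day1", make_text = FALSE
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synthetic_config, args)
}
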