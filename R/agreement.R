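# Rater agreement: (1) event-boundary matching between two raters' boundary
# time sets with a temporal tolerance, scored as precision / recall / F1;
# (2) intraclass correlation for detail-scoring reliability; (3) a paired test
# on per-video event counts.

#' Boundary set
#'
#' Event-boundary times (seconds) identified by one rater in one video.
#'
#' @param video_id,rater_id identifiers.
#' @param times_s strictly increasing numeric vector of boundary times, all
#'   `>= 0`.
#' @export
boundary_set <- function(video_id, rater_id, times_s) {
  times_s <- as.numeric(times_s)
  if (length(times_s) && (any(times_s < 0) || any(diff(times_s) <= 0))) {
    stop("boundary times must be >= 0 and strictly increasing", call. = FALSE)
  }
  structure(
    list(video_id = video_id, rater_id = rater_id, times_s = times_s),
    class = "narrec_boundaries"
  )
}

# Non-crossing matching of two sorted time lists under |dt| <= tol:
# maximize the number of matched pairs, then minimize the total |dt|.
# For 1-D points an optimal matching can always be taken non-crossing
# (uncrossing two crossed pairs never increases cost or breaks tolerance),
# so a quadratic DP over the two sorted lists is exact. Tie preference
# order (equal cardinality and cost): skip the later reference, then skip
# the later observation, then match — which resolves the two-candidates-
# at-exact-tolerance case toward the earlier reference/observed time.
.match_dp <- function(ref, obs, tol) {
  nr <- length(ref)
  no <- length(obs)
  card <- matrix(0L, nr + 1L, no + 1L)
  cost <- matrix(0, nr + 1L, no + 1L)
  take <- matrix(0L, nr + 1L, no + 1L) # 1 = skip ref, 2 = skip obs, 3 = match
  for (i in seq_len(nr)) {
    for (j in seq_len(no)) {
      best_c <- card[i, j + 1L]
      best_w <- cost[i, j + 1L]
      best_t <- 1L
      if (card[i + 1L, j] > best_c ||
        (card[i + 1L, j] == best_c && cost[i + 1L, j] < best_w)) {
        best_c <- card[i + 1L, j]
        best_w <- cost[i + 1L, j]
        best_t <- 2L
      }
      d <- abs(ref[i] - obs[j])
      if (d <= tol) {
        mc <- card[i, j] + 1L
        mw <- cost[i, j] + d
        if (mc > best_c || (mc == best_c && mw < best_w)) {
          best_c <- mc
          best_w <- mw
          best_t <- 3L
        }
      }
      card[i + 1L, j + 1L] <- best_c
      cost[i + 1L, j + 1L] <- best_w
      take[i + 1L, j + 1L] <- best_t
    }
  }
  pairs <- matrix(numeric(0), 0, 2)
  i <- nr
  j <- no
  while (i > 0L && j > 0L) {
    t <- take[i + 1L, j + 1L]
    if (t == 3L) {
      pairs <- rbind(c(ref[i], obs[j]), pairs)
      i <- i - 1L
      j <- j - 1L
    } else if (t == 1L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  pairs
}

#' Match two raters' event boundaries with a temporal tolerance
#'
#' Boundaries are considered to match when they fall within `tol_s` seconds of
#' each other (inclusive). The matching is one-to-one and optimal: it has
#' maximum cardinality and, among maximum matchings, minimum total `|dt|`
#' (computed by a deterministic dynamic program over the two sorted lists).
#' Precision is the fraction of `obs` boundaries matched, recall the fraction
#' of `ref` boundaries matched, F1 their harmonic mean; `mean_abs_diff_s` is
#' the mean `|dt|` over matched pairs (NA when there are none).
#'
#' @param ref,obs `narrec_boundaries` (or plain numeric vectors of times).
#' @param tol_s matching tolerance in seconds, default 1.
#' @return `narrec_agreement`: list with `precision`, `recall`, `f1`,
#'   `mean_abs_diff_s`, and `matches` (two-column matrix ref_time, obs_time).
#' @examples
#' match_boundaries(c(10, 20, 30), c(10.5, 29.8, 45))
#' @export
match_boundaries <- function(ref, obs, tol_s = 1.0) {
  if (inherits(ref, "narrec_boundaries")) ref <- ref$times_s
  if (inherits(obs, "narrec_boundaries")) obs <- obs$times_s
  stopifnot(is.numeric(ref), is.numeric(obs), tol_s > 0)
  ref <- sort(ref)
  obs <- sort(obs)
  if (length(ref) == 0L || length(obs) == 0L) {
    warning("empty boundary set: precision/recall defined as 0", call. = FALSE)
    return(structure(
      list(
        precision = 0, recall = 0, f1 = 0, mean_abs_diff_s = NA_real_,
        matches = matrix(numeric(0), 0, 2, dimnames = list(NULL, c("ref", "obs")))
      ),
      class = "narrec_agreement"
    ))
  }
  pairs <- .match_dp(ref, obs, tol_s)
  colnames(pairs) <- c("ref", "obs")
  m <- nrow(pairs)
  p <- m / length(obs)
  r <- m / length(ref)
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(
    list(
      precision = p, recall = r, f1 = f1,
      mean_abs_diff_s = if (m > 0) mean(abs(pairs[, 1] - pairs[, 2])) else NA_real_,
      matches = pairs
    ),
    class = "narrec_agreement"
  )
}

#' @export
print.narrec_agreement <- function(x, ...) {
  cat(sprintf(
    "boundary agreement: P = %.3f, R = %.3f, F1 = %.3f, mean |dt| = %s s (%d matches)\n",
    x$precision, x$recall, x$f1,
    if (is.na(x$mean_abs_diff_s)) "NA" else sprintf("%.3f", x$mean_abs_diff_s),
    nrow(x$matches)
  ))
  invisible(x)
}

#' Intraclass correlation, two-way random-effects model
#'
#' ICC(2,1): single-rater, absolute agreement, from the two-way ANOVA
#' decomposition of an `n x k` table (n targets rated by the same k raters,
#' both considered random samples):
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + k (MS_C - MS_E)/n}}
#' with `MS_R` the between-target, `MS_C` the between-rater, and `MS_E` the
#' residual mean square. `type = "average"` returns the average-measures form
#' ICC(2,k).
#'
#' @param ratings numeric matrix or data.frame, rows = targets, columns =
#'   raters, no missing cells.
#' @param type `"single"` (default, ICC(2,1)) or `"average"` (ICC(2,k)).
#' @return the ICC, a number `<= 1`.
#' @export
icc_two_way_random <- function(ratings, type = c("single", "average")) {
  type <- match.arg(type)
  x <- as.matrix(ratings)
  if (!is.numeric(x) || anyNA(x)) stop("ratings must be a complete numeric table", call. = FALSE)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L || k < 2L) stop("need >= 2 targets and >= 2 raters", call. = FALSE)
  grand <- mean(x)
  if (sum((x - grand)^2) == 0) stop("constant ratings: ICC undefined", call. = FALSE)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "single") {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (msc - mse) / n)
  }
}

#' Paired comparison of per-video event counts between two raters
#'
#' Two-sided paired t-test on the within-video differences in the number of
#' events each rater identified. All-zero differences return p = 1 with a
#' warning (no evidence of any difference, and the t statistic is undefined).
#'
#' @param counts_a,counts_b equal-length integer vectors, one entry per video.
#' @return list with `statistic`, `df`, `p`, `mean_diff`.
#' @export
compare_event_counts <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b), length(counts_a) >= 2L)
  d <- as.numeric(counts_a) - as.numeric(counts_b)
  if (all(d == 0)) {
    warning("identical counts in every video: p = 1", call. = FALSE)
    return(list(statistic = 0, df = length(d) - 1L, p = 1, mean_diff = 0))
  }
  if (stats::sd(d) == 0) {
    # constant nonzero difference: t is infinite, p -> 0
    return(list(
      statistic = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0,
      mean_diff = mean(d)
    ))
  }
  tt <- stats::t.test(d)
  list(
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p = tt$p.value, mean_diff = mean(d)
  )
}
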