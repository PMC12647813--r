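# Mixed-model inference on the long-format analysis table: logistic models on
# event recall, Poisson models on detail counts, Gaussian models on ratings —
# all with participant and video random intercepts — plus Type III Wald chi^2
# tests, simple slopes, Pearson correlations, and a simulation-based power
# engine with exact binomial confidence intervals.
#
# Categorical coding everywhere: treatment contrasts with reference levels
# young (group), day1 (session), multiple (recall_type). Wald (not profile)
# confidence intervals, beta +/- 1.96 SE, matching how coefficients are
# conventionally reported alongside SEs. No multiple-testing correction is
# applied.

#' Model specification
#'
#' @param family `"binomial"`, `"poisson"` or `"gaussian"`.
#' @param response column of the analysis table (e.g. `"recalled"`,
#'   `"n_central"`).
#' @param fixed character vector of fixed-effect terms over `group`,
#'   `session`, `recall_type`, `centrality_z` (interactions as `"a:b"`).
#' @param random random-intercept groupings, subset of
#'   `c("participant", "video", "event")` (default participant + video).
#' @export
model_spec <- function(family = c("binomial", "poisson", "gaussian"),
                       response, fixed,
                       random = c("participant", "video")) {
  family <- match.arg(family)
  stopifnot(is.character(response), length(response) == 1L, length(fixed) >= 1L)
  bad <- setdiff(random, c("participant", "video", "event"))
  if (length(bad)) stop("unknown random grouping: ", paste(bad, collapse = ", "), call. = FALSE)
  structure(
    list(family = family, response = response, fixed = fixed, random = random),
    class = "narrec_modelspec"
  )
}

.prepare_table <- function(rows) {
  df <- as.data.frame(rows)
  if ("group" %in% names(df)) df$group <- factor(df$group, levels = .groups)
  if ("session" %in% names(df)) df$session <- factor(df$session, levels = .sessions)
  if ("recall_type" %in% names(df)) df$recall_type <- factor(df$recall_type, levels = .recall_types)
  df$participant_id <- factor(df$participant_id)
  df$video_id <- factor(df$video_id)
  if (all(c("video_id", "event_index") %in% names(df))) {
    df$event_id <- factor(paste(df$video_id, df$event_index, sep = ":"))
  }
  droplevels(df)
}

#' Fit a generalized linear mixed model on the analysis table
#'
#' Thin, contract-enforcing wrapper around lme4 (`glmer` for binomial and
#' Poisson with the canonical links, `lmer` for Gaussian): documented factor
#' codings, fixed optimizer settings (bobyqa, 500 iterations), Wald
#' inference, and a Type III Wald chi^2 table for every fixed term. Laplace
#' approximation by default; `nAGQ = 0` selects lme4's faster penalized
#' least-squares step, used by the simulation loops.
#'
#' @param rows analysis table (data.frame of participant x video x event x
#'   session rows).
#' @param spec a [model_spec()].
#' @param nAGQ integer, passed to `glmer` (ignored for Gaussian).
#' @return `narrec_fit`: list with `coefficients` (estimate, se, z, ci_low,
#'   ci_high, p), `type3` (chisq, df, p per term), `vcov`, `converged`,
#'   `n_obs`, and the underlying lme4 `model`.
#' @export
fit_glmm <- function(rows, spec, nAGQ = 1L) {
  stopifnot(inherits(spec, "narrec_modelspec"))
  df <- .prepare_table(rows)
  y <- df[[spec$response]]
  if (is.null(y)) stop("response column not found: ", spec$response, call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("degenerate outcome: response '", spec$response, "' is constant", call. = FALSE)
  }
  if (spec$family == "binomial" && !all(y %in% c(0, 1))) {
    stop("binomial response must be 0/1", call. = FALSE)
  }
  if (spec$family == "poisson" && any(y < 0 | y != round(y))) {
    stop("poisson response must be non-negative counts", call. = FALSE)
  }
  re_cols <- c(participant = "participant_id", video = "video_id", event = "event_id")
  for (r in spec$random) {
    if (nlevels(df[[re_cols[[r]]]]) < 2L) {
      stop("random grouping '", r, "' has fewer than 2 levels", call. = FALSE)
    }
  }
  fml <- stats::as.formula(paste(
    spec$response, "~", paste(spec$fixed, collapse = " + "), "+",
    paste(sprintf("(1 | %s)", re_cols[spec$random]), collapse = " + ")
  ))
  if (spec$family == "gaussian") {
    model <- lme4::lmer(fml,
      data = df, REML = FALSE,
      control = lme4::lmerControl(optimizer = "bobyqa", optCtrl = list(maxfun = 500000))
    )
  } else {
    model <- lme4::glmer(fml,
      data = df, family = spec$family, nAGQ = nAGQ,
      control = lme4::glmerControl(
        optimizer = "bobyqa", optCtrl = list(maxfun = 500000),
        calc.derivs = nAGQ > 0
      )
    )
  }
  beta <- lme4::fixef(model)
  V <- as.matrix(stats::vcov(model))
  se <- sqrt(diag(V))
  z <- beta / se
  coefs <- data.frame(
    term = names(beta), estimate = unname(beta), se = unname(se),
    z = unname(z),
    ci_low = unname(beta - 1.96 * se), ci_high = unname(beta + 1.96 * se),
    p = unname(2 * stats::pnorm(-abs(z))),
    stringsAsFactors = FALSE
  )
  # a singular fit (variance component at the boundary) is a legitimate
  # converged solution, not an optimizer failure
  msgs <- model@optinfo$conv$lme4$messages
  msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  conv <- length(msgs) == 0 && model@optinfo$conv$opt == 0
  X <- stats::model.matrix(model)
  assign <- attr(X, "assign")
  term_labels <- attr(stats::terms(model), "term.labels")
  fit <- structure(
    list(
      spec = spec, coefficients = coefs, vcov = V, assign = assign,
      term_labels = term_labels, converged = conv, n_obs = nrow(df),
      model = model
    ),
    class = "narrec_fit"
  )
  fit$type3 <- do.call(rbind, lapply(term_labels, function(tl) {
    w <- type3_wald(fit, tl)
    data.frame(term = tl, chisq = w$chisq, df = w$df, p = w$p)
  }))
  if (!conv) {
    warning("model did not converge cleanly; inspect fit$model", call. = FALSE)
  }
  fit
}

#' @export
print.narrec_fit <- function(x, ...) {
  cat(sprintf(
    "%s mixed model on %s (n = %d, %sconverged)\n",
    x$spec$family, x$spec$response, x$n_obs, if (x$converged) "" else "NOT "
  ))
  print(x$coefficients, digits = 4, row.names = FALSE)
  cat("\nType III Wald chi-square tests:\n")
  print(x$type3, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Type III Wald chi-square test of a model term
#'
#' For the coefficients `b` belonging to `term` (all other terms present in
#' the model), the quadratic form `chi^2 = b' V^{-1} b` with `V` their
#' covariance block; `df = rank(V)`; p from the chi-square tail. For a
#' single-coefficient term this is exactly `(beta/SE)^2`.
#'
#' @param fit a `narrec_fit`.
#' @param term one of `fit$term_labels`.
#' @return list with `chisq`, `df`, `p`.
#' @export
type3_wald <- function(fit, term) {
  stopifnot(inherits(fit, "narrec_fit"))
  ti <- match(term, fit$term_labels)
  if (is.na(ti)) stop("term not in model: ", term, call. = FALSE)
  cols <- which(fit$assign == ti)
  b <- fit$coefficients$estimate[cols]
  V <- fit$vcov[cols, cols, drop = FALSE]
  qr_v <- qr(V)
  if (qr_v$rank < length(b)) stop("singular covariance block for term ", term, call. = FALSE)
  chisq <- drop(t(b) %*% solve(V, b))
  df <- qr_v$rank
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Simple slopes of a continuous predictor by moderator level
#'
#' The slope of `predictor` at each level of the interacting factor
#' `moderator`: for the reference level it is the predictor's main-effect
#' coefficient; for every other level the main effect plus the corresponding
#' interaction coefficient, with the SE from the delta rule on the coefficient
#' covariance (here, exact: the slope is linear in the coefficients).
#'
#' @param fit a `narrec_fit` containing a `moderator x predictor` interaction.
#' @param predictor continuous term name (default `"centrality_z"`).
#' @param moderator factor term name (default `"group"`).
#' @return data.frame with one row per moderator level: `level, estimate, se,
#'   ci_low, ci_high, z, p`.
#' @export
simple_slopes <- function(fit, predictor = "centrality_z", moderator = "group") {
  stopifnot(inherits(fit, "narrec_fit"))
  int_term <- c(
    paste(moderator, predictor, sep = ":"),
    paste(predictor, moderator, sep = ":")
  )
  int_term <- int_term[int_term %in% fit$term_labels]
  if (!length(int_term)) {
    stop(
      "no ", moderator, " x ", predictor, " interaction in the model",
      call. = FALSE
    )
  }
  nm <- fit$coefficients$term
  main_i <- match(predictor, nm)
  if (is.na(main_i)) stop("no main effect for ", predictor, call. = FALSE)
  int_cols <- which(fit$assign == match(int_term, fit$term_labels))
  levels_mod <- levels(stats::model.frame(fit$model)[[moderator]])
  ref <- levels_mod[1]
  rows <- lapply(levels_mod, function(lv) {
    w <- numeric(length(nm))
    w[main_i] <- 1
    if (lv != ref) {
      hit <- int_cols[grepl(paste0(moderator, lv), nm[int_cols], fixed = TRUE)]
      if (length(hit) != 1L) stop("cannot identify interaction column for level ", lv, call. = FALSE)
      w[hit] <- 1
    }
    est <- sum(w * fit$coefficients$estimate)
    se <- sqrt(drop(t(w) %*% fit$vcov %*% w))
    z <- est / se
    data.frame(
      level = lv, estimate = est, se = se,
      ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
      z = z, p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Pearson correlation with Fisher-transform confidence interval
#'
#' Product-moment correlation; p from the t distribution with `n - 2` df; 95%
#' CI via the Fisher z transform.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, finite, non-constant.
#' @param conf confidence level (default 0.95).
#' @return list with `r`, `df`, `ci_low`, `ci_high`, `p`.
#' @export
pearson_cor <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  df <- n - 2L
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tstat), df)
  }
  zr <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  half <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
  list(r = r, df = df, ci_low = tanh(zr - half), ci_high = tanh(zr + half), p = p)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The Beta-quantile form: lower bound `qbeta(alpha/2, x, n - x + 1)` (0 when
#' `x = 0`), upper bound `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#' For 0 successes the upper bound reduces to `1 - (alpha/2)^(1/n)`.
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return c(lower, upper).
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  stopifnot(x >= 0, x <= n, n >= 1)
  alpha <- 1 - conf
  low <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  high <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = low, upper = high)
}

#' Simulation-based power analysis for the group x centrality interaction
#'
#' Monte-Carlo power: `nsim` synthetic studies are generated from `template`
#' with the group x centrality interaction set to `effect`; each replicate is
#' scored by fitting the session-specific logistic mixed model
#' `recalled ~ group * centrality_z + (1 | participant) + (1 | video)` and
#' testing `term` with a Type III Wald chi-square at level `alpha`. Power is
#' the rejection fraction with an exact Clopper-Pearson 95% CI.
#' Non-converging replicates are excluded and counted (warning above 10%).
#'
#' @param template a `narrec_config`; its `sessions` are restricted to
#'   `session` and transcripts are skipped for speed.
#' @param effect true interaction coefficient on the logit scale.
#' @param nsim replicates (default 1000).
#' @param alpha test level (default 0.05).
#' @param seed integer; replicate r uses `template` reseeded with
#'   `seed + r`.
#' @param term tested term (default the interaction; `"centrality_z"` gives a
#'   type-I-error / power check for the main effect instead).
#' @param session which session's model to fit (default `"day1"`).
#' @param nAGQ lme4 integration setting for the replicate fits (default 0,
#'   the fast penalized least-squares step).
#' @return `narrec_power`: list with `nsim`, `n_significant`, `n_failed`,
#'   `power`, `ci_low`, `ci_high`, `alpha`, `effect`, `p_values`.
#' @export
power_simulation <- function(template, effect, nsim = 1000L, alpha = 0.05,
                             seed, term = "group:centrality_z",
                             session = "day1", nAGQ = 0L) {
  stopifnot(inherits(template, "narrec_config"), nsim >= 1L)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  spec <- model_spec("binomial", "recalled",
    fixed = c("group", "centrality_z", "group:centrality_z")
  )
  p_values <- rep(NA_real_, nsim)
  n_failed <- 0L
  for (r in seq_len(nsim)) {
    cfg <- template
    cfg$beta_interaction <- effect
    cfg$sessions <- session
    cfg$make_text <- FALSE
    cfg$seed <- (template$seed + seed + r) %% (2147483647L - 1000000L)
    sim <- generate_study(cfg)
    fit <- tryCatch(
      suppressWarnings(fit_glmm(sim$analysis, spec, nAGQ = nAGQ)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
      next
    }
    p_values[r] <- type3_wald(fit, term)$p
  }
  if (n_failed > 0.1 * nsim) {
    warning(n_failed, " of ", nsim, " replicates failed to converge", call. = FALSE)
  }
  ok <- !is.na(p_values)
  n_eff <- sum(ok)
  n_sig <- sum(p_values[ok] < alpha)
  ci <- clopper_pearson(n_sig, max(n_eff, 1L))
  structure(
    list(
      nsim = n_eff, n_significant = n_sig, n_failed = n_failed,
      power = n_sig / max(n_eff, 1L),
      ci_low = unname(ci[1]), ci_high = unname(ci[2]),
      alpha = alpha, effect = effect, p_values = p_values
    ),
    class = "narrec_power"
  )
}

#' @export
print.narrec_power <- function(x, ...) {
  cat(sprintf(
    "power = %.3f (%d/%d significant at alpha = %g), 95%% CI [%.4f, %.4f]%s\n",
    x$power, x$n_significant, x$nsim, x$alpha, x$ci_low, x$ci_high,
    if (x$n_failed > 0) sprintf(" (%d failed replicates)", x$n_failed) else ""
  ))
  invisible(x)
}
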