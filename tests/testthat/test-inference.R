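# a single shared paper-scale fit keeps this file fast
shared_fit_env <- new.env()
shared_sim <- function() {
  if (is.null(shared_fit_env$sim)) {
    shared_fit_env$sim <- generate_study(
      paper_scale_config(seed = 77, beta_interaction = 0.2)
    )
  }
  shared_fit_env$sim
}
shared_fit <- function() {
  if (is.null(shared_fit_env$fit)) {
    shared_fit_env$fit <- fit_glmm(
      shared_sim()$analysis,
      model_spec("binomial", "recalled",
        fixed = c("group", "centrality_z", "group:centrality_z")
      ),
      nAGQ = 0
    )
  }
  shared_fit_env$fit
}

test_that("model_spec validates family and random groupings", {
  expect_error(model_spec("gamma", "recalled", "group"))
  expect_error(
    model_spec("binomial", "recalled", "group", random = "scanner"),
    "unknown random grouping"
  )
})

test_that("with zero random-effect variance the GLMM matches an ordinary GLM", {
  cfg <- paper_scale_config(
    seed = 55, sigma_participant = 0, sigma_video = 0,
    beta_centrality = 0.3
  )
  sim <- generate_study(cfg)
  spec <- model_spec("binomial", "recalled", fixed = c("group", "centrality_z"))
  fit <- suppressWarnings(fit_glmm(sim$analysis, spec))
  oracle <- stats::glm(recalled ~ group + centrality_z,
    data = transform(sim$analysis, group = factor(group, c("young", "older"))),
    family = binomial
  )
  expect_equal(fit$coefficients$estimate, unname(coef(oracle)), tolerance = 1e-3)
})

test_that("degenerate and malformed inputs error cleanly", {
  sim <- shared_sim()
  tab <- sim$analysis
  tab$recalled <- 1L
  spec <- model_spec("binomial", "recalled", fixed = c("group", "centrality_z"))
  expect_error(fit_glmm(tab, spec), "degenerate outcome")
  tab2 <- sim$analysis
  tab2$recalled <- tab2$recalled + 0.5
  expect_error(fit_glmm(tab2, spec), "0/1")
  expect_error(
    fit_glmm(sim$analysis, model_spec("poisson", "centrality_z", "group")),
    "counts"
  )
  one_v <- sim$analysis[sim$analysis$video_id == "video01", ]
  expect_error(fit_glmm(one_v, spec), "fewer than 2 levels")
})

test_that("coefficient table satisfies the Wald identities", {
  fit <- shared_fit()
  co <- fit$coefficients
  expect_equal(co$ci_low, co$estimate - 1.96 * co$se, tolerance = 1e-12)
  expect_equal(co$ci_high, co$estimate + 1.96 * co$se, tolerance = 1e-12)
  # 1-df Type III Wald chi2 equals (beta/se)^2
  w <- type3_wald(fit, "centrality_z")
  i <- match("centrality_z", co$term)
  expect_equal(w$chisq, (co$estimate[i] / co$se[i])^2, tolerance = 1e-10)
  expect_equal(w$df, 1)
  expect_true(fit$converged)
  expect_equal(fit$n_obs, nrow(shared_sim()$analysis))
})

test_that("chi-square tail gives the textbook p-value", {
  expect_equal(pchisq(3.841, 1, lower.tail = FALSE), 0.0500, tolerance = 1e-3)
  fit <- shared_fit()
  t3 <- fit$type3
  expect_setequal(t3$term, c("group", "centrality_z", "group:centrality_z"))
  expect_true(all(t3$p >= 0 & t3$p <= 1))
  expect_error(type3_wald(fit, "not_a_term"), "not in model")
})

test_that("a two-coefficient term with diagonal covariance sums squared z-scores", {
  fit <- shared_fit()
  # splice a constructed 2-coefficient block into a copy of the fit
  fake <- fit
  fake$term_labels <- c(fit$term_labels, "constructed")
  fake$assign <- c(fit$assign, rep(length(fake$term_labels), 2L))
  fake$coefficients <- rbind(
    fit$coefficients,
    data.frame(
      term = c("c1", "c2"), estimate = c(0.6, -0.8), se = c(0.2, 0.4),
      z = NA, ci_low = NA, ci_high = NA, p = NA
    )
  )
  V <- diag(c(diag(fit$vcov), 0.2^2, 0.4^2))
  fake$vcov <- V
  w <- type3_wald(fake, "constructed")
  expect_equal(w$chisq, (0.6 / 0.2)^2 + (-0.8 / 0.4)^2, tolerance = 1e-12)
  expect_equal(w$df, 2)
})

test_that("simple slopes reproduce the coding identities", {
  fit <- shared_fit()
  ss <- simple_slopes(fit)
  co <- fit$coefficients
  b_c <- co$estimate[co$term == "centrality_z"]
  b_int <- co$estimate[co$term == "groupolder:centrality_z"]
  # reference-group slope is the main-effect coefficient
  expect_equal(ss$estimate[ss$level == "young"], b_c, tolerance = 1e-12)
  expect_equal(ss$estimate[ss$level == "older"], b_c + b_int, tolerance = 1e-12)

  # constructed coefficients: 0.10 and -0.097 give a 0.003 non-reference slope
  fake <- fit
  fake$coefficients$estimate[co$term == "centrality_z"] <- 0.10
  fake$coefficients$estimate[co$term == "groupolder:centrality_z"] <- -0.097
  ss2 <- simple_slopes(fake)
  expect_equal(ss2$estimate[ss2$level == "older"], 0.003, tolerance = 1e-12)

  # zero interaction: identical slopes in both groups
  fake2 <- fit
  fake2$coefficients$estimate[co$term == "groupolder:centrality_z"] <- 0
  ss3 <- simple_slopes(fake2)
  expect_equal(ss3$estimate[1], ss3$estimate[2], tolerance = 1e-12)

  no_int <- fit_glmm(
    shared_sim()$analysis,
    model_spec("binomial", "recalled", fixed = c("group", "centrality_z")),
    nAGQ = 0
  )
  expect_error(simple_slopes(no_int), "interaction")
})

test_that("poisson detail model recovers the generating coefficients roughly", {
  cfg <- paper_scale_config(seed = 91, gamma_centrality = 0.4)
  sim <- generate_study(cfg)
  tab <- sim$analysis[sim$analysis$recalled == 1, ]
  fit <- fit_glmm(
    tab, model_spec("poisson", "n_central", fixed = c("group", "centrality_z")),
    nAGQ = 0
  )
  co <- fit$coefficients[fit$coefficients$term == "centrality_z", ]
  expect_lt(abs(co$estimate - 0.4), 4 * co$se)
})

test_that("gaussian family fits ratings via lmer", {
  sim <- generate_study(small_config(seed = 61))
  tab <- merge(
    unique(sim$analysis[, c("participant_id", "group", "video_id", "session")]),
    sim$ratings
  )
  fit <- fit_glmm(tab, model_spec("gaussian", "vividness", fixed = c("group", "session")))
  expect_s4_class(fit$model, "lmerMod")
  expect_true("sessionday2" %in% fit$coefficients$term)
})

test_that("pearson correlation: closed-form values, oracle, errors", {
  expect_equal(pearson_cor(1:10, 2 * (1:10) + 1)$r, 1.0)
  res <- pearson_cor(c(1, 2, 3), c(1, 2, 4))
  expect_equal(res$r, 0.9820, tolerance = 1e-4)
  expect_equal(res$df, 1)

  set.seed(71)
  for (i in 1:10) {
    x <- rnorm(20)
    y <- rnorm(20)
    mine <- pearson_cor(x, y)
    ct <- cor.test(x, y)
    expect_equal(mine$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ct$p.value, tolerance = 1e-12)
    expect_equal(mine$ci_low, ct$conf.int[1], tolerance = 1e-9)
    expect_equal(mine$ci_high, ct$conf.int[2], tolerance = 1e-9)
  }
  expect_error(pearson_cor(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_cor(c(1, NA, 3), c(1, 2, 3)), "non-finite")
})

test_that("pearson test is calibrated under independence", {
  set.seed(81)
  p <- vapply(1:1000, function(i) pearson_cor(rnorm(25), rnorm(25))$p, numeric(1))
  rate <- mean(p < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.075)
})

test_that("clopper_pearson endpoints and invariants", {
  expect_equal(clopper_pearson(0, 1000)[["upper"]], 1 - 0.025^(1 / 1000), tolerance = 1e-12)
  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)
  expect_equal(clopper_pearson(10, 10)[["upper"]], 1)
  ci <- clopper_pearson(7, 20)
  expect_lt(ci[["lower"]], 7 / 20)
  expect_gt(ci[["upper"]], 7 / 20)
  # agrees with binom.test
  bt <- binom.test(7, 20)$conf.int
  expect_equal(unname(ci), c(bt[1], bt[2]), tolerance = 1e-9)
})

test_that("power simulation detects a strong interaction and is reproducible", {
  cfg <- synthetic_config(
    seed = 3, n_per_group = 10L, n_videos = 4L,
    events_per_video = c(9L, 9L), sigma_participant = 0.2, sigma_video = 0.2
  )
  res <- power_simulation(cfg, effect = 1.0, nsim = 25L, seed = 42)
  expect_gte(res$power, 0.9)
  expect_equal(res$power, res$n_significant / res$nsim)
  expect_lte(res$ci_low, res$power)
  expect_gte(res$ci_high, res$power)
  res2 <- power_simulation(cfg, effect = 1.0, nsim = 25L, seed = 42)
  expect_identical(res$p_values, res2$p_values)
})
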