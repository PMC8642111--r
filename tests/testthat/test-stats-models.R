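# small simulated mixed-model data with known structure
sim_mixed <- function(n_part = 20, n_obs = 8, group_effect = 0,
                      part_sd = 0.7, resid_sd = 1, seed = 1) {
  withr::with_seed(seed, {
    d <- expand.grid(obs = seq_len(n_obs),
                     participant = sprintf("p%02d", seq_len(n_part)))
    d$group <- ifelse(as.integer(factor(d$participant)) %% 2 == 0,
                      "young", "older")
    u <- rnorm(n_part, 0, part_sd)
    d$y <- 2 + group_effect * (d$group == "older") +
      u[as.integer(factor(d$participant))] + rnorm(nrow(d), 0, resid_sd)
  })
  d
}

test_that("intercept-only fit on balanced data recovers the grand mean", {
  d <- sim_mixed(seed = 7)
  f <- fit_mixed_model("y ~ 1 + (1|participant)", d)
  expect_true(f$converged)
  expect_equal(unname(lme4::fixef(f$model)), mean(d$y), tolerance = 1e-6)
})

test_that("the AIC identity holds for every fit", {
  d <- sim_mixed(seed = 3, group_effect = 0.5)
  for (fml in c("y ~ 1 + (1|participant)",
                "y ~ group + (1|participant)")) {
    f <- fit_mixed_model(fml, d)
    expect_equal(f$aic, 2 * f$npar - 2 * f$loglik, tolerance = 1e-8)
  }
})

test_that("a planted fixed effect is recovered within its 95% CI", {
  hits <- vapply(1:20, function(s) {
    d <- sim_mixed(n_part = 45, n_obs = 24, group_effect = -0.17,
                   part_sd = 0.3, resid_sd = 0.5, seed = 100 + s)
    f <- fit_mixed_model("y ~ group + (1|participant)", d)
    est <- lme4::fixef(f$model)[2]   # sum coding: older vs mean
    se <- sqrt(diag(as.matrix(stats::vcov(f$model))))[2]
    # contr.sum codes older as +1, young as -1: coefficient is half the
    # group difference
    abs(est * 2 - (-0.17)) < 1.96 * 2 * se
  }, logical(1))
  expect_gte(sum(hits), 17)          # 95% coverage, binomial slack
})

test_that("zero slope variance raises the singular flag in most runs", {
  flags <- vapply(1:12, function(s) {
    withr::with_seed(200 + s, {
      d <- data.frame(p = rep(sprintf("p%02d", 1:16), each = 10),
                      c = rep(c("a", "b"), 80))
      d$y <- rnorm(160) + rep(rnorm(16), each = 10)
    })
    fit_mixed_model("y ~ c + (c|p)", d)$singular
  }, logical(1))
  expect_gt(mean(flags), 0.5)
})

test_that("the ladder acceptance rule honors the AIC-2 boundary", {
  cand <- function(aic, converged = TRUE, singular = FALSE)
    structure(list(aic = aic, converged = converged, singular = singular),
              class = "av_fit")
  rule <- avdegrade:::ladder_accept
  expect_false(rule(100, cand(98.1)))        # drop of 1.9: keep simpler
  expect_true(rule(100, cand(98.0)))         # drop of exactly 2: accept
  expect_true(rule(100, cand(97.5)))
  expect_false(rule(100, cand(90, singular = TRUE)))   # singular: skip
  expect_false(rule(100, cand(90, converged = FALSE))) # unconverged: skip
})

test_that("the ladder selects better models and ignores rejected rungs", {
  d <- sim_mixed(n_part = 24, n_obs = 12, group_effect = 0.8, seed = 11)
  withr::with_seed(50, d$junk <- rnorm(nrow(d)))
  base <- "y ~ 1 + (1|participant)"
  better <- "y ~ group + (1|participant)"
  junk <- "y ~ group + junk + (1|participant)"
  sel <- aic_ladder(list(base, better), d)
  expect_equal(deparse(sel$formula[[3]])[1], deparse(as.formula(better)[[3]])[1])
  # appending a candidate that is rejected leaves the selection unchanged
  sel2 <- aic_ladder(list(base, better, junk), d)
  expect_equal(sel2$aic, sel$aic)
  expect_false(attr(sel2, "ladder")$accepted[3])
  expect_error(aic_ladder(list("y ~ nosuch + (1|participant)"), d),
               "failed")
})

test_that("wald_anova gives the single-contrast Wald identity", {
  d <- sim_mixed(seed = 21, group_effect = 0.4)
  f <- fit_mixed_model("y ~ group + (1|participant)", d)
  w <- wald_anova(f)
  est <- lme4::fixef(f$model)[2]
  se <- sqrt(diag(as.matrix(stats::vcov(f$model))))[2]
  row <- w[w$term == "group", ]
  expect_equal(row$chisq, unname((est / se)^2), tolerance = 1e-6)
  expect_equal(row$df, 1)
  expect_equal(row$p, unname(1 - pchisq((est / se)^2, 1)), tolerance = 1e-9)
})

test_that("wald_anova type-I error is near nominal under the null", {
  rej <- vapply(1:100, function(s) {
    d <- sim_mixed(n_part = 30, n_obs = 8, group_effect = 0,
                   seed = 300 + s)
    w <- wald_anova(fit_mixed_model("y ~ group + (1|participant)", d))
    w$p[w$term == "group"] < 0.05
  }, logical(1))
  # binomial(100, 0.05) band, allowing the mild small-sample inflation of
  # asymptotic Wald tests
  expect_gte(mean(rej), 0.005)
  expect_lte(mean(rej), 0.12)
})

test_that("post-hoc corrections order and cap as expected", {
  # frozen step-up example for the FDR procedure
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  d <- sim_mixed(n_part = 24, n_obs = 16, seed = 31)
  withr::with_seed(32,
    d$cond <- sample(letters[1:4], nrow(d), replace = TRUE))
  d$y <- d$y + 0.5 * (d$cond == "a")
  f <- fit_mixed_model("y ~ cond + group + (1|participant)", d)
  bon <- posthoc_contrasts(f, "cond", "bonferroni")
  fdr <- posthoc_contrasts(f, "cond", "fdr")
  raw <- summary(emmeans::contrast(
    emmeans::emmeans(f$model, "cond", lmer.df = "asymptotic"),
    method = "pairwise", adjust = "none"))$p.value
  expect_equal(bon$contrast, fdr$contrast)
  expect_true(all(bon$p >= fdr$p - 1e-12))
  expect_true(all(fdr$p >= raw - 1e-12))
  expect_true(all(bon$p <= 1))
  expect_equal(bon$p, pmin(raw * length(raw), 1), tolerance = 1e-9)
  # a single comparison needs no correction under either scheme
  fg <- posthoc_contrasts(f, "group", "bonferroni")
  fg2 <- posthoc_contrasts(f, "group", "fdr")
  expect_equal(fg$p, fg2$p)
  expect_error(posthoc_contrasts(f, "nosuch"), "not in the model")
})
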