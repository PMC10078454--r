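# Standardization, mixed-model contrasts, random forest, rating models.

test_that("standardize_features z-scores with log for Hz measures", {
  sc <- small_corpus()
  std <- standardize_features(sc$features)
  for (f in profile_fields()) {
    v <- std[[f]]
    expect_equal(mean(v, na.rm = TRUE), 0, tolerance = 1e-9)
    expect_equal(sd(v, na.rm = TRUE), 1, tolerance = 1e-9)
  }
  # stored transform: reapplying to the same table is idempotent
  tr <- attr(std, "transform")
  again <- apply_transform(sc$features, tr)
  expect_equal(again$f0_median_st, std$f0_median_st, tolerance = 1e-12)
  # log transform: doubling an Hz column shifts the pre-z value by log(2)
  doubled <- sc$features
  doubled$f1_hz <- doubled$f1_hz * 2
  std2 <- apply_transform(doubled, tr)
  expect_equal(std2$f1_hz - std$f1_hz,
               rep(log(2) / tr$scale[["f1_hz"]], nrow(std)),
               tolerance = 1e-9)
  # zero-variance column: warned and left at 0
  cst <- sc$features
  cst$novelty <- 5
  expect_warning(std3 <- standardize_features(cst, fields = "novelty"),
                 "zero-variance")
  expect_true(all(std3$novelty == 0))
})

test_that("condition contrasts achieve nominal coverage on null data", {
  set.seed(31)
  hits <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    tab <- simulate_feature_table(n_speakers = 20, takes = 2)
    tab$f0_median_st <- scale(tab$f0_median_st)[, 1]
    eff <- estimate_condition_effects(tab, fields = "f0_median_st")
    hits <- hits + (eff$lo[1] <= 0 & eff$hi[1] >= 0)
  }
  expect_gt(hits / n_rep, 0.92)
  expect_lt(hits / n_rep, 0.98)
})

test_that("condition contrasts recover simulated effects", {
  set.seed(32)
  tab <- simulate_feature_table(
    n_speakers = 33, takes = 3,
    effect = c(relaxed = 0, real = 0.6, concealed = 0.3, pretended = 1.0)
  )
  tab$f0_median_st <- (tab$f0_median_st - mean(tab$f0_median_st)) /
    sd(tab$f0_median_st)
  eff <- estimate_condition_effects(tab, fields = "f0_median_st")
  # effects were injected at 0.6/0.3/1.0 raw, table then standardized;
  # verify ordering and robustness flags rather than raw magnitudes
  est <- setNames(eff$contrast, eff$condition)
  expect_true(est["pretended"] > est["real"] &&
                est["real"] > est["concealed"])
  expect_true(all(eff$robust))
})

test_that("permuting condition labels nullifies the contrasts", {
  set.seed(33)
  tab <- simulate_feature_table(
    n_speakers = 25, takes = 2,
    effect = c(relaxed = 0, real = 0.8, concealed = 0.4, pretended = 1.2)
  )
  covered <- 0
  n_perm <- 60
  for (p in seq_len(n_perm)) {
    perm <- tab
    perm$f0_median_st <- sample(perm$f0_median_st)
    eff <- estimate_condition_effects(perm, fields = "f0_median_st")
    covered <- covered + mean(eff$lo <= 0 & eff$hi >= 0)
  }
  expect_gt(covered / n_perm, 0.88)
})

test_that("rf_classify is at chance for random labels, perfect when separable", {
  set.seed(34)
  n <- 240
  tab <- data.frame(matrix(rnorm(n * 19), n, 19))
  names(tab) <- profile_fields()
  tab$condition <- factor(sample(rep(conditions(), n / 4)))
  rf <- rf_classify(tab, n_reps = 25, n_tree = 300)
  expect_equal(unname(rf$accuracy["median"]), 0.25, tolerance = 0.03)
  expect_true(all(abs(rowSums(rf$confusion) - 1) < 1e-9))
  # perfectly separable features
  sep <- tab
  sep$f0_median_st <- as.integer(sep$condition) + rnorm(n, 0, 0.05)
  rf2 <- rf_classify(sep, n_reps = 10, n_tree = 200)
  expect_gt(rf2$accuracy["median"], 0.95)
  expect_equal(names(which.max(rf2$importance)), "f0_median_st")
  # a class with < 3 rows is rejected
  bad <- tab[c(which(tab$condition == "real")[1:2],
               which(tab$condition != "real")[1:60]), ]
  expect_error(rf_classify(bad, n_reps = 2), ">= 3 rows")
})

test_that("rf_classify separates the synthetic corpus above chance", {
  sc <- small_corpus()
  rf <- effortvoice:::with_seed(7, rf_classify(sc$features, n_reps = 10,
                                               n_tree = 300))
  expect_gt(rf$accuracy["median"], 0.25)
  expect_true(all(abs(rowSums(rf$confusion) - 1) < 1e-9))
})

test_that("simulate_ratings responds to its coefficients", {
  sc <- small_corpus()
  std <- standardize_features(sc$features)
  # all-zero coefficients: ratings unrelated to pitch
  spec0 <- rating_model_spec(coefficients = c(f0_median_st = 0))
  r0 <- simulate_ratings(std, spec0, n_listeners = 20,
                         ratings_per_listener = 40, seed = 5)
  m0 <- merge(r0, std[, c("id", "f0_median_st")], by.x = "sound", by.y = "id")
  expect_lt(abs(coef(lm(rating ~ f0_median_st, m0))[2]), 0.03)
  # positive pitch coefficient: ratings rise across pitch terciles
  specp <- rating_model_spec(coefficients = c(f0_median_st = 0.2))
  rp <- simulate_ratings(std, specp, n_listeners = 20,
                         ratings_per_listener = 40, seed = 5)
  mp <- merge(rp, std[, c("id", "f0_median_st")], by.x = "sound", by.y = "id")
  terc <- cut(mp$f0_median_st, quantile(mp$f0_median_st, 0:3 / 3),
              include.lowest = TRUE)
  means <- tapply(mp$rating, terc, mean)
  expect_true(all(diff(means) > 0))
  # determinism
  expect_identical(simulate_ratings(std, specp, 5, 10, seed = 9),
                   simulate_ratings(std, specp, 5, 10, seed = 9))
})

test_that("fit_rating_model recovers simulated coefficients", {
  sc <- small_corpus()
  std <- standardize_features(sc$features)
  spec <- rating_model_spec()
  r <- simulate_ratings(std, spec, n_listeners = 39,
                        ratings_per_listener = nrow(std), seed = 21)
  fit <- fit_rating_model(r, std)
  est <- setNames(fit$estimate, fit$feature)
  expect_lt(abs(est[["f0_median_st"]] - 0.16), 0.05)
  # weighting sanity: duplicating all rating rows leaves point estimates
  # essentially unchanged (smoothing parameters re-estimate slightly)
  fit2 <- fit_rating_model(rbind(r, r), std)
  expect_lt(max(abs(fit2$estimate - fit$estimate)), 0.01)
  expect_error(fit_rating_model(r[1:100, ], std), "500")
})

test_that("rating-model intervals cover zero under a null simulation", {
  sc <- small_corpus()
  std <- standardize_features(sc$features)
  spec0 <- rating_model_spec(coefficients = c(f0_median_st = 0,
                                              duration_s = 0))
  set.seed(44)
  cover <- 0
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    r <- simulate_ratings(std, spec0, n_listeners = 10,
                          ratings_per_listener = 50, seed = 5000 + i)
    fit <- fit_rating_model(r, std, features = c("f0_median_st", "duration_s"))
    cover <- cover + mean(fit$lo <= 0 & fit$hi >= 0)
  }
  expect_gt(cover / n_rep, 0.88)
})

test_that("summarize_choices row-normalizes the confusion matrix", {
  # all correct: identity
  ch <- data.frame(true = rep(conditions(), each = 5),
                   chosen = rep(conditions(), each = 5))
  cm <- summarize_choices(ch)
  expect_equal(unname(diag(cm)), rep(1, 4))
  expect_true(all(abs(rowSums(cm) - 1) < 1e-9))
  # uniform random choices: cells ~ 25%
  set.seed(11)
  chr <- data.frame(true = sample(conditions(), 8000, TRUE),
                    chosen = sample(conditions(), 8000, TRUE))
  cmr <- summarize_choices(chr)
  expect_true(all(abs(cmr - 0.25) < 0.05))
  # empty true category flagged with NA
  ch2 <- ch[ch$true != "real", ]
  cm2 <- summarize_choices(ch2)
  expect_true(all(is.na(cm2["real", ])))
})
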