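# Statistical layer: standardization, mixed-model condition contrasts,
# random-forest confusion matrices, and (simulated-listener) beta
# rating models.

#' Standardize the acoustic feature table
#'
#' Descriptors measured in Hz are log-transformed, then every descriptor is
#' z-scored (mean 0, SD 1) across the whole table, mirroring the
#' normalization applied before model fitting. The transform parameters are
#' attached as `attr(, "transform")`, and [apply_transform()] reapplies a
#' stored transform (idempotent given the stored parameters).
#'
#' @param t feature table (metadata + descriptor columns)
#' @param fields descriptor columns to standardize (default the 19)
#' @return the table with standardized descriptor columns
#' @export
standardize_features <- function(t, fields = profile_fields()) {
  stopifnot(nrow(t) >= 2, all(fields %in% names(t)))
  trans <- list(fields = fields, logged = intersect(fields, hz_fields()),
                center = numeric(0), scale = numeric(0))
  for (f in fields) {
    v <- t[[f]]
    if (f %in% trans$logged) v <- log(v)
    mu <- mean(v, na.rm = TRUE)
    sdv <- sd(v, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) {
      warning("zero-variance column '", f, "' left at 0")
      sdv <- 1
    }
    trans$center[f] <- mu
    trans$scale[f] <- sdv
    t[[f]] <- (v - mu) / sdv
  }
  attr(t, "transform") <- trans
  t
}

#' @rdname standardize_features
#' @param trans a transform stored by [standardize_features()]
#' @export
apply_transform <- function(t, trans) {
  for (f in trans$fields) {
    v <- t[[f]]
    if (f %in% trans$logged) v <- log(v)
    t[[f]] <- (v - trans$center[f]) / trans$scale[f]
  }
  attr(t, "transform") <- trans
  t
}

# cluster-robust (CR1) covariance for lm fits; `cl` must be aligned with
# the rows the model was fit on (no NA dropping may occur in between)
cluster_vcov <- function(fit, cl) {
  X <- stats::model.matrix(fit)
  u <- stats::residuals(fit)
  stopifnot(length(u) == length(cl))
  cl <- as.factor(cl)
  bread <- solve(crossprod(X))
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in levels(cl)) {
    i <- which(cl == g)
    xu <- crossprod(X[i, , drop = FALSE], u[i])
    meat <- meat + tcrossprod(xu)
  }
  m <- nlevels(cl)
  adj <- m / (m - 1)
  adj * bread %*% meat %*% bread
}

#' Standardized condition contrasts from linear mixed models
#'
#' For each standardized descriptor, fits
#' `feature ~ condition + sex + channel + (1 | speaker)` (REML via lme4)
#' and reports the contrast of every non-baseline condition against
#' `relaxed` with a 95% Wald interval, in SD units of the feature. The
#' `robust` flag marks contrasts whose one-sided tail probability reaches
#' 99% (`|z| > 2.326`), mirroring the convention of graying out uncertain
#' effects. Singular random-effect fits fall back to a fixed-effects model
#' with speaker-cluster-robust intervals, flagged in `method`.
#'
#' @param t a standardized feature table (see [standardize_features()])
#'   with columns `condition`, `sex`, `channel`, `speaker`
#' @param fields descriptor columns to analyze
#' @return data.frame with `feature`, `condition`, `contrast`, `lo`, `hi`,
#'   `robust`, `method`
#' @export
estimate_condition_effects <- function(t, fields = profile_fields()) {
  stopifnot(all(c("condition", "sex", "channel", "speaker") %in% names(t)))
  t$condition <- factor(t$condition, levels = conditions())
  if (nlevels(droplevels(t$condition)) < 2) stop("need >= 2 conditions")
  if (length(unique(t$speaker)) < 5) stop("need >= 5 speakers")
  out <- list()
  for (f in fields) {
    d <- t[, c(f, "condition", "sex", "channel", "speaker")]
    names(d)[1] <- "y"
    d <- d[complete.cases(d), ]
    if (nrow(d) < 10) next
    has_channel <- length(unique(d$channel)) > 1
    has_sex <- length(unique(d$sex)) > 1
    form <- paste("y ~ condition",
                  if (has_sex) "+ sex" else "",
                  if (has_channel) "+ channel" else "")
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(stats::as.formula(paste(form, "+ (1 | speaker)")), data = d)
    ))
    singular <- lme4::isSingular(fit, tol = 1e-5)
    if (singular) {
      lmfit <- lm(stats::as.formula(form), data = d)
      V <- cluster_vcov(lmfit, d$speaker)
      est <- coef(lmfit)
      se <- sqrt(diag(V))
      method <- "lm_cluster_robust"
    } else {
      est <- lme4::fixef(fit)
      se <- sqrt(diag(as.matrix(vcov(fit))))
      method <- "lmer_wald"
    }
    for (cond in setdiff(levels(droplevels(d$condition)), "relaxed")) {
      nm <- paste0("condition", cond)
      if (!nm %in% names(est)) next
      b <- unname(est[nm])
      s <- unname(se[names(est) == nm])
      out[[length(out) + 1]] <- data.frame(
        feature = f, condition = cond, contrast = b,
        lo = b - 1.96 * s, hi = b + 1.96 * s,
        robust = abs(b / s) > qnorm(0.99), method = method
      )
    }
  }
  do.call(rbind, out)
}

#' Random-forest classification of condition from acoustic features
#'
#' Repeatedly fits a random forest (default 500 trees, `floor(sqrt(p))`
#' features per split) to predict condition from the descriptor columns,
#' using out-of-bag predictions. The confusion matrix (row = true
#' condition, proportions summing to 1) and per-category accuracy are
#' summarized as the median and 2.5/97.5 percentiles over `n_reps`
#' repetitions, which differ only by RNG stream. Rows with missing
#' descriptor values are median-imputed.
#'
#' @param t feature table with a `condition` column
#' @param n_reps repetitions (default 1000; scale down for quick checks)
#' @param n_tree trees per forest
#' @param fields descriptor columns
#' @return list with `confusion` (median proportions), `confusion_lo`,
#'   `confusion_hi` (95% coverage), `accuracy` (overall = mean per-category,
#'   median + interval), `class_accuracy`, `importance`
#' @export
rf_classify <- function(t, n_reps = 1000, n_tree = 500,
                        fields = profile_fields()) {
  stopifnot("condition" %in% names(t), nrow(t) >= 40)
  y <- factor(t$condition)
  if (nlevels(y) < 2) stop("need >= 2 conditions")
  if (any(table(y) < 3)) stop("every class needs >= 3 rows")
  fields <- intersect(fields, names(t))
  X <- as.matrix(t[, fields])
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    v[!is.finite(v)] <- median(v[is.finite(v)])
    X[, j] <- v
  }
  K <- nlevels(y)
  mtry <- max(1L, floor(sqrt(ncol(X))))
  conf <- array(NA_real_, c(K, K, n_reps),
                dimnames = list(levels(y), levels(y), NULL))
  acc <- matrix(NA_real_, n_reps, K, dimnames = list(NULL, levels(y)))
  imp <- matrix(0, n_reps, ncol(X), dimnames = list(NULL, fields))
  for (r in seq_len(n_reps)) {
    res <- rf_oob_cpp(X, as.integer(y) - 1L, K, n_tree, mtry, 1L)
    votes <- res$votes
    pred <- max.col(votes, ties.method = "first")
    has_vote <- rowSums(votes) > 0
    cm <- table(factor(y[has_vote], levels = levels(y)),
                factor(levels(y)[pred[has_vote]], levels = levels(y)))
    cm <- sweep(cm, 1, pmax(rowSums(cm), 1), "/")
    conf[, , r] <- cm
    acc[r, ] <- diag(cm)
    imp[r, ] <- res$importance
  }
  qfun <- function(a, p) apply(a, c(1, 2), quantile, probs = p, na.rm = TRUE)
  overall <- rowMeans(acc)
  med <- qfun(conf, 0.5)
  # per-rep confusion rows sum to 1 exactly; cellwise medians do not quite,
  # so the summary matrix is row-renormalized
  med <- sweep(med, 1, pmax(rowSums(med), 1e-12), "/")
  list(
    confusion = med,
    confusion_lo = qfun(conf, 0.025),
    confusion_hi = qfun(conf, 0.975),
    accuracy = c(median = median(overall),
                 lo = unname(quantile(overall, 0.025)),
                 hi = unname(quantile(overall, 0.975))),
    class_accuracy = apply(acc, 2, median),
    importance = sort(colMeans(imp), decreasing = TRUE)
  )
}

#' Rating model specification for simulated listeners
#'
#' Fixed coefficients are average marginal effects on the 0-1 rating
#' scale per 1 SD of each standardized feature; defaults follow the main
#' acoustic predictors of perceived effort: pitch +0.16, energy in
#' harmonics +0.05, duration +0.04, FM depth +0.02. Random intercepts
#' (logit scale) for listener, speaker, and sound capture rating
#' idiosyncrasies; `precision` is the beta-noise precision.
#'
#' @param coefficients named numeric vector (names = descriptor columns)
#' @param intercept_mu baseline mean rating in `(0, 1)`
#' @param listener_sd,speaker_sd,sound_sd random-intercept SDs (logit)
#' @param precision beta precision (phi > 0)
#' @return object of class `RatingModelSpec`
#' @export
rating_model_spec <- function(coefficients = c(f0_median_st = 0.16,
                                               harm_energy_prop = 0.05,
                                               duration_s = 0.04,
                                               fm_depth_st = 0.02),
                              intercept_mu = 0.4, listener_sd = 0.4,
                              speaker_sd = 0.3, sound_sd = 0.2,
                              precision = 12) {
  stopifnot(intercept_mu > 0, intercept_mu < 1, precision > 0,
            !is.null(names(coefficients)))
  structure(list(coefficients = coefficients, intercept_mu = intercept_mu,
                 listener_sd = listener_sd, speaker_sd = speaker_sd,
                 sound_sd = sound_sd, precision = precision),
            class = "RatingModelSpec")
}

#' Simulate listener ratings of perceived effort
#'
#' Each simulated listener rates a random subset of the stimuli. Ratings
#' are beta-distributed around an inverse-logit linear predictor built
#' from standardized features and listener/speaker/sound random
#' intercepts; the specified coefficients (0-1 scale) are converted to
#' logit slopes via the derivative at the baseline mean, so the average
#' marginal effect of feature `j` is the specified coefficient. Ratings
#' are clamped to `[0.01, 0.99]`.
#'
#' @param t a standardized feature table with `id` and `speaker` columns
#' @param spec a [rating_model_spec()]
#' @param n_listeners number of listeners (default 39)
#' @param ratings_per_listener stimuli rated per listener (default 99,
#'   capped at `nrow(t)`)
#' @param seed integer seed
#' @return data.frame: `listener`, `sound`, `speaker`, `rating`
#' @export
simulate_ratings <- function(t, spec = rating_model_spec(),
                             n_listeners = 39, ratings_per_listener = 99,
                             seed = 1) {
  stopifnot(inherits(spec, "RatingModelSpec"),
            all(names(spec$coefficients) %in% names(t)),
            all(c("id", "speaker") %in% names(t)))
  with_seed(seed, {
    n <- nrow(t)
    mu0 <- spec$intercept_mu
    X <- as.matrix(t[, names(spec$coefficients), drop = FALSE])
    X[!is.finite(X)] <- 0
    speakers <- unique(t$speaker)
    u_spk <- setNames(rnorm(length(speakers), 0, spec$speaker_sd), speakers)
    u_snd <- rnorm(n, 0, spec$sound_sd)
    u_lst <- rnorm(n_listeners, 0, spec$listener_sd)
    k <- min(ratings_per_listener, n)
    picks <- lapply(seq_len(n_listeners), function(l) sample.int(n, k))
    # calibrate the common logit slope scale so the realized average
    # marginal effect on the 0-1 scale equals the specified coefficients
    all_pick <- unlist(picks)
    all_lst <- rep(seq_len(n_listeners), each = k)
    base <- qlogis(mu0) + u_lst[all_lst] + u_spk[t$speaker[all_pick]] +
      u_snd[all_pick]
    w <- mu0 * (1 - mu0)
    for (it in 1:3) {
      slope <- spec$coefficients / w
      eta <- base + as.numeric(X[all_pick, , drop = FALSE] %*% slope)
      mu <- plogis(eta)
      w <- mean(mu * (1 - mu))
    }
    r <- rbeta(length(mu), mu * spec$precision, (1 - mu) * spec$precision)
    data.frame(
      listener = sprintf("L%03d", all_lst), sound = t$id[all_pick],
      speaker = t$speaker[all_pick],
      rating = pmin(0.99, pmax(0.01, r))
    )
  })
}

#' Fit a multilevel beta regression to effort ratings
#'
#' Beta regression with logit link on standardized acoustic features,
#' with random intercepts (random-effect smooths) for listener, speaker,
#' and sound, fit with `mgcv::gam(family = betar)`. Coefficients are
#' reported as average marginal effects on the 0-1 rating scale: the
#' logit-scale slope times the mean of `mu (1 - mu)` over the fitted
#' values, with Wald 95% intervals mapped through the same factor.
#'
#' @param ratings rating table from [simulate_ratings()] (columns
#'   `listener`, `sound`, `speaker`, `rating`)
#' @param t the standardized feature table the ratings refer to (with
#'   `id` column)
#' @param features descriptor columns to include as fixed effects
#'   (default: the simulation defaults plus sex if available)
#' @return data.frame with `feature`, `estimate`, `lo`, `hi` (0-1 scale),
#'   `logit_coef`; attributes carry the fitted model's convergence info
#' @export
fit_rating_model <- function(ratings, t,
                             features = names(rating_model_spec()$coefficients)) {
  stopifnot(nrow(ratings) >= 500, all(features %in% names(t)))
  d <- merge(ratings, t[, c("id", features, intersect("sex", names(t)))],
             by.x = "sound", by.y = "id", sort = FALSE)
  d <- d[complete.cases(d[, c("rating", features)]), ]
  d$listener <- factor(d$listener)
  d$speaker <- factor(d$speaker)
  d$sound <- factor(d$sound)
  fixed <- paste(features, collapse = " + ")
  if ("sex" %in% names(d) && length(unique(d$sex)) > 1) {
    fixed <- paste(fixed, "+ sex")
  }
  form <- stats::as.formula(paste(
    "rating ~", fixed,
    "+ s(listener, bs = 're') + s(speaker, bs = 're') + s(sound, bs = 're')"
  ))
  fit <- mgcv::bam(form, data = d, family = mgcv::betar(link = "logit"),
                   method = "fREML", discrete = TRUE)
  if (!fit$converged) warning("beta rating model did not converge")
  mu <- stats::fitted(fit)
  scale_fac <- mean(mu * (1 - mu))
  b <- coef(fit)[features]
  se <- sqrt(diag(vcov(fit))[features])
  out <- data.frame(
    feature = features,
    estimate = unname(b * scale_fac),
    lo = unname((b - 1.96 * se) * scale_fac),
    hi = unname((b + 1.96 * se) * scale_fac),
    logit_coef = unname(b)
  )
  attr(out, "converged") <- fit$converged
  out
}

#' Summarize forced-choice classifications as a confusion matrix
#'
#' Row-normalized proportions of chosen labels per true condition. Empty
#' true categories are flagged with `NA` rows.
#'
#' @param choices data.frame with columns `true` and `chosen` (labels from
#'   [conditions()] or any common label set)
#' @return square matrix of proportions, rows (true categories) summing
#'   to 1
#' @export
summarize_choices <- function(choices) {
  stopifnot(all(c("true", "chosen") %in% names(choices)))
  labs <- union(unique(as.character(choices$true)),
                unique(as.character(choices$chosen)))
  if (all(labs %in% conditions())) labs <- conditions()
  tab <- table(factor(choices$true, levels = labs),
               factor(choices$chosen, levels = labs))
  n <- rowSums(tab)
  out <- sweep(tab, 1, pmax(n, 1), "/")
  out[n == 0, ] <- NA_real_
  m <- matrix(out, nrow = nrow(out), dimnames = dimnames(tab))
  m
}
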