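# End-to-end pipeline: configuration, seeds, run artifacts, manifest.

#' Pipeline configuration
#'
#' Bundles the corpus configuration, analysis parameters, tremor specs,
#' model settings, and the global seed; a run is reproducible from the
#' config alone. Serializable to JSON with [write_config()] /
#' [read_config()].
#'
#' @param corpus a [corpus_config()]
#' @param search_range pitch search range (Hz)
#' @param rf_reps random-forest repetitions in [run_pipeline()]
#' @param rf_trees trees per forest
#' @param rating_spec a [rating_model_spec()] or `NULL` to skip ratings
#' @param n_listeners,ratings_per_listener simulated-listener design
#' @param manipulate if `TRUE`, add tremor/control manipulations of each
#'   speaker's first relaxed take and record the FM-depth production check
#' @param seed global seed (overrides `corpus$seed`)
#' @return object of class `PipelineConfig`
#' @export
pipeline_config <- function(corpus = corpus_config(), search_range = c(60, 600),
                            rf_reps = 1000, rf_trees = 500,
                            rating_spec = rating_model_spec(),
                            n_listeners = 39, ratings_per_listener = 99,
                            manipulate = TRUE, seed = 1) {
  corpus$seed <- seed
  structure(list(
    corpus = corpus, search_range = search_range, rf_reps = rf_reps,
    rf_trees = rf_trees, rating_spec = rating_spec,
    n_listeners = n_listeners, ratings_per_listener = ratings_per_listener,
    manipulate = manipulate, seed = seed
  ), class = "PipelineConfig")
}

#' @rdname pipeline_config
#' @param config a `PipelineConfig`
#' @param path JSON file path
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  corpus <- raw$corpus
  cfg <- corpus_config(
    n_female = corpus$n_female, n_male = corpus$n_male, takes = corpus$takes,
    offsets = condition_offsets(as.data.frame(corpus$offsets)),
    rate = corpus$rate, speaker_sd = unlist(corpus$speaker_sd),
    take_sd = unlist(corpus$take_sd), female_f0 = corpus$female_f0,
    male_f0 = corpus$male_f0, seed = corpus$seed
  )
  rspec <- if (is.null(raw$rating_spec)) NULL else rating_model_spec(
    coefficients = unlist(raw$rating_spec$coefficients),
    intercept_mu = raw$rating_spec$intercept_mu,
    listener_sd = raw$rating_spec$listener_sd,
    speaker_sd = raw$rating_spec$speaker_sd,
    sound_sd = raw$rating_spec$sound_sd,
    precision = raw$rating_spec$precision
  )
  pipeline_config(
    corpus = cfg, search_range = unlist(raw$search_range),
    rf_reps = raw$rf_reps, rf_trees = raw$rf_trees, rating_spec = rspec,
    n_listeners = raw$n_listeners,
    ratings_per_listener = raw$ratings_per_listener,
    manipulate = raw$manipulate, seed = raw$seed
  )
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) {
    x <- as.data.frame(x)
    attr(x, "class") <- "data.frame"
  } else if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attributes(x) <- list(names = names(x))
  } else if (is.atomic(x) && !is.null(names(x))) {
    x <- as.list(x) # keep names: serialize as a JSON object, not an array
  } else {
    x <- unclass(x)
    attr(x, "class") <- NULL
  }
  x
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}

log_msg <- function(con, level, ...) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%H:%M:%S"), level,
                  paste0(...))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full pipeline
#'
#' Executes synthesis, feature extraction, the tremor/control
#' manipulation check, and the statistical layer, writing all artifacts to
#' `out_dir`: corpus WAVs (optional), `features.csv`, `effects.csv`,
#' `confusion.csv`, `ratings.csv` / `rating_effects.csv` (if configured),
#' a `manifest.json` stamped with the config hash and seed, and a plain
#' text run log. Stage failures are logged with the stage name and the
#' artifacts produced so far are retained.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created if needed)
#' @param write_audio write per-utterance WAV files (default `FALSE`;
#'   audio is always synthesized in memory)
#' @return invisibly, a list with the feature table, effect estimates,
#'   confusion summary, rating fit, and the manifest
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, write_audio = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out_dir, "run.log"), "wt")
  on.exit(close(logf))
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   package_version = as.character(utils::packageVersion("effortvoice")),
                   stages = list())
  res <- list()
  stage <- function(name, fn) {
    log_msg(logf, "INFO", "stage ", name, " started")
    out <- tryCatch(fn(), error = function(e) {
      log_msg(logf, "ERROR", "stage ", name, " failed: ", conditionMessage(e))
      NULL
    })
    manifest$stages[[name]] <<- if (is.null(out)) "failed" else "ok"
    out
  }
  write_config(config, file.path(out_dir, "config.json"))

  corpus <- stage("synth-corpus", function() generate_corpus(config$corpus))
  if (!is.null(corpus)) {
    utils::write.csv(corpus$meta, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
    if (write_audio) {
      adir <- file.path(out_dir, "audio")
      dir.create(adir, showWarnings = FALSE)
      for (id in names(corpus$audio)) {
        write_wav(corpus$audio[[id]], file.path(adir, paste0(id, ".wav")))
      }
    }
  }

  feats <- if (!is.null(corpus)) {
    stage("extract-features", function() {
      corpus_features(corpus, search_range = config$search_range)
    })
  }
  if (!is.null(feats)) {
    write_feature_csv(feats, file.path(out_dir, "features.csv"))
  }

  if (config$manipulate && !is.null(corpus)) {
    res$manip <- stage("add-tremor", function() {
      relaxed1 <- corpus$meta$id[corpus$meta$condition == "relaxed" &
                                   corpus$meta$take == 1]
      relaxed1 <- head(relaxed1, 10) # production check on a subsample
      rows <- lapply(relaxed1, function(id) {
        w <- corpus$audio[[id]]
        base <- fm_depth(track_pitch(w, config$search_range))
        data.frame(
          id = id, fm_base = base,
          fm_tremor = fm_depth(track_pitch(
            apply_manipulation(w, "tremor", seed = child_seed(config$seed, id, "t")),
            config$search_range)),
          fm_control = fm_depth(track_pitch(
            apply_manipulation(w, "control", seed = child_seed(config$seed, id, "c")),
            config$search_range))
        )
      })
      out <- do.call(rbind, rows)
      utils::write.csv(out, file.path(out_dir, "manipulation_check.csv"),
                       row.names = FALSE)
      out
    })
  }

  std <- if (!is.null(feats)) {
    stage("fit-effects", function() standardize_features(feats))
  }
  res$effects <- if (!is.null(std)) {
    stage("fit-effects", function() {
      eff <- estimate_condition_effects(std)
      utils::write.csv(eff, file.path(out_dir, "effects.csv"), row.names = FALSE)
      eff
    })
  }
  res$rf <- if (!is.null(feats)) {
    stage("classify", function() {
      rf <- with_seed(child_seed(config$seed, "rf"), {
        rf_classify(feats, n_reps = config$rf_reps, n_tree = config$rf_trees)
      })
      utils::write.csv(as.data.frame(rf$confusion),
                       file.path(out_dir, "confusion.csv"))
      rf
    })
  }
  if (!is.null(config$rating_spec) && !is.null(std)) {
    res$ratings <- stage("simulate-ratings", function() {
      r <- simulate_ratings(std, config$rating_spec,
                            n_listeners = config$n_listeners,
                            ratings_per_listener = config$ratings_per_listener,
                            seed = child_seed(config$seed, "ratings"))
      utils::write.csv(r, file.path(out_dir, "ratings.csv"), row.names = FALSE)
      fit <- fit_rating_model(r, std)
      utils::write.csv(fit, file.path(out_dir, "rating_effects.csv"),
                       row.names = FALSE)
      list(ratings = r, fit = fit)
    })
  }
  res$features <- feats
  res$manifest <- manifest
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_msg(logf, "INFO", "pipeline finished")
  invisible(res)
}

#' Write / read a feature table as CSV
#'
#' Undefined descriptor values are serialized as empty cells, never as
#' sentinel numbers.
#'
#' @param t feature table
#' @param path CSV path
#' @export
write_feature_csv <- function(t, path) {
  utils::write.csv(t, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  t <- utils::read.csv(path, na.strings = "")
  if ("condition" %in% names(t)) {
    t$condition <- factor(t$condition,
                          levels = intersect(conditions(), unique(t$condition)))
  }
  t
}
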