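#' Run configuration for end-to-end experiments
#'
#' One configuration drives the full workflow: generate (or load) a corpus,
#' apply a numerical representation, build the tokenizer, train, evaluate on a
#' held-out test split, extract structured measurements, and write everything
#' to a run directory with a manifest capturing config and seeds, so any run
#' can be reproduced from its manifest alone.
#'
#' @param n_train,n_test Synthetic corpus sizes (reports).
#' @param repr_mode Numerical representation (see [repr_modes()]).
#' @param train A [train_config()].
#' @param corpus A [corpus_config()] template; its `n_reports`/`seed` fields
#'   are overridden per split.
#' @param seed Global seed propagated to every stochastic stage.
#' @param decode Decoding for measurement extraction.
#' @param out_dir Run directory (created; default a fresh temporary dir).
#' @param schema_path Optional path to a schema document; default packaged
#'   schema.
#' @export
run_config <- function(n_train = 200L, n_test = 100L, repr_mode = "original",
                       train = train_config(max_epochs = 8L), corpus = corpus_config(),
                       seed = 1L, decode = "argmax",
                       out_dir = NULL, schema_path = NULL) {
  list(n_train = as.integer(n_train), n_test = as.integer(n_test),
       repr_mode = repr_mode, train = train, corpus = corpus,
       seed = as.integer(seed), decode = decode,
       out_dir = out_dir, schema_path = schema_path)
}

#' @rdname run_config
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, a list with `metrics`, `measurements`, `model`,
#'   `eval`, `run_dir`.
#' @export
run_end_to_end <- function(config = run_config(), verbose = FALSE) {
  if (!is.null(config$schema_path) && !file.exists(config$schema_path)) {
    abort(paste0("config error: schema path does not exist: ", config$schema_path))
  }
  schema <- if (is.null(config$schema_path)) default_schema() else load_schema(config$schema_path)
  run_dir <- config$out_dir %||% tempfile("cmr_run_")
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  stage <- "generate"
  res <- tryCatch({
    train_cfg <- modifyList(config$corpus,
                            list(n_reports = config$n_train, seed = config$seed))
    test_cfg <- modifyList(config$corpus,
                           list(n_reports = config$n_test, seed = config$seed + 1L))
    say("generating %d train / %d test reports", config$n_train, config$n_test)
    train_corp <- generate_corpus(do.call(corpus_config, train_cfg), schema)
    test_corp <- generate_corpus(do.call(corpus_config, test_cfg), schema)

    stage <- "transform"
    tr <- transform_corpus(train_corp$reports, train_corp$annotations, config$repr_mode)
    te <- transform_corpus(test_corp$reports, test_corp$annotations, config$repr_mode)

    stage <- "tokenize"
    tokenizer <- build_tokenizer(tr$reports$text)
    tcfg <- config$train
    tcfg$seed <- config$seed
    train_windows <- corpus_windows(tr$reports, tr$annotations, tokenizer, schema,
                                    max_len = tcfg$encoder$max_len)
    test_windows <- corpus_windows(te$reports, te$annotations, tokenizer, schema,
                                   max_len = tcfg$encoder$max_len)

    stage <- "train"
    say("training (%d windows, <= %d epochs)", length(train_windows), tcfg$max_epochs)
    model <- train_extractor(train_windows, schema, tokenizer, tcfg,
                             dev_windows = test_windows, verbose = verbose)

    stage <- "evaluate"
    pred <- predict_window_labels(model, test_windows, mode = "threshold")
    gold <- unlist(purrr::map(test_windows, ~ .x$tokens$label))
    ev <- evaluate_tokens(pred, gold, schema)

    stage <- "extract"
    meas <- extract_measurements(model, test_corp$reports, repr_mode = config$repr_mode,
                                 decode = config$decode)

    stage <- "write"
    metrics <- list(macro_f1 = ev$macro_f1, best_epoch = model$best_epoch,
                    n_train_windows = length(train_windows),
                    n_test_windows = length(test_windows))
    manifest <- list(package_version = as.character(utils::packageVersion("cmrextract")),
                     seed = config$seed, repr_mode = config$repr_mode,
                     encoder_profile = config$train$encoder_profile,
                     n_train = config$n_train, n_test = config$n_test,
                     train = config$train[c("learning_rate", "batch_size", "max_epochs",
                                            "seed", "decode_threshold")],
                     corpus = config$corpus,
                     config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]))
    jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    jsonlite::write_json(metrics, file.path(run_dir, "metrics.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    utils::write.csv(meas, file.path(run_dir, "measurements.csv"), row.names = FALSE)
    utils::write.csv(model$history, file.path(run_dir, "history.csv"), row.names = FALSE)
    utils::write.csv(tidy(ev), file.path(run_dir, "per_label_f1.csv"), row.names = FALSE)
    list(metrics = metrics, measurements = meas, model = model, eval = ev,
         run_dir = run_dir)
  }, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), parent = e)
  })
  say("macro-F1 %.3f (epoch %d); run dir %s", res$metrics$macro_f1,
      res$metrics$best_epoch, run_dir)
  invisible(res)
}

#' Grid over encoder profiles and numerical representations
#'
#' Runs [run_end_to_end()] for every (encoder profile, representation mode)
#' cell and collects the maximum macro-F1 per cell — the layout of the
#' architecture-by-representation comparison. A failing cell is recorded and
#' the grid continues.
#'
#' @param config A [run_config()] used as the template for every cell.
#' @param profiles List/vector of encoder profiles.
#' @param modes Character vector of representation modes.
#' @param verbose Print progress.
#' @return Tibble: `profile`, `mode`, `macro_f1`, `best_epoch`, `error`.
#' @export
grid_run <- function(config = run_config(), profiles = list("tiny_scratch"),
                     modes = repr_modes(), verbose = FALSE) {
  if (!length(profiles) || !length(modes)) abort("empty grid")
  profile_label <- function(p) {
    if (is.character(p)) p
    else paste0("custom(", paste(names(p), unlist(p), sep = "=", collapse = ","), ")")
  }
  cells <- tidyr::expand_grid(profile = profiles, mode = modes)
  rows <- purrr::pmap(cells, function(profile, mode) {
    cfg <- config
    cfg$repr_mode <- mode
    cfg$train$encoder_profile <- profile
    cfg$out_dir <- NULL
    res <- tryCatch({
      cfg$train$encoder <- encoder_dims(profile)
      NULL
    }, error = identity)
    if (inherits(res, "error")) {
      return(tibble(profile = profile_label(profile), mode = mode, macro_f1 = NA_real_,
                    best_epoch = NA_integer_, error = conditionMessage(res)))
    }
    res <- tryCatch(run_end_to_end(cfg, verbose = verbose), error = identity)
    if (inherits(res, "error")) {
      tibble(profile = profile_label(profile), mode = mode, macro_f1 = NA_real_,
             best_epoch = NA_integer_, error = conditionMessage(res))
    } else {
      tibble(profile = profile_label(profile), mode = mode,
             macro_f1 = res$metrics$macro_f1,
             best_epoch = as.integer(res$metrics$best_epoch), error = NA_character_)
    }
  })
  bind_rows(rows)
}
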