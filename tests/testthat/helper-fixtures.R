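# Shared fixtures. Heavy objects (corpora, small trained models) are built
# once per test run and memoised here.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

fixture_schema <- function() memo("schema", default_schema())

# small corpus for structural tests
fixture_corpus <- function() {
  memo("corpus_small",
       generate_corpus(corpus_config(n_reports = 20, seed = 101,
                                     out_of_range_rate = 0),
                       fixture_schema()))
}

# tokenizer built on the small corpus
fixture_tokenizer <- function() {
  memo("tokenizer_small", build_tokenizer(fixture_corpus()$reports$text))
}

# a fast, genuinely trained model on a mini corpus: smaller encoder and few
# reports, enough for smoke-level behavioural checks (not for accuracy ones)
fixture_mini_model <- function() {
  memo("mini_model", {
    sch <- fixture_schema()
    corp <- fixture_corpus()
    tok <- fixture_tokenizer()
    wins <- cmrextract:::corpus_windows(corp$reports, corp$annotations, tok, sch)
    cfg <- train_config(max_epochs = 2, seed = 7,
                        encoder_profile = list(d_model = 32L, n_heads = 2L,
                                               n_layers = 1L, d_ff = 64L))
    train_extractor(wins, sch, tok, cfg)
  })
}

# hand-built schema with two measurements, for compact oracle tests
toy_schema <- function() {
  memo("toy_schema", {
    doc <- list(null_label = "0", measurement_types = list(
      list(label = "lvef", display_name = "LV ejection fraction",
           aliases = list("LVEF", "LV EF"), unit = "%",
           physiologic_range = c(5, 90)),
      list(label = "rvef", display_name = "RV ejection fraction",
           aliases = list("RVEF"), unit = "%",
           physiologic_range = c(5, 90))))
    path <- tempfile(fileext = ".json")
    jsonlite::write_json(doc, path, auto_unbox = TRUE)
    load_schema(path)
  })
}
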