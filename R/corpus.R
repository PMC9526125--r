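#' Synthetic CMR-style report corpus
#'
#' Real CMR reports cannot be shared, so every stage of the workflow is
#' exercised on a seeded synthetic corpus that emulates the variability of
#' clinical report text: measurements appear in varying order under several
#' surface names, units come and go, values are integers or carry one or two
#' decimals, the name-value layout differs between narrative sentences, colon
#' lists and dense tabular lines, and reports carry distractor numbers (dates,
#' heart rates, slice thickness, patient age) that belong to no measurement.
#' Each report contains between 1 and 21 measurements; gold annotations are
#' standoff spans over the numeric value whose substring parses exactly to the
#' annotated value.
#'
#' @param n_reports Number of reports to generate.
#' @param seed Integer seed; generation is bit-reproducible given
#'   `(config, seed)`.
#' @param inclusion_prob Per-measurement inclusion probability: a single
#'   number applied to every schema label, or a named vector (labels absent
#'   from the names get probability 0).
#' @param style_weights Named weights over report styles `narrative`, `colon`,
#'   `tabular`.
#' @param out_of_range_rate Fraction of values sampled just outside the
#'   physiologic bounds, to exercise the physiologic filter.
#' @param distractor_rate Expected number of distractor sentences per report.
#' @param unit_prob Probability that a unit is printed after a value
#'   (tabular lines always omit units).
#' @return `corpus_config()` returns a config list; `generate_corpus()` a list
#'   with `reports` (tibble: `report_id`, `text`, `person_id`, `report_date`),
#'   `annotations` (gold standoff tibble) and `config`.
#' @examples
#' corp <- generate_corpus(corpus_config(n_reports = 3, seed = 7))
#' corp$reports$text[1]
#' @export
corpus_config <- function(n_reports = 100, seed = 1L, inclusion_prob = 0.5,
                          style_weights = c(narrative = 1, colon = 1, tabular = 1),
                          out_of_range_rate = 0.02, distractor_rate = 2,
                          unit_prob = 0.7) {
  stopifnot(n_reports >= 1, out_of_range_rate >= 0, out_of_range_rate <= 1,
            distractor_rate >= 0, all(inclusion_prob >= 0), all(inclusion_prob <= 1))
  list(n_reports = as.integer(n_reports), seed = as.integer(seed),
       inclusion_prob = inclusion_prob, style_weights = style_weights,
       out_of_range_rate = out_of_range_rate, distractor_rate = distractor_rate,
       unit_prob = unit_prob)
}

#' @rdname corpus_config
#' @param config A [corpus_config()].
#' @param schema A `cmr_schema` (default [default_schema()]).
#' @export
generate_corpus <- function(config = corpus_config(), schema = default_schema()) {
  labels <- schema$measurement_types$label
  p <- config$inclusion_prob
  if (is.null(names(p))) {
    p <- setNames(rep(p[1], length(labels)), labels)
  } else {
    full <- setNames(rep(0, length(labels)), labels)
    bad <- setdiff(names(p), labels)
    if (length(bad)) abort(paste0("inclusion_prob names not in schema: ", paste(bad, collapse = ", ")))
    full[names(p)] <- p
    p <- full
  }
  if (all(p == 0)) abort("all inclusion probabilities are zero; reports would be empty")

  with_seed(config$seed, {
    styles <- sample(names(config$style_weights), config$n_reports, replace = TRUE,
                     prob = config$style_weights)
    out <- purrr::map(seq_len(config$n_reports), function(i) {
      inc <- labels[runif(length(labels)) < p]
      if (!length(inc)) inc <- sample(labels, 1, prob = p / sum(p))
      inc <- sample(inc)  # randomize ordering
      vals <- purrr::map_chr(inc, ~ sample_value(.x, schema, config$out_of_range_rate))
      names(vals) <- inc
      rr <- render_report(vals, schema, style = styles[i],
                          unit_prob = config$unit_prob,
                          n_distractors = stats::rpois(1, config$distractor_rate))
      rid <- sprintf("R%05d", i)
      date <- as.Date("2005-01-01") + sample.int(5000, 1)
      list(report = tibble(report_id = rid, text = rr$text,
                           person_id = sprintf("P%05d", i),
                           report_date = as.character(date)),
           ann = if (nrow(rr$spans)) mutate(rr$spans, report_id = rid, .before = 1) else NULL)
    })
    reports <- bind_rows(purrr::map(out, "report"))
    annotations <- bind_rows(purrr::map(out, "ann"))
    list(reports = reports,
         annotations = arrange(annotations, .data$report_id, .data$start),
         config = config)
  })
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Sample and format one value for a measurement label. Returns the formatted
# string; the gold value is whatever this string parses to.
sample_value <- function(label, schema, out_of_range_rate) {
  rng <- schema_range(schema, label)
  lo <- rng$lower; hi <- rng$upper
  v <- if (runif(1) < out_of_range_rate) {
    if (runif(1) < 0.5) lo * runif(1, 0.3, 0.9) else hi * runif(1, 1.1, 1.8)
  } else {
    runif(1, lo, hi)
  }
  dp <- sample(0:2, 1, prob = c(0.4, 0.3, 0.3))
  sprintf(paste0("%.", dp, "f"), v)
}

#' Render one synthetic report
#'
#' Turns a named map of formatted measurement values into report text plus
#' gold value spans, in one of three layout styles: `narrative` sentences
#' ("The RVEF was 56 %."), `colon` lists ("RVEDV: 147.54 ml"), or dense
#' `tabular` lines with units omitted. Alias choice, unit presence and
#' distractor placement are drawn from the current RNG state.
#'
#' @param values Named character vector: formatted value strings keyed by
#'   schema label; must be non-empty.
#' @param schema A `cmr_schema`.
#' @param style One of `"narrative"`, `"colon"`, `"tabular"`.
#' @param unit_prob Probability a unit follows the value (ignored for tabular).
#' @param n_distractors Number of distractor sentences to intersperse.
#' @return List with `text` and `spans` (tibble `start`, `end`, `label`,
#'   `value`; 0-based half-open offsets into `text`).
#' @export
render_report <- function(values, schema, style = c("narrative", "colon", "tabular"),
                          unit_prob = 0.7, n_distractors = 2) {
  style <- match.arg(style)
  if (!length(values)) abort("render_report() needs at least one measurement")
  mt <- schema$measurement_types
  sep <- if (style == "narrative") " " else "\n"

  buf <- character(0)
  pos <- 0L
  spans <- list()
  emit <- function(s) {
    buf[[length(buf) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  emit_measurement <- function(label, val_str) {
    i <- match(label, mt$label)
    alias <- sample(mt$aliases[[i]], 1)
    unit <- mt$unit[i]
    show_unit <- style != "tabular" && nzchar(unit) && runif(1) < unit_prob
    if (style == "narrative") {
      lead <- sample(c(paste0("The ", alias, " was "),
                       paste0("The ", alias, " measured "),
                       paste0(alias, " is "),
                       paste0("Study shows ", alias, " of ")), 1)
      emit(lead)
    } else if (style == "colon") {
      emit(paste0(alias, ": "))
    } else {
      emit(paste0(alias, " "))
    }
    spans[[length(spans) + 1L]] <<- tibble(start = pos, end = pos + nchar(val_str),
                                           label = label, value = as.numeric(val_str))
    emit(val_str)
    if (show_unit) emit(paste0(" ", unit))
    if (style == "narrative") emit(".")
  }

  items <- c(as.list(names(values)), as.list(rep(NA_character_, n_distractors)))
  items <- sample(items)
  first <- TRUE
  for (it in items) {
    if (!first) emit(sep)
    first <- FALSE
    if (is.na(it)) emit(distractor_sentence()) else emit_measurement(it, values[[it]])
  }
  list(text = paste(buf, collapse = ""),
       spans = if (length(spans)) bind_rows(spans) else
         tibble(start = integer(), end = integer(), label = character(), value = numeric()))
}

distractor_sentence <- function() {
  k <- sample.int(6, 1)
  switch(k,
    sprintf("Study date %02d/%02d/%d.", sample.int(12, 1), sample.int(28, 1),
            sample(2005:2019, 1)),
    sprintf("Heart rate %d bpm.", sample(50:110, 1)),
    sprintf("Slice thickness %d mm.", sample(6:10, 1)),
    sprintf("Patient is %d years old.", sample(25:90, 1)),
    sprintf("TR %.1f ms.", runif(1, 2.5, 4.5)),
    sprintf("%d short axis slices were acquired.", sample(10:16, 1))
  )
}
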