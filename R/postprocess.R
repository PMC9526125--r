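#' Extend a predicted span to the full numeric token
#'
#' Model predictions occasionally cover only part of a number (e.g. the run
#' `51` with the adjacent `.01` left unlabeled). `merge_digits()` extends a
#' character span to cover the maximal numeric token it overlaps — adjacent
#' digits and an interior decimal point, with no whitespace crossing — and is
#' a no-op when the span already covers a full number or abuts non-numeric
#' text.
#'
#' @param text The text the span refers to.
#' @param start,end 0-based half-open span.
#' @return Integer `c(start, end)` of the (possibly extended) span.
#' @export
merge_digits <- function(text, start, end) {
  m <- gregexpr("[0-9]+(?:\\.[0-9]+)?", text, perl = TRUE)[[1]]
  if (m[1] != -1) {
    ns <- as.integer(m) - 1L
    ne <- ns + attr(m, "match.length")
    hit <- which(ns < end & start < ne)
    if (length(hit)) {
      start <- min(start, ns[hit])
      end <- max(end, ne[hit])
    }
  }
  c(as.integer(start), as.integer(end))
}

#' Consolidate per-token labels into structured measurements
#'
#' Maximal runs of identically labeled tokens become candidate measurement
#' spans. Each candidate is mapped back to original-text coordinates through
#' the representation's offset map, extended over missed significant digits
#' with [merge_digits()], and its numeric value parsed from the original text.
#' When one report yields several candidates for the same label, the candidate
#' with the highest mean token score is emitted and the others are retained
#' with `emitted = FALSE` and reason `"duplicate"`; candidates containing no
#' parseable number are retained with reason `"non-numeric"`. Nothing is
#' deleted, so candidates are conserved: every run appears as a row.
#'
#' @param tokens Tibble with `start`, `end` (offsets into the transformed
#'   text), `label` and `score` (per-token score of the assigned label).
#' @param tt The [transform_text()] result for the report (use mode
#'   `"original"` when no representation was applied).
#' @param report_id Report identifier carried into the output.
#' @param schema A `cmr_schema` (its null label delimits runs).
#' @return Measurement tibble: `report_id`, `label`, `value`, `start`, `end`
#'   (original-text offsets), `score`, `emitted`, `filtered`, `reason`.
#' @export
consolidate <- function(tokens, tt, report_id, schema) {
  null_label <- schema$null_label
  empty <- tibble(report_id = character(), label = character(), value = numeric(),
                  start = integer(), end = integer(), score = numeric(),
                  emitted = logical(), filtered = logical(), reason = NA_character_)
  if (!nrow(tokens)) return(empty)
  r <- rle(tokens$label)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  rows <- list()
  for (i in seq_along(r$values)) {
    lab <- r$values[i]
    if (lab == null_label) next
    tk <- tokens[starts[i]:stops[i], ]
    span_t <- c(min(tk$start), max(tk$end))
    span_o <- map_span(tt, span_t[1], span_t[2], "to_original")
    span_o <- merge_digits(tt$original, span_o[1], span_o[2])
    snippet <- span_text(tt$original, span_o[1], span_o[2])
    num <- regmatches(snippet, regexpr("-?[0-9]+(?:\\.[0-9]+)?", snippet, perl = TRUE))
    value <- if (length(num)) suppressWarnings(as.numeric(num)) else NA_real_
    rows[[length(rows) + 1L]] <- tibble(
      report_id = report_id, label = lab, value = value,
      start = span_o[1], end = span_o[2], score = mean(tk$score),
      emitted = !is.na(value), filtered = FALSE,
      reason = if (is.na(value)) "non-numeric" else NA_character_)
  }
  if (!length(rows)) return(empty)
  out <- bind_rows(rows)
  # per-label dedup: keep the highest mean score
  out <- out %>%
    group_by(.data$label) %>%
    mutate(best = .data$emitted & seq_along(.data$score) ==
             which.max(ifelse(.data$emitted, .data$score, -Inf))) %>%
    ungroup() %>%
    mutate(reason = case_when(!.data$emitted ~ .data$reason,
                              .data$best ~ NA_character_,
                              TRUE ~ "duplicate"),
           emitted = .data$best) %>%
    select(-"best")
  arrange(out, .data$start)
}

#' Flag measurements outside physiologic bounds
#'
#' Sets `filtered = TRUE` with reason `"out-of-range"` for values strictly
#' below the lower or strictly above the upper physiologic bound of their
#' measurement type. Rows are flagged, never deleted (counts are conserved);
#' [emitted_measurements()] excludes flagged rows. Idempotent and
#' order-independent.
#'
#' @param measurements Measurement tibble from [consolidate()].
#' @param schema A `cmr_schema` containing every label present.
#' @return The tibble with `filtered`/`reason` updated.
#' @export
filter_physiologic <- function(measurements, schema) {
  if (!nrow(measurements)) return(measurements)
  rng <- schema_range(schema, measurements$label)
  out <- !is.na(measurements$value) &
    (measurements$value < rng$lower | measurements$value > rng$upper)
  measurements %>%
    mutate(filtered = .data$filtered | out,
           reason = ifelse(out & (is.na(.data$reason) | .data$reason == "out-of-range"),
                           "out-of-range", .data$reason))
}

#' @rdname filter_physiologic
#' @export
emitted_measurements <- function(measurements) {
  filter(measurements, .data$emitted, !.data$filtered)
}

# choose, for every token position, the prediction from the window where the
# token is most interior (ties to the earlier window)
stitch_windows <- function(windows, scores_list, n_tokens, n_labels) {
  best <- rep(-Inf, n_tokens)
  out <- matrix(NA_real_, n_tokens, n_labels)
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    len <- nrow(w$tokens)
    pos <- w$token_start:(w$token_start + len - 1L)
    d <- pmin(seq_len(len), rev(seq_len(len)))
    take <- d > best[pos]
    if (any(take)) {
      out[pos[take], ] <- scores_list[[i]][take, , drop = FALSE]
      best[pos[take]] <- d[take]
    }
  }
  out
}

#' Extract structured measurements from reports
#'
#' End-to-end inference: each report is rewritten into the model's numerical
#' representation, tokenized, cut into overlapping inference windows, scored
#' by the model, decoded (`argmax` by default, as used when applying the model
#' at scale; `threshold` abstains below the configured score), consolidated
#' into spans mapped back to the original text, and filtered against
#' physiologic bounds.
#'
#' @param model A `cmr_extractor`.
#' @param reports Report tibble (`report_id`, `text`).
#' @param repr_mode Numerical representation the model was trained with.
#' @param decode `"argmax"` or `"threshold"`.
#' @param overlap Inference window overlap in tokens.
#' @return Measurement tibble (see [consolidate()]); apply
#'   [emitted_measurements()] for the final table.
#' @export
extract_measurements <- function(model, reports, repr_mode = "original",
                                 decode = c("argmax", "threshold"), overlap = 16L) {
  decode <- match.arg(decode)
  schema <- model$schema
  out <- list()
  for (i in seq_len(nrow(reports))) {
    tt <- transform_text(reports$text[i], repr_mode)
    toks <- tokenize_text(model$tokenizer, tt$text)
    if (!nrow(toks)) next
    ws <- window_tokens(toks, max_len = model$nn_cfg$max_len, mode = "infer",
                        overlap = overlap, report_id = reports$report_id[i])
    scores_list <- predict_window_scores(model, ws)
    scores <- stitch_windows(ws, scores_list, nrow(toks), model$nn_cfg$n_labels)
    colnames(scores) <- model$label_levels
    labels <- if (decode == "argmax") decode_argmax(scores)
    else decode_threshold(scores, t = model$config$decode_threshold,
                          null_label = schema$null_label)
    tok_scores <- scores[cbind(seq_len(nrow(scores)), match(labels, model$label_levels))]
    cand <- consolidate(mutate(toks, label = labels, score = tok_scores),
                        tt, reports$report_id[i], schema)
    out[[length(out) + 1L]] <- filter_physiologic(cand, schema)
  }
  if (!length(out)) return(filter_physiologic(consolidate(tibble(), transform_text("", "original"), "x", schema), schema))
  bind_rows(out)
}
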