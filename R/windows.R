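#' Align span annotations to subword tokens
#'
#' Tokenizes a report and assigns each token the label of any gold annotation
#' whose character span overlaps the token's span (containment-based with
#' any-overlap at boundaries, so every subword piece of an annotated value —
#' e.g. `51`, `.`, `01` — carries the value's label). Tokens outside all
#' annotations carry the schema's null label.
#'
#' @param text Report text (in the representation the annotations refer to).
#' @param annotations Annotations for this report (`start`, `end`, `label`),
#'   or `NULL`/empty for inference.
#' @param tokenizer A [build_tokenizer()] object.
#' @param schema A `cmr_schema`.
#' @return Tibble `token_id`, `token`, `start`, `end`, `label`.
#' @export
tokenize_with_labels <- function(text, annotations, tokenizer, schema) {
  toks <- tokenize_text(tokenizer, text)
  lab <- rep(schema$null_label, nrow(toks))
  if (!is.null(annotations) && nrow(annotations)) {
    bad <- setdiff(unique(annotations$label), schema$measurement_types$label)
    if (length(bad)) abort(paste0("unknown annotation label(s): ", paste(bad, collapse = ", ")))
    for (i in seq_len(nrow(annotations))) {
      hit <- toks$start < annotations$end[i] & annotations$start[i] < toks$end
      lab[hit] <- annotations$label[i]
    }
  }
  mutate(toks, label = lab)
}

#' Split labeled tokens into model windows
#'
#' Cuts a report's token sequence into sections of at most `max_len` tokens.
#' With gold labels (`mode = "train"`) windows are non-overlapping and a
#' boundary never splits a maximal same-label annotation run: when the report
#' `text` is supplied the cut prefers the last line or sentence boundary
#' inside the window (so a measurement name is not stranded away from its
#' value), otherwise it falls back to the last null-labeled token before a
#' straddling run. Flattening the windows reproduces tokens, offsets and
#' labels exactly and no annotation is divided. At inference (`mode = "infer"`,
#' no labels required) windows are cut at exactly `max_len` with a fixed
#' `overlap` (default 16 tokens) to limit boundary effects; predictions for
#' twice-covered tokens are later taken from the window where the token is
#' most interior.
#'
#' @param tokens Tibble from [tokenize_with_labels()] (needs `label` for
#'   `mode = "train"`).
#' @param max_len Window capacity in tokens (>= 2).
#' @param mode `"train"` or `"infer"`.
#' @param overlap Inference overlap in tokens.
#' @param null_label The schema null label (train mode).
#' @param report_id Carried into each window.
#' @param text Optional report text; enables line/sentence-aligned cuts.
#' @return List of windows: each a list with `report_id`, `window_index`,
#'   `token_start` (1-based index into the report token sequence) and
#'   `tokens` (the tibble slice).
#' @export
window_tokens <- function(tokens, max_len = 128L, mode = c("train", "infer"),
                          overlap = 16L, null_label = "0", report_id = NA_character_,
                          text = NULL) {
  mode <- match.arg(mode)
  stopifnot(max_len >= 2)
  n <- nrow(tokens)
  if (n == 0) return(list())
  windows <- list()
  if (mode == "train") {
    lab <- tokens$label
    # a cut after token j is clean when a line break or sentence end follows,
    # keeping measurement names attached to their values
    clean <- rep(FALSE, n)
    if (!is.null(text)) {
      gap <- substring(text, tokens$end[-n] + 1L, tokens$start[-1])
      clean[-n] <- grepl("\n", gap) | (tokens$token[-n] == "." & lab[-n] == null_label)
    }
    s <- 1L
    while (s <= n) {
      e <- min(s + max_len - 1L, n)
      if (e < n) {
        cuts <- which(clean[s:e])
        if (length(cuts)) {
          e <- s + max(cuts) - 1L
        } else if (lab[e] != null_label && lab[e + 1L] == lab[e]) {
          nulls <- which(lab[s:e] == null_label)
          if (!length(nulls)) {
            abort(sprintf("annotation run longer than window (max_len=%d) at token %d", max_len, s))
          }
          e <- s + max(nulls) - 1L
        }
      }
      windows[[length(windows) + 1L]] <- list(
        report_id = report_id, window_index = length(windows) + 1L,
        token_start = s, tokens = tokens[s:e, , drop = FALSE])
      s <- e + 1L
    }
  } else {
    stopifnot(overlap >= 0, overlap < max_len)
    stride <- max_len - overlap
    if (n <= max_len) {
      starts <- 1L
    } else {
      starts <- seq(1L, n - max_len + 1L, by = stride)
      if (tail(starts, 1) + max_len - 1L < n) starts <- c(starts, n - max_len + 1L)
    }
    ends <- pmin(starts + max_len - 1L, n)
    for (i in seq_along(starts)) {
      windows[[length(windows) + 1L]] <- list(
        report_id = report_id, window_index = i, token_start = starts[i],
        tokens = tokens[starts[i]:ends[i], , drop = FALSE])
    }
  }
  windows
}

#' @rdname window_tokens
#' @param windows A list of windows from `window_tokens()`.
#' @export
flatten_windows <- function(windows) {
  bind_rows(purrr::map(windows, "tokens"))
}

# Tokenize + label + window a whole corpus in one pass (training layout).
# Returns a flat list of windows across reports.
corpus_windows <- function(reports, annotations, tokenizer, schema, max_len = 128L) {
  out <- list()
  for (i in seq_len(nrow(reports))) {
    rid <- reports$report_id[i]
    ann <- if (is.null(annotations)) NULL else annotations[annotations$report_id == rid, ]
    toks <- tokenize_with_labels(reports$text[i], ann, tokenizer, schema)
    ws <- window_tokens(toks, max_len = max_len, mode = "train",
                        null_label = schema$null_label, report_id = rid,
                        text = reports$text[i])
    out <- c(out, ws)
  }
  out
}
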