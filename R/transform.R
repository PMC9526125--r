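#' Numerical token representations
#'
#' Subword vocabularies contain few numerals and no decimal numbers, so a
#' value like `51.01` fragments into several pieces during tokenization.
#' `transform_text()` rewrites every free-standing numeric token of a text
#' into one of five representations while leaving all other characters
#' untouched, and records an exact, invertible character-offset map between
#' the transformed and original text:
#'
#' * `original` — no rewrite (identity offset map).
#' * `replaced_decimal` — the decimal point becomes the separator `|`
#'   (`51.01` to `51|01`), which keeps the number intact as a single token
#'   when `|` is registered as a special vocabulary symbol.
#' * `consistent_digits` — every value becomes exactly 6 digits: 3 integer
#'   digits and 3 fractional digits, zero-padded, decimal point dropped
#'   (`51.01` to `051010`). Values at or above 1000 or below 0 are not
#'   representable; they are left untransformed and recorded in the
#'   `warnings` field.
#' * `scientific` — scientific notation with a 6-digit mantissa
#'   (`51.01` to `5.10100e+01`).
#' * `words` — lowercase English words, tens and units unhyphenated, decimal
#'   digits spoken individually (`51.01` to `fifty one point zero one`).
#'
#' Numeric tokens are maximal unsigned-or-signed digit runs with at most one
#' decimal point, delimited by non-alphanumeric characters. Components of
#' ranges (`55-60`), fractions and slashed dates (`03/14/2012`) pass through
#' untransformed.
#'
#' @param text A single string.
#' @param mode One of `"original"`, `"replaced_decimal"`, `"consistent_digits"`,
#'   `"scientific"`, `"words"`.
#' @return A `transformed_text` object: list with `mode`, `text` (transformed),
#'   `original`, `offset_map` (tibble mapping each rewritten token's
#'   transformed range `[t_start, t_end)` to its original range
#'   `[o_start, o_end)`, 0-based half-open), and `warnings` (tibble of tokens
#'   left untransformed and why).
#' @export
transform_text <- function(text, mode = repr_modes()) {
  mode <- match.arg(mode)
  stopifnot(is.character(text), length(text) == 1)
  toks <- find_numeric_tokens(text)
  warnings <- tibble(token = character(), start = integer(), reason = character())
  if (mode == "original" || nrow(toks) == 0) {
    return(structure(list(mode = mode, text = text, original = text,
                          offset_map = empty_offset_map(), warnings = warnings),
                     class = "transformed_text"))
  }
  pieces <- character(0)
  map_rows <- list()
  cursor <- 0L  # 0-based position in original consumed so far
  t_pos <- 0L   # 0-based position in transformed text built so far
  for (i in seq_len(nrow(toks))) {
    tok <- toks$token[i]
    o_start <- toks$start[i]
    o_end <- toks$end[i]
    rep <- render_number(tok, mode)
    if (is.na(rep)) {
      warnings <- bind_rows(warnings, tibble(token = tok, start = o_start,
                                             reason = "not representable in consistent_digits (>= 1000 or negative)"))
      rep <- tok
    }
    lit <- span_text(text, cursor, o_start)
    pieces <- c(pieces, lit, rep)
    t_start <- t_pos + nchar(lit)
    map_rows[[length(map_rows) + 1L]] <- tibble(
      o_start = o_start, o_end = o_end,
      t_start = t_start, t_end = t_start + nchar(rep),
      token = rep, orig_token = tok)
    t_pos <- t_start + nchar(rep)
    cursor <- o_end
  }
  pieces <- c(pieces, span_text(text, cursor, nchar(text)))
  structure(list(mode = mode, text = paste(pieces, collapse = ""), original = text,
                 offset_map = bind_rows(map_rows), warnings = warnings),
            class = "transformed_text")
}

#' @rdname transform_text
#' @export
repr_modes <- function() {
  c("original", "replaced_decimal", "consistent_digits", "scientific", "words")
}

#' @export
print.transformed_text <- function(x, ...) {
  cat(sprintf("<transformed_text mode=%s, %d rewritten token(s)>\n%s\n",
              x$mode, nrow(x$offset_map), x$text))
  invisible(x)
}

empty_offset_map <- function() {
  tibble(o_start = integer(), o_end = integer(), t_start = integer(),
         t_end = integer(), token = character(), orig_token = character())
}

# Maximal numeric tokens, excluding range/fraction/date components.
find_numeric_tokens <- function(text) {
  # trailing sentence periods are fine; a dot that continues into digits is not
  pat <- "(?<![A-Za-z0-9_.])-?[0-9]+(?:\\.[0-9]+)?(?![A-Za-z0-9_]|\\.[0-9])"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(tibble(token = character(), start = integer(), end = integer()))
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  end <- start + len
  token <- substring(text, start + 1L, end)
  keep <- purrr::map_lgl(seq_along(start), function(i) {
    before2 <- span_text(text, max(start[i] - 2L, 0L), start[i])
    after2 <- span_text(text, end[i], min(end[i] + 2L, nchar(text)))
    # part of a range (55-60), fraction or slashed date: pass through
    !(grepl("^[0-9][-/]$", before2) || grepl("^[-/][0-9]", after2))
  })
  tibble(token = token[keep], start = start[keep], end = end[keep])
}

# Render one numeric token string in a representation mode.
# Returns NA_character_ when the token is not representable in the mode.
render_number <- function(token, mode) {
  switch(mode,
    original = token,
    replaced_decimal = gsub(".", "|", token, fixed = TRUE),
    consistent_digits = {
      v <- as.numeric(token)
      n <- round(v * 1000)
      if (v < 0 || n >= 1e6) NA_character_ else sprintf("%06d", n)
    },
    scientific = sprintf("%.5e", as.numeric(token)),
    words = number_to_words(token),
    abort(paste0("unknown representation mode: ", mode))
  )
}

#' Invert a transformed numeric token back to its value
#'
#' Parses a token produced by [transform_text()] in the given mode back to the
#' numeric value it encodes. Exact for `replaced_decimal` and `scientific`;
#' exact to 3 decimals for `consistent_digits` (fixed 3 fractional digits) and
#' `words` (digits spoken individually after "point").
#'
#' @param token Token string in the representation.
#' @param mode Representation mode (see [repr_modes()]).
#' @return The numeric value.
#' @export
invert_value <- function(token, mode = repr_modes()) {
  mode <- match.arg(mode)
  out <- switch(mode,
    original = suppressWarnings(as.numeric(token)),
    replaced_decimal = suppressWarnings(as.numeric(gsub("|", ".", token, fixed = TRUE))),
    consistent_digits = {
      if (!grepl("^[0-9]{6}$", token)) NA_real_
      else as.numeric(paste0(substr(token, 1, 3), ".", substr(token, 4, 6)))
    },
    scientific = {
      if (!grepl("^-?[0-9]\\.[0-9]+e[+-][0-9]+$", token)) NA_real_
      else as.numeric(token)
    },
    words = words_to_number(token)
  )
  if (is.na(out)) abort(paste0("cannot parse token '", token, "' in mode '", mode, "'"))
  out
}

#' Map spans between transformed and original coordinates
#'
#' Translates a character span through the offset map of a
#' [transform_text()] result. Positions outside rewritten tokens shift by the
#' accumulated length difference; a span touching a rewritten token expands to
#' cover the whole corresponding token in the target coordinates, so a
#' transformed span over a rewritten number always maps back to the exact
#' original number span.
#'
#' @param tt A `transformed_text`.
#' @param start,end 0-based half-open span.
#' @param direction `"to_original"` (default) maps transformed coordinates to
#'   original ones; `"to_transformed"` the reverse.
#' @return Integer vector `c(start, end)` in the target coordinates.
#' @export
map_span <- function(tt, start, end, direction = c("to_original", "to_transformed")) {
  direction <- match.arg(direction)
  stopifnot(inherits(tt, "transformed_text"), start >= 0, end > start)
  src_len <- nchar(if (direction == "to_original") tt$text else tt$original)
  if (end > src_len) abort(sprintf("span [%d,%d) outside text of length %d", start, end, src_len))
  om <- tt$offset_map
  if (nrow(om) == 0) return(c(start, end))
  if (direction == "to_original") {
    src <- om[, c("t_start", "t_end")]; dst <- om[, c("o_start", "o_end")]
  } else {
    src <- om[, c("o_start", "o_end")]; dst <- om[, c("t_start", "t_end")]
  }
  names(src) <- c("s0", "s1"); names(dst) <- c("d0", "d1")
  delta_before <- function(pos) {
    i <- src$s1 <= pos
    sum(dst$d1[i] - dst$d0[i]) - sum(src$s1[i] - src$s0[i])
  }
  b_start <- which(src$s0 <= start & start < src$s1)
  b_end <- which(src$s0 < end & end <= src$s1)
  new_start <- if (length(b_start)) dst$d0[b_start[1]] else start + delta_before(start)
  new_end <- if (length(b_end)) dst$d1[b_end[1]] else end + delta_before(end)
  c(as.integer(new_start), as.integer(new_end))
}

#' Transform a report corpus and remap its annotations
#'
#' Applies [transform_text()] to every report and remaps gold annotation spans
#' into the transformed coordinates (values are unchanged). The returned
#' `transforms` list (named by report id) carries the offset maps needed to
#' map model predictions back to original text.
#'
#' @param reports Report tibble (`report_id`, `text`, ...).
#' @param annotations Annotation tibble, or `NULL`.
#' @param mode Representation mode.
#' @return List with `reports` (texts transformed), `annotations` (spans
#'   remapped) and `transforms`.
#' @export
transform_corpus <- function(reports, annotations = NULL, mode = repr_modes()) {
  mode <- match.arg(mode)
  tts <- setNames(purrr::map(reports$text, transform_text, mode = mode), reports$report_id)
  out_reports <- mutate(reports, text = purrr::map_chr(tts, "text")[.data$report_id])
  out_ann <- annotations
  if (!is.null(annotations) && nrow(annotations)) {
    spans <- purrr::pmap(annotations[, c("report_id", "start", "end")],
                         function(report_id, start, end) {
                           map_span(tts[[report_id]], start, end, "to_transformed")
                         })
    out_ann <- mutate(annotations,
                      start = purrr::map_int(spans, ~ .x[1]),
                      end = purrr::map_int(spans, ~ .x[2]))
  }
  list(reports = out_reports, annotations = out_ann, transforms = tts, mode = mode)
}

# ---- number words ----------------------------------------------------------

.ones <- c("zero", "one", "two", "three", "four", "five", "six", "seven",
           "eight", "nine", "ten", "eleven", "twelve", "thirteen", "fourteen",
           "fifteen", "sixteen", "seventeen", "eighteen", "nineteen")
.tens <- c("twenty", "thirty", "forty", "fifty", "sixty", "seventy", "eighty", "ninety")

int_to_words <- function(n) {
  stopifnot(n >= 0, n < 1e6)
  if (n < 20) return(.ones[n + 1])
  if (n < 100) {
    t <- .tens[n %/% 10 - 1]
    r <- n %% 10
    return(if (r == 0) t else paste(t, .ones[r + 1]))
  }
  if (n < 1000) {
    h <- paste(.ones[n %/% 100 + 1], "hundred")
    r <- n %% 100
    return(if (r == 0) h else paste(h, int_to_words(r)))
  }
  th <- paste(int_to_words(n %/% 1000), "thousand")
  r <- n %% 1000
  if (r == 0) th else paste(th, int_to_words(r))
}

# Renders the literal digit string: "51.01" -> "fifty one point zero one".
number_to_words <- function(token) {
  neg <- startsWith(token, "-")
  if (neg) token <- substring(token, 2)
  parts <- strsplit(token, ".", fixed = TRUE)[[1]]
  ip <- suppressWarnings(as.numeric(parts[1]))
  if (is.na(ip) || ip >= 1e6) return(token)  # out of lexicon; pass through
  words <- int_to_words(ip)
  if (length(parts) == 2) {
    digits <- strsplit(parts[2], "")[[1]]
    words <- paste(words, "point", paste(.ones[as.integer(digits) + 1], collapse = " "))
  }
  if (neg) words <- paste("minus", words)
  words
}

words_to_number <- function(words) {
  toks <- strsplit(trimws(words), "\\s+")[[1]]
  if (!length(toks)) return(NA_real_)
  neg <- toks[1] == "minus"
  if (neg) toks <- toks[-1]
  p <- match("point", toks)
  int_toks <- if (is.na(p)) toks else head(toks, p - 1)
  frac_toks <- if (is.na(p)) character(0) else tail(toks, length(toks) - p)
  total <- 0; chunk <- 0
  for (w in int_toks) {
    if (w %in% .ones) chunk <- chunk + (match(w, .ones) - 1)
    else if (w %in% .tens) chunk <- chunk + (match(w, .tens) + 1) * 10
    else if (w == "hundred") chunk <- chunk * 100
    else if (w == "thousand") { total <- total + chunk * 1000; chunk <- 0 }
    else return(NA_real_)
  }
  v <- total + chunk
  if (length(frac_toks)) {
    d <- match(frac_toks, .ones) - 1
    if (anyNA(d)) return(NA_real_)
    v <- v + sum(d * 10^(-seq_along(d)))
  }
  if (neg) -v else v
}
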