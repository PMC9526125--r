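#' Subword tokenizer with character offsets
#'
#' A vocabulary-based subword tokenizer in the WordPiece family, sufficient
#' for the token-classification contract used throughout the package: text in,
#' token ids plus exact 0-based half-open character offsets out. Any tokenizer
#' honouring that contract can be substituted.
#'
#' Pre-tokenization splits on whitespace into letter runs, digit runs and
#' single punctuation characters, so a decimal value like `51.01` fragments
#' into `51`, `.`, `01` exactly as the standard subword vocabularies fragment
#' numbers. Registered special symbols (by default the `|` separator of the
#' replaced-decimal representation) glue digit runs into a single pre-token
#' (`51|01`), which is emitted as one token — the point of that representation.
#' Within a pre-token, greedy longest-match against the vocabulary applies;
#' all observed single characters are always in the vocabulary, so
#' tokenization never fails, and anything else falls back to `[UNK]` (id 2;
#' `[PAD]` is id 1).
#'
#' Digit pieces are *shape-embedded*: a piece of 1-2 digits keeps its exact
#' text and offsets but maps to a shared id per shape (`<num1>`, `<num2>`,
#' `<numsep>` for glued separator numbers). The digits themselves carry no
#' information about which measurement a value belongs to — that lives in the
#' surrounding words — and distinct ids per digit string invite a small model
#' to memorize accidental digit-label correlations in a small training corpus
#' instead of reading the context.
#'
#' @param texts Character vector used to build the vocabulary.
#' @param min_count Minimum corpus frequency for a multi-character word piece.
#' @param specials Characters that glue numeric pre-tokens (default `"|"`).
#' @return A `subword_tokenizer` object.
#' @export
build_tokenizer <- function(texts, min_count = 2L, specials = "|") {
  pieces <- unlist(purrr::map(texts, ~ pre_tokenize(.x, specials)$piece))
  counts <- table(pieces)
  words <- names(counts)[counts >= min_count & nchar(names(counts)) > 1 &
                           !grepl("^[0-9.|]+$", names(counts))]
  chars <- unique(unlist(strsplit(pieces, "")))
  shapes <- c("<num1>", "<num2>", "<numsep>")
  vocab <- unique(c("[PAD]", "[UNK]", shapes, chars, sort(words)))
  index <- new.env(parent = emptyenv())
  for (i in seq_along(vocab)) assign(vocab[i], i, envir = index)
  structure(list(vocab = vocab, index = index, specials = specials,
                 max_piece = 24L, min_count = min_count),
            class = "subword_tokenizer")
}

#' @export
print.subword_tokenizer <- function(x, ...) {
  cat(sprintf("<subword_tokenizer> vocabulary of %d pieces (specials: %s)\n",
              length(x$vocab), paste(x$specials, collapse = " ")))
  invisible(x)
}

pre_tokenize <- function(text, specials = "|") {
  glue <- "|" %in% specials
  pat <- if (glue) "[A-Za-z]+|[0-9]+(?:\\|[0-9]+)+|[0-9]+|[^ \t\r\nA-Za-z0-9]"
  else "[A-Za-z]+|[0-9]+|[^ \t\r\nA-Za-z0-9]"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(tibble(piece = character(), start = integer(), end = integer()))
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  tibble(piece = substring(text, start + 1L, end), start = start, end = end)
}

#' Tokenize text into subword tokens with offsets
#'
#' @param tokenizer A [build_tokenizer()] object.
#' @param text A single string.
#' @return Tibble with `token_id`, `token`, `start`, `end` (0-based half-open
#'   character offsets into `text`).
#' @export
tokenize_text <- function(tokenizer, text) {
  stopifnot(inherits(tokenizer, "subword_tokenizer"))
  pre <- pre_tokenize(text, tokenizer$specials)
  idx <- tokenizer$index
  unk <- 2L
  out_tok <- character(0); out_id <- integer(0); out_s <- integer(0); out_e <- integer(0)
  for (i in seq_len(nrow(pre))) {
    piece <- pre$piece[i]
    base <- pre$start[i]
    if (grepl("|", piece, fixed = TRUE)) {
      # glued numeric pre-token stays intact (special separator), shape id
      out_tok <- c(out_tok, piece); out_id <- c(out_id, get("<numsep>", envir = idx))
      out_s <- c(out_s, base); out_e <- c(out_e, base + nchar(piece))
      next
    }
    if (grepl("^[0-9]+$", piece)) {
      # digit runs split into <=2-digit pieces with shared shape embeddings
      n <- nchar(piece)
      pos <- 1L
      while (pos <= n) {
        take <- min(2L, n - pos + 1L)
        out_tok <- c(out_tok, substr(piece, pos, pos + take - 1L))
        out_id <- c(out_id, get(if (take == 2L) "<num2>" else "<num1>", envir = idx))
        out_s <- c(out_s, base + pos - 1L); out_e <- c(out_e, base + pos - 1L + take)
        pos <- pos + take
      }
      next
    }
    n <- nchar(piece)
    pos <- 1L
    while (pos <= n) {
      len <- min(tokenizer$max_piece, n - pos + 1L)
      hit <- 0L
      while (len >= 1L) {
        cand <- substr(piece, pos, pos + len - 1L)
        if (exists(cand, envir = idx, inherits = FALSE)) { hit <- len; break }
        len <- len - 1L
      }
      if (hit == 0L) { hit <- 1L; cand <- substr(piece, pos, pos); id <- unk }
      else id <- get(cand, envir = idx)
      out_tok <- c(out_tok, cand); out_id <- c(out_id, id)
      out_s <- c(out_s, base + pos - 1L); out_e <- c(out_e, base + pos - 1L + hit)
      pos <- pos + hit
    }
  }
  if (length(out_e) && max(out_e) > nchar(text)) {
    abort("tokenizer produced offsets beyond text length")
  }
  tibble(token_id = out_id, token = out_tok, start = out_s, end = out_e)
}

#' @rdname build_tokenizer
#' @param tokenizer A `subword_tokenizer`.
#' @export
vocab_size <- function(tokenizer) length(tokenizer$vocab)
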