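#' Standoff annotations and report I/O
#'
#' Annotations are stored standoff: each row references a report by id and
#' carries 0-based half-open character offsets `[start, end)` into the raw
#' report text, the measurement `label`, and the numeric `value` parsed from
#' the annotated substring. The text itself is never modified, so annotations
#' remain valid as long as the report text is byte-identical.
#'
#' Files are JSON-lines: one object per annotation (or per report). On write,
#' annotations are canonicalized (sorted by `report_id`, then `start`) so that
#' write-then-read is the identity on canonical annotation tables.
#'
#' @param path File path.
#' @param annotations A tibble with columns `report_id`, `start`, `end`,
#'   `label`, `value`.
#' @param reports A tibble with columns `report_id`, `text` and optionally
#'   `person_id`, `report_date`.
#' @param schema Optional `cmr_schema`; when given, labels are checked.
#' @return `read_annotations()` returns the annotation tibble;
#'   `write_annotations()` returns `path` invisibly.
#' @export
read_annotations <- function(path, reports = NULL, schema = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  ann <- purrr::map(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    tibble(report_id = as.character(x$report_id), start = as.integer(x$start),
           end = as.integer(x$end), label = as.character(x$label),
           value = as.numeric(x$value))
  }) %>% bind_rows()
  if (nrow(ann) == 0) {
    ann <- tibble(report_id = character(), start = integer(), end = integer(),
                  label = character(), value = numeric())
  }
  ann <- arrange(ann, .data$report_id, .data$start)
  if (!is.null(reports) || !is.null(schema)) validate_annotations(ann, reports, schema)
  ann
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  annotations <- arrange(annotations, .data$report_id, .data$start)
  lines <- purrr::pmap_chr(
    annotations[, c("report_id", "start", "end", "label", "value")],
    function(report_id, start, end, label, value) {
      jsonlite::toJSON(list(report_id = report_id, start = start, end = end,
                            label = label, value = value),
                       auto_unbox = TRUE, digits = NA)
    })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_annotations
#' @export
read_reports <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  purrr::map(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    tibble(report_id = as.character(x$report_id), text = as.character(x$text),
           person_id = as.character(x$person_id %||% NA_character_),
           report_date = as.character(x$report_date %||% NA_character_))
  }) %>% bind_rows()
}

#' @rdname read_annotations
#' @export
write_reports <- function(reports, path) {
  cols <- intersect(c("report_id", "text", "person_id", "report_date"), names(reports))
  lines <- purrr::pmap_chr(reports[, cols], function(...) {
    jsonlite::toJSON(purrr::discard(list(...), ~ is.na(.x)), auto_unbox = TRUE, digits = NA)
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_annotations
#' @export
validate_annotations <- function(annotations, reports = NULL, schema = NULL) {
  if (!is.null(schema)) {
    bad <- setdiff(unique(annotations$label), schema$measurement_types$label)
    if (length(bad)) abort(paste0("unknown annotation label(s): ", paste(bad, collapse = ", ")))
  }
  if (any(annotations$start < 0) || any(annotations$start >= annotations$end)) {
    i <- which(annotations$start < 0 | annotations$start >= annotations$end)[1]
    abort(sprintf("invalid span [%d,%d) in report %s", annotations$start[i],
                  annotations$end[i], annotations$report_id[i]))
  }
  if (!is.null(reports)) {
    len <- setNames(nchar(reports$text), reports$report_id)
    missing <- setdiff(unique(annotations$report_id), reports$report_id)
    if (length(missing)) abort(paste0("annotations reference unknown report(s): ",
                                      paste(missing, collapse = ", ")))
    over <- annotations$end > len[annotations$report_id]
    if (any(over)) {
      i <- which(over)[1]
      abort(sprintf("span [%d,%d) beyond text length %d in report %s",
                    annotations$start[i], annotations$end[i],
                    len[[annotations$report_id[i]]], annotations$report_id[i]))
    }
  }
  invisible(annotations)
}

span_text <- function(text, start, end) substr(text, start + 1L, end)

#' Interannotator agreement
#'
#' Agreement between two annotators on the same report collection is the
#' proportion of matched extractions over the union of extractions. Two
#' annotations match when they come from the same report, carry the same
#' measurement label, their character spans overlap, and their parsed numeric
#' values are equal. Matching is one-to-one within each (report, label) group.
#' An empty union (neither annotator extracted anything) is defined as perfect
#' agreement, 1.
#'
#' @param a,b Annotation tibbles (see [read_annotations()]).
#' @return A list with `overall` (proportion in \[0, 1\]), `matched`, `union`,
#'   and `per_label`, a tibble of per-measurement agreement.
#' @export
interannotator_agreement <- function(a, b) {
  count_matches <- function(ga, gb) {
    used <- rep(FALSE, nrow(gb))
    m <- 0L
    if (nrow(ga)) ga <- arrange(ga, .data$start)
    if (nrow(gb)) gb <- arrange(gb, .data$start)
    for (i in seq_len(nrow(ga))) {
      for (j in seq_len(nrow(gb))) {
        if (!used[j] && ga$start[i] < gb$end[j] && gb$start[j] < ga$end[i] &&
            isTRUE(ga$value[i] == gb$value[j])) {
          used[j] <- TRUE
          m <- m + 1L
          break
        }
      }
    }
    m
  }
  keys <- unique(bind_rows(a[, c("report_id", "label")], b[, c("report_id", "label")]))
  per <- purrr::pmap(keys, function(report_id, label) {
    ga <- a[a$report_id == report_id & a$label == label, ]
    gb <- b[b$report_id == report_id & b$label == label, ]
    m <- count_matches(ga, gb)
    tibble(label = label, matched = m, union = nrow(ga) + nrow(gb) - m)
  }) %>% bind_rows()
  if (nrow(per) == 0) per <- tibble(label = character(), matched = integer(), union = integer())
  per_label <- per %>%
    group_by(.data$label) %>%
    summarise(matched = sum(.data$matched), union = sum(.data$union), .groups = "drop") %>%
    mutate(agreement = ifelse(.data$union == 0, 1, .data$matched / .data$union))
  matched <- sum(per$matched)
  un <- sum(per$union)
  list(overall = if (un == 0) 1 else matched / un,
       matched = matched, union = un, per_label = per_label)
}
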