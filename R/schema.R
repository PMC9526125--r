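#' Measurement schemas
#'
#' A schema defines the set of quantitative measurements to extract from
#' free-text reports. Each measurement type has a short unique `label`, a
#' human-readable `display_name`, one or more surface `aliases` as they appear
#' in report text, a canonical `unit` (possibly empty), and a physiologic
#' reference range `(lower, upper)` in that unit used to filter implausible
#' extractions. A reserved `null_label` marks tokens that belong to no
#' measurement, so a schema with `k` measurement types spans `k + 1` token
#' labels.
#'
#' The packaged default schema covers the 21 cardiac MRI measurements of
#' left-ventricular and right-ventricular anatomy and function plus left
#' atrial, pulmonary artery and aortic root dimensions, giving the 22-label
#' token space used throughout the package. Its physiologic bounds are
#' literature-typical reference ranges and are plain configuration: edit the
#' JSON/YAML document to adapt the workflow to other report types.
#'
#' @param path Path to a schema document (`.json`, `.yaml`/`.yml`).
#' @return A `cmr_schema` object: a list with `measurement_types` (a tibble
#'   with columns `label`, `display_name`, `aliases` (list column), `unit`,
#'   `lower`, `upper`) and `null_label` (string).
#' @examples
#' sch <- default_schema()
#' nrow(sch$measurement_types)  # 21
#' n_labels(sch)                # 22
#' @export
load_schema <- function(path) {
  if (!file.exists(path)) abort(paste0("schema file not found: ", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  new_schema(raw)
}

#' @rdname load_schema
#' @export
default_schema <- function() {
  load_schema(system.file("extdata", "cmr_schema.json", package = "cmrextract"))
}

new_schema <- function(raw) {
  if (is.null(raw$measurement_types)) abort("schema document lacks 'measurement_types'")
  null_label <- raw$null_label %||% "0"
  mt <- purrr::map(raw$measurement_types, function(m) {
    for (f in c("label", "display_name", "aliases", "unit", "physiologic_range")) {
      if (is.null(m[[f]])) abort(paste0("schema entry missing field '", f, "'",
                                        if (!is.null(m$label)) paste0(" (label ", m$label, ")")))
    }
    aliases <- as.character(unlist(m$aliases))
    if (length(aliases) == 0) abort(paste0("schema entry '", m$label, "' has no aliases"))
    rng <- as.numeric(unlist(m$physiologic_range))
    if (length(rng) != 2 || !all(is.finite(rng)) || rng[1] >= rng[2]) {
      abort(paste0("schema entry '", m$label, "' has an invalid physiologic range (need lower < upper)"))
    }
    tibble(label = as.character(m$label), display_name = as.character(m$display_name),
           aliases = list(aliases), unit = as.character(m$unit),
           lower = rng[1], upper = rng[2])
  }) %>% bind_rows()
  if (anyDuplicated(mt$label)) {
    dup <- unique(mt$label[duplicated(mt$label)])
    abort(paste0("duplicate schema label(s): ", paste(dup, collapse = ", ")))
  }
  if (null_label %in% mt$label) abort("null_label collides with a measurement label")
  structure(list(measurement_types = mt, null_label = null_label), class = "cmr_schema")
}

#' @export
print.cmr_schema <- function(x, ...) {
  cat(sprintf("<cmr_schema> %d measurement types (+ null label \"%s\", %d-label token space)\n",
              nrow(x$measurement_types), x$null_label, n_labels(x)))
  print(x$measurement_types, ...)
  invisible(x)
}

#' Label space helpers
#'
#' `schema_labels()` returns the full ordered label vector with the null label
#' first; `n_labels()` its length (21 measurements + null = 22 for the default
#' schema).
#'
#' @param schema A `cmr_schema`.
#' @export
schema_labels <- function(schema) {
  stopifnot(inherits(schema, "cmr_schema"))
  c(schema$null_label, schema$measurement_types$label)
}

#' @rdname schema_labels
#' @export
n_labels <- function(schema) length(schema_labels(schema))

schema_range <- function(schema, label) {
  mt <- schema$measurement_types
  i <- match(label, mt$label)
  if (anyNA(i)) abort(paste0("unknown measurement label(s): ",
                             paste(unique(label[is.na(i)]), collapse = ", ")))
  list(lower = mt$lower[i], upper = mt$upper[i])
}
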