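test_that("the worked snippet transforms bit-exactly in every mode", {
  s <- "RVESV: 51.01 ml"
  expect_identical(transform_text(s, "original")$text, s)
  expect_identical(transform_text(s, "replaced_decimal")$text, "RVESV: 51|01 ml")
  expect_identical(transform_text(s, "consistent_digits")$text, "RVESV: 051010 ml")
  expect_identical(transform_text(s, "scientific")$text, "RVESV: 5.10100e+01 ml")
  expect_identical(transform_text(s, "words")$text,
                   "RVESV: fifty one point zero one ml")
})

test_that("inverse parsing recovers the worked values exactly", {
  expect_equal(invert_value("51|01", "replaced_decimal"), 51.01)
  expect_equal(invert_value("051010", "consistent_digits"), 51.01)
  expect_equal(invert_value("5.10100e+01", "scientific"), 51.01)
  expect_equal(invert_value("fifty one point zero one", "words"), 51.01)
  expect_error(invert_value("51|0x", "replaced_decimal"), "cannot parse")
  expect_error(invert_value("12345", "consistent_digits"), "cannot parse")
})

test_that("text without numeric tokens passes through unchanged in every mode", {
  s <- "no numbers here, only words."
  for (m in repr_modes()) {
    tt <- transform_text(s, m)
    expect_identical(tt$text, s)
    expect_equal(nrow(tt$offset_map), 0)
  }
})

test_that("random values round-trip through every mode to 3 decimals", {
  set.seed(42)
  n <- 400
  dp <- sample(0:3, n, replace = TRUE)
  vals <- round(runif(n, 0.001, 999.999), dp)
  strs <- sprintf(paste0("%.", dp, "f"), vals)
  for (m in setdiff(repr_modes(), "original")) {
    toks <- vapply(strs, cmrextract:::render_number, "", mode = m)
    back <- vapply(toks, invert_value, 0, mode = m)
    expect_true(all(abs(back - vals) < 5e-4), info = m)
  }
})

test_that("consistent-digits tokens are always 6 characters; out-of-format values are flagged", {
  tt <- transform_text("LVEDV: 147 ml, LVM 99.5 g", "consistent_digits")
  expect_true(all(nchar(tt$offset_map$token) == 6))
  expect_identical(tt$text, "LVEDV: 147000 ml, LVM 099500 g")
  big <- transform_text("mass 1234 g and LVEF 55", "consistent_digits")
  expect_equal(nrow(big$warnings), 1)
  expect_match(big$warnings$token, "1234")
  expect_match(big$text, "1234", fixed = TRUE)      # left untransformed
  expect_match(big$text, "055000", fixed = TRUE)    # other token still rewritten
})

test_that("non-numeric characters are preserved byte-identically outside rewritten spans", {
  s <- "LVEF: 55.5 %; RVEDV 147.54 ml (normal)"
  for (m in setdiff(repr_modes(), "original")) {
    tt <- transform_text(s, m)
    om <- tt$offset_map
    strip <- function(text, starts, ends) {
      keep <- rep(TRUE, nchar(text))
      for (i in seq_along(starts)) keep[(starts[i] + 1):ends[i]] <- FALSE
      paste(strsplit(text, "")[[1]][keep], collapse = "")
    }
    expect_identical(strip(tt$text, om$t_start, om$t_end),
                     strip(tt$original, om$o_start, om$o_end), info = m)
  }
})

test_that("span mapping is the identity in original mode and inverts rewrites", {
  tt0 <- transform_text("LVEF 55", "original")
  expect_equal(map_span(tt0, 2, 6), c(2L, 6L))

  s <- "RVESV: 51.01 ml"
  tt <- transform_text(s, "replaced_decimal")
  # the rewritten token occupies [7,12) in both texts here (same length)
  expect_equal(map_span(tt, 7, 12, "to_original"), c(7L, 12L))
  expect_equal(substr(s, 8, 12), "51.01")

  tw <- transform_text(s, "words")
  om <- tw$offset_map
  sp <- map_span(tw, om$t_start[1], om$t_end[1], "to_original")
  expect_equal(cmrextract:::span_text(s, sp[1], sp[2]), "51.01")
  # a partial span over the rewritten token expands to the full original token
  sp2 <- map_span(tw, om$t_start[1] + 3, om$t_start[1] + 5, "to_original")
  expect_equal(cmrextract:::span_text(s, sp2[1], sp2[2]), "51.01")
  # spans over unit text shift but keep their width
  unit_span <- map_span(tw, om$t_end[1] + 1, om$t_end[1] + 3, "to_original")
  expect_equal(cmrextract:::span_text(s, unit_span[1], unit_span[2]), "ml")
  expect_error(map_span(tw, 0, 10 * nchar(tw$text)), "outside")
})

test_that("to_transformed and to_original are mutually inverse on annotation spans", {
  corp <- fixture_corpus()
  tc <- transform_corpus(corp$reports, corp$annotations, "words")
  ann_t <- tc$annotations
  for (i in seq_len(nrow(ann_t))) {
    tt <- tc$transforms[[ann_t$report_id[i]]]
    back <- map_span(tt, ann_t$start[i], ann_t$end[i], "to_original")
    orig <- corp$annotations[i, ]
    expect_equal(back, c(orig$start, orig$end))
    # transformed span substring parses back to the gold value
    token <- cmrextract:::span_text(tt$text, ann_t$start[i], ann_t$end[i])
    expect_equal(invert_value(token, "words"), orig$value, tolerance = 1e-9)
  }
})

test_that("ranges and slashed dates pass through untransformed", {
  s <- "LVEF 55-60 % on 03/14/2012, LVM 120 g"
  tt <- transform_text(s, "words")
  expect_match(tt$text, "55-60", fixed = TRUE)
  expect_match(tt$text, "03/14/2012", fixed = TRUE)
  expect_match(tt$text, "one hundred twenty", fixed = TRUE)
})
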