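test_that("digit merging extends a partial run to the full number and stops at whitespace", {
  text <- "LVEF: 51.01 ml"
  # run covering only "51" extends over ".01"
  expect_equal(merge_digits(text, 6, 8), c(6L, 11L))
  # full number is a fixed point (idempotence)
  expect_equal(merge_digits(text, 6, 11), c(6L, 11L))
  once <- merge_digits(text, 6, 8)
  expect_equal(merge_digits(text, once[1], once[2]), once)
  # whitespace stops extension: span over "51.01" never grabs "ml"
  expect_equal(merge_digits("x 51.01 ml", 2, 7), c(2L, 7L))
  # span with no adjacent digits is untouched
  expect_equal(merge_digits("no digits", 0, 2), c(0L, 2L))
})

test_that("consolidation merges token runs into one measurement with the parsed value", {
  sch <- fixture_schema()
  text <- "LVEF: 51.01 ml"
  tt <- transform_text(text, "original")
  tokens <- tibble::tibble(
    token = c("LVEF", ":", "51", ".", "01", "ml"),
    start = c(0L, 4L, 6L, 8L, 9L, 12L),
    end = c(4L, 5L, 8L, 9L, 11L, 14L),
    label = c("0", "0", "lvef", "lvef", "lvef", "0"),
    score = c(0.9, 0.9, 0.8, 0.7, 0.9, 0.9))
  out <- consolidate(tokens, tt, "r1", sch)
  expect_equal(nrow(out), 1)
  expect_equal(out$label, "lvef")
  expect_equal(out$value, 51.01)
  expect_equal(c(out$start, out$end), c(6L, 11L))
  expect_equal(out$score, mean(c(0.8, 0.7, 0.9)))

  # zero non-null labels -> empty result
  none <- dplyr::mutate(tokens, label = "0")
  expect_equal(nrow(consolidate(none, tt, "r1", sch)), 0)
})

test_that("duplicate candidates keep the highest mean score; the rest are flagged", {
  sch <- fixture_schema()
  text <- "LVEF 60 then LVEF 55"
  tt <- transform_text(text, "original")
  tokens <- tibble::tibble(
    token = c("LVEF", "60", "then", "LVEF", "55"),
    start = c(0L, 5L, 8L, 13L, 18L),
    end = c(4L, 7L, 12L, 17L, 20L),
    label = c("0", "lvef", "0", "0", "lvef"),
    score = c(1, 0.6, 1, 1, 0.9))
  out <- consolidate(tokens, tt, "r1", sch)
  expect_equal(nrow(out), 2)                      # conservation: both candidates kept
  emitted <- out[out$emitted, ]
  expect_equal(emitted$value, 55)                 # the 0.9 candidate wins
  flagged <- out[!out$emitted, ]
  expect_equal(flagged$reason, "duplicate")
  expect_equal(flagged$value, 60)
})

test_that("candidates without a parseable number are retained with reason non-numeric", {
  sch <- fixture_schema()
  tt <- transform_text("LVEF normal today", "original")
  tokens <- tibble::tibble(token = c("LVEF", "normal"), start = c(0L, 5L),
                           end = c(4L, 11L), label = c("0", "lvef"),
                           score = c(1, 0.8))
  out <- consolidate(tokens, tt, "r1", sch)
  expect_equal(nrow(out), 1)
  expect_false(out$emitted)
  expect_equal(out$reason, "non-numeric")
})

test_that("physiologic filtering flags but never deletes, idempotently", {
  sch <- fixture_schema()
  meas <- tibble::tibble(report_id = "r1", label = c("lvef", "lvef", "lvm"),
                         value = c(55, 150, 2000), start = 0L, end = 2L,
                         score = 1, emitted = TRUE, filtered = FALSE,
                         reason = NA_character_)
  out <- filter_physiologic(meas, sch)
  expect_equal(nrow(out), 3)
  expect_equal(out$filtered, c(FALSE, TRUE, TRUE))
  expect_equal(out$reason, c(NA, "out-of-range", "out-of-range"))
  # idempotent and order-independent
  expect_equal(filter_physiologic(out, sch), out)
  perm <- out[c(3, 1, 2), ]
  expect_equal(filter_physiologic(perm, sch), perm)
  # unknown label errors
  expect_error(filter_physiologic(dplyr::mutate(meas, label = "zzz"), sch), "unknown")
})

test_that("gold labels pass through consolidation + filtering to the exact gold annotations", {
  sch <- fixture_schema()
  tok <- fixture_tokenizer()
  corp <- fixture_corpus()   # generated with out_of_range_rate = 0
  recovered <- purrr::map(seq_len(nrow(corp$reports)), function(i) {
    rid <- corp$reports$report_id[i]
    ann <- corp$annotations[corp$annotations$report_id == rid, ]
    lt <- tokenize_with_labels(corp$reports$text[i], ann, tok, sch)
    lt$score <- 1
    out <- consolidate(lt, transform_text(corp$reports$text[i], "original"), rid, sch)
    emitted_measurements(filter_physiologic(out, sch))
  }) %>% dplyr::bind_rows()
  gold <- dplyr::arrange(corp$annotations, report_id, start)
  got <- dplyr::arrange(recovered[, c("report_id", "start", "end", "label", "value")],
                        report_id, start)
  expect_equal(got, gold[, c("report_id", "start", "end", "label", "value")])
})

test_that("the out-of-range flag rate tracks the generator's out-of-range rate", {
  sch <- fixture_schema()
  corp <- generate_corpus(corpus_config(n_reports = 150, seed = 202,
                                        out_of_range_rate = 0.1), sch)
  rng <- cmrextract:::schema_range(sch, corp$annotations$label)
  flagged <- corp$annotations$value < rng$lower | corp$annotations$value > rng$upper
  expect_gt(mean(flagged), 0.1 - 0.02)
  expect_lt(mean(flagged), 0.1 + 0.02)
})
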