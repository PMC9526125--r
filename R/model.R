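#' Training configuration
#'
#' Defaults follow the measurement-extraction training recipe: token-level
#' cross-entropy, batch size 32, up to 20 epochs, per-token decision threshold
#' 0.5, Adam with a linear learning-rate decay, decoupled weight decay and
#' residual dropout. The replication learning rate for fine-tuning a
#' pretrained encoder is 5e-5; the `tiny_scratch` profile (a compact 2-layer,
#' 128-hidden, 4-head encoder trained from random initialization so that the
#' full workflow runs without any model download) defaults to 1e-3, since a
#' randomly initialized encoder does not move at a fine-tuning rate. Pass
#' `learning_rate` explicitly to override either.
#'
#' @param learning_rate Adam learning rate; `NULL` resolves by profile
#'   (`tiny_scratch` 1e-3, otherwise 5e-5).
#' @param batch_size Windows per optimization step.
#' @param max_epochs Training epochs; per-epoch metrics are returned so the
#'   epoch maximizing dev macro-F1 is selected.
#' @param seed Seed for initialization and batch shuffling.
#' @param encoder_profile `"tiny_scratch"` or a list overriding encoder
#'   dimensions (`d_model`, `n_heads`, `n_layers`, `d_ff`, `max_len`).
#' @param decode_threshold Per-token score threshold for label assignment.
#' @param weight_decay Decoupled weight decay on weight matrices (AdamW);
#'   regularizes the from-scratch profile against memorizing its small
#'   training corpus.
#' @param dropout Residual dropout rate applied to the attention and
#'   feed-forward branch outputs during training (0 disables).
#' @param lr_decay `"linear"` decays the learning rate linearly to zero over
#'   the configured epochs (the usual fine-tuning schedule); `"none"` keeps it
#'   fixed.
#' @param ema_decay Per-step exponential-moving-average decay for the
#'   evaluated parameters (0 disables); averaging smooths the step-to-step
#'   noise of small-batch training.
#' @export
train_config <- function(learning_rate = NULL, batch_size = 32L, max_epochs = 20L,
                         seed = 1L, encoder_profile = "tiny_scratch",
                         decode_threshold = 0.5, weight_decay = 0.01,
                         dropout = 0.1, lr_decay = c("linear", "none"),
                         ema_decay = 0.998) {
  lr_decay <- match.arg(lr_decay)
  enc <- encoder_dims(encoder_profile)
  if (is.null(learning_rate)) {
    learning_rate <- if (identical(encoder_profile, "tiny_scratch") || is.list(encoder_profile))
      1e-3 else 5e-5
  }
  stopifnot(learning_rate > 0, max_epochs >= 1, batch_size >= 1)
  list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
       max_epochs = as.integer(max_epochs), seed = as.integer(seed),
       encoder_profile = encoder_profile, encoder = enc,
       decode_threshold = decode_threshold, weight_decay = weight_decay,
       dropout = dropout, lr_decay = lr_decay, ema_decay = ema_decay)
}

encoder_dims <- function(profile) {
  base <- list(d_model = 128L, n_heads = 4L, n_layers = 2L, d_ff = 256L, max_len = 128L)
  if (identical(profile, "tiny_scratch")) return(base)
  if (is.list(profile)) return(modifyList(base, profile))
  if (is.character(profile) && startsWith(profile, "pretrained:")) {
    abort(paste0("encoder profile '", profile, "' needs externally downloaded ",
                 "pretrained weights, which this installation does not ship; ",
                 "use 'tiny_scratch' or supply encoder dimensions as a list"))
  }
  abort(paste0("unknown encoder profile: ", profile))
}

# windows -> padded id/mask/label matrices (labels NA on padding)
make_batch <- function(windows, label_levels, max_len) {
  B <- length(windows)
  T <- min(max(purrr::map_int(windows, ~ nrow(.x$tokens))), max_len)
  ids <- matrix(1L, B, T)      # [PAD] id 1
  mask <- matrix(FALSE, B, T)
  labs <- matrix(NA_integer_, B, T)
  for (b in seq_len(B)) {
    tk <- windows[[b]]$tokens
    n <- min(nrow(tk), T)
    ids[b, seq_len(n)] <- tk$token_id[seq_len(n)]
    mask[b, seq_len(n)] <- TRUE
    if ("label" %in% names(tk)) labs[b, seq_len(n)] <- match(tk$label[seq_len(n)], label_levels)
  }
  list(ids = ids, mask = mask, labels = labs)
}

#' Train a transformer token classifier
#'
#' Fine-tunes (or trains from scratch, for the `tiny_scratch` profile) a
#' compact transformer encoder with a linear classification head producing a
#' distribution over the schema's label space (21 measurements + null = 22
#' for the default schema), using masked token-level cross-entropy and Adam.
#' Every epoch is evaluated on the dev windows (threshold decoding at the
#' configured threshold, macro-F1 over measurement labels) and the parameters
#' of the best epoch are kept, implementing select-the-epoch-that-maximizes
#' macro-F1. Training is deterministic given the config seed.
#'
#' @param train_windows,dev_windows Lists of labeled windows from
#'   [window_tokens()] / [corpus_windows()]; `dev_windows` may be `NULL`
#'   (the final epoch is then kept).
#' @param schema A `cmr_schema`.
#' @param tokenizer The tokenizer the windows were produced with.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A `cmr_extractor` object with elements `params` (selected epoch),
#'   `history` (per-epoch tibble: `epoch`, `train_loss`, `dev_macro_f1`),
#'   `best_epoch`, `nn_cfg`, `config`, `tokenizer`, `schema`, `label_levels`.
#' @export
train_extractor <- function(train_windows, schema, tokenizer,
                            config = train_config(), dev_windows = NULL,
                            verbose = FALSE) {
  if (!length(train_windows)) abort("empty training set")
  label_levels <- schema_labels(schema)
  bad <- setdiff(unique(unlist(purrr::map(train_windows, ~ .x$tokens$label))), label_levels)
  if (length(bad)) abort(paste0("window label(s) outside schema: ", paste(bad, collapse = ", ")))
  enc <- config$encoder
  nn_cfg <- nn_config(vocab_size(tokenizer), length(label_levels),
                      d_model = enc$d_model, n_heads = enc$n_heads,
                      n_layers = enc$n_layers, d_ff = enc$d_ff, max_len = enc$max_len)
  params <- nn_init(nn_cfg, seed = config$seed)
  st <- adam_init(params)
  ema_d <- config$ema_decay %||% 0
  ema <- if (ema_d > 0) params else NULL
  history <- list()
  best <- list(metric = -Inf, epoch = 0L, params = params)
  # bucket windows of similar length into fixed batches (less padding waste);
  # the batch ORDER is reshuffled every epoch
  len_ord <- order(purrr::map_int(train_windows, ~ nrow(.x$tokens)))
  batch_idx <- split(len_ord, ceiling(seq_along(len_ord) / config$batch_size))
  batches <- purrr::map(batch_idx, function(sel) {
    make_batch(train_windows[sel], label_levels, nn_cfg$max_len)
  })
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$max_epochs)) {
      lr_now <- if (identical(config$lr_decay %||% "none", "linear")) {
        config$learning_rate * (1 - (epoch - 1) / config$max_epochs)
      } else {
        config$learning_rate
      }
      losses <- numeric(0)
      for (bi in sample(length(batches))) {
        batch <- batches[[bi]]
        lg <- nn_loss_grad(params, batch$ids, batch$mask, batch$labels, nn_cfg,
                           dropout = config$dropout %||% 0)
        upd <- adam_step(params, lg$grads, st, lr = lr_now,
                         weight_decay = config$weight_decay %||% 0)
        params <- upd$p; st <- upd$state
        if (ema_d > 0) {
          for (nm in names(params)) {
            ema[[nm]] <- ema_d * ema[[nm]] + (1 - ema_d) * params[[nm]]
          }
        }
        losses <- c(losses, lg$loss)
      }
      eval_params <- if (ema_d > 0) ema else params
      dev_f1 <- NA_real_
      if (!is.null(dev_windows) && length(dev_windows)) {
        model_now <- new_extractor(eval_params, nn_cfg, config, tokenizer, schema,
                                   label_levels, history = NULL, best_epoch = epoch)
        pred <- predict_window_labels(model_now, dev_windows, mode = "threshold")
        gold <- unlist(purrr::map(dev_windows, ~ .x$tokens$label))
        dev_f1 <- evaluate_tokens(pred, gold, schema)$macro_f1
        if (!is.na(dev_f1) && dev_f1 > best$metric) {
          best <- list(metric = dev_f1, epoch = epoch, params = eval_params)
        }
      }
      history[[epoch]] <- tibble(epoch = epoch, train_loss = mean(losses),
                                 dev_macro_f1 = dev_f1)
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f dev macro-F1 %s", epoch, mean(losses),
                        ifelse(is.na(dev_f1), "-", sprintf("%.3f", dev_f1))))
      }
    }
  })
  if (is.null(dev_windows) || best$epoch == 0L) {
    best <- list(metric = NA_real_, epoch = config$max_epochs,
                 params = if (ema_d > 0) ema else params)
  }
  new_extractor(best$params, nn_cfg, config, tokenizer, schema, label_levels,
                history = bind_rows(history), best_epoch = best$epoch)
}

new_extractor <- function(params, nn_cfg, config, tokenizer, schema, label_levels,
                          history, best_epoch) {
  structure(list(params = params, nn_cfg = nn_cfg, config = config,
                 tokenizer = tokenizer, schema = schema,
                 label_levels = label_levels, history = history,
                 best_epoch = best_epoch),
            class = "cmr_extractor")
}

#' @export
print.cmr_extractor <- function(x, ...) {
  np <- sum(purrr::map_dbl(x$params, length))
  cat(sprintf("<cmr_extractor> %d-layer encoder, d=%d, %d heads; %s parameters; %d labels\n",
              x$nn_cfg$n_layers, x$nn_cfg$d_model, x$nn_cfg$n_heads,
              format(np, big.mark = ","), x$nn_cfg$n_labels))
  if (!is.null(x$history)) {
    cat(sprintf("selected epoch %d (dev macro-F1 %s)\n", x$best_epoch,
                ifelse(all(is.na(x$history$dev_macro_f1)), "-",
                       sprintf("%.3f", max(x$history$dev_macro_f1, na.rm = TRUE)))))
  }
  invisible(x)
}

#' @export
tidy.cmr_extractor <- function(x, ...) {
  x$history %||% tibble(epoch = integer(), train_loss = numeric(), dev_macro_f1 = numeric())
}

#' @export
glance.cmr_extractor <- function(x, ...) {
  tibble(best_epoch = x$best_epoch,
         best_dev_macro_f1 = if (is.null(x$history) || all(is.na(x$history$dev_macro_f1)))
           NA_real_ else max(x$history$dev_macro_f1, na.rm = TRUE),
         n_parameters = sum(purrr::map_dbl(x$params, length)),
         vocab_size = x$nn_cfg$vocab_size, n_labels = x$nn_cfg$n_labels,
         n_layers = x$nn_cfg$n_layers, d_model = x$nn_cfg$d_model)
}

#' Per-token label scores for a window
#'
#' Runs the encoder on one window and returns the per-token score
#' distributions over the label space; each row is a softmax distribution
#' summing to 1.
#'
#' @param model A `cmr_extractor`.
#' @param window A window (list with `tokens`) or a token tibble.
#' @return Matrix `n_tokens` x `n_labels` with label columns.
#' @export
predict_scores <- function(model, window) {
  tokens <- if (is.data.frame(window)) window else window$tokens
  if (nrow(tokens) > model$nn_cfg$max_len) {
    abort(sprintf("window of %d tokens exceeds model capacity %d",
                  nrow(tokens), model$nn_cfg$max_len))
  }
  ids <- matrix(tokens$token_id, 1)
  mask <- matrix(TRUE, 1, nrow(tokens))
  fw <- nn_forward(model$params, ids, mask, model$nn_cfg)
  probs <- softmax_rows(fw$logits)
  colnames(probs) <- model$label_levels
  probs
}

# Batched scores for a list of windows; returns list of per-window matrices.
predict_window_scores <- function(model, windows, batch_size = 32L) {
  out <- vector("list", length(windows))
  for (bi in seq(1, length(windows), by = batch_size)) {
    sel <- bi:min(bi + batch_size - 1L, length(windows))
    batch <- make_batch(windows[sel], model$label_levels, model$nn_cfg$max_len)
    fw <- nn_forward(model$params, batch$ids, batch$mask, model$nn_cfg)
    probs <- softmax_rows(fw$logits)
    T <- ncol(batch$ids)
    for (j in seq_along(sel)) {
      n <- nrow(windows[[sel[j]]]$tokens)
      rows <- ((j - 1L) * T + 1L):((j - 1L) * T + n)
      m <- probs[rows, , drop = FALSE]
      colnames(m) <- model$label_levels
      out[[sel[j]]] <- m
    }
  }
  out
}

# Decoded labels for a list of gold-layout windows, concatenated.
predict_window_labels <- function(model, windows, mode = c("threshold", "argmax"),
                                  threshold = model$config$decode_threshold) {
  mode <- match.arg(mode)
  scores <- predict_window_scores(model, windows)
  unlist(purrr::map(scores, function(m) {
    if (mode == "threshold") decode_threshold(m, t = threshold, null_label = model$schema$null_label)
    else decode_argmax(m)
  }))
}

#' Decode per-token scores into labels
#'
#' `decode_threshold()` assigns a label when its score exceeds `t` (with
#' scores normalized per token, at most one label can exceed 0.5) and
#' abstains to the null label otherwise. `decode_argmax()` always assigns the
#' highest-scoring label, breaking ties toward the lowest label index; this is
#' the decoding used when applying the model at scale for outcome analyses.
#'
#' @param scores Matrix of per-token score rows with label column names.
#' @param t Threshold in (0, 1).
#' @param null_label Label used when no score exceeds `t`.
#' @return Character vector of labels, one per row of `scores`.
#' @export
decode_threshold <- function(scores, t = 0.5, null_label = "0") {
  if (t <= 0 || t >= 1) abort("threshold must lie in (0, 1)")
  j <- max.col(scores, ties.method = "first")
  top <- scores[cbind(seq_len(nrow(scores)), j)]
  out <- colnames(scores)[j]
  out[top <= t] <- null_label
  out
}

#' @rdname decode_threshold
#' @export
decode_argmax <- function(scores) {
  colnames(scores)[max.col(scores, ties.method = "first")]
}

#' Most-attended tokens for a position
#'
#' Error inspection: returns the tokens that the encoder's final layer attends
#' to when labeling the token at `position`, with weights averaged over
#' attention heads (they sum to 1 over the window before truncation to the top
#' `k`). Useful for understanding why a value token was, or was not, tied to
#' its measurement name phrase.
#'
#' @param model A `cmr_extractor`.
#' @param window A window or token tibble.
#' @param position 1-based token position to inspect.
#' @param k Number of top tokens to return.
#' @return Tibble `position`, `token`, `weight`, sorted by decreasing weight;
#'   the full weight vector is in attribute `"weights"`.
#' @export
top_attended_tokens <- function(model, window, position, k = 5L) {
  tokens <- if (is.data.frame(window)) window else window$tokens
  n <- nrow(tokens)
  if (position < 1 || position > n) abort(sprintf("position %d out of range 1..%d", position, n))
  ids <- matrix(tokens$token_id, 1)
  mask <- matrix(TRUE, 1, n)
  fw <- nn_forward(model$params, ids, mask, model$nn_cfg, keep_attn = TRUE)
  last <- fw$attn[[model$nn_cfg$n_layers]]
  W <- Reduce(`+`, purrr::map(last, ~ .x[position, ])) / model$nn_cfg$n_heads
  ord <- order(W, decreasing = TRUE)
  out <- tibble(position = ord, token = tokens$token[ord], weight = W[ord]) %>%
    head(k)
  attr(out, "weights") <- W
  out
}
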