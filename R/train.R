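# End-to-end training (Adam), evaluation, cross-validation, multi-seed
# repetition and the ablation harness.

.adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

.make_drop <- function(p) {
  if (p <= 0) return(.no_drop)
  function(x) {
    v <- ad_value(x)
    keep <- matrix(stats::rbinom(length(v), 1L, 1 - p), nrow(v), ncol(v)) / (1 - p)
    op_mul(x, keep)
  }
}

#' Train the fusion model
#'
#' Runs minibatch Adam on the combined BCE + contrastive loss over the
#' training split. The functional-group vocabulary is mined from the
#' training SMILES, the token dictionary built from the training token
#' sequences. After every epoch the model is scored on the validation split
#' (training split when no validation data is present); the returned
#' parameters are the checkpoint with the best validation accuracy (ties
#' broken by MCC, then F1). Early stopping after `config$patience` epochs
#' without improvement. Fully deterministic for a fixed seed.
#'
#' @param split a `dataset_split` (or a list with at least `$train`;
#'   `$validation` may be empty)
#' @param config a `gsfl_config`
#' @param verbose print one line per epoch
#' @return object of class `gsfl_model`: list with `params` (best
#'   checkpoint), `final_params`, `config`, `vocab`, `dict`, `history`
#'   (per-epoch data.frame), `best_epoch`
#' @export
train <- function(split, config = gsfl_config(), verbose = FALSE) {
  train_df <- split$train
  val_df <- split$validation
  stopifnot(nrow(train_df) >= 2L)
  has_val <- !is.null(val_df) && nrow(val_df) >= 2L &&
    length(unique(val_df$label)) == 2L

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  vocab <- NULL; dict <- NULL; enc <- NULL
  if (config$use_sequence_branch) {
    vocab <- mine_functional_groups(train_df$smiles, config$min_count)
    tokfun <- if (config$use_fg_splitting)
      function(s) tokenize_smiles(s, vocab) else tokenize_chars
    dict <- build_token_dictionary(lapply(train_df$smiles, tokfun))
    enc <- .prepare_sequences(train_df$smiles, vocab, dict, config)
  }
  graphs <- build_mol_graphs(train_df$smiles)
  labels <- train_df$label

  P <- gsfl_init(config, if (is.null(dict)) NULL else dict$size)
  adam <- .adam_new(P)
  n <- nrow(train_df)
  history <- list()
  best <- list(score = c(-Inf, -Inf, -Inf), params = P, epoch = 0L)
  stall <- 0L

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_bce <- 0
    for (start in seq(1L, n, by = config$batch_size)) {
      ii <- ord[start:min(start + config$batch_size - 1L, n)]
      if (length(ii) < 2L) next
      tape <- new_tape()
      TP <- lapply(P, function(p) ad_param(tape, p))
      drop <- .make_drop(config$dropout)
      gbatch <- batch_graphs(graphs[ii])
      sbatch <- if (config$use_sequence_branch) batch_sequences(enc[ii])
      fw <- gsfl_forward(TP, gbatch, sbatch, config, drop)
      bce <- bce_with_logits(fw$logits, labels[ii])
      loss <- fusion_loss(fw$logits, labels[ii], fw$Z_s, fw$Z_g, config)
      lv <- as.numeric(ad_value(loss))
      if (!is.finite(lv))
        stop(sprintf("non-finite loss (%.3g) at epoch %d; check inputs/learning rate",
                     lv, epoch))
      grads_by_id <- ad_backward(loss)
      grads <- lapply(TP, function(tp) grads_by_id[[tp$id]])
      upd <- .adam_step(P, grads, adam, config$learning_rate)
      P <- upd$params; adam <- upd$state
      ep_loss <- ep_loss + lv
      ep_bce <- ep_bce + as.numeric(ad_value(bce))
    }

    train_scores <- .model_scores(P, train_df, vocab, dict, config)
    train_acc <- mean((train_scores >= 0.5) == (labels == 1))
    if (has_val) {
      vs <- .model_scores(P, val_df, vocab, dict, config)
      vm <- compute_metrics(val_df$label, vs)
      sel <- c(vm$ACC, vm$MCC, vm$F1)
      val_acc <- vm$ACC
    } else {
      sel <- c(train_acc, 0, 0)
      val_acc <- NA_real_
    }
    history[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss, bce = ep_bce,
                                   train_acc = train_acc, val_acc = val_acc)
    if (verbose)
      message(sprintf("epoch %3d  loss %9.4f  train_acc %.3f  val_acc %s",
                      epoch, ep_loss, train_acc,
                      ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
    better <- sel[1] > best$score[1] ||
      (sel[1] == best$score[1] && sel[2] > best$score[2]) ||
      (sel[1] == best$score[1] && sel[2] == best$score[2] && sel[3] > best$score[3])
    if (better) {
      best <- list(score = sel, params = P, epoch = epoch)
      stall <- 0L
    } else stall <- stall + 1L
    if (train_acc >= 1 && !has_val) break   # memorization reached; nothing to select
    if (stall >= config$patience) break
  }

  structure(list(params = best$params, final_params = P, config = config,
                 vocab = vocab, dict = dict,
                 history = do.call(rbind, history), best_epoch = best$epoch),
            class = "gsfl_model")
}

#' @export
print.gsfl_model <- function(x, ...) {
  cat(sprintf("gsfl_model: %d parameter matrices, best epoch %d/%d\n",
              length(x$params), x$best_epoch, nrow(x$history)))
  invisible(x)
}

#' Predict activity probabilities
#'
#' @param object a `gsfl_model`
#' @param newdata data.frame with a `smiles` column, or a character vector
#'   of SMILES
#' @param ... unused
#' @return numeric vector of activity probabilities
#' @export
predict.gsfl_model <- function(object, newdata, ...) {
  df <- if (is.character(newdata)) data.frame(smiles = newdata) else newdata
  .model_scores(object$params, df, object$vocab, object$dict, object$config)
}

#' Evaluate a trained model on labeled records
#'
#' @param model a `gsfl_model`
#' @param records data.frame with `smiles` and `label`
#' @param threshold decision threshold
#' @return a `metrics_report`
#' @export
evaluate_model <- function(model, records, threshold = 0.5) {
  compute_metrics(records$label, predict(model, records), threshold)
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by label (round-robin within shuffled classes);
#' every record appears in exactly one test fold. Each fold's model is
#' trained on the remaining folds (with a 10% stratified carve-out for
#' checkpoint selection when feasible) and evaluated on the held-out fold.
#'
#' @param records curated data.frame with `smiles` and `label`
#' @param k number of folds
#' @param config a `gsfl_config`
#' @param seed fold-assignment seed
#' @return list with `folds` (per-fold `metrics_report`), `assignments`
#'   (fold id per record), `summary` (mean and SD per metric)
#' @export
cross_validate <- function(records, k = 10L, config = gsfl_config(), seed = 1L) {
  stopifnot(k >= 2L)
  counts <- table(records$label)
  if (any(counts < k))
    stop("every class needs at least k members for stratified k-fold CV")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  fold <- integer(nrow(records))
  for (l in unique(records$label)) {
    ix <- sample(which(records$label == l))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- records[fold != f, , drop = FALSE]
    te <- records[fold == f, , drop = FALSE]
    can_carve <- all(table(tr$label) >= 20L)
    sp <- if (can_carve) {
      sp0 <- split_dataset(tr, c(0.8, 0.1, 0.1), seed = seed + f)
      list(train = rbind(sp0$train, sp0$test), validation = sp0$validation)
    } else list(train = tr, validation = tr[0, ], test = tr[0, ])
    m <- train(sp, config)
    reports[[f]] <- evaluate_model(m, te)
  }
  tab <- do.call(rbind, lapply(reports, as.data.frame))
  metric_cols <- c("ACC", "SE", "SP", "MCC", "F1", "PRC", "AUC")
  list(folds = reports, assignments = fold,
       summary = data.frame(metric = metric_cols,
                            mean = colMeans(tab[metric_cols], na.rm = TRUE),
                            sd = apply(tab[metric_cols], 2, stats::sd, na.rm = TRUE),
                            row.names = NULL))
}

#' Ablation study over the architectural components
#'
#' Trains and evaluates five variants under identical seeds and splits: the
#' complete model, without feature attention, without hierarchical
#' attention, without functional-group splitting (character-level tokens),
#' and graph-only.
#'
#' @param split a `dataset_split`
#' @param config base `gsfl_config`
#' @param eval_on which split to evaluate ("test", "validation", "train")
#' @return list with `reports` (named `metrics_report`s) and `table`
#'   (data.frame, one row per variant)
#' @export
run_ablation <- function(split, config = gsfl_config(),
                         eval_on = c("test", "validation", "train")) {
  eval_on <- match.arg(eval_on)
  variants <- list(
    all = config,
    without_fa = utils::modifyList(config, list(use_fa = FALSE)),
    without_ha = utils::modifyList(config, list(use_ha = FALSE)),
    without_fg_splitting = utils::modifyList(config, list(use_fg_splitting = FALSE)),
    graph_only = utils::modifyList(config, list(use_sequence_branch = FALSE))
  )
  eval_df <- split[[eval_on]]
  models <- list(); reports <- list()
  for (nm in names(variants)) {
    cfg <- structure(variants[[nm]], class = "gsfl_config")
    m <- train(split, cfg)
    models[[nm]] <- m
    reports[[nm]] <- evaluate_model(m, eval_df)
  }
  tab <- cbind(variant = names(reports),
               do.call(rbind, lapply(reports, as.data.frame)))
  rownames(tab) <- NULL
  list(reports = reports, models = models, table = tab)
}

#' Repeat training over multiple seeds
#'
#' Re-splits, trains and evaluates once per seed and reports mean and SD of
#' every test metric.
#'
#' @param records curated data.frame
#' @param config a `gsfl_config`
#' @param seeds integer vector of seeds (default 1:10)
#' @return list with `runs` (per-seed `metrics_report`), `summary`
#'   (mean/SD data.frame)
#' @export
run_seeds <- function(records, config = gsfl_config(), seeds = 1:10) {
  runs <- lapply(seeds, function(s) {
    sp <- split_dataset(records, seed = s)
    cfg <- utils::modifyList(config, list(seed = as.integer(s)))
    cfg <- structure(cfg, class = "gsfl_config")
    evaluate_model(train(sp, cfg), sp$test)
  })
  names(runs) <- paste0("seed_", seeds)
  tab <- do.call(rbind, lapply(runs, as.data.frame))
  metric_cols <- c("ACC", "SE", "SP", "MCC", "F1", "PRC", "AUC")
  list(runs = runs,
       summary = data.frame(metric = metric_cols,
                            mean = colMeans(tab[metric_cols], na.rm = TRUE),
                            sd = apply(tab[metric_cols], 2, stats::sd, na.rm = TRUE),
                            row.names = NULL))
}
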