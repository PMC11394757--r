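# Supervised training: weighted binary cross-entropy on per-vertex labels,
# Adam (lr 5e-4, weight decay 1e-5), graphs batched 4 at a time as
# independent graphs (no cross-graph edges), at most 50 epochs with early
# stopping on validation loss.

#' Training configuration
#'
#' @param batch_size Graphs per optimizer step (default 4).
#' @param lr Adam learning rate (default 5e-4).
#' @param weight_decay L2 weight decay (default 1e-5).
#' @param max_epochs Epoch cap (default 50).
#' @param seed RNG seed controlling shuffling.
#' @param pos_weight Positive-class loss weight; `"auto"` (default) uses the
#'   training split's negative/positive vertex ratio.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (default 10).
#' @return List of class `train_config`.
#' @export
train_config <- function(batch_size = 4L, lr = 5e-4, weight_decay = 1e-5,
                         max_epochs = 50L, seed = 1L, pos_weight = "auto",
                         early_stop_patience = 10L) {
  stopifnot(lr > 0, batch_size >= 1, max_epochs >= 1)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 weight_decay = weight_decay, max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), pos_weight = pos_weight,
                 early_stop_patience = as.integer(early_stop_patience)),
            class = "train_config")
}

#' Split specification for grouped train/validation/test partitioning
#'
#' Structures sharing a `group_key` (e.g. protein family) are always assigned
#' to the same split to avoid leakage.
#'
#' @param train,val,test Fractions, must sum to 1 (default 0.8/0.1/0.1).
#' @return List of class `split_spec`.
#' @export
split_spec <- function(train = 0.8, val = 0.1, test = 0.1) {
  stopifnot(abs(train + val + test - 1) < 1e-9, train > 0, val > 0, test > 0)
  structure(list(train = train, val = val, test = test), class = "split_spec")
}

#' Grouped train/val/test split
#'
#' Whole groups are assigned to splits; realized group fractions are within
#' one group of the targets; deterministic for a given seed.
#'
#' @param ids Character/integer vector of structure ids.
#' @param group_key Group identifier per id (same length).
#' @param spec A [split_spec()].
#' @param seed Integer seed.
#' @return List with elements `train`, `val`, `test` (id vectors).
#' @export
make_splits <- function(ids, group_key, spec = split_spec(), seed = 1L) {
  stopifnot(length(ids) == length(group_key))
  groups <- unique(as.character(group_key))
  if (length(groups) < 3L) {
    stop("make_splits: need at least 3 distinct groups", call. = FALSE)
  }
  ord <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    sample(groups)
  })
  ng <- length(groups)
  n_val <- max(1L, round(spec$val * ng))
  n_test <- max(1L, round(spec$test * ng))
  val_g <- ord[seq_len(n_val)]
  test_g <- ord[n_val + seq_len(n_test)]
  train_g <- ord[-(seq_len(n_val + n_test))]
  gk <- as.character(group_key)
  list(train = ids[gk %in% train_g], val = ids[gk %in% val_g],
       test = ids[gk %in% test_g])
}

# Mann-Whitney AUROC (verified against pROC in the test suite).
auroc <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

eval_split <- function(model, preps, pos_weight) {
  loss <- 0
  probs <- labels <- numeric(0)
  for (p in preps) {
    fw <- model_forward_full(model, p, training = FALSE)
    loss <- loss + bce_loss_grad(fw$logits, p$labels, pos_weight)$loss
    probs <- c(probs, fw$probs)
    labels <- c(labels, p$labels)
  }
  list(loss = loss / length(preps), auc = auroc(probs, labels))
}

#' Train the model
#'
#' @param train_preps,val_preps Lists of prepared labeled structures from
#'   [prepare_structure()].
#' @param model A freshly initialized (or warm-start) [init_model()].
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return List with `model` (checkpoint with the best validation loss),
#'   `log` (data.frame: epoch, train_loss, val_loss, val_auc) and
#'   `pos_weight` used.
#' @export
train_model <- function(train_preps, val_preps, model, cfg = train_config(),
                        verbose = FALSE) {
  stopifnot(length(train_preps) >= 1L)
  all_lab <- unlist(lapply(train_preps, `[[`, "labels"))
  n_pos <- sum(all_lab == 1)
  n_neg <- sum(all_lab == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("train_model: training vertices contain a single class (", n_pos,
         " positive / ", n_neg, " negative); cannot fit a classifier",
         call. = FALSE)
  }
  pos_weight <- if (identical(cfg$pos_weight, "auto")) n_neg / n_pos else cfg$pos_weight

  set.seed(cfg$seed)
  params <- trainable_model(model)
  opt <- adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0), val_auc = numeric(0))
  stale <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(length(train_preps))
    ep_loss <- 0
    nb <- 0L
    for (b in seq(1L, length(ord), by = cfg$batch_size)) {
      batch <- ord[b:min(length(ord), b + cfg$batch_size - 1L)]
      acc <- NULL
      bloss <- 0
      for (gi in batch) {
        model[c("chem", "embed", "layers", "clf")] <- params
        res <- model_loss_grads(model, train_preps[[gi]], pos_weight)
        params$chem$bn <- res$bn_updated
        bloss <- bloss + res$loss
        acc <- if (is.null(acc)) res$grads else add_trees(acc, res$grads)
      }
      acc <- map_leaves(acc, function(x, k) x / length(batch))
      st <- adam_step(params, acc, opt, lr = cfg$lr,
                      weight_decay = cfg$weight_decay)
      params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + bloss / length(batch)
      nb <- nb + 1L
    }
    model[c("chem", "embed", "layers", "clf")] <- params
    vl <- if (length(val_preps) > 0L) eval_split(model, val_preps, pos_weight)
          else list(loss = ep_loss / nb, auc = NA_real_)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                 val_loss = vl$loss, val_auc = vl$auc))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  val_auc %s", epoch,
                      ep_loss / nb, vl$loss,
                      ifelse(is.na(vl$auc), "-", sprintf("%.3f", vl$auc))))
    }
    if (vl$loss < best$loss - 1e-9) {
      best <- list(loss = vl$loss, params = params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$early_stop_patience) break
    }
  }
  model[c("chem", "embed", "layers", "clf")] <- best$params
  list(model = model, log = log, pos_weight = pos_weight,
       best_epoch = best$epoch)
}
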