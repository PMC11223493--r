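#' Build the per-event CNN classifier
#'
#' Constructs an untrained 1D convolutional network for per-event cOA
#' stoichiometry classification: two convolutional layers (10 filters of
#' width 25, ReLU), each followed by batch normalization and 20% dropout,
#' then max-pooling with pool size 10, a dense layer with one output node
#' per class and a softmax. Inputs are the 251-point event tensors of
#' [event_tensors()] (250 padded signal points plus the duration feature).
#'
#' @param n_classes number of output classes (>= 2); defaults to the three
#'   distinguishable stoichiometry classes cA3/4, cA5, cA6.
#' @param input_width input tensor length (default 251).
#' @param class_levels optional character vector of class names, length
#'   `n_classes`.
#' @return An object of class `coa_cnn` (untrained; see [train_classifier()]).
#' @examples
#' net <- build_classifier(3)
#' net
#' @export
build_classifier <- function(n_classes = 3L, input_width = 251L,
                             class_levels = NULL) {
  if (n_classes < 2) stop("`n_classes` must be >= 2", call. = FALSE)
  d <- cnn_dims(input_width, n_classes = as.integer(n_classes))
  if (!is.null(class_levels) && length(class_levels) != n_classes)
    stop("`class_levels` must have length `n_classes`", call. = FALSE)
  structure(list(dims = d, params = NULL, state = NULL,
                 class_levels = class_levels, trained = FALSE,
                 log = NULL, dur_stats = NULL),
            class = "coa_cnn")
}

#' @export
print.coa_cnn <- function(x, ...) {
  d <- x$dims
  cat("<coa_cnn> 1D convolutional event classifier\n")
  cat(sprintf("  input %d -> conv(%d filters, width %d, ReLU)+BN+dropout x2 -> maxpool(%d) -> dense(%d) -> softmax\n",
              d$W, d$F, d$K, d$pool, d$n_classes))
  cat(sprintf("  parameters: %d; trained: %s\n", n_params(x),
              if (x$trained) "yes" else "no"))
  if (!is.null(x$class_levels))
    cat("  classes:", paste(x$class_levels, collapse = ", "), "\n")
  invisible(x)
}

n_params <- function(net) {
  d <- net$dims
  conv1 <- d$K * d$F + d$F + 2L * d$F
  conv2 <- d$K * d$F * d$F + d$F + 2L * d$F
  dense <- d$n_flat * d$n_classes + d$n_classes
  conv1 + conv2 + dense
}

#' Train the CNN event classifier
#'
#' Trains with the Adam optimizer minimizing cross-entropy on one-hot
#' labels. Before each epoch, minority classes are oversampled (random
#' duplication with replacement, re-drawn every epoch) up to the majority
#' class count, then the epoch is shuffled into mini-batches. `restarts`
#' independent trainings are run and the restart with the highest final
#' training accuracy (evaluation mode, no dropout) is returned.
#'
#' @param net an untrained [build_classifier()] object.
#' @param x numeric matrix of event tensors (rows = events, `input_width`
#'   columns), as returned by [event_tensors()].
#' @param labels class labels (factor or character), aligned with rows of
#'   `x`; every class must have at least one event.
#' @param epochs training epochs per restart (default 100).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param restarts number of restarts (default 5).
#' @param batch_size mini-batch size (default 32).
#' @param dropout dropout probability (default 0.2).
#' @param seed integer seed; training is bit-reproducible given the seed.
#' @param verbose print per-epoch progress.
#' @return The trained `coa_cnn`; `$log` holds a data frame of per-epoch
#'   loss/accuracy for every restart, `$restart_accuracy` the final training
#'   accuracies.
#' @export
train_classifier <- function(net, x, labels, epochs = 100L,
                             learning_rate = 1e-3, restarts = 5L,
                             batch_size = 32L, dropout = 0.2, seed = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(net, "coa_cnn"), is.matrix(x))
  d <- net$dims
  if (ncol(x) != d$W)
    stop("`x` must have ", d$W, " columns", call. = FALSE)
  lev <- net$class_levels %||% sort(unique(as.character(labels)))
  y <- factor(as.character(labels), levels = lev)
  if (anyNA(y)) stop("labels outside the classifier's class set", call. = FALSE)
  counts <- table(y)
  if (any(counts == 0))
    stop("class with zero events: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  if (length(lev) != d$n_classes)
    stop("number of observed classes (", length(lev),
         ") does not match the network output dimension (", d$n_classes, ")",
         call. = FALSE)
  yi <- as.integer(y)
  Y1h <- matrix(0, nrow(x), d$n_classes)
  Y1h[cbind(seq_len(nrow(x)), yi)] <- 1

  with_seed(seed, {
    best <- NULL; best_acc <- -Inf
    logs <- list(); accs <- numeric(restarts)
    idx_by_class <- split(seq_len(nrow(x)), yi)
    nmax <- max(lengths(idx_by_class))
    for (r in seq_len(restarts)) {
      params <- cnn_init_params(d)
      state <- cnn_init_state(d)
      opt <- adam_init(params)
      log_r <- data.frame(restart = integer(), epoch = integer(),
                          loss = numeric(), accuracy = numeric())
      for (ep in seq_len(epochs)) {
        # oversample minority classes to the majority count
        ep_idx <- unlist(lapply(idx_by_class, function(ix) {
          if (length(ix) < nmax)
            c(ix, sample(ix, nmax - length(ix), replace = TRUE))
          else ix
        }), use.names = FALSE)
        ep_idx <- sample(ep_idx)
        loss_sum <- 0; acc_sum <- 0; nb <- 0L
        for (s in seq(1L, length(ep_idx), by = batch_size)) {
          bi <- ep_idx[s:min(s + batch_size - 1L, length(ep_idx))]
          Xb <- x[bi, , drop = FALSE]
          Yb <- Y1h[bi, , drop = FALSE]
          fwd <- cnn_forward(params, state, Xb, d, training = TRUE,
                             dropout = dropout)
          state <- update_running(state, fwd)
          p_true <- rowSums(fwd$probs * Yb)
          loss_sum <- loss_sum - sum(log(pmax(p_true, 1e-12)))
          acc_sum <- acc_sum +
            sum(max.col(fwd$probs, ties.method = "first") == yi[bi])
          nb <- nb + length(bi)
          grads <- cnn_backward(params, fwd, Yb, d, dropout = dropout)
          st <- adam_step(params, grads, opt, lr = learning_rate)
          params <- st$params; opt <- st$opt
        }
        log_r <- rbind(log_r, data.frame(restart = r, epoch = ep,
                                         loss = loss_sum / nb,
                                         accuracy = acc_sum / nb))
        if (verbose)
          message(sprintf("restart %d epoch %d: loss %.4f acc %.3f",
                          r, ep, loss_sum / nb, acc_sum / nb))
      }
      # restart selection by final training accuracy, evaluation mode
      pr <- cnn_probs(params, state, x, d)
      accs[r] <- mean(max.col(pr, ties.method = "first") == yi)
      logs[[r]] <- log_r
      if (accs[r] > best_acc) {
        best_acc <- accs[r]
        best <- list(params = params, state = state)
      }
    }
    net$params <- best$params
    net$state <- best$state
    net$class_levels <- lev
    net$trained <- TRUE
    net$log <- do.call(rbind, logs)
    net$restart_accuracy <- accs
    net
  })
}

#' Predict class probabilities or labels for event tensors
#'
#' @param object a trained [coa_cnn][build_classifier()].
#' @param x event tensor matrix (see [event_tensors()]).
#' @param type `"prob"` for the per-class probability matrix (rows sum to
#'   1), `"class"` for hard labels.
#' @param ... unused.
#' @return A probability matrix or a factor of predicted labels.
#' @export
predict.coa_cnn <- function(object, x, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (!object$trained) stop("classifier is not trained", call. = FALSE)
  stopifnot(is.matrix(x), ncol(x) == object$dims$W)
  pr <- cnn_probs(object$params, object$state, x, object$dims)
  colnames(pr) <- object$class_levels
  if (type == "prob") return(pr)
  factor(object$class_levels[max.col(pr, ties.method = "first")],
         levels = object$class_levels)
}

#' Trace-grouped k-fold cross-validation of the CNN
#'
#' Partitions traces (never events) into `k` folds, trains on `k - 1`
#' groups and evaluates on the held-out group, so that no trace contributes
#' events to both training and test sets. Returns the per-fold
#' row-normalized confusion matrices (mean and SD over folds), the overall
#' accuracy over all folds' predictions merged into one set, and the `k`
#' trained classifiers for downstream prediction intervals.
#'
#' @param x event tensor matrix.
#' @param labels ground-truth class labels per event.
#' @param trace_ids trace identifier per event (grouping variable).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @param ... passed to [train_classifier()] (epochs, restarts, ...).
#' @return A list of class `coa_cv` with `confusion_mean`, `confusion_sd`,
#'   `accuracy`, `models`, `folds` (trace-to-fold map) and `predictions`
#'   (merged out-of-fold hard labels, aligned with `labels`).
#' @export
grouped_cross_validate <- function(x, labels, trace_ids, k = 10L,
                                   seed = NULL, ...) {
  stopifnot(is.matrix(x), nrow(x) == length(labels),
            length(trace_ids) == length(labels))
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  traces <- unique(trace_ids)
  if (length(traces) < k)
    stop("need at least k = ", k, " traces", call. = FALSE)
  with_seed(seed, {
    fold_of <- NULL
    for (attempt in seq_len(20L)) {
      cand <- setNames(sample(rep_len(seq_len(k), length(traces))), traces)
      ok <- all(vapply(seq_len(k), function(f) {
        tr_lab <- labels[fold_of_events(cand, trace_ids) != f]
        all(lev %in% tr_lab)
      }, TRUE))
      if (ok) { fold_of <- cand; break }
    }
    if (is.null(fold_of))
      stop("could not build folds with every class present in training ",
           "after 20 attempts", call. = FALSE)
    ev_fold <- fold_of_events(fold_of, trace_ids)
    models <- vector("list", k)
    preds <- factor(rep(NA_character_, length(labels)), levels = lev)
    conf <- array(NA_real_, c(length(lev), length(lev), k),
                  dimnames = list(truth = lev, predicted = lev, fold = NULL))
    for (f in seq_len(k)) {
      tr <- ev_fold != f; te <- !tr
      net <- build_classifier(length(lev), input_width = ncol(x),
                              class_levels = lev)
      net <- train_classifier(net, x[tr, , drop = FALSE], labels[tr],
                              seed = sample.int(2^31 - 1, 1), ...)
      models[[f]] <- net
      pf <- predict(net, x[te, , drop = FALSE], type = "class")
      preds[te] <- pf
      conf[, , f] <- confusion_rows(labels[te], pf, lev)
    }
    structure(list(confusion_mean = apply(conf, c(1, 2), mean, na.rm = TRUE),
                   confusion_sd = apply(conf, c(1, 2), sd, na.rm = TRUE),
                   accuracy = mean(as.character(preds) == labels),
                   models = models, folds = fold_of, predictions = preds),
              class = "coa_cv")
  })
}

fold_of_events <- function(fold_of, trace_ids) {
  unname(fold_of[as.character(trace_ids)])
}

# row-normalized confusion matrix (rows = truth); all-NA row if a class is
# absent from the test fold
confusion_rows <- function(truth, pred, lev) {
  tab <- table(factor(truth, lev), factor(pred, lev))
  n <- rowSums(tab)
  out <- sweep(tab, 1L, pmax(n, 1L), "/")
  out[n == 0L, ] <- NA_real_
  as.matrix(out)
}

#' k-nearest-neighbour baseline classifier
#'
#' The conventional feature-based baseline the CNN is compared against:
#' majority vote among the `k` nearest training events in the standardized
#' two-dimensional feature space of relative blockade and log-transformed
#' dwell time (Euclidean metric; both features z-scored on the training
#' set). Vote ties are broken by the label of the single nearest neighbour
#' among the tied classes.
#'
#' @param train_x numeric matrix (or 2-column data frame) of training
#'   features `(rel_blockade, log_duration)`.
#' @param train_y training labels.
#' @param test_x feature matrix of events to classify.
#' @param k number of neighbours (default 3).
#' @return Factor of predicted labels for the rows of `test_x`.
#' @export
knn_baseline <- function(train_x, train_y, test_x, k = 3L) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (!nrow(train_x)) stop("empty training set", call. = FALSE)
  if (k > nrow(train_x))
    stop("`k` exceeds the training-set size", call. = FALSE)
  mu <- colMeans(train_x)
  sdv <- apply(train_x, 2L, sd)
  sdv[sdv == 0] <- 1
  tr <- sweep(sweep(train_x, 2L, mu, "-"), 2L, sdv, "/")
  te <- sweep(sweep(test_x, 2L, mu, "-"), 2L, sdv, "/")
  train_y <- as.character(train_y)
  lev <- sort(unique(train_y))
  out <- character(nrow(te))
  for (i in seq_len(nrow(te))) {
    d2 <- colSums((t(tr) - te[i, ])^2)
    nn <- order(d2)[seq_len(k)]
    votes <- table(train_y[nn])
    winners <- names(votes)[votes == max(votes)]
    out[i] <- if (length(winners) == 1L) winners
      else train_y[nn[match(TRUE, train_y[nn] %in% winners)]]
  }
  factor(out, levels = lev)
}
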