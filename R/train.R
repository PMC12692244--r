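#' Task loss weights of the joint objective
#'
#' @param alpha_task1 weight of the variety-task cross-entropy.
#' @param beta_task2 weight of the storage-period-task cross-entropy.
#' @return A list of class `loss_weights`.
#' @export
loss_weights <- function(alpha_task1 = 0.5, beta_task2 = 0.5) {
  if (alpha_task1 < 0 || beta_task2 < 0) stop("loss weights must be nonnegative")
  structure(list(alpha_task1 = alpha_task1, beta_task2 = beta_task2),
            class = "loss_weights")
}

#' Training configuration
#'
#' @param epochs training epochs (cosine-annealing period equals `epochs`).
#' @param lr initial AdamW learning rate.
#' @param weight_decay decoupled weight decay (applied to weight matrices).
#' @param batch_size minibatch size.
#' @param folds folds of [cross_validate()] and the implied 1/folds
#'   validation fraction of [fit_network()].
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping (best weights are restored).
#' @param seed RNG seed keying initialisation, shuffling, dropout and splits.
#' @param weights a [loss_weights()].
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 800L, lr = 0.001, weight_decay = 1e-4,
                         batch_size = 32L, folds = 5L,
                         early_stop_patience = 50L, seed = 42L,
                         weights = loss_weights()) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (lr <= 0) stop("lr must be > 0")
  if (folds < 2) stop("folds must be >= 2")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 folds = as.integer(folds),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed), weights = weights),
            class = "train_config")
}

#' Stratified egg-level train/test split
#'
#' Eggs (not scans) are split per variety at the given test fraction, so all
#' replicate scans and all storage days of one egg land on the same side —
#' no repeated-measures leakage. Every egg must appear at every storage day.
#'
#' @param table a [spectra_table()].
#' @param test_fraction fraction of eggs per variety assigned to the test
#'   side (default 0.2).
#' @param seed RNG seed.
#' @return List of class `split_spec` with `train_eggs`, `test_eggs`.
#' @export
stratified_egg_split <- function(table, test_fraction = 0.2, seed = 42L) {
  stopifnot(inherits(table, "spectra_table"))
  days <- sort(unique(table$day))
  egg_days <- tapply(table$day, table$egg_id, function(d) length(unique(d)))
  if (any(egg_days != length(days))) {
    stop("every egg must have records at every storage day")
  }
  egg_var <- tapply(table$variety, table$egg_id, function(v) v[1])
  train_eggs <- character(0); test_eggs <- character(0)
  with_seed(seed, {
    for (v in sort(unique(table$variety))) {
      eggs <- sort(names(egg_var)[egg_var == v])
      if (length(eggs) < 5) stop("fewer than 5 eggs for variety ", v)
      n_test <- round(test_fraction * length(eggs))
      te <- sample(eggs, n_test)
      test_eggs <- c(test_eggs, te)
      train_eggs <- c(train_eggs, setdiff(eggs, te))
    }
  })
  structure(list(train_eggs = sort(train_eggs), test_eggs = sort(test_eggs),
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "split_spec")
}

#' Cross-entropy task loss
#'
#' `-(1/N) sum_i sum_k y_ik log(p_ik)` with one-hot truth and the log
#' clamped at 1e-12.
#'
#' @param probabilities matrix of predicted class probabilities (rows sum
#'   to one within `tol`).
#' @param labels vector of true labels.
#' @param classes class order matching the probability columns; defaults to
#'   the column names.
#' @param tol tolerance of the row-sum check.
#' @return Scalar loss.
#' @export
task_loss <- function(probabilities, labels, classes = colnames(probabilities),
                      tol = 1e-6) {
  probabilities <- as.matrix(probabilities)
  if (any(abs(rowSums(probabilities) - 1) > tol)) {
    stop("probability rows must sum to 1")
  }
  if (is.null(classes)) classes <- seq_len(ncol(probabilities))
  idx <- match(labels, classes)
  if (anyNA(idx)) stop("labels outside the class set")
  -mean(log(pmax(probabilities[cbind(seq_along(idx), idx)], 1e-12)))
}

#' Weighted joint loss of the two tasks
#'
#' `alpha * L_task1 + beta * L_task2`.
#'
#' @param p1,p2 probability matrices of the two tasks.
#' @param y1,y2 true labels of the two tasks.
#' @param weights a [loss_weights()].
#' @param classes1,classes2 class orders (default: column names).
#' @return Scalar joint loss.
#' @export
joint_loss <- function(p1, y1, p2, y2, weights = loss_weights(),
                       classes1 = colnames(p1), classes2 = colnames(p2)) {
  l1 <- if (weights$alpha_task1 > 0) task_loss(p1, y1, classes1) else 0
  l2 <- if (weights$beta_task2 > 0) task_loss(p2, y2, classes2) else 0
  weights$alpha_task1 * l1 + weights$beta_task2 * l2
}

# label -> 1-based class index vectors used by the compiled core
task_labels <- function(table) {
  cls1 <- sort(unique(table$variety))
  cls2 <- sort(unique(table$day))
  list(y1 = match(table$variety, cls1), y2 = match(table$day, cls2),
       classes1 = cls1, classes2 = cls2)
}

#' Train a network on a spectra table
#'
#' AdamW with decoupled weight decay, cosine-annealed learning rate (period
#' = `epochs`, no restarts), dropout inside encoder layers, and early
#' stopping on the weighted validation loss with best-weights restoration.
#' The validation set is an egg-level stratified holdout of `1/folds` of the
#' training eggs; for single-task variants the inactive task's weight is
#' zero.
#'
#' @param network a [build_network()] object.
#' @param table training [spectra_table()] (already SNV-preprocessed).
#' @param bands integer indices of the input bands within the table's grid.
#' @param config a [train_config()].
#' @param classes1,classes2 optional fixed class orders (default: sorted
#'   unique labels of `table`).
#' @return The trained network, with `history` (per-epoch data frame),
#'   `best_epoch`, `classes1`, `classes2` and `bands` attached.
#' @export
fit_network <- function(network, table, bands, config = train_config(),
                        classes1 = NULL, classes2 = NULL) {
  stopifnot(inherits(network, "ctse_net"), inherits(table, "spectra_table"))
  if (length(bands) != network$config$n_bands_in) {
    stop("length(bands) must equal the network input length")
  }
  fl <- variant_flags(network$variant)
  if (is.null(classes1)) classes1 <- sort(unique(table$variety))
  if (is.null(classes2)) classes2 <- sort(unique(table$day))
  y1 <- match(table$variety, classes1)
  y2 <- match(table$day, classes2)
  if ((fl$task1 && anyNA(y1)) || (fl$task2 && anyNA(y2))) {
    stop("labels outside the declared class sets")
  }
  y1[is.na(y1)] <- 1L; y2[is.na(y2)] <- 1L
  X <- table$reflectance[, bands, drop = FALSE]

  # inner egg-level validation holdout for early stopping
  val_split <- stratified_egg_split(table, test_fraction = 1 / config$folds,
                                    seed = config$seed + 1L)
  is_val <- table$egg_id %in% val_split$test_eggs
  if (fl$task1 && length(unique(y1[!is_val])) < length(classes1)) {
    stop("a variety class is empty in the training fold")
  }
  if (fl$task2 && length(unique(y2[!is_val])) < length(classes2)) {
    stop("a storage-period class is empty in the training fold")
  }
  seeds <- with_seed(config$seed, sample.int(2^31 - 2, 2))
  wts <- config$weights
  # single-task variants optimise their task's plain loss (degenerate weights)
  alpha <- if (fl$task1) (if (fl$task2) wts$alpha_task1 else 1) else 0
  beta <- if (fl$task2) (if (fl$task1) wts$beta_task2 else 1) else 0
  res <- cpp_train(cpp_cfg(network$config, network$variant), network$params,
                   X[!is_val, , drop = FALSE], y1[!is_val], y2[!is_val],
                   X[is_val, , drop = FALSE], y1[is_val], y2[is_val],
                   config$epochs, config$batch_size, config$lr,
                   config$weight_decay, alpha, beta,
                   config$early_stop_patience, network$config$dropout,
                   seeds[1], seeds[2])
  network$params <- res$params
  network$history <- res$history
  network$best_epoch <- res$best_epoch
  network$classes1 <- classes1
  network$classes2 <- classes2
  network$bands <- bands
  network
}

#' k-fold cross-validation at egg level
#'
#' Egg-level, variety-stratified folds within the given table; each fold is
#' held out in turn as the validation set (also driving early stopping), a
#' fresh network is trained on the remainder, and per-fold validation
#' metrics are summarised as mean and sd.
#'
#' @param table training [spectra_table()] (SNV-preprocessed).
#' @param bands input band indices.
#' @param model_config a [model_config()].
#' @param variant one of [model_variants()].
#' @param config a [train_config()]; `config$folds` folds are built.
#' @return List with `histories` (one per fold), `fold_metrics` (data
#'   frame), and `summary` (mean/sd per metric).
#' @export
cross_validate <- function(table, bands, model_config, variant = "mt_ctse",
                           config = train_config()) {
  fl <- variant_flags(variant)
  egg_var <- tapply(table$variety, table$egg_id, function(v) v[1])
  eggs <- names(egg_var)
  fold_of <- integer(length(eggs)); names(fold_of) <- eggs
  with_seed(config$seed, {
    for (v in sort(unique(egg_var))) {
      ev <- sort(eggs[egg_var == v])
      fold_of[sample(ev)] <- rep(seq_len(config$folds), length.out = length(ev))
    }
  })
  classes1 <- sort(unique(table$variety))
  classes2 <- sort(unique(table$day))
  histories <- list()
  rows <- list()
  for (f in seq_len(config$folds)) {
    val_eggs <- names(fold_of)[fold_of == f]
    tr <- st_subset(table, !(table$egg_id %in% val_eggs))
    va <- st_subset(table, table$egg_id %in% val_eggs)
    net <- build_network(model_config, variant, seed = config$seed + f)
    y1 <- match(tr$variety, classes1); y2 <- match(tr$day, classes2)
    yv1 <- match(va$variety, classes1); yv2 <- match(va$day, classes2)
    wts <- config$weights
    alpha <- if (fl$task1) (if (fl$task2) wts$alpha_task1 else 1) else 0
    beta <- if (fl$task2) (if (fl$task1) wts$beta_task2 else 1) else 0
    seeds <- with_seed(config$seed + f, sample.int(2^31 - 2, 2))
    res <- cpp_train(cpp_cfg(model_config, variant), net$params,
                     tr$reflectance[, bands, drop = FALSE], y1, y2,
                     va$reflectance[, bands, drop = FALSE], yv1, yv2,
                     config$epochs, config$batch_size, config$lr,
                     config$weight_decay, alpha, beta,
                     config$early_stop_patience, model_config$dropout,
                     seeds[1], seeds[2])
    histories[[f]] <- res$history
    best <- res$history[res$best_epoch, ]
    rows[[f]] <- data.frame(fold = f, best_epoch = res$best_epoch,
                            val_loss = best$val_loss, val_acc1 = best$val_acc1,
                            val_acc2 = best$val_acc2)
  }
  fm <- do.call(rbind, rows)
  num <- fm[, c("val_loss", "val_acc1", "val_acc2")]
  summary <- data.frame(metric = names(num),
                        mean = vapply(num, mean, 0, na.rm = TRUE),
                        sd = vapply(num, stats::sd, 0, na.rm = TRUE),
                        row.names = NULL)
  list(histories = histories, fold_metrics = fm, summary = summary)
}
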