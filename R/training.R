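# Patient-level data splitting and the training loop: mini-batch SGD with
# momentum and weight decay, per-step gradient reset, training-time
# augmentation, reduce-on-plateau learning-rate scheduling, and early
# stopping on the validation (combined) loss.

#' Training configuration
#'
#' Defaults follow the study setup: batch size 32, up to 200 epochs,
#' SGD at learning rate 0.001 with momentum 0.9 and weight decay 1e-4,
#' reduce-on-plateau scheduling (factor 0.1, patience 10) and early
#' stopping (patience 20), all on the validation combined loss.
#'
#' @param batch_size,max_epochs,lr,momentum,weight_decay SGD settings.
#' @param scheduler_factor,scheduler_patience Learning-rate reduction on
#'   validation-loss plateau.
#' @param early_stopping_patience Epochs without validation improvement
#'   before training halts.
#' @param min_lr Floor below which the scheduler stops reducing.
#' @param augment Apply random flip/rotation augmentation to training
#'   patches (never at evaluation).
#' @param seed Seed governing shuffling and augmentation draws.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 32L, max_epochs = 200L, lr = 0.001,
                         momentum = 0.9, weight_decay = 1e-4,
                         scheduler_factor = 0.1, scheduler_patience = 10L,
                         early_stopping_patience = 20L, min_lr = 1e-6,
                         augment = TRUE, seed = 0L) {
  cfg <- list(
    batch_size = as.integer(batch_size), max_epochs = as.integer(max_epochs),
    lr = lr, momentum = momentum, weight_decay = weight_decay,
    scheduler_factor = scheduler_factor,
    scheduler_patience = as.integer(scheduler_patience),
    early_stopping_patience = as.integer(early_stopping_patience),
    min_lr = min_lr, augment = isTRUE(augment), seed = as.integer(seed)
  )
  if (cfg$batch_size < 1L || cfg$max_epochs < 1L) {
    hx_validation_error("batch_size and max_epochs must be positive")
  }
  if (cfg$lr < 0 || cfg$momentum < 0 || cfg$weight_decay < 0) {
    hx_validation_error("lr, momentum and weight_decay must be non-negative")
  }
  structure(cfg, class = "train_config")
}

#' Patient-level split plan
#'
#' Holds one patient out entirely as the test set and partitions the
#' remaining patients into `n_folds` cross-validation folds (each non-test
#' patient validates in exactly one fold; fold sizes differ by at most 1).
#' Splits are by patient, never by spot or section.
#'
#' @param patient_ids Character vector of all patient ids.
#' @param test_patient The held-out patient (must be in `patient_ids`).
#' @param n_folds Number of folds over the remaining patients.
#' @param seed Seed for the patient shuffle.
#' @return A `split_plan`: list with `test_patient` and `cv_folds`, a list
#'   of `n_folds` lists with `train_patients` / `val_patients`.
#' @export
make_splits <- function(patient_ids, test_patient, n_folds = 5L, seed = 0L) {
  patient_ids <- unique(as.character(patient_ids))
  if (!test_patient %in% patient_ids) {
    hx_validation_error("unknown test patient '", test_patient, "'")
  }
  rest <- setdiff(patient_ids, test_patient)
  if (n_folds > length(rest)) {
    hx_validation_error(
      "n_folds (", n_folds, ") exceeds the ", length(rest), " non-test patients"
    )
  }
  shuffled <- with_seed(seed, sample(rest))
  assignment <- rep_len(seq_len(n_folds), length(shuffled))
  folds <- lapply(seq_len(n_folds), function(f) {
    val <- shuffled[assignment == f]
    list(train_patients = setdiff(rest, val), val_patients = val)
  })
  structure(
    list(test_patient = test_patient, cv_folds = folds, seed = as.integer(seed)),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x$cv_folds, function(f) length(f$val_patients), integer(1))
  cat(sprintf(
    "<split_plan> test patient %s; %d folds with validation sizes {%s}\n",
    x$test_patient, length(x$cv_folds), paste(sizes, collapse = ", ")
  ))
  invisible(x)
}

# Random flip/rotation of a standardized (H, W, C, N) batch: three
# independent coin flips per sample, applied group-wise.
augment_batch <- function(x) {
  n <- dim(x)[4]
  flips <- matrix(runif(3L * n) < 0.5, n, 3L)
  for (n_i in seq_len(n)) {
    if (flips[n_i, 1]) x[, , , n_i] <- x[, dim(x)[2]:1, , n_i] # horizontal
    if (flips[n_i, 2]) x[, , , n_i] <- x[dim(x)[1]:1, , , n_i] # vertical
    if (flips[n_i, 3]) x[, , , n_i] <- aperm(x[, , , n_i, drop = FALSE], c(2L, 1L, 3L, 4L))[dim(x)[2]:1, , , 1L]
  }
  x
}

#' Fit an expression model
#'
#' The package's central fitting routine: minimises the combined loss
#' `L_main + lambda * L_aux` over mini-batches by SGD, with gradients
#' cleared at every step, optional flip/rotation augmentation of training
#' patches, learning-rate reduction when the validation loss plateaus, and
#' early stopping.  The returned model carries the best-validation-loss
#' parameters and the per-epoch history.
#'
#' @param patches Training patches, `N x 3 x s x s` (raw 8-bit values;
#'   channel standardization statistics are computed from this set).
#' @param y_main `N x K` matrix of log-expression targets for the main
#'   genes (columns named by gene).
#' @param y_aux `N x (G - K)` matrix for the auxiliary genes, or `NULL` to
#'   train without the auxiliary head.
#' @param val List with `patches`, `y_main` (and `y_aux`) used for
#'   scheduling, early stopping and checkpoint selection.
#' @param backbone Backbone name (see [build_model()]).
#' @param spec A [loss_spec()].
#' @param config A [train_config()].
#' @param seed Seed for weight initialisation (shuffling/augmentation use
#'   `config$seed`).
#' @return A fitted `expr_model`.
#' @export
fit_expression <- function(patches, y_main, y_aux = NULL, val,
                           backbone = "tiny_cnn", spec = loss_spec(),
                           config = train_config(), seed = 0L) {
  d <- dim(patches)
  stopifnot(length(d) == 4L, d[2] == 3L)
  n <- d[1]
  if (nrow(y_main) != n) hx_validation_error("y_main rows must match patches")
  aux_enabled <- !is.null(y_aux)
  if (aux_enabled && nrow(y_aux) != n) hx_validation_error("y_aux rows must match patches")

  model <- build_model(
    backbone = backbone, n_main = ncol(y_main),
    n_aux = if (aux_enabled) ncol(y_aux) else 0L,
    aux_enabled = aux_enabled, patch_size = d[3], seed = seed
  )
  model$loss_spec <- spec
  model$main_genes <- colnames(y_main)
  model$aux_genes <- if (aux_enabled) colnames(y_aux)
  model$norm_stats <- channel_stats(patches)

  # Output biases start at the per-gene training means so early epochs fit
  # structure, not offsets.
  model$main_head$params$b <- colMeans(y_main)
  if (aux_enabled) model$aux_head$params$b <- colMeans(y_aux)

  x_all <- prep_batch(patches, model$norm_stats)
  x_val <- prep_batch(val$patches, model$norm_stats)

  val_loss_of <- function() {
    out <- predict_standardized(model, x_val)
    combined_loss(out$main, val$y_main, out$aux, if (aux_enabled) val$y_aux, spec)$total
  }

  lr <- config$lr
  best_val <- Inf
  best_state <- NULL
  best_epoch <- 0L
  bad_epochs_sched <- 0L
  bad_epochs_stop <- 0L
  history <- list()

  with_seed(derive_seed(config$seed, "trainloop"), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      epoch_loss <- 0
      n_batches <- 0L
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- x_all[, , , idx, drop = FALSE]
        if (config$augment) xb <- augment_batch(xb)
        model_zero_grads(model)
        out <- model_forward(model, xb, train = TRUE)
        lm <- head_loss(out$main, y_main[idx, , drop = FALSE], spec$loss)
        total <- lm$value
        ga <- NULL
        if (aux_enabled) {
          la <- head_loss(out$aux, y_aux[idx, , drop = FALSE], spec$loss)
          total <- total + spec$lambda * la$value
          ga <- spec$lambda * la$grad
        }
        if (!is.finite(total)) {
          hx_stop(
            "NaN/Inf training loss at epoch ", epoch, ", batch ", n_batches + 1L,
            class = "histex_nan_loss_error"
          )
        }
        model_backward(model, lm$grad, ga)
        model_sgd_step(model, lr, config$momentum, config$weight_decay)
        epoch_loss <- epoch_loss + total
        n_batches <- n_batches + 1L
      }
      vl <- val_loss_of()
      history[[epoch]] <- data.frame(
        epoch = epoch, train_loss = epoch_loss / n_batches, val_loss = vl, lr = lr
      )
      if (vl < best_val - 1e-10) {
        best_val <- vl
        best_state <- model_state(model)
        best_epoch <- epoch
        bad_epochs_sched <- 0L
        bad_epochs_stop <- 0L
      } else {
        bad_epochs_sched <- bad_epochs_sched + 1L
        bad_epochs_stop <- bad_epochs_stop + 1L
        if (bad_epochs_sched >= config$scheduler_patience && lr > config$min_lr) {
          lr <- max(lr * config$scheduler_factor, config$min_lr)
          bad_epochs_sched <- 0L
        }
        if (bad_epochs_stop >= config$early_stopping_patience) break
      }
    }
  })
  if (!is.null(best_state)) model_load_state(model, best_state)
  model$history <- do.call(rbind, history)
  model$best_epoch <- best_epoch
  model$best_val_loss <- best_val
  model
}

# Forward pass on an already-standardized batch, batched for memory.
predict_standardized <- function(model, x, batch_size = 128L) {
  n <- dim(x)[4]
  main <- matrix(0, n, model$n_main)
  aux <- if (model$aux_enabled) matrix(0, n, model$n_aux)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out <- model_forward(model, x[, , , idx, drop = FALSE], train = FALSE)
    main[idx, ] <- out$main
    if (!is.null(aux)) aux[idx, ] <- out$aux
  }
  list(main = main, aux = aux)
}

#' Run the full cross-validated experiment
#'
#' Preprocesses the sections, holds one patient out as the test set, trains
#' one model per cross-validation fold on the remaining patients, and has
#' every fold model predict every retained spot of the test patient.  An id
#' audit guarantees no test-patient spot enters any training or validation
#' set.
#'
#' @param sections List of `section` objects (see [load_section()],
#'   [load_dataset()]).
#' @param test_patient Held-out patient id.
#' @param n_folds Number of cross-validation folds (default 5).
#' @param backbone,spec,config Model and training settings.
#' @param min_total,n_main_genes,patch_size,white_threshold,white_fraction
#'   Preprocessing settings (see [preprocess_dataset()]).
#' @param seed Master seed; per-fold seeds are derived from it.
#' @return An `experiment` object: list with `models` (per fold),
#'   `predictions` (list per fold of test-spot x main-gene matrices),
#'   `aux_predictions`, `targets` / `aux_targets` (log expression of the
#'   test spots), `test_refs`, `splits`, `selection`, `preprocessed`
#'   report, and the configuration used.
#' @export
run_experiment <- function(sections, test_patient, n_folds = 5L,
                           backbone = "tiny_cnn", spec = loss_spec(),
                           config = train_config(), min_total = 1000,
                           n_main_genes = 250, patch_size = 64L,
                           white_threshold = 220, white_fraction = 0.5,
                           seed = 0L) {
  prep <- preprocess_dataset(sections,
    min_total = min_total, n_main_genes = n_main_genes, patch_size = patch_size,
    white_threshold = white_threshold, white_fraction = white_fraction
  )
  patients <- unique(prep$refs$patient)
  splits <- make_splits(patients, test_patient, n_folds, seed = derive_seed(seed, "splits"))

  sel <- prep$selection
  y_main_all <- prep$log_counts[, sel$main_genes, drop = FALSE]
  y_aux_all <- if (length(sel$aux_genes)) prep$log_counts[, sel$aux_genes, drop = FALSE]

  is_test <- prep$refs$patient == test_patient
  test_idx <- which(is_test)
  if (length(test_idx) == 0L) hx_validation_error("no retained spots for test patient ", test_patient)

  models <- list()
  predictions <- list()
  aux_predictions <- list()
  for (f in seq_along(splits$cv_folds)) {
    fold <- splits$cv_folds[[f]]
    train_idx <- which(prep$refs$patient %in% fold$train_patients)
    val_idx <- which(prep$refs$patient %in% fold$val_patients)
    # split hygiene: the test patient must be invisible to this fold
    stopifnot(
      !any(is_test[train_idx]), !any(is_test[val_idx]),
      length(intersect(train_idx, val_idx)) == 0L
    )
    fold_cfg <- config
    fold_cfg$seed <- derive_seed(seed, paste0("fold", f, "_loop"))
    model <- fit_expression(
      patches = prep$patches[train_idx, , , , drop = FALSE],
      y_main = y_main_all[train_idx, , drop = FALSE],
      y_aux = if (!is.null(y_aux_all)) y_aux_all[train_idx, , drop = FALSE],
      val = list(
        patches = prep$patches[val_idx, , , , drop = FALSE],
        y_main = y_main_all[val_idx, , drop = FALSE],
        y_aux = if (!is.null(y_aux_all)) y_aux_all[val_idx, , drop = FALSE]
      ),
      backbone = backbone, spec = spec, config = fold_cfg,
      seed = derive_seed(seed, paste0("fold", f, "_init"))
    )
    models[[f]] <- model
    pred <- predict(model, prep$patches[test_idx, , , , drop = FALSE],
      type = if (model$aux_enabled) "both" else "main"
    )
    if (is.list(pred)) {
      predictions[[f]] <- pred$main
      aux_predictions[[f]] <- pred$aux
    } else {
      predictions[[f]] <- pred
    }
    rownames(predictions[[f]]) <- prep$refs$spot_id[test_idx]
  }
  structure(
    list(
      models = models, predictions = predictions,
      aux_predictions = if (length(aux_predictions)) aux_predictions,
      targets = y_main_all[test_idx, , drop = FALSE],
      aux_targets = if (!is.null(y_aux_all)) y_aux_all[test_idx, , drop = FALSE],
      test_refs = prep$refs[test_idx, , drop = FALSE],
      splits = splits, selection = sel, report = prep$report,
      backbone = backbone, spec = spec, config = config, seed = seed
    ),
    class = "experiment"
  )
}

#' @export
print.experiment <- function(x, ...) {
  cat(sprintf(
    "<experiment> backbone %s, %d fold models, test patient %s (%d spots x %d main genes)\n",
    x$backbone, length(x$models), x$splits$test_patient,
    nrow(x$targets), ncol(x$targets)
  ))
  invisible(x)
}

#' Persist an experiment run directory
#'
#' Writes fold checkpoints (RDS parameters + JSON metadata), the split
#' manifest, per-epoch training histories (JSON lines), the per-fold
#' prediction tables (TSV), and a frozen copy of the configuration.
#'
#' @param experiment An `experiment` from [run_experiment()].
#' @param run_dir Output directory.
#' @return `run_dir`, invisibly.
#' @export
save_experiment <- function(experiment, run_dir) {
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(
      test_patient = experiment$splits$test_patient,
      cv_folds = experiment$splits$cv_folds
    ),
    file.path(run_dir, "splits.json"),
    auto_unbox = TRUE
  )
  yaml::write_yaml(
    list(
      backbone = experiment$backbone,
      lambda = experiment$spec$lambda, loss = experiment$spec$loss,
      train = unclass(experiment$config), seed = experiment$seed
    ),
    file.path(run_dir, "config.yaml")
  )
  hist_con <- file(file.path(run_dir, "history.jsonl"), "w")
  for (f in seq_along(experiment$models)) {
    m <- experiment$models[[f]]
    saveRDS(model_state(m), file.path(run_dir, sprintf("model_fold%d.rds", f)))
    jsonlite::write_json(
      list(
        backbone = m$backbone_name, patch_size = m$patch_size,
        main_genes = m$main_genes, aux_genes = m$aux_genes,
        norm_stats = m$norm_stats, seed = m$seed
      ),
      file.path(run_dir, sprintf("model_fold%d.json", f)),
      auto_unbox = TRUE, digits = NA
    )
    h <- m$history
    for (i in seq_len(nrow(h))) {
      writeLines(jsonlite::toJSON(c(fold = f, as.list(h[i, ])), auto_unbox = TRUE, digits = NA), hist_con)
    }
    pred_df <- data.frame(
      fold = f, spot_id = rownames(experiment$predictions[[f]]),
      experiment$predictions[[f]], check.names = FALSE
    )
    data.table::fwrite(pred_df, file.path(run_dir, sprintf("predictions_fold%d.tsv", f)), sep = "\t")
  }
  close(hist_con)
  data.table::fwrite(experiment$test_refs, file.path(run_dir, "test_spots.tsv"), sep = "\t")
  targ_df <- data.frame(
    spot_id = rownames(experiment$targets) %||% experiment$test_refs$spot_id,
    experiment$targets,
    check.names = FALSE
  )
  data.table::fwrite(targ_df, file.path(run_dir, "targets.tsv"), sep = "\t")
  invisible(run_dir)
}
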