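# Patient-level splitting and the training loop.

test_that("splits partition non-test patients with balanced fold sizes", {
  ids <- sprintf("BC%02d", 1:23)
  plan <- make_splits(ids, test_patient = "BC23", n_folds = 5, seed = 1)
  sizes <- sort(vapply(plan$cv_folds, function(f) length(f$val_patients), integer(1)), decreasing = TRUE)
  expect_identical(sizes, c(5L, 5L, 4L, 4L, 4L)) # 22 patients over 5 folds

  val_all <- unlist(lapply(plan$cv_folds, `[[`, "val_patients"))
  expect_setequal(val_all, setdiff(ids, "BC23"))
  expect_false(anyDuplicated(val_all) > 0) # each patient validates exactly once
  for (f in plan$cv_folds) {
    expect_false("BC23" %in% c(f$train_patients, f$val_patients))
    expect_setequal(c(f$train_patients, f$val_patients), setdiff(ids, "BC23"))
  }

  # deterministic under seed
  expect_identical(plan, make_splits(ids, "BC23", 5, seed = 1))
  expect_false(identical(plan, make_splits(ids, "BC23", 5, seed = 2)))
})

test_that("degenerate and invalid split requests are handled", {
  ids <- paste0("P", 0:5)
  plan <- make_splits(ids, "P0", n_folds = 5, seed = 3)
  expect_true(all(vapply(plan$cv_folds, function(f) length(f$val_patients), integer(1)) == 1L))
  expect_error(make_splits(ids, "P9", 5), class = "histex_validation_error")
  expect_error(make_splits(ids, "P0", 6), class = "histex_validation_error")
})

# Small shared fixture for loop tests: 40 patches of 16 px, 3 + 2 genes.
tiny_fit_data <- function(seed = 6) {
  set.seed(seed)
  n <- 40
  patches <- array(runif(n * 3 * 16 * 16, 0, 255), c(n, 3, 16, 16))
  y_main <- matrix(rnorm(n * 3, mean = 2), n, 3, dimnames = list(NULL, paste0("g", 1:3)))
  y_aux <- matrix(rnorm(n * 2, mean = 1), n, 2, dimnames = list(NULL, paste0("a", 1:2)))
  val_idx <- 33:40
  list(
    patches = patches[1:32, , , , drop = FALSE],
    y_main = y_main[1:32, , drop = FALSE], y_aux = y_aux[1:32, , drop = FALSE],
    val = list(
      patches = patches[val_idx, , , , drop = FALSE],
      y_main = y_main[val_idx, , drop = FALSE], y_aux = y_aux[val_idx, , drop = FALSE]
    )
  )
}

test_that("a zero learning rate leaves parameters and the training loss unchanged", {
  d <- tiny_fit_data()
  cfg <- train_config(max_epochs = 3, lr = 0, augment = FALSE, early_stopping_patience = 10, seed = 1)
  m <- fit_expression(d$patches, d$y_main, d$y_aux, val = d$val, config = cfg, seed = 2)
  ref <- build_model("tiny_cnn", n_main = 3, n_aux = 2, patch_size = 16, seed = 2)
  # weights equal the (bias-initialised) starting point
  expect_equal(m$net |> histex:::nn_param_layers() |> lapply(function(l) l$params),
    ref$net |> histex:::nn_param_layers() |> lapply(function(l) l$params),
    tolerance = 0
  )
  expect_equal(diff(range(m$history$train_loss)), 0)
})

test_that("early stopping halts after patience epochs without improvement", {
  d <- tiny_fit_data()
  cfg <- train_config(
    max_epochs = 50, lr = 0, augment = FALSE,
    early_stopping_patience = 1, scheduler_patience = 99, seed = 1
  )
  m <- fit_expression(d$patches, d$y_main, d$y_aux, val = d$val, config = cfg, seed = 2)
  # frozen weights: epoch 1 sets the best, epoch 2 fails to improve, stop
  expect_equal(nrow(m$history), 2L)
  # the checkpoint is never worse than the best observed validation loss
  expect_equal(m$best_val_loss, min(m$history$val_loss))
})

test_that("a short smoke run reduces the training loss", {
  d <- tiny_fit_data()
  cfg <- train_config(max_epochs = 5, early_stopping_patience = 10, seed = 3)
  m <- fit_expression(d$patches, d$y_main, d$y_aux, val = d$val, config = cfg, seed = 4)
  expect_lt(tail(m$history$train_loss, 1), m$history$train_loss[1])
  expect_equal(nrow(m$history), 5L)
  expect_s3_class(m, "expr_model")
})

test_that("the learning-rate scheduler reduces on plateau", {
  d <- tiny_fit_data()
  cfg <- train_config(
    max_epochs = 6, lr = 0.001, augment = FALSE,
    scheduler_factor = 0.1, scheduler_patience = 2,
    early_stopping_patience = 99, seed = 1
  )
  # freeze improvement by zeroing the lr after epoch 1 is impossible from
  # config alone, so use lr = 0: the plateau is immediate and the recorded
  # lr sequence shows the scheduled reductions
  cfg$lr <- 0
  cfg$min_lr <- 0
  m <- fit_expression(d$patches, d$y_main, d$y_aux, val = d$val, config = cfg, seed = 2)
  expect_equal(nrow(m$history), 6L)
  expect_true(all(diff(m$history$lr) <= 0))
})

test_that("the cross-validated experiment respects split hygiene and reproduces itself", {
  exp1 <- cached("small_experiment_seed5", small_experiment(seed = 5))
  # no test-patient spot in any fold model's training or validation data is
  # asserted inside run_experiment; check the visible artifacts here
  expect_identical(unique(exp1$test_refs$patient), "SP03")
  expect_length(exp1$models, 2L)
  expect_length(exp1$predictions, 2L)
  for (p in exp1$predictions) {
    expect_identical(dim(p), dim(exp1$targets))
  }

  # determinism: an identical rerun gives identical prediction tables
  exp2 <- small_experiment(seed = 5)
  expect_identical(exp1$predictions, exp2$predictions)
  expect_identical(exp1$targets, exp2$targets)

  # the auxiliary toggle leaves the main prediction schema unchanged
  expect_identical(colnames(exp1$predictions[[1]]), exp1$selection$main_genes)
})

test_that("experiment runs persist checkpoints, histories, splits and predictions", {
  exp1 <- cached("small_experiment_seed5", small_experiment(seed = 5))
  run_dir <- tempfile("run")
  save_experiment(exp1, run_dir)
  expect_true(file.exists(file.path(run_dir, "splits.json")))
  expect_true(file.exists(file.path(run_dir, "config.yaml")))
  expect_true(file.exists(file.path(run_dir, "history.jsonl")))
  expect_true(all(file.exists(file.path(run_dir, c(
    "model_fold1.rds", "model_fold1.json",
    "predictions_fold1.tsv", "targets.tsv", "test_spots.tsv"
  )))))
  # the stored checkpoint state matches the in-memory model
  st <- readRDS(file.path(run_dir, "model_fold1.rds"))
  expect_identical(st, histex:::model_state(exp1$models[[1]]))
  unlink(run_dir, recursive = TRUE)
})
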