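# Error metrics, Pearson correlation, correlation classes and the
# aggregated report.

test_that("mae and rmse match direct formula evaluation", {
  expect_equal(mae_rmse(c(1, 2, 3), c(1, 2, 3)), c(mae = 0, rmse = 0))
  expect_equal(
    mae_rmse(c(1, 2, 3), c(2, 2, 5)),
    c(mae = 1, rmse = sqrt(5 / 3))
  )
  expect_error(mae_rmse(1:3, 1:2), class = "histex_validation_error")
  expect_error(mae_rmse(numeric(0), numeric(0)), class = "histex_validation_error")
})

test_that("pearson matches hand-derived cases and handles constants", {
  a <- c(1, 2, 3, 4)
  expect_equal(pearson(a, 2 * a + 1), 1)
  expect_equal(pearson(a, -a), -1)
  expect_equal(pearson(a, c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(pearson(a, rep(2, 4))))
  expect_error(pearson(1, 1), class = "histex_validation_error")
})

test_that("metrics agree with independent references on 1000 random pairs", {
  set.seed(314)
  max_pcc_err <- 0
  max_err_err <- 0
  for (i in 1:1000) {
    n <- sample(5:50, 1)
    a <- rnorm(n)
    b <- rnorm(n) + 0.3 * a
    max_pcc_err <- max(max_pcc_err, abs(pearson(a, b) - cor(a, b)))
    m <- mae_rmse(a, b)
    max_err_err <- max(
      max_err_err,
      abs(m["mae"] - sum(abs(a - b)) / n),
      abs(m["rmse"] - sqrt(sum((a - b)^2) / n))
    )
  }
  expect_lt(max_pcc_err, 1e-10)
  expect_lt(max_err_err, 1e-10)
})

test_that("rmse dominates mae on random pairs", {
  set.seed(99)
  for (i in 1:50) {
    m <- mae_rmse(rnorm(20), rnorm(20))
    expect_gte(m["rmse"], m["mae"])
  }
})

test_that("correlation classes use the strict strong boundary", {
  expect_equal(as.character(classify_pcc(0.6325)), "strong")
  expect_equal(as.character(classify_pcc(0.5)), "medium") # strictly > 0.50 is strong
  expect_equal(as.character(classify_pcc(0.31)), "medium")
  expect_equal(as.character(classify_pcc(0.3)), "weak")
  expect_equal(as.character(classify_pcc(0.05)), "negligible")
  expect_equal(as.character(classify_pcc(-0.2)), "non-positive")
  expect_equal(as.character(classify_pcc(0)), "non-positive")
  expect_equal(as.character(classify_pcc(NA_real_)), "undefined")
  expect_error(classify_pcc(1.5), class = "histex_validation_error")
})

make_eval_fixture <- function(unit_pccs, n = 40) {
  # Build prediction units whose per-gene PCC with the shared target is
  # controlled by mixing the target with independent noise.
  set.seed(8)
  target <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("gX", "gY")))
  preds <- lapply(unit_pccs, function(r) {
    p <- target
    for (j in 1:2) {
      noise <- rnorm(n)
      p[, j] <- r * scale(target[, j]) + sqrt(max(0, 1 - r^2)) * scale(noise)
    }
    p
  })
  list(target = target, preds = preds)
}

test_that("per-gene median PCC aggregates across units as the median", {
  fx <- make_eval_fixture(c(0.9))
  rep1 <- evaluate_predictions(fx$preds[[1]], fx$target)
  expect_equal(rep1$per_gene$median_pcc, as.vector(rep1$unit_pcc[, 1]))

  # three units with PCCs approximately 0.2 / 0.5 / 0.6 -> median is the middle
  fx3 <- make_eval_fixture(c(0.2, 0.5, 0.6))
  rep3 <- evaluate_predictions(fx3$preds, fx3$target)
  for (g in 1:2) {
    expect_equal(
      rep3$per_gene$median_pcc[g],
      median(rep3$unit_pcc[g, ])
    )
  }
})

test_that("perfect predictions give zero errors and all-strong classes", {
  set.seed(9)
  target <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  rep <- evaluate_predictions(list(target, target), target)
  expect_equal(rep$aggregates$amae, 0)
  expect_equal(rep$aggregates$armse, 0)
  expect_true(all(rep$per_gene$class == "strong"))
  expect_equal(rep$aggregates$n_positive, 3L)
})

test_that("evaluation is invariant to spot ordering within units", {
  fx <- make_eval_fixture(c(0.4, 0.7))
  rep_a <- evaluate_predictions(fx$preds, fx$target)
  perm <- sample(nrow(fx$target))
  rep_b <- evaluate_predictions(
    lapply(fx$preds, function(p) p[perm, , drop = FALSE]),
    fx$target[perm, , drop = FALSE]
  )
  expect_equal(rep_a$per_gene, rep_b$per_gene, tolerance = 1e-12)
})

test_that("constant genes yield undefined correlations, counted not zeroed", {
  set.seed(10)
  target <- cbind(gA = rnorm(20), gB = rep(1, 20))
  pred <- cbind(gA = rnorm(20), gB = rnorm(20))
  rep <- evaluate_predictions(pred, target)
  expect_true(is.na(rep$per_gene$median_pcc[rep$per_gene$gene == "gB"]))
  expect_equal(rep$aggregates$n_undefined, 1L)
  # classes + undefined account for every gene
  expect_equal(sum(rep$aggregates$class_counts), nrow(rep$per_gene))
})

test_that("section grouping computes per-section correlations of fold-averaged predictions", {
  set.seed(21)
  n <- 30
  target <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("g1", "g2")))
  sections <- rep(c("A", "B", "C"), each = 10)
  pred <- target + matrix(rnorm(2 * n, sd = 0.3), n, 2)
  rep_sec <- evaluate_predictions(list(pred, pred), target,
    grouping = "section", unit_of = sections
  )
  expect_identical(colnames(rep_sec$unit_pcc), c("A", "B", "C"))
  # hand check one unit: PCC of the averaged predictions within section B
  rows <- which(sections == "B")
  expect_equal(rep_sec$unit_pcc["g1", "B"], pearson(target[rows, "g1"], pred[rows, "g1"]))
  expect_equal(
    rep_sec$per_gene$median_pcc[1],
    median(rep_sec$unit_pcc["g1", ])
  )
  expect_error(
    evaluate_predictions(pred, target, grouping = "section"),
    class = "histex_validation_error"
  )
})

test_that("missing genes and mismatched spots are rejected", {
  target <- cbind(gA = rnorm(10))
  pred <- cbind(gZ = rnorm(10))
  expect_error(evaluate_predictions(pred, target), class = "histex_validation_error")
  expect_error(
    evaluate_predictions(cbind(gA = rnorm(8)), target),
    class = "histex_validation_error"
  )
})

test_that("reports serialize to TSV, JSON and a histogram image", {
  fx <- make_eval_fixture(c(0.6, 0.8))
  rep <- evaluate_predictions(fx$preds, fx$target)
  out <- tempfile("evalout")
  write_eval_report(rep, out)
  expect_true(file.exists(file.path(out, "per_gene.tsv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "pcc_histogram.png")))
  back <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(back$n_positive, rep$aggregates$n_positive)
  unlink(out, recursive = TRUE)
})
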