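# Per-gene error and correlation metrics, correlation classes, and the
# aggregated evaluation report.

#' Mean absolute error and root mean squared error
#'
#' `MAE = mean(|y - yhat|)`, `RMSE = sqrt(mean((y - yhat)^2))`; by Jensen's
#' inequality `RMSE >= MAE` for every vector pair.
#'
#' @param y_true,y_pred Equal-length numeric vectors, `n >= 1`.
#' @return Named numeric vector `c(mae, rmse)`.
#' @export
mae_rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) == 0L) {
    hx_validation_error("mae_rmse requires equal-length, non-empty vectors")
  }
  d <- y_true - y_pred
  c(mae = mean(abs(d)), rmse = sqrt(mean(d * d)))
}

#' Pearson correlation coefficient
#'
#' `sum((a - mean(a)) * (b - mean(b))) / sqrt(sum((a - mean(a))^2) *
#' sum((b - mean(b))^2))`.  When either vector is constant the correlation
#' is undefined and `NA` is returned (reported separately, never coerced to
#' zero).
#'
#' @param a,b Equal-length numeric vectors, `n >= 2`.
#' @return A value in `[-1, 1]`, or `NA` for a constant input.
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    hx_validation_error("pearson requires equal-length vectors with n >= 2")
  }
  ac <- a - mean(a)
  bc <- b - mean(b)
  den <- sqrt(sum(ac * ac) * sum(bc * bc))
  if (den == 0) return(NA_real_)
  min(1, max(-1, sum(ac * bc) / den))
}

#' Classify a correlation coefficient
#'
#' Classes follow the usual reading of correlation strength with a strict
#' upper boundary: strong when `pcc > 0.5`, medium in `(0.3, 0.5]`, weak in
#' `(0.1, 0.3]`, negligible in `(0, 0.1]`, and non-positive otherwise.
#' So exactly 0.5 is "medium" — "strong" is reserved for values strictly
#' greater than 0.50.
#'
#' @param pcc Correlation value(s) in `[-1, 1]` (`NA` allowed, classified
#'   as `"undefined"`).
#' @return Character vector of classes.
#' @export
classify_pcc <- function(pcc) {
  if (any(!is.na(pcc) & (pcc < -1 - 1e-12 | pcc > 1 + 1e-12))) {
    hx_validation_error("pcc out of [-1, 1]")
  }
  out <- ifelse(is.na(pcc), "undefined",
    ifelse(pcc > 0.5, "strong",
      ifelse(pcc > 0.3, "medium",
        ifelse(pcc > 0.1, "weak",
          ifelse(pcc > 0, "negligible", "non-positive")
        )
      )
    )
  )
  factor(out, levels = c("strong", "medium", "weak", "negligible", "non-positive", "undefined"))
}

#' Evaluate per-gene predictions
#'
#' For each gene, the Pearson correlation between prediction and truth is
#' computed within each evaluation unit (by default, each fold model's
#' predictions over the whole test patient) and the median is taken across
#' units; genes whose correlation is undefined in a unit (constant truth or
#' prediction) have that unit excluded from their median rather than
#' contributing a zero.  MAE/RMSE are pooled across all (unit, spot) pairs
#' per gene, and `aMAE`/`aRMSE` are their means over genes.
#'
#' @param predictions List of `spots x genes` matrices, one per fold model,
#'   or a single matrix (one unit).
#' @param targets `spots x genes` matrix of true log expression, columns
#'   matching `predictions`.
#' @param grouping Aggregation unit.  `"fold_model"` (default): the PCC is
#'   computed per fold model over all test spots.  `"section"`: fold
#'   predictions are averaged per spot and the PCC is computed within each
#'   section (given by `unit_of`).
#' @param unit_of For `grouping = "section"`: a vector (one entry per
#'   target row) assigning each spot to its section.
#' @return An `eval_report`: list with `per_gene` (data.frame: gene,
#'   median_pcc, mae, rmse, class, n_units), `unit_pcc` (genes x units
#'   matrix), and `aggregates` (aMAE, aRMSE, n_positive, class counts,
#'   n_undefined, histogram of positive PCCs in 0.05 bins).
#' @export
evaluate_predictions <- function(predictions, targets,
                                 grouping = c("fold_model", "section"),
                                 unit_of = NULL) {
  grouping <- match.arg(grouping)
  if (is.matrix(predictions)) predictions <- list(predictions)
  genes <- colnames(targets)
  if (is.null(genes)) hx_validation_error("targets must have gene column names")
  for (p in predictions) {
    if (is.null(colnames(p)) || !all(colnames(p) %in% genes)) {
      hx_validation_error("prediction genes missing from targets")
    }
    if (nrow(p) != nrow(targets)) hx_validation_error("prediction/target spot count mismatch")
  }
  pred_genes <- colnames(predictions[[1]])

  if (grouping == "section") {
    if (is.null(unit_of) || length(unit_of) != nrow(targets)) {
      hx_validation_error("grouping = 'section' needs unit_of, one entry per spot")
    }
    # fold models agree on the spots; average them and split rows by section
    avg <- Reduce(`+`, predictions) / length(predictions)
    units <- split(seq_len(nrow(targets)), unit_of)
    predictions <- lapply(units, function(i) avg[i, , drop = FALSE])
    target_rows <- units
    unit_names <- names(units)
  } else {
    target_rows <- rep(list(seq_len(nrow(targets))), length(predictions))
    unit_names <- paste0("fold", seq_along(predictions))
  }
  n_units <- length(predictions)

  unit_pcc <- matrix(NA_real_, length(pred_genes), n_units,
    dimnames = list(pred_genes, unit_names)
  )
  err_abs <- numeric(length(pred_genes))
  err_sq <- numeric(length(pred_genes))
  n_obs <- 0L
  for (u in seq_len(n_units)) {
    pu <- predictions[[u]]
    rows <- target_rows[[u]]
    n_obs <- n_obs + length(rows)
    for (g in seq_along(pred_genes)) {
      gene <- pred_genes[g]
      y <- targets[rows, gene]
      yh <- pu[, gene]
      unit_pcc[g, u] <- if (length(rows) >= 2L) pearson(y, yh) else NA_real_
      err_abs[g] <- err_abs[g] + sum(abs(y - yh))
      err_sq[g] <- err_sq[g] + sum((y - yh)^2)
    }
  }
  mae <- err_abs / n_obs
  rmse <- sqrt(err_sq / n_obs)
  median_pcc <- apply(unit_pcc, 1L, function(v) {
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
  })
  cls <- classify_pcc(median_pcc)
  per_gene <- data.frame(
    gene = pred_genes, median_pcc = median_pcc, mae = mae, rmse = rmse,
    class = cls, n_units = rowSums(!is.na(unit_pcc)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  pos <- median_pcc[!is.na(median_pcc) & median_pcc > 0]
  breaks <- seq(0, 1, by = 0.05)
  hist_counts <- table(cut(pos, breaks = breaks, include.lowest = FALSE))
  aggregates <- list(
    amae = mean(mae), armse = mean(rmse),
    n_positive = sum(!is.na(median_pcc) & median_pcc > 0),
    class_counts = table(cls),
    n_undefined = sum(is.na(median_pcc)),
    histogram = list(breaks = breaks, counts = as.integer(hist_counts))
  )
  structure(
    list(
      per_gene = per_gene, unit_pcc = unit_pcc,
      aggregates = aggregates, grouping = grouping
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  a <- x$aggregates
  cc <- a$class_counts
  cat(sprintf(
    paste0(
      "<eval_report> %d genes, %d unit(s) [%s]\n",
      "  aMAE %.4f, aRMSE %.4f; %d positively correlated\n",
      "  strong %d | medium %d | weak %d | negligible %d | non-positive %d | undefined %d\n"
    ),
    nrow(x$per_gene), ncol(x$unit_pcc), x$grouping,
    a$amae, a$armse, a$n_positive,
    cc[["strong"]], cc[["medium"]], cc[["weak"]], cc[["negligible"]],
    cc[["non-positive"]], cc[["undefined"]]
  ))
  top <- x$per_gene[order(-x$per_gene$median_pcc), ]
  top <- utils::head(top[!is.na(top$median_pcc), ], 5)
  cat("  top genes:", paste(sprintf("%s (%.3f)", top$gene, top$median_pcc), collapse = ", "), "\n")
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits the per-gene TSV (gene, median_pcc, mae, rmse, class), a JSON
#' aggregate summary, and a positive-PCC histogram PNG.
#'
#' @param report An `eval_report`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_eval_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report$per_gene, file.path(out_dir, "per_gene.tsv"), sep = "\t")
  a <- report$aggregates
  jsonlite::write_json(
    list(
      grouping = report$grouping, amae = a$amae, armse = a$armse,
      n_positive = a$n_positive, n_undefined = a$n_undefined,
      class_counts = as.list(setNames(as.integer(a$class_counts), names(a$class_counts)))
    ),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  png_path <- file.path(out_dir, "pcc_histogram.png")
  grDevices::png(png_path, width = 800, height = 500)
  on.exit(grDevices::dev.off(), add = TRUE)
  mids <- utils::head(a$histogram$breaks, -1) + 0.025
  graphics::barplot(a$histogram$counts,
    names.arg = sprintf("%.2f", mids),
    col = "steelblue", border = NA, las = 2,
    xlab = "median PCC", ylab = "genes",
    main = "Positively correlated genes"
  )
  invisible(out_dir)
}
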