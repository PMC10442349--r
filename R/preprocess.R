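# Gene/spot filtering, log transform, top-K gene selection, patch
# extraction with white-pixel exclusion, augmentation, and standardization.
#
# Fixed pipeline order: gene filter -> spot filter -> patch extraction ->
# (log transform, gene selection on retained spots).

#' Remove genes with zero mean expression
#'
#' Drops gene columns whose mean expression pooled across all spots of all
#' samples is zero (equivalently, all-zero columns); column order is
#' preserved.
#'
#' @param counts Spots x genes matrix, gene ids as colnames.
#' @return The filtered matrix.
#' @export
filter_genes <- function(counts) {
  validate_counts(counts)
  if (nrow(counts) == 0L || ncol(counts) == 0L) hx_validation_error("counts matrix is empty")
  keep <- colMeans(counts) > 0
  counts[, keep, drop = FALSE]
}

#' Keep spots with at least a minimum total read count
#'
#' Retains spots whose row sum is `>= min_total` ("at least": inclusive).
#' Row order is preserved; an empty result is allowed and warned about.
#'
#' @param counts Spots x genes matrix.
#' @param min_total Minimum total read count per spot (default 1000).
#' @return The filtered matrix.
#' @export
filter_spots <- function(counts, min_total = 1000) {
  validate_counts(counts)
  keep <- rowSums(counts) >= min_total
  if (!any(keep)) hx_warn("filter_spots: no spots reach ", min_total, " total counts")
  counts[keep, , drop = FALSE]
}

#' Log-transform counts
#'
#' Element-wise `ln(1 + x)`; zero maps to zero and the transform is
#' monotone.
#'
#' @param counts Non-negative numeric matrix or vector.
#' @return Transformed object of the same shape.
#' @export
log_transform <- function(counts) {
  if (anyNA(counts) || any(counts < 0)) hx_validation_error("log_transform requires non-negative input")
  log1p(counts)
}

#' Select the top-K genes by mean expression
#'
#' Ranks genes by mean expression across all retained spots (pooled over
#' patients), descending, ties broken lexicographically by gene id.  The
#' top `k` become the main-head genes; the remainder are assigned to the
#' auxiliary head.
#'
#' @param counts Spots x genes matrix (post-filter).
#' @param k Number of main genes (default 250).
#' @return A `gene_selection`: list with `main_genes`, `aux_genes`
#'   (character vectors in rank order) and `means` (named, all genes).
#' @export
select_genes <- function(counts, k = 250) {
  validate_counts(counts)
  if (!is_count(k) || k > ncol(counts)) {
    hx_validation_error("k must be a positive integer <= number of genes (", ncol(counts), ")")
  }
  means <- colMeans(counts)
  ord <- order(-means, colnames(counts), method = "radix")
  ranked <- colnames(counts)[ord]
  structure(
    list(
      main_genes = ranked[seq_len(k)],
      aux_genes = if (k < length(ranked)) ranked[(k + 1L):length(ranked)] else character(0),
      means = means
    ),
    class = "gene_selection"
  )
}

#' @export
print.gene_selection <- function(x, ...) {
  cat(sprintf(
    "<gene_selection> %d main + %d auxiliary genes; top: %s\n",
    length(x$main_genes), length(x$aux_genes),
    paste(utils::head(x$main_genes, 5), collapse = ", ")
  ))
  invisible(x)
}

# Half-open patch box around a spot center (0-based x = column, y = row):
# rows [y - floor(s/2), y - floor(s/2) + s), cols [x - floor(s/2), ... + s).
patch_box <- function(x, y, size) {
  r0 <- y - size %/% 2L
  c0 <- x - size %/% 2L
  list(row0 = r0, row1 = r0 + size, col0 = c0, col1 = c0 + size)
}

#' Extract spot-centered image patches
#'
#' Each retained spot yields the half-open `size x size` pixel box centered
#' on its coordinates.  Spots whose box exceeds the image bounds are skipped
#' (no padding) and counted; patches whose fraction of white pixels (all
#' three channels `>= white_threshold`) is strictly greater than
#' `white_fraction` are excluded as uninformative.
#'
#' @param section A `section` object (see [load_section()]).
#' @param retained_spots Character vector of spot ids to consider (after
#'   spot filtering); default all spots of the section.
#' @param patch_size Patch side in pixels (default 224).
#' @param white_threshold Intensity at or above which a channel counts as
#'   white (default 220).
#' @param white_fraction Maximum tolerated white-pixel fraction; exclusion
#'   is strict (`> white_fraction`), so a patch at exactly the boundary is
#'   retained.  Default 0.5.
#' @return A `patch_set`: list with `patches` (`N x 3 x s x s` array),
#'   `spot_refs` (data.frame: patient, section, spot_id, pixel_x, pixel_y)
#'   and `report` (n_out_of_bounds, n_white_excluded).
#' @export
extract_patches <- function(section, retained_spots = NULL, patch_size = 224,
                            white_threshold = 220, white_fraction = 0.5) {
  stopifnot(inherits(section, "section"))
  h <- dim(section$image)[1]; w <- dim(section$image)[2]
  if (patch_size > h || patch_size > w) {
    hx_validation_error("patch_size ", patch_size, " exceeds image size ", h, " x ", w)
  }
  spots <- section$spots
  if (!is.null(retained_spots)) spots <- spots[spots$spot_id %in% retained_spots, , drop = FALSE]

  n_oob <- 0L; n_white <- 0L
  kept <- logical(nrow(spots))
  patches <- array(0, c(nrow(spots), 3L, patch_size, patch_size))
  for (i in seq_len(nrow(spots))) {
    b <- patch_box(spots$pixel_x[i], spots$pixel_y[i], patch_size)
    if (b$row0 < 0 || b$col0 < 0 || b$row1 > h || b$col1 > w) {
      n_oob <- n_oob + 1L
      next
    }
    p <- section$image[(b$row0 + 1L):b$row1, (b$col0 + 1L):b$col1, , drop = FALSE]
    white <- p[, , 1] >= white_threshold & p[, , 2] >= white_threshold & p[, , 3] >= white_threshold
    if (mean(white) > white_fraction) {
      n_white <- n_white + 1L
      next
    }
    patches[i, , , ] <- aperm(p, c(3L, 1L, 2L)) # C x H x W
    kept[i] <- TRUE
  }
  if (n_oob > 0L) hx_warn("extract_patches: ", n_oob, " spot(s) skipped (patch outside image)")
  refs <- data.frame(
    patient = rep(section$patient_id, sum(kept)),
    section = rep(section$section_id, sum(kept)),
    spot_id = spots$spot_id[kept],
    pixel_x = spots$pixel_x[kept], pixel_y = spots$pixel_y[kept],
    stringsAsFactors = FALSE
  )
  structure(
    list(
      patches = patches[kept, , , , drop = FALSE],
      spot_refs = refs,
      report = list(n_out_of_bounds = n_oob, n_white_excluded = n_white)
    ),
    class = "patch_set"
  )
}

#' @export
print.patch_set <- function(x, ...) {
  d <- dim(x$patches)
  cat(sprintf(
    "<patch_set> %d patches of %d x %d (%d skipped out-of-bounds, %d white-excluded)\n",
    d[1], d[3], d[4], x$report$n_out_of_bounds, x$report$n_white_excluded
  ))
  invisible(x)
}

# Flattened N x (3*m*n) view of a patch set (channel fastest, then row, col).
flatten_patches <- function(patch_set) {
  d <- dim(patch_set$patches)
  matrix(patch_set$patches, nrow = d[1])
}

#' Randomly flip / rotate a patch
#'
#' Independently applies a horizontal flip, a vertical flip, and a 90-degree
#' rotation, each with probability 0.5.  The pixel multiset is preserved and
#' the result is deterministic under a fixed seed.  Augmentation is a
#' training-time operation only.
#'
#' @param patch `3 x s x s` numeric array (square).
#' @param rng Integer seed, or `NULL` to draw from the current RNG stream.
#' @return Transformed patch, same shape.
#' @export
augment_patch <- function(patch, rng = NULL) {
  d <- dim(patch)
  if (length(d) != 3L || d[2] != d[3]) {
    hx_validation_error("augment_patch requires a square 3 x s x s patch")
  }
  u <- with_seed(rng, runif(3)) < 0.5
  if (u[1]) patch <- patch[, , d[3]:1, drop = FALSE] # horizontal flip (reverse columns)
  if (u[2]) patch <- patch[, d[2]:1, , drop = FALSE] # vertical flip (reverse rows)
  if (u[3]) patch <- rotate90_patch(patch)
  patch
}

# 90-degree counter-clockwise rotation of a C x H x W patch.
rotate90_patch <- function(patch) {
  d <- dim(patch)
  if (d[2] != d[3]) hx_validation_error("rotation requires a square patch")
  aperm(patch, c(1L, 3L, 2L))[, d[3]:1, , drop = FALSE]
}

#' Standardize a patch to zero mean and unit variance
#'
#' `(x - mean) / std` per channel.  With `channel_means`/`channel_stds`
#' omitted, per-patch statistics are used; in the training pipeline the
#' statistics are computed once per fold from the training patches.
#'
#' @param patch `3 x s x s` array.
#' @param channel_means,channel_stds Length-3 numeric vectors, or `NULL`
#'   for per-patch statistics.
#' @return Standardized array of the same shape.
#' @export
standardize_patch <- function(patch, channel_means = NULL, channel_stds = NULL) {
  d <- dim(patch)
  if (length(d) != 3L || d[1] != 3L) hx_validation_error("patch must be a 3 x s x s array")
  if (is.null(channel_means) || is.null(channel_stds)) {
    channel_means <- apply(patch, 1L, mean)
    channel_stds <- apply(patch, 1L, stats::sd)
    # sd() normalises by n - 1; the standardization contract is population
    # variance, matching per-tensor normalization conventions.
    n <- prod(d[2:3])
    channel_stds <- channel_stds * sqrt((n - 1) / n)
  }
  if (any(channel_stds <= 0)) hx_validation_error("channel std must be > 0 (constant channel?)")
  (patch - channel_means) / channel_stds
}

# Per-channel mean/sd over a whole patch set (training-fold statistics).
channel_stats <- function(patches) {
  d <- dim(patches)
  m <- numeric(3); s <- numeric(3)
  for (c in 1:3) {
    v <- as.vector(patches[, c, , ])
    m[c] <- mean(v)
    s[c] <- sqrt(mean((v - m[c])^2))
  }
  list(mean = m, sd = s)
}

#' Preprocess a multi-section dataset
#'
#' Runs the fixed preprocessing order over a list of sections: pooled
#' zero-mean gene filter, per-spot minimum-count filter, patch extraction
#' with white-pixel exclusion, then log transform and top-K gene selection
#' on the retained spots.  Returns everything the training stage needs.
#'
#' @param sections List of `section` objects.
#' @param min_total Spot filter threshold (default 1000).
#' @param n_main_genes Number of main-head genes (default 250; capped at
#'   the post-filter gene count).
#' @param patch_size,white_threshold,white_fraction See [extract_patches()].
#' @param rank_on `"raw"` (default) ranks genes for selection on raw
#'   counts; `"log"` ranks on log-transformed counts.
#' @return A `preprocessed_dataset`: list with `bundle` (a [spot_bundle()]
#'   over retained, patch-bearing spots), `patches` (`N x 3 x s x s`),
#'   `refs` (per-patch spot references), `selection` (a `gene_selection`),
#'   `log_counts` (N x genes, aligned to patches), and `report`.
#' @export
preprocess_dataset <- function(sections, min_total = 1000, n_main_genes = 250,
                               patch_size = 224, white_threshold = 220,
                               white_fraction = 0.5, rank_on = c("raw", "log")) {
  rank_on <- match.arg(rank_on)
  stopifnot(length(sections) > 0)
  genes <- colnames(sections[[1]]$counts)
  for (s in sections) {
    if (!identical(colnames(s$counts), genes)) {
      hx_validation_error("all sections must share an identical gene set")
    }
  }
  pooled <- do.call(rbind, lapply(sections, function(s) unname(s$counts)))
  colnames(pooled) <- genes # spot ids repeat across sections; gene filter pools rows
  pooled <- filter_genes(pooled)
  genes_kept <- colnames(pooled)

  patch_list <- list(); ref_list <- list(); count_list <- list()
  n_oob <- 0L; n_white <- 0L; n_low <- 0L
  for (s in sections) {
    counts <- s$counts[, genes_kept, drop = FALSE]
    counts <- filter_spots(counts, min_total = min_total)
    n_low <- n_low + (nrow(s$counts) - nrow(counts))
    if (nrow(counts) == 0L) next
    ps <- extract_patches(s, rownames(counts),
      patch_size = patch_size,
      white_threshold = white_threshold, white_fraction = white_fraction
    )
    n_oob <- n_oob + ps$report$n_out_of_bounds
    n_white <- n_white + ps$report$n_white_excluded
    if (nrow(ps$spot_refs) == 0L) next
    patch_list[[length(patch_list) + 1L]] <- ps$patches
    ref_list[[length(ref_list) + 1L]] <- ps$spot_refs
    count_list[[length(count_list) + 1L]] <- counts[ps$spot_refs$spot_id, , drop = FALSE]
  }
  if (length(patch_list) == 0L) hx_validation_error("no spots survived preprocessing")
  patches <- abind_first(patch_list)
  refs <- do.call(rbind, ref_list)
  rownames(refs) <- NULL
  counts <- do.call(rbind, count_list)
  rownames(counts) <- NULL # spot ids can repeat across sections; refs carry identity

  selection <- select_genes(
    if (rank_on == "log") log_transform(counts) else counts,
    k = min(n_main_genes, ncol(counts))
  )
  bundle <- spot_bundle(
    count = counts,
    pixel = as.matrix(refs[, c("pixel_x", "pixel_y")]),
    patient = refs$patient
  )
  structure(
    list(
      bundle = bundle, patches = patches, refs = refs,
      selection = selection, log_counts = log_transform(counts),
      report = list(
        n_genes_in = length(genes), n_genes_kept = length(genes_kept),
        n_spots_low_count = n_low, n_out_of_bounds = n_oob,
        n_white_excluded = n_white, n_spots_kept = nrow(refs)
      )
    ),
    class = "preprocessed_dataset"
  )
}

#' @export
print.preprocessed_dataset <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    paste0(
      "<preprocessed_dataset> %d spots x %d genes (%d main + %d aux)\n",
      "  gene filter: %d -> %d; spot filter removed %d; patches skipped: %d oob, %d white\n"
    ),
    nrow(x$bundle$count), ncol(x$bundle$count),
    length(x$selection$main_genes), length(x$selection$aux_genes),
    r$n_genes_in, r$n_genes_kept, r$n_spots_low_count, r$n_out_of_bounds, r$n_white_excluded
  ))
  invisible(x)
}

# rbind-like concatenation of N x ... arrays along the first margin.
abind_first <- function(arrs) {
  if (length(arrs) == 1L) return(arrs[[1]])
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(0, c(n, d[-1]))
  at <- 0L
  for (a in arrs) {
    na <- dim(a)[1]
    if (na > 0) out[(at + 1L):(at + na), , , ] <- a
    at <- at + na
  }
  out
}
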