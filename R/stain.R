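# Stain separation and normalization.  H&E stain mixing is approximately
# linear in optical density (Beer-Lambert): OD = C %*% S with C >= 0 the
# per-pixel stain concentrations and S the 2 x 3 matrix of unit-norm stain
# color vectors.  S is estimated by sparse non-negative factorization over
# tissue pixels (the Vahadane approach); normalization maps an image's
# concentrations through a reference stain basis.

#' Convert 8-bit RGB intensities to optical density
#'
#' `od = -ln(clamp(I, 1, 255) / background_intensity)`, element-wise.  The
#' clamp at 1 keeps the transform finite; pure background maps to OD 0.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param background_intensity Incident-light intensity (default 255).
#' @return Array of the same shape, non-negative.
#' @export
rgb_to_od <- function(image, background_intensity = 255) {
  check_rgb_image(image)
  -log(pmin(pmax(image, 1), background_intensity) / background_intensity)
}

#' @rdname rgb_to_od
#' @param od Optical-density array as produced by `rgb_to_od()`.
#' @export
od_to_rgb <- function(od, background_intensity = 255) {
  out <- round(background_intensity * exp(-od))
  out[out > 255] <- 255
  out[out < 0] <- 0
  out
}

#' Tissue mask from luminosity
#'
#' A pixel is tissue when its CIELAB luminosity (L scaled to `[0, 1]`) is
#' below 0.8; near-white background is excluded from stain estimation.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param luminosity_threshold Upper L bound (0-1 scale) for tissue.
#' @return Logical `H x W` matrix, `TRUE` where tissue.
#' @export
tissue_mask <- function(image, luminosity_threshold = 0.8) {
  lab <- rgb_to_lab(image)
  lab$L / 100 < luminosity_threshold
}

# Non-negative concentrations C (n x 2) for OD rows X given stain matrix S
# (2 x 3), minimizing ||X - C S||^2 + sparsity * sum(C) by vectorised
# coordinate descent (closed-form per coordinate).
stain_concentrations <- function(X, S, sparsity = 0, n_iter = 30L) {
  s1 <- S[1, ]; s2 <- S[2, ]
  s11 <- sum(s1 * s1); s22 <- sum(s2 * s2); s12 <- sum(s1 * s2)
  x1 <- as.vector(X %*% s1); x2 <- as.vector(X %*% s2)
  c1 <- pmax(0, x1 / s11); c2 <- pmax(0, x2 / s22)
  half <- sparsity / 2
  for (i in seq_len(n_iter)) {
    c1 <- pmax(0, (x1 - c2 * s12 - half) / s11)
    c2 <- pmax(0, (x2 - c1 * s12 - half) / s22)
  }
  cbind(c1, c2, deparse.level = 0)
}

new_stain_profile <- function(stain_matrix, concentration_ref) {
  stain_matrix <- as.matrix(stain_matrix)
  if (!all(dim(stain_matrix) == c(2L, 3L))) hx_validation_error("stain matrix must be 2 x 3")
  if (any(stain_matrix < 0)) hx_validation_error("stain matrix entries must be non-negative")
  nrm <- sqrt(rowSums(stain_matrix^2))
  if (any(nrm <= 0)) hx_validation_error("stain matrix rows must be non-zero")
  stain_matrix <- stain_matrix / nrm
  if (any(concentration_ref <= 0)) hx_validation_error("concentration_ref must be > 0")
  rownames(stain_matrix) <- c("hematoxylin", "eosin")
  colnames(stain_matrix) <- c("R", "G", "B")
  structure(
    list(stain_matrix = stain_matrix, concentration_ref = as.numeric(concentration_ref)),
    class = "stain_profile"
  )
}

#' @export
print.stain_profile <- function(x, ...) {
  cat("<stain_profile>\n")
  print(round(x$stain_matrix, 4))
  cat("concentration_ref (p99):", sprintf("%.4f", x$concentration_ref), "\n")
  invisible(x)
}

#' Estimate a stain profile by sparse non-negative factorization
#'
#' Solves `OD ~ C %*% S` over tissue pixels with two non-negative unit-norm
#' stain rows and an L1 sparsity penalty on the concentrations, by
#' alternating vectorised coordinate descent on `C` and a projected
#' least-squares update of `S`.  Rows are ordered so that row 1 is
#' hematoxylin, identified as the stain with the larger red-channel optical
#' density (hematoxylin absorbs red strongly; eosin barely).
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param sparsity_weight L1 penalty on concentrations (default 0.1).
#' @param max_iter,tol Alternation cap and convergence tolerance on the
#'   stain-matrix update.
#' @param max_pixels At most this many tissue pixels are used (seeded
#'   subsample) for the factorization.
#' @param seed Seed for the pixel subsample; fixed seed gives a
#'   deterministic profile.
#' @return A `stain_profile`: unit-norm 2 x 3 `stain_matrix` (rows
#'   hematoxylin, eosin) and `concentration_ref`, the 99th percentile of
#'   each concentration channel over tissue pixels.
#' @export
estimate_stain_profile <- function(image, sparsity_weight = 0.1, max_iter = 200L,
                                   tol = 1e-4, max_pixels = 50000L, seed = 0L) {
  check_rgb_image(image)
  mask <- tissue_mask(image)
  n_tissue <- sum(mask)
  if (n_tissue < 100L) {
    hx_stop("no tissue: only ", n_tissue, " tissue pixels (>= 100 required)",
      class = "histex_no_tissue_error"
    )
  }
  od <- rgb_to_od(image)
  X <- cbind(od[, , 1][mask], od[, , 2][mask], od[, , 3][mask])
  if (nrow(X) > max_pixels) {
    keep <- with_seed(seed, sample.int(nrow(X), max_pixels))
    Xs <- X[keep, , drop = FALSE]
  } else {
    Xs <- X
  }

  # Literature H&E OD directions as a deterministic, well-posed start.
  S <- rbind(c(0.65, 0.70, 0.29), c(0.07, 0.99, 0.11))
  S <- S / sqrt(rowSums(S^2))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    C <- stain_concentrations(Xs, S, sparsity = sparsity_weight)
    G <- crossprod(C) # 2 x 2
    if (abs(det(G)) < 1e-12) {
      # Degenerate second stain (single-stain image): keep the dominant
      # direction, retain the other row from the previous iterate.
      dom <- which.max(diag(G))
      d <- colSums(C[, dom] * Xs) # = t(C[,dom]) %*% Xs
      S_new <- S
      S_new[dom, ] <- pmax(d, 0)
      message("histex: degenerate second stain; profile flagged low-confidence")
      S_next <- S_new
    } else {
      S_next <- pmax(solve(G, crossprod(C, Xs)), 0)
    }
    nrm <- sqrt(rowSums(S_next^2))
    dead <- nrm < 1e-8
    if (any(dead)) {
      # a stain unused by the image collapses to zero; keep the previous
      # (unit-norm) direction so the profile stays well-posed
      S_next[dead, ] <- S[dead, , drop = FALSE]
      nrm[dead] <- 1
      if (it == 1L) message("histex: degenerate second stain; profile flagged low-confidence")
    }
    S_next <- S_next / nrm
    delta <- max(abs(S_next - S))
    S <- S_next
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged && delta > 50 * tol) {
    hx_stop("stain factorization did not converge within ", max_iter, " iterations",
      class = "histex_convergence_error"
    )
  }
  # Row order: hematoxylin has the larger red-channel OD.
  if (S[1, 1] < S[2, 1]) S <- S[c(2L, 1L), , drop = FALSE]
  C_all <- stain_concentrations(X, S, sparsity = 0)
  ref <- apply(C_all, 2, stats::quantile, probs = 0.99, names = FALSE)
  ref[ref <= 0] <- 1e-6
  new_stain_profile(S, ref)
}

#' Normalize an image's stains to a reference profile
#'
#' Per-pixel concentrations under the source profile are rescaled
#' channel-wise by `reference_ref / source_ref` (99th-percentile ratios) and
#' re-composed through the reference stain matrix.  Background pixels carry
#' near-zero optical density and therefore remain white.  Images with no
#' tissue are returned unchanged.
#'
#' @param source_image `H x W x 3` array in `[0, 255]`.
#' @param source_profile,reference_profile `stain_profile` objects.
#' @return Normalized image, same shape and range as the input.
#' @export
normalize_stains <- function(source_image, source_profile, reference_profile) {
  check_rgb_image(source_image)
  stopifnot(inherits(source_profile, "stain_profile"), inherits(reference_profile, "stain_profile"))
  if (any(source_profile$concentration_ref <= 0)) {
    hx_validation_error("source concentration_ref must be > 0")
  }
  if (!any(tissue_mask(source_image))) {
    return(source_image)
  }
  d <- dim(source_image)
  od <- rgb_to_od(source_image)
  X <- matrix(od, ncol = 3L) # column k = channel k, pixel order preserved
  C <- stain_concentrations(X, source_profile$stain_matrix, sparsity = 0)
  scale <- reference_profile$concentration_ref / source_profile$concentration_ref
  C <- sweep(C, 2L, scale, `*`)
  od_new <- C %*% reference_profile$stain_matrix
  array(od_to_rgb(od_new), dim = d)
}

#' Standardize image luminosity
#'
#' Divides the CIELAB L channel by its 95th percentile and clips to the
#' valid range, so that differently exposed images of the same section reach
#' a common brightness.  Idempotent to within one intensity level.
#'
#' @param image `H x W x 3` array in `[0, 255]`.
#' @param percentile Percentile of L used as the white point.
#' @return Standardized image, same shape and range.
#' @export
standardize_luminosity <- function(image, percentile = 0.95) {
  check_rgb_image(image)
  lab <- rgb_to_lab(image)
  p <- stats::quantile(lab$L / 100, probs = percentile, names = FALSE)
  if (p <= 0) return(image)
  L_new <- pmin(pmax(lab$L / 100 / p, 0), 1) * 100
  lab_to_rgb(L_new, lab$a, lab$b)
}

#' Serialize a stain profile to / from JSON
#'
#' @param profile A `stain_profile`.
#' @param path JSON file path.
#' @return `write_stain_profile()` returns `path` invisibly;
#'   `read_stain_profile()` returns the `stain_profile`.
#' @export
write_stain_profile <- function(profile, path) {
  stopifnot(inherits(profile, "stain_profile"))
  jsonlite::write_json(
    list(
      stain_matrix = unclass(unname(profile$stain_matrix)),
      concentration_ref = profile$concentration_ref
    ),
    path,
    digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_stain_profile
#' @export
read_stain_profile <- function(path) {
  if (!file.exists(path)) hx_io_error("stain profile not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_stain_profile(obj$stain_matrix, obj$concentration_ref)
}
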