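# Shared fixtures, all built in code.  Expensive artifacts (the reference
# desk-scale experiment) are computed lazily once per test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Uniform-color image helper.
solid_image <- function(h, w, rgb) {
  img <- array(0, c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

# Synthetic two-stain mixture from known unit OD vectors; the mixer is the
# oracle for stain-vector recovery.
stain_mixture <- function(seed, n = 64L) {
  set.seed(seed)
  h <- c(0.55, 0.75, 0.30) + runif(3, -0.08, 0.08)
  h <- h / sqrt(sum(h^2))
  e <- c(0.10, 0.95, 0.15) + runif(3, -0.05, 0.05)
  e <- e / sqrt(sum(e^2))
  Ch <- rgamma(n * n, 2, scale = 0.35)
  Ce <- rgamma(n * n, 2, scale = 0.45)
  od <- cbind(Ch, Ce) %*% rbind(h, e)
  list(image = array(od_to_rgb(od), c(n, n, 3L)), h = h, e = e)
}

angular_deg <- function(u, v) {
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u * u) * sum(v * v))))) * 180 / pi
}

# Write a toy section (image + spots + counts files) and return the paths.
write_toy_section <- function(dir = tempfile("sec"),
                              spots = data.frame(
                                spot_id = c("1x1", "1x2", "2x1", "2x2"),
                                pixel_x = c(10, 40, 12, 44),
                                pixel_y = c(12, 14, 44, 46)
                              ),
                              n_genes = 10, img_size = 64, seed = 1) {
  dir.create(dir, showWarnings = FALSE)
  set.seed(seed)
  img <- array(round(runif(img_size * img_size * 3, 60, 240)), c(img_size, img_size, 3L))
  image_path <- file.path(dir, "image.png")
  write_image(img, image_path)
  spots_path <- file.path(dir, "spots.tsv")
  write.table(spots, spots_path, sep = "\t", row.names = FALSE, quote = FALSE)
  counts <- matrix(rpois(nrow(spots) * n_genes, 20),
    nrow(spots), n_genes,
    dimnames = list(spots$spot_id, sprintf("ENSGT%04d", seq_len(n_genes)))
  )
  counts_path <- file.path(dir, "counts.tsv")
  write.table(data.frame(spot_id = rownames(counts), counts, check.names = FALSE),
    counts_path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  list(
    dir = dir, image = image_path, spots = spots_path, counts = counts_path,
    img = img, spots_df = spots, counts_mat = counts
  )
}

# Small synthetic study used for fast pipeline/determinism tests.
small_synth_config <- function(seed = 33) {
  synth_config(
    n_patients = 3L, sections_per_patient = 1L, spots_per_section = 48L,
    image_size = 160L, patch_size = 32L, n_signal_genes = 5L,
    n_noise_genes = 10L, signal_strength = 0.9, count_scale = 1500,
    seed = seed
  )
}

small_experiment <- function(seed = 5, cfg = small_synth_config()) {
  dir <- tempfile("smallds")
  ds <- generate_dataset(cfg, dir)
  sections <- load_dataset(ds$manifest_path)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  run_experiment(sections,
    test_patient = "SP03", n_folds = 2L,
    config = train_config(
      max_epochs = 4L, scheduler_patience = 2L,
      early_stopping_patience = 4L
    ),
    n_main_genes = 5L, patch_size = 32L, seed = seed
  )
}

# The reference desk-scale study: 6 patients x 200 spots, 64-px patches,
# 20 signal + 50 noise genes, tiny_cnn + auxiliary head (lambda = 40),
# 5-fold patient-level CV with one held-out patient.  Computed once.
reference_experiment <- function() {
  cached("reference_experiment", {
    cfg <- synth_config(seed = 101L)
    dir <- tempfile("refds")
    ds <- generate_dataset(cfg, dir)
    sections <- load_dataset(ds$manifest_path)
    exp <- run_experiment(sections,
      test_patient = "SP06", n_folds = 5L,
      spec = loss_spec(lambda = 40),
      config = train_config(
        max_epochs = 25L, scheduler_patience = 4L,
        early_stopping_patience = 8L
      ),
      n_main_genes = cfg$n_signal_genes, patch_size = cfg$patch_size, seed = 7L
    )
    exp$dataset_dir <- dir
    exp$gene_params <- ds$gene_params
    exp
  })
}

cli_path <- function() {
  system.file("cli", "histex.R", package = "histex")
}

run_cli <- function(...) {
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(rscript, c(cli_path(), ...), stdout = TRUE, stderr = TRUE))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
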