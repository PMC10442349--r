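# Synthetic data generator: determinism, image structure, the
# image -> expression link, and on-disk round-trips.

test_that("image generation is seeded and structurally sensible", {
  cfg <- small_synth_config()
  a <- generate_tissue_image(cfg, rng = 5)
  b <- generate_tissue_image(cfg, rng = 5)
  expect_identical(a, b) # bit-identical under a fixed seed

  # tissue is darker than background
  lum <- (a$image[, , 1] + a$image[, , 2] + a$image[, , 3]) / 3
  expect_lt(mean(lum[a$tissue]), mean(lum[!a$tissue]))

  # dark blobs appear exactly where the nuclei latent map is set: pixels
  # free of nuclei carry only the (weakly red-absorbing) eosin stain
  nuc <- a$latent$nuclei > 0
  if (any(nuc)) {
    expect_lt(mean(a$image[, , 1][nuc]), mean(a$image[, , 1][a$tissue & !nuc]))
  }
  expect_true(all(a$image[, , 1][!a$tissue & !nuc] > 250))
})

test_that("expression generation is seeded, non-negative and integer", {
  cfg <- small_synth_config()
  img <- generate_tissue_image(cfg, rng = 2)
  spots <- histex:::generate_spot_table(cfg, rng = 3)
  e1 <- generate_expression(img$latent, spots, cfg, rng = 4)
  e2 <- generate_expression(img$latent, spots, cfg, rng = 4)
  expect_identical(e1$counts, e2$counts)
  expect_true(all(e1$counts >= 0))
  expect_true(all(e1$counts == floor(e1$counts)))

  e3 <- generate_expression(img$latent, spots, cfg, rng = 5)
  expect_false(identical(e1$counts, e3$counts)) # different seed, different draws
})

test_that("count_scale 2000 keeps every spot above the 1000-count filter", {
  cfg <- synth_config(
    n_patients = 1, spots_per_section = 100, image_size = 256,
    patch_size = 64, count_scale = 2000, seed = 9
  )
  img <- generate_tissue_image(cfg, rng = 21)
  spots <- histex:::generate_spot_table(cfg, rng = 22)
  e <- generate_expression(img$latent, spots, cfg, rng = 23)
  expect_true(all(rowSums(e$counts) >= 1000))
})

test_that("zero signal strength leaves counts uncorrelated with image features", {
  cfg <- synth_config(
    n_patients = 1, spots_per_section = 150, image_size = 256,
    patch_size = 64, n_signal_genes = 100, n_noise_genes = 1,
    signal_strength = 0, count_scale = 2000, seed = 31
  )
  img <- generate_tissue_image(cfg, rng = 1)
  spots <- histex:::generate_spot_table(cfg, rng = 2)
  e <- generate_expression(img$latent, spots, cfg, rng = 3)

  # permutation test of the count ~ feature correlation, per signal gene
  set.seed(77)
  n_perm <- 200
  p_vals <- vapply(seq_len(cfg$n_signal_genes), function(j) {
    obs <- max(abs(cor(e$counts[, j], e$features)))
    null <- vapply(seq_len(n_perm), function(k) {
      max(abs(cor(sample(e$counts[, j]), e$features)))
    }, numeric(1))
    (1 + sum(null >= obs)) / (1 + n_perm)
  }, numeric(1))
  expect_gte(mean(p_vals > 0.01), 0.95)
})

test_that("noise-free rates are linearly recoverable from the latent features", {
  # signal_strength 1: a linear readout of the latent features explains the
  # per-gene rates essentially exactly (softplus operates in its near-linear
  # range), establishing the ceiling the trained model is measured against.
  cfg <- synth_config(
    n_patients = 1, spots_per_section = 150, image_size = 256,
    patch_size = 64, n_signal_genes = 10, n_noise_genes = 2,
    signal_strength = 1, seed = 13
  )
  img <- generate_tissue_image(cfg, rng = 6)
  spots <- histex:::generate_spot_table(cfg, rng = 7)
  e <- generate_expression(img$latent, spots, cfg, rng = 8)
  fz <- scale(e$features)
  pccs <- vapply(seq_len(10), function(j) {
    fit <- lm(e$rates[, j] ~ fz[, 1] * fz[, 2] + I(fz[, 1]^2) + I(fz[, 2]^2))
    pearson(e$rates[, j], fitted(fit))
  }, numeric(1))
  expect_true(all(pccs > 0.99))
})

test_that("generated datasets are complete on disk and load cleanly", {
  cfg <- synth_config(
    n_patients = 6, sections_per_patient = 1, spots_per_section = 100,
    image_size = 256, patch_size = 64, seed = 55
  )
  dir <- tempfile("gds")
  ds <- generate_dataset(cfg, dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  expect_equal(nrow(ds$manifest), 6L)

  sections <- expect_no_warning(load_dataset(ds$manifest_path))
  expect_length(sections, 6L)
  expect_equal(sum(vapply(sections, function(s) nrow(s$spots), integer(1))), 600L)

  # toy gene map covers the generated ids
  gm <- read_gene_map(ds$gene_map_path)
  gi <- convert_gene_ids(colnames(sections[[1]]$counts), gm)
  expect_equal(gi$n_unmapped, 0L)

  # different master seeds give different counts
  ds2 <- generate_dataset(synth_config(
    n_patients = 1, spots_per_section = 50,
    image_size = 160, patch_size = 32, seed = 56
  ), tempfile("gds2"))
  ds3 <- generate_dataset(synth_config(
    n_patients = 1, spots_per_section = 50,
    image_size = 160, patch_size = 32, seed = 57
  ), tempfile("gds3"))
  c2 <- read_count_matrix(file.path(ds2$dir, ds2$manifest$counts[1]))
  c3 <- read_count_matrix(file.path(ds3$dir, ds3$manifest$counts[1]))
  expect_false(identical(c2, c3))
})
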