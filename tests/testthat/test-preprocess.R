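# Filtering, log transform, gene selection, patch extraction,
# augmentation and standardization.

toy_counts <- function() {
  # spot totals 999, 1000, 1500, 0; genes g2 and g4 all-zero
  m <- rbind(
    c(500, 0, 499, 0, 0),
    c(400, 0, 400, 0, 200),
    c(700, 0, 500, 0, 300),
    c(0, 0, 0, 0, 0)
  )
  dimnames(m) <- list(paste0("s", 1:4), paste0("g", 1:5))
  m
}

test_that("gene filter removes exactly the all-zero genes and is idempotent", {
  m <- toy_counts()
  f <- filter_genes(m)
  expect_identical(colnames(f), c("g1", "g3", "g5"))
  expect_identical(filter_genes(f), f)

  # a single count among many zeros is kept
  m2 <- matrix(0, 100, 2, dimnames = list(NULL, c("a", "b")))
  m2[57, 2] <- 1
  expect_identical(colnames(filter_genes(m2)), "b")

  expect_error(filter_genes(matrix(numeric(0), 0, 0)), class = "histex_validation_error")
})

test_that("spot filter keeps totals >= 1000 inclusively and is idempotent", {
  m <- toy_counts()
  f <- filter_spots(m, min_total = 1000)
  expect_identical(rownames(f), c("s2", "s3")) # 1000 and 1500 kept, 999 dropped
  expect_identical(filter_spots(f, 1000), f)

  expect_identical(filter_spots(m, 0), m)
  expect_warning(empty <- filter_spots(m * 0, 1000), "no spots")
  expect_equal(nrow(empty), 0L)
})

test_that("log transform is ln(1 + x) exactly", {
  expect_identical(log_transform(0), 0)
  expect_equal(log_transform(exp(1) - 1), 1)
  set.seed(1)
  m <- matrix(rpois(40, 5), 8, 5, dimnames = list(NULL, paste0("g", 1:5)))
  expect_equal(log_transform(m), log(1 + m), tolerance = 1e-12)
  expect_error(log_transform(-1), class = "histex_validation_error")
})

test_that("gene selection ranks by mean with lexicographic ties", {
  m <- matrix(
    rep(c(3, 1, 4, 1, 5), each = 4), 4, 5,
    dimnames = list(paste0("s", 1:4), c("gA", "gB", "gC", "gD", "gE"))
  )
  sel <- select_genes(m, 2)
  expect_identical(sel$main_genes, c("gE", "gC")) # means 5 and 4
  expect_identical(sel$aux_genes, c("gA", "gB", "gD"))

  # tie: gB and gD both mean 1 -> lexicographically smaller first
  sel4 <- select_genes(m, 4)
  expect_identical(sel4$main_genes, c("gE", "gC", "gA", "gB"))

  sel_all <- select_genes(m, 5)
  expect_length(sel_all$aux_genes, 0)

  # invariant to column order
  perm <- m[, c(3, 5, 1, 2, 4)]
  expect_identical(select_genes(perm, 2)$main_genes, sel$main_genes)

  expect_error(select_genes(m, 6), class = "histex_validation_error")
})

test_that("patch boxes follow the half-open centered convention", {
  b <- histex:::patch_box(500, 600, 224)
  expect_equal(c(b$row0, b$row1), c(488, 712))
  expect_equal(c(b$col0, b$col1), c(388, 612))

  # even size: floor(s/2) shift; box [y-1, y+2) x [x-1, x+2) for size 3
  b3 <- histex:::patch_box(5, 9, 3)
  expect_equal(c(b3$row0, b3$row1, b3$col0, b3$col1), c(8, 11, 4, 7))
})

test_that("patch extraction skips boundary spots and applies the strict white rule", {
  img <- solid_image(40, 40, c(100, 100, 100))
  # right half white -> a patch centered on the boundary is exactly 50% white
  img[, 21:40, ] <- 255
  spots <- data.frame(
    spot_id = c("mid", "boundary", "white", "edge"),
    pixel_x = c(10, 20, 30, 2), # 'boundary' box cols [14, 26): 6 dark, 6 white columns
    pixel_y = c(20, 20, 20, 20)
  )
  counts <- matrix(10, 4, 3, dimnames = list(spots$spot_id, c("g1", "g2", "g3")))
  sec <- histex:::new_section("P", "S", img, spots, counts)

  expect_warning(
    ps <- extract_patches(sec, patch_size = 12, white_threshold = 220, white_fraction = 0.5),
    "outside image"
  )
  # 'edge' out of bounds; 'white' all-white excluded; exact-50% 'boundary' retained
  expect_setequal(ps$spot_refs$spot_id, c("mid", "boundary"))
  expect_equal(ps$report$n_out_of_bounds, 1L)
  expect_equal(ps$report$n_white_excluded, 1L)

  # one more white column pushes the fraction strictly over 0.5 -> excluded
  img2 <- img
  img2[, 20, ] <- 255
  sec2 <- histex:::new_section("P", "S", img2, spots, counts)
  expect_warning(
    ps2 <- extract_patches(sec2, patch_size = 12, white_fraction = 0.5),
    "outside image"
  )
  expect_setequal(ps2$spot_refs$spot_id, "mid")

  expect_error(extract_patches(sec, patch_size = 64), class = "histex_validation_error")
})

test_that("patch content matches the image box exactly", {
  set.seed(4)
  img <- array(round(runif(30 * 30 * 3, 0, 200)), c(30, 30, 3))
  spots <- data.frame(spot_id = "s", pixel_x = 14, pixel_y = 16)
  counts <- matrix(5, 1, 2, dimnames = list("s", c("g1", "g2")))
  sec <- histex:::new_section("P", "S", img, spots, counts)
  ps <- extract_patches(sec, patch_size = 8)
  # rows [12,20), cols [10,18) in 0-based half-open convention
  expected <- aperm(img[13:20, 11:18, , drop = FALSE], c(3, 1, 2))
  expect_equal(ps$patches[1, , , ], expected)
})

test_that("augmentation transforms form the expected group and preserve pixels", {
  set.seed(2)
  p <- array(rnorm(3 * 6 * 6), c(3, 6, 6))

  r <- histex:::rotate90_patch
  expect_equal(r(r(r(r(p)))), p) # rotation has order 4
  flip_h <- function(x) x[, , 6:1, drop = FALSE]
  expect_equal(flip_h(flip_h(p)), p)

  a1 <- augment_patch(p, rng = 99)
  a2 <- augment_patch(p, rng = 99)
  expect_identical(a1, a2) # deterministic under a fixed seed
  expect_equal(sort(as.vector(a1)), sort(as.vector(p))) # pixel multiset preserved

  expect_error(augment_patch(array(1, c(3, 4, 5))), class = "histex_validation_error")
})

test_that("standardization hits zero mean / unit variance and matches hand formula", {
  set.seed(3)
  p <- array(runif(3 * 8 * 8, 0, 255), c(3, 8, 8))
  z <- standardize_patch(p)
  for (c in 1:3) {
    expect_lt(abs(mean(z[c, , ])), 1e-6)
    expect_lt(abs(sqrt(mean((z[c, , ] - mean(z[c, , ]))^2)) - 1), 1e-6)
  }

  # hand-computed toy: per-channel (x - mean) / population sd
  toy <- array(c(1, 2, 3, 4), c(1, 2, 2))
  toy3 <- array(0, c(3, 2, 2))
  for (c in 1:3) toy3[c, , ] <- toy[1, , ] * c
  z3 <- standardize_patch(toy3)
  for (c in 1:3) {
    v <- c(1, 2, 3, 4) * c
    expect_equal(as.vector(z3[c, , ]), (v - mean(v)) / sqrt(mean((v - mean(v))^2)))
  }

  # dataset statistics: constant patch stays constant
  zc <- standardize_patch(array(100, c(3, 4, 4)), channel_means = c(90, 90, 90), channel_stds = c(20, 20, 20))
  expect_true(all(zc == 0.5))
  expect_error(standardize_patch(array(1, c(3, 4, 4))), class = "histex_validation_error")
})

test_that("the preprocessing pipeline composes in fixed order on a synthetic dataset", {
  cfg <- small_synth_config(seed = 44)
  dir <- tempfile("ppds")
  ds <- generate_dataset(cfg, dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  sections <- load_dataset(ds$manifest_path)
  prep <- preprocess_dataset(sections, n_main_genes = 5, patch_size = 32)

  n_spots_total <- sum(vapply(sections, function(s) nrow(s$spots), integer(1)))
  expect_lte(nrow(prep$refs), n_spots_total)
  expect_equal(dim(prep$patches)[1], nrow(prep$refs))
  # every retained spot passes the spot filter
  expect_true(all(rowSums(prep$bundle$count) >= 1000))
  # gene selection operates on the post-filter gene set
  expect_setequal(
    c(prep$selection$main_genes, prep$selection$aux_genes),
    colnames(prep$bundle$count)
  )
  expect_equal(prep$log_counts, log1p(prep$bundle$count), ignore_attr = TRUE)
})
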