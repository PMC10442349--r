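# Section loading, gene-id conversion, and the spot-bundle archive.

test_that("load_section returns a validated section from toy files", {
  toy <- write_toy_section()
  sec <- load_section(toy$image, toy$spots, toy$counts, patient_id = "P1", section_id = "A")
  expect_s3_class(sec, "section")
  expect_equal(nrow(sec$spots), 4L)
  expect_equal(dim(sec$image), c(64L, 64L, 3L))
  expect_identical(rownames(sec$counts), sec$spots$spot_id)

  # determinism: two loads of identical files give identical sections
  sec2 <- load_section(toy$image, toy$spots, toy$counts, patient_id = "P1", section_id = "A")
  expect_identical(sec, sec2)
})

test_that("out-of-bounds spots are dropped with a warning", {
  spots <- data.frame(
    spot_id = c("1x1", "1x2", "2x1", "2x2"),
    pixel_x = c(10, 1000, 12, 44),
    pixel_y = c(12, 10, 44, 46)
  )
  toy <- write_toy_section(spots = spots)
  expect_warning(
    sec <- load_section(toy$image, toy$spots, toy$counts),
    "outside image bounds"
  )
  expect_equal(nrow(sec$spots), 3L)
  expect_false("1x2" %in% sec$spots$spot_id)
})

test_that("duplicate gene columns and id mismatches are rejected", {
  toy <- write_toy_section()
  counts <- toy$counts_mat
  colnames(counts)[2] <- colnames(counts)[1]
  bad_path <- file.path(toy$dir, "bad_counts.tsv")
  write.table(data.frame(spot_id = rownames(counts), counts, check.names = FALSE),
    bad_path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  expect_error(
    load_section(toy$image, toy$spots, bad_path),
    class = "histex_validation_error"
  )

  # heavy spot/count mismatch names the offending ids
  counts2 <- toy$counts_mat
  rownames(counts2) <- paste0("Z", seq_len(nrow(counts2)))
  bad2 <- file.path(toy$dir, "bad_counts2.tsv")
  write.table(data.frame(spot_id = rownames(counts2), counts2, check.names = FALSE),
    bad2,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  expect_error(load_section(toy$image, toy$spots, bad2), "mismatch")
})

test_that("spot tables parse in both separators, with or without header", {
  df <- data.frame(spot_id = c("a", "b"), pixel_x = c(5, 6), pixel_y = c(7, 8))
  tsv <- tempfile(fileext = ".tsv")
  write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  csv <- tempfile(fileext = ".csv")
  write.table(df, csv, sep = ",", row.names = FALSE, quote = FALSE)
  bare <- tempfile(fileext = ".txt")
  write.table(df, bare, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  for (p in c(tsv, csv, bare)) {
    st <- read_spot_table(p)
    expect_equal(st$spot_id, c("a", "b"))
    expect_equal(st$pixel_x, c(5, 6))
    expect_equal(st$pixel_y, c(7, 8))
  }
})

test_that("gene id conversion maps known ids and falls back on the rest", {
  res <- convert_gene_ids(c("g1", "g2"), c(g1 = "B2M"))
  expect_equal(res$symbols, c("B2M", "g2"))
  expect_equal(res$n_unmapped, 1L)

  res2 <- convert_gene_ids("g1", c(g1 = "ACTB"))
  expect_equal(res2$symbols, "ACTB")
  expect_equal(res2$n_unmapped, 0L)

  expect_error(convert_gene_ids(c("g1", "g1"), c(g1 = "A")), class = "histex_validation_error")
  expect_error(convert_gene_ids("g1", character(0)), class = "histex_validation_error")
})

test_that("spot bundles round-trip losslessly through the archive", {
  set.seed(42)
  for (i in 1:5) {
    n <- sample(1:30, 1)
    g <- sample(1:8, 1)
    b <- spot_bundle(
      matrix(rpois(n * g, 50), n, g, dimnames = list(NULL, sprintf("ENSG%03d", seq_len(g)))),
      cbind(sample(0:500, n, TRUE), sample(0:500, n, TRUE)),
      sample(c("P1", "P2", "P3"), n, TRUE),
      sample(0:(n - 1))
    )
    path <- tempfile(fileext = ".zip")
    write_spot_bundle(b, path)
    b2 <- read_spot_bundle(path)
    # element-wise identity, including array order
    expect_equal(unname(b2$count), unname(b$count))
    expect_identical(colnames(b2$count), colnames(b$count))
    expect_equal(unname(b2$pixel), unname(b$pixel))
    expect_identical(b2$patient, b$patient)
    expect_identical(b2$index, b$index)
    unlink(path)
  }
})

test_that("archives written here are plain ZIP files readable by utils::unzip", {
  b <- spot_bundle(
    matrix(1:6, 3, 2, dimnames = list(NULL, c("g1", "g2"))),
    cbind(1:3, 4:6), rep("P1", 3)
  )
  path <- tempfile(fileext = ".zip")
  write_spot_bundle(b, path)
  listing <- unzip(path, list = TRUE)
  expect_setequal(listing$Name, c("count.tsv", "pixel.tsv", "patient.tsv", "index.tsv"))
})

test_that("empty and malformed bundles are handled", {
  empty <- spot_bundle(
    matrix(numeric(0), 0, 3, dimnames = list(NULL, c("a", "b", "c"))),
    matrix(numeric(0), 0, 2), character(0), integer(0)
  )
  path <- tempfile(fileext = ".zip")
  write_spot_bundle(empty, path)
  back <- read_spot_bundle(path)
  expect_equal(nrow(back$count), 0L)
  expect_length(back$patient, 0L)

  expect_error(
    spot_bundle(matrix(1:4, 2, 2), cbind(1, 2), c("P1", "P2")),
    class = "histex_validation_error"
  )
  expect_error(
    spot_bundle(matrix(1:4, 2, 2), cbind(1:2, 3:4), c("P1", "P2"), index = c(0L, 2L)),
    "contiguous"
  )
  expect_error(read_spot_bundle(tempfile()), class = "histex_io_error")
  junk <- tempfile(fileext = ".zip")
  writeBin(as.raw(1:100), junk)
  expect_error(read_spot_bundle(junk), class = "histex_io_error")
})

test_that("a directory of per-spot archives reads as one bundle", {
  b <- spot_bundle(
    matrix(rpois(12, 30), 6, 2, dimnames = list(NULL, c("g1", "g2"))),
    cbind(1:6, 7:12), rep(c("P1", "P2"), each = 3)
  )
  dir <- tempfile("bundledir")
  dir.create(dir)
  # one archive per spot, each carrying the spot's global ordinal index
  for (i in 1:6) {
    entries <- list(
      "count.tsv" = histex:::bundle_array_raw(b$count[i, , drop = FALSE]),
      "pixel.tsv" = histex:::bundle_array_raw(b$pixel[i, , drop = FALSE]),
      "patient.tsv" = histex:::bundle_array_raw(data.frame(patient = b$patient[i])),
      "index.tsv" = histex:::bundle_array_raw(data.frame(index = b$index[i]))
    )
    histex:::write_zip_stored(entries, file.path(dir, sprintf("spot_%d.zip", i)))
  }
  merged <- read_spot_bundle(dir)
  expect_equal(unname(merged$count), unname(b$count))
  expect_identical(merged$patient, b$patient)
  expect_identical(merged$index, b$index)
})
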