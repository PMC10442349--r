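# Readers and domain types for per-section spatial transcriptomics data:
# spot coordinate tables, counts matrices, gene-symbol maps, sections, and
# the filtered spot-bundle archive.

# ---------------------------------------------------------------- spot table

#' Read a spot coordinate table
#'
#' Accepts tab- or comma-separated text with or without a header.  The table
#' must provide a spot identifier (grid label such as `"12x24"`) and integer
#' pixel coordinates of the spot center.  Column names `spot_id`/`id`,
#' `pixel_x`/`x` and `pixel_y`/`y` are recognised; without a header the first
#' three columns are taken as id, x, y.  Coordinates are 0-based with
#' x = column and y = row.
#'
#' @param path Path to the table.
#' @param diameter_um Physical spot diameter in micrometres (metadata only).
#' @return A `data.frame` with columns `spot_id`, `pixel_x`, `pixel_y` and
#'   attribute `diameter_um`.
#' @export
read_spot_table <- function(path, diameter_um = 100) {
  if (!file.exists(path)) hx_io_error("spot table not found: ", path)
  dt <- tryCatch(
    data.table::fread(path, header = "auto", data.table = FALSE),
    error = function(e) hx_io_error("unreadable spot table '", path, "': ", conditionMessage(e))
  )
  if (nrow(dt) == 0L || ncol(dt) < 3L) {
    hx_validation_error("spot table must have at least 3 columns (id, x, y)")
  }
  nm <- tolower(names(dt))
  pick <- function(cands, fallback) {
    hit <- which(nm %in% cands)
    if (length(hit)) hit[1] else fallback
  }
  ci <- pick(c("spot_id", "id", "spot"), 1L)
  cx <- pick(c("pixel_x", "x", "px"), 2L)
  cy <- pick(c("pixel_y", "y", "py"), 3L)
  out <- data.frame(
    spot_id = as.character(dt[[ci]]),
    pixel_x = as.numeric(dt[[cx]]),
    pixel_y = as.numeric(dt[[cy]]),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$pixel_x) || anyNA(out$pixel_y)) {
    hx_validation_error("spot table coordinates failed to parse as numbers")
  }
  if (anyDuplicated(out$spot_id)) {
    hx_validation_error(
      "duplicate spot ids in spot table: ",
      paste(unique(out$spot_id[duplicated(out$spot_id)]), collapse = ", ")
    )
  }
  out$pixel_x <- round(out$pixel_x)
  out$pixel_y <- round(out$pixel_y)
  attr(out, "diameter_um") <- diameter_um
  out
}

# ------------------------------------------------------------- counts matrix

#' Read a spots-by-genes counts matrix
#'
#' Tab- or comma-separated text; first column holds spot ids, remaining
#' column names are gene identifiers (Ensembl-style).  Values must be
#' non-negative integers.
#'
#' @param path Path to the counts table.
#' @return Integer matrix with spot ids as rownames and gene ids as colnames.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) hx_io_error("counts file not found: ", path)
  # check the raw header: fread would silently deduplicate repeated columns
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  head_ids <- strsplit(header, sep, fixed = TRUE)[[1]][-1]
  if (anyDuplicated(head_ids)) {
    hx_validation_error(
      "duplicate gene columns in counts: ",
      paste(unique(head_ids[duplicated(head_ids)]), collapse = ", ")
    )
  }
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, data.table = FALSE),
    error = function(e) hx_io_error("unreadable counts file '", path, "': ", conditionMessage(e))
  )
  if (ncol(dt) < 2L) hx_validation_error("counts file must have a spot-id column plus gene columns")
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  validate_counts(m)
  m
}

validate_counts <- function(counts) {
  if (!is.matrix(counts)) hx_validation_error("counts must be a matrix (spots x genes)")
  if (is.null(colnames(counts))) hx_validation_error("counts matrix must have gene column names")
  if (anyDuplicated(colnames(counts))) {
    hx_validation_error(
      "duplicate gene columns in counts: ",
      paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", ")
    )
  }
  if (anyDuplicated(rownames(counts))) hx_validation_error("duplicate spot ids in counts")
  if (anyNA(counts) || any(counts < 0)) hx_validation_error("counts must be non-negative and complete")
  invisible(TRUE)
}

# ------------------------------------------------------------------ sections

#' Load one tissue section
#'
#' Reads the H&E image, the spot coordinate table and the counts matrix of a
#' single section, validates their mutual consistency, and returns a
#' `section` object.  Spots whose pixel coordinates fall outside the image
#' are dropped with a warning.  Counts rows and spot-table rows are matched
#' by spot id; if more than `max_mismatch` of either side has no partner, a
#' validation error names the offending ids.
#'
#' @param image_path,spots_path,counts_path Paths to the three files.
#' @param patient_id,section_id Identifiers recorded on the section.
#' @param max_mismatch Maximum tolerated fraction of unmatched spot ids.
#' @return A `section` object: list with `patient_id`, `section_id`, `image`,
#'   `spots` (see [read_spot_table()]) and `counts` (spots x genes matrix,
#'   rows aligned to `spots`).
#' @export
load_section <- function(image_path, spots_path, counts_path,
                         patient_id = "P0", section_id = "S0",
                         max_mismatch = 0.1) {
  image <- read_image(image_path)
  spots <- read_spot_table(spots_path)
  counts <- read_count_matrix(counts_path)

  in_spots <- rownames(counts) %in% spots$spot_id
  in_counts <- spots$spot_id %in% rownames(counts)
  mism <- max(mean(!in_spots), mean(!in_counts))
  if (mism > max_mismatch) {
    bad <- union(rownames(counts)[!in_spots], spots$spot_id[!in_counts])
    hx_validation_error(
      "spot/count id mismatch fraction ", sprintf("%.2f", mism),
      " exceeds ", max_mismatch, "; unmatched ids: ",
      paste(utils::head(bad, 10), collapse = ", ")
    )
  }
  spots <- spots[in_counts, , drop = FALSE]
  counts <- counts[spots$spot_id, , drop = FALSE]

  h <- dim(image)[1]; w <- dim(image)[2]
  inb <- spots$pixel_x >= 0 & spots$pixel_x < w & spots$pixel_y >= 0 & spots$pixel_y < h
  if (any(!inb)) {
    hx_warn(
      sum(!inb), " spot(s) outside image bounds dropped: ",
      paste(utils::head(spots$spot_id[!inb], 10), collapse = ", ")
    )
    spots <- spots[inb, , drop = FALSE]
    counts <- counts[spots$spot_id, , drop = FALSE]
  }
  rownames(spots) <- NULL
  new_section(patient_id, section_id, image, spots, counts)
}

new_section <- function(patient_id, section_id, image, spots, counts) {
  check_rgb_image(image)
  validate_counts(counts)
  if (!all(rownames(counts) == spots$spot_id)) {
    hx_validation_error("counts rows must align with the spot table")
  }
  structure(
    list(
      patient_id = as.character(patient_id),
      section_id = as.character(section_id),
      image = image, spots = spots, counts = counts
    ),
    class = "section"
  )
}

#' @export
print.section <- function(x, ...) {
  cat(sprintf(
    "<section> patient %s, section %s: %d x %d px image, %d spots, %d genes\n",
    x$patient_id, x$section_id, dim(x$image)[1], dim(x$image)[2],
    nrow(x$spots), ncol(x$counts)
  ))
  invisible(x)
}

# ----------------------------------------------------------- gene conversion

#' Read a two-column Ensembl-id to gene-symbol mapping table
#'
#' @param path Tab- or comma-separated file with id and symbol columns
#'   (header optional).
#' @return Named character vector: `symbols[ensembl_id]`.
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) hx_io_error("gene mapping table not found: ", path)
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  if (ncol(dt) < 2L) hx_validation_error("gene mapping table must have two columns (id, symbol)")
  stats::setNames(as.character(dt[[2]]), as.character(dt[[1]]))
}

#' Convert Ensembl-style gene ids to symbols
#'
#' Every id found in the mapping receives its symbol; ids absent from the
#' mapping keep the original id as their symbol and are counted as unmapped.
#'
#' @param ids Character vector of unique gene identifiers.
#' @param mapping Named character vector (`id -> symbol`) as returned by
#'   [read_gene_map()].
#' @return A `gene_index` object: list with `ids`, `symbols` (parallel
#'   character vectors) and `n_unmapped`.
#' @export
convert_gene_ids <- function(ids, mapping) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    hx_validation_error(
      "gene ids must be unique; duplicated: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    )
  }
  if (length(mapping) == 0L) hx_validation_error("gene mapping table is empty")
  symbols <- unname(mapping[ids])
  unmapped <- is.na(symbols)
  symbols[unmapped] <- ids[unmapped]
  structure(
    list(ids = ids, symbols = symbols, n_unmapped = sum(unmapped)),
    class = "gene_index"
  )
}

#' @export
print.gene_index <- function(x, ...) {
  cat(sprintf("<gene_index> %d genes (%d unmapped)\n", length(x$ids), x$n_unmapped))
  invisible(x)
}

# ---------------------------------------------------------------- spot bundle

#' Construct a filtered spot bundle
#'
#' The bundle is the product of gene/spot filtering: parallel per-spot
#' arrays of expression counts, pixel coordinates, patient ids and a
#' contiguous 0-based ordinal index.
#'
#' @param count Spots x genes numeric matrix (post-filter), gene ids as
#'   colnames.
#' @param pixel Spots x 2 matrix of pixel coordinates (x, y).
#' @param patient Character vector of per-spot patient ids.
#' @param index Integer vector of per-spot ordinals, `0:(n-1)`; default
#'   generates them.
#' @return A `spot_bundle` object.
#' @export
spot_bundle <- function(count, pixel, patient,
                        index = seq_len(NROW(count)) - 1L) {
  count <- as.matrix(count)
  storage.mode(count) <- "double"
  pixel <- as.matrix(pixel)
  storage.mode(pixel) <- "double"
  n <- nrow(count)
  if (nrow(pixel) != n || length(patient) != n || length(index) != n) {
    hx_validation_error(
      "bundle arrays disagree in length: count ", n, ", pixel ", nrow(pixel),
      ", patient ", length(patient), ", index ", length(index)
    )
  }
  if (ncol(pixel) != 2L) hx_validation_error("pixel array must have 2 columns (x, y)")
  index <- as.integer(index)
  if (n > 0 && !identical(sort(index), 0:(n - 1L))) {
    hx_validation_error("bundle index must be unique and contiguous from 0")
  }
  colnames(pixel) <- c("x", "y")
  structure(
    list(count = count, pixel = pixel, patient = as.character(patient), index = index),
    class = "spot_bundle"
  )
}

#' @export
print.spot_bundle <- function(x, ...) {
  cat(sprintf(
    "<spot_bundle> %d spots x %d genes, %d patient(s)\n",
    nrow(x$count), ncol(x$count), length(unique(x$patient))
  ))
  invisible(x)
}

bundle_array_raw <- function(x) {
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf), add = TRUE)
  df <- as.data.frame(x)
  data.table::fwrite(df, tf, sep = "\t", row.names = FALSE, col.names = TRUE)
  readBin(tf, "raw", n = file.info(tf)$size)
}

raw_to_table <- function(bytes) {
  tf <- tempfile(fileext = ".tsv")
  on.exit(unlink(tf), add = TRUE)
  writeBin(bytes, tf)
  data.table::fread(tf, header = TRUE, sep = "\t", data.table = FALSE)
}

#' Write / read the spot-bundle archive
#'
#' The archive is a plain ZIP file of named arrays (`count`, `pixel`,
#' `patient`, `index`) stored as TSV text, one archive per dataset.
#' `read_spot_bundle()` also accepts a directory of per-spot archives
#' (one bundle per spot), which are concatenated in index order.
#'
#' @param bundle A [spot_bundle()].
#' @param path Archive path (`.zip`/`.npz`-style) for writing; archive path
#'   or directory of archives for reading.
#' @return `write_spot_bundle()` returns `path` invisibly;
#'   `read_spot_bundle()` returns a `spot_bundle`.
#' @export
write_spot_bundle <- function(bundle, path) {
  if (!inherits(bundle, "spot_bundle")) {
    bundle <- spot_bundle(bundle$count, bundle$pixel, bundle$patient, bundle$index)
  }
  entries <- list(
    "count.tsv" = bundle_array_raw(bundle$count),
    "pixel.tsv" = bundle_array_raw(bundle$pixel),
    "patient.tsv" = bundle_array_raw(data.frame(patient = bundle$patient)),
    "index.tsv" = bundle_array_raw(data.frame(index = bundle$index))
  )
  write_zip_stored(entries, path)
  invisible(path)
}

#' @rdname write_spot_bundle
#' @export
read_spot_bundle <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(zip|npz)$", full.names = TRUE)
    if (length(files) == 0L) hx_io_error("no bundle archives found in directory: ", path)
    parts <- lapply(files, read_spot_bundle_one)
    merged <- list(
      count = do.call(rbind, lapply(parts, `[[`, "count")),
      pixel = do.call(rbind, lapply(parts, `[[`, "pixel")),
      patient = unlist(lapply(parts, `[[`, "patient")),
      index = unlist(lapply(parts, `[[`, "index"))
    )
    ord <- order(merged$index)
    return(spot_bundle(
      merged$count[ord, , drop = FALSE], merged$pixel[ord, , drop = FALSE],
      merged$patient[ord], merged$index[ord]
    ))
  }
  b <- read_spot_bundle_one(path)
  spot_bundle(b$count, b$pixel, b$patient, b$index)
}

read_spot_bundle_one <- function(path) {
  entries <- read_zip_stored(path)
  need <- c("count.tsv", "pixel.tsv", "patient.tsv", "index.tsv")
  if (!all(need %in% names(entries))) {
    hx_io_error(
      "bundle archive missing arrays: ",
      paste(setdiff(need, names(entries)), collapse = ", ")
    )
  }
  count <- as.matrix(raw_to_table(entries[["count.tsv"]]))
  storage.mode(count) <- "double"
  pixel <- as.matrix(raw_to_table(entries[["pixel.tsv"]]))
  list(
    count = count,
    pixel = pixel,
    patient = as.character(raw_to_table(entries[["patient.tsv"]])[[1]]),
    index = as.integer(raw_to_table(entries[["index.tsv"]])[[1]])
  )
}
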