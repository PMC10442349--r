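# Minimal stored (uncompressed) ZIP writer used for the spot-bundle archive.
# Reading goes through utils::unzip(unzip = "internal"), so archives written
# here are also plain ZIP files any standard tool can open.

.crc_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!is.null(.crc_env$table)) return(.crc_env$table)
  tab <- integer(256)
  poly <- -306674912L # 0xEDB88320 as signed 32-bit
  for (i in 0:255) {
    c <- as.integer(i)
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(bitwShiftR(c, 1L), poly) else bitwShiftR(c, 1L)
    }
    tab[i + 1L] <- c
  }
  .crc_env$table <- tab
  tab
}

# CRC-32 of a raw vector, returned as a double in [0, 2^32).
crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(bitwShiftR(crc, 8L), tab[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) 4294967296 + crc else as.double(crc)
}

# Little-endian unsigned integer as raw bytes.
le_bytes <- function(value, n) {
  v <- as.double(value)
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(v %% 256)
    v <- v %/% 256
  }
  out
}

# entries: named list of raw vectors.  Writes a stored ZIP archive.
write_zip_stored <- function(entries, zipfile) {
  stopifnot(is.list(entries), length(names(entries)) == length(entries))
  con <- file(zipfile, "wb")
  on.exit(close(con), add = TRUE)
  offsets <- numeric(length(entries))
  crcs <- numeric(length(entries))
  pos <- 0
  dos_time <- le_bytes(0, 2) # fixed timestamp: archives are content-addressed
  dos_date <- le_bytes(33, 2) # 1980-01-01
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    crcs[i] <- crc32(data)
    offsets[i] <- pos
    hdr <- c(
      le_bytes(0x04034b50, 4), le_bytes(20, 2), le_bytes(0, 2), le_bytes(0, 2),
      dos_time, dos_date, le_bytes(crcs[i], 4),
      le_bytes(length(data), 4), le_bytes(length(data), 4),
      le_bytes(length(name), 2), le_bytes(0, 2)
    )
    writeBin(hdr, con)
    writeBin(name, con)
    if (length(data)) writeBin(data, con)
    pos <- pos + length(hdr) + length(name) + length(data)
  }
  cd_start <- pos
  cd_size <- 0
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    rec <- c(
      le_bytes(0x02014b50, 4), le_bytes(20, 2), le_bytes(20, 2), le_bytes(0, 2),
      le_bytes(0, 2), dos_time, dos_date, le_bytes(crcs[i], 4),
      le_bytes(length(data), 4), le_bytes(length(data), 4),
      le_bytes(length(name), 2), le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2),
      le_bytes(0, 2), le_bytes(0, 4), le_bytes(offsets[i], 4)
    )
    writeBin(rec, con)
    writeBin(name, con)
    cd_size <- cd_size + length(rec) + length(name)
  }
  eocd <- c(
    le_bytes(0x06054b50, 4), le_bytes(0, 2), le_bytes(0, 2),
    le_bytes(length(entries), 2), le_bytes(length(entries), 2),
    le_bytes(cd_size, 4), le_bytes(cd_start, 4), le_bytes(0, 2)
  )
  writeBin(eocd, con)
  invisible(zipfile)
}

# Extract all entries of a ZIP archive as a named list of raw vectors.
read_zip_stored <- function(zipfile) {
  if (!file.exists(zipfile)) hx_io_error("archive not found: ", zipfile)
  exdir <- tempfile("zipx")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  files <- tryCatch(
    utils::unzip(zipfile, exdir = exdir, unzip = "internal"),
    error = function(e) hx_io_error("corrupt or unreadable archive '", zipfile, "': ", conditionMessage(e)),
    warning = function(w) hx_io_error("corrupt or unreadable archive '", zipfile, "': ", conditionMessage(w))
  )
  if (length(files) == 0) hx_io_error("corrupt or empty archive: ", zipfile)
  out <- lapply(files, function(f) readBin(f, "raw", n = file.info(f)$size))
  names(out) <- substring(files, nchar(exdir) + 2L)
  out
}
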