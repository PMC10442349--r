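# Internal helpers shared across the package.

`%||%` <- function(x, y) if (is.null(x)) y else x

hx_stop <- function(..., class = "histex_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = NULL)
  ))
}

hx_validation_error <- function(...) hx_stop(..., class = "histex_validation_error")
hx_io_error <- function(...) hx_stop(..., class = "histex_io_error")

hx_warn <- function(...) warning(paste0(...), call. = FALSE)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards.  seed = NULL runs the code under the current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible 31-bit child seed from a parent seed and a stream tag.
derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  h <- as.double(seed)
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)

assert_that <- function(ok, ...) if (!isTRUE(ok)) hx_validation_error(...)
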