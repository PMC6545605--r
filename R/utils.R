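`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

.check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) {
    .stopf("strand must be '+' or '-' (got: %s)",
           paste(unique(setdiff(strand, c("+", "-"))), collapse = ", "))
  }
  invisible(strand)
}

# Sum of a per-base Rle over the 0-based half-open interval [start, end),
# treating positions beyond the stored vector as zero coverage.
.rle_sum <- function(r, start, end) {
  if (is.null(r) || end <= start) return(0)
  lo <- max(start, 0L)
  hi <- min(end, length(r))
  if (hi <= lo) return(0)
  w <- S4Vectors::window(r, lo + 1L, hi)
  sum(as.numeric(S4Vectors::runValue(w)) * S4Vectors::runLength(w))
}

# md5 of an R object via a deterministic serialization to a temp file.
.object_hash <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}
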