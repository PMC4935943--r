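# Internal helpers shared across modules.

# Read a 2+ column tab-separated file, skipping '#' comment lines and blank
# lines. Returns a character matrix of the first `min_cols` columns together
# with the original line numbers (for error reporting).
read_tsv_pairs <- function(path, min_cols = 2L, what = "edge") {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  lineno <- seq_along(raw)[keep]
  if (length(lines) == 0L) {
    stop("empty ", what, " file: ", path, call. = FALSE)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < min_cols | vapply(parts, function(p) {
    any(!nzchar(trimws(p[seq_len(min(length(p), min_cols))])))
  }, logical(1)))
  if (length(bad) > 0L) {
    stop("malformed ", what, " file ", path, ": line ", lineno[bad[1L]],
         " has fewer than ", min_cols, " non-empty fields", call. = FALSE)
  }
  mat <- t(vapply(parts, function(p) trimws(p[seq_len(min_cols)]),
                  character(min_cols)))
  list(fields = mat, lineno = lineno)
}

# Canonical undirected edge key, used wherever edges index a table.
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
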