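# Internal helpers shared across modules.

#' @importFrom rlang abort warn %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate arrange select group_by summarise ungroup
#'   bind_rows left_join distinct desc n
#' @importFrom stats phyper p.adjust rgeom runif setNames
#' @importFrom utils head combn
NULL

stop_lookup <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("snapsets_lookup_error", "snapsets_error"))
}

stop_auth <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("snapsets_auth_error", "snapsets_error"))
}

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = c("snapsets_validation_error", "snapsets_error"))
}

# Tab-separated reader: UTF-8, one header row, '#' comment lines skipped.
# Returns a zero-row tibble with `cols` when the file is absent or empty,
# so optional bundle files degrade gracefully.
read_tsv_table <- function(path, cols) {
  if (!file.exists(path)) {
    return(empty_tbl(cols))
  }
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  kept <- which(!startsWith(raw, "#") & nzchar(raw))
  lines <- raw[kept]
  if (length(lines) <= 1L) {
    return(empty_tbl(cols))
  }
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  missing <- setdiff(cols, header)
  if (length(missing) > 0L) {
    stop_validation("%s: missing column(s): %s", basename(path),
                    paste(missing, collapse = ", "))
  }
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nc <- length(header)
  mat <- vapply(body, function(x) {
    length(x) <- nc
    x
  }, character(nc))
  mat <- if (nc == 1L) matrix(mat, nrow = 1L) else mat
  out <- as_tibble(setNames(
    lapply(seq_len(nc), function(i) {
      v <- mat[i, ]
      v[is.na(v)] <- ""
      v
    }),
    header
  ))
  # source line numbers (1-based, counting header & comment lines)
  out$.line <- kept[-1L]
  out[, c(cols, ".line")]
}

empty_tbl <- function(cols) {
  out <- as_tibble(setNames(rep(list(character()), length(cols)), cols))
  out$.line <- integer()
  out
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  lines <- c(
    paste(names(df), collapse = "\t"),
    if (nrow(df) > 0L) {
      do.call(paste, c(lapply(df, as.character), sep = "\t"))
    }
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# atomic write: temp file in the same directory, then rename
write_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp, useBytes = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

sort_ids <- function(x) {
  x <- unique(as.character(x))
  x[order(x, method = "radix")]
}
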