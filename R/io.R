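#' Read and write the plain-text formats used throughout the pipeline
#'
#' All interval tables are held in memory as data frames in BED convention:
#' 0-based, half-open `[start, end)` coordinates. Coverage tracks are
#' bedGraph-style data frames with columns `chrom`, `start`, `end`, `value`
#' whose runs are non-overlapping within a chromosome. Writers emit
#' tab-separated text with deterministic formatting, so identical inputs
#' produce byte-identical files.
#'
#' @param x data frame to write (see individual writers for required columns).
#' @param path file path.
#' @name trivalent-io
NULL

fmt_num <- function(x) {
  # deterministic, locale-free numeric formatting (no scientific notation)
  if (is.integer(x)) return(as.character(x))
  format(x, trim = TRUE, scientific = FALSE, digits = 15)
}

write_lines_raw <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname trivalent-io
#' @export
write_chrom_sizes <- function(x, path) {
  stopifnot(all(c("chrom", "length") %in% names(x)))
  write_lines_raw(paste(x$chrom, fmt_num(as.integer(x$length)), sep = "\t"), path)
}

#' @rdname trivalent-io
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "length")
  df
}

#' @rdname trivalent-io
#' @param columns how many BED columns to write (3, 4 or 6).
#' @export
write_bed <- function(x, path, columns = NULL) {
  columns <- columns %||% if ("strand" %in% names(x)) 6L else
    if ("name" %in% names(x)) 4L else 3L
  fields <- list(x$chrom, fmt_num(as.integer(x$start)), fmt_num(as.integer(x$end)))
  if (columns >= 4L) fields <- c(fields, list(x$name))
  if (columns >= 6L) {
    fields <- c(fields, list(fmt_num(as.integer(x$score %||% rep(0L, nrow(x)))),
                             x$strand %||% rep(".", nrow(x))))
  }
  write_lines_raw(do.call(paste, c(fields, sep = "\t")), path)
}

#' @rdname trivalent-io
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  nms <- c("chrom", "start", "end", "name", "score", "strand")
  names(df) <- nms[seq_len(ncol(df))]
  df
}

#' @rdname trivalent-io
#' @export
write_bedgraph <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(x)))
  write_lines_raw(paste(x$chrom, fmt_num(as.integer(x$start)),
                        fmt_num(as.integer(x$end)), fmt_num(x$value),
                        sep = "\t"), path)
}

#' @rdname trivalent-io
#' @export
read_bedgraph <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "value")
  df
}

#' @rdname trivalent-io
#' @export
write_tsv <- function(x, path) {
  is_num <- vapply(x, is.numeric, logical(1L))
  out <- x
  out[is_num] <- lapply(x[is_num], fmt_num)
  lines <- c(paste(names(x), collapse = "\t"),
             do.call(paste, c(unname(out), sep = "\t")))
  if (nrow(x) == 0L) lines <- lines[1L]
  write_lines_raw(lines, path)
}

#' @rdname trivalent-io
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

# interval data frame (BED convention) -> GRanges (1-based, inclusive)
df_to_granges <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand %||% "*"
  )
  if (!is.null(df$name)) names(gr) <- df$name
  gr
}
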