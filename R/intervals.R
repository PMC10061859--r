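#' Define promoter CpG islands
#'
#' A promoter CGI is a CpG island of length 200-5000 bp with at least 1 bp
#' of overlap with some TSS +/- 1 kb window. Each surviving CGI is linked to
#' the gene whose TSS (among the overlapping windows) is nearest the CGI
#' midpoint; exact ties are broken by lexicographic gene id so the result
#' is deterministic. Coordinates follow the BED convention (0-based,
#' half-open) and the TSS window is `[tss - 1000, tss + 1000)`.
#'
#' @param cgis data frame of CGI intervals (`chrom`, `start`, `end`,
#'   optional `name`; names are generated when absent).
#' @param tss data frame of TSS records, one per gene: `chrom`, `start`
#'   (the 0-based TSS position), `end = start + 1`, `name` (gene id).
#' @return data frame of class `promoter_cgis` with columns `cgi_id`,
#'   `chrom`, `start`, `end`, `gene_id`, `tss`, `tss_distance`, sorted by
#'   coordinate (so the result is independent of input row order). An empty
#'   data frame (not an error) when nothing qualifies.
#' @export
define_promoter_cgis <- function(cgis, tss) {
  stopifnot(all(c("chrom", "start", "end") %in% names(cgis)),
            all(c("chrom", "start", "name") %in% names(tss)))
  if (is.null(cgis$name))
    cgis$name <- sprintf("cgi_%05d", seq_len(nrow(cgis)))

  missing_chrom <- setdiff(unique(cgis$chrom), unique(tss$chrom))
  if (length(missing_chrom) > 0L) {
    t_warn("skipping %d CGI(s) on chromosome(s) absent from the TSS annotation: %s",
           sum(cgis$chrom %in% missing_chrom), paste(missing_chrom, collapse = ", "))
    cgis <- cgis[!cgis$chrom %in% missing_chrom, , drop = FALSE]
  }

  len <- cgis$end - cgis$start
  cgis <- cgis[len >= 200L & len <= 5000L, , drop = FALSE]
  empty <- data.frame(cgi_id = character(0L), chrom = character(0L),
                      start = integer(0L), end = integer(0L),
                      gene_id = character(0L), tss = integer(0L),
                      tss_distance = numeric(0L), stringsAsFactors = FALSE)
  if (nrow(cgis) == 0L) {
    class(empty) <- c("promoter_cgis", "data.frame")
    return(empty)
  }

  win <- data.frame(chrom = tss$chrom, start = tss$start - 1000L,
                    end = tss$start + 1000L)
  hits <- GenomicRanges::findOverlaps(df_to_granges(cgis), df_to_granges(win),
                                      minoverlap = 1L)
  if (length(hits) == 0L) {
    class(empty) <- c("promoter_cgis", "data.frame")
    return(empty)
  }
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  mid <- (cgis$start[qi] + cgis$end[qi]) / 2
  d <- abs(mid - tss$start[si])
  # per CGI: nearest TSS, ties by lexicographic gene id
  ord <- order(qi, d, tss$name[si], method = "radix")
  keep <- ord[!duplicated(qi[ord])]

  out <- data.frame(
    cgi_id = cgis$name[qi[keep]],
    chrom = cgis$chrom[qi[keep]],
    start = cgis$start[qi[keep]], end = cgis$end[qi[keep]],
    gene_id = tss$name[si[keep]], tss = tss$start[si[keep]],
    tss_distance = d[keep], stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start, out$end, out$cgi_id, method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("promoter_cgis", "data.frame")
  out
}

#' Assign the gene of a single CGI
#'
#' Returns the id of the gene whose TSS +/- 1 kb window overlaps the CGI and
#' whose TSS is nearest the CGI midpoint (lexicographic gene id on ties).
#' Errors when no window overlaps, i.e. the interval is not a promoter CGI.
#'
#' @param cgi one-row data frame (or list) with `chrom`, `start`, `end`.
#' @param tss TSS annotation as in [define_promoter_cgis()].
#' @return gene id (length-1 character).
#' @export
assign_gene <- function(cgi, tss) {
  cand <- tss[tss$chrom == cgi$chrom &
              tss$start - 1000L < cgi$end &
              cgi$start < tss$start + 1000L, , drop = FALSE]
  if (nrow(cand) == 0L)
    t_stop("interval %s:%d-%d overlaps no TSS +/- 1 kb window: not a promoter CGI",
           cgi$chrom, cgi$start, cgi$end)
  mid <- (cgi$start + cgi$end) / 2
  d <- abs(mid - cand$start)
  cand$name[order(d, cand$name, method = "radix")][1L]
}

#' Define enhancers from H3K4me1 peaks and assign the nearest one per gene
#'
#' Peaks whose midpoint lies within 5 kb of any TSS are discarded; each gene
#' then receives the nearest surviving peak (midpoint distance to the
#' gene's TSS), ties broken by leftmost coordinate. Genes without a
#' surviving peak on their chromosome are omitted (with a message).
#'
#' @param peaks data frame of H3K4me1 peak intervals (`chrom`, `start`,
#'   `end`, optional `name`).
#' @param tss TSS annotation as in [define_promoter_cgis()].
#' @return data frame of class `enhancer_assignments`: `gene_id`, `chrom`,
#'   `start`, `end`, `name` (peak id) and `distance` (> 5000), one row per
#'   gene with an assigned enhancer.
#' @export
define_enhancers <- function(peaks, tss) {
  stopifnot(nrow(peaks) > 0L)
  if (is.null(peaks$name))
    peaks$name <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  mid <- (peaks$start + peaks$end) / 2

  # distance from each peak midpoint to the nearest TSS on its chromosome
  min_d <- rep(Inf, nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    tpos <- sort(tss$start[tss$chrom == ch])
    if (length(tpos) == 0L) next
    pi <- which(peaks$chrom == ch)
    idx <- findInterval(mid[pi], tpos)
    d_lo <- ifelse(idx >= 1L, mid[pi] - tpos[pmax(idx, 1L)], Inf)
    d_hi <- ifelse(idx < length(tpos), tpos[pmin(idx + 1L, length(tpos))] - mid[pi], Inf)
    min_d[pi] <- pmin(d_lo, d_hi)
  }
  surv <- peaks[min_d > 5000, , drop = FALSE]
  mid_s <- (surv$start + surv$end) / 2

  rows <- vector("list", nrow(tss))
  dropped <- character(0L)
  for (g in seq_len(nrow(tss))) {
    pi <- which(surv$chrom == tss$chrom[g])
    if (length(pi) == 0L) { dropped <- c(dropped, tss$name[g]); next }
    d <- abs(mid_s[pi] - tss$start[g])
    best <- pi[order(d, surv$start[pi], method = "radix")][1L]
    rows[[g]] <- data.frame(gene_id = tss$name[g], chrom = surv$chrom[best],
                            start = surv$start[best], end = surv$end[best],
                            name = surv$name[best], distance = min(d),
                            stringsAsFactors = FALSE)
  }
  if (length(dropped) > 0L)
    message(sprintf("define_enhancers: %d gene(s) without a surviving peak on their chromosome omitted",
                    length(dropped)))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) {
    out <- data.frame(gene_id = character(0L), chrom = character(0L),
                      start = integer(0L), end = integer(0L),
                      name = character(0L), distance = numeric(0L),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$gene_id, method = "radix"), ]
  rownames(out) <- NULL
  class(out) <- c("enhancer_assignments", "data.frame")
  out
}
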