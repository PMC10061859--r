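# Slot layout (per promoter, left to right, bp):
#   pre gap | left shore | CGI body | right shore | gap | enhancer | post gap
# Gaps guarantee (i) no overlap between adjacent promoter+shore windows and
# (ii) every planted enhancer midpoint lies > 5 kb from every TSS.
.slot_pre   <- 6000L
.slot_gap   <- 5500L
.enh_width  <- 500L
.slot_post  <- 6000L

slot_width <- function(cgi_len, flank) {
  .slot_pre + flank + cgi_len + flank + .slot_gap + .enh_width + .slot_post
}

#' Generate a synthetic genome bundle with planted ground truth
#'
#' Lays out `n_promoters` promoter CpG islands (with 1 kb shores and one
#' planted distal enhancer each) across `n_chroms` chromosomes, assigns each
#' promoter a chromatin class (`low`, `bivalent`, `active`), plants
#' bimodal-loss / bimodal-gain transition subsets among the bivalent
#' promoters, and marks a subset of bivalent genes as tissue-specific for
#' each tissue. Geometry satisfies the promoter-CGI definition by
#' construction: every CGI length lies within `cgi_length_range` (itself
#' constrained to 200-5000 bp) and every CGI contains its TSS, hence
#' overlaps the TSS +/- 1 kb window.
#'
#' All randomness derives from `config$seed`; the same configuration always
#' yields byte-identical output files via [write_genome_bundle()].
#'
#' @param config a [synthetic_config()].
#' @return an object of class `trivalent_genome`: a list with elements
#'   `chrom_sizes`, `tss` (BED6, one 1-bp record per gene), `cgis` (BED4),
#'   `enhancers` (BED4 + `gene_id`), `peaks` (planted enhancer peaks plus
#'   TSS-proximal decoys), `truth` (per-promoter class / transition /
#'   pattern / tissue-specificity labels) and `config`.
#' @export
make_genome <- function(config) {
  validate_synthetic_config(config)
  n  <- config$n_promoters
  nc <- config$n_chroms
  fl <- config$flank

  withr::with_seed(config$seed, {
    # -- class labels: deterministic counts (largest remainder), shuffled order
    cls <- rep(names(config$class_proportions),
               times = apportion(config$class_proportions, n))
    cls <- sample(cls)

    # -- transitions planted on bivalent promoters only, disjoint subsets
    biv_idx <- which(cls == "bivalent")
    n_loss <- round(config$transition_fractions[["biloss"]] * length(biv_idx))
    n_gain <- round(config$transition_fractions[["bigain"]] * length(biv_idx))
    trans <- rep("none", n)
    picked <- sample(biv_idx, n_loss + n_gain)
    trans[picked[seq_len(n_loss)]] <- "biloss"
    if (n_gain > 0L) trans[picked[n_loss + seq_len(n_gain)]] <- "bigain"

    # -- tissue-specific genes drawn from the bivalent class
    n_spec <- config$n_tissues * config$n_specific_per_tissue
    if (n_spec > length(biv_idx))
      t_stop("cannot plant %d tissue-specific genes: only %d bivalent promoters",
             n_spec, length(biv_idx))
    spec_idx <- sample(biv_idx, n_spec)
    target <- rep(NA_character_, n)
    target[spec_idx] <- rep(paste0("tissue_", seq_len(config$n_tissues)),
                            each = config$n_specific_per_tissue)

    # -- geometry
    lens <- sample(seq(config$cgi_length_range[1L], config$cgi_length_range[2L]),
                   n, replace = TRUE)
    tss_off <- vapply(lens, function(L) sample.int(L, 1L) - 1L, integer(1L))
    strand <- sample(c("+", "-"), n, replace = TRUE)

    chrom_of <- rep(seq_len(nc), each = ceiling(n / nc))[seq_len(n)]
    cgi_start <- integer(n); enh_start <- integer(n)
    req_len <- integer(nc)
    for (ch in seq_len(nc)) {
      idx <- which(chrom_of == ch)
      offs <- cumsum(c(0L, slot_width(lens[idx], fl)))[seq_along(idx)]
      cgi_start[idx] <- offs + .slot_pre + fl
      enh_start[idx] <- cgi_start[idx] + lens[idx] + fl + .slot_gap
      req_len[ch] <- if (length(idx) > 0L)
        offs[length(idx)] + slot_width(lens[idx[length(idx)]], fl) + 1000L else 0L
    }
    chrom_len <- config$chrom_length %||% max(req_len)
    if (any(req_len > chrom_len))
      t_stop("infeasible packing: %d promoters need chromosomes of at least %d bp (chrom_length = %d)",
             n, max(req_len), chrom_len)
  })

  chroms <- paste0("chr", chrom_of)
  gene_id <- sprintf("gene_%05d", seq_len(n))
  cgi_id  <- sprintf("cgi_%05d", seq_len(n))
  enh_id  <- sprintf("enh_%05d", seq_len(n))
  tss0 <- cgi_start + tss_off

  pattern_of <- function(class, trans, cond) {
    ifelse(class == "low", "flat",
      ifelse(class == "active", "typical_bimodal", "untypical_unimodal"))
  }

  genome <- list(
    chrom_sizes = data.frame(chrom = paste0("chr", seq_len(nc)),
                             length = chrom_len, stringsAsFactors = FALSE),
    tss = data.frame(chrom = chroms, start = tss0, end = tss0 + 1L,
                     name = gene_id, score = 0L, strand = strand,
                     stringsAsFactors = FALSE),
    cgis = data.frame(chrom = chroms, start = cgi_start,
                      end = cgi_start + lens, name = cgi_id,
                      stringsAsFactors = FALSE),
    enhancers = data.frame(chrom = chroms, start = enh_start,
                           end = enh_start + .enh_width, name = enh_id,
                           gene_id = gene_id, stringsAsFactors = FALSE),
    truth = data.frame(
      cgi_id = cgi_id, gene_id = gene_id, chrom = chroms,
      class = cls, transition = trans,
      pattern_cond1 = pattern_of(cls, trans, 1L),
      pattern_cond2 = pattern_of(cls, trans, 2L),
      shore_cond1 = ifelse(cls == "low", "low",
                    ifelse(trans == "bigain", "low", "high")),
      shore_cond2 = ifelse(cls == "low", "low",
                    ifelse(trans == "biloss", "low", "high")),
      tissue_specific = !is.na(target), target_tissue = target,
      stringsAsFactors = FALSE),
    config = config
  )
  # H3K4me1 peak calls: the planted enhancers plus TSS-proximal decoy peaks
  # (centred on each CGI start, hence within 5 kb of the TSS) that the
  # enhancer-definition filter must discard.
  genome$peaks <- rbind(
    data.frame(chrom = chroms, start = enh_start, end = enh_start + .enh_width,
               name = paste0("peak_", enh_id), stringsAsFactors = FALSE),
    data.frame(chrom = chroms, start = cgi_start - 250L, end = cgi_start + 250L,
               name = sprintf("peak_decoy_%05d", seq_len(n)),
               stringsAsFactors = FALSE)
  )
  genome$peaks <- genome$peaks[order(genome$peaks$chrom, genome$peaks$start), ]
  rownames(genome$peaks) <- NULL
  class(genome) <- "trivalent_genome"
  genome
}

# split n into integer counts proportional to weights (largest remainder)
apportion <- function(w, n) {
  raw <- w / sum(w) * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0L) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

#' @export
print.trivalent_genome <- function(x, ...) {
  cat(sprintf("trivalent_genome: %d promoters on %d chromosome(s) (%d bp)\n",
              nrow(x$cgis), nrow(x$chrom_sizes), x$chrom_sizes$length[1L]))
  print(table(class = x$truth$class, transition = x$truth$transition))
  invisible(x)
}

#' Write a genome bundle to plain-text files
#'
#' Emits `chrom.sizes`, `tss.bed` (BED6), `cgis.bed` (BED4),
#' `enhancers.bed`, `h3k4me1_peaks.bed` and `truth.tsv` under `dir`.
#' Deterministic: identical bundles give byte-identical files.
#'
#' @param genome a `trivalent_genome`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_genome_bundle <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_chrom_sizes(genome$chrom_sizes, file.path(dir, "chrom.sizes"))
  write_bed(genome$tss, file.path(dir, "tss.bed"), columns = 6L)
  write_bed(genome$cgis, file.path(dir, "cgis.bed"), columns = 4L)
  write_bed(genome$enhancers, file.path(dir, "enhancers.bed"), columns = 4L)
  write_bed(genome$peaks, file.path(dir, "h3k4me1_peaks.bed"), columns = 4L)
  write_tsv(genome$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
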