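#' Per-site base counts from an alignment file
#'
#' Counts the plus-strand base calls observed at a single genomic position in
#' a coordinate-sorted, indexed BAM, after the filters used for hotspot
#' editing quantification: only mapped, primary, non-duplicate,
#' non-supplementary reads with mapping quality >= `min_mapq` contribute, and
#' only base calls with base quality >= `min_baseq`; deletions and reference
#' skips spanning the position contribute nothing. These defaults mirror
#' bam-readcount run with `-q 20 -b 20` on uniquely mapped reads.
#'
#' When `dedup_overlaps = TRUE` (default) the two reads of a mate pair that
#' both cover the position are counted once per fragment, keeping the call
#' with the higher base quality; set it to `FALSE` for strict parity with
#' tools that count mates independently.
#'
#' @param bam Path to an indexed BAM file.
#' @param site A single panel row (or any list) with elements `chrom`, `pos`,
#'   `site_id`.
#' @param min_mapq Minimum mapping quality (default 20).
#' @param min_baseq Minimum base quality (default 20).
#' @param dedup_overlaps Count overlapping mate pairs once per fragment.
#' @return A one-row `data.frame`: `site_id`, `n_A`, `n_C`, `n_G`, `n_T`,
#'   `n_other`, `depth`.
#' @seealso [orient_counts()], [pileup_sample()]
#' @export
count_bases_at_site <- function(bam, site, min_mapq = 20L, min_baseq = 20L,
                                dedup_overlaps = TRUE) {
  calls <- site_base_calls(bam, site$chrom, site$pos, min_mapq, min_baseq,
                           dedup_overlaps)
  tab <- c(A = 0L, C = 0L, G = 0L, T = 0L, other = 0L)
  if (nrow(calls) > 0L) {
    b <- ifelse(calls$base %in% c("A", "C", "G", "T"), calls$base, "other")
    cnt <- table(factor(b, levels = names(tab)))
    tab <- tab + as.integer(cnt)
  }
  data.frame(site_id = site$site_id,
             n_A = tab[["A"]], n_C = tab[["C"]], n_G = tab[["G"]],
             n_T = tab[["T"]], n_other = tab[["other"]],
             depth = sum(tab))
}

## One row per counted read: qname, base call and base quality at `pos`.
## Filters and mate-overlap deduplication are applied here.
site_base_calls <- function(bam, chrom, pos, min_mapq, min_baseq,
                            dedup_overlaps) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (!chrom %in% names(hdr))
    stop("chromosome '", chrom, "' absent from the alignment header of ", bam)
  if (!has_bam_index(bam))
    stop("missing BAM index for ", bam, " (expected ", bam, ".bai)")
  which <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  param <- Rsamtools::ScanBamParam(
    which = which, flag = flag, mapqFilter = min_mapq,
    what = c("qname", "pos", "cigar", "seq", "qual"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n <- length(rec$qname)
  empty <- data.frame(qname = character(), base = character(),
                      qual = integer())
  if (n == 0L) return(empty)
  qpos <- query_position_at(rec$cigar, rec$pos, pos)
  keep <- !is.na(qpos)
  if (!any(keep)) return(empty)
  idx <- which(keep)
  base <- substring(as.character(rec$seq[idx]), qpos[idx], qpos[idx])
  qual <- vapply(seq_along(idx), function(k) {
    utf8ToInt(substring(as.character(rec$qual[idx[k]]),
                        qpos[idx[k]], qpos[idx[k]])) - 33L
  }, integer(1))
  out <- data.frame(qname = rec$qname[idx], base = base, qual = qual)
  out <- out[out$qual >= min_baseq, , drop = FALSE]
  if (dedup_overlaps && anyDuplicated(out$qname)) {
    # keep the higher-quality call of an overlapping mate pair (first on tie)
    out <- out[order(out$qname, -out$qual), , drop = FALSE]
    out <- out[!duplicated(out$qname), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

## 1-based query coordinate of genomic position `gpos` for each alignment,
## NA when a deletion/refskip spans it or the read does not reach it.
query_position_at <- function(cigar, start, gpos) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  vapply(seq_along(cigar), function(j) {
    roff <- start[j]   # next reference position to consume
    qoff <- 1L         # next query position to consume
    for (k in seq_along(ops[[j]])) {
      op <- ops[[j]][k]; len <- lens[[j]][k]
      if (op %in% c("M", "=", "X")) {
        if (gpos >= roff && gpos < roff + len)
          return(qoff + (gpos - roff))
        roff <- roff + len; qoff <- qoff + len
      } else if (op %in% c("D", "N")) {
        if (gpos >= roff && gpos < roff + len) return(NA_integer_)
        roff <- roff + len
      } else if (op %in% c("I", "S")) {
        qoff <- qoff + len
      } # H, P consume nothing
    }
    NA_integer_
  }, integer(1))
}

has_bam_index <- function(bam) {
  file.exists(paste0(bam, ".bai")) ||
    file.exists(sub("\\.bam$", ".bai", bam))
}

#' Orient plus-strand base counts into reference/edit counts
#'
#' At a plus-strand site (`ref_base_plus == "A"`) editing reads as A>G, so
#' the A count supports the unedited allele and the G count the edited one.
#' At a minus-strand site (`ref_base_plus == "T"`) editing reads as T>C on
#' the sequenced strand, so T is the reference count and C the edit count.
#' Other observed bases (sequencing errors) enter neither count.
#'
#' @param base_counts A one-row `data.frame` from [count_bases_at_site()].
#' @param site Panel row with `ref_base_plus` and `site_id`.
#' @return A one-row `data.frame`: `site_id`, `ref_count`, `edit_count`.
#' @export
orient_counts <- function(base_counts, site) {
  rb <- site$ref_base_plus
  if (identical(rb, "A")) {
    ref <- base_counts$n_A; edit <- base_counts$n_G
  } else if (identical(rb, "T")) {
    ref <- base_counts$n_T; edit <- base_counts$n_C
  } else {
    stop("corrupted panel: ref_base_plus must be 'A' or 'T', got '", rb,
         "' at site ", site$site_id)
  }
  data.frame(site_id = site$site_id, ref_count = ref, edit_count = edit)
}

#' Panel-wide edit counts for one sample
#'
#' Runs [count_bases_at_site()] and [orient_counts()] over every panel site.
#' Sites with no covering reads yield `(0, 0)` rather than being dropped, so
#' the result always has exactly one row per panel site, in panel order.
#'
#' @inheritParams count_bases_at_site
#' @param panel An `editing_panel` (see [load_panel()]).
#' @param sample_id Sample identifier attached to the result.
#' @return A `sample_site_counts` object: `data.frame` with columns
#'   `site_id`, `ref_count`, `edit_count` and attribute `sample_id`.
#' @export
pileup_sample <- function(bam, panel, sample_id = basename(bam),
                          min_mapq = 20L, min_baseq = 20L,
                          dedup_overlaps = TRUE) {
  stopifnot(inherits(panel, "editing_panel"))
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    site <- panel[i, ]
    bc <- tryCatch(
      count_bases_at_site(bam, site, min_mapq, min_baseq, dedup_overlaps),
      error = function(e) stop("site ", site$site_id, " (", site$gene, "): ",
                               conditionMessage(e), call. = FALSE))
    orient_counts(bc, site)
  })
  new_sample_site_counts(do.call(rbind, rows), sample_id)
}

new_sample_site_counts <- function(df, sample_id) {
  rownames(df) <- NULL
  structure(df, class = c("sample_site_counts", "data.frame"),
            sample_id = sample_id)
}

#' @export
print.sample_site_counts <- function(x, ...) {
  cat("site counts for sample '", attr(x, "sample_id"), "': ",
      nrow(x), " sites, total depth ",
      sum(x$ref_count + x$edit_count), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  invisible(x)
}

#' Read / write per-sample edit-count tables
#'
#' The on-disk schema is a TSV with columns `sample_id`, `site_id`,
#' `ref_count`, `edit_count`. On reading, rows are grouped by sample and
#' checked against the supplied panel: an unknown `site_id` or a negative
#' count is an error, and panel sites absent for a sample are filled with
#' `(0, 0)`.
#'
#' @param path TSV path.
#' @param panel An `editing_panel`.
#' @return `read_counts_table()`: a named list of `sample_site_counts`, one
#'   per sample in file order.
#' @export
read_counts_table <- function(path, panel) {
  stopifnot(inherits(panel, "editing_panel"))
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  required <- c("sample_id", "site_id", "ref_count", "edit_count")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L)
    stop("counts table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  unknown <- setdiff(unique(tab$site_id), panel$site_id)
  if (length(unknown) > 0L)
    stop("counts table ", path, " contains site_id(s) not in the panel: ",
         paste(unknown, collapse = ", "))
  if (any(tab$ref_count < 0) || any(tab$edit_count < 0))
    stop("counts table ", path, " contains negative counts")
  samples <- unique(tab$sample_id)
  out <- lapply(samples, function(s) {
    sub <- tab[tab$sample_id == s, , drop = FALSE]
    if (anyDuplicated(sub$site_id))
      stop("counts table ", path, ": duplicated site_id for sample ", s)
    i <- match(panel$site_id, sub$site_id)
    df <- data.frame(site_id = panel$site_id,
                     ref_count = ifelse(is.na(i), 0L, sub$ref_count[i]),
                     edit_count = ifelse(is.na(i), 0L, sub$edit_count[i]))
    new_sample_site_counts(df, s)
  })
  stats::setNames(out, samples)
}

#' @param counts A `sample_site_counts` or a list of them.
#' @rdname read_counts_table
#' @export
write_counts_table <- function(counts, path) {
  if (inherits(counts, "sample_site_counts")) counts <- list(counts)
  rows <- lapply(counts, function(x) {
    data.frame(sample_id = attr(x, "sample_id"), as.data.frame(x))
  })
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t", quote = FALSE)
  invisible(path)
}
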