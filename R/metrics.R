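#' Per-site editing rate
#'
#' The editing rate of a site is the fraction of edit-supporting reads among
#' reads supporting either allele, `edit / (edit + ref) * 100`. It is
#' undefined (`NA`) at zero coverage; zero is a meaningful editing level and
#' is never substituted for missing.
#'
#' @param counts A `data.frame` with columns `ref_count` and `edit_count`
#'   (e.g. a `sample_site_counts`); vectorized over rows.
#' @return Numeric vector of percentages in `[0, 100]`, `NA` where
#'   `ref_count + edit_count == 0`.
#' @export
site_rate <- function(counts) {
  tot <- counts$ref_count + counts$edit_count
  ifelse(tot > 0, 100 * counts$edit_count / tot, NA_real_)
}

#' Coverage-weighted editing index
#'
#' The weighted index pools reads over all (non-excluded) panel sites before
#' taking the ratio:
#' \deqn{100 \times \sum_i e_i \,/\, \sum_i (e_i + r_i)}
#' where \eqn{e_i} and \eqn{r_i} are the edit- and reference-supporting read
#' counts of site \eqn{i}. Sites with deeper coverage therefore weigh more.
#' No per-site depth filter is applied by default (the depth filter belongs
#' to the mean index); pass `min_total` to restrict to sites with
#' `ref + edit > min_total` reads.
#'
#' @param counts A `sample_site_counts` (or any `data.frame` with `site_id`,
#'   `ref_count`, `edit_count`).
#' @param excluded Character vector of `site_id`s to drop (germline
#'   exclusions).
#' @param min_total Optional strict per-site depth threshold; `NULL` (the
#'   default) disables it.
#' @return List with `index` (percent, `NA` when the pooled denominator is
#'   zero) and `n_sites_used` (sites contributing at least one read).
#' @export
weighted_editing <- function(counts, excluded = character(), min_total = NULL) {
  use <- !(counts$site_id %in% excluded)
  if (!is.null(min_total))
    use <- use & (counts$ref_count + counts$edit_count > min_total)
  e <- counts$edit_count[use]; r <- counts$ref_count[use]
  denom <- sum(e) + sum(r)
  list(index = if (denom > 0) 100 * sum(e) / denom else NA_real_,
       n_sites_used = sum((e + r) > 0))
}

#' Mean editing index
#'
#' The mean index averages per-site editing rates with equal weight over the
#' (non-excluded) sites whose coverage strictly exceeds `min_total` reads of
#' either allele (default: more than five), reducing the influence of
#' expression level on the index:
#' \deqn{\frac{100}{n} \sum_i \frac{e_i}{e_i + r_i}}
#'
#' @inheritParams weighted_editing
#' @param min_total Strict depth threshold: a site contributes only when
#'   `ref + edit > min_total` (default `5L`).
#' @return List with `index` (percent, `NA` when no site passes the filter)
#'   and `n_sites_used`.
#' @export
mean_editing <- function(counts, excluded = character(), min_total = 5L) {
  use <- !(counts$site_id %in% excluded) &
    (counts$ref_count + counts$edit_count > min_total)
  rates <- site_rate(counts[use, , drop = FALSE])
  list(index = if (length(rates) > 0) mean(rates) else NA_real_,
       n_sites_used = length(rates))
}

#' Germline exclusion of panel sites from a matched-DNA VCF
#'
#' A DNA A/G (or T/C) polymorphism at a panel site is indistinguishable from
#' editing in RNA reads, so such sites are excluded from both indices for
#' the affected sample. Any passing single-nucleotide variant overlapping a
#' panel position whose unordered ref/alt pair is `{A,G}` or `{T,C}` (either
#' orientation) triggers exclusion; other substitutions (e.g. A>C) never do.
#'
#' @param vcf_path Path to a VCF (v4.x) for the sample (or cohort-level
#'   exclusion list).
#' @param panel An `editing_panel`.
#' @param passing_only Keep only records with `FILTER` of `PASS` or `.`
#'   (default `TRUE`).
#' @return Character vector of excluded `site_id`s (possibly empty).
#' @export
germline_exclusions <- function(vcf_path, panel, passing_only = TRUE) {
  stopifnot(inherits(panel, "editing_panel"))
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "hg38")
  if (length(vcf) == 0L) return(character())
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- normalize_chrom(as.character(GenomicRanges::seqnames(rr)), "chr")
  if (!any(chrom %in% unique(panel$chrom)))
    stop("contig-name mismatch: no VCF contig (after 'chr' normalization) ",
         "matches a panel chromosome; check genome builds / naming")
  filt <- as.character(rr$FILTER)
  keep <- if (passing_only) filt %in% c("PASS", ".") else rep(TRUE, length(rr))
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  pos <- GenomicRanges::start(rr)
  hits <- vapply(seq_along(rr), function(i) {
    if (!keep[i] || nchar(ref[i]) != 1L) return(NA_character_)
    sid <- paste0(chrom[i], ":", pos[i])
    if (!sid %in% panel$site_id) return(NA_character_)
    alts <- as.character(altl[[i]])
    alts <- alts[nchar(alts) == 1L]
    pairs <- vapply(alts, function(a)
      paste(sort(c(ref[i], a)), collapse = ""), character(1))
    if (any(pairs %in% c("AG", "CT"))) sid else NA_character_
  }, character(1))
  unique(hits[!is.na(hits)])
}

#' Score one sample: per-site rates plus both editing indices
#'
#' Composes germline exclusion, the coverage-weighted index and the mean
#' index into one per-sample record.
#'
#' @inheritParams weighted_editing
#' @param panel An `editing_panel`; `counts` must be keyed by its sites.
#' @param vcf_path Optional matched-DNA VCF used for germline exclusion.
#' @param excluded Additional `site_id`s to exclude (e.g. a cohort-level
#'   exclusion list); merged with VCF-derived exclusions.
#' @param mean_min_total Strict depth filter of the mean index (default 5).
#' @param weighted_min_total Optional depth filter of the weighted index
#'   (default `NULL`, i.e. none).
#' @return A `sample_editing_result`: list with `sample_id`, `sites` (per-site
#'   table with `rate` and `excluded` flags), `weighted_index`, `mean_index`,
#'   `n_sites_used_weighted`, `n_sites_used_mean`, `excluded_sites`.
#' @export
score_sample <- function(counts, panel, vcf_path = NULL,
                         excluded = character(), mean_min_total = 5L,
                         weighted_min_total = NULL) {
  stopifnot(inherits(panel, "editing_panel"))
  if (!setequal(counts$site_id, panel$site_id))
    stop("counts are not keyed by the panel's site_ids")
  counts <- counts[match(panel$site_id, counts$site_id), , drop = FALSE]
  if (!is.null(vcf_path))
    excluded <- union(excluded, germline_exclusions(vcf_path, panel))
  excluded <- intersect(excluded, panel$site_id)
  w <- weighted_editing(counts, excluded, weighted_min_total)
  m <- mean_editing(counts, excluded, mean_min_total)
  sites <- data.frame(site_id = counts$site_id,
                      gene = panel$gene,
                      ref_count = counts$ref_count,
                      edit_count = counts$edit_count,
                      rate = site_rate(counts),
                      excluded = counts$site_id %in% excluded)
  structure(list(sample_id = attr(counts, "sample_id"),
                 sites = sites,
                 weighted_index = w$index,
                 mean_index = m$index,
                 n_sites_used_weighted = w$n_sites_used,
                 n_sites_used_mean = m$n_sites_used,
                 excluded_sites = excluded),
            class = "sample_editing_result")
}

#' @export
print.sample_editing_result <- function(x, ...) {
  cat(sprintf(
    "sample '%s': weighted index %s%%, mean index %s%% (%d / %d sites used, %d excluded)\n",
    x$sample_id, format(round(x$weighted_index, 3)),
    format(round(x$mean_index, 3)),
    x$n_sites_used_weighted, x$n_sites_used_mean, length(x$excluded_sites)))
  invisible(x)
}

#' Score a batch of samples and tabulate the results
#'
#' @param counts_list A list of `sample_site_counts` (e.g. from
#'   [read_counts_table()] or repeated [pileup_sample()] calls).
#' @param vcf_paths Optional named character vector / list mapping sample id
#'   to its matched-DNA VCF.
#' @inheritParams score_sample
#' @return List with `summary` (one row per sample: `sample_id`,
#'   `weighted_index`, `mean_index`, `n_sites_used_weighted`,
#'   `n_sites_used_mean`, `excluded_sites` comma-joined) and `sites`
#'   (long-format per-site table).
#' @export
score_samples <- function(counts_list, panel, vcf_paths = NULL,
                          excluded = character(), mean_min_total = 5L,
                          weighted_min_total = NULL) {
  results <- lapply(counts_list, function(cts) {
    sid <- attr(cts, "sample_id")
    vcf <- if (!is.null(vcf_paths) && sid %in% names(vcf_paths))
      vcf_paths[[sid]] else NULL
    score_sample(cts, panel, vcf_path = vcf, excluded = excluded,
                 mean_min_total = mean_min_total,
                 weighted_min_total = weighted_min_total)
  })
  summary <- do.call(rbind, lapply(results, function(r) {
    data.frame(sample_id = r$sample_id,
               weighted_index = r$weighted_index,
               mean_index = r$mean_index,
               n_sites_used_weighted = r$n_sites_used_weighted,
               n_sites_used_mean = r$n_sites_used_mean,
               excluded_sites = paste(r$excluded_sites, collapse = ","))
  }))
  sites <- do.call(rbind, lapply(results, function(r)
    data.frame(sample_id = r$sample_id, r$sites)))
  rownames(summary) <- rownames(sites) <- NULL
  list(summary = summary, sites = sites, results = results)
}
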