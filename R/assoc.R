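#' Spearman correlation of a per-sample score against a feature matrix
#'
#' Correlates one score vector (e.g. the weighted editing index) with every
#' row of a feature matrix (gene expression, pathway activation, instability
#' metrics), using only samples where both values are defined. Being
#' rank-based, the result is invariant under strictly monotone transforms of
#' either side. Features constant across the usable samples have undefined
#' correlation: they are reported with `NA` and excluded from testing.
#'
#' @param score Named numeric vector, sample id -> score.
#' @param features Numeric matrix, features x samples (colnames = sample
#'   ids). A vector is treated as a single feature.
#' @param min_n Minimum overlapping samples per feature (default 3).
#' @return `data.frame` with `feature_id`, `rho`, `p` (two-sided), `n`.
#' @export
correlate_profile <- function(score, features, min_n = 3L) {
  if (is.vector(features))
    features <- matrix(features, nrow = 1,
                       dimnames = list("feature", names(features)))
  common <- intersect(names(score), colnames(features))
  if (length(common) == 0L) stop("no overlapping samples between score and features")
  s <- score[common]
  out <- do.call(rbind, lapply(rownames(features), function(f) {
    x <- features[f, common]
    ok <- !is.na(x) & !is.na(s)
    n <- sum(ok)
    if (n < min_n || length(unique(x[ok])) < 2L || length(unique(s[ok])) < 2L)
      return(data.frame(feature_id = f, rho = NA_real_, p = NA_real_, n = n))
    ct <- suppressWarnings(
      stats::cor.test(s[ok], x[ok], method = "spearman", exact = FALSE))
    data.frame(feature_id = f, rho = unname(ct$estimate), p = ct$p.value,
               n = n)
  }))
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values, order-preserving with the input vector.
#' `NA`s pass through untouched.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

#' Split association records into significant positive / negative sets
#'
#' A feature is called positive when `rho > rho_threshold` and
#' `p_adj < p_adj_threshold`; negative symmetrically; otherwise `none`.
#' `rho_threshold = 0` reproduces a pure-FDR screen; `0.2` adds the absolute
#' correlation cutoff used when screening instability features.
#'
#' @param records Output of [correlate_profile()]; a `p_adj` column is added
#'   via [bh_adjust()] if absent.
#' @param p_adj_threshold Default 0.05 (strict `<`).
#' @param rho_threshold Default 0 (strict `>` on `|rho|`).
#' @param label Group label (e.g. "COAD/TCGA") carried in the result.
#' @return A `significant_sets` list: `label`, `positive`, `negative`
#'   (feature-id character vectors), `universe` (all tested feature ids),
#'   `records` (with `p_adj` and `direction` columns).
#' @export
significant_sets <- function(records, p_adj_threshold = 0.05,
                             rho_threshold = 0, label = NA_character_) {
  if (!"p_adj" %in% names(records)) records$p_adj <- bh_adjust(records$p)
  sig <- !is.na(records$p_adj) & records$p_adj < p_adj_threshold &
    !is.na(records$rho) & abs(records$rho) > rho_threshold
  records$direction <- ifelse(sig & records$rho > 0, "positive",
                              ifelse(sig & records$rho < 0, "negative",
                                     "none"))
  structure(list(label = label,
                 positive = records$feature_id[records$direction == "positive"],
                 negative = records$feature_id[records$direction == "negative"],
                 universe = records$feature_id[!is.na(records$rho)],
                 records = records),
            class = "significant_sets")
}

#' Intersect significant sets across groups
#'
#' The "double intersection": features significant in the same direction in
#' every group (e.g. 2 cancer types x 2 datasets = 4 groups).
#'
#' @param sets List of `significant_sets` (length >= 2).
#' @return List with `common_positive` and `common_negative` feature-id
#'   vectors.
#' @export
double_intersection <- function(sets) {
  stopifnot(length(sets) >= 2L)
  list(common_positive = Reduce(intersect, lapply(sets, `[[`, "positive")),
       common_negative = Reduce(intersect, lapply(sets, `[[`, "negative")))
}

#' Permutation test of an intersection size
#'
#' Null model: each group's significant set is redrawn uniformly at random
#' from the universe at its observed size; the intersection over groups is
#' recomputed; the empirical p-value is
#' `(1 + #permutations with intersection >= observed) / (B + 1)`.
#'
#' @param group_sets List of feature-id vectors (one per group).
#' @param universe Feature-id vector to resample from; must contain every
#'   set. The choice of universe (all genes vs tested genes) is deliberately
#'   an explicit parameter.
#' @param B Number of permutations (default 999).
#' @param seed Integer seed; the draw is reproducible for a fixed seed.
#' @return List: `observed` (intersection size), `p` (empirical p-value),
#'   `B`, `perm_sizes` (integer vector of permuted intersection sizes).
#' @export
permutation_intersection_test <- function(group_sets, universe, B = 999L,
                                          seed = 1L) {
  stopifnot(B >= 1L)
  sizes <- lengths(group_sets)
  if (any(sizes > length(universe)))
    stop("a group's set is larger than the universe")
  for (g in group_sets)
    if (length(setdiff(g, universe)) > 0L)
      stop("a group's set contains features outside the universe")
  observed <- length(Reduce(intersect, group_sets))
  nu <- length(universe)
  k <- length(group_sets)
  perm_sizes <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      hits <- integer(nu)
      for (j in seq_len(k)) {
        idx <- sample.int(nu, sizes[j])
        hits[idx] <- hits[idx] + 1L
      }
      sum(hits == k)
    }, integer(1))
  })
  list(observed = observed,
       p = (1 + sum(perm_sizes >= observed)) / (B + 1),
       B = B, perm_sizes = perm_sizes)
}

#' Average correlations on the Fisher z scale
#'
#' Correlations are mapped through `atanh`, averaged, and mapped back with
#' `tanh` — the standard way to average dependent correlation estimates
#' (e.g. the per-gene correlations inside one pathway node). Values at
#' exactly +/-1 are clamped to 1 - 1e-12 with a warning.
#'
#' @param rhos Numeric vector of correlations in `[-1, 1]`.
#' @return The back-transformed mean correlation.
#' @export
fisher_z_mean <- function(rhos) {
  rhos <- rhos[!is.na(rhos)]
  if (length(rhos) == 0L) return(NA_real_)
  if (any(abs(rhos) > 1)) stop("correlations must lie in [-1, 1]")
  if (any(abs(rhos) == 1)) {
    warning("correlation(s) at +/-1 clamped for the Fisher z transform")
    rhos <- sign(rhos) * pmin(abs(rhos), 1 - 1e-12)
  }
  tanh(mean(atanh(rhos)))
}

#' Mann-Whitney comparisons of a score across groups
#'
#' Runs a two-sided Mann-Whitney (Wilcoxon rank-sum) test with tie
#' correction for every pair of group labels and BH-adjusts the battery.
#'
#' @param values Named numeric vector, sample id -> value.
#' @param labels Named character/factor vector, sample id -> group.
#' @return `data.frame`: `group1`, `group2`, `n1`, `n2`, `U` (statistic of
#'   `group1`), `p`, `p_adj`.
#' @export
compare_groups <- function(values, labels) {
  common <- intersect(names(values), names(labels))
  v <- values[common]; g <- as.character(labels[common])
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]; g <- g[ok]
  lv <- sort(unique(g))
  if (length(lv) < 2L) stop("need at least two groups")
  pairs <- utils::combn(lv, 2L, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    x <- v[g == pr[1L]]; y <- v[g == pr[2L]]
    if (length(x) == 0L || length(y) == 0L) stop("empty group: ",
                                                 pr[which(c(length(x), length(y)) == 0L)[1L]])
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                              exact = FALSE, correct = TRUE))
    data.frame(group1 = pr[1L], group2 = pr[2L],
               n1 = length(x), n2 = length(y),
               U = unname(wt$statistic), p = wt$p.value)
  }))
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
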