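#' Case-to-normal expression ratios
#'
#' Each gene's expression in a sample is normalized by the geometric mean of
#' that gene across the samples of a comparison group (typically: same tissue
#' status within the same dataset). A pseudocount is added before the ratio
#' so that zero expression stays finite:
#' \deqn{CNR(g, s) = \frac{x_{gs} + c}{\left(\prod_{t \in G}(x_{gt} + c)\right)^{1/|G|}}}
#'
#' @param expr Numeric matrix, genes x samples (rownames = gene symbols).
#' @param group_samples Character vector of sample (column) names forming
#'   the normalization group; the geometric mean is taken over these.
#' @param samples Columns for which CNRs are returned (default: the group
#'   itself).
#' @param pseudocount Added to every value before the ratio (default 1).
#' @return Matrix of strictly positive CNRs, genes x `samples`.
#' @export
compute_cnr <- function(expr, group_samples, samples = group_samples,
                        pseudocount = 1) {
  stopifnot(is.matrix(expr))
  if (length(group_samples) == 0L) stop("empty normalization group")
  missing <- setdiff(c(group_samples, samples), colnames(expr))
  if (length(missing) > 0L)
    stop("sample(s) not in the expression matrix: ",
         paste(missing, collapse = ", "))
  if (any(expr[, group_samples] + pseudocount <= 0))
    stop("expression + pseudocount must be positive for the geometric mean")
  # geometric mean via mean of logs, numerically safe for long groups
  gm <- exp(rowMeans(log(expr[, group_samples, drop = FALSE] + pseudocount)))
  sweep(expr[, samples, drop = FALSE] + pseudocount, 1L, gm, "/")
}

#' Pathway activation level of one sample
#'
#' The activation level of pathway \eqn{p} aggregates the log case-to-normal
#' ratios of its member genes, signed by each gene's activator/repressor
#' role \eqn{ARR_{n,p} \in \{-1, 0, +1\}}:
#' \deqn{PAL_p = 100 \times \frac{\sum_n ARR_{n,p}\,\log_{10} CNR_n}{\sum_n |ARR_{n,p}|}}
#' Genes absent from the expression data are dropped from both sums;
#' ambiguous-role genes (`ARR = 0`) contribute to neither, which is the
#' literal reading of the denominator.
#'
#' @param cnr_sample Named numeric vector of CNRs (names = gene symbols).
#' @param pathway A `pathway` object (see [load_pathway_db()]) or a named
#'   numeric vector of roles in `{-1, 0, 1}`.
#' @param log_base Base of the logarithm (default 10; any base only rescales
#'   all PALs uniformly).
#' @return List with `pathway_id`, `pal` (`NA` with a diagnostic attribute
#'   when no nonzero-role gene is measured) and `n_genes_used`.
#' @export
pal_score <- function(cnr_sample, pathway, log_base = 10) {
  arr <- if (inherits(pathway, "pathway")) pathway$arr else pathway
  pid <- if (inherits(pathway, "pathway")) pathway$pathway_id else NA_character_
  stopifnot(all(arr %in% c(-1, 0, 1)))
  present <- intersect(names(arr), names(cnr_sample))
  a <- arr[present]
  denom <- sum(abs(a))
  if (denom == 0)
    return(structure(list(pathway_id = pid, pal = NA_real_, n_genes_used = 0L),
                     reason = "no measured gene with nonzero role"))
  num <- sum(a * log(cnr_sample[present], base = log_base))
  list(pathway_id = pid, pal = 100 * num / denom,
       n_genes_used = sum(a != 0))
}

#' Load a pathway database with activator/repressor roles
#'
#' The native format is a TSV with columns `pathway_id`, `gene`,
#' `arr` (role, one of -1, 0, 1). A GMT file plus a parallel role TSV
#' (`pathway_id`, `gene`, `arr`) is also accepted; genes present in the GMT
#' but missing from the role table default to role +1.
#'
#' @param path TSV (or GMT) path.
#' @param roles_path Optional role table when `path` is a GMT file.
#' @return A list of `pathway` objects (`pathway_id`, `arr` = named numeric
#'   vector of roles).
#' @export
load_pathway_db <- function(path, roles_path = NULL) {
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    roles <- if (!is.null(roles_path))
      data.table::fread(roles_path, sep = "\t", header = TRUE,
                        data.table = FALSE)
    else NULL
    db <- lapply(fields, function(f) {
      genes <- f[-(1:2)]
      arr <- rep(1, length(genes)); names(arr) <- genes
      if (!is.null(roles)) {
        sub <- roles[roles$pathway_id == f[1L], , drop = FALSE]
        hit <- match(genes, sub$gene)
        arr[!is.na(hit)] <- sub$arr[hit[!is.na(hit)]]
      }
      new_pathway(f[1L], arr)
    })
    return(db)
  }
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  required <- c("pathway_id", "gene", "arr")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L)
    stop("pathway DB ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  lapply(split(tab, tab$pathway_id), function(sub)
    new_pathway(sub$pathway_id[1L],
                stats::setNames(as.numeric(sub$arr), sub$gene)))
}

new_pathway <- function(pathway_id, arr) {
  if (length(arr) == 0L) stop("pathway ", pathway_id, " has no member genes")
  if (!all(arr %in% c(-1, 0, 1)))
    stop("pathway ", pathway_id, ": roles must be -1, 0 or 1")
  if (anyDuplicated(names(arr)))
    stop("pathway ", pathway_id, ": duplicated member gene")
  structure(list(pathway_id = pathway_id, arr = arr), class = "pathway")
}

#' Keep pathways with more than `min_genes` member gene products
#'
#' @param db List of `pathway` objects.
#' @param min_genes Strict lower bound on pathway size (default 10: a
#'   pathway with exactly 10 genes is dropped).
#' @return Filtered list.
#' @export
filter_pathways <- function(db, min_genes = 10L) {
  Filter(function(p) length(p$arr) > min_genes, db)
}

#' Pathway activation levels for a whole expression matrix
#'
#' Computes CNRs per normalization group (each sample against the geometric
#' mean of its own group, e.g. tumor vs normal within a dataset) and then a
#' PAL for every retained pathway in every sample.
#'
#' @inheritParams compute_cnr
#' @param db List of `pathway` objects; passed through [filter_pathways()]
#'   unless `min_genes` is `NULL`.
#' @param groups Named character/factor vector mapping sample id to its
#'   normalization group; samples sharing a level form one group. Default:
#'   all columns in one group.
#' @param min_genes See [filter_pathways()]; `NULL` disables the filter.
#' @param log_base See [pal_score()].
#' @return Long-format `data.frame`: `sample_id`, `pathway_id`, `pal`,
#'   `n_genes_used`.
#' @export
pal_matrix <- function(expr, db, groups = NULL, pseudocount = 1,
                       min_genes = 10L, log_base = 10) {
  if (is.null(groups))
    groups <- stats::setNames(rep("all", ncol(expr)), colnames(expr))
  groups <- groups[colnames(expr)]
  if (anyNA(groups)) stop("every expression column needs a group label")
  if (!is.null(min_genes)) db <- filter_pathways(db, min_genes)
  if (length(db) == 0L)
    return(data.frame(sample_id = character(), pathway_id = character(),
                      pal = numeric(), n_genes_used = integer()))
  cnr <- matrix(NA_real_, nrow(expr), ncol(expr),
                dimnames = dimnames(expr))
  for (g in unique(groups)) {
    cols <- names(groups)[groups == g]
    cnr[, cols] <- compute_cnr(expr, cols, pseudocount = pseudocount)
  }
  rows <- lapply(colnames(expr), function(s) {
    v <- cnr[, s]
    do.call(rbind, lapply(db, function(p) {
      r <- pal_score(v, p, log_base = log_base)
      data.frame(sample_id = s, pathway_id = r$pathway_id, pal = r$pal,
                 n_genes_used = r$n_genes_used)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
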