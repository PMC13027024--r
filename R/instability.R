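## Gene sets used by the expression-based instability scores.
MMR_GENES <- c("MLH1", "MSH2", "MSH6", "PMS2")
HYPERMUTATOR_GENES <- c("EPM2AIP1", "TTC30A", "SMAP1", "RNLS", "WNT11",
                        "SFXN1", "SREBF1", "TYMS", "EIF5AL1", "WDR76")
INSERTIONAL_FEATURES <- c("L1Hs", "L1PA2", "TERT", "APOBEC3B")

extract_genes <- function(expr_sample, genes, what, strict) {
  missing <- setdiff(genes, names(expr_sample))
  if (length(missing) > 0L) {
    if (strict)
      stop(what, ": gene(s) missing from the expression data: ",
           paste(missing, collapse = ", "))
    return(NULL)
  }
  expr_sample[genes]
}

#' Mismatch-repair deficiency score
#'
#' The negative sum of log-transformed expression of the core MMR genes
#' MLH1, MSH2, MSH6 and PMS2: low MMR expression (a deficient mismatch
#' repair system) gives a high score.
#'
#' @param expr_sample Named numeric vector of expression values for one
#'   sample (names = gene symbols).
#' @param pseudocount Added before the log (default 1).
#' @param log_base Default 2.
#' @param strict Error on a missing gene (default `TRUE`); otherwise return
#'   `NA` so the sample's MSI call becomes undetermined.
#' @return Numeric score (or `NA` under `strict = FALSE` with missing genes).
#' @export
mmr_deficiency_score <- function(expr_sample, pseudocount = 1, log_base = 2,
                                 strict = TRUE) {
  x <- extract_genes(expr_sample, MMR_GENES, "mmr_deficiency_score", strict)
  if (is.null(x)) return(NA_real_)
  -sum(log(x + pseudocount, base = log_base))
}

#' Hypermutator transcriptional-signature score
#'
#' A weighted linear combination of log-transformed expression over a
#' 10-gene hypermutator signature (EPM2AIP1, TTC30A, SMAP1, RNLS, WNT11,
#' SFXN1, SREBF1, TYMS, EIF5AL1, WDR76). The gene-specific coefficients are
#' not distributed with this package: they are a mandatory input (see
#' `inst/extdata/msi_coefficients_synthetic_example.tsv` for the file
#' format, whose values are placeholders for testing only).
#'
#' @inheritParams mmr_deficiency_score
#' @param coefficients Named numeric vector (or TSV path with columns
#'   `gene`, `weight`) giving the signature weights.
#' @return Numeric score.
#' @export
hypermutator_score <- function(expr_sample, coefficients, pseudocount = 1,
                               log_base = 2, strict = TRUE) {
  if (is.character(coefficients) && length(coefficients) == 1L) {
    tab <- data.table::fread(coefficients, sep = "\t", header = TRUE,
                             data.table = FALSE)
    if (!all(c("gene", "weight") %in% names(tab)))
      stop("coefficient file needs columns 'gene' and 'weight'")
    coefficients <- stats::setNames(tab$weight, tab$gene)
  }
  missing <- setdiff(HYPERMUTATOR_GENES, names(coefficients))
  if (length(missing) > 0L)
    stop("hypermutator_score: missing coefficient(s) for: ",
         paste(missing, collapse = ", "))
  x <- extract_genes(expr_sample, HYPERMUTATOR_GENES, "hypermutator_score",
                     strict)
  if (is.null(x)) return(NA_real_)
  sum(coefficients[HYPERMUTATOR_GENES] * log(x + pseudocount, base = log_base))
}

#' Linear MSI classification from the two composite scores
#'
#' Classifies a sample as microsatellite instable (MSI) when it falls
#' strictly on the positive side of a line in the
#' (MMR-deficiency, hypermutator) score plane:
#' `a * mmr_score + b * hypermutator_score + c > 0`. Points exactly on the
#' line are called MSS (documented tie rule). The boundary parameters are a
#' mandatory configuration input; no default is shipped.
#'
#' @param mmr_score,hypermutator_score Numeric (vectorized).
#' @param boundary List or named vector with elements `a`, `b`, `c`, or a
#'   JSON file path with those keys.
#' @return Character vector: `"MSI"`, `"MSS"`, or `"undetermined"` when a
#'   score is `NA`.
#' @export
classify_msi <- function(mmr_score, hypermutator_score, boundary) {
  if (is.character(boundary) && length(boundary) == 1L)
    boundary <- jsonlite::read_json(boundary, simplifyVector = TRUE)
  if (is.null(boundary) || !all(c("a", "b", "c") %in% names(boundary)))
    stop("MSI classification requires boundary parameters a, b, c ",
         "(no defaults are shipped)")
  boundary <- lapply(boundary[c("a", "b", "c")], as.numeric)
  lin <- boundary$a * mmr_score + boundary$b * hypermutator_score + boundary$c
  ifelse(is.na(lin), "undetermined", ifelse(lin > 0, "MSI", "MSS"))
}

#' Retroelement insertional-signature score
#'
#' The sum of normalized, log-transformed expression of the L1Hs and L1PA2
#' transposable-element families, TERT and APOBEC3B — a proxy for
#' retroelement insertional activity. TE family expression rows come from
#' upstream TE quantification and are supplied as rows of the expression
#' matrix.
#'
#' @inheritParams mmr_deficiency_score
#' @return Numeric score.
#' @export
insertional_signature <- function(expr_sample, pseudocount = 1, log_base = 2,
                                  strict = TRUE) {
  x <- extract_genes(expr_sample, INSERTIONAL_FEATURES,
                     "insertional_signature", strict)
  if (is.null(x)) return(NA_real_)
  sum(log(x + pseudocount, base = log_base))
}

#' Tumor mutational burden
#'
#' Somatic coding mutations (SNVs and indels) per megabase of coding exome.
#' The exome size is a mandatory configuration value.
#'
#' @param n_variants Non-negative count of somatic coding variants, or a
#'   `data.frame` of variant records with a logical/0-1 `coding` column
#'   (rows with `coding` true are counted).
#' @param exome_mb Size of the coding exome in megabases (> 0).
#' @return List with `mutations`, `exome_mb` and `tmb` (mutations/Mb).
#' @export
tmb <- function(n_variants, exome_mb) {
  if (is.data.frame(n_variants)) {
    if (!"coding" %in% names(n_variants))
      stop("variant table needs a 'coding' column")
    n_variants <- sum(as.logical(n_variants$coding))
  }
  if (length(exome_mb) != 1L || is.na(exome_mb) || exome_mb <= 0)
    stop("exome_mb must be a positive number (mutations per megabase)")
  if (n_variants < 0) stop("variant count must be non-negative")
  list(mutations = as.integer(n_variants), exome_mb = exome_mb,
       tmb = n_variants / exome_mb)
}

#' Per-sample instability score table
#'
#' @param expr Genes x samples matrix (must contain the MMR genes, the
#'   hypermutator signature genes and the four insertional-signature
#'   features for the respective scores).
#' @param coefficients See [hypermutator_score()].
#' @param boundary See [classify_msi()]; `NULL` leaves `msi_call` out.
#' @param pseudocount,log_base Shared log-transform settings (defaults 1, 2).
#' @return `data.frame` with one row per sample: `sample_id`, `mmr_score`,
#'   `hypermutator_score`, `insertional_signature` and (with a boundary)
#'   `msi_call`.
#' @export
instability_scores <- function(expr, coefficients, boundary = NULL,
                               pseudocount = 1, log_base = 2) {
  out <- do.call(rbind, lapply(colnames(expr), function(s) {
    v <- expr[, s]
    data.frame(
      sample_id = s,
      mmr_score = mmr_deficiency_score(v, pseudocount, log_base),
      hypermutator_score = hypermutator_score(v, coefficients, pseudocount,
                                              log_base),
      insertional_signature = insertional_signature(v, pseudocount, log_base))
  }))
  if (!is.null(boundary))
    out$msi_call <- classify_msi(out$mmr_score, out$hypermutator_score,
                                 boundary)
  rownames(out) <- NULL
  out
}
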