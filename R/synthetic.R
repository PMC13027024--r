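#' Simulation configuration
#'
#' One configuration object drives every synthetic generator, and a fixed
#' seed makes all of them byte-deterministic. Defaults describe a small but
#' realistic cohort: per-site true editing rates of 40% at the two
#' strongly edited hotspot genes (NEIL1, IGFBP7) and 3% elsewhere (most
#' panel positions sit below 5% in real tissue), negative-binomial read
#' depth (uneven coverage), and an expression matrix with monotone planted
#' associations to the per-sample editing score on top of log-normal noise.
#'
#' @param seed Integer seed.
#' @param n_samples Number of samples (default 20).
#' @param panel An `editing_panel` (default [default_panel()]).
#' @param rates Named per-site true editing rates in `[0,1]` (names =
#'   `site_id`); default as described above.
#' @param depth_mean,depth_dispersion Negative-binomial depth model (mean
#'   50, size 5); `depth_dispersion = Inf` gives fixed depth.
#' @param n_genes Number of expression features beside the named score
#'   genes (default 300).
#' @param n_planted_positive,n_planted_negative Features generated with
#'   monotone (increasing / decreasing) dependence on the editing score
#'   (defaults 20 and 20).
#' @param effect_size Slope of the planted log2-expression dependence per
#'   SD of editing score (default 2).
#' @param noise_sd SD of the log2-scale noise (default 0.5).
#' @param germline_fraction Fraction of panel sites carrying a planted
#'   germline A/G (T/C) variant (default 0).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_samples = 20L, panel = default_panel(),
                       rates = NULL, depth_mean = 50, depth_dispersion = 5,
                       n_genes = 300L, n_planted_positive = 20L,
                       n_planted_negative = 20L, effect_size = 2,
                       noise_sd = 0.5, germline_fraction = 0) {
  if (is.null(rates)) {
    rates <- ifelse(panel$gene %in% c("NEIL1", "IGFBP7"), 0.40, 0.03)
    names(rates) <- panel$site_id
  }
  stopifnot(all(rates >= 0 & rates <= 1),
            setequal(names(rates), panel$site_id),
            depth_mean >= 0, n_samples >= 1,
            germline_fraction >= 0, germline_fraction <= 1)
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 panel = panel, rates = rates[panel$site_id],
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 n_genes = as.integer(n_genes),
                 n_planted_positive = as.integer(n_planted_positive),
                 n_planted_negative = as.integer(n_planted_negative),
                 effect_size = effect_size, noise_sd = noise_sd,
                 germline_fraction = germline_fraction),
            class = "sim_config")
}

sim_depths <- function(n, config) {
  if (is.infinite(config$depth_dispersion))
    rep(round(config$depth_mean), n)
  else
    stats::rnbinom(n, size = config$depth_dispersion, mu = config$depth_mean)
}

#' Simulate per-site edit counts with known truth
#'
#' For every sample and panel site, draws a read depth from the configured
#' depth model and an edit count from `Binomial(depth, rate)`.
#'
#' @param config A [sim_config()].
#' @return List: `counts` (named list of `sample_site_counts`), `truth`
#'   (long `data.frame`: `sample_id`, `site_id`, `rate`, `depth`,
#'   `edit_count`).
#' @export
simulate_site_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- config$panel
  withr::with_seed(config$seed, {
    samples <- sprintf("sim%03d", seq_len(config$n_samples))
    counts <- list(); truth <- list()
    for (s in samples) {
      depth <- sim_depths(nrow(panel), config)
      edit <- stats::rbinom(nrow(panel), depth, config$rates)
      df <- data.frame(site_id = panel$site_id,
                       ref_count = depth - edit, edit_count = edit)
      counts[[s]] <- new_sample_site_counts(df, s)
      truth[[s]] <- data.frame(sample_id = s, site_id = panel$site_id,
                               rate = unname(config$rates), depth = depth,
                               edit_count = edit)
    }
    list(counts = counts, truth = do.call(rbind, truth))
  })
}

#' Simulate an expression matrix with planted monotone associations
#'
#' Planted features follow
#' `log2(expr) = baseline + direction * effect_size * z(score) + noise`,
#' null features are independent log-normal noise. The matrix always
#' includes rows for the MMR genes, the 10-gene hypermutator signature and
#' the four insertional-signature features (as null features) so the
#' instability scores are computable on simulated data.
#'
#' @param config A [sim_config()].
#' @param editing_scores Named numeric vector of per-sample scores (names
#'   become the matrix columns).
#' @return List: `expr` (features x samples matrix, linear scale), `truth`
#'   (`data.frame`: `feature_id`, `planted` in
#'   `{"positive","negative","null"}`).
#' @export
simulate_expression <- function(config, editing_scores) {
  stopifnot(inherits(config, "sim_config"))
  samples <- names(editing_scores)
  stopifnot(!is.null(samples), all(!is.na(editing_scores)))
  z <- as.numeric(scale(editing_scores))
  if (any(is.na(z))) z <- rep(0, length(editing_scores))  # constant score
  npos <- config$n_planted_positive; nneg <- config$n_planted_negative
  nnull <- max(config$n_genes - npos - nneg, 0L)
  special <- c(MMR_GENES, HYPERMUTATOR_GENES, INSERTIONAL_FEATURES)
  ids <- c(if (npos > 0) sprintf("plantpos%04d", seq_len(npos)),
           if (nneg > 0) sprintf("plantneg%04d", seq_len(nneg)),
           if (nnull > 0) sprintf("null%04d", seq_len(nnull)),
           special)
  dirs <- c(rep(1, npos), rep(-1, nneg), rep(0, nnull), rep(0, length(special)))
  withr::with_seed(config$seed + 1L, {
    baseline <- stats::rnorm(length(ids), mean = 6, sd = 1.5)
    log2e <- outer(dirs * config$effect_size, z) + baseline +
      matrix(stats::rnorm(length(ids) * length(z), sd = config$noise_sd),
             nrow = length(ids))
    expr <- 2^log2e
    dimnames(expr) <- list(ids, samples)
    truth <- data.frame(
      feature_id = ids,
      planted = c(rep("positive", npos), rep("negative", nneg),
                  rep("null", nnull), rep("null", length(special))))
    list(expr = expr, truth = truth)
  })
}

#' Plant germline A/G (T/C) variants at panel sites in a VCF
#'
#' Selects `round(fraction * n_sites)` panel sites (without replacement)
#' and writes a minimal VCF v4.2 with one passing SNV per chosen site:
#' ref A -> alt G at plus-strand sites, ref T -> alt C at minus-strand
#' sites. Downstream, [germline_exclusions()] must recover exactly this set.
#'
#' @param panel An `editing_panel`.
#' @param fraction Fraction of sites to plant (default 0.25).
#' @param seed Integer seed.
#' @param path Output VCF path (default: a tempfile).
#' @return List: `path`, `excluded_sites` (truth set of planted site ids).
#' @export
simulate_germline_vcf <- function(panel, fraction = 0.25, seed = 1L,
                                  path = tempfile(fileext = ".vcf")) {
  stopifnot(inherits(panel, "editing_panel"),
            fraction >= 0, fraction <= 1)
  n <- round(fraction * nrow(panel))
  chosen <- withr::with_seed(seed, sort(sample.int(nrow(panel), n)))
  sites <- panel[chosen, , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=adarindex.simulate_germline_vcf",
           sprintf("##contig=<ID=%s,length=250000000>",
                   unique(panel$chrom)),
           "##INFO=<ID=GL,Number=0,Type=Flag,Description=\"Planted germline variant\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (n > 0) {
    ord <- order(sites$chrom, sites$pos)
    sites <- sites[ord, , drop = FALSE]
    sprintf("%s\t%d\t.\t%s\t%s\t100\tPASS\tGL",
            sites$chrom, sites$pos, sites$ref_base_plus,
            ifelse(sites$ref_base_plus == "A", "G", "C"))
  } else character()
  writeLines(c(hdr, body), path)
  list(path = path, excluded_sites = sites$site_id)
}
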