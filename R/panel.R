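#' Hotspot editing-site panels
#'
#' An editing panel is an ordered table of curated A-to-I hotspot sites. Each
#' site records the gene symbol, chromosome ("chr"-prefixed GRCh38 naming),
#' 1-based genomic position, the plus-strand reference base (`"A"` for
#' plus-strand genes where editing reads as A>G, `"T"` for minus-strand genes
#' where it reads as T>C), and a free-text substitution label. Sites are keyed
#' by `site_id = "chrom:pos"`, unique within a panel.
#'
#' The default panel shipped with the package contains 24 exonic hotspot sites
#' in 20 genes (AZIN1, BLCAP, COG3, COPA, EEF1A1, FLNA, FLNB, FTH1, GIPC1,
#' IGFBP7, NEIL1, RPL15, RPL24, RPL32, RPL7A, RPLP1, RPS23, RPS9, UQCRHL,
#' ZNF358).
#'
#' @param path Path to a tab-separated panel file with header columns
#'   `gene`, `chrom`, `pos`, `ref_base_plus`, `label`. Lines starting with
#'   `#` are comments. Positions are 1-based, fully closed.
#' @param name Panel name stored as an attribute.
#' @param genome_build Genome build tag, default `"hg38"`.
#' @param chrom_style `"chr"` (default) normalizes chromosome names to the
#'   "chr"-prefixed dialect; `"plain"` strips the prefix.
#' @return `load_panel()` and `default_panel()` return an `editing_panel`:
#'   a `data.frame` with columns `gene`, `chrom`, `pos`, `ref_base_plus`,
#'   `label`, `site_id`, preserving file order.
#' @examples
#' p <- default_panel()
#' nrow(p)                     # 24 sites
#' length(unique(p$gene))      # 20 genes
#' @export
load_panel <- function(path, name = basename(path), genome_build = "hg38",
                       chrom_style = c("chr", "plain")) {
  chrom_style <- match.arg(chrom_style)
  if (!file.exists(path)) stop("panel file not found: ", path)
  raw <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                           colClasses = "character", quote = "")
  required <- c("gene", "chrom", "pos", "ref_base_plus", "label")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L)
    stop("panel file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(raw) == 0L) stop("empty panel: ", path, " has a header but no sites")
  new_panel(raw[required], name = name, genome_build = genome_build,
            chrom_style = chrom_style, origin = path)
}

#' @rdname load_panel
#' @export
default_panel <- function(chrom_style = c("chr", "plain")) {
  path <- system.file("extdata", "hotspot_panel.tsv", package = "adarindex",
                      mustWork = TRUE)
  load_panel(path, name = "hotspot24", chrom_style = chrom_style)
}

## Construct + validate; `origin` only used for error messages.
new_panel <- function(df, name, genome_build, chrom_style, origin = "<panel>") {
  pos_num <- suppressWarnings(as.numeric(df$pos))
  bad <- which(is.na(pos_num) | pos_num != floor(pos_num) | pos_num <= 0)
  if (length(bad) > 0L)
    stop("panel ", origin, ": pos must be a positive integer; offending row(s): ",
         paste(bad, collapse = ", "))
  bad <- which(!df$ref_base_plus %in% c("A", "T"))
  if (length(bad) > 0L)
    stop("panel ", origin, ": ref_base_plus must be 'A' or 'T'; offending row(s): ",
         paste(bad, collapse = ", "))
  df$pos <- as.integer(pos_num)
  df$chrom <- normalize_chrom(df$chrom, chrom_style)
  df$site_id <- paste0(df$chrom, ":", df$pos)
  dup <- df$site_id[duplicated(df$site_id)]
  if (length(dup) > 0L)
    stop("panel ", origin, ": duplicate site_id: ",
         paste(unique(dup), collapse = ", "))
  rownames(df) <- NULL
  structure(df, class = c("editing_panel", "data.frame"),
            name = name, genome_build = genome_build)
}

#' @param x Character vector of chromosome names.
#' @rdname load_panel
#' @export
normalize_chrom <- function(x, chrom_style = c("chr", "plain")) {
  chrom_style <- match.arg(chrom_style)
  bare <- sub("^chr", "", x)
  if (chrom_style == "chr") paste0("chr", bare) else bare
}

#' Write a panel back to its tab-separated file format
#'
#' Round-trips with [load_panel()]: loading a written panel reproduces the
#' original sites in the original order.
#'
#' @param panel An `editing_panel`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "editing_panel"))
  df <- as.data.frame(panel)[c("gene", "chrom", "pos", "ref_base_plus", "label")]
  ok <- tryCatch({
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write panel to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Export a panel as BED (0-based, half-open) for interoperability
#'
#' @inheritParams write_panel
#' @param path Output path, or `NULL` to return the BED `data.frame`.
#' @return The BED table (chrom, start, end, name) invisibly if written.
#' @export
panel_to_bed <- function(panel, path = NULL) {
  stopifnot(inherits(panel, "editing_panel"))
  bed <- data.frame(chrom = panel$chrom, start = panel$pos - 1L,
                    end = panel$pos, name = paste0(panel$gene, "|", panel$site_id))
  if (is.null(path)) return(bed)
  data.table::fwrite(bed, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(bed)
}

#' @export
print.editing_panel <- function(x, ...) {
  cat(sprintf("editing panel '%s' (%s): %d sites in %d genes\n",
              attr(x, "name"), attr(x, "genome_build"),
              nrow(x), length(unique(x$gene))))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more sites\n")
  invisible(x)
}

## GRanges view of the panel, used by the BAM counting layer.
panel_granges <- function(panel) {
  GenomicRanges::GRanges(panel$chrom,
                         IRanges::IRanges(panel$pos, panel$pos),
                         site_id = panel$site_id,
                         ref_base_plus = panel$ref_base_plus)
}
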