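#' Simulate a toy reference and aligned reads over the panel
#'
#' Builds a miniature genome with one short contig per panel site (the
#' hotspot locus remapped to the contig centre; the mapping back to the
#' genome-scale panel is returned as a sidecar table), then generates
#' single-end reads spanning each site: a binomial share carries the edited
#' base (G at ref-A sites, C at ref-T sites), the rest the reference base.
#' Reads are emitted as SAM text, converted, sorted and indexed to BAM, so
#' the exact counting path used on real data is exercised end to end. The
#' per-site truth counts are returned alongside.
#'
#' @param config A [sim_config()]; `rates` and the depth model are keyed by
#'   the genome-scale panel inside it.
#' @param dir Output directory (created; default a tempdir subdirectory).
#' @param read_length Read length (default 50).
#' @param flank Reference flank on each side of the site (default 60; must
#'   be >= `read_length`).
#' @param mapq Mapping quality of simulated reads (default 60).
#' @param baseq Phred base quality of every base (default 40).
#' @param low_mapq_extra Additional edited reads per site written with
#'   MAPQ 10 (default 0); these must be invisible to counting at
#'   `min_mapq = 20` and exist to test the filter.
#' @return List: `bam`, `fasta`, `panel` (toy-coordinate `editing_panel`),
#'   `sidecar` (`data.frame` mapping toy `site_id` to the genome-scale
#'   `hg38_site_id`), `truth` (`data.frame`: toy `site_id`, `ref_count`,
#'   `edit_count`).
#' @export
simulate_alignments <- function(config, dir = tempfile("simaln"),
                                read_length = 50L, flank = 60L,
                                mapq = 60L, baseq = 40L,
                                low_mapq_extra = 0L) {
  stopifnot(inherits(config, "sim_config"), flank >= read_length)
  panel <- config$panel
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_sites <- nrow(panel)
  contig <- sprintf("chrS%02d", seq_len(n_sites))
  contig_len <- 2L * flank + 1L
  site_pos <- flank + 1L
  qual_char <- rawToChar(as.raw(baseq + 33L))

  withr::with_seed(config$seed + 2L, {
    # reference: random sequence with the annotated base at the site
    seqs <- vapply(seq_len(n_sites), function(i) {
      s <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE)
      s[site_pos] <- panel$ref_base_plus[i]
      paste(s, collapse = "")
    }, character(1))
    ref <- Biostrings::DNAStringSet(seqs)
    names(ref) <- contig
    fasta <- file.path(dir, "toyref.fa")
    Biostrings::writeXStringSet(ref, fasta)

    depth <- sim_depths(n_sites, config)
    edit <- stats::rbinom(n_sites, depth, config$rates[panel$site_id])
    recs <- list(); truth <- list()
    for (i in seq_len(n_sites)) {
      n <- depth[i]
      edit_alt <- if (panel$ref_base_plus[i] == "A") "G" else "C"
      n_extra <- if (n > 0 || low_mapq_extra > 0) low_mapq_extra else 0L
      total <- n + n_extra
      if (total == 0L) {
        truth[[i]] <- data.frame(site_id = paste0(contig[i], ":", site_pos),
                                 ref_count = 0L, edit_count = 0L)
        next
      }
      starts <- sample(seq(site_pos - read_length + 1L, site_pos), total,
                       replace = TRUE)
      is_edit <- c(rep(TRUE, edit[i]), rep(FALSE, n - edit[i]),
                   rep(TRUE, n_extra))
      rd_mapq <- c(rep(mapq, n), rep(10L, n_extra))
      seq_i <- vapply(seq_len(total), function(j) {
        s <- substring(seqs[i], starts[j], starts[j] + read_length - 1L)
        if (is_edit[j])
          substring(s, site_pos - starts[j] + 1L,
                    site_pos - starts[j] + 1L) <- edit_alt
        s
      }, character(1))
      recs[[i]] <- data.frame(
        qname = sprintf("r%s_%04d", contig[i], seq_len(total)),
        flag = 0L, rname = contig[i], pos = starts, mapq = rd_mapq,
        cigar = paste0(read_length, "M"), rnext = "*", pnext = 0L,
        tlen = 0L, seq = seq_i,
        qual = strrep(qual_char, read_length))
      truth[[i]] <- data.frame(site_id = paste0(contig[i], ":", site_pos),
                               ref_count = n - edit[i], edit_count = edit[i])
    }
    sam <- file.path(dir, "reads.sam")
    write_sam(do.call(rbind, recs), stats::setNames(rep(contig_len, n_sites),
                                                    contig), sam)
    bam <- sam_to_bam(sam, file.path(dir, "reads"))

    toy_panel <- new_panel(
      data.frame(gene = panel$gene, chrom = contig,
                 pos = as.character(site_pos),
                 ref_base_plus = panel$ref_base_plus, label = panel$label),
      name = "toy", genome_build = "toy", chrom_style = "chr",
      origin = "<simulated>")
    sidecar <- data.frame(site_id = toy_panel$site_id, chrom = contig,
                          pos = site_pos, hg38_site_id = panel$site_id,
                          gene = panel$gene)
    list(bam = bam, fasta = fasta, panel = toy_panel, sidecar = sidecar,
         truth = do.call(rbind, truth))
  })
}

#' Low-level SAM writing and BAM conversion helpers
#'
#' `write_sam()` writes a minimal SAM file (used by the simulator and handy
#' for constructing exact read fixtures in tests); `sam_to_bam()` converts,
#' coordinate-sorts and indexes it via Rsamtools.
#'
#' @param records `data.frame` with the 11 mandatory SAM columns `qname`,
#'   `flag`, `rname`, `pos`, `mapq`, `cigar`, `rnext`, `pnext`, `tlen`,
#'   `seq`, `qual`.
#' @param ref_lengths Named integer vector: contig name -> length (becomes
#'   the `@SQ` header lines).
#' @param path Output SAM path.
#' @return `write_sam()`: `path`, invisibly. `sam_to_bam()`: the indexed BAM
#'   path.
#' @export
write_sam <- function(records, ref_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  cols <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "rnext",
            "pnext", "tlen", "seq", "qual")
  body <- if (is.null(records) || nrow(records) == 0L) character() else
    do.call(paste, c(lapply(records[cols], function(x)
      trimws(as.character(x))), sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @param sam SAM path.
#' @param prefix Destination prefix (the BAM lands at `<prefix>.bam`).
#' @rdname write_sam
#' @export
sam_to_bam <- function(sam, prefix = sub("\\.sam$", "", sam)) {
  bam <- Rsamtools::asBam(sam, destination = prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}
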