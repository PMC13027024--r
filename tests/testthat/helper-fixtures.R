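# Shared fixture builders. Everything is generated in code at test time.

# Write a panel TSV and load it back through the public loader.
make_panel <- function(genes, chroms, pos, ref = NULL, labels = NULL) {
  if (is.null(ref)) ref <- rep("A", length(genes))
  if (is.null(labels)) labels <- rep("synthetic", length(genes))
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("gene\tchrom\tpos\tref_base_plus\tlabel",
               paste(genes, chroms, pos, ref, labels, sep = "\t")), path)
  load_panel(path, name = "test")
}

# sample_site_counts from bare vectors (exercised through the public
# counts-table reader so the object is built the way users build it).
make_counts <- function(panel, ref, edit, sample_id = "s1") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  df <- data.frame(sample_id = sample_id, site_id = panel$site_id,
                   ref_count = ref, edit_count = edit)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  read_counts_table(path, panel)[[sample_id]]
}

# A default SAM record with overridable fields.
sam_rec <- function(qname, rname, pos, seq, flag = 0L, mapq = 60L,
                    cigar = paste0(nchar(seq), "M"), rnext = "*",
                    pnext = 0L, tlen = 0L,
                    qual = strrep("I", nchar(seq))) {  # "I" = Q40
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, rnext = rnext, pnext = pnext,
             tlen = tlen, seq = seq, qual = qual)
}

# Build an indexed BAM from SAM records.
make_bam <- function(records, ref_lengths, dir = withr::local_tempdir(
                       .local_envir = parent.frame())) {
  sam <- file.path(dir, "fix.sam")
  write_sam(records, ref_lengths, sam)
  sam_to_bam(sam)
}

# Minimal VCF writer for exclusion tests.
make_vcf <- function(chrom, pos, ref, alt, filter = "PASS",
                     contigs = unique(chrom)) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=250000000>", contigs),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (length(chrom) > 0)
    sprintf("%s\t%d\t.\t%s\t%s\t99\t%s\t.", chrom, pos, ref, alt, filter)
  else character()
  writeLines(c(hdr, body), path)
  path
}
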