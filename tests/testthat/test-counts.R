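# Reads are 20 bp, site at chrT1:100, read start 91 => site is query pos 10.
read_at_site <- function(base, qname, mapq = 60L, site_qual = "I",
                         flag = 0L, rname = "chrT1", pos = 91L) {
  sam_rec(qname, rname, pos,
          seq = paste0(strrep("C", 9), base, strrep("C", 10)),
          mapq = mapq, flag = flag,
          qual = paste0(strrep("I", 9), site_qual, strrep("I", 10)))
}

toy_site <- function() make_panel("G1", "chrT1", 100, "A")[1, ]

test_that("base counting applies MAPQ, baseq, flag and deletion filters", {
  recs <- rbind(
    do.call(rbind, lapply(1:7, function(i) read_at_site("A", paste0("a", i)))),
    do.call(rbind, lapply(1:3, function(i) read_at_site("G", paste0("g", i)))),
    # below the MAPQ >= 20 filter: invisible
    do.call(rbind, lapply(1:5, function(i)
      read_at_site("G", paste0("lq", i), mapq = 10L))),
    # base quality 2 ('#') at the site: invisible
    read_at_site("G", "bq1", site_qual = "#"),
    # secondary / duplicate / supplementary: invisible
    read_at_site("G", "sec1", flag = 256L),
    read_at_site("G", "dup1", flag = 1024L),
    read_at_site("G", "sup1", flag = 2048L),
    # deletion spanning the site: contributes nothing
    sam_rec("del1", "chrT1", 91L, seq = strrep("G", 20),
            cigar = "9M2D11M"))
  bam <- make_bam(recs, c(chrT1 = 300L))
  bc <- count_bases_at_site(bam, toy_site())
  expect_identical(bc$n_A, 7L)
  expect_identical(bc$n_G, 3L)
  expect_identical(bc$n_C + bc$n_T + bc$n_other, 0L)
  expect_identical(bc$depth, 10L)

  # empty region
  empty <- count_bases_at_site(bam, list(chrom = "chrT1", pos = 250L,
                                         site_id = "chrT1:250"))
  expect_identical(empty$depth, 0L)

  expect_error(count_bases_at_site(bam, list(chrom = "chrZZ", pos = 1L,
                                             site_id = "chrZZ:1")),
               "absent from the alignment header")
})

test_that("counting agrees with the Rsamtools pileup oracle on single-end reads", {
  withr::local_seed(11)
  bases <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
  quals <- sample(c("#", "5", "I"), 60, replace = TRUE)   # Q2, Q20, Q40
  mapqs <- sample(c(10L, 25L, 60L), 60, replace = TRUE)
  recs <- do.call(rbind, lapply(seq_along(bases), function(i)
    read_at_site(bases[i], paste0("r", i), mapq = mapqs[i],
                 site_qual = quals[i])))
  bam <- make_bam(recs, c(chrT1 = 300L))
  bc <- count_bases_at_site(bam, toy_site(), min_mapq = 20L, min_baseq = 20L)

  pu <- Rsamtools::pileup(
    bam,
    scanBamParam = Rsamtools::ScanBamParam(
      which = GenomicRanges::GRanges("chrT1", IRanges::IRanges(100, 100)),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE,
                                    isDuplicate = FALSE),
      mapqFilter = 20L),
    pileupParam = Rsamtools::PileupParam(min_base_quality = 20L,
                                         min_mapq = 20L,
                                         distinguish_strands = FALSE,
                                         include_deletions = FALSE,
                                         include_insertions = FALSE))
  oracle <- setNames(rep(0L, 4), c("A", "C", "G", "T"))
  oracle[as.character(pu$nucleotide)] <- pu$count
  expect_identical(c(bc$n_A, bc$n_C, bc$n_G, bc$n_T), unname(oracle))

  # tightening either filter never increases any count
  loose <- count_bases_at_site(bam, toy_site(), min_mapq = 20L, min_baseq = 2L)
  tight <- count_bases_at_site(bam, toy_site(), min_mapq = 60L, min_baseq = 40L)
  for (col in c("n_A", "n_C", "n_G", "n_T", "depth")) {
    expect_lte(tight[[col]], bc[[col]])
    expect_lte(bc[[col]], loose[[col]])
  }
})

test_that("overlapping mates count once per fragment by default", {
  # one fragment whose mates both cover the site and agree (G)
  m1 <- read_at_site("G", "frag1", flag = 99L)
  m2 <- read_at_site("G", "frag1", flag = 147L, pos = 95L)
  m2$seq <- paste0(strrep("C", 5), "G", strrep("C", 14))
  m2$qual <- strrep("I", 20)
  # one fragment whose mates disagree: G at Q40 vs A at Q25 (':') -> G wins
  d1 <- read_at_site("G", "frag2", flag = 99L, site_qual = "I")
  d2 <- read_at_site("A", "frag2", flag = 147L, site_qual = ":")
  bam <- make_bam(rbind(m1, m2, d1, d2), c(chrT1 = 300L))

  dd <- count_bases_at_site(bam, toy_site(), dedup_overlaps = TRUE)
  expect_identical(c(dd$n_G, dd$n_A), c(2L, 0L))
  nd <- count_bases_at_site(bam, toy_site(), dedup_overlaps = FALSE)
  expect_identical(c(nd$n_G, nd$n_A), c(3L, 1L))
})

test_that("orient_counts maps plus- and minus-strand sites correctly", {
  bc <- data.frame(site_id = "s", n_A = 7L, n_C = 2L, n_G = 3L, n_T = 8L,
                   n_other = 0L, depth = 20L)
  a <- orient_counts(bc, list(site_id = "s", ref_base_plus = "A"))
  expect_identical(c(a$ref_count, a$edit_count), c(7L, 3L))
  t <- orient_counts(bc, list(site_id = "s", ref_base_plus = "T"))
  expect_identical(c(t$ref_count, t$edit_count), c(8L, 2L))
  expect_error(orient_counts(bc, list(site_id = "s", ref_base_plus = "G")),
               "corrupted panel")
})

test_that("pileup_sample covers every panel site, zeros included, deterministically", {
  panel <- make_panel(sprintf("G%02d", 1:24), rep("chrT1", 24),
                      seq(100L, by = 100L, length.out = 24L))
  covered <- c(100L, 500L, 1200L)
  recs <- do.call(rbind, lapply(seq_along(covered), function(i)
    do.call(rbind, lapply(1:4, function(j)
      read_at_site("G", sprintf("c%d_%d", i, j), pos = covered[i] - 9L)))))
  bam <- make_bam(recs, c(chrT1 = 3000L))
  cts <- pileup_sample(bam, panel, sample_id = "sA")
  expect_identical(nrow(cts), 24L)
  expect_identical(cts$site_id, panel$site_id)
  zero <- cts$ref_count == 0L & cts$edit_count == 0L
  expect_identical(sum(zero), 21L)
  expect_true(all(cts$edit_count[!zero] == 4L))
  expect_identical(attr(cts, "sample_id"), "sA")
  # determinism
  expect_identical(as.data.frame(pileup_sample(bam, panel, sample_id = "sA")),
                   as.data.frame(cts))
  # missing index is reported explicitly
  file.remove(paste0(bam, ".bai"))
  expect_error(count_bases_at_site(bam, toy_site()), "missing BAM index")
})

test_that("counts tables round-trip, fill absent sites, and reject bad rows", {
  panel <- make_panel(c("G1", "G2", "G3"), rep("chrT1", 3),
                      c(100L, 200L, 300L))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsite_id\tref_count\tedit_count",
               "s1\tchrT1:100\t5\t5",
               "s1\tchrT1:200\t90\t10",
               "s2\tchrT1:100\t7\t0",
               "s2\tchrT1:200\t1\t1",
               "s2\tchrT1:300\t2\t2"), path)
  lst <- read_counts_table(path, panel)
  expect_named(lst, c("s1", "s2"))
  expect_identical(nrow(lst$s1), 3L)
  # omitted site filled with zeros
  expect_identical(lst$s1$ref_count[lst$s1$site_id == "chrT1:300"], 0L)

  out <- withr::local_tempfile(fileext = ".tsv")
  write_counts_table(lst, out)
  lst2 <- read_counts_table(out, panel)
  expect_identical(lapply(lst2, as.data.frame), lapply(lst, as.data.frame))

  writeLines(c("sample_id\tsite_id\tref_count\tedit_count",
               "s1\tchrT1:999\t5\t5"), path)
  expect_error(read_counts_table(path, panel), "not in the panel")
  writeLines(c("sample_id\tsite_id\tref_count\tedit_count",
               "s1\tchrT1:100\t-1\t5"), path)
  expect_error(read_counts_table(path, panel), "negative")
})
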