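two_site_panel <- function() make_panel(c("G1", "G2"), c("chrT1", "chrT1"),
                                        c(100L, 200L))

test_that("site rates and the two indices reproduce hand arithmetic", {
  panel <- two_site_panel()
  cts <- make_counts(panel, ref = c(5L, 90L), edit = c(5L, 10L))
  expect_equal(site_rate(cts), c(50, 10))
  expect_equal(weighted_editing(cts)$index, 100 * 15 / 110)  # 13.6363...
  expect_equal(mean_editing(cts)$index, 30)

  # zero coverage -> undefined rate, never 0
  z <- make_counts(panel, ref = c(0L, 7L), edit = c(0L, 0L))
  expect_identical(site_rate(z), c(NA_real_, 0))

  # single covered site: weighted index degenerates to the site rate
  one <- make_counts(panel, ref = c(7L, 0L), edit = c(3L, 0L))
  expect_equal(weighted_editing(one)$index, 30)

  # all edit counts zero with positive ref -> 0, not NA
  expect_equal(weighted_editing(z)$index, 0)
  # no reads at all -> undefined
  none <- make_counts(panel, ref = c(0L, 0L), edit = c(0L, 0L))
  expect_true(is.na(weighted_editing(none)$index))
})

test_that("the mean index applies the strict depth-over-5 filter", {
  panel <- two_site_panel()
  # depth 5 is filtered (strict >5); depth 10 passes
  cts <- make_counts(panel, ref = c(3L, 9L), edit = c(2L, 1L))
  m <- mean_editing(cts)
  expect_equal(m$index, 10)
  expect_identical(m$n_sites_used, 1L)
  # depth 6 passes
  cts6 <- make_counts(panel, ref = c(3L, 9L), edit = c(3L, 1L))
  expect_identical(mean_editing(cts6)$n_sites_used, 2L)
  # nothing passes -> undefined
  low <- make_counts(panel, ref = c(2L, 3L), edit = c(1L, 2L))
  expect_true(is.na(mean_editing(low)$index))
  expect_identical(mean_editing(low)$n_sites_used, 0L)
})

test_that("index invariances hold on random count fixtures", {
  withr::local_seed(99)
  panel <- make_panel(sprintf("G%d", 1:6), rep("chrT1", 6),
                      seq(100L, 600L, by = 100L))
  for (rep in 1:20) {
    depth <- rpois(6, 40)
    edit <- rbinom(6, depth, runif(1, 0, 1))
    cts <- make_counts(panel, ref = depth - edit, edit = edit)
    w <- weighted_editing(cts)$index
    m <- mean_editing(cts)$index
    # both indices in [0, 100] whenever defined
    for (v in c(w, m)) if (!is.na(v)) expect_true(v >= 0 && v <= 100)
    # weighted index == coverage-weighted average of defined site rates
    rates <- site_rate(cts); tot <- cts$ref_count + cts$edit_count
    ok <- tot > 0
    if (any(ok))
      expect_equal(w, sum(rates[ok] * tot[ok]) / sum(tot[ok]))
    # mean index invariant under scaling both counts of a passing site
    pass <- which(tot > 5)
    if (length(pass) > 0) {
      k <- sample(2:5, 1); i <- pass[1]
      ref2 <- cts$ref_count; edit2 <- cts$edit_count
      ref2[i] <- ref2[i] * k; edit2[i] <- edit2[i] * k
      cts2 <- make_counts(panel, ref = ref2, edit = edit2)
      expect_equal(mean_editing(cts2)$index, m)
    }
    # excluding a site leaves the others' pooled contribution untouched
    drop <- panel$site_id[1]
    keep <- cts$site_id != drop
    expect_equal(weighted_editing(cts, excluded = drop)$index,
                 if (sum(tot[keep]) > 0)
                   100 * sum(cts$edit_count[keep]) / sum(tot[keep])
                 else NA_real_)
  }
  # weighted index is generally NOT scale-invariant (crafted counterexample)
  cts <- make_counts(panel, ref = c(5L, 90L, 0L, 0L, 0L, 0L),
                     edit = c(5L, 10L, 0L, 0L, 0L, 0L))
  scaled <- make_counts(panel, ref = c(50L, 90L, 0L, 0L, 0L, 0L),
                        edit = c(50L, 10L, 0L, 0L, 0L, 0L))
  expect_false(isTRUE(all.equal(weighted_editing(cts)$index,
                                weighted_editing(scaled)$index)))
})

test_that("germline exclusion triggers on A/G (T/C) SNVs only, exactly", {
  panel <- default_panel()
  sim <- simulate_germline_vcf(panel, fraction = 0.25, seed = 5)
  expect_length(sim$excluded_sites, 6L)  # 0.25 * 24
  expect_setequal(germline_exclusions(sim$path, panel), sim$excluded_sites)

  # empty VCF -> empty set (contig names still match the panel)
  empty <- simulate_germline_vcf(panel, fraction = 0, seed = 1)
  expect_length(germline_exclusions(empty$path, panel), 0L)

  # A>C at a panel site does not exclude; G>A (reverse orientation) does
  vcf <- make_vcf(c("chr15", "chr15"), c(75353745L, 69455463L),
                  c("A", "G"), c("C", "A"))
  expect_identical(germline_exclusions(vcf, panel), "chr15:69455463")

  # non-passing records are ignored
  vcf2 <- make_vcf("chr15", 75353745L, "A", "G", filter = "germline_risk")
  expect_length(germline_exclusions(vcf2, panel), 0L)

  # contig dialect "15" still matches after normalization
  vcf3 <- make_vcf("15", 75353745L, "A", "G")
  expect_identical(germline_exclusions(vcf3, panel), "chr15:75353745")

  # a VCF on contigs unknown to the panel errors rather than silently empty
  vcf4 <- make_vcf("chrUn_KI270742v1", 1000L, "A", "G")
  expect_error(germline_exclusions(vcf4, panel), "contig-name mismatch")
})

test_that("score_sample composes exclusions and both indices", {
  panel <- make_panel(c("G1", "G2", "G3"), rep("chrT1", 3),
                      c(100L, 200L, 300L))
  cts <- make_counts(panel, ref = c(5L, 90L, 10L), edit = c(5L, 10L, 10L),
                     sample_id = "sX")
  r <- score_sample(cts, panel)
  expect_s3_class(r, "sample_editing_result")
  expect_equal(r$weighted_index, 100 * 25 / 130)
  expect_equal(r$mean_index, mean(c(50, 10, 50)))
  expect_identical(r$sample_id, "sX")

  # excluding the third site by id reproduces the two-site arithmetic
  r2 <- score_sample(cts, panel, excluded = "chrT1:300")
  expect_equal(r2$weighted_index, 100 * 15 / 110)
  expect_equal(r2$mean_index, 30)
  expect_identical(r2$excluded_sites, "chrT1:300")
  expect_true(r2$sites$excluded[3])

  # the only covered site germline-flagged -> both indices undefined
  only <- make_counts(panel, ref = c(5L, 0L, 0L), edit = c(5L, 0L, 0L))
  r3 <- score_sample(only, panel, excluded = "chrT1:100")
  expect_true(is.na(r3$weighted_index) && is.na(r3$mean_index))

  # determinism
  expect_identical(score_sample(cts, panel), r)

  # counts not keyed by the panel are rejected
  other <- make_panel("G9", "chrT9", 5L)
  expect_error(score_sample(make_counts(other, 1L, 1L), panel),
               "not keyed by the panel")
})

test_that("weighted index recovers a known binomial truth at high depth", {
  # true rate 0.3 spread over the panel at total depth ~1e5:
  # |index - 30| < 3 * 100 * sqrt(.3 * .7 / 1e5) with probability ~99.7%
  panel <- default_panel()
  withr::local_seed(314)
  depth <- rep(ceiling(1e5 / 24), 24)
  edit <- rbinom(24, depth, 0.3)
  cts <- make_counts(panel, ref = as.integer(depth - edit),
                     edit = as.integer(edit))
  se <- 100 * sqrt(0.3 * 0.7 / sum(depth))
  expect_lt(abs(weighted_editing(cts)$index - 30), 3 * se)
})
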