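mk_calls <- function(context, state, read_id = paste0("r", seq_along(context)),
                     contig = "c1", site = seq_along(context),
                     strand = "OT") {
  data.frame(read_id = read_id, contig = contig, site = site,
             base_pos = site, offset = site, strand = strand,
             context = context, state = state, stringsAsFactors = FALSE)
}

test_that("conversion rate uses CHH+CHG calls only", {
  calls <- mk_calls(c(rep("CHH", 100), rep("CpG", 50)),
                    c(rep("converted", 99), "methylated",
                      rep("methylated", 50)))
  expect_equal(conversion_rate(calls), 99.0)
  calls2 <- mk_calls(c("CHH", "CHG"), c("converted", "converted"))
  expect_equal(conversion_rate(calls2), 100.0)
  expect_warning(v <- conversion_rate(mk_calls("CpG", "methylated")),
                 "undefined")
  expect_true(is.na(v))
})

test_that("deduplication keys on position, strand and sequence", {
  # 23 reads collapsing to 9 distinct keys (same stack structure as a
  # high-coverage locus with duplicates)
  seqs <- paste0("TGG", c("AAT", "AAG", "ATT", "CAT", "CCT", "GAT", "GGT",
                          "TAT", "TTT"))
  reps <- c(5, 4, 3, 3, 2, 2, 2, 1, 1)  # sums to 23
  al <- make_aligned("c1", rep(100L, 23), "OT", rep(seqs, reps),
                     read_id = sprintf("r%02d", 1:23))
  dd <- deduplicate(al)
  expect_equal(nrow(dd$unique), 9L)
  expect_equal(sum(dd$multiplicity$n), 23L)
  expect_setequal(dd$multiplicity$n, reps)
  # same position, different methylation pattern (sequence) stays unique
  expect_equal(length(unique(dd$unique$sequence)), 9L)
  # all-distinct input is identity
  al2 <- make_aligned("c1", c(0L, 50L, 100L), "OT",
                      c("ACGT", "ACGT", "ACGT"))
  expect_equal(nrow(deduplicate(al2)$unique), 3L)
})

test_that("per-CpG summaries tally methylated and total calls", {
  calls <- mk_calls(rep("CpG", 4), c("methylated", "methylated",
                                     "methylated", "converted"),
                    site = rep(10L, 4), read_id = paste0("r", 1:4))
  sm <- cpg_summaries(calls)
  expect_equal(sm$n_methylated, 3L)
  expect_equal(sm$n_total, 4L)
  expect_equal(sm$frequency, 0.75)
  # read subset restriction
  sm2 <- cpg_summaries(calls, read_ids = c("r1", "r4"))
  expect_equal(sm2$frequency, 0.5)
  # non-CpG calls and uncovered sites never appear
  sm3 <- cpg_summaries(mk_calls("CHH", "converted"))
  expect_equal(nrow(sm3), 0L)
})

test_that("coverage report thresholds and mean are correct", {
  sm <- data.frame(contig = "c1", site = 1:3, n_methylated = 0L,
                   n_total = c(1L, 5L, 10L), frequency = 0)
  cov <- coverage_report(sm)
  expect_equal(cov$n_cpgs_1x, 3L)
  expect_equal(cov$n_cpgs_5x, 2L)
  expect_equal(cov$n_cpgs_10x, 1L)
  expect_equal(cov$mean_coverage, mean(c(1, 5, 10)), tolerance = 1e-12)
  expect_true(cov$n_cpgs_10x <= cov$n_cpgs_5x &&
              cov$n_cpgs_5x <= cov$n_cpgs_1x)
  sm$n_total <- 1L
  expect_equal(coverage_report(sm)$mean_coverage, 1.0)
  expect_warning(cov0 <- coverage_report(sm[0, ]), "no covered")
  expect_equal(cov0$n_cpgs_1x, 0L)
})

test_that("with-duplicates coverage dominates unique-only coverage", {
  fx <- sim_fixture(cfg = sim_config(depth = 12, seed = 41L))
  al <- align_reads(fx$sim$reads, build_index(fx$genome))
  rep <- meth_qc_report(al, fx$genome)
  expect_gte(rep$coverage_all$mean_coverage,
             rep$coverage_unique$mean_coverage)
  expect_gte(rep$coverage_all$n_cpgs_5x, rep$coverage_unique$n_cpgs_5x)
  # dedup multiplicities conserve the input
  expect_equal(sum(rep$dedup$multiplicity$n),
               sum(al$status == "unique"))
})

test_that("methylation histogram bins 5% blocks with a closed last bin", {
  sm <- data.frame(contig = "c1", site = 1:4, n_methylated = 0L,
                   n_total = 10L,
                   frequency = c(0.00, 0.999, 0.05, 0.47))
  h <- methylation_histogram(sm)
  expect_equal(nrow(h), 20L)
  expect_equal(h$count[1], 1L)              # 0.00 -> [0,5)
  expect_equal(h$count[20], 1L)             # 0.999 -> [95,100]
  expect_equal(h$count[2], 1L)              # 0.05 -> [5,10)
  expect_equal(h$count[10], 1L)             # 0.47 -> [45,50)
  expect_equal(sum(h$count), 4L)
  # frequency exactly 1 lands in the closed last bin
  sm$frequency <- 1
  expect_equal(methylation_histogram(sm)$count[20], 4L)
  # simulator parameter recovery: the first and last bins track the low
  # and high mixture modes. At finite coverage, sites with levels near a
  # bin edge (e.g. 0.04 at 40x) legitimately flip into the neighboring
  # bin, so the bands below allow for that binomial leakage.
  fx <- sim_fixture(cfg = sim_config(depth = 60, seq_error_rate = 0,
                                     conversion_failure = 0, seed = 29L))
  al <- align_reads(fx$sim$reads, build_index(fx$genome))
  sm2 <- cpg_summaries(extract_calls(al, fx$genome))
  sm2 <- sm2[sm2$n_total >= 20, ]
  h2 <- methylation_histogram(sm2)
  frac1 <- h2$count[1] / sum(h2$count)
  frac20 <- h2$count[20] / sum(h2$count)
  expect_gt(frac1, 0.45); expect_lt(frac1, 0.70)   # low mode 0.60
  expect_gt(frac20, 0.15); expect_lt(frac20, 0.40) # high mode 0.275
})

test_that("coverage histogram is on the log10 scale and conserves totals", {
  sm <- data.frame(contig = "c1", site = 1:3, n_methylated = 0L,
                   n_total = c(1L, 10L, 100L), frequency = 0)
  h <- coverage_log_histogram(sm)
  expect_equal(sum(h$count), 3L)
  in_bin <- function(x) h$count[h$bin_low <= x & h$bin_high > x]
  expect_equal(in_bin(0.001), 1L)   # coverage 1 -> log10 = 0
  expect_equal(in_bin(1.001), 1L)   # coverage 10 -> log10 = 1
  expect_equal(in_bin(2.001), 1L)   # coverage 100 -> log10 = 2
})

test_that("locus selection requires unique depth and differential CpGs", {
  # CpG-dense synthetic contig: CGT repeats give CpGs every 3 bp
  gg <- ref_genome(c(c1 = paste0(strrep("A", 100), strrep("CGT", 30),
                                 strrep("A", 100))))
  win <- find_cpg_sites(gg)$pos
  win <- win[win >= 100 & win < 150]
  ref50 <- chartr("C", "T", substr(gg[["c1"]], 101, 150))
  # read i methylates the first four window CpGs per the bits of i:
  # 12 distinct patterns, intermediate frequencies at those four sites
  seqs <- vapply(1:12, function(i) {
    chars <- strsplit(ref50, "", fixed = TRUE)[[1]]
    for (j in 1:4) if (bitwAnd(i, bitwShiftL(1L, j - 1L)) > 0L)
      chars[win[j] - 100L + 1L] <- "C"
    paste(chars, collapse = "")
  }, character(1))
  al <- make_aligned("c1", rep(100L, 12), "OT", seqs,
                     read_id = sprintf("s%02d", 1:12))
  calls <- extract_calls(al, gg)
  loci <- select_test_loci(al, calls, min_unique_reads = 11,
                           min_diff_cpgs = 4)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$start, 100L)
  expect_gte(loci$n_unique_reads, 11)
  # all-extreme stacks are rejected: fully converted reads
  al0 <- make_aligned("c1", rep(100L, 12), "OT", rep(ref50, 12),
                      read_id = sprintf("t%02d", 1:12))
  calls0 <- extract_calls(al0, gg)
  expect_equal(nrow(select_test_loci(al0, calls0, 11, 1)), 0L)
})

test_that("duplicate-representativeness correlation behaves", {
  # identical vectors: r^2 = 1
  expect_equal(dup_correlation(c(.1, .5, .9, .3), c(.1, .5, .9, .3))$r_squared,
               1.0)
  # p-value equals the hand-computed t transform
  x <- c(0.2, 0.5, 0.8, 0.4, 0.9)
  y <- c(0.25, 0.45, 0.7, 0.5, 0.8)
  res <- dup_correlation(x, y)
  r <- cor(x, y)
  tt <- r * sqrt(3) / sqrt(1 - r^2)
  expect_equal(res$p_value, 2 * pt(-abs(tt), df = 3), tolerance = 1e-10)
  expect_error(dup_correlation(c(.1, .2), c(.1, .2)), ">= 3")
  expect_warning(res0 <- dup_correlation(c(.5, .5, .5), c(.1, .2, .3)),
                 "zero variance")
  expect_true(is.na(res0$r_squared))
})

test_that("duplicate representativeness responds to amplification excess", {
  # Per-locus Pearson r2 is robust to a coherent (all sites dragged the
  # same way) distortion, but degrades when heavy-tailed per-molecule
  # amplification randomly over-represents individual molecules. Fixed
  # seeds make the comparison deterministic.
  median_r2 <- function(dup_p) {
    fx <- sim_fixture(genome_len = 60000L, genome_seed = 77L, meth_seed = 5L,
                      cfg = sim_config(depth = 25, seq_error_rate = 0,
                                       dup_geometric_p = dup_p, seed = 101L))
    al <- align_reads(fx$sim$reads, build_index(fx$genome))
    al <- al[al$status == "unique", ]
    calls <- extract_calls(al, fx$genome)
    loci <- select_test_loci(al, calls, min_unique_reads = 8,
                             min_diff_cpgs = 3)
    r2 <- vapply(seq_len(nrow(loci)), function(i) {
      sub <- al[al$contig == loci$contig[i] & al$start == loci$start[i] &
                al$strand == loci$strand[i], ]
      res <- tryCatch(suppressWarnings(
        duplicate_representativeness(sub, calls)), error = function(e) NULL)
      if (is.null(res) || is.na(res$r_squared)) NA_real_ else res$r_squared
    }, numeric(1))
    stats::median(r2, na.rm = TRUE)
  }
  light <- median_r2(0.5)   # mean multiplicity 2
  heavy <- median_r2(0.08)  # mean multiplicity 12.5, heavy tail
  expect_gt(light, 0.8)
  expect_gt(light, heavy)
})

test_that("cytosine-content bias suppresses duplication of C-rich reads", {
  mult_cor <- function(c_bias) {
    fx <- sim_fixture(genome_len = 60000L, genome_seed = 77L, meth_seed = 5L,
                      cfg = sim_config(depth = 10, seq_error_rate = 0,
                                       dup_geometric_p = 0.3,
                                       dup_c_bias = c_bias, seed = 55L))
    tr <- fx$sim$truth
    mult <- table(tr$template_id)
    first <- tr[!tr$is_pcr_dup, ]
    seqs <- fx$sim$reads$sequence[match(first$read_id,
                                        fx$sim$reads$read_id)]
    nc <- nchar(gsub("[^C]", "", seqs))
    cor(nc, as.integer(mult[as.character(first$template_id)]))
  }
  expect_lt(abs(mult_cor(0)), 0.1)   # unbiased: no association
  expect_lt(mult_cor(0.5), -0.25)    # biased: C-rich molecules duplicate less
})
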