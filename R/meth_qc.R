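#' Bisulfite conversion rate from non-CpG calls
#'
#' Mammalian methylation is almost exclusively CpG, so cytosines in CHH and
#' CHG context (H = any non-G base) should convert completely; the fraction
#' that did is the conversion-rate estimate. CpG calls are excluded.
#'
#' @param calls data.frame from [extract_calls()].
#' @return percentage in `[0,100]`; `NA` with a warning when no non-CpG
#'   calls exist.
#' @export
conversion_rate <- function(calls) {
  nc <- calls[calls$context %in% c("CHH", "CHG"), , drop = FALSE]
  if (nrow(nc) == 0L) {
    warning("no CHH/CHG calls; conversion rate undefined")
    return(NA_real_)
  }
  100 * mean(nc$state == "converted")
}

#' Collapse PCR duplicates
#'
#' Duplicate key is (contig, start, strand, read sequence): same-position
#' reads whose methylation patterns (hence sequences) differ are kept as
#' distinct unique reads, since such diversity is genuine in RRBS where
#' fragments share MspI-defined ends.
#'
#' @param aligned data.frame of unique-status alignments.
#' @return list with `unique` (one representative row per key),
#'   `multiplicity` (data.frame key columns + `n`), and `kept_ids`.
#' @export
deduplicate <- function(aligned) {
  al <- aligned[aligned$status == "unique", , drop = FALSE]
  key <- paste(al$contig, al$start, al$strand, al$sequence, sep = "\r")
  first <- !duplicated(key)
  mult <- as.data.frame(table(key), stringsAsFactors = FALSE)
  names(mult) <- c("key", "n")
  parts <- strsplit(mult$key, "\r", fixed = TRUE)
  mult <- data.frame(contig = vapply(parts, `[`, "", 1L),
                     start = as.integer(vapply(parts, `[`, "", 2L)),
                     strand = vapply(parts, `[`, "", 3L),
                     sequence = vapply(parts, `[`, "", 4L),
                     n = mult$n, stringsAsFactors = FALSE)
  list(unique = al[first, , drop = FALSE],
       multiplicity = mult,
       kept_ids = al$read_id[first])
}

#' Per-CpG methylation summaries
#'
#' Tallies methylated/total CpG-context calls per site. `read_ids`
#' restricts the tally to a read subset (e.g. the deduplicated pool).
#'
#' @param calls data.frame from [extract_calls()].
#' @param read_ids optional character vector of read ids to include.
#' @return data.frame with `contig`, `site` (0-based forward C position),
#'   `n_methylated`, `n_total`, `frequency`, sorted by contig and site.
#' @export
cpg_summaries <- function(calls, read_ids = NULL) {
  cg <- calls[calls$context == "CpG", , drop = FALSE]
  if (!is.null(read_ids))
    cg <- cg[cg$read_id %in% read_ids, , drop = FALSE]
  if (nrow(cg) == 0L)
    return(data.frame(contig = character(0), site = integer(0),
                      n_methylated = integer(0), n_total = integer(0),
                      frequency = numeric(0)))
  key <- paste(cg$contig, cg$site, sep = "\r")
  tot <- rowsum(rep(1L, nrow(cg)), key)
  met <- rowsum(as.integer(cg$state == "methylated"), key)
  parts <- strsplit(rownames(tot), "\r", fixed = TRUE)
  out <- data.frame(contig = vapply(parts, `[`, "", 1L),
                    site = as.integer(vapply(parts, `[`, "", 2L)),
                    n_methylated = as.integer(met),
                    n_total = as.integer(tot),
                    stringsAsFactors = FALSE)
  out$frequency <- out$n_methylated / out$n_total
  out <- out[order(out$contig, out$site), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' CpG coverage report
#'
#' Counts of CpGs covered at >= 1x, 5x and 10x and the mean coverage over
#' covered CpGs (coverage over all-genome CpGs is deliberately not used:
#' low-depth libraries report means like 1.4x, consistent with
#' covered-only averaging).
#'
#' @param summaries data.frame from [cpg_summaries()].
#' @param dedup_mode label recorded in the report
#'   (`"unique_only"`/`"all_reads"`).
#' @return list with `n_cpgs_1x`, `n_cpgs_5x`, `n_cpgs_10x`,
#'   `mean_coverage`, `dedup_mode`.
#' @export
coverage_report <- function(summaries, dedup_mode = "all_reads") {
  if (nrow(summaries) == 0L) {
    warning("no covered CpGs")
    return(list(n_cpgs_1x = 0L, n_cpgs_5x = 0L, n_cpgs_10x = 0L,
                mean_coverage = NA_real_, dedup_mode = dedup_mode))
  }
  nt <- summaries$n_total
  list(n_cpgs_1x = sum(nt >= 1L), n_cpgs_5x = sum(nt >= 5L),
       n_cpgs_10x = sum(nt >= 10L),
       mean_coverage = mean(nt[nt >= 1L]), dedup_mode = dedup_mode)
}

#' Methylation-frequency histogram in 5% bins
#'
#' Bins per-CpG methylation frequencies into `[0,5), [5,10), ..., [95,100]`
#' percent (the last bin is closed). A healthy brain methylome is strongly
#' bimodal with a reproducible small bump in the 45-50% bin.
#'
#' @param summaries data.frame from [cpg_summaries()].
#' @param bin_width_pct bin width in percentage points (default 5).
#' @return data.frame with `bin_low`, `bin_high`, `count`; counts sum to
#'   `nrow(summaries)`.
#' @export
methylation_histogram <- function(summaries, bin_width_pct = 5) {
  breaks <- seq(0, 100, by = bin_width_pct)
  pct <- 100 * summaries$frequency
  idx <- pmin(findInterval(pct, breaks), length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
             count = counts)
}

#' Coverage histogram on the log10 scale
#'
#' Histogram of `log10(n_total)` per covered CpG with fixed bin width
#' (1 on the x-axis = 10x coverage).
#'
#' @param summaries data.frame from [cpg_summaries()].
#' @param bin_width bin width on the log10 axis (default 0.1).
#' @return data.frame with `bin_low`, `bin_high`, `count` (log10 units).
#' @export
coverage_log_histogram <- function(summaries, bin_width = 0.1) {
  nt <- summaries$n_total[summaries$n_total >= 1L]
  lg <- log10(nt)
  hi <- max(1, ceiling(max(lg) / bin_width)) * bin_width
  breaks <- seq(0, hi + bin_width, by = bin_width)
  idx <- pmin(findInterval(lg, breaks), length(breaks) - 1L)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1],
             count = counts)
}

#' Select loci for the duplicate-representativeness test
#'
#' The test needs power (many unique reads) and informative sites
#' (intermediate methylation) at one read stack. Loci are the distinct
#' (contig, start, strand) stacks; kept are those with at least
#' `min_unique_reads` deduplicated reads and at least `min_diff_cpgs` CpG
#' sites whose unique-pool frequency is strictly between 0 and 1.
#'
#' @param aligned unique-status alignments.
#' @param calls data.frame from [extract_calls()] on `aligned`.
#' @param min_unique_reads minimum deduplicated reads per stack
#'   (default 11, i.e. "> 10").
#' @param min_diff_cpgs minimum differentially-methylated CpGs.
#' @return data.frame with `contig`, `start`, `strand`, `n_unique_reads`,
#'   `n_diff_cpgs`.
#' @export
select_test_loci <- function(aligned, calls, min_unique_reads = 11L,
                             min_diff_cpgs = 4L) {
  al <- aligned[aligned$status == "unique", , drop = FALSE]
  if (nrow(al) == 0L)
    return(data.frame(contig = character(0), start = integer(0),
                      strand = character(0), n_unique_reads = integer(0),
                      n_diff_cpgs = integer(0)))
  dd <- deduplicate(al)
  locus_of <- function(df) paste(df$contig, df$start, df$strand, sep = "\r")
  out <- lapply(split(seq_len(nrow(al)), locus_of(al)), function(ridx) {
    stack <- al[ridx, , drop = FALSE]
    uniq_ids <- intersect(stack$read_id, dd$kept_ids)
    if (length(uniq_ids) < min_unique_reads) return(NULL)
    sm <- cpg_summaries(calls, read_ids = uniq_ids)
    ndiff <- sum(sm$frequency > 0 & sm$frequency < 1)
    if (ndiff < min_diff_cpgs) return(NULL)
    data.frame(contig = stack$contig[1], start = stack$start[1],
               strand = stack$strand[1],
               n_unique_reads = length(uniq_ids), n_diff_cpgs = ndiff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(contig = character(0), start = integer(0),
                      strand = character(0), n_unique_reads = integer(0),
                      n_diff_cpgs = integer(0))
  rownames(out) <- NULL
  out
}

#' Correlation between unique-pool and all-read methylation frequencies
#'
#' The core duplicate-representativeness statistic: Pearson correlation r
#' between per-CpG methylation frequencies computed from deduplicated
#' reads and from all reads at the same locus, reported as r-squared with
#' a two-sided p-value from `t = r*sqrt(n-2)/sqrt(1-r^2)` on n-2 degrees
#' of freedom. A low correlation signals PCR over-amplification of some
#' fragments, i.e. duplicates should not be trusted for coverage.
#'
#' @param freq_unique,freq_all paired per-CpG frequency vectors.
#' @return list with `r_squared`, `p_value`, `n_sites`.
#' @export
dup_correlation <- function(freq_unique, freq_all) {
  if (length(freq_unique) != length(freq_all))
    stop("frequency vectors must be paired")
  n <- length(freq_unique)
  if (n < 3L) stop("need >= 3 paired CpG sites for a defined p-value")
  if (stats::sd(freq_unique) == 0 || stats::sd(freq_all) == 0) {
    warning("zero variance in a frequency vector; correlation undefined")
    return(list(r_squared = NA_real_, p_value = NA_real_, n_sites = n))
  }
  ct <- stats::cor.test(freq_unique, freq_all, method = "pearson",
                        alternative = "two.sided")
  list(r_squared = unname(ct$estimate)^2, p_value = ct$p.value, n_sites = n)
}

#' Duplicate-representativeness test at one locus
#'
#' Computes per-CpG frequencies at a read stack from its deduplicated pool
#' and from all its reads, then applies [dup_correlation()].
#'
#' @param locus_aligned unique-status alignments of one read stack.
#' @param calls calls for those reads (a superset is fine; rows are
#'   matched by read id).
#' @return list with `n_unique_reads`, `n_all_reads`, `sites`,
#'   `freq_unique`, `freq_all`, `r_squared`, `p_value`.
#' @export
duplicate_representativeness <- function(locus_aligned, calls) {
  al <- locus_aligned[locus_aligned$status == "unique", , drop = FALSE]
  dd <- deduplicate(al)
  calls <- calls[calls$read_id %in% al$read_id, , drop = FALSE]
  sm_u <- cpg_summaries(calls, read_ids = dd$kept_ids)
  sm_a <- cpg_summaries(calls)
  keyu <- paste(sm_u$contig, sm_u$site)
  keya <- paste(sm_a$contig, sm_a$site)
  common <- intersect(keyu, keya)
  if (length(common) < 3L)
    stop("fewer than 3 CpG sites with defined frequencies in both pools")
  fu <- sm_u$frequency[match(common, keyu)]
  fa <- sm_a$frequency[match(common, keya)]
  res <- dup_correlation(fu, fa)
  list(n_unique_reads = nrow(dd$unique), n_all_reads = nrow(al),
       sites = common, freq_unique = fu, freq_all = fa,
       r_squared = res$r_squared, p_value = res$p_value)
}
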