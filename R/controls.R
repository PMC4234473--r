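#' Bundled imprinted-region reference table
#'
#' Control CpG islands with expected brain methylation percentages:
#' imprinted regions (parent-of-origin monoallelic methylation, expected
#' mid-level values with narrow between-subject spread) and two
#' housekeeping promoters expected near zero. Intervals are converted to
#' the package's 0-based half-open convention. The sperm column is
#' annotation only (imprinting is tissue-specific) and is never used in
#' pass/fail logic.
#'
#' @return data.frame with columns `gene`, `contig`, `start`, `end`
#'   (0-based half-open), `polarity`, per-subject percentages, `sperm_pct`,
#'   `expected_mean_pct`, `expected_sd_pct`.
#' @export
imprinted_reference <- function() {
  path <- system.file("extdata", "imprinted_controls_hg19.tsv",
                      package = "rrbsqc", mustWork = TRUE)
  x <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE)
  x$start <- x$start_hg19 - 1L
  x$end <- x$end_hg19
  x
}

#' Region-level methylation summary
#'
#' Aggregates per-CpG counts over a genomic interval. The default percent
#' is coverage-weighted (total methylated calls over total calls); the
#' unweighted mean of per-CpG frequencies is available via `mode`.
#'
#' @param summaries data.frame from [cpg_summaries()].
#' @param region list or one-row data.frame with `name` (or `gene`),
#'   `contig`, `start`, `end` (0-based half-open).
#' @param mode `"coverage_weighted"` or `"mean_of_freqs"`.
#' @return list with `name`, `pct_methylation`, `n_cpgs_covered`,
#'   `mean_cov_per_cpg`, `defined` (FALSE when no CpG is covered).
#' @export
region_summary <- function(summaries, region,
                           mode = c("coverage_weighted", "mean_of_freqs")) {
  mode <- match.arg(mode)
  nm <- if (!is.null(region$name)) region$name else region$gene
  inside <- summaries$contig == region$contig &
    summaries$site >= region$start & summaries$site < region$end &
    summaries$n_total >= 1L
  sm <- summaries[inside, , drop = FALSE]
  if (nrow(sm) == 0L) {
    warning("no covered CpG in region ", nm)
    return(list(name = nm, pct_methylation = NA_real_,
                n_cpgs_covered = 0L, mean_cov_per_cpg = NA_real_,
                defined = FALSE))
  }
  pct <- if (mode == "coverage_weighted")
    100 * sum(sm$n_methylated) / sum(sm$n_total)
  else 100 * mean(sm$frequency)
  list(name = nm, pct_methylation = pct, n_cpgs_covered = nrow(sm),
       mean_cov_per_cpg = mean(sm$n_total), defined = TRUE)
}

#' Check an observed region summary against its expectation
#'
#' Passes iff the observed percent lies within `k_sd` reference SDs of the
#' reference mean (with an SD floor so near-zero-variance references do
#' not flag trivially); regions expected unmethylated additionally require
#' the percent to stay below a ceiling. Large deviations at imprinted
#' regions suggest alignment or conversion problems.
#'
#' @param summary result of [region_summary()].
#' @param region one row of [imprinted_reference()] (or any list with
#'   `expected_mean_pct`, `expected_sd_pct`, `polarity`).
#' @param k_sd tolerance in SD units (default 3).
#' @param floor_sd minimum SD, percentage points (default 1).
#' @param low_ceiling ceiling for `unmethylated_low` regions (default 5).
#' @return list with `pass`, `message`.
#' @export
control_check <- function(summary, region, k_sd = 3, floor_sd = 1,
                          low_ceiling = 5) {
  if (!isTRUE(summary$defined))
    return(list(pass = FALSE, message = paste0(summary$name,
                ": no covered CpGs; cannot assess")))
  dev <- abs(summary$pct_methylation - region$expected_mean_pct)
  tol <- k_sd * max(region$expected_sd_pct, floor_sd)
  pass <- dev <= tol
  if (pass && identical(region$polarity, "unmethylated_low"))
    pass <- summary$pct_methylation <= low_ceiling
  msg <- sprintf("%s: observed %.1f%% vs expected %.1f%% +/- %.1f (k=%g): %s",
                 summary$name, summary$pct_methylation,
                 region$expected_mean_pct, region$expected_sd_pct, k_sd,
                 if (pass) "pass" else "FLAG")
  list(pass = pass, message = msg)
}

#' Mitochondrial negative control
#'
#' Mammalian MT genomes are unmethylated, so on the MT contig every
#' cytosine - CpG context included - should convert; this gives an
#' all-context conversion-rate estimate (unlike the genome-wide estimator,
#' which must exclude CpG). Residual CpG-context methylation above the
#' threshold is flagged.
#'
#' @param calls data.frame from [extract_calls()].
#' @param mt_contig name of the mitochondrial contig.
#' @param max_cpg_meth_pct flag threshold on CpG-context methylation
#'   (default 2).
#' @return list with `n_calls`, `conversion_rate_pct` (all contexts),
#'   `cpg_meth_pct`, `flag`.
#' @export
mt_negative_control <- function(calls, mt_contig = "chrM",
                                max_cpg_meth_pct = 2) {
  mt <- calls[calls$contig == mt_contig, , drop = FALSE]
  if (nrow(mt) == 0L) {
    warning("no calls on MT contig '", mt_contig, "'")
    return(list(n_calls = 0L, conversion_rate_pct = NA_real_,
                cpg_meth_pct = NA_real_, flag = FALSE))
  }
  conv <- 100 * mean(mt$state == "converted")
  cg <- mt[mt$context == "CpG", , drop = FALSE]
  cpg_meth <- if (nrow(cg) > 0L) 100 * mean(cg$state == "methylated")
              else NA_real_
  flag <- !is.na(cpg_meth) && cpg_meth > max_cpg_meth_pct
  list(n_calls = nrow(mt), conversion_rate_pct = conv,
       cpg_meth_pct = cpg_meth, flag = flag)
}

#' Per-library lane fraction under equimolar pooling with spike-in
#'
#' With `n` bisulfite libraries pooled equimolar and a non-bisulfite
#' spike-in fraction `s`, each library occupies `100*(1-s)/n` percent of
#' the lane (e.g. 4 libraries at 30% spike-in: 17.5% each).
#'
#' @param n_bis_libraries number of bisulfite libraries (>= 1).
#' @param spike_in_fraction non-bisulfite spike-in fraction in `[0,1)`.
#' @return per-library percentage of the lane.
#' @export
lane_fractions <- function(n_bis_libraries, spike_in_fraction = 0) {
  if (n_bis_libraries < 1L) stop("n_bis_libraries must be >= 1")
  if (spike_in_fraction < 0 || spike_in_fraction >= 1)
    stop("spike_in_fraction must be in [0,1)")
  100 * (1 - spike_in_fraction) / n_bis_libraries
}

#' Base diversity of the first read positions
#'
#' Shannon entropy (bits) over {A,C,G,T} per position. Pure RRBS reads are
#' monomorphic G at positions 2-3 (entropy 0), which degrades cluster
#' calling; spiking in non-bisulfite DNA with balanced base content
#' restores diversity (maximum 2 bits).
#'
#' @param reads data.frame with a `sequence` column, or a character vector.
#' @param n_positions number of leading positions to assess (default 3).
#' @return numeric vector of entropies, one per position.
#' @export
first_bases_diversity <- function(reads, n_positions = 3L) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  seqs <- seqs[nchar(seqs) >= n_positions]
  if (length(seqs) == 0L) stop("no reads of length >= n_positions")
  vapply(seq_len(n_positions), function(p) {
    b <- substr(seqs, p, p)
    cnt <- table(factor(b, levels = c("A", "C", "G", "T")))
    pr <- cnt / sum(cnt)
    pr <- pr[pr > 0]
    -sum(pr * log2(pr))
  }, numeric(1))
}

#' Bundled protocol oligo table
#'
#' @return data.frame with `name` and annotated `sequence` columns.
#' @export
load_oligos <- function() {
  path <- system.file("extdata", "protocol_oligos.tsv",
                      package = "rrbsqc", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Strip annotation characters from an oligo sequence
#'
#' Removes methylation bold markers and index asterisks (`*`), the 5'
#' phosphate (`p-`), the 3' hydroxyl (`-OH`) and phosphorothioate bonds
#' (`s`), leaving the plain nucleotide string.
#'
#' @param seq annotated oligo sequence(s).
#' @return cleaned sequence(s).
#' @export
clean_oligo <- function(seq) {
  x <- gsub("*", "", seq, fixed = TRUE)
  x <- sub("^p-", "", x)
  x <- sub("-OH$", "", x)
  gsub("s", "", x, fixed = TRUE)
}

#' Nucleotide lengths of oligos
#'
#' @param oligos data.frame from [load_oligos()] (default: bundled table).
#' @return named integer vector of cleaned lengths.
#' @export
oligo_lengths <- function(oligos = load_oligos()) {
  stats::setNames(nchar(clean_oligo(oligos$sequence)), oligos$name)
}

#' Adaptor-dimer amplicon length
#'
#' Length of the dimer formed by the two annealed adaptor oligos; the
#' two-step design yields a 65 bp dimer, small enough to remove with spin
#' columns.
#'
#' @param oligos data.frame from [load_oligos()].
#' @param pe1,pe2 names of the two adaptor oligos.
#' @return integer length in bp.
#' @export
adaptor_dimer_length <- function(oligos = load_oligos(),
                                 pe1 = "mC-PE1", pe2 = "mC-PE2") {
  len <- oligo_lengths(oligos)
  if (!all(c(pe1, pe2) %in% names(len)))
    stop("adaptor oligo(s) not found in table")
  unname(len[pe1] + len[pe2])
}

#' Extract the 6-nt sample index from an indexing primer
#'
#' The index sits between two constant flanks in every Index_#R primer.
#'
#' @param seq annotated or cleaned primer sequence(s).
#' @param flank5,flank3 constant flanking sequences.
#' @return character vector of index sequences.
#' @export
extract_index <- function(seq,
                          flank5 = "CAAGCAGAAGACGGCATACGAGAT",
                          flank3 = "GTGACTGGAGTTC") {
  x <- clean_oligo(seq)
  pat <- paste0(flank5, "([ACGT]+)", flank3)
  m <- regmatches(x, regexec(pat, x))
  idx <- vapply(m, function(g) if (length(g) == 2L) g[2] else NA_character_,
                character(1))
  if (anyNA(idx))
    stop("index flanks not found in sequence(s): ",
         paste(x[is.na(idx)], collapse = ", "))
  idx
}
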