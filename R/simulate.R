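#' Bimodal methylome profile
#'
#' Describes the mixture from which per-CpG methylation levels are drawn.
#' Adult brain methylomes are strongly bimodal: with the defaults, 60% of
#' CpGs fall in a low mode below 5% methylation, 27.5% in a high mode above
#' 95%, a small bump (2%) sits in the 45--50% bin (imprinted-like loci are
#' 2-3x enriched there relative to neighboring bins), and the remainder is
#' uniform in between.
#'
#' @param frac_low proportion of CpGs in the low mode.
#' @param frac_high proportion in the high mode.
#' @param low_max upper bound of the low mode.
#' @param high_min lower bound of the high mode.
#' @param mid_bump_weight extra mass placed uniformly on `[0.45, 0.50)`.
#' @param seed integer seed used by [sample_methylome()].
#' @return a `methylome_profile` list.
#' @export
methylome_profile <- function(frac_low = 0.60, frac_high = 0.275,
                              low_max = 0.05, high_min = 0.95,
                              mid_bump_weight = 0.02, seed = 1L) {
  if (frac_low < 0 || frac_high < 0 || mid_bump_weight < 0 ||
      frac_low + frac_high + mid_bump_weight > 1)
    stop("mixture weights must be non-negative and sum to <= 1")
  if (!(low_max > 0 && low_max < high_min && high_min < 1))
    stop("need 0 < low_max < high_min < 1")
  structure(list(frac_low = frac_low, frac_high = frac_high,
                 low_max = low_max, high_min = high_min,
                 mid_bump_weight = mid_bump_weight, seed = as.integer(seed)),
            class = "methylome_profile")
}

#' Sample a synthetic methylome
#'
#' Assigns each CpG site an independent methylation level drawn from the
#' mixture described by the profile. Deterministic given `profile$seed`.
#'
#' @param sites data.frame from [find_cpg_sites()].
#' @param profile a [methylome_profile()].
#' @return data.frame with columns `contig`, `pos`, `level`.
#' @export
sample_methylome <- function(sites, profile = methylome_profile()) {
  stopifnot(inherits(profile, "methylome_profile"))
  if (nrow(sites) == 0L) stop("sites must be non-empty")
  n <- nrow(sites)
  p <- profile
  with_seed(p$seed, {
    comp <- sample(c("low", "high", "mid", "rest"), n, replace = TRUE,
                   prob = c(p$frac_low, p$frac_high, p$mid_bump_weight,
                            1 - p$frac_low - p$frac_high - p$mid_bump_weight))
    u <- stats::runif(n)
    level <- numeric(n)
    level[comp == "low"] <- u[comp == "low"] * p$low_max
    level[comp == "high"] <- p$high_min + u[comp == "high"] * (1 - p$high_min)
    level[comp == "mid"] <- 0.45 + u[comp == "mid"] * 0.05
    level[comp == "rest"] <- p$low_max +
      u[comp == "rest"] * (p$high_min - p$low_max)
    data.frame(contig = sites$contig, pos = sites$pos, level = level,
               stringsAsFactors = FALSE)
  })
}

#' Simulation configuration
#'
#' Parameters of the directional RRBS read simulator. Defaults emulate a
#' single-end 50-cycle run: constant phred-37 qualities, a 1% bisulfite
#' conversion failure rate (real libraries convert at 97-99%), equal
#' original-top/original-bottom sampling, and unbiased PCR duplication
#' (each molecule gains `Geometric(dup_geometric_p)` identical extra
#' copies). Setting `dup_length_bias`/`dup_c_bias` > 0 tilts duplication
#' toward short and cytosine-poor fragments via the multiplicative factor
#' `exp(-a*(len-150)/250 - b*retainedC)` on the per-copy probability,
#' creating the PCR over-amplification failure mode the representativeness
#' test is designed to catch.
#'
#' @param read_length bases sequenced per read (>= 20).
#' @param conversion_failure probability an unmethylated C escapes
#'   conversion and is read as C.
#' @param seq_error_rate per-base substitution probability.
#' @param ot_fraction probability a molecule is read from the original-top
#'   strand.
#' @param depth mean molecules per fragment (Poisson).
#' @param dup_geometric_p success parameter of the PCR copy-number law.
#' @param dup_length_bias,dup_c_bias bias coefficients (see above).
#' @param phred constant quality assigned to every base.
#' @param include_terminal also sequence chromosome-terminal fragments
#'   (default FALSE: only MspI-flanked inserts receive adaptors).
#' @param seed integer; the single source of randomness.
#' @return a `sim_config` list.
#' @export
sim_config <- function(read_length = 50L, conversion_failure = 0.01,
                       seq_error_rate = 0.001, ot_fraction = 0.5,
                       depth = 20, dup_geometric_p = 0.5,
                       dup_length_bias = 0, dup_c_bias = 0,
                       phred = 37L, include_terminal = FALSE, seed = 1L) {
  probs <- c(conversion_failure, seq_error_rate, ot_fraction)
  if (any(probs < 0) || any(probs > 1) || conversion_failure >= 1)
    stop("probabilities must lie in [0,1] (conversion_failure < 1)")
  if (read_length < 20L) stop("read_length must be >= 20")
  if (depth <= 0) stop("depth must be > 0")
  if (dup_geometric_p <= 0 || dup_geometric_p > 1)
    stop("dup_geometric_p must be in (0,1]")
  structure(list(read_length = as.integer(read_length),
                 conversion_failure = conversion_failure,
                 seq_error_rate = seq_error_rate, ot_fraction = ot_fraction,
                 depth = depth, dup_geometric_p = dup_geometric_p,
                 dup_length_bias = dup_length_bias, dup_c_bias = dup_c_bias,
                 phred = as.integer(phred),
                 include_terminal = isTRUE(include_terminal),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate directional bisulfite RRBS reads
#'
#' Embodies the two-step directional library model: every molecule is read
#' from either the original top (OT) strand, starting at the fragment's
#' left MspI end, or the original bottom (OB) strand, starting at the right
#' MspI end, so all reads begin `CGG` (site CpG methylated) or `TGG`
#' (converted). Per molecule, each CpG cytosine on the sequenced strand is
#' methylated with the methylome's level at its site; every unmethylated
#' and non-CpG cytosine converts to T except with probability
#' `conversion_failure`; sequencing errors substitute a different base per
#' position; PCR duplication then emits extra byte-identical copies. Reads
#' are truncated (never padded) to the fragment length.
#'
#' @param fragments data.frame from [mspi_digest()] (optionally
#'   [size_select()]ed).
#' @param methylome data.frame from [sample_methylome()].
#' @param cfg a [sim_config()].
#' @return list of class `rrbs_sim` with elements `reads` (data.frame
#'   `read_id`, `sequence`, `quality`) and `truth` (per-read metadata:
#'   placement, strand of origin, per-CpG states as
#'   `"pos=M"`/`"pos=U"` comma strings, conversion-failure and error
#'   counts, template molecule id and PCR-duplicate flag).
#' @export
simulate_reads <- function(fragments, methylome, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  frs <- if (cfg$include_terminal) fragments
         else fragments[fragments$flanked_both_ends, , drop = FALSE]
  empty <- list(
    reads = data.frame(read_id = character(0), sequence = character(0),
                       quality = character(0), stringsAsFactors = FALSE),
    truth = data.frame())
  class(empty) <- "rrbs_sim"
  if (nrow(frs) == 0L) return(empty)
  lv <- stats::setNames(methylome$level,
                        paste0(methylome$contig, ":", methylome$pos))
  qchar <- intToUtf8(33L + cfg$phred)

  with_seed(cfg$seed, {
    nmol <- stats::rpois(nrow(frs), cfg$depth)
    mol_frag <- rep(seq_len(nrow(frs)), nmol)
    ntot <- length(mol_frag)
    if (ntot == 0L) return(empty)
    is_ot <- stats::runif(ntot) < cfg$ot_fraction

    groups <- vector("list", 2L * nrow(frs))
    gi <- 0L
    idx_by_frag <- split(seq_len(ntot), factor(mol_frag, seq_len(nrow(frs))))
    for (fi in seq_len(nrow(frs))) {
      topseq <- frs$sequence[fi]
      len <- nchar(topseq)
      m <- min(cfg$read_length, len)
      contig <- frs$contig[fi]
      fstart <- frs$start[fi]
      for (ot in c(TRUE, FALSE)) {
        mols <- idx_by_frag[[fi]][is_ot[idx_by_frag[[fi]]] == ot]
        k <- length(mols)
        if (k == 0L) next
        stext <- if (ot) topseq else revcomp(topseq)
        tchars <- strsplit(substr(stext, 1L, m), "", fixed = TRUE)[[1]]
        cpos <- which(tchars == "C")
        kc <- length(cpos)
        nextch <- substring(stext, cpos + 1L, cpos + 1L)
        is_cpg <- nextch == "G"
        j0 <- cpos - 1L
        site <- if (ot) fstart + j0 else fstart + len - 2L - j0
        lvl <- rep(0, kc)
        if (any(is_cpg)) {
          got <- lv[paste0(contig, ":", site[is_cpg])]
          got[is.na(got)] <- 0
          lvl[is_cpg] <- got
        }
        mat <- matrix(rep(tchars, each = k), nrow = k)
        n_conv_fail <- integer(k)
        states_str <- rep("", k)
        retained_c <- integer(k)
        if (kc > 0L) {
          meth <- matrix(stats::runif(k * kc), k, kc) <
            matrix(lvl, k, kc, byrow = TRUE)
          fail <- matrix(stats::runif(k * kc), k, kc) <
            cfg$conversion_failure
          as_c <- meth | fail
          mat[, cpos] <- ifelse(as_c, "C", "T")
          n_conv_fail <- rowSums(!meth & fail)
          retained_c <- rowSums(as_c)
          if (any(is_cpg)) {
            sc <- site[is_cpg]
            mm <- meth[, is_cpg, drop = FALSE]
            states_str <- vapply(seq_len(k), function(r) {
              paste0(sc, "=", ifelse(mm[r, ], "M", "U"), collapse = ",")
            }, character(1))
          }
        }
        n_seq_err <- integer(k)
        if (cfg$seq_error_rate > 0) {
          errm <- matrix(stats::runif(k * m), k, m) < cfg$seq_error_rate
          ne <- sum(errm)
          if (ne > 0L) {
            bases <- c("A", "C", "G", "T")
            cur <- mat[errm]
            mat[errm] <- vapply(cur, function(b)
              sample(bases[bases != b], 1L), character(1))
          }
          n_seq_err <- rowSums(errm)
        }
        seqs <- do.call(paste0, split(mat, col(mat)))
        # PCR duplication: per-copy probability tilted by fragment length
        # and retained-C content
        d0 <- 1 - cfg$dup_geometric_p
        f <- exp(-cfg$dup_length_bias * (len - 150) / 250 -
                 cfg$dup_c_bias * retained_c)
        d <- pmin(pmax(d0 * f, 0), 0.99)
        extra <- stats::rgeom(k, 1 - d)
        rep_idx <- rep(seq_len(k), extra + 1L)
        is_dup <- sequence(extra + 1L) > 1L
        rstart <- if (ot) fstart else fstart + len - m
        gi <- gi + 1L
        groups[[gi]] <- data.frame(
          sequence = seqs[rep_idx],
          contig = contig,
          read_start = rstart,
          read_end = rstart + m,
          strand = if (ot) "OT" else "OB",
          frag_start = fstart, frag_end = frs$end[fi],
          meth_states = states_str[rep_idx],
          n_conv_fail = n_conv_fail[rep_idx],
          n_seq_err = n_seq_err[rep_idx],
          template_id = mols[rep_idx],
          is_pcr_dup = is_dup,
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, groups[seq_len(gi)])
    rownames(truth) <- NULL
    ids <- sprintf("read_%07d", seq_len(nrow(truth)))
    reads <- data.frame(read_id = ids, sequence = truth$sequence,
                        quality = strrep(qchar, nchar(truth$sequence)),
                        stringsAsFactors = FALSE)
    truth <- cbind(read_id = ids, truth[, setdiff(names(truth), "sequence")],
                   stringsAsFactors = FALSE)
    structure(list(reads = reads, truth = truth), class = "rrbs_sim")
  })
}

#' Write reads to FASTQ (phred+33)
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qs <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$sequence),
    Biostrings::PhredQuality(reads$quality))
  names(qs) <- reads$read_id
  # Biostrings warns about dropping its own internal quality mcols here;
  # the qualities are written, so the warning is noise
  withCallingHandlers(
    Biostrings::writeQualityScaledXStringSet(qs, path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  invisible(path)
}

#' Read a FASTQ file (phred+33)
#'
#' @param path FASTQ path.
#' @return data.frame with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  data.frame(read_id = unname(sub("\\s.*$", "", names(x))),
             sequence = unname(as.character(x)),
             quality = unname(as.character(Biostrings::quality(x))),
             stringsAsFactors = FALSE)
}

# phred integer vectors from a phred+33 quality string vector
phred_ints <- function(quality) {
  lapply(quality, function(q) utf8ToInt(q) - 33L)
}
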