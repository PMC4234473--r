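# Shared fixture builders. Everything is generated in code at test time.

# A small simulated dataset used by several module tests.
sim_fixture <- function(genome_len = 50000L, genome_seed = 42L,
                        meth_seed = 7L, cfg = NULL) {
  genome <- random_genome(c(chr1 = genome_len), seed = genome_seed)
  fragments <- size_select(mspi_digest(genome))
  sites <- find_cpg_sites(genome)
  methylome <- sample_methylome(sites, methylome_profile(seed = meth_seed))
  if (is.null(cfg)) cfg <- sim_config(depth = 20, seed = 11L)
  sim <- simulate_reads(fragments, methylome, cfg)
  list(genome = genome, fragments = fragments, sites = sites,
       methylome = methylome, cfg = cfg, sim = sim)
}

# Explode the truth table's per-CpG state strings ("pos=M,pos=U,...") into
# one row per (read, site).
explode_truth_states <- function(truth) {
  has <- nzchar(truth$meth_states)
  tr <- truth[has, , drop = FALSE]
  parts <- strsplit(tr$meth_states, ",", fixed = TRUE)
  nper <- lengths(parts)
  kv <- strsplit(unlist(parts, use.names = FALSE), "=", fixed = TRUE)
  data.frame(read_id = rep(tr$read_id, nper),
             contig = rep(tr$contig, nper),
             template_id = rep(tr$template_id, nper),
             is_pcr_dup = rep(tr$is_pcr_dup, nper),
             site = as.integer(vapply(kv, `[`, "", 1L)),
             methylated = vapply(kv, `[`, "", 2L) == "M",
             stringsAsFactors = FALSE)
}

# Hand-built alignment rows for meth-qc tests that need exact control over
# positions/sequences without running the aligner.
make_aligned <- function(contig, start, strand, sequence,
                         read_id = sprintf("r%03d", seq_along(start))) {
  data.frame(read_id = read_id, status = "unique", contig = contig,
             start = start, end = start + nchar(sequence), strand = strand,
             mismatches = 0L, sequence = sequence,
             quality = strrep("F", nchar(sequence)),
             stringsAsFactors = FALSE)
}
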