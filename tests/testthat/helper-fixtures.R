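# Shared fixtures, built once per test run. Everything is generated in code;
# no files ship with the tests.

# The study panel (deterministic for seed 1) used across test files.
fx_panel <- build_panel(panel_config(), seed = 1)

# A tiny generic panel: 3 random amplicons, two target SNPs on amp01.
fx_generic_panel <- build_panel(
  panel_config(n_amplicons = 3, length_range = c(350, 450),
               amplicon_defs = NULL, alternate_reference = FALSE,
               target_snps = data.frame(amplicon = c("amp01", "amp01"),
                                        offset = c(100L, 250L),
                                        ref = c("A", "C"),
                                        alt = c("G", "T"))),
  seed = 7
)

# Small cohort pushed through simulate -> demux -> trim -> align, reused by
# the alignment/pileup and genotype tests. Error-free so that truth-table
# checks are exact.
fx_cohort <- local({
  pops <- default_populations(c(Bayamon = 4L, Ponce = 4L))
  gs <- combine_genotypes(lapply(seq_along(pops), function(i)
    simulate_genotypes(fx_panel, pops[[i]], seed = 20 + i)))
  sheet <- build_sample_sheet(gs, seed = 3)
  spec <- read_sim_spec(mean_coverage = 30, coverage_dispersion = 0,
                        substitution_error_rate = 0, mistag_rate = 0,
                        min_pool_reads = 1)
  sim <- simulate_reads(fx_panel, gs, spec, sheet, seed = 4)
  dmx <- demultiplex(sim$reads, sheet)
  trm <- trim_reads(dmx$assigned)
  idx <- build_ref_index(fx_panel)
  aligned <- align_reads(pairs_to_mates(trm$reads), fx_panel, index = idx)
  list(genotypes = gs, sheet = sheet, sim = sim, demux = dmx,
       trimmed = trm, aligned = aligned, index = idx)
})

# Brute-force alignment oracle: best ungapped placement of a read over every
# amplicon (and alternate reference), every offset, both strands; returns the
# minimum mismatch count over full-overlap placements.
brute_force_align <- function(seq, panel) {
  best <- list(mm = Inf, amplicon = NA)
  refs <- panel$amplicons$sequence
  names(refs) <- panel$amplicons$amplicon_id
  alts <- panel$amplicons$alt_sequence
  ok <- !is.na(alts)
  if (any(ok)) {
    a <- alts[ok]
    names(a) <- panel$amplicons$amplicon_id[ok]
    refs <- c(refs, a)
  }
  for (orient in c(seq, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq))))) {
    n <- nchar(orient)
    rr <- charToRaw(orient)
    for (ai in seq_along(refs)) {
      L <- nchar(refs[ai])
      if (L < n) next
      ref_raw <- charToRaw(refs[ai])
      for (off in 0:(L - n)) {
        mm <- sum(rr != ref_raw[(off + 1):(off + n)])
        if (mm < best$mm) best <- list(mm = mm, amplicon = names(refs)[ai])
      }
    }
  }
  best
}
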