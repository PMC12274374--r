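test_that("likelihood caller matches the closed-form binomial posterior", {
  expect_equal(call_genotype_likelihood(100, 0)$genotype, "hom_ref")
  expect_equal(call_genotype_likelihood(48, 52)$genotype, "het")
  expect_equal(call_genotype_likelihood(0, 100)$genotype, "hom_alt")
  low <- call_genotype_likelihood(4, 3)
  expect_equal(low$genotype, "no_call")
  expect_equal(low$reason, "low_depth")

  # posterior and decision equal a direct enumeration of the three pmfs
  e <- 0.01
  set.seed(14)
  for (i in 1:50) {
    d <- sample(10:200, 1)
    k <- sample(0:d, 1)
    got <- call_genotype_likelihood(d - k, k, error_rate = e)
    lik <- dbinom(k, d, c(e, 0.5, 1 - e))
    post <- lik / sum(lik)
    o <- order(post, decreasing = TRUE)
    want <- if (post[o[1]] / post[o[2]] < 10) "no_call"
            else c("hom_ref", "het", "hom_alt")[o[1]]
    expect_equal(got$genotype, want)
    if (!is.null(got$posteriors)) expect_equal(got$posteriors, post)
  }
})

test_that("threshold caller bands and gap zones behave as stated", {
  f <- function(af, d = 100) {
    k <- round(af * d)
    call_genotype_threshold(d - k, k)$genotype
  }
  expect_equal(f(0), "hom_ref")
  expect_equal(f(0.05), "hom_ref")
  expect_equal(f(0.10), "no_call")    # gap zone [0.1, 0.2)
  expect_equal(f(0.20), "het")
  expect_equal(f(0.50), "het")
  expect_equal(f(0.80), "het")
  expect_equal(f(0.85), "no_call")    # gap zone (0.8, 0.9]
  expect_equal(f(0.90), "no_call")
  expect_equal(f(0.95), "hom_alt")
  expect_equal(call_genotype_threshold(3, 2)$reason, "low_depth")
})

test_that("consensus is the strict intersection of the two callers", {
  a <- call_genotype_likelihood(50, 50, pos = 10L)
  b <- call_genotype_threshold(50, 50, pos = 10L)
  cc <- consensus_call(a, b)
  expect_equal(cc$genotype, "het")
  expect_true(cc$agreement)

  hom <- call_genotype_likelihood(0, 100, pos = 10L)
  cc2 <- consensus_call(a, hom)
  expect_equal(cc2$genotype, "no_call")
  expect_equal(cc2$reason, "discordant")

  nc <- call_genotype_likelihood(2, 1, pos = 10L)
  cc3 <- consensus_call(a, nc)
  expect_equal(cc3$genotype, "no_call")

  other <- call_genotype_threshold(50, 50, pos = 11L)
  expect_error(consensus_call(a, other), "different positions")
})

test_that("sample QC applies the 6-of-10 covered-amplicon rule", {
  fake <- function(n) structure(list(n_covered = n, min_depth = 5,
                                     table = NULL),
                                class = "coverage_summary")
  expect_true(sample_qc(fake(6)))
  expect_false(sample_qc(fake(5)))
  expect_true(sample_qc(fake(10)))
})

test_that("variant annotation covers all effect classes and is involutive", {
  p <- fx_panel
  a <- annotate_variant(p, "3", 315939224, "A", "C")
  expect_equal(a[c("codon", "aa_ref", "aa_alt", "effect")],
               list(codon = 1534L, aa_ref = "F", aa_alt = "C",
                    effect = "missense"))

  # third-position change preserving the amino acid: rdl codon 301 GCT->GCC
  syn <- annotate_variant(p, "2", 41847792, "T", "C")
  expect_equal(syn$effect, "synonymous")
  expect_equal(syn$codon, 301L)

  expect_equal(annotate_variant(p, "3", 315983900, "A", "C")$effect,
               "intronic")
  expect_equal(annotate_variant(p, "3", 315983784, "A", "C")$effect,
               "splice_region")
  expect_equal(annotate_variant(p, "3", 315931943, "G", "A")$effect,
               "stop_class")
  expect_error(annotate_variant(p, "9", 1, "A", "C"), "outside panel")

  # involution: annotating with the alleles swapped names the same codon
  # (and warns that the stated ref is not the panel reference base)
  fwd <- annotate_variant(p, "3", 316080722, "C", "A")
  bwd <- suppressWarnings(annotate_variant(p, "3", 316080722, "A", "C"))
  expect_warning(annotate_variant(p, "3", 316080722, "A", "C"), "ref allele")
  expect_equal(fwd$codon, bwd$codon)
  expect_equal(fwd$codon_pos, bwd$codon_pos)
})

test_that("nomenclature mapping is a reversible lookup", {
  expect_equal(map_nomenclature("vgsc", 910L, "L910I"), "L944I")
  expect_equal(map_nomenclature("rdl", 301L, "A301S"), "A296S")
  expect_equal(map_nomenclature("vgsc", 1534L, "F1534C"), "F1534C")
  expect_equal(map_nomenclature("vgsc", 910L, "L944I",
                                direction = "to_native"), "L910I")
  # round trip over the whole table
  tab <- nomenclature_table()
  for (i in seq_len(nrow(tab))) {
    f <- map_nomenclature(tab$gene[i], tab$codon[i], tab$native_name[i])
    expect_equal(map_nomenclature(tab$gene[i], tab$codon[i], f,
                                  direction = "to_native"),
                 tab$native_name[i])
  }
})

# helper: fabricate aligned reads spanning codon 1016 with given haplotype
# bases at (315983762, 315983763), plus matching calls
mk_1016 <- function(hap_counts, genotypes) {
  amp <- fx_panel$amplicons[fx_panel$amplicons$amplicon_id == "vgsc_1016", ]
  base_seq <- amp$sequence
  reads <- do.call(rbind, lapply(seq_along(hap_counts), function(h) {
    bases <- strsplit(names(hap_counts)[h], "")[[1]]
    s <- substr(base_seq, 1, 150)
    substr(s, 315983762 - amp$start + 1, 315983762 - amp$start + 1) <- bases[1]
    substr(s, 315983763 - amp$start + 1, 315983763 - amp$start + 1) <- bases[2]
    if (hap_counts[h] == 0) return(NULL)
    data.frame(read_id = sprintf("h%d_%d", h, seq_len(hap_counts[h])),
               amplicon_id = "vgsc_1016", offset = 0L,
               aligned_len = 150L, seq_plus = s, pass = TRUE,
               stringsAsFactors = FALSE)
  }))
  calls <- data.frame(
    snp_id = c("V1016G", "V1016I"),
    pos = c(315983762L, 315983763L),
    ref = c("A", "C"), alt = c("C", "T"),
    genotype = genotypes, stringsAsFactors = FALSE
  )
  list(aligned = reads, calls = calls)
}

test_that("codon-1016 phasing resolves homozygotes and compound heterozygotes", {
  # V1016I homozygote: alt only at 315983763 -> Ile/Ile
  x <- mk_1016(c(AT = 10), c("hom_ref", "hom_alt"))
  ph <- resolve_codon_phase(fx_panel, "vgsc_1016", 1016L, x$calls, x$aligned)
  expect_equal(ph$status, "resolved")
  expect_equal(ph$aa, c("I", "I"))

  # trans double het: reads support CC (Gly) and AT (Ile) haplotypes
  y <- mk_1016(c(CC = 6, AT = 7), c("het", "het"))
  ph2 <- resolve_codon_phase(fx_panel, "vgsc_1016", 1016L, y$calls, y$aligned)
  expect_equal(ph2$status, "resolved")
  expect_setequal(ph2$aa, c("G", "I"))
  expect_setequal(ph2$haplotype_names, c("V1016G", "V1016I"))
  expect_equal(sort(ph2$support), c(6L, 7L))

  # no variant in the codon: wild type / wild type
  z <- mk_1016(c(AC = 8), c("hom_ref", "hom_ref"))
  ph3 <- resolve_codon_phase(fx_panel, "vgsc_1016", 1016L, z$calls, z$aligned)
  expect_equal(ph3$status, "wildtype")
  expect_equal(ph3$aa, c("V", "V"))

  # multi-variant codon without spanning reads: unresolved, unphased aa kept
  ph4 <- resolve_codon_phase(fx_panel, "vgsc_1016", 1016L, y$calls,
                             y$aligned[0, ])
  expect_equal(ph4$status, "unresolved")
  expect_setequal(ph4$haplotype_names, c("V1016G", "V1016I"))
})

test_that("consensus genotyping is near-perfect in the validated regime", {
  # depth ~60, 0.5% error: >= 99% of sample x locus consensus calls match
  # the simulated truth, and the two callers agree on >= 95% of calls
  pops <- default_populations(c(Bayamon = 5L, Dorado = 5L))
  gs <- combine_genotypes(lapply(1:2, function(i)
    simulate_genotypes(fx_panel, pops[[i]], seed = 60 + i)))
  sheet <- build_sample_sheet(gs, seed = 63)
  spec <- read_sim_spec(mean_coverage = 60, coverage_dispersion = 0,
                        substitution_error_rate = 0.005, mistag_rate = 0,
                        min_pool_reads = 1)
  sim <- simulate_reads(fx_panel, gs, spec, sheet, seed = 64)
  dmx <- demultiplex(sim$reads, sheet)
  trm <- trim_reads(dmx$assigned)
  idx <- fx_cohort$index
  acc <- agree <- 0L; tot <- 0L
  for (s in sheet$sample_id) {
    mates <- pairs_to_mates(trm$reads[trm$reads$sample_id == s, ])
    al <- align_reads(mates, fx_panel, index = idx)
    pl <- build_pileup(al, fx_panel)
    calls <- call_sample_genotypes(pl, fx_panel)
    truth <- gs$geno[match(s, gs$sample_ids), calls$snp_id]
    want <- c("hom_ref", "het", "hom_alt")[truth + 1L]
    acc <- acc + sum(calls$genotype == want)
    agree <- agree + sum(calls$gt_likelihood == calls$gt_threshold)
    tot <- tot + nrow(calls)
  }
  expect_gte(acc / tot, 0.99)
  expect_gte(agree / tot, 0.95)
})

test_that("the VCF writer emits parseable records that match the calls", {
  pl <- build_pileup(fx_cohort$aligned[
    fx_cohort$aligned$sample_id == fx_cohort$sheet$sample_id[1], ], fx_panel)
  calls <- call_sample_genotypes(pl, fx_panel)
  calls$sample_id <- fx_cohort$sheet$sample_id[1]
  f <- tempfile(fileext = ".vcf")
  write_vcf(calls, fx_panel, f)
  v <- suppressWarnings(vcfR::read.vcfR(f, verbose = FALSE))
  expect_equal(nrow(v@fix), nrow(fx_panel$snps))
  gt <- vcfR::extract.gt(v)
  code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")
  m <- match(as.integer(v@fix[, "POS"]), calls$pos)
  called <- calls$genotype[m] != "no_call"
  expect_equal(unname(gt[called, 1]), unname(code[calls$genotype[m][called]]))
})
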