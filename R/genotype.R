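## Diploid genotype calling (two independent callers intersected), sample
## QC, amino-acid consequence annotation and read-backed resolution of
## multi-SNP codons (the V1016G/V1016I compound-heterozygote case).

GT_LEVELS <- c("hom_ref", "het", "hom_alt", "no_call")

new_call <- function(genotype, depth, alt_fraction, reason = NA_character_,
                     posteriors = NULL, pos = NA_integer_) {
  structure(list(genotype = genotype, depth = depth,
                 alt_fraction = alt_fraction, reason = reason,
                 posteriors = posteriors, pos = pos),
            class = "genotype_call")
}

#' Binomial-likelihood genotype caller
#'
#' Likelihood of the alt-read count under Binomial(depth, p) with
#' p = `error_rate`, 0.5, 1 - `error_rate` for hom-ref / het / hom-alt, a
#' flat prior, call by maximum posterior; no-call when the posterior odds of
#' the best against the second-best genotype fall below `min_odds`.
#'
#' @param ref_count,alt_count ref and alt base counts at the site
#' @param error_rate per-base error rate
#' @param min_depth minimum depth (ref + alt) to attempt a call
#' @param min_odds posterior-odds threshold
#' @param pos optional genomic position carried on the call
#' @return a `genotype_call`
#' @export
call_genotype_likelihood <- function(ref_count, alt_count, error_rate = 0.01,
                                     min_depth = 10L, min_odds = 10,
                                     pos = NA_integer_) {
  d <- ref_count + alt_count
  af <- if (d > 0) alt_count / d else NA_real_
  if (d < min_depth)
    return(new_call("no_call", d, af, reason = "low_depth", pos = pos))
  lik <- dbinom(alt_count, d, prob = c(error_rate, 0.5, 1 - error_rate))
  post <- lik / sum(lik)
  o <- order(post, decreasing = TRUE)
  if (post[o[2]] > 0 && post[o[1]] / post[o[2]] < min_odds)
    return(new_call("no_call", d, af, reason = "low_conf",
                    posteriors = post, pos = pos))
  new_call(GT_LEVELS[o[1]], d, af, posteriors = post, pos = pos)
}

#' Allele-fraction threshold genotype caller
#'
#' Alt fraction below 0.1 is hom-ref, within \[0.2, 0.8\] het, above 0.9
#' hom-alt; fractions in the two gap zones are no-calls (`ambiguous`).
#'
#' @inheritParams call_genotype_likelihood
#' @return a `genotype_call`
#' @export
call_genotype_threshold <- function(ref_count, alt_count, min_depth = 10L,
                                    pos = NA_integer_) {
  d <- ref_count + alt_count
  af <- if (d > 0) alt_count / d else NA_real_
  if (d < min_depth)
    return(new_call("no_call", d, af, reason = "low_depth", pos = pos))
  gt <- if (af < 0.1) "hom_ref"
        else if (af >= 0.2 && af <= 0.8) "het"
        else if (af > 0.9) "hom_alt"
        else NA_character_
  if (is.na(gt))
    return(new_call("no_call", d, af, reason = "ambiguous", pos = pos))
  new_call(gt, d, af, pos = pos)
}

#' Strict two-caller consensus
#'
#' Identical genotypes are kept with the agreement flag set; any
#' disagreement or any no-call propagates to a no-call.
#'
#' @param call_a,call_b `genotype_call`s for the same sample and position
#' @return a `genotype_call` with an `agreement` element
#' @export
consensus_call <- function(call_a, call_b) {
  if (!is.na(call_a$pos) && !is.na(call_b$pos) && call_a$pos != call_b$pos)
    stop("consensus of calls at different positions")
  out <- call_a
  if (call_a$genotype == "no_call" || call_b$genotype == "no_call") {
    out$genotype <- "no_call"
    out$reason <- "low_conf"
    out$agreement <- FALSE
  } else if (call_a$genotype != call_b$genotype) {
    out$genotype <- "no_call"
    out$reason <- "discordant"
    out$agreement <- FALSE
  } else {
    out$reason <- NA_character_
    out$agreement <- TRUE
  }
  out
}

#' Sample-level coverage QC
#'
#' @param covsum a [coverage_summary()]
#' @param min_amplicons minimum number of covered amplicons (default 6 of
#'   the 10-amplicon panel)
#' @return logical pass/fail
#' @export
sample_qc <- function(covsum, min_amplicons = 6L) {
  stopifnot(inherits(covsum, "coverage_summary"))
  covsum$n_covered >= min_amplicons
}

#' Annotate the coding consequence of a variant
#'
#' Extracts the codon in the transcript frame of the panel
#' (reverse-complemented for minus-strand transcripts), translates the
#' reference and alternative codon, and classifies the effect.
#'
#' @param panel an `amplicon_panel`
#' @param chrom,pos variant location (1-based genomic)
#' @param ref,alt plus-strand alleles
#' @return list with `gene`, `codon`, `codon_pos`, `aa_ref`, `aa_alt`,
#'   `effect` (`missense`, `synonymous`, `stop_class`, `splice_region`,
#'   `intronic` or `noncoding`) and `native_name`
#' @export
annotate_variant <- function(panel, chrom, pos, ref, alt) {
  loc <- locate_position(panel, chrom, pos)
  out <- list(gene = loc$gene, amplicon_id = loc$amplicon_id,
              codon = NA_integer_, codon_pos = NA_integer_,
              aa_ref = NA_character_, aa_alt = NA_character_,
              effect = NA_character_, native_name = NA_character_)
  if (loc$region != "cds") {
    out$effect <- switch(loc$region, intron = "intronic", loc$region)
    return(out)
  }
  strand <- amplicon_strand(panel, loc$amplicon_id)
  ref_codon <- reference_codon(panel, loc$amplicon_id, loc$codon)
  if (is.na(ref_codon)) {
    out$effect <- "cds_edge"
    return(out)
  }
  tx_ref <- if (strand == "-") complement_base(ref) else ref
  if (substr(ref_codon, loc$codon_pos, loc$codon_pos) != tx_ref)
    warning("stated ref allele disagrees with panel reference at ",
            chrom, ":", pos)
  alt_codon <- ref_codon
  substr(alt_codon, loc$codon_pos, loc$codon_pos) <-
    if (strand == "-") complement_base(alt) else alt
  aa_ref <- translate_codon(ref_codon)
  aa_alt <- translate_codon(alt_codon)
  out$codon <- loc$codon
  out$codon_pos <- loc$codon_pos
  out$aa_ref <- aa_ref
  out$aa_alt <- aa_alt
  out$effect <- if (aa_alt == "*") "stop_class"
                else if (aa_ref == aa_alt) "synonymous" else "missense"
  out$native_name <- paste0(aa_ref, loc$codon, aa_alt)
  out
}

#' Map between native and legacy mutation nomenclature
#'
#' @param gene gene symbol
#' @param codon codon number in the panel transcript frame (native) or in
#'   the legacy frame, depending on `direction`
#' @param name the name to map
#' @param direction `"to_field"` maps a native name to the field-standard
#'   (cross-species legacy) name; `"to_native"` reverses it
#' @param table nomenclature table (defaults to the panel's)
#' @return the mapped name, or `name` unchanged when the table has no row
#' @export
map_nomenclature <- function(gene, codon, name,
                             direction = c("to_field", "to_native"),
                             table = nomenclature_table()) {
  direction <- match.arg(direction)
  if (direction == "to_field") {
    i <- which(table$gene == gene & table$codon == codon &
                 table$native_name == name)
    if (length(i)) table$field_name[i[1]] else name
  } else {
    i <- which(table$gene == gene & table$field_name == name)
    if (length(i)) table$native_name[i[1]] else name
  }
}

#' Call consensus genotypes for one sample over the panel's target SNPs
#'
#' Runs both callers on the sample's pileup columns and intersects them.
#'
#' @param pileups the sample's `pileup_set`
#' @param panel an `amplicon_panel`
#' @param error_rate per-base error rate for the likelihood caller
#' @param min_depth minimum depth for calling
#' @return data frame, one row per target SNP: counts, both caller
#'   genotypes, consensus `genotype`, `agreement`, `no_call_reason`
#' @export
call_sample_genotypes <- function(pileups, panel, error_rate = 0.01,
                                  min_depth = 10L) {
  snps <- panel$snps
  rows <- lapply(seq_len(nrow(snps)), function(k) {
    col <- pileup_column(pileups, snps$amplicon_id[k], snps$pos[k])
    rc <- col[[snps$ref[k]]]
    ac <- col[[snps$alt[k]]]
    a <- call_genotype_likelihood(rc, ac, error_rate = error_rate,
                                  min_depth = min_depth, pos = snps$pos[k])
    b <- call_genotype_threshold(rc, ac, min_depth = min_depth,
                                 pos = snps$pos[k])
    cc <- consensus_call(a, b)
    data.frame(snp_id = snps$snp_id[k], chrom = snps$chrom[k],
               pos = snps$pos[k], ref = snps$ref[k], alt = snps$alt[k],
               depth = rc + ac, alt_count = ac,
               alt_fraction = cc$alt_fraction,
               gt_likelihood = a$genotype, gt_threshold = b$genotype,
               genotype = cc$genotype, agreement = cc$agreement,
               no_call_reason = cc$reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Resolve a multi-SNP codon by read-backed phasing
#'
#' Each read spanning the codon votes for a codon haplotype; the
#' best-supported pair of haplotypes consistent with the sample's diploid
#' genotype calls is translated and reported as the codon-level genotype.
#' Single-variant codons reduce to the plain annotation; a multi-variant
#' codon with no spanning reads is reported unresolved with the unphased
#' amino acids.
#'
#' @param panel an `amplicon_panel`
#' @param amplicon_id amplicon carrying the codon
#' @param codon codon number (transcript frame)
#' @param calls the sample's calls (from [call_sample_genotypes()]) at the
#'   variant positions inside the codon
#' @param aligned the sample's aligned reads (from [align_reads()])
#' @return list of class `codon_phase`: `gene`, `codon`, `aa` (two
#'   haplotype amino acids), `haplotype_names`, `support` (votes for the
#'   chosen haplotypes), `status` (`wildtype`, `resolved`, `unresolved`)
#' @export
resolve_codon_phase <- function(panel, amplicon_id, codon, calls, aligned) {
  amp <- amplicon_row(panel, amplicon_id)
  strand <- amp$strand
  gp <- codon_genomic_positions(panel, amplicon_id, codon)
  ref_codon <- reference_codon(panel, amplicon_id, codon)
  aa_ref <- translate_codon(ref_codon)
  gene <- amp$gene

  calls <- calls[calls$pos %in% gp & calls$genotype != "no_call", ,
                 drop = FALSE]
  variant <- calls[calls$genotype %in% c("het", "hom_alt"), , drop = FALSE]
  out <- structure(list(gene = gene, codon = codon, aa = c(aa_ref, aa_ref),
                        haplotype_names = rep(paste0(aa_ref, codon, aa_ref), 2),
                        support = c(NA_integer_, NA_integer_),
                        status = "wildtype"),
                   class = "codon_phase")
  if (!nrow(variant)) return(out)

  ## plus-strand ref bases of the codon and the variant positions within it
  off0 <- gp - amp$start               # 0-based amplicon offsets, tx order
  plus_ref <- vapply(off0 + 1L, function(o) substr(amp$sequence, o, o),
                     character(1))
  vpos <- variant$pos
  vi <- match(vpos, gp)

  ## dose required per variant by the diploid calls
  dose <- ifelse(variant$genotype == "het", 1L, 2L)

  ## spanning reads vote: bases at the variant positions (plus strand)
  ar <- aligned[aligned$pass & aligned$amplicon_id == amplicon_id, ,
                drop = FALSE]
  votes <- table(character(0))
  if (nrow(ar)) {
    lo <- min(vpos) - amp$start + 1L    # 1-based amplicon coords
    hi <- max(vpos) - amp$start + 1L
    span <- ar$offset + 1L <= lo & ar$offset + ar$aligned_len >= hi
    ar <- ar[span, , drop = FALSE]
    if (nrow(ar)) {
      haps <- vapply(seq_len(nrow(ar)), function(i) {
        paste(vapply(vpos - amp$start + 1L, function(p) {
          substr(ar$seq_plus[i], p - ar$offset[i], p - ar$offset[i])
        }, character(1)), collapse = "")
      }, character(1))
      haps <- haps[grepl("^[ACGT]+$", haps)]
      votes <- table(haps)
    }
  }

  hap_aa <- function(hap_bases) {
    ## hap_bases: plus-strand bases at the variant positions
    codon_chars <- plus_ref
    codon_chars[vi] <- hap_bases
    tx <- if (strand == "-") complement_base(codon_chars) else codon_chars
    translate_codon(paste(tx, collapse = ""))
  }
  hap_name <- function(hap_bases) {
    aa <- hap_aa(hap_bases)
    paste0(aa_ref, codon, aa)
  }
  dose_of <- function(hap_bases) as.integer(hap_bases == variant$alt)

  ref_hap <- paste(plus_ref[vi], collapse = "")
  cand <- union(names(votes), ref_hap)
  split_bases <- function(h) strsplit(h, "")[[1]]

  ## best-supported consistent pair
  best <- NULL
  for (i in seq_along(cand)) for (j in i:length(cand)) {
    d <- dose_of(split_bases(cand[i])) + dose_of(split_bases(cand[j]))
    if (all(d == dose)) {
      sup <- sum(votes[cand[i]], votes[cand[j]], na.rm = TRUE)
      if (is.null(best) || sup > best$sup)
        best <- list(i = i, j = j, sup = sup)
    }
  }
  if (is.null(best) || (nrow(variant) > 1 && sum(votes) == 0)) {
    ## no read support to phase a multi-variant codon
    out$status <- "unresolved"
    out$aa <- c(NA_character_, NA_character_)
    out$haplotype_names <-
      vapply(seq_len(nrow(variant)), function(k) {
        b <- plus_ref[vi]; b[k] <- variant$alt[k]
        hap_name(b)
      }, character(1))
    return(out)
  }
  h1 <- split_bases(cand[best$i]); h2 <- split_bases(cand[best$j])
  out$aa <- c(hap_aa(h1), hap_aa(h2))
  out$haplotype_names <- c(hap_name(h1), hap_name(h2))
  out$support <- c(if (cand[best$i] %in% names(votes)) votes[[cand[best$i]]] else 0L,
                   if (cand[best$j] %in% names(votes)) votes[[cand[best$j]]] else 0L)
  out$status <- "resolved"
  out
}

#' Write consensus calls as a minimal VCF
#'
#' One record per target SNP with per-sample `GT:DP:AF`; codon-phased
#' genotype pairs can be written phased with a phase-set (`PS`) tag.
#'
#' @param calls data frame of per-sample calls (rows from
#'   [call_sample_genotypes()] with a `sample_id` column)
#' @param panel an `amplicon_panel`
#' @param path output path
#' @param phase optional data frame `sample_id`, `pos`, `gt` (e.g.
#'   `"0|1"`), `ps` overriding the genotype string for phased records
#' @return `path`, invisibly
#' @export
write_vcf <- function(calls, panel, path, phase = NULL) {
  snps <- panel$snps
  samples <- sort(unique(calls$sample_id))
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               no_call = "./.")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=kdrseq",
           paste0("##contig=<ID=", unique(snps$chrom), ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth (ref+alt)">',
           '##FORMAT=<ID=AF,Number=1,Type=Float,Description="Alt allele fraction">',
           '##FORMAT=<ID=PS,Number=1,Type=Integer,Description="Phase set">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(order(snps$chrom, snps$pos), function(k) {
    cells <- vapply(samples, function(s) {
      row <- calls[calls$sample_id == s & calls$pos == snps$pos[k] &
                     calls$alt == snps$alt[k], , drop = FALSE]
      if (!nrow(row))
        return(if (is.null(phase)) "./.:.:." else "./.:.:.:.")
      gt <- gt_code[[row$genotype[1]]]
      ps <- if (is.null(phase)) "" else ":."
      if (!is.null(phase)) {
        ph <- phase[phase$sample_id == s & phase$pos == snps$pos[k], ,
                    drop = FALSE]
        if (nrow(ph)) { gt <- ph$gt[1]; ps <- paste0(":", ph$ps[1]) }
      }
      sprintf("%s:%d:%.4g%s", gt, row$depth[1],
              if (is.na(row$alt_fraction[1])) 0 else row$alt_fraction[1], ps)
    }, character(1))
    paste(c(snps$chrom[k], snps$pos[k], snps$snp_id[k], snps$ref[k],
            snps$alt[k], ".", "PASS", ".",
            if (is.null(phase)) "GT:DP:AF" else "GT:DP:AF:PS", cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
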