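## Amplicon panel: reference sequences, genomic coordinates, target SNPs and
## transcript models. The panel is the coordinate frame for every downstream
## stage (alignment offsets, pileup genomic positions, codon annotation).

#' Panel configuration
#'
#' Describes an amplicon panel to be materialised by [build_panel()]. The
#' default configuration reproduces the 10-amplicon *Ae. aegypti* resistance
#' panel used throughout the package: 9 resistance amplicons across *vgsc*,
#' *ace-1*, *rdl* and *GSTe2* plus one mitochondrial COI amplicon for species
#' identification, mean length 453 bp (range 321-709 bp), with 14 target SNPs
#' at their published genomic coordinates and a divergent-intron alternate
#' reference for the *vgsc* 1016-codon amplicon.
#'
#' @param n_amplicons number of amplicons (used only when `amplicon_defs` is
#'   `NULL` and random amplicons are generated)
#' @param length_range integer pair, allowed amplicon lengths in bp
#' @param target_snps `"default"` for the study panel SNPs, `NULL` for none,
#'   or a data frame with columns `amplicon`, `offset` (0-based), `ref`,
#'   `alt` for generated panels
#' @param barcode_length dual-index tag length in bp
#' @param alternate_reference logical; carry a divergent-intron alternate
#'   reference for the *vgsc* 1016 amplicon (default configuration only)
#' @param amplicon_defs `"default"` for the study layout or `NULL` to
#'   generate `n_amplicons` random amplicons on a simulated chromosome
#' @return a list of class `panel_config`
#' @export
panel_config <- function(n_amplicons = 10,
                         length_range = c(321L, 709L),
                         target_snps = "default",
                         barcode_length = 8L,
                         alternate_reference = TRUE,
                         amplicon_defs = "default") {
  stopifnot(length(length_range) == 2, length_range[1] <= length_range[2],
            n_amplicons >= 1, barcode_length >= 4)
  cfg <- list(n_amplicons = as.integer(n_amplicons),
              length_range = as.integer(length_range),
              target_snps = target_snps,
              barcode_length = as.integer(barcode_length),
              alternate_reference = isTRUE(alternate_reference),
              amplicon_defs = amplicon_defs)
  class(cfg) <- "panel_config"
  cfg
}

## ---- default study layout ---------------------------------------------------
## Amplicon coordinates anchor the published SNP positions; transcript CDS
## segments are chosen so that the mapped codon numbers reproduce the printed
## "codon position in reference" for every target SNP (vgsc and ace-1 are
## minus-strand, rdl and GSTe2 plus-strand).

default_amplicon_defs <- function() {
  data.frame(
    amplicon_id = c("coi", "rdl", "gste2", "ace1", "ace1_2",
                    "vgsc_dom4", "vgsc_1534", "vgsc_1016", "vgsc_dom2",
                    "vgsc_410"),
    chrom = c("MT", "2", "2", "3", "3", "3", "3", "3", "3", "3"),
    start = c(1500L, 41847600L, 352000L, 161499950L, 161502000L,
              315931700L, 315939000L, 315983680L, 315998300L, 316080500L),
    end   = c(2208L, 41848000L, 352400L, 161500350L, 161502382L,
              315932250L, 315939440L, 315984180L, 315998620L, 316080920L),
    gene  = c("COI", "rdl", "GSTe2", "ace1", "ace1",
              "vgsc", "vgsc", "vgsc", "vgsc", "vgsc"),
    strand = c("*", "+", "+", "-", "-", "-", "-", "-", "-", "-"),
    role = c("species", rep("resistance", 9)),
    has_alt = c(FALSE, FALSE, FALSE, FALSE, FALSE,
                FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

## CDS segments: gstart/gend genomic (1-based inclusive); cds_start is the
## 0-based CDS index of the transcript-first base of the segment (gstart on
## plus strand, gend on minus strand).
default_segments <- function() {
  data.frame(
    amplicon_id = c("rdl", "gste2", "ace1", "ace1_2",
                    "vgsc_dom4", "vgsc_dom4", "vgsc_1534",
                    "vgsc_1016", "vgsc_1016", "vgsc_dom2", "vgsc_410"),
    gstart = c(41847600L, 352000L, 161499950L, 161502000L,
               315931866L, 315931700L, 315939000L,
               315984040L, 315983680L, 315998300L, 316080500L),
    gend   = c(41848000L, 352400L, 161500350L, 161502382L,
               315932250L, 315931799L, 315939440L,
               315984180L, 315983782L, 315998620L, 316080920L),
    cds_start = c(710L, 0L, 1243L, 900L,
                  5132L, 5517L, 4384L,
                  2885L, 3026L, 2560L, 1029L),
    stringsAsFactors = FALSE
  )
}

## Target SNPs of the study panel. `snp_id` is the field-standard mutation
## name (legacy cross-species numbering where that is the common usage);
## `ref_codon` is the reference codon in transcript sense used to seed the
## synthetic reference sequence so the annotated consequence is correct.
default_target_snps <- function() {
  data.frame(
    snp_id = c("A296S", "A482T", "I1845S", "Q1805stop", "G1738S", "V1716L",
               "F1534C", "V1016G", "V1016I", "F967C", "F943Y", "L944I",
               "L895R", "V410L"),
    amplicon_id = c("rdl", "ace1", "vgsc_dom4", "vgsc_dom4", "vgsc_dom4",
                    "vgsc_dom4", "vgsc_1534", "vgsc_1016", "vgsc_1016",
                    "vgsc_1016", "vgsc_dom2", "vgsc_dom2", "vgsc_dom2",
                    "vgsc_410"),
    pos = c(41847790L, 161500150L, 315931756L, 315931943L, 315932144L,
            315932210L, 315939224L, 315983762L, 315983763L, 315984130L,
            315998386L, 315998453L, 315998530L, 316080722L),
    ref = c("G", "C", "A", "G", "C", "C", "A", "A", "C", "A",
            "A", "A", "A", "C"),
    alt = c("T", "T", "C", "A", "T", "A", "C", "C", "T", "C",
            "T", "T", "C", "A"),
    ref_codon = c("GCT", "GCA", "ATT", "CAA", "GGT", "GTA", "TTT", "GTA",
                  "GTA", "TTC", "TTT", "TTA", "CTG", "GTA"),
    stringsAsFactors = FALSE
  )
}

#' Legacy / native nomenclature table for the default panel
#'
#' Maps the codon number in the panel's transcript frame to the
#' field-standard (cross-species legacy) mutation name where the two differ;
#' kdr mutations such as V410L, V1016I/G and F1534C already carry the same
#' number in both frames.
#'
#' @return data frame with columns `gene`, `codon`, `native_name`,
#'   `field_name`
#' @export
nomenclature_table <- function() {
  data.frame(
    gene = c("rdl", "vgsc", "vgsc", "vgsc", "vgsc", "vgsc", "vgsc", "vgsc"),
    codon = c(301L, 1854L, 1814L, 1747L, 1725L, 979L, 910L, 884L),
    native_name = c("A301S", "I1854S", "Q1814*", "G1747S", "V1725L",
                    "F979C", "L910I", "L884R"),
    field_name = c("A296S", "I1845S", "Q1805stop", "G1738S", "V1716L",
                   "F967C", "L944I", "L895R"),
    stringsAsFactors = FALSE
  )
}

## ---- panel construction -----------------------------------------------------

#' Build an amplicon panel
#'
#' Materialises reference sequences (random background with the target-SNP
#' codons forced to their reference codons), genomic coordinates, transcript
#' CDS segments and the annotated target-SNP table. Deterministic for a fixed
#' `config` + `seed`.
#'
#' @param config a [panel_config()]
#' @param seed integer seed
#' @return an object of class `amplicon_panel`: list with data frames
#'   `amplicons` (id, coordinates, gene, strand, role, sequence,
#'   alt_sequence), `snps` (annotated target SNPs) and `segments`
#'   (transcript CDS segments)
#' @export
build_panel <- function(config = panel_config(), seed = 1L) {
  stopifnot(inherits(config, "panel_config"))
  use_default <- identical(config$amplicon_defs, "default")
  with_seed(seed, {
    if (use_default) {
      amp <- default_amplicon_defs()
      seg <- default_segments()
      snps <- if (identical(config$target_snps, "default")) {
        default_target_snps()
      } else if (is.null(config$target_snps)) {
        default_target_snps()[0, ]
      } else stop("custom target_snps require amplicon_defs = NULL")
    } else {
      n <- config$n_amplicons
      len <- sample(seq(config$length_range[1], config$length_range[2]),
                    n, replace = TRUE)
      amp <- data.frame(
        amplicon_id = sprintf("amp%02d", seq_len(n)),
        chrom = "sim1",
        start = as.integer(10000 * seq_len(n)),
        end = as.integer(10000 * seq_len(n) + len - 1L),
        gene = sprintf("gene%02d", seq_len(n)),
        strand = "+", role = "resistance", has_alt = FALSE,
        stringsAsFactors = FALSE
      )
      seg <- data.frame(amplicon_id = amp$amplicon_id, gstart = amp$start,
                        gend = amp$end, cds_start = 0L,
                        stringsAsFactors = FALSE)
      snps <- generic_snp_table(config$target_snps, amp)
    }
    amp$length <- amp$end - amp$start + 1L
    if (any(amp$length < config$length_range[1] |
            amp$length > config$length_range[2]))
      stop("amplicon length outside configured length_range")
    if (anyDuplicated(paste(snps$amplicon_id, snps$pos, snps$alt)))
      stop("duplicate target SNP definition (same amplicon/position/alt)")

    amp$sequence <- vapply(amp$length, random_dna, character(1))

    panel <- list(amplicons = amp, snps = snps, segments = seg,
                  config = config, seed = as.integer(seed))
    class(panel) <- "amplicon_panel"

    if (use_default && nrow(snps)) panel <- force_reference_codons(panel)
    panel <- check_snp_offsets(panel)

    ## divergent-intron alternate reference (resampled intron bases)
    panel$amplicons$alt_sequence <- NA_character_
    if (config$alternate_reference) {
      for (i in which(panel$amplicons$has_alt)) {
        panel$amplicons$alt_sequence[i] <-
          diverge_introns(panel, panel$amplicons$amplicon_id[i])
      }
    }
    panel$snps <- annotate_snp_table(panel)
    panel
  })
}

generic_snp_table <- function(ts, amp) {
  if (is.null(ts) || identical(ts, "default") || !NROW(ts)) {
    return(data.frame(snp_id = character(), amplicon_id = character(),
                      pos = integer(), ref = character(), alt = character(),
                      ref_codon = character(), stringsAsFactors = FALSE))
  }
  stopifnot(all(c("amplicon", "offset", "ref", "alt") %in% names(ts)))
  j <- match(ts$amplicon, amp$amplicon_id)
  if (anyNA(j)) stop("target SNP refers to unknown amplicon")
  len <- amp$end - amp$start + 1L
  if (any(ts$offset < 0 | ts$offset >= len[j]))
    stop("target SNP offset outside its amplicon")
  data.frame(snp_id = sprintf("%s_p%d", ts$amplicon, ts$offset),
             amplicon_id = ts$amplicon,
             pos = amp$start[j] + as.integer(ts$offset),
             ref = ts$ref, alt = ts$alt, ref_codon = NA_character_,
             stringsAsFactors = FALSE)
}

check_snp_offsets <- function(panel) {
  if (!nrow(panel$snps)) return(panel)
  j <- match(panel$snps$amplicon_id, panel$amplicons$amplicon_id)
  off <- panel$snps$pos - panel$amplicons$start[j]
  if (any(off < 0 | off >= panel$amplicons$length[j]))
    stop("target SNP position outside its amplicon")
  ## force stated ref base (generic panels; default panel already consistent)
  for (k in seq_len(nrow(panel$snps))) {
    s <- panel$amplicons$sequence[j[k]]
    if (substr(s, off[k] + 1, off[k] + 1) != panel$snps$ref[k]) {
      substr(s, off[k] + 1, off[k] + 1) <- panel$snps$ref[k]
      panel$amplicons$sequence[j[k]] <- s
    }
  }
  panel$snps$offset <- as.integer(off)
  panel
}

## Write the three plus-strand bases of each target-SNP reference codon into
## the amplicon sequence so translation yields the intended amino acid.
force_reference_codons <- function(panel) {
  for (k in seq_len(nrow(panel$snps))) {
    sn <- panel$snps[k, ]
    loc <- locate_position(panel, amplicon_chrom(panel, sn$amplicon_id), sn$pos)
    stopifnot(loc$region == "cds")
    gp <- codon_genomic_positions(panel, sn$amplicon_id, loc$codon)
    if (anyNA(gp)) stop("target SNP codon not fully inside amplicon")
    codon <- strsplit(sn$ref_codon, "")[[1]]
    strand <- amplicon_strand(panel, sn$amplicon_id)
    plus_bases <- if (strand == "-") complement_base(codon) else codon
    i <- match(sn$amplicon_id, panel$amplicons$amplicon_id)
    s <- panel$amplicons$sequence[i]
    for (b in 1:3) {
      o <- gp[b] - panel$amplicons$start[i] + 1L
      substr(s, o, o) <- plus_bases[b]
    }
    panel$amplicons$sequence[i] <- s
  }
  panel
}

diverge_introns <- function(panel, amplicon_id) {
  i <- match(amplicon_id, panel$amplicons$amplicon_id)
  amp <- panel$amplicons[i, ]
  seg <- panel$segments[panel$segments$amplicon_id == amplicon_id, ]
  in_cds <- rep(FALSE, amp$length)
  for (r in seq_len(nrow(seg))) {
    a <- max(seg$gstart[r], amp$start) - amp$start + 1L
    b <- min(seg$gend[r], amp$end) - amp$start + 1L
    in_cds[a:b] <- TRUE
  }
  chars <- strsplit(amp$sequence, "")[[1]]
  n_int <- sum(!in_cds)
  chars[!in_cds] <- sample(c("A", "C", "G", "T"), n_int, replace = TRUE)
  paste(chars, collapse = "")
}

## ---- coordinate machinery ---------------------------------------------------

amplicon_row <- function(panel, amplicon_id) {
  i <- match(amplicon_id, panel$amplicons$amplicon_id)
  if (is.na(i)) stop("unknown amplicon: ", amplicon_id)
  panel$amplicons[i, ]
}
amplicon_strand <- function(panel, amplicon_id) amplicon_row(panel, amplicon_id)$strand
amplicon_chrom <- function(panel, amplicon_id) amplicon_row(panel, amplicon_id)$chrom

#' Map a genomic position into the panel's transcript frame
#'
#' @param panel an `amplicon_panel`
#' @param chrom chromosome name
#' @param pos 1-based genomic position
#' @return list with `amplicon_id`, `offset` (0-based within amplicon),
#'   `region` (`"cds"`, `"intron"`, `"splice_region"` or `"noncoding"`), and
#'   for CDS positions `cds` (0-based), `codon` (1-based) and `codon_pos`
#'   (1-3 within codon, transcript sense)
#' @export
locate_position <- function(panel, chrom, pos) {
  amp <- panel$amplicons
  i <- which(amp$chrom == chrom & amp$start <= pos & amp$end >= pos)
  if (!length(i)) stop("position ", chrom, ":", pos, " outside panel")
  i <- i[1]
  out <- list(amplicon_id = amp$amplicon_id[i],
              offset = as.integer(pos - amp$start[i]),
              gene = amp$gene[i], region = "noncoding",
              cds = NA_integer_, codon = NA_integer_, codon_pos = NA_integer_)
  seg <- panel$segments[panel$segments$amplicon_id == amp$amplicon_id[i], ]
  if (!nrow(seg)) return(out)
  hit <- which(seg$gstart <= pos & seg$gend >= pos)
  if (length(hit)) {
    s <- seg[hit[1], ]
    cds <- if (amp$strand[i] == "-") s$cds_start + (s$gend - pos)
           else s$cds_start + (pos - s$gstart)
    out$region <- "cds"
    out$cds <- as.integer(cds)
    out$codon <- as.integer(cds %/% 3 + 1)
    out$codon_pos <- as.integer(cds %% 3 + 1)
  } else {
    ## intronic within the amplicon; splice region = within 2 bp of an
    ## exon/intron junction (intron side)
    d <- pmin(abs(pos - seg$gstart), abs(pos - seg$gend))
    out$region <- if (min(d) <= 2) "splice_region" else "intron"
  }
  out
}

#' Genomic positions of a codon's three bases
#'
#' Positions are returned in transcript order (codon position 1, 2, 3); `NA`
#' where a base falls outside the amplicon's CDS segments.
#'
#' @param panel an `amplicon_panel`
#' @param amplicon_id amplicon carrying the codon
#' @param codon 1-based codon number in the transcript frame
#' @return integer vector of length 3
#' @export
codon_genomic_positions <- function(panel, amplicon_id, codon) {
  seg <- panel$segments[panel$segments$amplicon_id == amplicon_id, ]
  strand <- amplicon_strand(panel, amplicon_id)
  cds <- (codon - 1L) * 3L + 0:2
  vapply(cds, function(ci) {
    for (r in seq_len(nrow(seg))) {
      span <- seg$gend[r] - seg$gstart[r]
      if (ci >= seg$cds_start[r] && ci <= seg$cds_start[r] + span) {
        return(if (strand == "-") seg$gend[r] - (ci - seg$cds_start[r])
               else seg$gstart[r] + (ci - seg$cds_start[r]))
      }
    }
    NA_integer_
  }, numeric(1)) |> as.integer()
}

## Reference codon (transcript sense) read out of the amplicon sequence.
reference_codon <- function(panel, amplicon_id, codon) {
  gp <- codon_genomic_positions(panel, amplicon_id, codon)
  if (anyNA(gp)) return(NA_character_)
  amp <- amplicon_row(panel, amplicon_id)
  bases <- vapply(gp, function(p) substr(amp$sequence, p - amp$start + 1L,
                                         p - amp$start + 1L), character(1))
  if (amp$strand == "-") bases <- complement_base(bases)
  paste(bases, collapse = "")
}

## ---- annotation of the SNP table -------------------------------------------

annotate_snp_table <- function(panel) {
  snps <- panel$snps
  if (!nrow(snps)) {
    snps$chrom <- character(0); snps$gene <- character(0)
    snps$codon <- integer(0); snps$codon_pos <- integer(0)
    snps$aa_ref <- character(0); snps$aa_alt <- character(0)
    snps$effect <- character(0); snps$native_name <- character(0)
    return(snps)
  }
  ann <- lapply(seq_len(nrow(snps)), function(k) {
    annotate_variant(panel, amplicon_chrom(panel, snps$amplicon_id[k]),
                     snps$pos[k], snps$ref[k], snps$alt[k])
  })
  snps$chrom <- vapply(snps$amplicon_id, function(a) amplicon_chrom(panel, a),
                       character(1))
  snps$gene <- vapply(ann, `[[`, character(1), "gene")
  snps$codon <- vapply(ann, `[[`, integer(1), "codon")
  snps$codon_pos <- vapply(ann, `[[`, integer(1), "codon_pos")
  snps$aa_ref <- vapply(ann, `[[`, character(1), "aa_ref")
  snps$aa_alt <- vapply(ann, `[[`, character(1), "aa_alt")
  snps$effect <- vapply(ann, `[[`, character(1), "effect")
  snps$native_name <- vapply(ann, `[[`, character(1), "native_name")
  rownames(snps) <- NULL
  snps
}

## ---- writers ----------------------------------------------------------------

#' Write panel reference sequences as FASTA
#'
#' @param panel an `amplicon_panel`
#' @param path output FASTA path
#' @param include_alt also write alternate references (named `<id>_alt`)
#' @return `path`, invisibly
#' @export
write_panel_fasta <- function(panel, path, include_alt = TRUE) {
  seqs <- panel$amplicons$sequence
  names(seqs) <- panel$amplicons$amplicon_id
  if (include_alt) {
    alt <- !is.na(panel$amplicons$alt_sequence)
    if (any(alt)) {
      a <- panel$amplicons$alt_sequence[alt]
      names(a) <- paste0(panel$amplicons$amplicon_id[alt], "_alt")
      seqs <- c(seqs, a)
    }
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Panel summary table (coordinates and target SNPs)
#'
#' @param panel an `amplicon_panel`
#' @return list of two data frames: `amplicons` (without sequences) and
#'   `snps`
#' @export
panel_table <- function(panel) {
  amp <- panel$amplicons
  amp$sequence <- NULL
  amp$alt_sequence <- NULL
  list(amplicons = amp, snps = panel$snps)
}

#' @export
print.amplicon_panel <- function(x, ...) {
  cat(sprintf("<amplicon_panel> %d amplicons (%d-%d bp, mean %.1f), %d target SNPs\n",
              nrow(x$amplicons), min(x$amplicons$length),
              max(x$amplicons$length), mean(x$amplicons$length),
              nrow(x$snps)))
  invisible(x)
}
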