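## Read-to-amplicon assignment by k-mer-seeded ungapped extension, pileup
## accumulation, coverage summaries and the COI species check. Ungapped
## alignment is deliberate: the panel targets SNPs, and indel-bearing reads
## fail the identity threshold and are dropped with a reason.

BASE_CODE <- {
  v <- integer(256); v[] <- 5L
  v[utf8ToInt("A") + 1L] <- 1L; v[utf8ToInt("C") + 1L] <- 2L
  v[utf8ToInt("G") + 1L] <- 3L; v[utf8ToInt("T") + 1L] <- 4L
  v
}

#' Build a k-mer index over the panel references
#'
#' Indexes every reference (and alternate reference, when present) k-mer so
#' reads can be seeded onto candidate (amplicon, offset) diagonals.
#'
#' @param panel an `amplicon_panel`
#' @param k seed k-mer length
#' @return list of class `ref_index`
#' @export
build_ref_index <- function(panel, k = 15L) {
  amp <- panel$amplicons
  refs <- data.frame(amplicon_id = amp$amplicon_id, is_alt = FALSE,
                     seq = amp$sequence, stringsAsFactors = FALSE)
  alt <- which(!is.na(amp$alt_sequence))
  if (length(alt)) {
    refs <- rbind(refs, data.frame(amplicon_id = amp$amplicon_id[alt],
                                   is_alt = TRUE,
                                   seq = amp$alt_sequence[alt],
                                   stringsAsFactors = FALSE))
  }
  refs$raw <- lapply(refs$seq, charToRaw)
  kmers <- character(0); ref_of <- integer(0); pos_of <- integer(0)
  for (i in seq_len(nrow(refs))) {
    L <- nchar(refs$seq[i])
    if (L < k) next
    p <- seq_len(L - k + 1L)
    kmers <- c(kmers, substring(refs$seq[i], p, p + k - 1L))
    ref_of <- c(ref_of, rep.int(i, length(p)))
    pos_of <- c(pos_of, p)
  }
  o <- order(kmers)
  idx <- split(seq_along(kmers)[o], kmers[o])
  env <- list2env(lapply(idx, function(j) cbind(ref_of[j], pos_of[j])),
                  hash = TRUE, size = length(idx))
  structure(list(refs = refs, k = as.integer(k), env = env,
                 panel_start = setNames(amp$start, amp$amplicon_id)),
            class = "ref_index")
}

#' Assign and align a single read
#'
#' The read is seeded against every reference in both orientations; each
#' seeded diagonal is scored by ungapped base agreement over the overlap,
#' the best-scoring reference wins, and the read fails if its identity over
#' the aligned span falls below `min_identity`.
#'
#' @param seq read sequence (barcode-stripped)
#' @param index a [build_ref_index()]
#' @param min_identity minimum fraction of matching bases (default 0.8)
#' @param rc optional precomputed reverse complement of `seq` (batch
#'   callers avoid recomputing it per read)
#' @return list with `amplicon_id`, `is_alt`, `offset` (0-based on the
#'   amplicon), `strand`, `seq_plus` (plus-strand aligned portion),
#'   `aligned_len`, `mismatches`, `identity`, `pass`, `reason`
#' @export
assign_and_align <- function(seq, index, min_identity = 0.8, rc = NULL) {
  fail <- function(reason) list(amplicon_id = NA_character_, is_alt = NA,
                                offset = NA_integer_, strand = NA_character_,
                                seq_plus = NA_character_,
                                aligned_len = 0L, mismatches = NA_integer_,
                                identity = NA_real_, pass = FALSE,
                                reason = reason)
  if (is.na(seq) || nchar(seq) == 0L) return(fail("empty"))
  k <- index$k
  if (nchar(seq) < k) return(fail("too_short"))
  best <- NULL
  for (strand in c("+", "-")) {
    rs <- if (strand == "+") seq else (rc %||% revcomp(seq))
    rraw <- charToRaw(rs)
    n <- length(rraw)
    seed_pos <- unique(pmin(c(1L, 1L + k, 1L + 2L * k, n - k + 1L), n - k + 1L))
    cand <- NULL
    for (sp in seed_pos) {
      hit <- index$env[[substr(rs, sp, sp + k - 1L)]]
      if (!is.null(hit)) cand <- rbind(cand, cbind(hit[, 1], hit[, 2] - sp))
    }
    if (is.null(cand)) next
    cand <- unique(cand)
    for (ci in seq_len(nrow(cand))) {
      ri <- cand[ci, 1]; off <- cand[ci, 2]   # 0-based read start on ref
      ref_raw <- index$refs$raw[[ri]]
      L <- length(ref_raw)
      a <- max(1L, 1L - off); b <- min(n, L - off)  # read coords of overlap
      if (b - a + 1L < min(30L, n)) next
      mm <- sum(rraw[a:b] != ref_raw[(a + off):(b + off)])
      len <- b - a + 1L
      score <- len - mm
      if (is.null(best) || score > best$score) {
        best <- list(score = score, ri = ri, off = off, a = a, b = b,
                     mm = mm, len = len, strand = strand, rs = rs)
      }
    }
    if (!is.null(best) && best$mm == 0L && best$len == n) break
  }
  if (is.null(best)) return(fail("no_seed"))
  identity <- (best$len - best$mm) / best$len
  if (identity < min_identity) return(fail("low_identity"))
  list(amplicon_id = index$refs$amplicon_id[best$ri],
       is_alt = index$refs$is_alt[best$ri],
       offset = as.integer(best$off + best$a - 1L),
       strand = best$strand,
       seq_plus = substr(best$rs, best$a, best$b),
       aligned_len = as.integer(best$len),
       mismatches = as.integer(best$mm),
       identity = identity, pass = TRUE, reason = NA_character_)
}

#' Explode paired reads into single mates for alignment
#'
#' @param reads data frame with `seq1`/`seq2` (and optionally `sample_id`)
#' @return data frame with one row per mate (`mate` 1 or 2)
#' @export
pairs_to_mates <- function(reads) {
  base <- reads[, intersect(c("read_id", "sample_id"), names(reads)),
                drop = FALSE]
  rbind(cbind(base, mate = 1L, seq = reads$seq1, stringsAsFactors = FALSE),
        cbind(base, mate = 2L, seq = reads$seq2, stringsAsFactors = FALSE))
}

#' Align a set of reads to the panel
#'
#' @param mates data frame with `read_id`, `seq` and optionally
#'   `sample_id`, `mate` (see [pairs_to_mates()] for paired input)
#' @param panel an `amplicon_panel`
#' @param min_identity minimum identity fraction
#' @param index optional prebuilt [build_ref_index()]
#' @return data frame of per-read alignment results (one row per mate),
#'   failed reads included with `pass = FALSE` and a `reason`
#' @export
align_reads <- function(mates, panel, min_identity = 0.8, index = NULL) {
  if (is.null(index)) index <- build_ref_index(panel)
  rc_all <- rep(NA_character_, nrow(mates))
  ok <- !is.na(mates$seq) & nzchar(mates$seq)
  rc_all[ok] <- revcomp(mates$seq[ok])
  res <- lapply(seq_len(nrow(mates)), function(i)
    assign_and_align(mates$seq[i], index, min_identity, rc = rc_all[i]))
  out <- data.frame(
    read_id = mates$read_id,
    mate = if ("mate" %in% names(mates)) mates$mate else 1L,
    sample_id = if ("sample_id" %in% names(mates)) mates$sample_id else NA,
    amplicon_id = vapply(res, `[[`, character(1), "amplicon_id"),
    is_alt = vapply(res, `[[`, logical(1), "is_alt"),
    offset = vapply(res, `[[`, integer(1), "offset"),
    strand = vapply(res, `[[`, character(1), "strand"),
    aligned_len = vapply(res, `[[`, integer(1), "aligned_len"),
    mismatches = vapply(res, `[[`, integer(1), "mismatches"),
    identity = vapply(res, `[[`, numeric(1), "identity"),
    pass = vapply(res, `[[`, logical(1), "pass"),
    reason = vapply(res, `[[`, character(1), "reason"),
    seq_plus = vapply(res, `[[`, character(1), "seq_plus"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Accumulate per-position base counts
#'
#' Every aligned base of every passing read contributes once; positions are
#' reported in 1-based genomic coordinates via the panel.
#'
#' @param aligned data frame from [align_reads()]
#' @param panel an `amplicon_panel`
#' @return list of class `pileup_set`: per amplicon a list with `counts`
#'   (positions x A/C/G/T/N), `depth` and genomic `positions`
#' @export
build_pileup <- function(aligned, panel) {
  aligned <- aligned[aligned$pass, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(panel$amplicons))) {
    aid <- panel$amplicons$amplicon_id[i]
    L <- panel$amplicons$length[i]
    rows <- which(aligned$amplicon_id == aid)
    counts <- matrix(0L, nrow = L, ncol = 5L,
                     dimnames = list(NULL, c("A", "C", "G", "T", "N")))
    if (length(rows)) {
      pos_all <- integer(0); code_all <- integer(0)
      codes <- lapply(aligned$seq_plus[rows],
                      function(s) BASE_CODE[utf8ToInt(s) + 1L])
      lens <- lengths(codes)
      pos_all <- sequence(lens, from = aligned$offset[rows] + 1L)
      code_all <- unlist(codes, use.names = FALSE)
      ok <- pos_all >= 1L & pos_all <= L
      counts[] <- tabulate((code_all[ok] - 1L) * L + pos_all[ok],
                           nbins = 5L * L)
    }
    out[[aid]] <- list(amplicon_id = aid, counts = counts,
                       depth = rowSums(counts),
                       positions = seq(panel$amplicons$start[i],
                                       panel$amplicons$end[i]))
  }
  class(out) <- "pileup_set"
  out
}

#' Pileup column at a genomic position
#'
#' @param pileups a `pileup_set`
#' @param amplicon_id amplicon name
#' @param pos 1-based genomic position
#' @return named integer vector of A/C/G/T/N counts
#' @export
pileup_column <- function(pileups, amplicon_id, pos) {
  p <- pileups[[amplicon_id]]
  if (is.null(p)) stop("no pileup for amplicon ", amplicon_id)
  j <- match(pos, p$positions)
  if (is.na(j)) stop("position ", pos, " not on amplicon ", amplicon_id)
  p$counts[j, ]
}

#' Per-amplicon coverage summary
#'
#' @param pileups a `pileup_set`
#' @param min_depth median depth at which an amplicon counts as covered
#' @return list of class `coverage_summary` with `table` (amplicon_id,
#'   median_depth, covered) and `n_covered`
#' @export
coverage_summary <- function(pileups, min_depth = 5L) {
  tab <- data.frame(
    amplicon_id = vapply(pileups, `[[`, character(1), "amplicon_id"),
    median_depth = vapply(pileups, function(p) median(p$depth), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab$covered <- tab$median_depth >= min_depth
  structure(list(table = tab, n_covered = sum(tab$covered),
                 min_depth = min_depth),
            class = "coverage_summary")
}

#' COI consensus species check
#'
#' Builds the majority consensus over covered positions of the species
#' (COI) amplicon pileup and compares it to the reference sequence.
#'
#' @param coi_pileup single amplicon pileup (element of a `pileup_set`)
#' @param reference_seq reference COI sequence (plus strand, same frame)
#' @param min_identity identity at or above which the sample is flagged as
#'   the expected species (default 0.95)
#' @return list with `identity`, `n_covered` and `species_match` (`TRUE`,
#'   `FALSE`, or `"undetermined"` when nothing is covered)
#' @export
species_check <- function(coi_pileup, reference_seq, min_identity = 0.95) {
  covered <- which(coi_pileup$depth > 0)
  if (!length(covered))
    return(list(identity = NA_real_, n_covered = 0L,
                species_match = "undetermined"))
  cons <- c("A", "C", "G", "T", "N")[
    apply(coi_pileup$counts[covered, , drop = FALSE], 1, which.max)]
  ref <- strsplit(reference_seq, "")[[1]][covered]
  identity <- mean(cons == ref)
  list(identity = identity, n_covered = length(covered),
       species_match = identity >= min_identity)
}
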