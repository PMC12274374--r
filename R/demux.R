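## Dual-index demultiplexing with mis-tag (index-hop) removal, and
## quality trimming of the assigned reads.

#' Demultiplex pooled read pairs by dual 8-bp tags
#'
#' A pair is assigned iff both its forward and reverse tag each match
#' exactly one known tag within `max_mismatch` substitutions and the two
#' resolved tags identify a single sample. Pairs whose two tags resolve to
#' different samples (a hopped index) are discarded as `"mis-tag"`; pairs
#' with an unmatched or ambiguous tag are discarded as `"unknown"`.
#' Tags are stripped from assigned reads.
#'
#' @param read_pairs data frame with `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2` (tags at the 5' end of each mate)
#' @param sample_sheet data frame with `sample_id`, `fwd_tag`, `rev_tag`
#'   (every tag combination unique)
#' @param max_mismatch per-tag substitution tolerance (default 1; the
#'   barcode design guarantees pairwise distance >= 3 so one mismatch is
#'   unambiguous)
#' @return list with `assigned` (read pairs plus `sample_id`, tags
#'   removed), `discard_log` (data frame `read_id`, `reason`) and `counts`
#'   (named totals: assigned, mistag, unknown)
#' @export
demultiplex <- function(read_pairs, sample_sheet, max_mismatch = 1L) {
  if (anyDuplicated(paste(sample_sheet$fwd_tag, sample_sheet$rev_tag)))
    stop("duplicate barcode combination in sample sheet")
  tag_len <- nchar(sample_sheet$fwd_tag[1])
  stopifnot(all(nchar(c(sample_sheet$fwd_tag, sample_sheet$rev_tag)) == tag_len))

  obs_f <- substr(read_pairs$seq1, 1L, tag_len)
  obs_r <- substr(read_pairs$seq2, 1L, tag_len)

  ## resolve each distinct observed tag once against the known tag pool:
  ## index of the unique known tag within max_mismatch, NA otherwise
  resolve <- function(obs, known) {
    u <- unique(obs)
    hit <- vapply(u, function(tag) {
      d <- hamming_many(tag, known)
      ok <- which(d <= max_mismatch)
      if (length(ok) == 1L) ok else
        if (length(ok) > 1L && sum(d == min(d)) == 1L && min(d) <= max_mismatch)
          which.min(d) else NA_integer_
    }, integer(1), USE.NAMES = FALSE)
    hit[match(obs, u)]
  }
  known_f <- unique(sample_sheet$fwd_tag)
  known_r <- unique(sample_sheet$rev_tag)
  fi <- resolve(obs_f, known_f)
  ri <- resolve(obs_r, known_r)

  ## map resolved tag pair -> sample
  key_known <- paste(match(sample_sheet$fwd_tag, known_f),
                     match(sample_sheet$rev_tag, known_r))
  sample_idx <- match(paste(fi, ri), key_known)

  reason <- rep(NA_character_, nrow(read_pairs))
  unknown <- is.na(fi) | is.na(ri)
  mistag <- !unknown & is.na(sample_idx)
  reason[unknown] <- "unknown"
  reason[mistag] <- "mis-tag"
  keep <- !unknown & !mistag

  assigned <- read_pairs[keep, , drop = FALSE]
  assigned$sample_id <- sample_sheet$sample_id[sample_idx[keep]]
  assigned$seq1 <- substring(assigned$seq1, tag_len + 1L)
  assigned$qual1 <- substring(assigned$qual1, tag_len + 1L)
  assigned$seq2 <- substring(assigned$seq2, tag_len + 1L)
  assigned$qual2 <- substring(assigned$qual2, tag_len + 1L)
  rownames(assigned) <- NULL

  list(assigned = assigned,
       discard_log = data.frame(read_id = read_pairs$read_id[!keep],
                                reason = reason[!keep],
                                stringsAsFactors = FALSE),
       counts = c(assigned = sum(keep), mistag = sum(mistag),
                  unknown = sum(unknown)))
}

#' Trimming parameters
#'
#' The canonical leading/trailing/sliding-window/minimum-length rule set
#' (defaults LEADING:3, TRAILING:3, SLIDINGWINDOW:4:20, MINLEN:36).
#'
#' @param leading_q drop leading bases with quality below this Phred score
#' @param trailing_q drop trailing bases with quality below this
#' @param window_size sliding window width in bases
#' @param window_q minimum mean window quality
#' @param min_len minimum surviving read length
#' @return list of class `trim_params`
#' @export
trim_params <- function(leading_q = 3L, trailing_q = 3L, window_size = 4L,
                        window_q = 20, min_len = 36L) {
  stopifnot(leading_q >= 0, trailing_q >= 0, window_size >= 1,
            window_q >= 0, min_len > 0)
  out <- list(leading_q = leading_q, trailing_q = trailing_q,
              window_size = as.integer(window_size), window_q = window_q,
              min_len = as.integer(min_len))
  class(out) <- "trim_params"
  out
}

#' Trim a single read
#'
#' Applies, in order: leading low-quality base removal, trailing removal,
#' then a 5'->3' sliding window — the read is truncated before the first
#' window whose mean quality falls below `window_q`, and the kept portion is
#' clipped back to the last base at or above `window_q`.
#'
#' @param seq,qual sequence and Phred+33 quality strings of equal length
#' @param params a [trim_params()]
#' @return list with trimmed `seq` and `qual` (possibly empty strings)
#' @export
trim_read <- function(seq, qual, params = trim_params()) {
  if (nchar(seq) != nchar(qual)) stop("seq/qual length mismatch")
  q <- utf8ToInt(qual) - 33L
  n <- length(q)
  lo <- 1L
  while (lo <= n && q[lo] < params$leading_q) lo <- lo + 1L
  hi <- n
  while (hi >= lo && q[hi] < params$trailing_q) hi <- hi - 1L
  if (lo > hi) return(list(seq = "", qual = ""))
  q <- q[lo:hi]
  m <- length(q)
  w <- params$window_size
  cut <- m
  if (m >= w) {
    cs <- cumsum(c(0L, q))
    wsum <- cs[(w + 1L):(m + 1L)] - cs[1:(m - w + 1L)]   # rolling sums
    bad <- which(wsum < w * params$window_q)
    if (length(bad)) {
      cut <- bad[1] - 1L
      while (cut > 0L && q[cut] < params$window_q) cut <- cut - 1L
    }
  }
  if (cut == 0L) return(list(seq = "", qual = ""))
  list(seq = substr(seq, lo, lo + cut - 1L),
       qual = substr(qual, lo, lo + cut - 1L))
}

#' Quality-trim demultiplexed read pairs
#'
#' Both mates are trimmed independently with [trim_read()]; a pair is
#' dropped (and logged) if either mate ends up shorter than `min_len`, and
#' malformed records (sequence/quality length mismatch) are rejected with a
#' log entry.
#'
#' @param reads data frame with `read_id`, `seq1`, `qual1`, `seq2`, `qual2`
#'   (extra columns such as `sample_id` are carried through)
#' @param params a [trim_params()]
#' @return list with `reads` (trimmed pairs) and `drop_log` (data frame
#'   `read_id`, `reason`)
#' @export
trim_reads <- function(reads, params = trim_params()) {
  n <- nrow(reads)
  keep <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  malformed <- nchar(reads$seq1) != nchar(reads$qual1) |
    nchar(reads$seq2) != nchar(reads$qual2)
  keep[malformed] <- FALSE
  reason[malformed] <- "malformed"

  ## fast path: a read whose worst base clears every threshold is untouched
  thr <- max(params$leading_q, params$trailing_q, params$window_q)
  min_q <- function(qual) vapply(qual, function(x) min(utf8ToInt(x)),
                                 integer(1), USE.NAMES = FALSE) - 33L
  clean <- keep
  clean[keep] <- min_q(reads$qual1[keep]) >= thr &
    min_q(reads$qual2[keep]) >= thr &
    nchar(reads$seq1[keep]) >= params$min_len &
    nchar(reads$seq2[keep]) >= params$min_len
  for (i in which(keep & !clean)) {
    t1 <- trim_read(reads$seq1[i], reads$qual1[i], params)
    t2 <- trim_read(reads$seq2[i], reads$qual2[i], params)
    if (nchar(t1$seq) < params$min_len || nchar(t2$seq) < params$min_len) {
      keep[i] <- FALSE
      reason[i] <- "min_len"
    } else {
      reads$seq1[i] <- t1$seq; reads$qual1[i] <- t1$qual
      reads$seq2[i] <- t2$seq; reads$qual2[i] <- t2$qual
    }
  }
  list(reads = reads[keep, , drop = FALSE],
       drop_log = data.frame(read_id = reads$read_id[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}
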