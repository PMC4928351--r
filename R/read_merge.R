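# Statistical merging of overlapping paired-end reads: the overlap degree
# minimising a one-sided binomial tail probability is chosen, and a pair is
# merged only when that probability falls below a stringent threshold.

#' One-sided binomial tail probability of an overlap match count
#'
#' Probability of observing at least `n_match` matching bases among
#' `n_overlap` aligned bases when bases match by chance with probability
#' `p_null`.
#'
#' @param n_overlap number of aligned (overlapping) bases.
#' @param n_match number of matching bases (0..n_overlap).
#' @param p_null chance match probability (0.25 for uniform bases).
#' @return P(X >= n_match | n_overlap, p_null).
#' @export
overlap_pvalue <- function(n_overlap, n_match, p_null = 0.25) {
  if (any(n_match > n_overlap) || any(n_match < 0))
    stop("n_match must lie in [0, n_overlap]")
  pbinom(n_match - 1, n_overlap, p_null, lower.tail = FALSE)
}

#' A quality-tagged sequencing read
#'
#' @param id read identifier.
#' @param seq sequence over A/C/G/T/N.
#' @param qual integer Phred qualities, one per base.
#' @param mate mate flag (1 or 2).
#' @return object of class `ahe_read`.
#' @export
qual_read <- function(id, seq, qual, mate = 1L) {
  if (nchar(seq) != length(qual)) stop("|sequence| must equal |quality|")
  structure(list(id = id, seq = toupper(seq), qual = as.integer(qual),
                 mate = as.integer(mate)), class = "ahe_read")
}

#' Merge one read pair by the lowest-probability overlap criterion
#'
#' Read 2 is taken in sequencing orientation and reverse-complemented
#' internally. Every overlap degree 1..min(|r1|,|r2|) is scored by the
#' binomial tail probability of its match count; the degree with the
#' smallest p-value wins (ties broken toward the longer overlap) and the
#' pair is merged only if that p-value is below `alpha`. In the overlap,
#' agreeing bases keep the base with quality `min(cap, q1+q2)`; disagreeing
#' bases take the higher-quality base with quality `|q1-q2|` (an N never
#' wins a disagreement).
#'
#' @param r1,r2 [qual_read()] objects (r2 in sequencing orientation).
#' @param alpha p-value required to merge (default 1e-10).
#' @param p_null chance match probability (default 0.25).
#' @param qual_cap maximum combined quality (default 93, the Phred+33
#'   encodable ceiling).
#' @return on merge, an object of class `ahe_merged_read` (fields `id`,
#'   `seq`, `qual`, `overlap`, `p_value`); otherwise `NULL`.
#' @export
merge_pair <- function(r1, r2, alpha = 1e-10, p_null = 0.25, qual_cap = 93L) {
  if (nchar(r1$seq) == 0L || nchar(r2$seq) == 0L) {
    warning("zero-length read; pair passed through unmerged")
    return(NULL)
  }
  s2 <- revcomp(r2$seq)
  q2 <- rev(r2$qual)
  counts <- overlap_match_counts(r1$seq, s2)
  pv <- overlap_pvalue(seq_along(counts), counts, p_null)
  best <- max(which(pv == min(pv)))          # tie -> longer overlap
  if (pv[best] >= alpha) return(NULL)
  o <- best
  n1 <- nchar(r1$seq); n2 <- nchar(s2)
  a <- seq_chars(r1$seq)[(n1 - o + 1L):n1]
  b <- seq_chars(s2)[seq_len(o)]
  qa <- r1$qual[(n1 - o + 1L):n1]
  qb <- q2[seq_len(o)]
  agree <- a == b & a != "N"
  base <- ifelse(agree, a, ifelse(b == "N" | (qa >= qb & a != "N"), a, b))
  qual <- ifelse(agree, pmin(qual_cap, qa + qb), abs(qa - qb))
  merged_seq <- paste0(substr(r1$seq, 1L, n1 - o),
                       paste(base, collapse = ""),
                       substr(s2, o + 1L, n2))
  merged_qual <- c(r1$qual[seq_len(n1 - o)], as.integer(qual),
                   q2[seq(o + 1L, length.out = n2 - o)])
  structure(list(id = r1$id, seq = merged_seq, qual = merged_qual,
                 overlap = o, p_value = pv[best]),
            class = "ahe_merged_read")
}

#' Merge all pairs of an individual's read set
#'
#' Produces the three-way partition used downstream: merged reads plus the
#' two unmerged mate files. Counts always satisfy
#' merged + unmerged = input pairs.
#'
#' @param r1,r2 character vectors of read sequences (r2 in sequencing
#'   orientation).
#' @param q1,q2 lists of integer Phred qualities.
#' @param ids read pair identifiers.
#' @param alpha merge threshold on the overlap p-value.
#' @param p_null chance match probability.
#' @return object of class `ahe_merge_result`: `merged` (list with `seq`,
#'   `qual`, `id`, `overlap`, `p_value`), `unmerged1`, `unmerged2` (same
#'   shape, no overlap fields), `n_pairs`.
#' @export
merge_pairs <- function(r1, q1, r2, q2, ids = NULL, alpha = 1e-10,
                        p_null = 0.25) {
  n <- length(r1)
  if (is.null(ids)) ids <- sprintf("pair%06d", seq_len(n))
  m_seq <- character(0); m_qual <- list(); m_id <- character(0)
  m_ov <- integer(0); m_p <- numeric(0)
  u_idx <- integer(0)
  for (i in seq_len(n)) {
    m <- merge_pair(qual_read(ids[i], r1[i], q1[[i]], 1L),
                    qual_read(ids[i], r2[i], q2[[i]], 2L),
                    alpha = alpha, p_null = p_null)
    if (is.null(m)) {
      u_idx <- c(u_idx, i)
    } else {
      k <- length(m_seq) + 1L
      m_seq[k] <- m$seq; m_qual[[k]] <- m$qual; m_id[k] <- m$id
      m_ov[k] <- m$overlap; m_p[k] <- m$p_value
    }
  }
  structure(list(
    merged = list(seq = m_seq, qual = m_qual, id = m_id,
                  overlap = m_ov, p_value = m_p),
    unmerged1 = list(seq = r1[u_idx], qual = q1[u_idx], id = ids[u_idx]),
    unmerged2 = list(seq = r2[u_idx], qual = q2[u_idx], id = ids[u_idx]),
    n_pairs = n), class = "ahe_merge_result")
}

#' @export
print.ahe_merge_result <- function(x, ...) {
  cat("Read merging:", x$n_pairs, "pairs ->", length(x$merged$seq),
      "merged,", length(x$unmerged1$seq), "left unmerged\n")
  invisible(x)
}

#' Write a merge result as the conventional three FASTQ files
#'
#' @param mr an `ahe_merge_result`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @export
write_merge_result <- function(mr, dir, prefix = "sample") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(mr$merged$seq, mr$merged$qual, mr$merged$id,
              file.path(dir, paste0(prefix, "_merged.fastq")))
  write_fastq(mr$unmerged1$seq, mr$unmerged1$qual, mr$unmerged1$id,
              file.path(dir, paste0(prefix, "_unmerged_R1.fastq")))
  write_fastq(mr$unmerged2$seq, mr$unmerged2$qual, mr$unmerged2$id,
              file.path(dir, paste0(prefix, "_unmerged_R2.fastq")))
  invisible(dir)
}
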