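# Offset refinement within assembly clusters and binomial consensus calling
# with IUPAC ambiguity codes and coverage-based soft-masking.

# Contig column of each read base, honouring an optional single gap after
# base `gap` (bases beyond the gap shift right by one).
.read_cols <- function(offset, len, gap) {
  cols <- offset + seq_len(len) - 1L
  if (!is.na(gap) && gap > 0L && gap < len)
    cols[(gap + 1L):len] <- cols[(gap + 1L):len] + 1L
  cols
}

# Base counts (4 x span) over cluster columns; non-ACGT bases are ignored.
.cluster_counts <- function(cluster, pad = 0L) {
  span <- cluster$span + 1L + pad            # +1 allows one gap shift
  counts <- matrix(0L, 4L, span + pad)
  for (i in seq_along(cluster$seq)) {
    rb <- match(seq_chars(cluster$seq[i]), DNA_BASES)
    cols <- .read_cols(cluster$offset[i], length(rb), cluster$gap[i]) + pad
    ok <- !is.na(rb) & cols >= 1L & cols <= ncol(counts)
    for (j in which(ok))
      counts[rb[j], cols[j]] <- counts[rb[j], cols[j]] + 1L
  }
  counts
}

#' Refine read offsets within an assembly cluster
#'
#' Greedy passes over the reads: each read tries offset shifts within
#' `max_shift` and a single gap insertion at every read position, adopting
#' the variant that maximises its agreement with the majority profile of the
#' remaining reads; a change is kept only if the total column agreement of
#' the cluster does not decrease. Passes repeat until a full pass makes no
#' change.
#'
#' @param cluster an `ahe_cluster`.
#' @param max_shift maximum offset shift per pass (default 3).
#' @param max_passes pass cap (default 10).
#' @return the refined `ahe_cluster` (offsets re-normalised to start at 1,
#'   with an `agreement` field).
#' @export
refine_offsets <- function(cluster, max_shift = 3L, max_passes = 10L) {
  n <- length(cluster$seq)
  pad <- max_shift + 1L
  rb_list <- lapply(cluster$seq, function(s) match(seq_chars(s), DNA_BASES))
  counts <- .cluster_counts(cluster, pad = pad)
  total_agreement <- function(cm) sum(apply(cm, 2L, max))
  add_read <- function(cm, i, sign) {
    rb <- rb_list[[i]]
    cols <- .read_cols(cluster$offset[i], length(rb), cluster$gap[i]) + pad
    ok <- !is.na(rb) & cols >= 1L & cols <= ncol(cm)
    for (j in which(ok)) cm[rb[j], cols[j]] <- cm[rb[j], cols[j]] + sign
    cm
  }
  for (pass in seq_len(max_passes)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      rb <- rb_list[[i]]
      len <- length(rb)
      cm0 <- add_read(counts, i, -1L)
      # majority-of-others profile (0 = no majority base)
      prof <- max.col(t(cm0), ties.method = "first")
      prof[colSums(cm0) == 0L] <- 0L
      prof_pad <- c(rep(0L, max_shift + 1L), prof, rep(0L, max_shift + 2L))
      p0 <- max_shift + 1L
      score_of <- function(off, gap) {
        cols <- .read_cols(off, len, gap) + pad
        sum(rb == prof_pad[cols + p0], na.rm = TRUE)
      }
      cur <- score_of(cluster$offset[i], cluster$gap[i])
      best <- list(score = cur, off = cluster$offset[i],
                   gap = cluster$gap[i])
      for (d in 0:max_shift) for (sg in if (d == 0L) 1L else c(1L, -1L)) {
        off <- cluster$offset[i] + d * sg
        cols <- off + seq_len(len) - 1L + pad
        m0 <- !is.na(rb) & rb == prof_pad[cols + p0]
        m1 <- !is.na(rb) & rb == prof_pad[cols + 1L + p0]
        sc_nogap <- sum(m0)
        if (sc_nogap > best$score)
          best <- list(score = sc_nogap, off = off, gap = NA_integer_)
        if (len > 1L) {
          c0 <- cumsum(m0); c1 <- cumsum(m1)
          g <- seq_len(len - 1L)
          sc_gap <- c0[g] + sum(m1) - c1[g]
          gi <- which.max(sc_gap)
          if (sc_gap[gi] > best$score)
            best <- list(score = sc_gap[gi], off = off, gap = g[gi])
        }
      }
      if (best$score > cur) {
        old_off <- cluster$offset[i]; old_gap <- cluster$gap[i]
        before <- total_agreement(counts)
        cluster$offset[i] <- best$off; cluster$gap[i] <- best$gap
        counts_new <- add_read(cm0, i, +1L)
        if (total_agreement(counts_new) >= before) {
          counts <- counts_new
          changed <- TRUE
        } else {                              # revert
          cluster$offset[i] <- old_off; cluster$gap[i] <- old_gap
        }
      }
    }
    if (!changed) break
  }
  shift <- 1L - min(cluster$offset)
  cluster$offset <- cluster$offset + shift
  lens <- nchar(cluster$seq)
  cluster$span <- max(cluster$offset + lens - 1L +
                        ifelse(!is.na(cluster$gap), 1L, 0L))
  cluster$agreement <- total_agreement(.cluster_counts(cluster))
  cluster
}

#' Call a soft-masked IUPAC consensus from an assembly cluster
#'
#' Per column with coverage n and majority-base count m: the majority base
#' is called when all bases agree or when the minority count n - m can be
#' explained as sequencing error under Binomial(n, `p_err`) at level
#' `alpha`; otherwise the IUPAC code over the majority base and every minor
#' base whose own count is individually significant is called. Bases at
#' columns with coverage below `mask_cov` are soft-masked (lowercase).
#'
#' @param cluster an (ideally refined) `ahe_cluster`.
#' @param p_err assumed per-base sequencing error probability (0.1).
#' @param alpha significance level of the error explanation (0.05).
#' @param mask_cov soft-mask coverage threshold (5).
#' @return object of class `ahe_consensus`: `locus`, `individual`, `seq`
#'   (lowercase = soft-masked), `coverage` (per site), `n_reads`.
#' @export
call_consensus <- function(cluster, p_err = 0.1, alpha = 0.05,
                           mask_cov = 5L) {
  counts <- .cluster_counts(cluster)
  # drop trailing all-zero columns introduced by the gap allowance
  last <- max(c(1L, which(colSums(counts) > 0L)))
  counts <- counts[, seq_len(last), drop = FALSE]
  n <- colSums(counts)
  out <- character(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    if (n[j] == 0L) { out[j] <- "N"; next }
    cj <- counts[, j]
    mi <- which.max(cj)
    m <- cj[mi]
    if (m == n[j] ||
        pbinom(n[j] - m - 1, n[j], p_err, lower.tail = FALSE) >= alpha) {
      out[j] <- DNA_BASES[mi]
    } else {
      minor <- setdiff(which(cj > 0L), mi)
      sig <- minor[pbinom(cj[minor] - 1, n[j], p_err,
                          lower.tail = FALSE) < alpha]
      out[j] <- iupac_code(DNA_BASES[c(mi, sig)])
    }
  }
  low <- n < mask_cov
  out[low] <- tolower(out[low])
  structure(list(locus = cluster$locus, individual = cluster$individual,
                 seq = paste(out, collapse = ""), coverage = as.integer(n),
                 n_reads = cluster$n_reads),
            class = "ahe_consensus")
}

#' @export
print.ahe_consensus <- function(x, ...) {
  cat("Consensus", x$locus, "/", x$individual, ":", nchar(x$seq), "bp,",
      x$n_reads, "reads, median coverage", stats::median(x$coverage), "\n")
  invisible(x)
}

#' Refine and call consensus for every cluster of an assembly
#'
#' @param assembly an [assemble_individual()] result.
#' @param ... passed to [call_consensus()].
#' @return list of `ahe_consensus` objects.
#' @export
consensus_sequences <- function(assembly, ...) {
  lapply(assembly$clusters, function(cl) call_consensus(refine_offsets(cl),
                                                        ...))
}
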