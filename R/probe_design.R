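# Probe/target design from multi-species locus alignments: pairwise-identity
# screening, exon-boundary detection with exact 40-mers, high-copy 15-mer
# masking against a genome, and uniform probe tiling.

#' Multi-species locus alignment container
#'
#' @param id locus identifier.
#' @param seqs named character vector of equal-length aligned sequences over
#'   A/C/G/T/-/N (case preserved).
#' @return object of class `ahe_locus_alignment`.
#' @export
locus_alignment <- function(id, seqs) {
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows must have equal length")
  if (anyDuplicated(names(seqs))) stop("taxon labels must be unique")
  structure(list(id = id, seqs = seqs, ncol = nchar(seqs[[1]])),
            class = "ahe_locus_alignment")
}

#' @export
print.ahe_locus_alignment <- function(x, ...) {
  cat("Locus alignment", x$id, ":", length(x$seqs), "taxa x", x$ncol,
      "columns\n")
  invisible(x)
}

# Alignment rows as an upper-case character matrix (rows = taxa).
aln_matrix <- function(seqs) {
  do.call(rbind, strsplit(toupper(unname(seqs)), ""))
}

#' Mean (or minimum) pairwise identity of an alignment window
#'
#' For every pair of rows, columns where either row carries a gap are
#' excluded from that pair's comparison; a pair's identity is matching
#' columns over compared columns. Returns the mean (default) or minimum over
#' pairs, as a percentage.
#'
#' @param rows character vector of equal-length aligned sequences (>= 2).
#' @param stat `"mean"` or `"min"` over row pairs.
#' @return identity in percent.
#' @export
pairwise_identity <- function(rows, stat = c("mean", "min")) {
  stat <- match.arg(stat)
  if (length(rows) < 2L) stop("undefined identity: need >= 2 rows")
  m <- aln_matrix(rows)
  gap <- m == "-"
  n <- nrow(m)
  vals <- c()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- !gap[i, ] & !gap[j, ]
    if (!any(comp)) next
    vals <- c(vals, sum(m[i, comp] == m[j, comp]) / sum(comp))
  }
  if (!length(vals)) stop("undefined identity: no comparable row pair")
  100 * if (stat == "mean") mean(vals) else min(vals)
}

#' Locate exon boundaries by exact 40-mer matching
#'
#' Assigns each transcript position the genome coordinate implied by the
#' leftmost exact `k`-mer match covering it; a boundary is reported wherever
#' the genome coordinates of adjacent assigned positions are non-consecutive.
#' Positions covered by no matching `k`-mer are returned as unknown runs.
#'
#' @param transcript,genome DNA strings (transcript length >= `k`).
#' @param k k-mer length (default 40).
#' @return list with `assignment` (genome coordinate per transcript position,
#'   NA when unknown), `boundaries` (0-based positions: number of transcript
#'   bases before each break) and `unknown` (data.frame of unassigned runs).
#' @export
find_exon_boundaries <- function(transcript, genome, k = 40L) {
  n <- nchar(transcript)
  if (n < k) stop("transcript shorter than k")
  tk <- consecutive_kmers(toupper(transcript), k)
  gk <- consecutive_kmers(toupper(genome), k)
  hit <- match(tk, gk)                       # leftmost genome start per k-mer
  assign <- rep(NA_integer_, n)
  for (s in seq_along(tk)) {
    if (is.na(hit[s])) next
    pos <- s:(s + k - 1L)
    new <- pos[is.na(assign[pos])]
    assign[new] <- hit[s] + (new - s)
  }
  if (all(is.na(assign))) warning("no ", k, "-mer matches found")
  adj <- which(!is.na(assign[-n]) & !is.na(assign[-1L]) &
                 assign[-1L] != assign[-n] + 1L)
  unknown <- .runs(is.na(assign))
  list(assignment = assign, boundaries = adj, unknown = unknown)
}

# Maximal runs of TRUE as data.frame(start, end) (1-based inclusive).
.runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Select capture target regions from a locus alignment
#'
#' A target is a maximal run of columns that (1) belongs to an alignment with
#' at least `min_taxa` rows, (2) is at least `min_len` columns long, (3)
#' spans no exon boundary of any member taxon, (4) contains no gap character
#' in any row, and (5) holds at least one `window`-column sub-window whose
#' pairwise identity is strictly greater than `min_ident` percent.
#'
#' @param aln an [locus_alignment()].
#' @param boundaries optional list (per taxon) of 0-based alignment-column
#'   boundary positions (a boundary at b cuts between columns b and b+1).
#' @param min_taxa minimum number of rows (default 6).
#' @param min_len minimum region length in bp (default 150).
#' @param window identity window length (default 120).
#' @param min_ident identity threshold in percent, strict (default 50).
#' @param stat identity statistic over pairs, `"mean"` or `"min"`.
#' @return data.frame of target regions with 0-based half-open `start`/`end`,
#'   `length`, `n_taxa`, `mean_identity`, `min_identity`,
#'   `best_window_identity`; empty when nothing qualifies.
#' @export
select_targets <- function(aln, boundaries = NULL, min_taxa = 6L,
                           min_len = 150L, window = 120L, min_ident = 50,
                           stat = c("mean", "min")) {
  stat <- match.arg(stat)
  empty <- data.frame(locus = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      n_taxa = integer(0), mean_identity = numeric(0),
                      min_identity = numeric(0),
                      best_window_identity = numeric(0))
  if (length(aln$seqs) < min_taxa) return(empty)
  m <- aln_matrix(aln$seqs)
  ok <- colSums(m == "-") == 0L
  cuts <- sort(unique(unlist(boundaries)))
  # a cut at 0-based b separates columns b and b+1 (1-based)
  allowed_after <- rep(TRUE, ncol(m))        # col i may extend to col i+1
  allowed_after[cuts[cuts >= 1 & cuts < ncol(m)]] <- FALSE
  regions <- list()
  runs <- .runs(ok)
  for (ri in seq_len(nrow(runs))) {
    s <- runs$start[ri]; e <- runs$end[ri]
    # split the run at boundary cuts
    brk <- which(!allowed_after[s:(e - 1L)]) + s - 1L
    starts <- c(s, brk + 1L); ends <- c(brk, e)
    for (pi in seq_along(starts))
      regions[[length(regions) + 1L]] <- c(starts[pi], ends[pi])
  }
  out <- list()
  for (rg in regions) {
    len <- rg[2] - rg[1] + 1L
    if (len < min_len) next
    sub <- m[, rg[1]:rg[2], drop = FALSE]
    wid <- .best_window_identity(sub, window, stat)
    if (is.na(wid) || wid <= min_ident) next
    rows <- apply(sub, 1L, paste, collapse = "")
    out[[length(out) + 1L]] <- data.frame(
      locus = aln$id, start = rg[1] - 1L, end = rg[2], length = len,
      n_taxa = nrow(m),
      mean_identity = pairwise_identity(rows, "mean"),
      min_identity = pairwise_identity(rows, "min"),
      best_window_identity = wid)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

# Best identity over all length-`window` sub-windows of a gap-free region
# (rolling mean over pairs via per-column pair-match totals). NA if the
# region is shorter than the window.
.best_window_identity <- function(m, window, stat = "mean") {
  L <- ncol(m)
  if (L < window) return(NA_real_)
  n <- nrow(m)
  pairs <- utils::combn(n, 2L)
  pm <- matrix(0, ncol(pairs), L)            # pair x column match indicator
  for (pi in seq_len(ncol(pairs)))
    pm[pi, ] <- m[pairs[1, pi], ] == m[pairs[2, pi], ]
  cs <- cbind(0, t(apply(pm, 1L, cumsum)))
  starts <- seq_len(L - window + 1L)
  wm <- (cs[, starts + window] - cs[, starts, drop = FALSE]) / window
  wstat <- if (stat == "mean") colMeans(wm) else apply(wm, 2L, min)
  100 * max(wstat)
}

#' Mask high-copy positions of a design sequence against a genome
#'
#' Builds the set of all `k`-mers of the sequence plus every `k`-mer at
#' Hamming distance 1, scans the genome exhaustively, tallies each genome
#' match at the `k` positions of the originating `k`-mer, and masks positions
#' whose tally exceeds `count_threshold`.
#'
#' @param seq design sequence for one species (gaps, if present, are ignored
#'   for k-mer extraction but positions are reported in the input
#'   coordinates).
#' @param genome genome sequence to scan.
#' @param count_threshold tally above which a position is masked (the
#'   production-scale default is 100000; desk-scale analyses use small
#'   values).
#' @param k k-mer length (default 15).
#' @return integer vector of masked positions (1-based, input coordinates).
#' @export
mask_high_copy <- function(seq, genome, count_threshold = 100000L, k = 15L) {
  ch <- seq_chars(toupper(seq))
  keep <- which(ch != "-")
  if (length(keep) < k) {
    warning("sequence shorter than ", k, "; nothing masked")
    return(integer(0))
  }
  ungap <- ch[keep]
  n <- length(ungap)
  starts <- seq_len(n - k + 1L)
  kmers <- vapply(starts, function(s) paste(ungap[s:(s + k - 1L)],
                                            collapse = ""), "")
  # dictionary: variant k-mer -> origin starts (original + Hamming-1)
  var_kmer <- character(0); var_start <- integer(0)
  for (si in seq_along(starts)) {
    km <- kmers[si]
    kch <- seq_chars(km)
    vars <- km
    for (p in seq_len(k)) for (b in setdiff(DNA_BASES, kch[p])) {
      v <- kch; v[p] <- b
      vars <- c(vars, paste(v, collapse = ""))
    }
    var_kmer <- c(var_kmer, vars)
    var_start <- c(var_start, rep(starts[si], length(vars)))
  }
  gk <- consecutive_kmers(toupper(genome), k)
  gcount <- table(gk)
  hits <- gcount[var_kmer]
  hits[is.na(hits)] <- 0L
  start_tally <- tapply(as.integer(hits), var_start, sum)
  tally_by_start <- rep(0L, length(starts))
  tally_by_start[as.integer(names(start_tally))] <- as.integer(start_tally)
  # position tally = sum over the k-mers covering the position
  cs <- c(0L, cumsum(tally_by_start))
  lo <- pmax(1L, seq_len(n) - k + 1L)
  hi <- pmin(length(starts), seq_len(n))
  pos_tally <- ifelse(hi < lo, 0L, cs[hi + 1L] - cs[lo])
  masked_ungap <- which(pos_tally > count_threshold)
  keep[masked_ungap]
}

#' Tile capture probes uniformly across a target region
#'
#' Probes of `probe_len` bases are placed with step `probe_len / density`;
#' the first probe starts at the region start and the last ends exactly at
#' the region end, so realised per-base coverage converges to `density` for
#' long regions.
#'
#' @param region_seq ungapped source sequence of the target region (one
#'   chosen source taxon).
#' @param probe_len probe length in bp (default 120).
#' @param density tiling density, mean probes covering each base
#'   (default 1.72).
#' @param locus,source optional labels carried into the output.
#' @return data.frame with `locus`, `source`, `start` (0-based), `length`,
#'   `sequence`; zero rows (with a warning) when the region is shorter than
#'   `probe_len`.
#' @export
tile_probes <- function(region_seq, probe_len = 120L, density = 1.72,
                        locus = NA_character_, source = NA_character_) {
  L <- nchar(region_seq)
  empty <- data.frame(locus = character(0), source = character(0),
                      start = integer(0), length = integer(0),
                      sequence = character(0))
  if (L < probe_len) {
    warning("region shorter than probe length; no probes")
    return(empty)
  }
  step <- probe_len / density
  n <- max(1L, as.integer(ceiling((L - probe_len) / step)) + 1L)
  starts <- if (n == 1L) 0L else
    as.integer(floor((seq_len(n) - 1L) * (L - probe_len) / (n - 1L)))
  data.frame(locus = locus, source = source, start = starts,
             length = probe_len,
             sequence = substring(region_seq, starts + 1L, starts + probe_len))
}

#' Split targets at masked positions and re-apply the length filter
#'
#' Masked columns are excluded from probe tiling; a masked position inside a
#' target splits it, and fragments shorter than `min_len` are dropped.
#'
#' @param targets data.frame from [select_targets()].
#' @param masked integer vector of masked alignment columns (1-based).
#' @param min_len minimum surviving fragment length.
#' @return data.frame with the same columns as `targets`.
#' @export
split_masked_targets <- function(targets, masked, min_len = 150L) {
  if (!length(masked) || !nrow(targets)) return(targets)
  out <- list()
  for (i in seq_len(nrow(targets))) {
    s <- targets$start[i] + 1L; e <- targets$end[i]     # 1-based inclusive
    cols <- setdiff(s:e, masked)
    if (!length(cols)) next
    runs <- .runs(seq(s, e) %in% cols)
    for (ri in seq_len(nrow(runs))) {
      rs <- s + runs$start[ri] - 1L; re <- s + runs$end[ri] - 1L
      if (re - rs + 1L < min_len) next
      row <- targets[i, ]
      row$start <- rs - 1L; row$end <- re; row$length <- re - rs + 1L
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) return(targets[0, ])
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
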