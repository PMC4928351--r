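# Hybrid reference/de-novo assembly: reads seed onto per-locus references
# through spaced 20-mer matches confirmed by a 100-base gap-free alignment
# score, then recruit further reads through exact 60-mer sharing until a
# fixed point; 60-mer components split reads into clusters, offsets are
# refined, and a soft-masked IUPAC consensus is called per cluster.

SPACED_K <- 20L
SPACED_STEP <- 3L
SPACED_SPAN <- (SPACED_K - 1L) * SPACED_STEP + 1L   # 58 bp window

#' Build a spaced 20-mer reference library from design alignments
#'
#' For each locus the reference is the majority-rule consensus of the design
#' alignment restricted to the probe (anchor) region when given; spaced
#' 20-mers (20 positions, every third base, 58 bp span) are anchored at
#' conserved alignment columns (modal-base frequency >= `min_identity`),
#' thinned evenly to at most `max_kmers_per_locus` per locus.
#'
#' @param loci named list; each element has `haps` (named character vector of
#'   equal-length ungapped design sequences) and optionally `anchor`
#'   (1-based inclusive probe-region interval).
#' @param min_identity column conservation level anchoring a spaced k-mer.
#' @param max_kmers_per_locus cap on indexed k-mers per locus.
#' @return object of class `ahe_reference_library`.
#' @export
reference_library <- function(loci, min_identity = 0.9,
                              max_kmers_per_locus = 12L) {
  pattern <- (seq_len(SPACED_K) - 1L) * SPACED_STEP      # 0-based offsets
  refs <- list()
  kl <- list()
  for (ln in names(loci)) {
    m <- aln_matrix(loci[[ln]]$haps)
    cons <- apply(m, 2L, function(col) {
      tb <- table(factor(col, DNA_BASES))
      names(tb)[which.max(tb)]
    })
    freq <- apply(m, 2L, function(col) max(table(col)) / length(col))
    anchor <- loci[[ln]]$anchor
    if (is.null(anchor)) anchor <- c(1L, ncol(m))
    idx <- anchor[1]:anchor[2]
    ref <- paste(cons[idx], collapse = "")
    cf <- freq[idx]
    starts <- which(cf >= min_identity)
    starts <- starts[starts + SPACED_SPAN - 1L <= length(idx)]
    if (length(starts) > max_kmers_per_locus)
      starts <- starts[unique(round(seq(1L, length(starts),
                                        length.out = max_kmers_per_locus)))]
    refs[[ln]] <- ref
    if (length(starts)) {
      ch <- seq_chars(ref)
      kseq <- vapply(starts, function(s)
        paste(ch[s + pattern], collapse = ""), "")
      kl[[ln]] <- data.frame(locus = ln, ref_pos = starts, seq = kseq)
    }
  }
  kmers <- if (length(kl)) do.call(rbind, kl) else
    data.frame(locus = character(0), ref_pos = integer(0), seq = character(0))
  rownames(kmers) <- NULL
  structure(list(refs = refs, kmers = kmers, pattern = pattern,
                 k = SPACED_K, span = SPACED_SPAN),
            class = "ahe_reference_library")
}

#' @export
print.ahe_reference_library <- function(x, ...) {
  cat("Spaced-kmer reference library:", length(x$refs), "loci,",
      nrow(x$kmers), "spaced", paste0(x$k, "-mers"),
      "(span", x$span, "bp)\n")
  invisible(x)
}

#' Preliminary locus hits of a read by spaced k-mer matching
#'
#' Counts positional matches between each indexed spaced 20-mer and every
#' read window; windows matching at least `min_hits` of the 20 sampled
#' positions are reported with the implied locus and reference offset.
#'
#' @param read read sequence (forward strand as given).
#' @param library an [reference_library()].
#' @param min_hits minimum positional matches out of 20 (default 17).
#' @return data.frame with `locus`, `offset` (1-based reference position of
#'   read base 1 implied by the hit), `read_start`, `matches`.
#' @export
spaced_kmer_match <- function(read, library, min_hits = 17L) {
  empty <- data.frame(locus = character(0), offset = integer(0),
                      read_start = integer(0), matches = integer(0))
  if (nchar(read) < library$span || !nrow(library$kmers)) return(empty)
  h <- spaced_kmer_scan(toupper(read), library$kmers$seq,
                        as.integer(library$pattern), as.integer(min_hits))
  if (!nrow(h)) return(empty)
  data.frame(locus = library$kmers$locus[h[, 1L]],
             offset = library$kmers$ref_pos[h[, 1L]] - h[, 2L] + 1L,
             read_start = h[, 2L], matches = h[, 3L])
}

#' Map a read against a locus reference by the best gap-free placement
#'
#' Scores every gap-free offset of the read against the reference by the
#' maximum number of matches within any `window` consecutive aligned bases;
#' the read maps if the best score reaches `min_matches`, with ties broken
#' toward the smallest offset.
#'
#' @param read,reference DNA strings.
#' @param min_matches mapping threshold (default 55 of 100).
#' @param window scoring window (default 100).
#' @return list with `mapped` (logical), `matches`, `offset` (1-based
#'   reference position of read base 1; may be <= 0 when the read overhangs
#'   the reference start).
#' @export
map_read <- function(read, reference, min_matches = 55L, window = 100L) {
  r <- best_gapfree_placement(toupper(read), toupper(reference),
                              as.integer(window))
  list(mapped = r[1] >= min_matches, matches = r[1], offset = r[2] + 1L)
}

# --- internal assembly machinery ------------------------------------------

# 60-mers of a sequence with their 1-based start positions.
.denovo_kmers <- function(seq, k = 60L) {
  km <- consecutive_kmers(seq, k)
  if (!length(km)) return(NULL)
  list(seq = km, pos = seq_along(km))
}

# Try to place a read (both orientations) on a locus via the reference
# library; returns list(locus, offset, seq_oriented) or NULL.
.place_by_reference <- function(seq, library, min_hits, min_matches, window,
                                max_candidates = 3L) {
  best <- NULL
  for (s in c("+", "-")) {
    sq <- if (s == "+") seq else revcomp(seq)
    hits <- spaced_kmer_match(sq, library, min_hits)
    if (!nrow(hits)) next
    cand <- unique(hits$locus[order(-hits$matches)])
    cand <- head(cand, max_candidates)
    for (lc in cand) {
      mr <- map_read(sq, library$refs[[lc]], min_matches, window)
      if (mr$mapped && (is.null(best) || mr$matches > best$matches))
        best <- list(locus = lc, offset = mr$offset, seq = sq,
                     matches = mr$matches)
    }
  }
  best
}

# Try to place a read via exact 60-mer sharing with the hash `env`
# (key = 60-mer, value = c(locus_index, contig_pos)); returns
# list(locus_idx, offset, seq_oriented) or NULL.
.place_by_denovo <- function(seq, env, k = 60L) {
  for (s in c("+", "-")) {
    sq <- if (s == "+") seq else revcomp(seq)
    km <- .denovo_kmers(sq, k)
    if (is.null(km)) next
    hit_loc <- integer(0); hit_off <- integer(0)
    for (i in seq_along(km$seq)) {
      v <- env[[km$seq[i]]]
      if (!is.null(v)) {
        hit_loc <- c(hit_loc, v[1L])
        hit_off <- c(hit_off, v[2L] - (km$pos[i] - 1L))
      }
    }
    if (length(hit_loc)) {
      tb <- table(hit_loc)
      lc <- as.integer(names(tb)[which.max(tb)])
      off <- as.integer(round(stats::median(hit_off[hit_loc == lc])))
      return(list(locus_idx = lc, offset = off, seq = sq))
    }
  }
  NULL
}

# Register a placed read's 60-mers in the hash (first placement wins).
.register_kmers <- function(env, seq, locus_idx, offset, k = 60L) {
  km <- .denovo_kmers(seq, k)
  if (is.null(km)) return(invisible())
  for (i in seq_along(km$seq)) {
    key <- km$seq[i]
    if (is.null(env[[key]]))
      env[[key]] <- c(locus_idx, offset + km$pos[i] - 1L)
  }
  invisible()
}

#' Assemble one individual's reads into per-locus clusters
#'
#' Iterates over the three read files (merged, unmerged mate 1 and 2): a
#' read joins a locus either through the spaced-k-mer/100-base reference
#' mapping or by sharing at least one exact 60-mer with an already-placed
#' read; each newly placed read contributes its 60-mers, and passes repeat
#' until no read is added. 60-mers co-occurring in at least two reads are
#' then unioned and reads are partitioned into clusters by the component
#' holding the majority of their 60-mers.
#'
#' @param mr an [merge_pairs()] result (or a list with `merged`,
#'   `unmerged1`, `unmerged2` entries of `seq` + `id`).
#' @param library an [reference_library()].
#' @param individual sample label carried into the clusters.
#' @param min_hits spaced k-mer threshold (17 of 20).
#' @param min_matches mapping threshold (55 of 100).
#' @param window mapping window (100).
#' @param k_denovo de-novo k-mer length (60).
#' @param min_pair_reads reads in which a 60-mer pair must co-occur to be
#'   unioned (2).
#' @param max_iter fixed-point iteration cap.
#' @return object of class `ahe_assembly`: `clusters` (list of
#'   `ahe_cluster`), `n_reads`, `unplaced` ids.
#' @export
assemble_individual <- function(mr, library, individual = "sample",
                                min_hits = 17L, min_matches = 55L,
                                window = 100L, k_denovo = 60L,
                                min_pair_reads = 2L, max_iter = 50L) {
  seqs <- toupper(c(mr$merged$seq, mr$unmerged1$seq, mr$unmerged2$seq))
  ids <- c(paste0(mr$merged$id, "/m"),
           paste0(mr$unmerged1$id, "/1"),
           paste0(mr$unmerged2$id, "/2"))
  n <- length(seqs)
  locus_names <- names(library$refs)
  placed_locus <- rep(NA_integer_, n)
  placed_offset <- rep(NA_integer_, n)
  placed_seq <- character(n)
  env <- new.env(hash = TRUE, size = 4L * sum(nchar(seqs)))
  it <- 0L
  repeat {
    it <- it + 1L
    added <- 0L
    for (i in which(is.na(placed_locus))) {
      p <- .place_by_reference(seqs[i], library, min_hits, min_matches,
                               window)
      if (!is.null(p)) {
        li <- match(p$locus, locus_names)
        placed_locus[i] <- li; placed_offset[i] <- p$offset
        placed_seq[i] <- p$seq
        .register_kmers(env, p$seq, li, p$offset, k_denovo)
        added <- added + 1L
        next
      }
      p <- .place_by_denovo(seqs[i], env, k_denovo)
      if (!is.null(p)) {
        placed_locus[i] <- p$locus_idx; placed_offset[i] <- p$offset
        placed_seq[i] <- p$seq
        .register_kmers(env, p$seq, p$locus_idx, p$offset, k_denovo)
        added <- added + 1L
      }
    }
    if (added == 0L) break
    if (it >= max_iter) {
      warning("assembly fixed point not reached after ", max_iter, " passes")
      break
    }
  }
  clusters <- list()
  for (li in sort(unique(placed_locus[!is.na(placed_locus)]))) {
    ridx <- which(placed_locus == li)
    comp <- .cluster_reads(placed_seq[ridx], k_denovo, min_pair_reads)
    for (ci in sort(unique(comp))) {
      sel <- ridx[comp == ci]
      off <- placed_offset[sel]
      shift <- 1L - min(off)
      clusters[[length(clusters) + 1L]] <- structure(
        list(locus = locus_names[li], individual = individual,
             id = ids[sel], seq = placed_seq[sel], offset = off + shift,
             gap = rep(NA_integer_, length(sel)),
             n_reads = length(sel),
             span = max(off + shift + nchar(placed_seq[sel]) - 1L)),
        class = "ahe_cluster")
    }
  }
  structure(list(individual = individual, clusters = clusters,
                 n_reads = n, unplaced = ids[is.na(placed_locus)],
                 iterations = it),
            class = "ahe_assembly")
}

#' @export
print.ahe_assembly <- function(x, ...) {
  cat("Assembly of", x$individual, ":", x$n_reads, "reads ->",
      length(x$clusters), "clusters (", length(x$unplaced), "unplaced )\n")
  invisible(x)
}

#' @export
print.ahe_cluster <- function(x, ...) {
  cat("Assembly cluster", x$locus, "/", x$individual, ":", x$n_reads,
      "reads, span", x$span, "bp\n")
  invisible(x)
}

# Partition reads of one locus into components of their 60-mers: pairs of
# 60-mers at adjacent read positions co-occurring in >= min_pair_reads reads
# are unioned; each read goes to the component holding the majority of its
# 60-mers (ties -> larger component).
.cluster_reads <- function(seqs, k, min_pair_reads) {
  n <- length(seqs)
  if (n == 1L) return(1L)
  read_kmers <- lapply(seqs, consecutive_kmers, k = k)
  all_k <- unique(unlist(read_kmers))
  if (!length(all_k)) return(seq_len(n))     # reads shorter than k
  kid <- lapply(read_kmers, match, table = all_k)
  pair_keys <- unlist(lapply(kid, function(ki) {
    if (length(ki) < 2L) return(character(0))
    a <- ki[-length(ki)]; b <- ki[-1L]
    unique(paste(pmin(a, b), pmax(a, b)))
  }))
  tb <- table(pair_keys)
  good <- names(tb)[tb >= min_pair_reads]
  parent <- seq_along(all_k)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (key in good) {
    ab <- as.integer(strsplit(key, " ", fixed = TRUE)[[1]])
    ra <- find(ab[1]); rb <- find(ab[2])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(all_k), find, 0L)
  comp_size <- table(roots)
  read_comp <- vapply(kid, function(ki) {
    if (!length(ki)) return(NA_integer_)
    r <- roots[ki]
    tb <- table(r)
    best <- names(tb)[tb == max(tb)]
    if (length(best) > 1L)
      best <- best[which.max(comp_size[best])]
    as.integer(best)
  }, 0L)
  if (anyNA(read_comp)) read_comp[is.na(read_comp)] <- -seq_len(sum(is.na(read_comp)))
  match(read_comp, unique(read_comp))
}
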