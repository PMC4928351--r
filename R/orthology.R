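# Contamination filtering and orthology assignment: low-coverage consensus
# removal, shared-20-mer Jaccard distance (consecutive + spaced every-third-
# base k-mers), and constrained agglomeration allowing at most one sequence
# per individual per cluster.

#' Keep or drop a consensus sequence by assembly-cluster read count
#'
#' Consensus sequences from very low coverage clusters are treated as
#' possible low-level contaminants and removed.
#'
#' @param consensus an `ahe_consensus` (or anything with an `n_reads`
#'   field), or a bare read count.
#' @param min_reads minimum read count to keep (default 10; clusters with
#'   fewer reads are removed).
#' @return logical: keep?
#' @export
filter_low_coverage <- function(consensus, min_reads = 10L) {
  n <- if (is.numeric(consensus)) consensus else consensus$n_reads
  n >= min_reads
}

#' Combined k-mer set of a sequence for orthology distance
#'
#' Union of all consecutive 20-mers and all spaced 20-mers (20 positions,
#' every third base, 58 bp span), case-folded so soft-masked bases
#' participate.
#'
#' @param seq DNA string.
#' @param k k-mer length (default 20).
#' @param step spacing of the spaced k-mers (default 3).
#' @return character vector of distinct k-mers.
#' @export
ortho_kmers <- function(seq, k = 20L, step = 3L) {
  s <- toupper(seq)
  unique(c(consecutive_kmers(s, k), spaced_kmers(s, k, step)))
}

#' Shared-k-mer distance between two sequences
#'
#' One minus the Jaccard similarity of the two combined k-mer sets
#' ([ortho_kmers()]).
#'
#' @param a,b DNA strings.
#' @return distance in `[0, 1]`; 1 (with a warning) when a sequence is too
#'   short to yield any k-mer.
#' @export
kmer_distance <- function(a, b) {
  ka <- ortho_kmers(a); kb <- ortho_kmers(b)
  if (!length(ka) || !length(kb)) {
    warning("sequence too short for k-mer distance; returning 1")
    return(1)
  }
  inter <- length(intersect(ka, kb))
  1 - inter / (length(ka) + length(kb) - inter)
}

#' Cluster homologs of one locus into ortholog sets
#'
#' Pairwise shared-k-mer distances are ranked from smallest to largest and
#' sequences agglomerated in that order; a merge is skipped (not deferred)
#' when the union would hold two sequences from the same individual, so
#' every final cluster holds at most one sequence per individual. Clusters
#' covering fewer than `min_occupancy` of the study's species are dropped.
#' Equal distances are processed in lexicographic order of the member-id
#' pair, making the output invariant to input order.
#'
#' @param homologs list of `ahe_consensus` objects (or lists with `seq` and
#'   `individual`), all from one locus; names are used as member ids
#'   (defaults to `individual.k`).
#' @param n_species total number of species in the study (occupancy
#'   denominator); defaults to the number of distinct individuals present.
#' @param min_occupancy minimum species-occupancy fraction (default 0.5).
#' @param max_dist pairs at or above this distance never join (default 1:
#'   sequences sharing no k-mer at all are not clustered together).
#' @return list of ortholog clusters: each has `locus`, `members` (named
#'   list of the input elements), `individuals`, `occupancy`.
#' @export
cluster_orthologs <- function(homologs, n_species = NULL,
                              min_occupancy = 0.5, max_dist = 1) {
  n <- length(homologs)
  if (!n) return(list())
  inds <- vapply(homologs, function(h) h$individual, "")
  if (is.null(names(homologs)) || anyDuplicated(names(homologs)))
    names(homologs) <- make.unique(inds, sep = ".")
  ids <- names(homologs)
  if (is.null(n_species)) n_species <- length(unique(inds))
  locus <- if (!is.null(homologs[[1]]$locus)) homologs[[1]]$locus else NA
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n > 1L) {
    pr <- utils::combn(n, 2L)
    d <- apply(pr, 2L, function(p)
      kmer_distance(homologs[[p[1]]]$seq, homologs[[p[2]]]$seq))
    key <- apply(pr, 2L, function(p)
      paste(sort(c(ids[p[1]], ids[p[2]])), collapse = "\r"))
    ord <- order(d, key)
    for (e in ord) {
      if (d[e] >= max_dist) break
      a <- find(pr[1, e]); b <- find(pr[2, e])
      if (a == b) next
      mem_a <- which(vapply(seq_len(n), find, 0L) == a)
      mem_b <- which(vapply(seq_len(n), find, 0L) == b)
      if (length(intersect(inds[mem_a], inds[mem_b]))) next
      parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  out <- list()
  for (r in unique(roots)) {
    mem <- which(roots == r)
    occ <- length(unique(inds[mem])) / n_species
    if (occ < min_occupancy) next
    cl <- list(locus = locus, members = homologs[mem],
               individuals = unname(inds[mem]), occupancy = occ)
    out[[length(out) + 1L]] <- cl
  }
  # deterministic output order: by lexicographically smallest member id
  if (length(out) > 1L)
    out <- out[order(vapply(out, function(cl) min(names(cl$members)), ""))]
  out
}

#' Filter consensus sequences and build per-locus ortholog sets
#'
#' Applies the low-coverage contamination filter, groups the survivors by
#' locus into homolog sets, and clusters each set with the per-individual
#' constraint and the species-occupancy filter.
#'
#' @param consensus list of `ahe_consensus` objects across individuals.
#' @param n_species total species count in the study.
#' @param min_reads contamination filter threshold (default 10).
#' @param min_occupancy occupancy filter (default 0.5).
#' @return named list (by locus) of lists of ortholog clusters (see
#'   [cluster_orthologs()]).
#' @export
orthology_sets <- function(consensus, n_species, min_reads = 10L,
                           min_occupancy = 0.5) {
  keep <- vapply(consensus, filter_low_coverage, TRUE,
                 min_reads = min_reads)
  consensus <- consensus[keep]
  loci <- vapply(consensus, function(x) x$locus, "")
  out <- list()
  for (lc in sort(unique(loci))) {
    hs <- consensus[loci == lc]
    cls <- cluster_orthologs(hs, n_species = n_species,
                             min_occupancy = min_occupancy)
    if (length(cls)) out[[lc]] <- cls
  }
  out
}
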