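# Supermatrix construction: concatenation of trimmed loci with a partition
# table, occupancy/informativeness statistics, phylogenetics-tool output
# (relaxed PHYLIP / FASTA / RAxML partition file) and a neighbor-joining
# sanity tree.

#' Concatenate trimmed locus alignments into a partitioned supermatrix
#'
#' Taxa are the union over loci; a taxon absent from a locus is padded with
#' `?` across that locus' columns. Partition intervals are 1-based
#' inclusive, disjoint, contiguous and cover all columns.
#'
#' @param trimmed named list (by locus) of `ahe_trimmed` objects or named
#'   character vectors of equal-length aligned sequences.
#' @return object of class `ahe_supermatrix`: `seqs` (named character
#'   vector), `partitions` (data.frame locus/start/end), `n_taxa`,
#'   `n_sites`, `informative_sites`, `missing_frac`, `taxon_missing`,
#'   `locus_missing`.
#' @export
concatenate_loci <- function(trimmed) {
  stopifnot(length(trimmed) >= 1L)
  alns <- lapply(trimmed, function(x) if (inherits(x, "ahe_trimmed")) x$aln
                 else x)
  if (is.null(names(alns)))
    names(alns) <- sprintf("locus%03d", seq_along(alns))
  for (ln in names(alns))
    if (anyDuplicated(names(alns[[ln]])))
      stop("duplicate taxon labels within locus ", ln)
  taxa <- sort(unique(unlist(lapply(alns, names))))
  lens <- vapply(alns, function(a) nchar(a[[1]]), 0L)
  parts <- data.frame(locus = names(alns),
                      start = cumsum(c(1L, head(lens, -1L))),
                      end = cumsum(lens))
  rownames(parts) <- NULL
  seqs <- setNames(character(length(taxa)), taxa)
  locus_missing <- setNames(numeric(length(alns)), names(alns))
  for (li in seq_along(alns)) {
    a <- alns[[li]]
    block <- vapply(taxa, function(tx)
      if (tx %in% names(a)) a[[tx]] else strrep("?", lens[li]), "")
    seqs <- paste0(seqs, block)
    locus_missing[li] <- mean(vapply(block, function(s) {
      ch <- seq_chars(s); mean(ch == "?" | ch == "-")
    }, 0))
  }
  names(seqs) <- taxa
  taxon_missing <- vapply(seqs, function(s) {
    ch <- seq_chars(s); mean(ch == "?" | ch == "-")
  }, 0)
  structure(list(seqs = seqs, partitions = parts,
                 n_taxa = length(taxa), n_sites = sum(lens),
                 informative_sites = count_informative(seqs),
                 missing_frac = mean(taxon_missing),
                 taxon_missing = taxon_missing,
                 locus_missing = locus_missing),
            class = "ahe_supermatrix")
}

#' @export
print.ahe_supermatrix <- function(x, ...) {
  cat("Supermatrix:", x$n_taxa, "taxa x", x$n_sites, "sites over",
      nrow(x$partitions), "loci;", x$informative_sites,
      sprintf("informative sites; %.1f%% missing\n", 100 * x$missing_frac))
  invisible(x)
}

#' Count parsimony-informative sites
#'
#' A site is parsimony-informative when at least two distinct A/C/G/T states
#' each occur in at least two taxa; IUPAC ambiguities, `N`, `-` and `?` are
#' treated as missing.
#'
#' @param x an `ahe_supermatrix` or a named character vector of equal-length
#'   sequences.
#' @return number of informative sites.
#' @export
count_informative <- function(x) {
  seqs <- if (inherits(x, "ahe_supermatrix")) x$seqs else x
  m <- aln_matrix(seqs)
  sum(vapply(seq_len(ncol(m)), function(j) {
    tb <- table(factor(m[, j], DNA_BASES))
    sum(tb >= 2L) >= 2L
  }, TRUE))
}

#' Neighbor-joining sanity tree from a supermatrix
#'
#' Pairwise p-distances with pairwise deletion of missing data (anything
#' outside A/C/G/T), then [ape::nj()]; negative branch lengths are clamped
#' to zero.
#'
#' @param x an `ahe_supermatrix` or named character vector of sequences.
#' @param outgroup optional taxon to root the returned tree on.
#' @return an [ape::phylo] tree.
#' @export
nj_tree <- function(x, outgroup = NULL) {
  seqs <- if (inherits(x, "ahe_supermatrix")) x$seqs else x
  if (length(seqs) < 3L) stop("need >= 3 taxa")
  m <- aln_matrix(seqs)
  valid <- matrix(m %in% DNA_BASES, nrow(m))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- valid[i, ] & valid[j, ]
    if (!any(comp))
      stop("no comparable sites between ", names(seqs)[i], " and ",
           names(seqs)[j])
    d[i, j] <- d[j, i] <- mean(m[i, comp] != m[j, comp])
  }
  tr <- ape::nj(d)
  tr$edge.length <- pmax(tr$edge.length, 0)
  if (!is.null(outgroup))
    tr <- ape::root(tr, outgroup, resolve.root = TRUE)
  tr
}

#' Write a supermatrix and its companion files
#'
#' Emits relaxed PHYLIP, FASTA (upper-cased, with a sidecar BED of any
#' soft-masked lowercase cells), a RAxML-style partition file
#' (`DNA, locus = a-b`, 1-based inclusive) and a stats TSV.
#'
#' @param sm an `ahe_supermatrix`.
#' @param dir output directory.
#' @param prefix file-name prefix (default `"supermatrix"`).
#' @export
write_supermatrix <- function(sm, dir, prefix = "supermatrix") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_phylip(sm$seqs, file.path(dir, paste0(prefix, ".phy")))
  lower <- lapply(sm$seqs, function(s)
    which(seq_chars(s) %in% letters))
  if (any(lengths(lower) > 0L)) {
    bed <- do.call(rbind, lapply(names(lower), function(tx) {
      if (!length(lower[[tx]])) return(NULL)
      r <- .runs(seq_len(nchar(sm$seqs[[tx]])) %in% lower[[tx]])
      data.frame(chrom = tx, start = r$start - 1L, end = r$end)
    }))
    write.table(bed, file.path(dir, paste0(prefix, "_softmask.bed")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  write_fasta(toupper(sm$seqs), file.path(dir, paste0(prefix, ".fasta")))
  writeLines(sprintf("DNA, %s = %d-%d", sm$partitions$locus,
                     sm$partitions$start, sm$partitions$end),
             file.path(dir, paste0(prefix, "_partitions.txt")))
  stats <- data.frame(taxa = sm$n_taxa, loci = nrow(sm$partitions),
                      sites = sm$n_sites,
                      informative_sites = sm$informative_sites,
                      pct_missing = round(100 * sm$missing_frac, 2))
  write.table(stats, file.path(dir, paste0(prefix, "_stats.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
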