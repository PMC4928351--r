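# File formats: FASTQ (Phred+33), case-preserving FASTA, truth tables,
# relaxed PHYLIP. Parsing of FASTQ goes through Biostrings; FASTA through
# seqinr (which preserves soft-mask case).

#' Write reads to a 4-line FASTQ file (Phred+33)
#'
#' @param seqs character vector of read sequences.
#' @param quals list of integer Phred quality vectors (one per read).
#' @param ids read identifiers.
#' @param path output file.
#' @export
write_fastq <- function(seqs, quals, ids, path) {
  stopifnot(length(seqs) == length(quals), length(seqs) == length(ids))
  qstr <- vapply(quals, function(q) intToUtf8(pmin(q, 93L) + 33L), "")
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qstr), path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (Phred+33).
#' @return list with `seq` (named character vector), `qual` (list of integer
#'   vectors) and `id`.
#' @export
read_fastq <- function(path) {
  # suppress Biostrings' note about dropped metadata columns on subsetting
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  quals <- suppressWarnings(
    lapply(as(Biostrings::quality(x), "IntegerList"), as.integer))
  seqs <- suppressWarnings(as.character(x))
  ids <- sub("\\s.*$", "", names(x))
  names(seqs) <- ids
  list(seq = seqs, qual = unname(quals), id = ids)
}

#' Write sequences to FASTA, preserving case
#'
#' Case matters here: lowercase encodes coverage soft-masking in consensus
#' sequences.
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = width)
  invisible(path)
}

#' Read a FASTA file as a named character vector (case preserved)
#'
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  setNames(vapply(x, function(s) as.character(s)[1], ""), names(x))
}

#' Write simulated reads and truth tables to a directory
#'
#' Emits per-individual paired FASTQ (`<ind>_R1.fastq`, `<ind>_R2.fastq`),
#' the provenance table as TSV, the species tree as Newick and the true
#' haplotypes as one FASTA per locus.
#'
#' @param sim list from [simulate_ahe()] (or `truth` + `reads` separately).
#' @param dir output directory (created if needed).
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tx in names(sim$reads$individuals)) {
    ind <- sim$reads$individuals[[tx]]
    write_fastq(ind$r1, ind$q1, paste0(ind$id, "/1"),
                file.path(dir, paste0(tx, "_R1.fastq")))
    write_fastq(ind$r2, ind$q2, paste0(ind$id, "/2"),
                file.path(dir, paste0(tx, "_R2.fastq")))
  }
  write.table(sim$reads$provenance, file.path(dir, "provenance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$truth$tree, file.path(dir, "species_tree.nwk"))
  for (ln in names(sim$truth$loci))
    write_fasta(sim$truth$loci[[ln]]$haps,
                file.path(dir, paste0(ln, "_truth.fasta")))
  invisible(dir)
}

#' Write a supermatrix in relaxed PHYLIP format
#'
#' @param mat character matrix (taxa x sites, single characters) or named
#'   character vector of equal-length sequences.
#' @param path output file.
#' @export
write_phylip <- function(mat, path) {
  seqs <- if (is.matrix(mat)) {
    setNames(apply(mat, 1L, paste, collapse = ""), rownames(mat))
  } else mat
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(seqs), nchar(seqs[[1]])), con)
  writeLines(paste(names(seqs), seqs), con)
  invisible(path)
}

#' Read a relaxed PHYLIP alignment
#'
#' @param path PHYLIP file written by [write_phylip()].
#' @return named character vector of sequences.
#' @export
read_phylip <- function(path) {
  ln <- readLines(path)
  hd <- as.integer(strsplit(trimws(ln[1]), "\\s+")[[1]])
  rows <- strsplit(trimws(ln[1 + seq_len(hd[1])]), "\\s+")
  out <- setNames(vapply(rows, `[`, "", 2L), vapply(rows, `[`, "", 1L))
  stopifnot(all(nchar(out) == hd[2]))
  out
}
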