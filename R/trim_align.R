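# Multiple alignment (external MAFFT, with a bundled star aligner as a
# fallback) and the three-step conservation-based trimming/masking
# procedure: conserved-column flagging, per-sequence window masking, and
# sparse-column removal.

#' Align an ortholog set
#'
#' Invokes the configured external aligner (MAFFT, with `--genafpair
#' --maxiterate 1000` by default) and parses the aligned FASTA back in input
#' row order. When `method = "fallback"` a bundled center-star progressive
#' aligner (global pairwise alignments against the longest sequence, merged
#' on the star center) is used instead; it is intended for tests and tiny
#' inputs only.
#'
#' @param seqs named character vector of >= 2 unaligned sequences.
#' @param method `"mafft"` or `"fallback"`.
#' @param exe aligner executable (config key `aligner_exe`).
#' @param flags aligner flags, recorded in the result's `aligner_cmd`
#'   attribute.
#' @return named character vector of equal-length aligned (upper-case)
#'   sequences, in input order.
#' @export
run_aligner <- function(seqs, method = c("mafft", "fallback"),
                        exe = "mafft",
                        flags = c("--genafpair", "--maxiterate", "1000")) {
  method <- match.arg(method)
  stopifnot(length(seqs) >= 2L)
  if (method == "mafft") {
    if (Sys.which(exe) == "")
      stop("aligner executable '", exe, "' not found; set aligner_exe ",
           "or use method = \"fallback\"")
    fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
    on.exit(unlink(c(fin, fout)))
    write_fasta(setNames(toupper(seqs), names(seqs)), fin)
    status <- system2(exe, c(flags, "--quiet", fin), stdout = fout)
    if (status != 0L) stop("aligner exited with status ", status)
    aln <- toupper(read_fasta(fout))
    aln <- aln[names(seqs)]
    attr(aln, "aligner_cmd") <- paste(exe, paste(flags, collapse = " "))
    return(aln)
  }
  aln <- .star_align(toupper(seqs))
  attr(aln, "aligner_cmd") <- "internal center-star aligner"
  aln
}

# Center-star progressive alignment: global pairwise alignment of every
# sequence against the longest one, merged by taking the per-gap maximum
# insertion length at each center position.
.star_align <- function(seqs) {
  n <- length(seqs)
  center <- which.max(nchar(seqs))
  cs <- seqs[[center]]
  L <- nchar(cs)
  others <- setdiff(seq_len(n), center)
  # per pair: aligned pattern/subject strings
  pats <- vector("list", n)
  ins <- matrix(0L, n, L + 1L)     # insertions before center pos c (0..L)
  for (i in others) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(gsub("[^ACGT]", "N", seqs[[i]])),
      Biostrings::DNAString(gsub("[^ACGT]", "N", cs)),
      type = "global", gapOpening = 10, gapExtension = 0.5)
    ap <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
    as_ <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
    pats[[i]] <- list(p = ap, s = as_)
    cpos <- cumsum(as_ != "-")               # center coordinate per column
    run <- rle(as_ == "-")
    # insertion runs: columns where subject is gapped
    idx <- cumsum(run$lengths)
    for (ri in which(run$values)) {
      before <- cpos[idx[ri]]                # center pos the run sits after
      ins[i, before + 1L] <- max(ins[i, before + 1L], run$lengths[ri])
    }
  }
  master_ins <- apply(ins, 2L, max)
  # rebuild rows in master coordinates
  out <- character(n)
  # center row
  parts <- character(0)
  for (c in 0:L) {
    parts <- c(parts, strrep("-", master_ins[c + 1L]),
               if (c < L) substr(cs, c + 1L, c + 1L) else "")
  }
  out[center] <- paste(parts, collapse = "")
  for (i in others) {
    ap <- pats[[i]]$p; as_ <- pats[[i]]$s
    cpos <- c(0L, cumsum(as_ != "-"))
    row <- character(0)
    col <- 1L
    for (c in 0:L) {
      # columns of the pairwise alignment inserted before center pos c+1
      seg <- character(0)
      while (col <= length(as_) && as_[col] == "-" &&
             (col == 1L || cpos[col] == c)) {
        seg <- c(seg, ap[col]); col <- col + 1L
      }
      row <- c(row, seg, rep("-", master_ins[c + 1L] - length(seg)))
      if (c < L) {
        row <- c(row, if (col <= length(as_)) ap[col] else "-")
        col <- col + 1L
      }
    }
    out[i] <- paste(row, collapse = "")
  }
  # restore original characters (ambiguities were N-masked for alignment)
  for (i in seq_len(n)) {
    ch <- seq_chars(out[i])
    orig <- seq_chars(seqs[[i]])
    ch[ch != "-"] <- orig
    out[i] <- paste(ch, collapse = "")
  }
  setNames(out, names(seqs))
}

# TRUE when `char` matches the modal character: equal after case folding, or
# an IUPAC ambiguity whose member set contains the modal base.
.matches_modal <- function(chars, modal) {
  ch <- toupper(chars)
  eq <- ch == modal & modal != ""
  amb <- !eq & ch %in% setdiff(unname(.IUPAC), c(DNA_BASES, "N"))
  if (any(amb))
    eq[amb] <- vapply(which(amb), function(i)
      modal[i] %in% iupac_members(ch[i]), TRUE)
  eq
}

#' Flag conserved alignment columns
#'
#' A column is conserved when its most common non-gap character (case
#' folded; `?` and `-` excluded) is present in strictly more than
#' `threshold` of the sequences.
#'
#' @param aln named character vector of equal-length aligned sequences.
#' @param threshold conservation level (default 0.40, strict `>`).
#' @return list with `conserved` (logical per column) and `modal`
#'   (modal character per column, `""` for all-gap columns).
#' @export
flag_conserved <- function(aln, threshold = 0.40) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  modal <- character(ncol(m)); conserved <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[!(col %in% c("-", "?"))]
    if (!length(col)) { modal[j] <- ""; conserved[j] <- FALSE; next }
    tb <- sort(table(col), decreasing = TRUE)
    modal[j] <- names(tb)[1L]
    conserved[j] <- tb[1L] / n > threshold
  }
  list(conserved = conserved, modal = modal)
}

#' Mask poorly aligned regions of each sequence
#'
#' For each row, a site is stable when its column is conserved and the
#' row's character matches the column's modal character (IUPAC ambiguities
#' match when the modal base is among their members). Every window of
#' `window` consecutive ungapped row positions containing fewer than
#' `min_stable` stable sites is masked to `?`; overlapping masked windows
#' union. Rows with fewer ungapped positions than `window` are evaluated as
#' a single window.
#'
#' @param aln named character vector of aligned sequences.
#' @param flags result of [flag_conserved()] on `aln`.
#' @param window window length in (ungapped) bp (default 20).
#' @param min_stable minimum stable sites per window (default 10).
#' @return the alignment with masked residues replaced by `?`.
#' @export
mask_unstable_regions <- function(aln, flags, window = 20L,
                                  min_stable = 10L) {
  out <- aln
  for (i in seq_along(aln)) {
    ch <- seq_chars(aln[[i]])
    idx <- which(!(ch %in% c("-", "?")))
    m <- length(idx)
    if (!m) next
    stable <- flags$conserved[idx] &
      .matches_modal(ch[idx], flags$modal[idx])
    if (m < window) {
      if (sum(stable) < min_stable) ch[idx] <- "?"
    } else {
      cs <- c(0L, cumsum(stable))
      starts <- seq_len(m - window + 1L)
      bad <- starts[cs[starts + window] - cs[starts] < min_stable]
      if (length(bad)) {
        maskpos <- unique(unlist(lapply(bad, function(s) s:(s + window - 1L))))
        ch[idx[maskpos]] <- "?"
      }
    }
    out[i] <- paste(ch, collapse = "")
  }
  out
}

#' Remove alignment columns with too few unmasked bases
#'
#' Columns with fewer than `min_unmasked` characters outside `{?, -}` are
#' removed and the survivors re-indexed.
#'
#' @param aln named character vector of aligned sequences.
#' @param min_unmasked minimum unmasked bases per retained column
#'   (default 12).
#' @return list with `aln` (trimmed alignment) and `removed` (count of
#'   dropped columns). An empty result (all columns dropped) warns.
#' @export
drop_sparse_columns <- function(aln, min_unmasked = 12L) {
  m <- aln_matrix(aln)
  unmasked <- colSums(!(m == "-" | m == "?"))
  keep <- unmasked >= min_unmasked
  if (!any(keep)) warning("no columns survive; locus dropped")
  trimmed <- vapply(seq_along(aln), function(i)
    paste(seq_chars(aln[[i]])[keep], collapse = ""), "")
  list(aln = setNames(trimmed, names(aln)), removed = sum(!keep))
}

#' Conservation-based trimming/masking of one locus alignment
#'
#' Applies the three steps — conserved-column flagging, per-sequence window
#' masking, sparse-column removal — and iterates them to a fixed point, so
#' the procedure is idempotent: running it on its own output changes
#' nothing.
#'
#' @param aln named character vector of aligned sequences.
#' @param locus optional locus label.
#' @param threshold conserved-column level (0.40, strict).
#' @param window,min_stable masking window parameters (20 bp, 10 stable).
#' @param min_unmasked column-removal threshold (12).
#' @param max_iter fixed-point iteration cap.
#' @return object of class `ahe_trimmed`: `aln`, `locus`,
#'   `removed_columns`, `masked_cells`, `conserved` flags of the final
#'   alignment, `iterations`.
#' @export
trim_alignment <- function(aln, locus = NA_character_, threshold = 0.40,
                           window = 20L, min_stable = 10L,
                           min_unmasked = 12L, max_iter = 25L) {
  cur <- aln
  removed <- 0L
  it <- 0L
  repeat {
    it <- it + 1L
    flags <- flag_conserved(cur, threshold)
    masked <- mask_unstable_regions(cur, flags, window, min_stable)
    dropped <- drop_sparse_columns(masked, min_unmasked)
    removed <- removed + dropped$removed
    if (identical(unname(dropped$aln), unname(cur)) || it >= max_iter) {
      cur <- dropped$aln
      break
    }
    cur <- dropped$aln
    if (!nchar(cur[[1]])) break
  }
  masked_cells <- sum(vapply(cur, function(s)
    sum(seq_chars(s) == "?"), 0L)) -
    sum(vapply(aln, function(s) sum(seq_chars(s) == "?"), 0L))
  structure(list(aln = cur, locus = locus,
                 removed_columns = removed,
                 masked_cells = max(masked_cells, 0L),
                 conserved = flag_conserved(cur, threshold)$conserved,
                 iterations = it),
            class = "ahe_trimmed")
}

#' @export
print.ahe_trimmed <- function(x, ...) {
  cat("Trimmed alignment", x$locus, ":", length(x$aln), "taxa x",
      nchar(x$aln[[1]]), "columns (", x$removed_columns, "columns removed,",
      x$masked_cells, "cells masked )\n")
  invisible(x)
}
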