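# Independent brute-force oracles used to cross-check the package's
# implementations. These are deliberately naive loop implementations kept
# separate from the code paths they verify.

oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(toupper(x), "")[[1]]])), collapse = "")
}

# Exhaustive overlap evaluation for read merging: for every overlap degree,
# count matches between the r1 suffix and the reverse-complemented r2
# prefix; return per-degree matches and binomial tail p-values.
oracle_overlap <- function(r1, r2, p_null = 0.25) {
  s2 <- oracle_revcomp(r2)
  a <- strsplit(r1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  omax <- min(length(a), length(b))
  matches <- integer(omax)
  for (o in seq_len(omax)) {
    m <- 0L
    for (i in seq_len(o)) {
      x <- a[length(a) - o + i]; y <- b[i]
      if (x == y && x %in% c("A", "C", "G", "T")) m <- m + 1L
    }
    matches[o] <- m
  }
  pv <- numeric(omax)
  for (o in seq_len(omax))
    pv[o] <- sum(dbinom(matches[o]:o, o, p_null))
  best <- max(which(pv == min(pv)))
  list(matches = matches, pvalues = pv, best_overlap = best,
       best_p = pv[best])
}

# All-offset gap-free scorer for read mapping: for every offset, the best
# `window`-length run of aligned matches; returns the global best score and
# the smallest offset attaining it (offset d: read base i pairs ref d + i).
oracle_map <- function(read, ref, window = 100) {
  a <- strsplit(toupper(read), "")[[1]]
  b <- strsplit(toupper(ref), "")[[1]]
  best <- -1L; best_d <- NA_integer_
  for (d in seq(-(length(a) - 1L), length(b) - 1L)) {
    i0 <- max(1L, 1L - d); i1 <- min(length(a), length(b) - d)
    if (i1 < i0) next
    mvec <- vapply(i0:i1, function(i)
      a[i] == b[i + d] && a[i] %in% c("A", "C", "G", "T"), TRUE)
    len <- length(mvec)
    w <- min(window, len)
    sc <- 0L
    for (s in seq_len(len - w + 1L))
      sc <- max(sc, sum(mvec[s:(s + w - 1L)]))
    if (sc > best) { best <- sc; best_d <- d }
  }
  list(matches = best, offset = best_d + 1L)   # 1-based like map_read()
}

# Independent binomial-tail consensus classifier over a column profile
# (named counts for A/C/G/T).
oracle_consensus_base <- function(counts, p_err = 0.1, alpha = 0.05,
                                  mask_cov = 5) {
  iupac <- c(A = "A", C = "C", G = "G", T = "T", AC = "M", AG = "R",
             AT = "W", CG = "S", CT = "Y", GT = "K", ACG = "V", ACT = "H",
             AGT = "D", CGT = "B", ACGT = "N")
  n <- sum(counts)
  if (n == 0) return("N")
  maj <- names(counts)[which.max(counts)]
  m <- max(counts)
  p_minor <- 1 - pbinom(n - m - 1, n, p_err)
  base <- if (m == n || p_minor >= alpha) maj else {
    set <- maj
    for (b in setdiff(names(counts), maj)) {
      k <- counts[[b]]
      if (k > 0 && 1 - pbinom(k - 1, n, p_err) < alpha) set <- c(set, b)
    }
    unname(iupac[paste(sort(set), collapse = "")])
  }
  if (n < mask_cov) tolower(base) else base
}

# Per-pair loop oracle for alignment identity (pairwise-gap exclusion).
oracle_pairwise_identity <- function(rows) {
  n <- length(rows)
  ch <- lapply(rows, function(r) strsplit(toupper(r), "")[[1]])
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    comp <- ch[[i]] != "-" & ch[[j]] != "-"
    vals <- c(vals, sum(ch[[i]][comp] == ch[[j]][comp]) / sum(comp))
  }
  100 * mean(vals)
}

# Enumerated k-mer sets (consecutive + every-third-base spaced) and Jaccard
# distance, written as plain loops.
oracle_kmer_set <- function(seq, k = 20, step = 3) {
  ch <- strsplit(toupper(seq), "")[[1]]
  out <- character(0)
  if (length(ch) >= k)
    for (s in 1:(length(ch) - k + 1))
      out <- c(out, paste(ch[s:(s + k - 1)], collapse = ""))
  span <- (k - 1) * step + 1
  if (length(ch) >= span)
    for (s in 1:(length(ch) - span + 1))
      out <- c(out, paste(ch[s + step * (0:(k - 1))], collapse = ""))
  unique(out)
}

oracle_kmer_distance <- function(a, b) {
  ka <- oracle_kmer_set(a); kb <- oracle_kmer_set(b)
  1 - length(intersect(ka, kb)) / length(union(ka, kb))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Random alignment with a mixture of conserved and noisy columns, for the
# trimming property suite.
random_alignment <- function(n_rows = 15, n_cols = 60, p_conserved = 0.6) {
  cols <- vapply(seq_len(n_cols), function(j) {
    if (runif(1) < p_conserved) {
      base <- sample(c("A", "C", "G", "T"), 1)
      ch <- rep(base, n_rows)
      flip <- runif(n_rows) < 0.1
      ch[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
      ch
    } else sample(c("A", "C", "G", "T"), n_rows, replace = TRUE)
  }, character(n_rows))
  setNames(apply(cols, 1, paste, collapse = ""),
           sprintf("t%02d", seq_len(n_rows)))
}
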