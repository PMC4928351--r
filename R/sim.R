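# Ground-truthed simulator of anchored-enrichment sequencing experiments:
# species tree -> anchor/flank locus haplotypes -> enriched fragments ->
# paired 150 bp reads with Phred qualities, contaminants and planted paralogs.

#' Configuration for the synthetic AHE experiment
#'
#' Bundles every knob of the simulator with validation. Defaults describe a
#' small but realistic target-capture experiment: 8 individuals, 30 loci of a
#' conserved 200 bp anchor flanked by two faster-evolving 150 bp flanks,
#' fragments of 150-350 bp sequenced as 150 bp pairs at 20x mean depth.
#'
#' @param seed integer seed; every stage derives its randomness from it.
#' @param n_taxa number of sampled individuals/species (>= 3).
#' @param tree_height expected substitutions/site from root to tip at
#'   relative rate 1.
#' @param n_loci number of target loci.
#' @param anchor_len,flank_len lengths (bp) of the conserved anchor and each
#'   of the two flanks; locus length is `anchor_len + 2 * flank_len`.
#' @param anchor_rate_scale,flank_rate_scale relative substitution-rate
#'   multipliers; the anchor must be the slower region.
#' @param coverage_mean target mean per-base sequencing depth per locus per
#'   individual.
#' @param fragment_len_range inclusive bp interval fragments are drawn from
#'   uniformly (sonication emulation; default 150-350).
#' @param read_len read length in bp (default 150, PE150 emulation).
#' @param base_error_rate per-base sequencing error probability (< 0.5).
#' @param contam_fraction fraction of read pairs drawn from an unrelated
#'   random contaminant sequence.
#' @param dup_loci optional data.frame with columns `locus` (index) and
#'   `taxon` (tip label) naming locus copies to duplicate in one individual.
#' @param dup_divergence per-site divergence applied to duplicated copies.
#' @param model substitution model, `"JC"` or `"HKY"`.
#' @param kappa transition/transversion rate ratio for HKY.
#' @param base_freq equilibrium base frequencies (A, C, G, T) for HKY.
#' @return object of class `ahe_sim_config`.
#' @export
sim_config <- function(seed = 1L, n_taxa = 8L, tree_height = 0.15,
                       n_loci = 30L, anchor_len = 200L, flank_len = 150L,
                       anchor_rate_scale = 0.3, flank_rate_scale = 1.5,
                       coverage_mean = 20, fragment_len_range = c(150L, 350L),
                       read_len = 150L, base_error_rate = 0.003,
                       contam_fraction = 0.01, dup_loci = NULL,
                       dup_divergence = 0.10, model = c("JC", "HKY"),
                       kappa = 2, base_freq = rep(0.25, 4)) {
  model <- match.arg(model)
  fragment_len_range <- as.integer(fragment_len_range)
  if (length(fragment_len_range) != 2L ||
      fragment_len_range[1] > fragment_len_range[2])
    stop("fragment_len_range must be an increasing length-2 interval")
  if (fragment_len_range[1] < read_len / 2)
    stop("invalid config: min fragment length must be >= read_len/2")
  if (base_error_rate < 0 || base_error_rate >= 0.5)
    stop("invalid config: base_error_rate must lie in [0, 0.5)")
  if (anchor_rate_scale >= flank_rate_scale)
    stop("invalid config: anchor_rate_scale must be < flank_rate_scale")
  if (anchor_len < 1L || flank_len < 1L)
    stop("invalid config: zero-length anchor or flank region")
  if (!is.null(dup_loci)) {
    dup_loci <- as.data.frame(dup_loci)
    stopifnot(all(c("locus", "taxon") %in% names(dup_loci)))
  }
  if (abs(sum(base_freq) - 1) > 1e-8) stop("base_freq must sum to 1")
  structure(list(seed = as.integer(seed), n_taxa = as.integer(n_taxa),
                 tree_height = tree_height, n_loci = as.integer(n_loci),
                 anchor_len = as.integer(anchor_len),
                 flank_len = as.integer(flank_len),
                 anchor_rate_scale = anchor_rate_scale,
                 flank_rate_scale = flank_rate_scale,
                 coverage_mean = coverage_mean,
                 fragment_len_range = fragment_len_range,
                 read_len = as.integer(read_len),
                 base_error_rate = base_error_rate,
                 contam_fraction = contam_fraction,
                 dup_loci = dup_loci, dup_divergence = dup_divergence,
                 model = model, kappa = kappa, base_freq = base_freq),
            class = "ahe_sim_config")
}

#' @export
print.ahe_sim_config <- function(x, ...) {
  cat("AHE simulation config:", x$n_taxa, "taxa,", x$n_loci, "loci of",
      x$anchor_len + 2L * x$flank_len, "bp,",
      sprintf("%gx depth, PE%d reads, seed %d\n",
              x$coverage_mean, x$read_len, x$seed))
  invisible(x)
}

#' Simulate a rooted binary species tree
#'
#' Draws a coalescent topology, rescales the root-to-tip height to
#' `tree_height` and floors branch lengths at 5% of the height so every
#' internal edge carries recoverable signal.
#'
#' @param config an [sim_config()] object.
#' @return an [ape::phylo] rooted binary tree with `n_taxa` leaves.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "ahe_sim_config"))
  if (config$n_taxa < 3L) stop("invalid config: n_taxa must be >= 3")
  set.seed(config$seed)
  tips <- sprintf("taxon%02d", seq_len(config$n_taxa))
  tr <- ape::rcoal(config$n_taxa, tip.label = tips)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * config$tree_height / depth
  tr$edge.length <- pmax(tr$edge.length, 0.05 * config$tree_height)
  tr
}

# HKY85 transition-probability matrix for branch length t (expected
# substitutions/site at relative rate 1). kappa = 1 with uniform frequencies
# reduces exactly to Jukes-Cantor.
hky_pmat <- function(t, kappa = 2, pi = rep(0.25, 4)) {
  ti <- matrix(c(0, 0, 1, 0,  0, 0, 0, 1,  1, 0, 0, 0,  0, 1, 0, 0), 4, 4)
  Q <- matrix(rep(pi, each = 4), 4, 4) * ifelse(ti == 1, kappa, 1)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * pi)        # normalise to 1 expected sub/site/unit
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
  P[P < 0] <- 0
  P / rowSums(P)
  }

# Evolve integer-coded (1..4) child states from parent states given a
# 4x4 transition matrix; vectorised over sites by parent base.
evolve_states <- function(parent, P) {
  child <- parent
  for (b in 1:4) {
    idx <- which(parent == b)
    if (length(idx))
      child[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[b, ])
  }
  child
}

#' Evolve true locus haplotypes along the species tree
#'
#' Each locus is an ungapped `anchor_len + 2*flank_len` sequence per taxon
#' evolved under JC or HKY with region-specific rate multipliers: a slow
#' conserved central anchor and two faster flanks, emulating the structure of
#' capture targets. Planted paralogs (from `dup_loci`) are divergent copies
#' of one taxon's haplotype.
#'
#' @param tree the species tree from [simulate_tree()].
#' @param config an [sim_config()] object.
#' @return object of class `ahe_truth`: list with `tree`, `loci` (per locus a
#'   named character vector of haplotypes plus the anchor interval),
#'   `paralogs`, and `config`.
#' @export
evolve_loci <- function(tree, config) {
  stopifnot(inherits(config, "ahe_sim_config"))
  set.seed(config$seed + 1L)
  al <- config$anchor_len; fl <- config$flank_len
  L <- al + 2L * fl
  anchor <- c(fl + 1L, fl + al)              # 1-based inclusive
  rate <- c(rep(config$flank_rate_scale, fl),
            rep(config$anchor_rate_scale, al),
            rep(config$flank_rate_scale, fl))
  kappa <- if (config$model == "JC") 1 else config$kappa
  pi <- if (config$model == "JC") rep(0.25, 4) else config$base_freq
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  elen <- ape::reorder.phylo(tree, "cladewise")$edge.length
  rate_classes <- sort(unique(rate))
  class_of <- match(rate, rate_classes)

  loci <- vector("list", config$n_loci)
  for (lc in seq_len(config$n_loci)) {
    states <- matrix(NA_integer_, ntip + tree$Nnode, L)
    states[root, ] <- sample.int(4L, L, replace = TRUE, prob = pi)
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1L]; chl <- edges[e, 2L]
      child <- states[par, ]
      for (ci in seq_along(rate_classes)) {
        idx <- which(class_of == ci)
        P <- hky_pmat(elen[e] * rate_classes[ci], kappa, pi)
        child[idx] <- evolve_states(states[par, idx], P)
      }
      states[chl, ] <- child
    }
    haps <- apply(states[seq_len(ntip), , drop = FALSE], 1L,
                  function(s) paste(DNA_BASES[s], collapse = ""))
    names(haps) <- tree$tip.label
    loci[[lc]] <- list(haps = haps, anchor = anchor)
  }
  names(loci) <- sprintf("locus%03d", seq_len(config$n_loci))

  paralogs <- list()
  if (!is.null(config$dup_loci)) {
    for (i in seq_len(nrow(config$dup_loci))) {
      lc <- config$dup_loci$locus[i]; tx <- config$dup_loci$taxon[i]
      src <- loci[[lc]]$haps[[tx]]
      paralogs[[paste0(names(loci)[lc], "|", tx)]] <-
        mutate_bases(src, config$dup_divergence)$seq
    }
  }
  structure(list(tree = tree, loci = loci, paralogs = paralogs,
                 config = config), class = "ahe_truth")
}

#' @export
print.ahe_truth <- function(x, ...) {
  cat("AHE truth set:", length(x$tree$tip.label), "taxa,",
      length(x$loci), "loci,", length(x$paralogs), "planted paralog(s)\n")
  invisible(x)
}

# Expected distinct bases covered by one fragment pair (merged footprint).
.expected_footprint <- function(config) {
  f <- seq(config$fragment_len_range[1], config$fragment_len_range[2])
  mean(pmin(f, 2L * config$read_len))
}

# Draw one read pair from a source haplotype; returns NULL if the haplotype
# is shorter than the minimum fragment.
.draw_pair <- function(hap, config) {
  L <- nchar(hap)
  flen <- sample(seq(config$fragment_len_range[1],
                     config$fragment_len_range[2]), 1L)
  flen <- min(flen, L)
  if (flen < 1L) return(NULL)
  start <- sample.int(L - flen + 1L, 1L)
  frag <- substr(hap, start, start + flen - 1L)
  strand <- sample(c("+", "-"), 1L)
  if (strand == "-") frag <- revcomp(frag)
  rl <- min(config$read_len, flen)
  r1 <- substr(frag, 1L, rl)
  r2 <- revcomp(substr(frag, flen - rl + 1L, flen))
  list(r1 = r1, r2 = r2, start = start, flen = flen, strand = strand)
}

# Apply sequencing errors and emit Phred qualities (40 for correct calls,
# uniform 2-20 at error positions so quality-aware merging is testable).
.sequence_read <- function(seq, config) {
  mb <- mutate_bases(seq, config$base_error_rate)
  q <- rep(40L, nchar(seq))
  if (length(mb$errors)) q[mb$errors] <- sample(2:20, length(mb$errors),
                                                replace = TRUE)
  list(seq = mb$seq, qual = q)
}

#' Generate paired reads (with provenance) from a truth set
#'
#' Fragments are drawn uniformly from `fragment_len_range` at positions
#' uniform over each locus haplotype (fragments never span loci), sequenced
#' as a PE pair (read 2 reverse-complemented), with per-base errors at
#' `base_error_rate` and Phred qualities consistent with the error draw.
#' `contam_fraction` of pairs come from an unrelated random sequence. Every
#' pair is labelled in the provenance table.
#'
#' @param truth an `ahe_truth` object from [evolve_loci()].
#' @param config the same [sim_config()] object.
#' @return object of class `ahe_reads`: per-individual read sets
#'   (`r1`, `q1`, `r2`, `q2`, `id`) and a `provenance` data.frame.
#' @export
make_reads <- function(truth, config) {
  stopifnot(inherits(truth, "ahe_truth"))
  set.seed(config$seed + 2L)
  foot <- .expected_footprint(config)
  individuals <- list()
  prov_all <- list()
  for (tx in truth$tree$tip.label) {
    sources <- list()
    for (ln in names(truth$loci))
      sources[[ln]] <- list(hap = truth$loci[[ln]]$haps[[tx]],
                            type = "target", locus = ln)
    for (pk in names(truth$paralogs)) {
      parts <- strsplit(pk, "|", fixed = TRUE)[[1]]
      if (parts[2] == tx)
        sources[[paste0(parts[1], ".dup")]] <-
          list(hap = truth$paralogs[[pk]], type = "paralog", locus = parts[1])
    }
    r1 <- character(0); r2 <- character(0)
    q1 <- list(); q2 <- list()
    prov <- list()
    n <- 0L
    emit <- function(pair, type, locus) {
      n <<- n + 1L
      s1 <- .sequence_read(pair$r1, config)
      s2 <- .sequence_read(pair$r2, config)
      r1[n] <<- s1$seq; r2[n] <<- s2$seq
      q1[[n]] <<- s1$qual; q2[[n]] <<- s2$qual
      prov[[n]] <<- data.frame(id = NA_character_, individual = tx,
                               type = type, locus = locus,
                               start = pair$start, frag_len = pair$flen,
                               strand = pair$strand)
    }
    for (src in sources) {
      L <- nchar(src$hap)
      nfrag <- rpois(1L, config$coverage_mean * L / foot)
      for (i in seq_len(nfrag)) {
        pair <- .draw_pair(src$hap, config)
        if (is.null(pair)) { warning("skipping zero-length fragment"); next }
        emit(pair, src$type, src$locus)
      }
    }
    if (config$contam_fraction > 0) {
      contam_src <- random_dna(2000L)
      n_cont <- round(config$contam_fraction / (1 - config$contam_fraction) * n)
      for (i in seq_len(n_cont)) {
        pair <- .draw_pair(contam_src, config)
        emit(pair, "contaminant", NA_character_)
      }
    }
    ids <- sprintf("%s:%05d", tx, seq_len(n))
    prov <- do.call(rbind, prov)
    prov$id <- ids
    individuals[[tx]] <- list(r1 = r1, q1 = q1, r2 = r2, q2 = q2, id = ids)
    prov_all[[tx]] <- prov
  }
  structure(list(individuals = individuals,
                 provenance = do.call(rbind, prov_all),
                 config = config), class = "ahe_reads")
}

#' @export
print.ahe_reads <- function(x, ...) {
  n <- vapply(x$individuals, function(i) length(i$id), 0L)
  cat("AHE read set:", length(n), "individuals,", sum(n), "read pairs (",
      sum(x$provenance$type == "contaminant"), "contaminant )\n")
  invisible(x)
}

#' One-call simulation of a full AHE experiment
#'
#' @param config an [sim_config()] object.
#' @return list with `truth` ([evolve_loci()]) and `reads` ([make_reads()]).
#' @export
simulate_ahe <- function(config = sim_config()) {
  tree <- simulate_tree(config)
  truth <- evolve_loci(tree, config)
  list(truth = truth, reads = make_reads(truth, config))
}
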