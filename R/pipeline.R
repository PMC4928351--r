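# End-to-end orchestration of the anchored-enrichment workflow on simulated
# (or user-supplied) reads, plus planted-truth evaluation helpers.

#' Run the full AHE pipeline on a simulated experiment
#'
#' simulate -> merge pairs -> assemble per individual -> refine + consensus
#' -> contamination filter -> orthology -> align -> trim -> supermatrix ->
#' NJ tree.
#'
#' @param config an [sim_config()]; ignored when `sim` is supplied.
#' @param sim optional pre-built [simulate_ahe()] result.
#' @param aligner `"auto"` (MAFFT when on PATH, fallback otherwise),
#'   `"mafft"` or `"fallback"`.
#' @param min_reads contamination filter threshold (10).
#' @param min_occupancy ortholog species-occupancy filter (0.5).
#' @param alpha merge p-value threshold (1e-10).
#' @param min_unmasked sparse-column threshold for trimming; the published
#'   default of 12 presumes a few dozen taxa, so it is clamped to the number
#'   of species simulated.
#' @return object of class `ahe_pipeline`: the simulation, per-individual
#'   merge/assembly results, consensus list, ortholog sets, trimmed
#'   alignments, supermatrix and NJ tree.
#' @export
ahe_pipeline <- function(config = sim_config(), sim = NULL,
                         aligner = c("auto", "mafft", "fallback"),
                         min_reads = 10L, min_occupancy = 0.5,
                         alpha = 1e-10, min_unmasked = NULL) {
  aligner <- match.arg(aligner)
  if (aligner == "auto")
    aligner <- if (Sys.which("mafft") != "") "mafft" else "fallback"
  if (is.null(sim)) sim <- simulate_ahe(config)
  config <- sim$truth$config
  if (is.null(min_unmasked)) min_unmasked <- min(12L, config$n_taxa)
  library <- reference_library(sim$truth$loci)
  merges <- list(); assemblies <- list(); consensus <- list()
  for (tx in names(sim$reads$individuals)) {
    ind <- sim$reads$individuals[[tx]]
    mr <- merge_pairs(ind$r1, ind$q1, ind$r2, ind$q2, ids = ind$id,
                      alpha = alpha)
    asm <- assemble_individual(mr, library, individual = tx)
    merges[[tx]] <- mr
    assemblies[[tx]] <- asm
    consensus <- c(consensus, consensus_sequences(asm))
  }
  orth <- orthology_sets(consensus, n_species = config$n_taxa,
                         min_reads = min_reads,
                         min_occupancy = min_occupancy)
  trimmed <- list()
  for (lc in names(orth)) {
    for (ci in seq_along(orth[[lc]])) {
      cl <- orth[[lc]][[ci]]
      if (length(cl$members) < 2L) next
      seqs <- setNames(vapply(cl$members, function(m) m$seq, ""),
                       cl$individuals)
      aln <- run_aligner(seqs, method = aligner)
      key <- if (length(orth[[lc]]) > 1L) paste0(lc, ".", ci) else lc
      tr <- trim_alignment(aln, locus = key, min_unmasked = min_unmasked)
      if (nchar(tr$aln[[1]]) > 0L) trimmed[[key]] <- tr
    }
  }
  sm <- concatenate_loci(trimmed)
  tree <- nj_tree(sm)
  structure(list(sim = sim, library = library, merges = merges,
                 assemblies = assemblies, consensus = consensus,
                 orthologs = orth, trimmed = trimmed, supermatrix = sm,
                 nj_tree = tree, aligner = aligner),
            class = "ahe_pipeline")
}

#' @export
print.ahe_pipeline <- function(x, ...) {
  cat("AHE pipeline run:", length(x$assemblies), "individuals,",
      length(x$consensus), "consensus sequences,", length(x$trimmed),
      "trimmed loci\n")
  print(x$supermatrix)
  invisible(x)
}

# Best gap-free identity of a consensus against a set of candidate true
# haplotypes; uppercase (well-covered) consensus sites only.
.consensus_identity <- function(cons_seq, candidates) {
  ch <- seq_chars(cons_seq)
  upper <- ch %in% DNA_BASES                 # uppercase unambiguous sites
  best <- 0
  for (hap in candidates) {
    pl <- best_gapfree_placement(toupper(cons_seq), toupper(hap),
                                 window = nchar(cons_seq) + nchar(hap))
    off <- pl[2]
    hch <- seq_chars(toupper(hap))
    pos <- off + seq_along(ch)
    ok <- upper & pos >= 1L & pos <= length(hch)
    if (!any(ok)) next
    best <- max(best, sum(ch[ok] == hch[pos[ok]]) / sum(ok))
  }
  best
}

#' Evaluate a pipeline run against its planted truth
#'
#' Measures, per locus x individual, whether a surviving consensus recovers
#' the true haplotype (gap-free identity on uppercase sites at least
#' `min_identity`), audits contaminant-derived clusters against the
#' provenance labels, and compares the NJ tree with the generating species
#' tree by Robinson-Foulds distance.
#'
#' @param pipe an [ahe_pipeline()] result.
#' @param min_identity identity level defining recovery (default 0.99).
#' @param min_reads the contamination filter threshold used (10).
#' @return list with `recovered_frac`, `n_recovered`, `n_expected`,
#'   `mean_identity`, `contaminant_clusters_before`,
#'   `contaminant_clusters_after`, `rf_distance`.
#' @export
evaluate_pipeline <- function(pipe, min_identity = 0.99, min_reads = 10L) {
  truth <- pipe$sim$truth
  taxa <- truth$tree$tip.label
  loci <- names(truth$loci)
  kept <- pipe$consensus[vapply(pipe$consensus, filter_low_coverage, TRUE,
                                min_reads = min_reads)]
  ident <- matrix(0, length(loci), length(taxa),
                  dimnames = list(loci, taxa))
  for (cs in kept) {
    cand <- truth$loci[[cs$locus]]$haps[[cs$individual]]
    pk <- paste0(cs$locus, "|", cs$individual)
    if (pk %in% names(truth$paralogs))
      cand <- c(cand, truth$paralogs[[pk]])
    idv <- .consensus_identity(cs$seq, cand)
    ident[cs$locus, cs$individual] <- max(ident[cs$locus, cs$individual],
                                          idv)
  }
  recovered <- ident >= min_identity
  # contaminant audit: a cluster is contaminant-derived when the majority of
  # its reads carry the contaminant provenance label
  prov <- pipe$sim$reads$provenance
  contam_ids <- paste0(prov$id[prov$type == "contaminant"], "")
  cluster_contam <- function(cl) {
    base_ids <- sub("/[m12]$", "", cl$id)
    mean(base_ids %in% contam_ids) > 0.5
  }
  all_clusters <- unlist(lapply(pipe$assemblies, function(a) a$clusters),
                         recursive = FALSE)
  is_contam <- vapply(all_clusters, cluster_contam, TRUE)
  big <- vapply(all_clusters, function(cl) cl$n_reads >= min_reads, TRUE)
  rf <- as.numeric(ape::dist.topo(ape::unroot(pipe$nj_tree),
                                  ape::unroot(truth$tree)))
  list(recovered_frac = mean(recovered),
       n_recovered = sum(recovered),
       n_expected = length(recovered),
       mean_identity = mean(ident[ident > 0]),
       contaminant_clusters_before = sum(is_contam),
       contaminant_clusters_after = sum(is_contam & big),
       rf_distance = rf)
}
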