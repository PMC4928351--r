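# Assembly: spaced-k-mer seeding, 100-base gap-free mapping, hybrid
# fixed-point read recruitment, cluster separation, offset refinement and
# binomial consensus calling.

make_library <- function(seed = 1, n_loci = 2, n_taxa = 6) {
  cfg <- sim_config(seed = seed, n_taxa = n_taxa, n_loci = n_loci,
                    tree_height = 0.1)
  truth <- evolve_loci(simulate_tree(cfg), cfg)
  list(truth = truth, lib = reference_library(truth$loci), cfg = cfg)
}

test_that("spaced k-mer matching counts pattern-position mismatches", {
  mk <- make_library()
  lib <- mk$lib
  kr <- lib$kmers[1, ]
  ref <- lib$refs[[kr$locus]]
  window <- substr(ref, kr$ref_pos, kr$ref_pos + lib$span - 1L)
  read <- paste0(random_seq(20), window, random_seq(20))

  h <- spaced_kmer_match(read, lib)
  exact <- h[h$read_start == 21L &
               lib$kmers$locus[1] == h$locus, , drop = FALSE]
  expect_true(any(exact$matches == 20L))
  expect_true(21L %in% exact$read_start)
  expect_equal(exact$offset[exact$matches == 20L][1], kr$ref_pos - 20L)

  mutate_at <- function(read, pattern_pos) {
    ch <- strsplit(read, "")[[1]]
    for (p in pattern_pos) {
      i <- 20L + 1L + lib$pattern[p]         # window starts at read pos 21
      ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
    }
    paste(ch, collapse = "")
  }
  h17 <- spaced_kmer_match(mutate_at(read, c(2, 9, 16)), lib)
  at <- h17[h17$read_start == 21L, , drop = FALSE]
  expect_true(any(at$matches == 17L))
  h16 <- spaced_kmer_match(mutate_at(read, c(2, 9, 16, 20)), lib)
  expect_false(21L %in% h16$read_start[h16$matches >= 17L])
})

test_that("an exact reference slice maps with a full scoring window", {
  mk <- make_library(seed = 2)
  ref <- mk$lib$refs[[1]]
  read <- substr(ref, 21, 170)
  mr <- map_read(read, ref)
  expect_true(mr$mapped)
  expect_equal(mr$matches, 100L)
  expect_equal(mr$offset, 21L)
})

test_that("a best window of 54 matches stays unmapped (threshold 55)", {
  set.seed(33)
  ref <- random_seq(300)
  read_ch <- strsplit(substr(ref, 101, 200), "")[[1]]
  flip <- sample(100, 46)                    # leaves exactly 54 matches
  for (i in flip)
    read_ch[i] <- setdiff(c("A", "C", "G", "T"), read_ch[i])[1]
  read <- paste(read_ch, collapse = "")
  orc <- oracle_map(read, ref)
  mr <- map_read(read, ref)
  expect_equal(mr$matches, orc$matches)
  expect_equal(mr$offset, orc$offset)
  if (orc$matches == 54L) expect_false(mr$mapped)
})

test_that("mapping equals the exhaustive all-offset oracle", {
  set.seed(35)
  for (i in 1:25) {
    ref <- random_seq(sample(120:260, 1))
    if (i %% 2 == 0) {
      read <- random_seq(sample(60:150, 1))  # unrelated
    } else {
      s <- sample(30:(nchar(ref) - 60), 1)
      read_ch <- strsplit(substr(ref, s, min(nchar(ref), s + 120)), "")[[1]]
      flip <- which(runif(length(read_ch)) < 0.3)
      for (f in flip)
        read_ch[f] <- sample(setdiff(c("A", "C", "G", "T"), read_ch[f]), 1)
      read <- paste(read_ch, collapse = "")
    }
    orc <- oracle_map(read, ref)
    mr <- map_read(read, ref)
    expect_equal(mr$matches, orc$matches)
    expect_equal(mr$offset, orc$offset)
    expect_equal(mr$mapped, orc$matches >= 55)
  }
})

sim_and_assemble <- function(cfg) {
  sim <- simulate_ahe(cfg)
  lib <- reference_library(sim$truth$loci)
  tx <- names(sim$reads$individuals)[1]
  ind <- sim$reads$individuals[[tx]]
  mr <- merge_pairs(ind$r1, ind$q1, ind$r2, ind$q2, ids = ind$id)
  list(sim = sim, mr = mr, lib = lib,
       asm = assemble_individual(mr, lib, individual = tx), tx = tx)
}

test_that("error-free high-coverage reads form one cluster per locus", {
  cfg <- sim_config(seed = 41, n_taxa = 4, n_loci = 3, coverage_mean = 20,
                    base_error_rate = 0, contam_fraction = 0)
  sa <- sim_and_assemble(cfg)
  asm <- sa$asm
  expect_equal(length(asm$clusters), 3L)
  expect_setequal(vapply(asm$clusters, function(cl) cl$locus, ""),
                  names(sa$sim$truth$loci))
  # every on-target read unit (merged read or unmerged mate) is clustered
  n_units <- length(sa$mr$merged$seq) + 2L * length(sa$mr$unmerged1$seq)
  n_in <- sum(vapply(asm$clusters, function(cl) cl$n_reads, 0L))
  expect_gte(n_in / n_units, 0.98)
})

test_that("a 10% divergent duplicated locus splits into two clusters", {
  cfg <- sim_config(seed = 43, n_taxa = 4, n_loci = 2, coverage_mean = 20,
                    base_error_rate = 0, contam_fraction = 0,
                    dup_loci = data.frame(locus = 1, taxon = "taxon01"))
  sim <- simulate_ahe(cfg)
  lib <- reference_library(sim$truth$loci)
  ind <- sim$reads$individuals[["taxon01"]]
  mr <- merge_pairs(ind$r1, ind$q1, ind$r2, ind$q2, ids = ind$id)
  asm <- assemble_individual(mr, lib, individual = "taxon01")
  n_l1 <- sum(vapply(asm$clusters, function(cl)
    cl$locus == "locus001", TRUE))
  expect_equal(n_l1, 2L)
})

test_that("flanking reads extend contigs beyond the probe region", {
  cfg <- sim_config(seed = 47, n_taxa = 4, n_loci = 2, coverage_mean = 25,
                    base_error_rate = 0, contam_fraction = 0)
  sa <- sim_and_assemble(cfg)
  ref_len <- nchar(sa$lib$refs[[sa$asm$clusters[[1]]$locus]])
  expect_gt(max(vapply(sa$asm$clusters, function(cl) cl$span, 0L)), ref_len)
})

test_that("offset refinement restores planted misplacements and indels", {
  set.seed(53)
  hap <- random_seq(260)
  reads <- vapply(seq(1, 111, by = 10), function(s)
    substr(hap, s, s + 149), "")
  offsets <- seq(1L, 111L, by = 10L)
  mk_cluster <- function(seqs, off, gaps = rep(NA_integer_, length(seqs))) {
    structure(list(locus = "locus001", individual = "i",
                   id = sprintf("r%02d", seq_along(seqs)), seq = seqs,
                   offset = off, gap = gaps, n_reads = length(seqs),
                   span = max(off + nchar(seqs) - 1L) + 1L),
              class = "ahe_cluster")
  }
  perfect <- refine_offsets(mk_cluster(reads, offsets))
  expect_equal(perfect$offset, offsets)
  expect_true(all(is.na(perfect$gap)))

  shifted <- offsets; shifted[4] <- shifted[4] + 2L
  fixed <- refine_offsets(mk_cluster(reads, shifted))
  expect_equal(fixed$offset, offsets)
  unrefined <- refine_offsets(mk_cluster(reads, shifted), max_passes = 0L)
  expect_gt(fixed$agreement, unrefined$agreement)

  # read from a haplotype with a 1 bp deletion: one gap gets inserted
  del_read <- paste0(substr(hap, 41, 100), substr(hap, 102, 191))
  cl <- mk_cluster(c(reads, del_read), c(offsets, 41L))
  ref <- refine_offsets(cl)
  expect_equal(ref$gap[length(ref$gap)], 60L)
  expect_true(all(is.na(ref$gap[seq_along(reads)])))
})

test_that("consensus calls follow the binomial error model and IUPAC rule", {
  col_cluster <- function(bases) {
    structure(list(locus = "l", individual = "i",
                   id = sprintf("r%02d", seq_along(bases)), seq = bases,
                   offset = rep(1L, length(bases)),
                   gap = rep(NA_integer_, length(bases)),
                   n_reads = length(bases), span = 1L),
              class = "ahe_cluster")
  }
  expect_identical(call_consensus(col_cluster(rep("A", 10)))$seq, "A")
  expect_identical(call_consensus(col_cluster(c(rep("A", 9), "C")))$seq, "A")
  expect_identical(call_consensus(col_cluster(c(rep("A", 5),
                                                rep("C", 5))))$seq, "M")
  expect_identical(call_consensus(col_cluster(rep("A", 4)))$seq, "a")
  expect_identical(call_consensus(col_cluster(rep("A", 5)))$seq, "A")
})

test_that("consensus matches the independent classifier on random profiles", {
  set.seed(57)
  for (i in 1:200) {
    n <- sample(1:30, 1)
    bases <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
                    prob = c(0.7, 0.1, 0.1, 0.1))
    cl <- structure(list(locus = "l", individual = "i",
                         id = sprintf("r%03d", seq_len(n)), seq = bases,
                         offset = rep(1L, n), gap = rep(NA_integer_, n),
                         n_reads = n, span = 1L),
                    class = "ahe_cluster")
    counts <- table(factor(bases, c("A", "C", "G", "T")))
    expect_identical(call_consensus(cl)$seq,
                     oracle_consensus_base(counts))
  }
})

test_that("planted-truth consensus equals the true haplotype when error-free", {
  cfg <- sim_config(seed = 59, n_taxa = 4, n_loci = 2, coverage_mean = 20,
                    base_error_rate = 0, contam_fraction = 0)
  sa <- sim_and_assemble(cfg)
  cons <- consensus_sequences(sa$asm)
  for (cs in cons) {
    hap <- sa$sim$truth$loci[[cs$locus]]$haps[[sa$tx]]
    up <- gsub("[a-z]", "", cs$seq)          # uppercase (cov >= 5) sites
    expect_true(grepl(up, hap, fixed = TRUE) ||
                  grepl(up, revcomp(hap), fixed = TRUE))
  }
})
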