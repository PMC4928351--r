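# Synthetic-data generator: tree shape, seed determinism, region-structured
# locus evolution, read emission and provenance.

test_that("simulated trees are rooted, binary and seed-deterministic", {
  cfg <- sim_config(seed = 11, n_taxa = 8)
  t1 <- simulate_tree(cfg)
  t2 <- simulate_tree(cfg)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(length(t1$tip.label), 8L)
  expect_equal(t1$Nnode, 7L)                  # binary rooted: n - 1 internal
  expect_equal(nrow(t1$edge), 14L)            # 2n - 2 branches
  expect_true(all(t1$edge.length > 0))
  expect_true(ape::is.rooted(t1) && ape::is.binary(t1))

  t30 <- simulate_tree(sim_config(seed = 3, n_taxa = 30))
  expect_equal(length(t30$tip.label), 30L)

  expect_error(simulate_tree(sim_config(n_taxa = 3)), NA)
  expect_error(sim_config(n_taxa = 2) |> simulate_tree(), "n_taxa")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(fragment_len_range = c(50, 350)), "fragment")
  expect_error(sim_config(base_error_rate = 0.6), "base_error_rate")
  expect_error(sim_config(anchor_rate_scale = 2, flank_rate_scale = 1),
               "anchor_rate_scale")
  expect_error(sim_config(anchor_len = 0), "zero-length")
})

test_that("zero tree height yields identical haplotypes everywhere", {
  cfg <- sim_config(seed = 5, n_taxa = 4, n_loci = 3, tree_height = 0)
  truth <- evolve_loci(simulate_tree(cfg), cfg)
  for (lc in truth$loci)
    expect_equal(length(unique(lc$haps)), 1L)
})

test_that("anchors are more conserved than flanks", {
  cfg <- sim_config(seed = 21, n_taxa = 6, n_loci = 50, tree_height = 0.3,
                    anchor_rate_scale = 0.2, flank_rate_scale = 2.0)
  truth <- evolve_loci(simulate_tree(cfg), cfg)
  id_region <- function(hap_mat, idx) {
    n <- nrow(hap_mat)
    vals <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      vals <- c(vals, mean(hap_mat[i, idx] == hap_mat[j, idx]))
    mean(vals)
  }
  anchor_id <- flank_id <- c()
  for (lc in truth$loci) {
    m <- do.call(rbind, strsplit(unname(lc$haps), ""))
    a <- lc$anchor
    anchor_id <- c(anchor_id, id_region(m, a[1]:a[2]))
    flank_id <- c(flank_id, id_region(m, c(1:(a[1] - 1),
                                           (a[2] + 1):ncol(m))))
  }
  expect_gt(mean(anchor_id), mean(flank_id))
})

test_that("pairwise anchor divergence matches the JC expectation", {
  cfg <- sim_config(seed = 9, n_taxa = 3, n_loci = 60, tree_height = 0.4,
                    anchor_rate_scale = 0.2, flank_rate_scale = 1.0,
                    anchor_len = 300, flank_len = 10)
  tree <- simulate_tree(cfg)
  truth <- evolve_loci(tree, cfg)
  dmat <- ape::cophenetic.phylo(tree)
  pair <- c("taxon01", "taxon02")
  t_path <- dmat[pair[1], pair[2]]
  expected <- 0.75 * (1 - exp(-4 * 0.2 * t_path / 3))
  diffs <- total <- 0
  for (lc in truth$loci) {
    a <- lc$anchor
    x <- strsplit(lc$haps[[pair[1]]], "")[[1]][a[1]:a[2]]
    y <- strsplit(lc$haps[[pair[2]]], "")[[1]][a[1]:a[2]]
    diffs <- diffs + sum(x != y)
    total <- total + length(x)
  }
  se <- sqrt(expected * (1 - expected) / total)
  expect_lt(abs(diffs / total - expected), 4 * se)
})

test_that("error-free reads are exact haplotype substrings in range", {
  cfg <- sim_config(seed = 13, n_taxa = 3, n_loci = 4, base_error_rate = 0,
                    contam_fraction = 0, coverage_mean = 8)
  sim <- simulate_ahe(cfg)
  prov <- sim$reads$provenance
  expect_true(all(prov$frag_len >= 150 & prov$frag_len <= 350))
  for (tx in names(sim$reads$individuals)) {
    ind <- sim$reads$individuals[[tx]]
    pr <- prov[prov$individual == tx, ]
    for (i in seq_along(ind$id)) {
      hap <- sim$truth$loci[[pr$locus[i]]]$haps[[tx]]
      frag <- substr(hap, pr$start[i], pr$start[i] + pr$frag_len[i] - 1L)
      if (pr$strand[i] == "-") frag <- revcomp(frag)
      expect_identical(ind$r1[i], substr(frag, 1, nchar(ind$r1[i])))
      expect_identical(revcomp(ind$r2[i]),
                       substr(frag, nchar(frag) - nchar(ind$r2[i]) + 1L,
                              nchar(frag)))
    }
  }
})

test_that("empirical error rate matches the configured rate", {
  cfg <- sim_config(seed = 17, n_taxa = 4, n_loci = 10,
                    base_error_rate = 0.01, contam_fraction = 0,
                    coverage_mean = 20)
  sim <- simulate_ahe(cfg)
  prov <- sim$reads$provenance
  mism <- total <- 0
  for (tx in names(sim$reads$individuals)) {
    ind <- sim$reads$individuals[[tx]]
    pr <- prov[prov$individual == tx, ]
    for (i in seq_along(ind$id)) {
      hap <- sim$truth$loci[[pr$locus[i]]]$haps[[tx]]
      frag <- substr(hap, pr$start[i], pr$start[i] + pr$frag_len[i] - 1L)
      if (pr$strand[i] == "-") frag <- revcomp(frag)
      tr1 <- substr(frag, 1, nchar(ind$r1[i]))
      tr2 <- revcomp(ind$r2[i])
      tt2 <- substr(frag, nchar(frag) - nchar(ind$r2[i]) + 1L, nchar(frag))
      mism <- mism + sum(strsplit(ind$r1[i], "")[[1]] !=
                           strsplit(tr1, "")[[1]]) +
        sum(strsplit(tr2, "")[[1]] != strsplit(tt2, "")[[1]])
      total <- total + nchar(tr1) + nchar(tr2)
    }
  }
  expect_gt(total, 1e5)
  se <- sqrt(0.01 * 0.99 / total)
  expect_lt(abs(mism / total - 0.01), 3 * se)
})

test_that("FASTQ output is byte-identical across repeated runs", {
  cfg <- sim_config(seed = 23, n_taxa = 3, n_loci = 2, coverage_mean = 6)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_sim(simulate_ahe(cfg), d1)
  write_sim(simulate_ahe(cfg), d2)
  for (f in list.files(d1, pattern = "fastq$"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("every read pair carries exactly one provenance label", {
  cfg <- sim_config(seed = 29, n_taxa = 3, n_loci = 3, coverage_mean = 10,
                    contam_fraction = 0.05)
  sim <- simulate_ahe(cfg)
  n_reads <- sum(vapply(sim$reads$individuals,
                        function(i) length(i$id), 0L))
  expect_equal(nrow(sim$reads$provenance), n_reads)
  expect_false(anyDuplicated(sim$reads$provenance$id) > 0)
  expect_true(all(sim$reads$provenance$type %in%
                    c("target", "paralog", "contaminant")))
})

test_that("FASTQ round-trips through write and read", {
  cfg <- sim_config(seed = 31, n_taxa = 3, n_loci = 2, coverage_mean = 5)
  sim <- simulate_ahe(cfg)
  ind <- sim$reads$individuals[[1]]
  f <- tempfile(fileext = ".fastq")
  write_fastq(ind$r1, ind$q1, ind$id, f)
  back <- read_fastq(f)
  expect_identical(unname(back$seq), ind$r1)
  expect_identical(back$qual, ind$q1)
  unlink(f)
})
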