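# Probe design: identity screening, exon boundaries, target selection,
# high-copy masking and probe tiling.

test_that("pairwise identity handles direct counts, gaps and many rows", {
  expect_equal(pairwise_identity(c(strrep("A", 120), strrep("A", 120))), 100)
  expect_equal(pairwise_identity(c("AAAA", "AATT")), 50)
  expect_equal(pairwise_identity(c("AA--", "AAAA")), 100)   # gap exclusion
  expect_error(pairwise_identity("AAAA"), "undefined")

  set.seed(101)
  for (rep in 1:5) {
    rows <- replicate(6, random_seq(40))
    expect_equal(pairwise_identity(rows), oracle_pairwise_identity(rows))
  }
})

test_that("exon boundaries appear exactly at constructed splice points", {
  set.seed(7)
  genome <- random_seq(1500)
  expect_equal(find_exon_boundaries(substr(genome, 101, 400),
                                    genome)$boundaries, integer(0))
  spliced <- paste0(substr(genome, 1, 200), substr(genome, 1001, 1200))
  fb <- find_exon_boundaries(spliced, genome)
  expect_equal(fb$boundaries, 200L)
  expect_equal(formals(find_exon_boundaries)$k, 40L)
  expect_warning(find_exon_boundaries(strrep("A", 50), genome), "40-mer")
})

test_that("target selection enforces all published criteria", {
  # fewer than 6 taxa: nothing
  few <- locus_alignment("l1", setNames(replicate(5, strrep("A", 200)),
                                        paste0("t", 1:5)))
  expect_equal(nrow(select_targets(few)), 0L)

  # 6 identical gap-free taxa, 200 columns: a single 200 bp target
  six <- locus_alignment("l2", setNames(rep(random_seq(200), 6),
                                        paste0("t", 1:6)))
  tg <- select_targets(six)
  expect_equal(nrow(tg), 1L)
  expect_equal(tg$length, 200L)
  expect_equal(c(tg$start, tg$end), c(0L, 200L))

  # a boundary inside the region splits it below min_len
  tg_b <- select_targets(six, boundaries = list(t1 = 100L))
  expect_equal(nrow(tg_b), 0L)

  # a gap column voids the region
  gapped <- six
  gseqs <- six$seqs
  substr(gseqs[[3]], 100, 100) <- "-"
  expect_equal(nrow(select_targets(locus_alignment("l3", gseqs))), 0L)
})

test_that("window identity at exactly 50% is rejected (strict >)", {
  # two groups of 3 identical rows; cross-group rows match every 6th column:
  # every 120-column window has mean pairwise identity exactly 50%
  set.seed(31)
  L <- 150L
  s1 <- random_seq(L)
  ch <- strsplit(s1, "")[[1]]
  other <- c(A = "C", C = "G", G = "T", T = "A")
  s2ch <- unname(other[ch])
  match_idx <- seq(6L, L, by = 6L)
  s2ch[match_idx] <- ch[match_idx]
  s2 <- paste(s2ch, collapse = "")
  aln <- locus_alignment("b1", setNames(c(s1, s1, s1, s2, s2, s2),
                                        paste0("t", 1:6)))
  expect_equal(.best <- select_targets(aln) |> nrow(), 0L)
  # one extra matching column tips every window strictly above 50%
  s2ch[1L] <- ch[1L]
  aln2 <- locus_alignment("b2", setNames(c(s1, s1, s1,
                                           paste(s2ch, collapse = ""),
                                           paste(s2ch, collapse = ""),
                                           paste(s2ch, collapse = "")),
                                         paste0("t", 1:6)))
  expect_equal(nrow(select_targets(aln2)), 1L)
})

test_that("accepted targets satisfy an independent rule oracle", {
  set.seed(41)
  n_accepted <- 0L
  for (rep in 1:5) {
    base <- random_seq(400)
    seqs <- vapply(1:7, function(i) {
      ch <- strsplit(base, "")[[1]]
      flip <- runif(400) < 0.25
      ch[flip] <- sample(c("A", "C", "G", "T"), sum(flip), replace = TRUE)
      if (rep > 3 && i <= 2) ch[sample(400, 2)] <- "-"
      paste(ch, collapse = "")
    }, "")
    aln <- locus_alignment("r", setNames(seqs, paste0("t", 1:7)))
    tg <- select_targets(aln)
    n_accepted <- n_accepted + nrow(tg)
    for (i in seq_len(nrow(tg))) {
      cols <- (tg$start[i] + 1L):tg$end[i]
      slice <- vapply(seqs, function(s)
        paste(strsplit(s, "")[[1]][cols], collapse = ""), "")
      expect_false(any(grepl("-", slice, fixed = TRUE)))
      expect_gte(tg$length[i], 150L)
      # at least one 120-column window above 50% by the independent oracle
      wins <- vapply(seq_len(length(cols) - 119L), function(s)
        oracle_pairwise_identity(substring(slice, s, s + 119L)), 0)
      expect_gt(max(wins), 50)
    }
  }
  expect_gte(n_accepted, 1L)
})

test_that("high-copy masking tallies 15-mers with a 1 bp neighborhood", {
  set.seed(51)
  seq <- random_seq(80)
  genome <- random_seq(3000)                 # all 15-mers effectively unique
  expect_equal(mask_high_copy(seq, genome, count_threshold = 2),
               integer(0))

  # one 15-mer repeated 60x in tandem: its 15 positions masked at threshold 50
  unit <- substr(seq, 31, 45)
  genome2 <- paste0(random_dna_fixture <- random_seq(200),
                    strrep(unit, 60), random_seq(200))
  masked <- mask_high_copy(seq, genome2, count_threshold = 50)
  expect_true(all(31:45 %in% masked))
  expect_false(any(setdiff(1:80, 28:48) %in% masked))

  # a Hamming-1 variant of the 15-mer still counts toward the tally
  vch <- strsplit(unit, "")[[1]]
  vch[8] <- setdiff(c("A", "C", "G", "T"), vch[8])[1]
  genome3 <- paste0(random_seq(200), strrep(paste(vch, collapse = ""), 60),
                    random_seq(200))
  masked3 <- mask_high_copy(seq, genome3, count_threshold = 50)
  expect_true(all(31:45 %in% masked3))

  expect_warning(mask_high_copy("ACGTACGT", genome), "shorter")
})

test_that("masking is monotone in the count threshold", {
  set.seed(61)
  seq <- random_seq(60)
  genome <- paste0(strrep(substr(seq, 11, 25), 30), random_seq(500))
  m_low <- mask_high_copy(seq, genome, count_threshold = 5)
  m_high <- mask_high_copy(seq, genome, count_threshold = 20)
  expect_true(all(m_high %in% m_low))
})

test_that("probe tiling matches the step formula and spans the region", {
  p1 <- tile_probes(random_seq(120))
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$start, 0L)

  p2 <- tile_probes(random_seq(189))
  expect_equal(nrow(p2), 2L)
  expect_equal(p2$start, c(0L, 69L))

  expect_warning(p0 <- tile_probes(random_seq(100)), "shorter")
  expect_equal(nrow(p0), 0L)

  reg <- random_seq(700)
  pr <- tile_probes(reg)
  expect_equal(pr$sequence[1], substr(reg, 1, 120))
  expect_equal(pr$start[nrow(pr)] + 120L, 700L)   # last probe right-anchored
  expect_true(all(nchar(pr$sequence) == 120L))
})

test_that("realized tiling coverage approaches the configured density", {
  set.seed(71)
  for (L in c(1200L, 2000L, 3111L)) {
    pr <- tile_probes(random_seq(L))
    cov <- rep(0L, L)
    for (i in seq_len(nrow(pr))) {
      idx <- (pr$start[i] + 1L):(pr$start[i] + 120L)
      cov[idx] <- cov[idx] + 1L
    }
    expect_lt(abs(mean(cov) - 1.72) / 1.72, 0.05)
  }
})

test_that("masked positions split targets and re-apply the length filter", {
  tg <- data.frame(locus = "l", start = 0L, end = 400L, length = 400L,
                   n_taxa = 6L, mean_identity = 100, min_identity = 100,
                   best_window_identity = 100)
  sp <- split_masked_targets(tg, masked = 200L)
  expect_equal(nrow(sp), 2L)
  expect_equal(sp$length, c(199L, 200L))
  sp2 <- split_masked_targets(tg, masked = 100L)   # left piece < 150 dropped
  expect_equal(nrow(sp2), 1L)
  expect_equal(sp2$start, 100L)
})
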