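# snp_features: candidate selection, neighbor windows, feature tensors

test_that("alt_allele_frequency follows the max-alt over depth formula", {
  mkcol <- function(bases, ref = "A") {
    reads <- lapply(seq_along(bases), function(i)
      mk_read(paste0("r", i), 0, "1M", bases[i]))
    pileup(reads, "chrT", 0, ref)
  }
  expect_equal(alt_allele_frequency(mkcol(rep(c("A", "G"), c(12, 4)))), 0.25)
  expect_equal(alt_allele_frequency(mkcol(rep("A", 16))), 0)
  expect_equal(alt_allele_frequency(mkcol(rep(c("A", "G", "T"), each = 5))),
               1 / 3)
  empty <- pileup(list(), "chrT", 0, "A")
  expect_error(alt_allele_frequency(empty), "depth 0")
})

test_that("candidate gate needs both depth and AAF at the 15% default", {
  ref <- strrep("A", 30)
  # depth 20, 5 reads carry G at position 10 -> aaf 0.25
  seqs_alt <- paste0(strrep("A", 10), "G", strrep("A", 19))
  reads <- c(mk_cov(15, 0, ref), mk_cov(5, 0, seqs_alt, prefix = "alt"))
  cand <- select_snp_candidates(reads, "chrT", 0, 30, ref)
  expect_equal(cand$pos, 10L)
  expect_equal(cand$aaf, 0.25)
  expect_equal(cand$top_alt, "G")

  # aaf 0.10 (2/20) is excluded
  reads2 <- c(mk_cov(18, 0, ref), mk_cov(2, 0, seqs_alt, prefix = "alt"))
  expect_equal(nrow(select_snp_candidates(reads2, "chrT", 0, 30, ref)), 0)

  # error-free homozygous-reference reads: no candidates
  expect_equal(nrow(select_snp_candidates(mk_cov(20, 0, ref), "chrT", 0, 30,
                                          ref)), 0)

  # the gate flips exactly at 15%: 6/40 in, 5/40 out
  r6 <- c(mk_cov(34, 0, ref), mk_cov(6, 0, seqs_alt, prefix = "alt"))
  r5 <- c(mk_cov(35, 0, ref), mk_cov(5, 0, seqs_alt, prefix = "alt"))
  expect_equal(select_snp_candidates(r6, "chrT", 0, 30, ref)$pos, 10L)
  expect_equal(nrow(select_snp_candidates(r5, "chrT", 0, 30, ref)), 0)

  # depth gate: aaf 0.25 but depth 4 < 8
  r4 <- c(mk_cov(3, 0, ref), mk_cov(1, 0, seqs_alt, prefix = "alt"))
  expect_equal(nrow(select_snp_candidates(r4, "chrT", 0, 30, ref)), 0)
})

test_that("likely heterozygous sites use the 40-60% band or truth hets", {
  cand <- data.frame(chrom = "chrT", pos = c(10L, 20L, 30L, 40L),
                     ref_base = c("A", "C", "G", "T"),
                     depth = 20L, aaf = c(0.50, 0.39, 0.60, 0.95),
                     top_alt = "A", stringsAsFactors = FALSE)
  hs <- select_het_sites(cand)
  expect_equal(hs$pos, c(10L, 30L))                # 0.39 and 0.95 excluded

  truth <- variant_calls(rep("chrT", 4), c(5L, 6L, 7L, 8L),
                         c("A", "C", "G", "AT"), c("T", "G,T", "A", "A"),
                         c("0|1", "1|2", "1|1", "0|1"), 0)
  ht <- select_het_sites(cand, mode = "training", truth = truth)
  # het SNP and multiallelic SNP qualify; hom SNP and indel do not
  expect_equal(ht$pos, c(4L, 5L))
})

test_that("nearest neighbor selection takes 20 per flank within the limit", {
  # one long read ties everything to b; het sites every 500 bp
  big <- mk_read("big", 0, "100000M", strrep("A", 100000))
  hs <- structure(data.frame(pos = seq(500L, 99500L, by = 500L),
                             ref_base = "A", stringsAsFactors = FALSE),
                  class = c("het_sites", "data.frame"))
  nbr <- choose_neighbor_sites(50000L, "A", hs, list(big),
                               strategy = "nearest",
                               distance_limit = 50000L)
  expect_equal(nbr$n_sites, 40)
  expect_equal(sum(!is.na(nbr$pos)), 41)
  expect_equal(nbr$pos[21], 50000L)
  # nearest sites hug the candidate
  expect_equal(nbr$pos[20], 49500L)
  expect_equal(nbr$pos[22], 50500L)
  # all within the distance limit
  expect_true(all(abs(nbr$pos - 50000L) <= 50000L, na.rm = TRUE))
})

test_that("banded strategy fills 2/3/4/5/6 quotas per distance band", {
  big <- mk_read("big", 0, "100000M", strrep("A", 100000))
  hs <- structure(data.frame(pos = seq(100L, 99900L, by = 100L),
                             ref_base = "A", stringsAsFactors = FALSE),
                  class = c("het_sites", "data.frame"))
  b <- 50000L
  nbr <- choose_neighbor_sites(b, "A", hs, list(big), strategy = "banded")
  expect_equal(nbr$n_sites, 40)
  up <- nbr$pos[1:20]; down <- nbr$pos[22:41]
  band_of <- function(p) findInterval(abs(p - b) - 1,
                                      c(0, 2000, 5000, 10000, 20000))
  expect_equal(as.integer(table(band_of(up))), c(2L, 3L, 4L, 5L, 6L))
  expect_equal(as.integer(table(band_of(down))), c(2L, 3L, 4L, 5L, 6L))
})

test_that("sparse flanks yield fewer sites and the gate fires", {
  big <- mk_read("big", 0, "10000M", strrep("A", 10000))
  hs <- structure(data.frame(pos = c(1000L, 2000L, 7000L),
                             ref_base = "A", stringsAsFactors = FALSE),
                  class = c("het_sites", "data.frame"))
  nbr <- choose_neighbor_sites(5000L, "A", hs, list(big))
  expect_equal(nbr$n_sites, 3)
  expect_equal(sum(!is.na(nbr$pos)), 4)            # including b
  expect_true(min_neighbor_gate(nbr, 1))
  expect_false(min_neighbor_gate(nbr, 4))

  none <- choose_neighbor_sites(5000L, "A",
                                structure(data.frame(pos = integer(),
                                                     ref_base = character()),
                                          class = c("het_sites",
                                                    "data.frame")),
                                list(big))
  expect_false(min_neighbor_gate(none, 1))         # default minimum is 1
  expect_true(min_neighbor_gate(nbr, 1))
})

test_that("neighbor sites must share a read with the candidate", {
  # two disjoint reads: sites under the second read don't qualify for a
  # candidate under the first
  r1 <- mk_read("r1", 0, "1000M", strrep("A", 1000))
  r2 <- mk_read("r2", 5000, "1000M", strrep("A", 1000))
  hs <- structure(data.frame(pos = c(100L, 5500L), ref_base = "A",
                             stringsAsFactors = FALSE),
                  class = c("het_sites", "data.frame"))
  nbr <- choose_neighbor_sites(500L, "A", hs, list(r1, r2))
  expect_equal(nbr$pos[!is.na(nbr$pos)], c(100L, 500L))
})

test_that("feature tensor matches shape, signs and the counting oracle", {
  # 8 reads: 4 carry A (ref) at b=2, 4 carry G; a linked het site at 0
  seq_refhap <- "CAAAT"
  seq_althap <- "TAGAT"
  reads <- c(mk_cov(4, 0, seq_refhap, prefix = "h1"),
             mk_cov(4, 0, seq_althap, prefix = "h2"))
  hs <- structure(data.frame(pos = 0L, ref_base = "C",
                             stringsAsFactors = FALSE),
                  class = c("het_sites", "data.frame"))
  nbr <- choose_neighbor_sites(2L, "A", hs, reads)
  tns <- build_snp_feature_tensor(nbr, reads)
  expect_equal(dim(tns), c(5L, 41L, 5L))
  # padded columns all zero
  expect_true(all(tns[, c(1:19, 23:41), ] == 0))
  # center column: R_A group (row 1) has 4 reads with A = reference -> -4
  expect_equal(tns[1, 21, 1], -4)
  # R_G group (row 2) has 4 reads with G (not ref) -> +4 in G channel
  expect_equal(tns[2, 21, 2], 4)
  # linked column 20 (site 0, ref C): R_A reads carry C there -> negative
  expect_equal(tns[1, 20, 4], -4)
  # R_G reads carry T at site 0 -> positive in T channel
  expect_equal(tns[2, 20, 3], 4)
  # channel 5 marks the reference base at b (A -> row 1) on window columns
  expect_equal(tns[1, 20:21, 5], rep(1, 2))
  expect_true(all(tns[2:4, , 5] == 0))
  # row 5 one-hot encodes window site reference bases
  expect_equal(tns[5, 21, 1], 1)                   # b's ref A
  expect_equal(tns[5, 20, 4], 1)                   # site 0 ref C
  # a site with no read support errors as uncallable
  del_reads <- list(mk_read("d", 0, "1M3D1M", "AA"))
  nbr2 <- choose_neighbor_sites(2L, "A", hs, del_reads)
  expect_error(build_snp_feature_tensor(nbr2, del_reads), "uncallable")
})

test_that("tensor equals the naive per-read per-site counting oracle", {
  ts <- tiny_sim()
  reads <- ts$sim$reads
  ref_seq <- ts$truth$ref_seq
  cand <- select_snp_candidates(reads, ts$truth$chrom, 0,
                                ts$cfg$region_length, ref_seq)
  het <- select_het_sites(cand)
  set.seed(3)
  pick <- sample(seq_len(nrow(cand)), min(30, nrow(cand)))
  maps <- lapply(reads, oracle_read_map)
  for (i in pick) {
    nbr <- choose_neighbor_sites(cand$pos[i], cand$ref_base[i], het, reads)
    tns <- build_snp_feature_tensor(nbr, reads)
    oracle <- snp_tensor_oracle(nbr, reads, maps)
    expect_equal(tns, oracle)
    # per-column absolute counts never exceed the group size
    codes <- haplocall:::base_codes_at(reads, cand$pos[i])
    for (g in 1:4) {
      grow <- haplocall:::CODE_TO_TENSOR[g]
      expect_true(all(rowSums(abs(tns[grow, , 1:4])) <= sum(codes == g)))
    }
  }
})

test_that("rescale_counts scales counts only, preserving signs and Q", {
  ts <- tiny_sim()
  reads <- ts$sim$reads
  cand <- select_snp_candidates(reads, ts$truth$chrom, 0,
                                ts$cfg$region_length, ts$truth$ref_seq)
  het <- select_het_sites(cand)
  nbr <- choose_neighbor_sites(cand$pos[1], cand$ref_base[1], het, reads)
  tns <- build_snp_feature_tensor(nbr, reads)
  expect_equal(rescale_counts(tns, 40, 40), tns)
  dbl <- rescale_counts(tns, 80, 40)
  expect_equal(dbl[1:4, , 1:4], tns[1:4, , 1:4] * 2)
  expect_equal(dbl[, , 5], tns[, , 5])
  expect_equal(dbl[5, , ], tns[5, , ])
  expect_true(all(sign(dbl) == sign(tns)))
  expect_error(rescale_counts(tns, 0, 40), "positive")
})

test_that("read groups at a het candidate have anti-correlated patterns", {
  tc <- tiny_sim_clean()
  reads <- tc$sim$reads
  truth_snps <- truth_snp_calls(tc$truth)
  het_truth <- truth_snps[truth_snps$genotype %in% c("0|1", "1|0"), ]
  skip_if(nrow(het_truth) < 3, "no het SNPs in fixture")
  cand <- select_snp_candidates(reads, tc$truth$chrom, 0,
                                tc$cfg$region_length, tc$truth$ref_seq)
  het <- select_het_sites(cand)
  b <- het_truth$pos[ceiling(nrow(het_truth) / 2)] - 1L
  i <- match(b, cand$pos)
  skip_if(is.na(i), "candidate gate suppressed the site")
  nbr <- choose_neighbor_sites(b, cand$ref_base[i], het, reads)
  tns <- build_snp_feature_tensor(nbr, reads)
  occupied <- apply(abs(tns[1:4, , 1:4]), 1, sum) > 0
  expect_equal(sum(occupied), 2)                   # exactly two read groups
  rows <- which(occupied)
  live <- which(!is.na(nbr$pos))
  # per-column signed signature: negative where the group matches the
  # site's reference base, positive where it carries the alternative
  s1 <- rowSums(tns[rows[1], live, 1:4])
  s2 <- rowSums(tns[rows[2], live, 1:4])
  shared <- s1 != 0 & s2 != 0
  expect_lt(cor(s1[shared], s2[shared]), 0)
})

test_that("platform profiles bundle the documented defaults", {
  ont <- platform_profile("ONT")
  expect_equal(ont$neighbor_strategy, "banded")
  expect_equal(c(ont$het_lower, ont$het_upper), c(0.4, 0.6))
  expect_equal(ont$distance_limit, 50000L)
  ccs <- platform_profile("CCS")
  expect_equal(ccs$neighbor_strategy, "nearest")
  expect_equal(c(ccs$het_lower, ccs$het_upper), c(0.3, 0.7))
  expect_equal(ccs$distance_limit, 20000L)
  expect_equal(platform_profile("CLR")$het_upper, 0.6)
})
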