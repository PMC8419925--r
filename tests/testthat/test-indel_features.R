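# indel_features: window frequencies, candidates, MSA tensors, alleles

test_that("window frequencies count qualifying events per phase", {
  ref <- strrep("A", 60)
  with_ins <- function(id, len) {
    # insertion of `len` C bases after ref position 24
    mk_read(id, 0, sprintf("25M%dI35M", len),
            paste0(strrep("A", 25), strrep("C", len), strrep("A", 35)))
  }
  p1 <- lapply(1:10, function(i) with_ins(paste0("p1_", i), 5))
  p2 <- mk_cov(10, 0, ref, prefix = "p2_")
  # insertion at 25, 5 bp: inside the large window at pos 20
  f <- indel_window_frequencies(list(p1, p2), 20L)
  expect_equal(unname(f["insertion_frequency"]), 1.0)  # max policy
  expect_equal(unname(f["deletion_frequency"]), 0.0)
  fmin <- indel_window_frequencies(list(p1, p2), 20L, phase_combine = "min")
  expect_equal(unname(fmin["insertion_frequency"]), 0.0)
  # error-free reads, no indel
  f0 <- indel_window_frequencies(list(p2, p2), 20L)
  expect_equal(unname(f0), c(0, 0))
})

test_that("a 2 bp event is seen by the small window only", {
  p1 <- lapply(1:6, function(i)
    mk_read(paste0("a", i), 0, "25M2I35M",
            paste0(strrep("A", 25), "CC", strrep("A", 35))))
  p2 <- mk_cov(6, 0, strrep("A", 60), prefix = "b")
  # pos 18: insertion at 25 is inside the large window [18,28) but the
  # event is < 3 bp, and outside the small window [18,22) -> not counted
  f_far <- indel_window_frequencies(list(p1, p2), 18L)
  expect_equal(unname(f_far["insertion_frequency"]), 0)
  # pos 22: small window [22,26) catches it
  f_near <- indel_window_frequencies(list(p1, p2), 22L)
  expect_equal(unname(f_near["insertion_frequency"]), 1)
  # a 12 bp event is too long for the small window but the large window
  # (no upper length limit) still counts it
  p3 <- lapply(1:6, function(i)
    mk_read(paste0("c", i), 0, "25M12I35M",
            paste0(strrep("A", 25), strrep("C", 12), strrep("A", 35))))
  expect_equal(unname(indel_window_frequencies(list(p3, p2),
                                               18L)["insertion_frequency"]),
               1)
  # outside the large window it is not counted at all
  expect_equal(unname(indel_window_frequencies(list(p3, p2),
                                               14L)["insertion_frequency"]),
               0)
})

test_that("candidate selection gates on per-phase depth and frequency", {
  tc <- tiny_sim_clean()
  reads <- tc$sim$reads
  icand <- select_indel_candidates(reads, tc$truth$chrom, 0,
                                   tc$cfg$region_length)
  clusters <- haplocall:::cluster_candidates(icand)
  ind_truth <- truth_indel_calls(tc$truth)
  # every truth indel is discovered by some candidate cluster
  found <- vapply(ind_truth$pos - 1L, function(p)
    any(clusters$pos >= p - 10L & clusters$pos <= p), logical(1))
  expect_true(all(found))
  # no candidate at a min depth above the coverage
  none <- select_indel_candidates(reads, tc$truth$chrom, 0,
                                  tc$cfg$region_length,
                                  min_phase_depth = 100L)
  expect_equal(nrow(none), 0)
  # with the min policy, heterozygous indels disappear
  icand_min <- select_indel_candidates(reads, tc$truth$chrom, 0,
                                       tc$cfg$region_length,
                                       phase_combine = "min")
  het_pos <- ind_truth$pos[ind_truth$genotype %in% c("0|1", "1|0")] - 1L
  found_min <- vapply(het_pos, function(p)
    any(icand_min$pos >= p - 10L & icand_min$pos <= p), logical(1))
  expect_false(any(found_min))
})

test_that("window sequences start at the candidate and truncate", {
  reads <- list(mk_read("long", 0, "300M", strrep("A", 300)),
                mk_read("short", 0, "100M", strrep("G", 100)),
                mk_read("away", 200, "50M", strrep("T", 50)))
  ws <- extract_window_sequences(reads, 50L, strrep("A", 160), 160L)
  expect_equal(nchar(ws$ref), 160)
  expect_equal(nchar(ws$reads[["long"]]), 160)
  expect_equal(nchar(ws$reads[["short"]]), 50)      # truncated at read end
  expect_false("away" %in% names(ws$reads))
})

test_that("msa_realign produces normalised frequency matrices", {
  ref <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  p <- msa_realign(c(ref, rep(ref, 5)), max_cols = 128)
  expect_s3_class(p, "msa_pileup")
  expect_equal(dim(p$M), c(5L, 128L))
  expect_equal(colSums(p$M), rep(1, 128))           # every column sums to 1
  expect_equal(colSums(p$Q), rep(1, 128))           # one-hot reference
  # identical sequences: M - Q vanishes on covered columns
  expect_true(all(abs(p$M - p$Q) < 1e-12))

  # a 3 bp insertion opens a gap run in the reference row
  ins <- paste0(substr(ref, 1, 30), "TTT", substr(ref, 31, 60))
  p2 <- msa_realign(c(ref, rep(ins, 4)), max_cols = 128)
  gaps <- which(p2$aln[1, ] == "-")
  gaps <- gaps[gaps <= 63]                          # inside covered region
  expect_equal(length(gaps), 3)
  expect_equal(diff(gaps), c(1, 1))
  expect_equal(colSums(p2$M), rep(1, 128))
})

test_that("alignment reconstruction matches the gapped-string oracle", {
  skip_if_not_installed("Biostrings")
  set.seed(9)
  for (rep in 1:60) {
    L <- sample(60:160, 1)
    center <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    s <- strsplit(center, "", fixed = TRUE)[[1]]
    for (k in seq_len(sample(0:5, 1))) {
      op <- sample(3, 1); p <- sample(length(s), 1)
      if (op == 1) s[p] <- sample(c("A", "C", "G", "T"), 1)
      if (op == 2) s <- append(s, sample(c("A", "C", "G", "T"),
                                         sample(1:8, 1), TRUE), after = p)
      if (op == 3 && p + 6 < length(s)) s <- s[-(p:(p + sample(1:6, 1)))]
    }
    a <- sample(1:max(1, length(s) - 40), 1)
    b <- min(length(s), a + sample(30:150, 1))
    readseq <- paste(s[a:b], collapse = "")
    pa <- haplocall:::pairwise_affine(readseq, center)
    ac <- haplocall:::alignment_columns(pa, 1)
    po <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(readseq), Biostrings::DNAString(center),
      type = "overlap", substitutionMatrix = haplocall:::nuc_submat(),
      gapOpening = 8, gapExtension = 1)
    P <- strsplit(as.character(Biostrings::alignedPattern(po)), "")[[1]]
    S <- strsplit(as.character(Biostrings::alignedSubject(po)), "")[[1]]
    expect_equal(ac$ncols, length(P))
    expect_equal(ac$is_ins, S == "-")
    expect_equal(ac$is_del, P == "-")
  }
})

test_that("internal and mafft backends agree on error-free consensus", {
  skip_if(Sys.which("mafft") == "", "mafft not on PATH")
  set.seed(5)
  ref <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  alt <- paste0(substr(ref, 1, 40), "CTGAA", substr(ref, 41, 80))
  seqs <- c(ref, rep(alt, 8))
  ci <- consensus_from_msa(msa_realign(seqs, backend = "internal"))
  cm <- consensus_from_msa(msa_realign(seqs, backend = "mafft"))
  expect_equal(ci, cm)
  expect_equal(ci, substr(alt, 1, nchar(ci)))
})

test_that("consensus majority respects the reference tie-break", {
  ref <- "ACGT"
  # 2 reads C, 2 reads A at column 1 -> tie; reference A wins
  p <- msa_realign(c(ref, "ACGT", "ACGT", "CCGT", "CCGT"), max_cols = 8)
  expect_equal(substr(consensus_from_msa(p), 1, 4), "ACGT")
  # clear majority overrides the reference
  p2 <- msa_realign(c(ref, "CCGT", "CCGT", "CCGT", "ACGT"), max_cols = 8)
  expect_equal(substr(consensus_from_msa(p2), 1, 4), "CCGT")
})

test_that("indel tensor stacks the three read sets", {
  ref <- paste(sample(c("A", "C", "G", "T"), 160, TRUE), collapse = "")
  alt <- paste0(substr(ref, 1, 50), "TTTT", substr(ref, 51, 160))
  p_all <- msa_realign(c(ref, ref, ref, alt, alt))
  p_1 <- msa_realign(c(ref, ref, ref))
  p_2 <- msa_realign(c(ref, alt, alt))
  tns <- build_indel_feature_tensor(p_all, p_1, p_2)
  expect_equal(dim(tns), c(15L, 128L, 2L))
  expect_true(all(tns[, , 1] >= -1 & tns[, , 1] <= 1))
  expect_true(all(tns[, , 2] %in% c(0, 1)))
  # when the realigned references agree (no alt reads in either set), the
  # Q blocks coincide
  hom <- build_indel_feature_tensor(p_1, p_1, p_1)
  expect_equal(hom[6:10, , 2], hom[1:5, , 2])
  expect_equal(hom[11:15, , 2], hom[1:5, , 2])
  miss <- build_indel_feature_tensor(p_all, NULL, p_2)
  expect_true(all(miss[6:10, , ] == 0))
  expect_equal(attr(miss, "empty_sets"), "phase1")
})

test_that("infer_allele recovers hand-built insertions and deletions", {
  set.seed(41)
  ref <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  # pin the local context so the gap placement is unambiguous:
  # inserted GGT cannot slide left (T != ref[20]) or right (G != ref[21])
  substr(ref, 20, 26) <- "ACGTACG"
  ins <- paste0(substr(ref, 1, 20), "GGT", substr(ref, 21, 60))
  a <- infer_allele(ins, ref)
  expect_equal(a$ref, substr(ref, 20, 20))
  expect_equal(a$alt, paste0(substr(ref, 20, 20), "GGT"))
  expect_equal(a$offset, 19L)

  del <- paste0(substr(ref, 1, 20), substr(ref, 26, 60))
  d <- infer_allele(del, ref)
  expect_equal(d$ref, substr(ref, 20, 25))
  expect_equal(d$alt, substr(ref, 20, 20))
  expect_equal(d$offset, 19L)

  expect_null(infer_allele(ref, ref))
})

test_that("combine_phase_calls covers all zygosity outcomes", {
  a1 <- list(ref = "AT", alt = "A", offset = 4L)
  a2 <- list(ref = "A", alt = "AT", offset = 4L)
  c10 <- combine_phase_calls(a1, NULL, "chrT", 100L, 50)
  expect_equal(c10$genotype, "1|0")
  expect_equal(c10$pos, 105L)
  c01 <- combine_phase_calls(NULL, a1, "chrT", 100L, 50)
  expect_equal(c01$genotype, "0|1")
  c11 <- combine_phase_calls(a1, a1, "chrT", 100L, 50)
  expect_equal(c11$genotype, "1|1")
  expect_null(combine_phase_calls(NULL, NULL, "chrT", 100L, 50))
  # two different insertions -> 1|2 sharing one record
  b1 <- list(ref = "A", alt = "AT", offset = 4L)
  b2 <- list(ref = "A", alt = "ATT", offset = 4L)
  c12 <- combine_phase_calls(b1, b2, "chrT", 100L, 50)
  expect_equal(c12$genotype, "1|2")
  expect_equal(c12$alt, "AT,ATT")
  # deletions of different lengths unify to the longer reference allele
  d1 <- list(ref = "ATG", alt = "A", offset = 4L)
  d2 <- list(ref = "AT", alt = "A", offset = 4L)
  cd <- combine_phase_calls(d1, d2, "chrT", 100L, 50)
  expect_equal(cd$ref, "ATG")
  expect_setequal(strsplit(cd$alt, ",")[[1]], c("A", "AG"))
})

test_that("exact allele recovery across indel lengths and zygosities", {
  set.seed(12)
  ref <- paste(sample(c("A", "C", "G", "T"), 160, TRUE), collapse = "")
  for (len in c(1L, 2L, 5L, 12L, 21L, 30L)) {
    for (kind in c("ins", "del")) {
      alt_seq <- if (kind == "ins")
        paste0(substr(ref, 1, 40),
               paste(sample(c("A", "C", "G", "T"), len, TRUE),
                     collapse = ""), substr(ref, 41, 160))
      else paste0(substr(ref, 1, 40), substr(ref, 41 + len, 160))
      for (zyg in c("hom", "het")) {
        h1 <- rep(alt_seq, 8)
        h2 <- if (zyg == "hom") rep(alt_seq, 8)
              else rep(ref, 8)
        p1 <- msa_realign(c(ref, h1))
        p2 <- msa_realign(c(ref, h2))
        a1 <- infer_allele(consensus_from_msa(p1), ref)
        a2 <- infer_allele(consensus_from_msa(p2), ref)
        vc <- combine_phase_calls(a1, a2, "chrT", 0L, 10)
        expect_equal(nrow(vc), 1)
        expect_equal(vc$genotype, if (zyg == "hom") "1|1" else "1|0")
        if (kind == "ins") {
          expect_equal(nchar(vc$alt) - nchar(vc$ref), len)
        } else {
          expect_equal(nchar(vc$ref) - nchar(vc$alt), len)
        }
        # the called allele reproduces the simulated haplotype exactly
        rebuilt <- paste0(substr(ref, 1, vc$pos - 1), vc$alt,
                          substr(ref, vc$pos + nchar(vc$ref), 160))
        expect_equal(rebuilt, substr(alt_seq, 1, nchar(rebuilt)))
      }
    }
  }
})
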