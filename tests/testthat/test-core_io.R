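# core_io: FASTA/BAM/VCF plumbing and the pileup contract

test_that("read_reference slices, uppercases and validates bounds", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgtACGT"), fa)
  expect_equal(read_reference(fa, "chr1", 0, 4), "ACGT")
  expect_equal(read_reference(fa, "chr1", 4, 8), "ACGT")
  expect_equal(read_reference(fa, "chr1", 0, 8), "ACGTACGT")
  expect_error(read_reference(fa, "chrX", 0, 4), "not found")
  expect_error(read_reference(fa, "chr1", 0, 9), "bounds")
})

test_that("aligned_read decodes CIGARs into pairs and events", {
  r <- mk_read("r1", 10, "5M2I5M", "ACGTACCGTACG")
  p <- aligned_pairs(r)
  expect_equal(nrow(p), 12)
  expect_equal(sum(is.na(p$ref_pos)), 2)           # the insertion
  expect_equal(p$ref_pos[!is.na(p$ref_pos)], 10:19)
  expect_true(all(diff(p$read_index) > 0))
  expect_equal(r$ins$pos, 15L)
  expect_equal(r$ins$len, 2L)

  d <- mk_read("r2", 0, "3M2D3M", "ACGTAC")
  expect_equal(d$del$pos, 3L)
  expect_equal(d$del$len, 2L)
  expect_equal(d$ref_end, 8L)
  # CIGAR/sequence length mismatch is rejected
  expect_error(mk_read("bad", 0, "5M", "ACG"), "consumes")
})

test_that("pileup reports spanning reads, deletions, and skips others", {
  reads <- c(mk_cov(10, 0, "AAAAAA"),
             list(mk_read("del1", 0, "3M2D3M", "AAAAAA"),
                  mk_read("short", 0, "2M", "AA")))
  col <- pileup(reads, "chrT", 3, "A")
  expect_s3_class(col, "pileup_column")
  expect_equal(col$depth, 11)                      # 10 spanning + deletion
  expect_equal(unname(col$per_read_base[["del1"]]), "-")
  expect_false("short" %in% names(col$per_read_base))
  expect_equal(sum(col$per_read_base == "A"), 10)
  expect_equal(col$depth, length(col$per_read_base))
})

test_that("simulator BAM round-trips through read_alignments", {
  ts <- tiny_sim()
  reads <- read_alignments(ts$sim$bam, ts$truth$chrom, 0,
                           ts$cfg$region_length)
  expect_equal(length(reads), length(ts$sim$reads))
  expect_true(all(vapply(reads, `[[`, integer(1), "haplotype") %in% 1:2))
  # a high mapq threshold removes everything
  expect_length(read_alignments(ts$sim$bam, ts$truth$chrom, 0, 1000,
                                min_mapq = 61), 0)
  # round trip preserves sequence and cigar for a spot-checked read
  orig <- ts$sim$reads[[5]]
  back <- reads[[which(vapply(reads, `[[`, character(1), "read_id") ==
                         orig$read_id)]]
  expect_equal(back$sequence, orig$sequence)
  expect_equal(back$cigar, orig$cigar)
  expect_equal(back$ref_start, orig$ref_start)
})

test_that("pileup depth is conserved against per-read aligned lengths", {
  ts <- tiny_sim()
  reads <- ts$sim$reads[1:25]
  lo <- min(vapply(reads, `[[`, integer(1), "ref_start"))
  hi <- max(vapply(reads, `[[`, integer(1), "ref_end"))
  rp <- haplocall:::region_pileup_counts(reads, lo, hi)
  expect_equal(sum(rp$depth),
               sum(vapply(reads, function(r) r$ref_end - r$ref_start,
                          integer(1))))
})

test_that("write_vcf emits parseable VCF 4.2 that round-trips exactly", {
  set.seed(1)
  n <- 1000
  gts <- c("0/1", "1/1", "1|0", "0|1", "1|1")
  pos <- sort(sample.int(1e6, n))
  ref <- sample(c("A", "C", "G", "T"), n, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                "")
  calls <- variant_calls("chr1", pos, ref, alt, sample(gts, n, TRUE),
                         round(runif(n, 0, 999), 2))
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, "S1", path, contigs = c(chr1 = 2000000L))
  back <- read_vcf(path)
  expect_equal(back$chrom, calls$chrom)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$ref, calls$ref)
  expect_equal(back$alt, calls$alt)
  expect_equal(back$genotype, calls$genotype)
  expect_equal(back$qual, calls$qual, tolerance = 1e-9)
})

test_that("write_vcf handles multiallelics, empty sets and rejects unsorted", {
  ma <- variant_calls("chr3", 5336450L, "A", "T,C", "1|2", 200)
  path <- tempfile(fileext = ".vcf")
  write_vcf(ma, "S1", path, phased = TRUE)
  line <- grep("^chr3", readLines(path), value = TRUE)
  expect_match(line, "A\tT,C\t200.00\tPASS\t.\tGT\t1\\|2")

  empty <- variant_calls()
  p2 <- tempfile(fileext = ".vcf")
  write_vcf(empty, "S1", p2)
  expect_true(all(startsWith(readLines(p2), "#")))
  expect_equal(nrow(read_vcf(p2)), 0)

  uns <- variant_calls(c("chr1", "chr1"), c(100L, 50L), c("A", "C"),
                       c("T", "G"), c("0/1", "0/1"), c(10, 10))
  expect_error(write_vcf(uns, "S1", tempfile()), "sorted")
})

test_that("write_vcf output round-trips through an independent VCF parser", {
  skip_if_not_installed("VariantAnnotation")
  calls <- variant_calls(c("chr1", "chr1", "chr2"),
                         c(100L, 250L, 30L),
                         c("A", "AT", "G"), c("T", "A", "GCC,GA"),
                         c("0/1", "1/1", "1/2"), c(31.42, 999, 8.5))
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, "S1", path, contigs = c(chr1 = 1000L, chr2 = 1000L))
  v <- VariantAnnotation::readVcf(path, genome = "test")
  expect_equal(length(v), 3)
  expect_equal(unname(as.character(VariantAnnotation::ref(v))),
               calls$ref)
  alts <- methods::as(VariantAnnotation::alt(v), "CharacterList")
  expect_equal(unname(vapply(alts, paste, "", collapse = ",")), calls$alt)
  expect_equal(unname(VariantAnnotation::geno(v)$GT[, 1]),
               c("0/1", "1/1", "1/2"))
})

test_that("classify_variant distinguishes SNP, insertion and deletion", {
  expect_equal(classify_variant("A", "T"), "SNP")
  expect_equal(classify_variant("A", "ATATC"), "insertion")
  expect_equal(classify_variant("GGGGGGGC", "A"), "deletion")
  expect_equal(classify_variant("GCA", "G"), "deletion")
  expect_error(classify_variant("A", "A"), "identical")
})

test_that("classifier agrees with a length comparator on the Sanger list", {
  tab <- sanger_validated_variants()
  expect_equal(nrow(tab), 41)
  got <- unlist(lapply(seq_len(nrow(tab)), function(i) {
    alts <- strsplit(tab$alt[i], ",", fixed = TRUE)[[1]]
    vapply(alts, classify_variant, "", ref_allele = tab$ref[i])
  }))
  # independent brute-force comparator on allele lengths
  oracle <- unlist(lapply(seq_len(nrow(tab)), function(i) {
    alts <- strsplit(tab$alt[i], ",", fixed = TRUE)[[1]]
    vapply(alts, function(a) {
      if (nchar(tab$ref[i]) == 1 && nchar(a) == 1) "SNP"
      else if (nchar(a) > nchar(tab$ref[i])) "insertion"
      else "deletion"
    }, "")
  }))
  expect_equal(got, oracle)
})

test_that("read_bed parses 0-based half-open regions", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t1000", "chr2\t500\t600"), bed)
  r <- read_bed(bed)
  expect_equal(r$chrom, c("chr1", "chr2"))
  expect_equal(r$start, c(0L, 500L))
  expect_equal(r$end, c(1000L, 600L))
})
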