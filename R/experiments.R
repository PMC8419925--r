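# Self-contained simulation experiments: train on one synthetic diploid
# genome, call an independently simulated genome, and score against its
# truth. Used by the test suite and the acceptance script; also a
# convenient way to sanity-check the whole method end to end.

#' Cross-genome SNP calling experiment
#'
#' Simulates a training genome, harvests labelled candidate tensors (with
#' the truth heterozygous SNPs as feature anchors and a lowered AAF floor
#' so that noise negatives are represented), trains the SNP network, then
#' simulates a second, independent genome and calls it with the full
#' pipeline. Returns precision/recall/F1 of the SNP calls against the
#' second genome's truth.
#'
#' @param seed base seed; the two genomes use offset seeds derived from
#'   it.
#' @param train_length,test_length region lengths in bp.
#' @param coverage diploid coverage (default 30).
#' @param error_sub substitution error rate (default 0.01).
#' @param epochs,batch_size training schedule (defaults 100 and 64).
#' @param work_dir scratch directory for the simulated files.
#' @return list with `metrics` (precision/recall/F1), `counts`
#'   (an [compare_calls()] result), `model`, and the two coverages.
#' @export
snp_recovery_experiment <- function(seed = 1L, train_length = 1200000L,
                                    test_length = 200000L, coverage = 30,
                                    error_sub = 0.01, epochs = 100L,
                                    batch_size = 64L,
                                    work_dir = tempfile("snp_exp")) {
  cfg_a <- simulation_config(region_length = train_length,
                             coverage = coverage, error_sub = error_sub,
                             seed = seed)
  truth_a <- simulate_diploid(cfg_a)
  sim_a <- simulate_reads(truth_a, cfg_a, dir = file.path(work_dir, "train"),
                          test_mode = TRUE)
  cand_a <- select_snp_candidates(sim_a$reads, truth_a$chrom, 0,
                                  train_length, truth_a$ref_seq,
                                  min_aaf = 0.05)
  ex <- make_training_examples(truth_a, sim_a$reads,
                               snp_candidates = cand_a, seed = seed)
  model <- build_snp_network(snp_network_config(epochs = epochs,
                                               batch_size = batch_size,
                                               seed = seed))
  model <- train_snp_network(model, ex$snp)
  model$train_coverage <- sim_a$coverage

  cfg_b <- simulation_config(region_length = test_length,
                             coverage = coverage, error_sub = error_sub,
                             seed = seed + 1000L)
  truth_b <- simulate_diploid(cfg_b)
  sim_b <- simulate_reads(truth_b, cfg_b, dir = file.path(work_dir, "test"))
  res <- call_variants(run_config(mode = "snps_unphased", bam = sim_b$bam,
                                  ref = sim_b$fasta,
                                  out_dir = file.path(work_dir, "out"),
                                  snp_model = model,
                                  train_coverage = model$train_coverage))
  truth_snps <- truth_b$truth[nchar(truth_b$truth$ref) == 1 &
                                !grepl("[A-Z]{2}", truth_b$truth$alt), ,
                              drop = FALSE]
  counts <- compare_calls(res$calls, truth_snps)
  list(metrics = prf1(counts), counts = counts, model = model,
       train_coverage = sim_a$coverage, test_coverage = sim_b$coverage)
}

#' Exhaustive indel allele recovery sweep
#'
#' For every indel length in `lengths`, both types (insertion, deletion)
#' and both zygosities (het, hom), builds error-free read windows, runs
#' the MSA consensus and allele inference, combines phases, and checks
#' that the called allele reproduces the simulated haplotype exactly and
#' the genotype matches.
#'
#' @param seed RNG seed for the window sequences.
#' @param lengths indel lengths to sweep (default 1:30).
#' @param depth reads per haplotype (default 8).
#' @param window_length MSA window length (default 160).
#' @return list with `recovery_rate` (fraction of cases recovered
#'   exactly) and `cases` (per-case data.frame).
#' @export
indel_recovery_sweep <- function(seed = 1L, lengths = 1:30, depth = 8L,
                                 window_length = 160L) {
  set.seed(seed)
  ref <- paste(sample(BASES, window_length, TRUE), collapse = "")
  rows <- list()
  for (len in lengths) {
    for (kind in c("insertion", "deletion")) {
      alt_seq <- if (kind == "insertion")
        paste0(substr(ref, 1, 40),
               paste(sample(BASES, len, TRUE), collapse = ""),
               substr(ref, 41, window_length))
      else paste0(substr(ref, 1, 40), substr(ref, 41 + len, window_length))
      for (zyg in c("het", "hom")) {
        h1 <- rep(alt_seq, depth)
        h2 <- if (zyg == "hom") rep(alt_seq, depth) else rep(ref, depth)
        a1 <- infer_allele(consensus_from_msa(msa_realign(c(ref, h1))), ref)
        a2 <- infer_allele(consensus_from_msa(msa_realign(c(ref, h2))), ref)
        vc <- combine_phase_calls(a1, a2, "chrSweep", 0L, 10)
        ok <- FALSE
        if (!is.null(vc) && nrow(vc) == 1) {
          want_gt <- if (zyg == "hom") "1|1" else "1|0"
          rebuilt <- paste0(substr(ref, 1, vc$pos - 1), vc$alt,
                            substr(ref, vc$pos + nchar(vc$ref),
                                   window_length))
          ok <- vc$genotype == want_gt &&
            rebuilt == substr(alt_seq, 1, nchar(rebuilt))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          length = len, kind = kind, zygosity = zyg, recovered = ok)
      }
    }
  }
  cases <- do.call(rbind, rows)
  list(recovery_rate = mean(cases$recovered), cases = cases)
}
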