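# Shared fixtures: hand-built reads and a small cached simulation.

# build a read with explicit CIGAR; sequence defaults to all-A of the
# right length
mk_read <- function(id, start, cigar, seq = NULL, chrom = "chrT",
                    mapq = 60L, hap = NA_integer_) {
  if (is.null(seq)) {
    cg <- haplocall:::parse_cigar(cigar)
    n <- sum(cg$len[cg$op %in% c("M", "=", "X", "I", "S")])
    seq <- strrep("A", n)
  }
  aligned_read(id, chrom, start, seq, cigar, mapq = mapq, haplotype = hap)
}

# n error-free reads spanning [start, start+len) carrying sequence `seq`
mk_cov <- function(n, start, seq, prefix = "r", hap = NA_integer_) {
  lapply(seq_len(n), function(i)
    mk_read(paste0(prefix, i), start, paste0(nchar(seq), "M"), seq,
            hap = hap))
}

# small cached simulation shared by several test files (built once per run)
.sim_cache <- new.env(parent = emptyenv())

tiny_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    cfg <- simulation_config(region_length = 60000L, seed = 42L)
    truth <- simulate_diploid(cfg)
    sim <- simulate_reads(truth, cfg, dir = file.path(tempdir(), "tiny_sim"),
                          test_mode = TRUE)
    .sim_cache$sim <- list(cfg = cfg, truth = truth, sim = sim)
  }
  .sim_cache$sim
}

# error-free variant of the cached simulation
tiny_sim_clean <- function() {
  if (is.null(.sim_cache$clean)) {
    cfg <- simulation_config(region_length = 40000L, seed = 7L,
                             error_sub = 0, error_ins = 0, error_del = 0)
    truth <- simulate_diploid(cfg)
    sim <- simulate_reads(truth, cfg, dir = file.path(tempdir(), "tiny_clean"),
                          test_mode = TRUE)
    .sim_cache$clean <- list(cfg = cfg, truth = truth, sim = sim)
  }
  .sim_cache$clean
}

truth_snp_calls <- function(truth) {
  tv <- truth$truth
  tv[nchar(tv$ref) == 1 & !grepl("[A-Z]{2}", tv$alt), , drop = FALSE]
}

truth_indel_calls <- function(truth) {
  tv <- truth$truth
  tv[nchar(tv$ref) > 1 | grepl("[A-Z]{2}", tv$alt), , drop = FALSE]
}

# coarsely trained models shared by the pipeline tests (structure-level
# checks; the parameter-recovery experiment lives in the acceptance tests)
tiny_models <- function() {
  if (is.null(.sim_cache$models)) {
    ts <- tiny_sim()
    reads <- ts$sim$reads
    cand <- select_snp_candidates(reads, ts$truth$chrom, 0,
                                  ts$cfg$region_length, ts$truth$ref_seq,
                                  min_aaf = 0.05)
    icand <- select_indel_candidates(reads, ts$truth$chrom, 0,
                                     ts$cfg$region_length)
    ex <- make_training_examples(ts$truth, reads, snp_candidates = cand,
                                 indel_candidates = icand)
    snp <- build_snp_network(snp_network_config(epochs = 25L,
                                                batch_size = 48L,
                                                seed = 2L))
    snp <- train_snp_network(snp, ex$snp)
    snp$train_coverage <- ts$sim$coverage
    indel <- build_indel_network(indel_network_config(epochs = 20L,
                                                      seed = 2L))
    indel <- suppressWarnings(train_indel_network(indel, ex$indel))
    .sim_cache$models <- list(snp = snp, indel = indel)
  }
  .sim_cache$models
}
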