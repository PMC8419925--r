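# simulate: deterministic diploid genome and long-read simulator.
#
# Generates a random reference, plants phased SNPs and indels on two
# haplotypes, samples error-bearing long reads per haplotype and emits
# them with exact alignments (no external aligner needed), as in-memory
# aligned_read objects and as sorted/indexed BAM + indexed FASTA + truth
# VCF. Every random draw flows from the single config seed.

#' Simulation configuration
#'
#' Defaults emulate a 30x ONT-like diploid sample: about one SNP per
#' 1000 bp (two thirds heterozygous), one indel per 5000 bp with lengths
#' 1-30 bp, 20 kb mean read length, 1% substitution errors and 0.5%
#' insertion/deletion errors with deletions enriched 3x inside
#' homopolymer runs.
#'
#' @param region_length reference length in bp.
#' @param chrom contig name.
#' @param snp_rate,indel_rate per-bp variant rates.
#' @param het_fraction fraction of variants that are heterozygous.
#' @param multiallelic_fraction fraction of het variants carrying two
#'   different alternative alleles (genotype 1|2).
#' @param indel_max_len,indel_geom_p indel length model: 1 + geometric,
#'   truncated at `indel_max_len`.
#' @param min_variant_spacing minimum bp between variant anchors.
#' @param coverage total diploid coverage (split evenly over haplotypes).
#' @param read_length_mean,read_length_sd,read_length_min read length
#'   model (normal, truncated below).
#' @param error_sub,error_ins,error_del per-base error rates.
#' @param homopolymer_mult,homopolymer_min deletion-rate multiplier inside
#'   homopolymer runs of at least `homopolymer_min` bases.
#' @param seed RNG seed; fixes all downstream randomness.
#' @return named list of class `simulation_config`.
#' @export
simulation_config <- function(region_length = 100000L, chrom = "chrSim",
                              snp_rate = 1 / 1000, indel_rate = 1 / 5000,
                              het_fraction = 2 / 3,
                              multiallelic_fraction = 0.02,
                              indel_max_len = 30L, indel_geom_p = 0.3,
                              min_variant_spacing = 50L,
                              coverage = 30, read_length_mean = 20000,
                              read_length_sd = 5000,
                              read_length_min = 1000,
                              error_sub = 0.01, error_ins = 0.005,
                              error_del = 0.005,
                              homopolymer_mult = 3, homopolymer_min = 4L,
                              seed = 1L) {
  rates <- c(snp_rate, indel_rate, het_fraction, multiallelic_fraction,
             error_sub, error_ins, error_del)
  stopifnot(all(rates >= 0 & rates <= 1), coverage > 0, region_length > 0)
  structure(as.list(environment())[setdiff(ls(), "rates")],
            class = "simulation_config")
}

# random base codes different from `ref_code`
other_base <- function(ref_code, n = 1L) {
  (ref_code - 1L + sample(1:3, n, replace = TRUE)) %% 4L + 1L
}

#' Simulate a diploid genome with truth variants
#'
#' @param config a [simulation_config()].
#' @return object of class `sim_truth`: reference codes/sequence, the two
#'   haplotypes with their alignment to the reference, and the truth call
#'   table (phased genotypes).
#' @export
simulate_diploid <- function(config) {
  set.seed(config$seed)
  L <- config$region_length
  ref <- sample.int(4L, L, replace = TRUE)

  margin <- config$indel_max_len + 10L
  p_any <- config$snp_rate + config$indel_rate
  anchors <- which(stats::runif(L) < p_any)
  anchors <- anchors[anchors > margin & anchors < L - margin]
  keep <- c()
  last <- -Inf
  for (a in anchors) {
    if (a - last >= config$min_variant_spacing) { keep <- c(keep, a); last <- a }
  }
  anchors <- keep
  is_snp <- stats::runif(length(anchors)) <
    config$snp_rate / max(p_any, 1e-12)

  chrom <- config$chrom
  vc <- list()
  edits <- list(`1` = list(), `2` = list())
  for (i in seq_along(anchors)) {
    pos <- anchors[i]                       # 1-based anchor
    het <- stats::runif(1) < config$het_fraction
    multi <- het && stats::runif(1) < config$multiallelic_fraction
    if (is_snp[i]) {
      if (multi) {
        alts <- BASES[sample(setdiff(1:4, ref[pos]), 2L)]
        gt <- "1|2"
        edits[["1"]][[length(edits[["1"]]) + 1L]] <-
          list(type = "sub", pos = pos, base = alts[1])
        edits[["2"]][[length(edits[["2"]]) + 1L]] <-
          list(type = "sub", pos = pos, base = alts[2])
        rec <- data.frame(chrom = chrom, pos = pos,
                          ref = BASES[ref[pos]],
                          alt = paste(alts, collapse = ","),
                          genotype = gt)
      } else {
        alt <- BASES[other_base(ref[pos])]
        hap <- if (het) sample(1:2, 1L) else NA
        gt <- if (!het) "1|1" else if (hap == 1L) "1|0" else "0|1"
        for (h in 1:2) {
          if (het && h != hap) next
          edits[[as.character(h)]][[length(edits[[as.character(h)]]) + 1L]] <-
            list(type = "sub", pos = pos, base = alt)
        }
        rec <- data.frame(chrom = chrom, pos = pos, ref = BASES[ref[pos]],
                          alt = alt, genotype = gt)
      }
    } else {
      is_ins <- stats::runif(1) < 0.5
      rlen <- function() min(1L + stats::rgeom(1L, config$indel_geom_p),
                             config$indel_max_len)
      mk <- function(len) {
        if (is_ins) {
          seq <- codes_to_seq(sample.int(4L, len, replace = TRUE))
          list(edit = list(type = "ins", pos = pos, seq = seq),
               ref = BASES[ref[pos]],
               alt = paste0(BASES[ref[pos]], seq))
        } else {
          list(edit = list(type = "del", pos = pos, len = len),
               ref = codes_to_seq(ref[pos:(pos + len)]),
               alt = BASES[ref[pos]])
        }
      }
      if (multi) {
        l1 <- rlen(); l2 <- rlen()
        while (l2 == l1) l2 <- rlen()
        m1 <- mk(l1); m2 <- mk(l2)
        edits[["1"]][[length(edits[["1"]]) + 1L]] <- m1$edit
        edits[["2"]][[length(edits[["2"]]) + 1L]] <- m2$edit
        # unify to a shared REF (the longer one for deletions)
        if (nchar(m1$ref) >= nchar(m2$ref)) { lo <- m1; sh <- m2 }
        else { lo <- m2; sh <- m1 }
        sfx <- substr(lo$ref, nchar(sh$ref) + 1L, nchar(lo$ref))
        alt_of <- function(m) if (identical(m, lo)) m$alt
                              else paste0(m$alt, sfx)
        rec <- data.frame(chrom = chrom, pos = pos, ref = lo$ref,
                          alt = paste(alt_of(m1), alt_of(m2), sep = ","),
                          genotype = "1|2")
      } else {
        m <- mk(rlen())
        hap <- if (het) sample(1:2, 1L) else NA
        gt <- if (!het) "1|1" else if (hap == 1L) "1|0" else "0|1"
        for (h in 1:2) {
          if (het && h != hap) next
          edits[[as.character(h)]][[length(edits[[as.character(h)]]) + 1L]] <-
            m$edit
        }
        rec <- data.frame(chrom = chrom, pos = pos, ref = m$ref, alt = m$alt,
                          genotype = gt)
      }
    }
    vc[[length(vc) + 1L]] <- rec
  }
  truth <- if (length(vc) > 0) do.call(rbind, vc)
           else data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           genotype = character())
  truth <- variant_calls(truth$chrom, truth$pos, truth$ref, truth$alt,
                         truth$genotype, rep(0, nrow(truth)))

  haps <- lapply(1:2, function(h) apply_edits(ref, edits[[as.character(h)]]))
  structure(list(config = config, chrom = chrom, ref = ref,
                 ref_seq = codes_to_seq(ref), hap = haps, truth = truth),
            class = "sim_truth")
}

# apply sorted non-overlapping edits to the reference; returns the
# haplotype codes plus per-column alignment to the reference
apply_edits <- function(ref, edits) {
  L <- length(ref)
  if (length(edits) > 0) {
    ord <- order(vapply(edits, `[[`, numeric(1), "pos"))
    edits <- edits[ord]
  }
  hap <- integer(0); col_ref <- integer(0)
  cur <- 1L
  for (e in edits) {
    if (e$pos >= cur) {
      span <- cur:e$pos
      hap <- c(hap, ref[span]); col_ref <- c(col_ref, span)
      cur <- e$pos + 1L
    }
    if (e$type == "sub") {
      hap[length(hap)] <- base_to_code(e$base)
    } else if (e$type == "ins") {
      ic <- seq_to_codes(e$seq)
      hap <- c(hap, ic); col_ref <- c(col_ref, rep(NA_integer_, length(ic)))
    } else if (e$type == "del") {
      cur <- cur + e$len                   # skip deleted reference bases
    }
  }
  if (cur <= L) { hap <- c(hap, ref[cur:L]); col_ref <- c(col_ref, cur:L) }
  list(codes = hap, col_ref = col_ref, seq = codes_to_seq(hap))
}

# simulate one read: slice the haplotype alignment and inject errors
sim_one_read <- function(truth, hap_idx, a, b, config, read_id) {
  hp <- truth$hap[[hap_idx]]
  sel <- a:b                               # 1-based haplotype coords
  rbase <- hp$codes[sel]
  rpos <- hp$col_ref[sel]
  # deletion columns (reference bases absent from the haplotype) inside span
  covered_ref <- rpos[!is.na(rpos)]
  if (length(covered_ref) >= 2) {
    lo <- min(covered_ref); hi <- max(covered_ref)
    missing <- setdiff(lo:hi, covered_ref)
    if (length(missing) > 0) {
      rbase <- c(rbase, rep(NA_integer_, length(missing)))
      rpos <- c(rpos, missing)
      ord <- order_columns(rpos, rbase)
      rbase <- rbase[ord]; rpos <- rpos[ord]
    }
  }
  n <- length(rbase)
  readp <- !is.na(rbase)

  # substitution errors
  subs <- readp & stats::runif(n) < config$error_sub
  if (any(subs)) rbase[subs] <- other_base(rbase[subs], sum(subs))

  # insertion errors: one extra base after a read base
  insp <- which(readp & stats::runif(n) < config$error_ins)
  if (length(insp) > 0) {
    rbase <- append_at(rbase, insp, sample.int(4L, length(insp), TRUE))
    rpos <- append_at(rpos, insp, rep(NA_integer_, length(insp)))
    n <- length(rbase)
    readp <- !is.na(rbase)
  }

  # deletion errors, enriched in homopolymer context
  delr <- rep(config$error_del, n)
  hpmask <- homopolymer_mask(rbase, config$homopolymer_min)
  delr[hpmask] <- pmin(delr[hpmask] * config$homopolymer_mult, 0.9)
  dels <- readp & stats::runif(n) < delr
  if (any(dels)) {
    drop_col <- dels & is.na(rpos)         # deleted inserted base: drop
    rbase[dels] <- NA_integer_
    keepc <- !(drop_col)
    rbase <- rbase[keepc]; rpos <- rpos[keepc]
  }

  # trim: a read must start and end on an aligned base
  readp <- !is.na(rbase)
  if (!any(readp & !is.na(rpos))) return(NULL)
  first <- min(which(readp)); last <- max(which(readp))
  rbase <- rbase[first:last]; rpos <- rpos[first:last]

  cls <- ifelse(!is.na(rbase) & !is.na(rpos), "M",
                ifelse(!is.na(rbase), "I", "D"))
  if (!any(cls == "M")) return(NULL)
  # leading/trailing I and D columns carry no anchored evidence
  a0 <- min(which(cls == "M")); b0 <- max(which(cls == "M"))
  cls <- cls[a0:b0]; rbase <- rbase[a0:b0]; rpos <- rpos[a0:b0]
  r <- rle(cls)
  cigar <- paste0(r$lengths, r$values, collapse = "")
  aligned_read(read_id, truth$chrom,
               ref_start = min(rpos, na.rm = TRUE) - 1L,
               sequence = codes_to_seq(rbase[!is.na(rbase)]),
               cigar = cigar, mapq = 60L, haplotype = hap_idx)
}

# stable column order: by reference coordinate, insertion columns attached
# after the last preceding reference column
order_columns <- function(rpos, rbase) {
  key <- numeric(length(rpos))
  lastref <- 0
  nins <- 0
  for (i in seq_along(rpos)) {
    if (!is.na(rpos[i])) { lastref <- rpos[i]; nins <- 0; key[i] <- rpos[i] }
    else { nins <- nins + 1; key[i] <- lastref + nins * 1e-6 }
  }
  order(key)
}

append_at <- function(x, after_idx, values) {
  key <- c(seq_along(x), after_idx + 0.5)
  c(x, values)[order(key)]
}

homopolymer_mask <- function(codes, min_len) {
  x <- ifelse(is.na(codes), -seq_along(codes), codes)  # NAs break runs
  r <- rle(x)
  rep(r$lengths >= min_len & r$values > 0, r$lengths)
}

#' Simulate reads from a diploid truth
#'
#' Samples reads per haplotype at half the configured coverage each, with
#' alignments exact by construction, injects substitution/insertion/
#' deletion errors, and writes an indexed reference FASTA, a sorted and
#' indexed BAM and the truth VCF into `dir`.
#'
#' @param truth a [simulate_diploid()] result.
#' @param config the same [simulation_config()].
#' @param dir output directory (created).
#' @param test_mode if `TRUE`, reads carry their true haplotype in the HP
#'   tag; otherwise the tag is withheld (read ids always encode the origin
#'   haplotype for truth-based evaluation).
#' @param realign if `TRUE`, reads are additionally written to FASTQ and
#'   realigned with minimap2 instead of using the constructed alignments.
#' @return list with `reads` (in-memory [aligned_read()] list), `bam`,
#'   `fasta`, `vcf` paths and `coverage` (realised mean depth).
#' @export
simulate_reads <- function(truth, config, dir = tempfile("sim"),
                           test_mode = FALSE, realign = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 7L)
  reads <- list()
  for (h in 1:2) {
    hapL <- length(truth$hap[[h]]$codes)
    target <- config$coverage / 2 * hapL
    covered <- 0
    i <- 0L
    while (covered < target) {
      i <- i + 1L
      len <- max(config$read_length_min,
                 round(stats::rnorm(1, config$read_length_mean,
                                    config$read_length_sd)))
      s <- sample.int(hapL + len - 1L, 1L) - len + 1L   # allow edge overlap
      a <- max(1L, s); b <- min(hapL, s + len - 1L)
      if (b - a + 1L < config$read_length_min / 2) next
      rd <- sim_one_read(truth, h, a, b, config,
                         sprintf("sim_h%d_%05d", h, i))
      if (is.null(rd)) next
      if (!test_mode) rd$haplotype <- NA_integer_
      covered <- covered + (b - a + 1L)
      reads[[length(reads) + 1L]] <- rd
    }
  }
  reads <- reads[order(vapply(reads, `[[`, integer(1), "ref_start"))]

  fasta <- file.path(dir, "ref.fa")
  write_fasta(stats::setNames(truth$ref_seq, truth$chrom), fasta)
  vcf <- file.path(dir, "truth.vcf")
  write_vcf(sort_calls(truth$truth), "truth", vcf, phased = TRUE,
            contigs = stats::setNames(length(truth$ref), truth$chrom))
  bam <- if (realign) realign_reads(reads, fasta, dir)
         else write_read_bam(reads, truth, dir, with_hp = test_mode)
  cov <- sum(vapply(reads, function(r) r$ref_end - r$ref_start,
                    integer(1))) / length(truth$ref)
  list(reads = reads, bam = bam, fasta = fasta, vcf = vcf, coverage = cov)
}

write_read_bam <- function(reads, truth, dir, with_hp = FALSE) {
  sam <- file.path(dir, "reads.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", truth$chrom, length(truth$ref)))
  recs <- vapply(reads, function(r) {
    base <- sprintf("%s\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                    r$read_id, r$chrom, r$ref_start + 1L, r$mapq, r$cigar,
                    r$sequence)
    if (with_hp && !is.na(r$haplotype))
      base <- paste0(base, sprintf("\tHP:i:%d", r$haplotype))
    base
  }, character(1))
  writeLines(c(hdr, recs), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "reads"), overwrite = TRUE)
  unlink(sam)
  bam
}

realign_reads <- function(reads, fasta, dir) {
  exe <- Sys.which("minimap2")
  if (!nzchar(exe)) stopf("minimap2 not found on PATH for realign mode")
  fq <- file.path(dir, "reads.fq")
  writeLines(unlist(lapply(reads, function(r)
    c(paste0("@", r$read_id), r$sequence, "+",
      strrep("I", nchar(r$sequence))))), fq)
  sam <- file.path(dir, "realigned.sam")
  status <- system2(exe, c("-a", "-x", "map-ont", fasta, fq), stdout = sam,
                    stderr = FALSE)
  if (status != 0) stopf("minimap2 exited with status %d", status)
  bam <- Rsamtools::asBam(sam, file.path(dir, "realigned"), overwrite = TRUE)
  unlink(c(fq, sam))
  bam
}

#' Build labelled training examples from simulated data
#'
#' SNP candidates get per-base presence labels and a zygosity label from
#' the truth set (candidates absent from the truth become homozygous-
#' reference negatives, downsampled to `neg_ratio` times the positives);
#' indel candidates get one of the four zygosity classes. Feature tensors
#' are built exactly as in calling, with truth heterozygous SNPs as the
#' likely-heterozygous site set.
#'
#' @param truth a [simulate_diploid()] result.
#' @param reads reads with true haplotypes set (from
#'   [simulate_reads()] with `test_mode = TRUE`).
#' @param snp_candidates,indel_candidates candidate tables from
#'   [select_snp_candidates()] / [select_indel_candidates()]; either may be
#'   `NULL` to skip that set.
#' @param profile a [platform_profile()].
#' @param neg_ratio negatives kept per positive (SNP set).
#' @param window_length indel MSA window length.
#' @param msa_backend MSA backend for indel tensors.
#' @param seed seed for negative downsampling.
#' @return list with `snp` (features, base_labels, zygosity, pos) and
#'   `indel` (features, class, pos).
#' @export
make_training_examples <- function(truth, reads, snp_candidates = NULL,
                                   indel_candidates = NULL,
                                   profile = platform_profile("ONT"),
                                   neg_ratio = 2, window_length = 160L,
                                   msa_backend = "internal", seed = 1L) {
  out <- list(snp = NULL, indel = NULL)
  tv <- truth$truth

  if (!is.null(snp_candidates) && nrow(snp_candidates) > 0) {
    het <- select_het_sites(NULL, mode = "training", truth = tv)
    snp_truth <- tv[nchar(tv$ref) == 1 &
                      !grepl("[A-Z]{2}", tv$alt), , drop = FALSE]
    truth_at <- match(snp_candidates$pos, snp_truth$pos - 1L)
    is_pos <- !is.na(truth_at)
    set.seed(seed)
    neg_idx <- which(!is_pos)
    keep_neg <- sort(sample(neg_idx,
                            min(length(neg_idx),
                                ceiling(neg_ratio * sum(is_pos)))))
    use <- sort(c(which(is_pos), keep_neg))
    feats <- list(); labs <- list(); zygs <- integer(0); poss <- integer(0)
    for (i in use) {
      b <- snp_candidates$pos[i]
      nbr <- choose_neighbor_sites(b, snp_candidates$ref_base[i], het, reads,
                                   strategy = profile$neighbor_strategy,
                                   distance_limit = profile$distance_limit)
      if (!min_neighbor_gate(nbr)) next
      tns <- tryCatch(build_snp_feature_tensor(nbr, reads),
                      error = function(e) NULL)
      if (is.null(tns)) next
      lab <- numeric(4); names(lab) <- TENSOR_BASES
      ti <- truth_at[i]
      if (!is.na(ti)) {
        alts <- strsplit(snp_truth$alt[ti], ",", fixed = TRUE)[[1]]
        gidx <- as.integer(strsplit(snp_truth$genotype[ti], "[/|]")[[1]])
        alleles <- unique(c(snp_truth$ref[ti], alts)[gidx + 1L])
        lab[alleles] <- 1
        zyg <- if (length(alleles) == 2) 2L else 1L
      } else {
        lab[snp_candidates$ref_base[i]] <- 1
        zyg <- 1L
      }
      feats[[length(feats) + 1L]] <- as.vector(tns)
      labs[[length(labs) + 1L]] <- lab
      zygs <- c(zygs, zyg); poss <- c(poss, b)
    }
    if (length(feats) > 0)
      out$snp <- list(features = do.call(cbind, feats),
                      base_labels = do.call(cbind, labs),
                      zygosity = zygs, pos = poss)
  }

  if (!is.null(indel_candidates) && nrow(indel_candidates) > 0) {
    indel_truth <- tv[nchar(tv$ref) > 1 |
                        grepl("[A-Z]{2}", tv$alt), , drop = FALSE]
    cand <- cluster_candidates(indel_candidates)
    # the candidate gates rarely fire at non-indel sites on clean data, so
    # homozygous-reference training windows are drawn away from any variant
    n_homref <- ceiling(0.4 * nrow(cand))
    L <- nchar(truth$ref_seq)
    set.seed(seed + 1L)
    pool <- sample.int(L - 2L * window_length, min(20L * n_homref,
                                                   L - 2L * window_length)) +
      window_length
    far <- vapply(pool, function(p)
      all(abs(p - tv$pos) > window_length), logical(1))
    homref_pos <- utils::head(pool[far], n_homref)
    cand <- rbind(cand[, c("chrom", "pos")],
                  data.frame(chrom = rep(truth$chrom, length(homref_pos)),
                             pos = as.integer(homref_pos)))
    feats <- list(); cls <- integer(0); poss <- integer(0)
    for (i in seq_len(nrow(cand))) {
      b <- cand$pos[i]
      hit <- which(indel_truth$pos - 1L >= b &
                     indel_truth$pos - 1L < b + 10L)
      klass <- if (length(hit) == 0) 1L else {
        gt <- gsub("|", "/", indel_truth$genotype[hit[1]], fixed = TRUE)
        switch(gt, "1/1" = 2L, "0/1" = 3L, "1/0" = 3L, "1/2" = 4L, 1L)
      }
      tns <- indel_candidate_tensor(reads, b, truth$ref_seq, window_length,
                                    msa_backend)
      if (is.null(tns)) next
      feats[[length(feats) + 1L]] <- as.vector(tns$tensor)
      cls <- c(cls, klass); poss <- c(poss, b)
    }
    if (length(feats) > 0)
      out$indel <- list(features = do.call(cbind, feats), class = cls,
                        pos = poss)
  }
  out
}

# collapse runs of consecutive candidate positions to the run start
cluster_candidates <- function(cand) {
  if (nrow(cand) == 0) return(cand)
  cand <- cand[order(cand$pos), , drop = FALSE]
  run_start <- c(TRUE, diff(cand$pos) > 1L)
  cand[run_start, , drop = FALSE]
}

# the three MSA pileups and the stacked tensor for one indel candidate
indel_candidate_tensor <- function(reads, b, ref_seq, window_length = 160L,
                                   msa_backend = "internal") {
  ref_window <- substr(ref_seq, b + 1L, b + window_length)
  if (nchar(ref_window) < window_length) return(NULL)
  span <- vapply(reads, function(r) b >= r$ref_start && b < r$ref_end,
                 logical(1))
  s_all <- reads[span]
  if (length(s_all) == 0) return(NULL)
  hap <- vapply(s_all, `[[`, integer(1), "haplotype")
  ws <- extract_window_sequences(s_all, b, ref_window, window_length)
  if (length(ws$reads) == 0) return(NULL)
  hap <- hap[match(names(ws$reads),
                   vapply(s_all, `[[`, character(1), "read_id"))]
  idx_sets <- list(all = seq_along(ws$reads),
                   phase1 = which(!is.na(hap) & hap == 1L),
                   phase2 = which(!is.na(hap) & hap == 2L))
  pileups <- if (msa_backend == "internal") {
    # phase sets are subsets of the all-reads set: align once, assemble
    # each subset from the shared pairwise alignments
    pa <- pairwise_affine(ws$reads, ws$ref)
    rchars <- strsplit(ws$reads, "", fixed = TRUE)
    lapply(idx_sets, function(idx) {
      if (length(idx) == 0) return(NULL)
      pileup_from_aln(star_assemble(ws$ref,
                                    star_rows(pa, rchars, nchar(ws$ref),
                                              idx)))
    })
  } else {
    lapply(idx_sets, function(idx) {
      if (length(idx) == 0) return(NULL)
      msa_realign(c(ws$ref, ws$reads[idx]), backend = msa_backend)
    })
  }
  if (is.null(pileups$all)) return(NULL)
  list(tensor = build_indel_feature_tensor(pileups$all, pileups$phase1,
                                           pileups$phase2),
       pileups = pileups,
       candidate = list(chrom = reads[[1]]$chrom, pos = b,
                        ref_window = ref_window))
}
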