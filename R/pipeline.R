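# pipeline_cli: orchestration of the four run modes over BAM + FASTA
# inputs, mirroring the snps_unphased / snps / indels / both workflow.

#' Pipeline run configuration
#'
#' @param mode one of `"snps_unphased"`, `"snps"`, `"indels"`, `"both"`.
#' @param bam,ref input alignment (indexed BAM) and reference (indexed
#'   FASTA) paths.
#' @param out_dir output directory for VCFs.
#' @param snp_model,indel_model model objects or checkpoint paths.
#' @param platform `"ONT"`, `"CCS"` or `"CLR"` (sets neighbor strategy,
#'   het range, distance limit, indel window length).
#' @param bed optional BED path restricting calling.
#' @param sample_name VCF sample column.
#' @param min_depth,min_aaf SNP candidate gates.
#' @param min_neighbor_sites minimum likely-het neighbors per candidate.
#' @param train_coverage coverage of the model's training data (counts are
#'   rescaled by `train_coverage / test_coverage`); `NULL` disables
#'   rescaling.
#' @param min_phase_depth,ins_threshold,del_threshold indel candidate
#'   gates.
#' @param phase_combine `"max"` or `"min"` across phases for indel
#'   frequencies.
#' @param chunk_size SNP-calling chunk width in bp (chunks are padded by
#'   the neighbor distance limit so results are chunk-invariant).
#' @param min_mapq mapping-quality filter.
#' @param msa_backend `"internal"` or `"mafft"`.
#' @param phaser `"internal"` or an external phaser executable name.
#' @return named list of class `run_config`.
#' @export
run_config <- function(mode = c("both", "snps_unphased", "snps", "indels"),
                       bam, ref, out_dir,
                       snp_model = NULL, indel_model = NULL,
                       platform = "ONT", bed = NULL,
                       sample_name = "SAMPLE",
                       min_depth = 8L, min_aaf = 0.15,
                       min_neighbor_sites = 1L, train_coverage = NULL,
                       min_phase_depth = 8L, ins_threshold = 0.4,
                       del_threshold = 0.6,
                       phase_combine = "max",
                       chunk_size = 50000L, min_mapq = 0L,
                       msa_backend = "internal", phaser = "internal") {
  mode <- match.arg(mode)
  cfg <- as.list(environment())
  cfg$profile <- platform_profile(platform)
  class(cfg) <- "run_config"
  cfg
}

resolve_model <- function(m, loader) {
  if (is.character(m)) loader(m) else m
}

pipeline_regions <- function(config) {
  if (!file.exists(paste0(config$ref, ".fai"))) Rsamtools::indexFa(config$ref)
  info <- Rsamtools::seqinfo(Rsamtools::FaFile(config$ref))
  contigs <- data.frame(chrom = GenomeInfoDb::seqnames(info),
                        start = 0L,
                        end = unname(GenomeInfoDb::seqlengths(info)),
                        stringsAsFactors = FALSE)
  if (is.null(config$bed)) return(contigs)
  bed <- read_bed(config$bed)
  bed$end <- pmin(bed$end, contigs$end[match(bed$chrom, contigs$chrom)])
  bed
}

# SNP calling over one region, chunked with neighbor-limit padding
call_snps_region <- function(config, snp_model, chrom, rstart, rend,
                             contig_len) {
  pad <- config$profile$distance_limit
  calls <- list()
  for (cs in seq(rstart, rend - 1L, by = config$chunk_size)) {
    ce <- min(cs + config$chunk_size, rend)
    ps <- max(0L, cs - pad); pe <- min(contig_len, ce + pad)
    reads <- read_alignments(config$bam, chrom, ps, pe, config$min_mapq)
    if (length(reads) == 0) next
    ref_seq <- read_reference(config$ref, chrom, ps, pe)
    cand <- select_snp_candidates(reads, chrom, ps, pe, ref_seq,
                                  min_depth = config$min_depth,
                                  min_aaf = config$min_aaf)
    if (nrow(cand) == 0) next
    het <- select_het_sites(cand, lower = config$profile$het_lower,
                            upper = config$profile$het_upper)
    in_chunk <- which(cand$pos >= cs & cand$pos < ce)
    if (length(in_chunk) == 0) next
    test_cov <- sum(vapply(reads, function(r)
      max(0L, min(r$ref_end, ce) - max(r$ref_start, cs)),
      integer(1))) / (ce - cs)
    ratio_ok <- !is.null(config$train_coverage) && test_cov > 0
    tensors <- list(); meta <- list()
    for (i in in_chunk) {
      nbr <- choose_neighbor_sites(cand$pos[i], cand$ref_base[i], het, reads,
                                   strategy = config$profile$neighbor_strategy,
                                   distance_limit = pad)
      if (!min_neighbor_gate(nbr, config$min_neighbor_sites)) next
      tns <- tryCatch(build_snp_feature_tensor(nbr, reads),
                      error = function(e) NULL)
      if (is.null(tns)) next
      if (ratio_ok)
        tns <- rescale_counts(tns, config$train_coverage, test_cov)
      tensors[[length(tensors) + 1L]] <- tns
      meta[[length(meta) + 1L]] <- list(pos = cand$pos[i],
                                        ref = cand$ref_base[i])
    }
    if (length(tensors) == 0) next
    pred <- predict_snp_network(snp_model, tensors)
    for (j in seq_along(meta)) {
      g <- decide_genotype(pred$base_probs[j, ], meta[[j]]$ref)
      if (is.null(g)) next
      calls[[length(calls) + 1L]] <- variant_calls(
        chrom, meta[[j]]$pos + 1L, g$ref, paste(g$alt, collapse = ","),
        g$genotype, quality_score(pred$base_probs[j, ], g$alt))
    }
  }
  if (length(calls) == 0) return(variant_calls())
  sort_calls(do.call(rbind, calls))
}

call_indels_region <- function(config, indel_model, reads, chrom, rstart,
                               rend, contig_len) {
  wl <- config$profile$indel_window_length
  cand <- select_indel_candidates(reads, chrom, rstart, rend,
                                  min_phase_depth = config$min_phase_depth,
                                  ins_threshold = config$ins_threshold,
                                  del_threshold = config$del_threshold,
                                  phase_combine = config$phase_combine)
  cand <- cluster_candidates(cand)
  if (nrow(cand) == 0) return(variant_calls())
  ref_start <- max(0L, rstart - 1L)
  ref_end <- min(contig_len, rend + wl + 64L)
  ref_seq_off <- read_reference(config$ref, chrom, 0L, ref_end)
  calls <- list()
  for (i in seq_len(nrow(cand))) {
    b <- cand$pos[i]
    ct <- indel_candidate_tensor(reads, b, ref_seq_off, wl,
                                 config$msa_backend)
    if (is.null(ct)) next
    probs <- predict_indel_network(indel_model, list(ct$tensor))[1, ]
    vc <- call_indel(probs, ct$pileups, ct$candidate)
    if (!is.null(vc)) calls[[length(calls) + 1L]] <- vc
  }
  if (length(calls) == 0) return(variant_calls())
  out <- do.call(rbind, calls)
  # identical records from overlapping windows collapse to one
  key <- paste(out$chrom, out$pos, out$ref, out$alt, out$genotype)
  out <- out[!duplicated(key), , drop = FALSE]
  sort_calls(out)
}

#' Run the variant-calling pipeline
#'
#' `snps_unphased` predicts SNPs only; `snps` additionally phases the SNP
#' calls; `indels` calls indels from already-phased reads (HP tags in the
#' BAM); `both` runs SNP calling, phases calls and reads, then calls
#' indels and merges.
#'
#' @param config a [run_config()].
#' @return named list of output VCF paths (and the final merged call
#'   table as `$calls`).
#' @export
call_variants <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  mode <- config$mode
  needs_snp <- mode %in% c("snps_unphased", "snps", "both")
  needs_indel <- mode %in% c("indels", "both")
  snp_model <- if (needs_snp) {
    m <- resolve_model(config$snp_model, load_snp_model)
    if (is.null(m)) stopf("mode '%s' requires a SNP model", mode)
    m
  }
  indel_model <- if (needs_indel) {
    m <- resolve_model(config$indel_model, load_indel_model)
    if (is.null(m)) stopf("mode '%s' requires an indel model", mode)
    m
  }
  if (mode == "indels" && config$phaser == "internal") {
    # pre-flight: standalone indel mode needs phased reads in the input
    regions0 <- pipeline_regions(config)
    r0 <- read_alignments(config$bam, regions0$chrom[1], regions0$start[1],
                          regions0$end[1], config$min_mapq)
    if (length(r0) > 0 &&
        all(is.na(vapply(r0, `[[`, integer(1), "haplotype"))))
      stopf("indels mode requires phased reads (HP tags) in the BAM")
  }
  regions <- pipeline_regions(config)
  info <- Rsamtools::seqinfo(Rsamtools::FaFile(config$ref))
  clen <- stats::setNames(GenomeInfoDb::seqlengths(info),
                          GenomeInfoDb::seqnames(info))
  out <- list()

  snp_calls <- variant_calls()
  if (needs_snp) {
    per_region <- lapply(seq_len(nrow(regions)), function(i)
      call_snps_region(config, snp_model, regions$chrom[i],
                       regions$start[i], regions$end[i],
                       clen[[regions$chrom[i]]]))
    snp_calls <- sort_calls(do.call(rbind, c(list(variant_calls()),
                                             per_region)))
    out$snp_vcf <- file.path(config$out_dir, "snps.vcf")
    write_vcf(snp_calls, config$sample_name, out$snp_vcf, contigs = clen)
  }

  blocks_by_chrom <- list()
  phased_calls <- snp_calls
  if (mode %in% c("snps", "both")) {
    if (config$phaser != "internal") {
      out$phased_vcf <- file.path(config$out_dir, "snps.phased.vcf")
      phase_with_external(out$snp_vcf, config$bam, config$ref,
                          out$phased_vcf, phaser = config$phaser)
      phased_calls <- read_vcf(out$phased_vcf)
      if (mode == "both") {
        # read haplotype assignment always uses the built-in linkage
        # blocks; the external phaser only rewrites the VCF genotypes
        for (ch in unique(regions$chrom)) {
          het <- snp_calls[snp_calls$chrom == ch &
                             snp_calls$genotype %in% c("0/1", "1/2"), ,
                           drop = FALSE]
          reads <- read_alignments(config$bam, ch, 0L, clen[[ch]],
                                   config$min_mapq)
          blocks_by_chrom[[ch]] <- phase_internal(het, reads)
        }
      }
    } else {
      for (ch in unique(regions$chrom)) {
        het <- snp_calls[snp_calls$chrom == ch &
                           snp_calls$genotype %in% c("0/1", "1/2"), ,
                         drop = FALSE]
        reads <- read_alignments(config$bam, ch, 0L, clen[[ch]],
                                 config$min_mapq)
        blocks_by_chrom[[ch]] <- phase_internal(het, reads)
        phased_calls[phased_calls$chrom == ch, ] <-
          apply_phasing(phased_calls[phased_calls$chrom == ch, ,
                                     drop = FALSE],
                        blocks_by_chrom[[ch]])
      }
      out$phased_vcf <- file.path(config$out_dir, "snps.phased.vcf")
      write_vcf(phased_calls, config$sample_name, out$phased_vcf,
                phased = TRUE, contigs = clen)
    }
  }

  indel_calls <- variant_calls()
  if (needs_indel) {
    per_region <- lapply(seq_len(nrow(regions)), function(i) {
      ch <- regions$chrom[i]
      reads <- read_alignments(config$bam, ch, 0L, clen[[ch]],
                               config$min_mapq)
      if (mode == "both")
        reads <- assign_read_phases(reads, blocks_by_chrom[[ch]] %||% list())
      call_indels_region(config, indel_model, reads, ch,
                         regions$start[i], regions$end[i], clen[[ch]])
    })
    indel_calls <- sort_calls(do.call(rbind, c(list(variant_calls()),
                                               per_region)))
    out$indel_vcf <- file.path(config$out_dir, "indels.vcf")
    write_vcf(indel_calls, config$sample_name, out$indel_vcf,
              contigs = clen)
  }

  final <- sort_calls(rbind(phased_calls, indel_calls))
  key <- paste(final$chrom, final$pos, final$ref, final$alt)
  final <- final[!duplicated(key), , drop = FALSE]
  out$final_vcf <- file.path(config$out_dir, "final.vcf")
  write_vcf(final, config$sample_name, out$final_vcf, contigs = clen)
  out$calls <- final
  out
}
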