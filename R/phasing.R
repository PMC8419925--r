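# phasing: assign heterozygous SNP alleles and reads to haplotypes.
#
# The production contract is an external read-based phaser invoked as a
# subprocess; a greedy read-linkage phaser is built in so that the full
# pipeline (and its tests) run without any external binary.

#' Phase heterozygous SNP calls from read linkage
#'
#' Greedy read-backed phasing: heterozygous sites joined by shared reads
#' form a block; within a block each site's allele orientation is chosen to
#' maximise agreement with the reads covering it and previously phased
#' sites. Output is correct up to a global haplotype swap per block.
#'
#' @param het_calls a [variant_calls()] table of heterozygous SNP calls
#'   (genotype `0/1`; multiallelic `1/2` sites are phased on their two alt
#'   alleles).
#' @param reads list of [aligned_read()].
#' @return list of `phased_block` objects: `block_id`, `pos` (0-based
#'   positions), `hap1`/`hap2` allele bases per site.
#' @export
phase_internal <- function(het_calls, reads) {
  if (nrow(het_calls) == 0) return(list())
  het_calls <- sort_calls(het_calls)
  pos0 <- het_calls$pos - 1L
  # two alleles per site: ref/alt for 0/1, alt1/alt2 for 1/2
  alle <- lapply(seq_len(nrow(het_calls)), function(i) {
    alts <- strsplit(het_calls$alt[i], ",", fixed = TRUE)[[1]]
    if (length(alts) >= 2) c(alts[1], alts[2]) else c(het_calls$ref[i], alts[1])
  })
  n <- length(pos0)
  bm <- read_base_matrix(reads, pos0)        # reads x sites, base codes

  # per site, per read: +1 first allele, -1 second, 0 otherwise
  obs <- matrix(0L, nrow = nrow(bm), ncol = n)
  for (j in seq_len(n)) {
    a <- base_to_code(alle[[j]])
    obs[bm[, j] == a[1], j] <- 1L
    obs[bm[, j] == a[2], j] <- -1L
  }

  # orientation o[j] in {+1,-1}: +1 keeps allele order (first allele -> hap1)
  orient <- integer(n)
  block <- integer(n)
  cur_block <- 0L
  for (j in seq_len(n)) {
    prev <- which(block == cur_block & orient != 0L)
    score <- 0L
    if (j > 1 && cur_block > 0L) {
      for (k in prev) {
        shared <- obs[, j] != 0L & obs[, k] != 0L
        if (any(shared))
          score <- score + sum(obs[shared, j] * obs[shared, k] * orient[k])
      }
    }
    linked <- j > 1 && cur_block > 0L &&
      any(vapply(prev, function(k) any(obs[, j] != 0L & obs[, k] != 0L),
                 logical(1)))
    if (!linked) {
      cur_block <- cur_block + 1L
      orient[j] <- 1L
    } else {
      orient[j] <- if (score >= 0L) 1L else -1L
    }
    block[j] <- cur_block
  }

  lapply(unique(block), function(bid) {
    sel <- which(block == bid)
    structure(list(
      block_id = bid,
      pos = pos0[sel],
      hap1 = vapply(seq_along(sel), function(i) {
        a <- alle[[sel[i]]]
        if (orient[sel[i]] > 0) a[1] else a[2]
      }, character(1)),
      hap2 = vapply(seq_along(sel), function(i) {
        a <- alle[[sel[i]]]
        if (orient[sel[i]] > 0) a[2] else a[1]
      }, character(1))
    ), class = "phased_block")
  })
}

#' Apply phasing to a call table
#'
#' Rewrites heterozygous genotypes with `|` separators according to the
#' phased blocks; hom calls become `1|1`; calls outside any block keep
#' their unphased genotype.
#'
#' @param calls a [variant_calls()] table.
#' @param blocks output of [phase_internal()].
#' @return the call table with phased genotype strings.
#' @export
apply_phasing <- function(calls, blocks) {
  pos_map <- list()
  for (b in blocks) {
    for (i in seq_along(b$pos)) {
      pos_map[[as.character(b$pos[i])]] <- c(b$hap1[i], b$hap2[i])
    }
  }
  for (i in seq_len(nrow(calls))) {
    gt <- calls$genotype[i]
    if (gt == "1/1") { calls$genotype[i] <- "1|1"; next }
    hp <- pos_map[[as.character(calls$pos[i] - 1L)]]
    if (is.null(hp)) next
    alts <- strsplit(calls$alt[i], ",", fixed = TRUE)[[1]]
    code <- function(allele) {
      if (allele == calls$ref[i]) "0" else as.character(match(allele, alts))
    }
    calls$genotype[i] <- paste0(code(hp[1]), "|", code(hp[2]))
  }
  calls
}

#' Assign reads to haplotypes from phased blocks
#'
#' Each read votes with the phased alleles it carries and is tagged with
#' the majority haplotype; ties or reads with no informative site stay
#' unassigned. Reads spanning several blocks are tagged by the block
#' contributing more informative sites.
#'
#' @param reads list of [aligned_read()].
#' @param blocks output of [phase_internal()].
#' @return the reads, with `$haplotype` set to 1, 2 or `NA`.
#' @export
assign_read_phases <- function(reads, blocks) {
  if (length(blocks) == 0) return(reads)
  all_pos <- unlist(lapply(blocks, `[[`, "pos"))
  blk_of <- rep(seq_along(blocks), vapply(blocks, function(b) length(b$pos),
                                          integer(1)))
  hap1_code <- base_to_code(unlist(lapply(blocks, `[[`, "hap1")))
  hap2_code <- base_to_code(unlist(lapply(blocks, `[[`, "hap2")))
  bm <- read_base_matrix(reads, all_pos)
  for (i in seq_along(reads)) {
    codes <- bm[i, ]
    informative <- codes != 0L & (codes == hap1_code | codes == hap2_code)
    if (!any(informative)) { reads[[i]]$haplotype <- NA_integer_; next }
    # restrict to the block with the most informative sites
    tab <- table(blk_of[informative])
    best_blk <- as.integer(names(tab)[which.max(tab)])
    sel <- informative & blk_of == best_blk
    v1 <- sum(codes[sel] == hap1_code[sel])
    v2 <- sum(codes[sel] == hap2_code[sel])
    reads[[i]]$haplotype <-
      if (v1 > v2) 1L else if (v2 > v1) 2L else NA_integer_
  }
  reads
}

#' Phase a VCF with an external read-based phaser
#'
#' Subprocess contract around a WhatsHap-style phaser. By default the
#' genotype-altering options (`--distrust-genotypes`,
#' `--include-homozygous`) are disabled so phasing never changes a
#' genotype; `distrust_genotypes = TRUE` enables them.
#'
#' @param vcf_path unphased VCF.
#' @param bam_path indexed alignment file.
#' @param ref_path indexed reference FASTA.
#' @param out_path output phased VCF.
#' @param distrust_genotypes allow the phaser to flip genotypes.
#' @param phaser executable name (default `"whatshap"`).
#' @return `out_path` invisibly.
#' @export
phase_with_external <- function(vcf_path, bam_path, ref_path, out_path,
                                distrust_genotypes = FALSE,
                                phaser = "whatshap") {
  exe <- Sys.which(phaser)
  if (!nzchar(exe))
    stopf(paste0("external phaser '%s' not found on PATH; install it or ",
                 "use the built-in phaser (phase_internal)"), phaser)
  args <- c("phase", "-o", out_path, "--reference", ref_path)
  if (distrust_genotypes)
    args <- c(args, "--distrust-genotypes", "--include-homozygous")
  args <- c(args, vcf_path, bam_path)
  log <- suppressWarnings(system2(exe, args, stdout = TRUE, stderr = TRUE))
  status <- attr(log, "status") %||% 0L
  if (status != 0)
    stopf("phaser exited with status %d:\n%s", status,
          paste(log, collapse = "\n"))
  invisible(out_path)
}
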