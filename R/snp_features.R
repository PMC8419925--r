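# snp_features: SNP candidate selection and the long-range haplotype
# feature tensor.
#
# For a candidate site b, reads covering b are split into four groups by the
# base they carry at b. For each of up to 41 likely-heterozygous sites t
# (20 per flank plus b at the center), the tensor stores per-group,
# per-base signed read counts: negative where the counted base equals the
# reference base at t. A fifth channel marks the reference base at b, and a
# fifth row one-hot encodes the reference base of every site in the window.

#' Alternative allele frequency of a pileup column
#'
#' Fraction of reads supporting the most frequent non-reference base.
#' Deletion-marker entries count toward the depth denominator but not as
#' alternative bases.
#'
#' @param column a [pileup()] column.
#' @return fraction in `[0, 1]`.
#' @export
alt_allele_frequency <- function(column) {
  if (column$depth == 0) stopf("alt_allele_frequency undefined at depth 0")
  bases <- column$per_read_base
  alt <- setdiff(BASES, column$ref_base)
  max(vapply(alt, function(b) sum(bases == b), numeric(1))) / column$depth
}

# per-position base counts (4 x L) and depth (L) over 0-based [start, end)
region_pileup_counts <- function(reads, start, end) {
  L <- end - start
  counts <- matrix(0L, nrow = 4, ncol = L)
  depth <- integer(L)
  for (r in reads) {
    lo <- max(r$ref_start, start); hi <- min(r$ref_end, end)
    if (lo >= hi) next
    codes <- r$ref_codes[(lo - r$ref_start + 1L):(hi - r$ref_start)]
    cols <- (lo - start + 1L):(hi - start)
    depth[cols] <- depth[cols] + 1L
    sel <- codes >= 1L & codes <= 4L
    if (any(sel)) {
      ij <- cbind(codes[sel], cols[sel])
      counts[ij] <- counts[ij] + 1L
    }
  }
  list(counts = counts, depth = depth)
}

#' Select SNP candidate sites in a region
#'
#' A position is a candidate when its total read depth and its alternative
#' allele frequency both reach the thresholds (inclusive at the bound).
#'
#' @param reads list of [aligned_read()].
#' @param chrom contig name.
#' @param start,end 0-based half-open region.
#' @param ref_seq reference sequence of the region (length `end - start`).
#' @param min_depth minimum depth (default 8).
#' @param min_aaf minimum alternative allele frequency (default 0.15).
#' @return data.frame with `chrom`, `pos` (0-based), `ref_base`, `depth`,
#'   `aaf`, `top_alt`, sorted by position.
#' @export
select_snp_candidates <- function(reads, chrom, start, end, ref_seq,
                                  min_depth = 8L, min_aaf = 0.15) {
  rp <- region_pileup_counts(reads, start, end)
  ref_codes <- base_to_code(strsplit(toupper(ref_seq), "", fixed = TRUE)[[1]])
  stopifnot(length(ref_codes) == end - start)
  counts <- rp$counts
  # zero out the reference base row per column, then take the max alt count
  idx <- which(ref_codes >= 1L & ref_codes <= 4L)
  cm <- counts
  cm[cbind(ref_codes[idx], idx)] <- 0L
  alt_count <- apply(cm, 2, max)
  aaf <- ifelse(rp$depth > 0, alt_count / rp$depth, 0)
  keep <- which(rp$depth >= min_depth & aaf >= min_aaf & alt_count > 0)
  top_alt <- BASES[apply(cm[, keep, drop = FALSE], 2, which.max)]
  out <- data.frame(chrom = rep(chrom, length(keep)),
                    pos = start + keep - 1L,
                    ref_base = BASES[ref_codes[keep]],
                    depth = rp$depth[keep], aaf = aaf[keep],
                    top_alt = top_alt, stringsAsFactors = FALSE)
  out[order(out$pos), , drop = FALSE]
}

#' Select likely heterozygous SNP sites
#'
#' In calling mode, filters candidates to those with alternative allele
#' frequency inside `[lower, upper]` (heterozygous sites are expected near
#' 50%). In training mode, returns the truth heterozygous SNP positions
#' instead, so that features are built from known-correct haplotype anchors.
#'
#' @param candidates output of [select_snp_candidates()].
#' @param lower,upper inclusive frequency bounds (defaults 0.4, 0.6).
#' @param mode `"calling"` or `"training"`.
#' @param truth for training mode, a [variant_calls()] truth table.
#' @return data.frame with `pos` (0-based) and `ref_base`, ordered.
#' @export
select_het_sites <- function(candidates, lower = 0.4, upper = 0.6,
                             mode = c("calling", "training"), truth = NULL) {
  mode <- match.arg(mode)
  stopifnot(lower < upper)
  if (mode == "calling") {
    keep <- candidates$aaf >= lower & candidates$aaf <= upper
    out <- data.frame(pos = candidates$pos[keep],
                      ref_base = candidates$ref_base[keep],
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(truth)) stopf("training mode requires a truth call set")
    keep <- vapply(seq_len(nrow(truth)), function(i) {
      alts <- strsplit(truth$alt[i], ",", fixed = TRUE)[[1]]
      if (nchar(truth$ref[i]) != 1 || any(nchar(alts) != 1)) return(FALSE)
      gidx <- as.integer(strsplit(truth$genotype[i], "[/|]")[[1]])
      length(unique(gidx)) == 2            # het, incl. multiallelic 1|2
    }, logical(1))
    out <- data.frame(pos = truth$pos[keep] - 1L,
                      ref_base = truth$ref[keep], stringsAsFactors = FALSE)
  }
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("het_sites", "data.frame"))
}

#' Choose neighbor sites for a SNP candidate
#'
#' Builds the ordered site window Z: up to 20 likely-heterozygous sites per
#' flank that share at least one read with `b` and lie within
#' `distance_limit`. The `"nearest"` strategy takes the nearest sites; the
#' `"banded"` strategy fills per-flank quotas of 2, 3, 4, 5 and 6 sites from
#' the distance bands (0,2], (2,5], (5,10], (10,20] and (20,50] kb, which
#' spreads the anchors along the read length instead of crowding them next
#' to `b`. Ties break toward smaller distance, then smaller coordinate.
#'
#' @param b candidate position (0-based).
#' @param b_ref reference base at `b`.
#' @param het_sites output of [select_het_sites()].
#' @param reads list of [aligned_read()] (used for the shared-read test).
#' @param strategy `"banded"` or `"nearest"`.
#' @param distance_limit maximum distance in bp (default 50000).
#' @param band_edges,band_quota banded-strategy bands (upper edges, bp) and
#'   per-band site quotas.
#' @return object of class `neighbor_set`: positions and reference bases laid
#'   out on 41 columns with `b` at center column 21, `NA` in padded columns.
#' @export
choose_neighbor_sites <- function(b, b_ref, het_sites, reads,
                                  strategy = c("banded", "nearest"),
                                  distance_limit = 50000L,
                                  band_edges = c(2000L, 5000L, 10000L, 20000L,
                                                 50000L),
                                  band_quota = c(2L, 3L, 4L, 5L, 6L)) {
  strategy <- match.arg(strategy)
  cover <- vapply(reads, function(r) b >= r$ref_start && b < r$ref_end,
                  logical(1))
  if (any(cover)) {
    span_lo <- min(vapply(reads[cover], `[[`, integer(1), "ref_start"))
    span_hi <- max(vapply(reads[cover], `[[`, integer(1), "ref_end"))
  } else {
    span_lo <- b; span_hi <- b + 1L
  }
  p <- het_sites$pos
  dist <- abs(p - b)
  ok <- p != b & dist <= distance_limit & p >= span_lo & p < span_hi
  pick_flank <- function(flank_sel) {
    pp <- p[flank_sel]; dd <- dist[flank_sel]
    if (strategy == "nearest") {
      o <- order(dd, pp)
      sort(pp[o][seq_len(min(20L, length(pp)))])
    } else {
      lowers <- c(0L, band_edges[-length(band_edges)])
      chosen <- integer(0)
      for (k in seq_along(band_edges)) {
        inb <- dd > lowers[k] & dd <= band_edges[k]
        cand <- pp[inb]; dcand <- dd[inb]
        o <- order(dcand, cand)
        chosen <- c(chosen, cand[o][seq_len(min(band_quota[k], length(cand)))])
      }
      sort(chosen)
    }
  }
  up <- pick_flank(ok & p < b)
  down <- pick_flank(ok & p > b)
  pos41 <- rep(NA_integer_, 41L)
  ref41 <- rep(NA_character_, 41L)
  if (length(up) > 0) {
    pos41[(21L - length(up)):20L] <- up
    ref41[(21L - length(up)):20L] <- het_sites$ref_base[match(up, p)]
  }
  pos41[21L] <- b
  ref41[21L] <- toupper(b_ref)
  if (length(down) > 0) {
    pos41[22L:(21L + length(down))] <- down
    ref41[22L:(21L + length(down))] <- het_sites$ref_base[match(down, p)]
  }
  structure(list(b = as.integer(b), b_ref = toupper(b_ref),
                 pos = pos41, ref_base = ref41,
                 center = 21L, n_sites = length(up) + length(down)),
            class = "neighbor_set")
}

#' Gate a candidate on its neighbor count
#'
#' Candidates with fewer likely-heterozygous neighbor sites than `min_sites`
#' are not predicted (they become no-calls upstream of the network).
#'
#' @param neighbor_set a [choose_neighbor_sites()] result.
#' @param min_sites minimum number of neighbor sites excluding `b`
#'   (default 1).
#' @return `TRUE` if the candidate should be predicted.
#' @export
min_neighbor_gate <- function(neighbor_set, min_sites = 1L) {
  neighbor_set$n_sites >= min_sites
}

#' Build the SNP feature tensor for one candidate
#'
#' Returns the 5 x 41 x 5 image: rows 1-4 are the read groups R_A, R_G, R_T,
#' R_C (reads grouped by their base at `b`), row 5 encodes the reference
#' bases of the window sites; columns are the neighbor window with `b` at
#' column 21; channels 1-4 hold signed per-base counts (negative where the
#' counted base is the site's reference base), channel 5 marks the reference
#' base at `b` with a row of ones.
#'
#' @param neighbor_set a [choose_neighbor_sites()] result.
#' @param reads list of [aligned_read()].
#' @return numeric array `c(5, 41, 5)`.
#' @export
build_snp_feature_tensor <- function(neighbor_set, reads) {
  b <- neighbor_set$b
  codes_at_b <- base_codes_at(reads, b)
  support <- codes_at_b >= 1L & codes_at_b <= 4L
  if (!any(support))
    stopf("no read supports a base at site %d; uncallable", b)
  reads <- reads[support]
  codes_at_b <- codes_at_b[support]

  tensor <- array(0, dim = c(5L, 41L, 5L))
  live <- which(!is.na(neighbor_set$pos))
  site_pos <- neighbor_set$pos[live]
  site_ref_code <- base_to_code(neighbor_set$ref_base[live])
  bm <- read_base_matrix(reads, site_pos)

  for (gcode in 1:4) {                      # read group by base at b
    grow <- CODE_TO_TENSOR[gcode]
    in_group <- codes_at_b == gcode
    if (!any(in_group)) next
    sub <- bm[in_group, , drop = FALSE]
    for (dcode in 1:4) {                    # counted base D at site t
      dchan <- CODE_TO_TENSOR[dcode]
      cnt <- colSums(sub == dcode)
      sign <- ifelse(site_ref_code == dcode, -1, 1)
      tensor[grow, live, dchan] <- cnt * sign
    }
  }
  # channel 5: row of ones for the reference base at b (padded columns of
  # the window stay all-zero)
  tensor[CODE_TO_TENSOR[base_to_code(neighbor_set$b_ref)], live, 5L] <- 1
  # row 5: one-hot reference base of each window site across channels 1-4
  for (j in seq_along(live)) {
    tensor[5L, live[j], CODE_TO_TENSOR[site_ref_code[j]]] <- 1
  }
  tensor
}

#' Rescale tensor counts for coverage differences
#'
#' Multiplies the signed count entries by
#' `train_coverage / test_coverage` so a model trained at one depth
#' transfers to another; the reference channel and reference row are left
#' unchanged.
#'
#' @param tensor a [build_snp_feature_tensor()] result.
#' @param train_coverage,test_coverage positive coverages.
#' @return rescaled tensor.
#' @export
rescale_counts <- function(tensor, train_coverage, test_coverage) {
  if (train_coverage <= 0 || test_coverage <= 0)
    stopf("coverages must be positive")
  ratio <- train_coverage / test_coverage
  tensor[1:4, , 1:4] <- tensor[1:4, , 1:4] * ratio
  tensor
}

#' Platform profile defaults
#'
#' Bundled defaults per sequencing platform: neighbor-selection strategy,
#' likely-heterozygous frequency range, neighbor distance limit and the
#' indel MSA window length.
#'
#' @param platform `"ONT"`, `"CCS"` or `"CLR"`.
#' @return named list of defaults.
#' @export
platform_profile <- function(platform = c("ONT", "CCS", "CLR")) {
  platform <- match.arg(platform)
  switch(platform,
    ONT = list(platform = "ONT", neighbor_strategy = "banded",
               het_lower = 0.4, het_upper = 0.6, distance_limit = 50000L,
               indel_window_length = 160L),
    CCS = list(platform = "CCS", neighbor_strategy = "nearest",
               het_lower = 0.3, het_upper = 0.7, distance_limit = 20000L,
               indel_window_length = 260L),
    CLR = list(platform = "CLR", neighbor_strategy = "nearest",
               het_lower = 0.3, het_upper = 0.6, distance_limit = 20000L,
               indel_window_length = 260L))
}
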