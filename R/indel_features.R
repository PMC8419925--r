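# indel_features: indel candidate selection from phased reads, MSA-based
# frequency tensors, consensus and allele inference.
#
# For a candidate b, three read sets (all reads, phase 1, phase 2) are
# realigned against the reference window starting at b; each set yields a
# 5 x 128 symbol-frequency matrix M and a one-hot reference matrix Q, and
# the stacked tensor [M - Q, Q] over the three sets feeds the zygosity
# network. Alleles come from consensus-vs-reference affine-gap alignment.

MSA_SYMBOLS <- c("A", "G", "T", "C", "-")

# does read r carry a qualifying insertion/deletion for windows at pos?
# large window: events >= 3 bp; small window: events <= 10 bp.
read_has_indel <- function(read, pos, large_window, small_window) {
  ins <- read$ins; del <- read$del
  ins_hit <- FALSE; del_hit <- FALSE
  if (nrow(ins) > 0) {
    in_large <- ins$pos >= pos & ins$pos < pos + large_window & ins$len >= 3L
    in_small <- ins$pos >= pos & ins$pos < pos + small_window & ins$len <= 10L
    ins_hit <- any(in_large | in_small)
  }
  if (nrow(del) > 0) {
    ov_large <- del$pos < pos + large_window & del$pos + del$len > pos &
      del$len >= 3L
    ov_small <- del$pos < pos + small_window & del$pos + del$len > pos &
      del$len <= 10L
    del_hit <- any(ov_large | ov_small)
  }
  c(ins = ins_hit, del = del_hit)
}

#' Per-phase indel window frequencies at a site
#'
#' For each phase, the fraction of reads covering `pos` that carry a
#' qualifying insertion (resp. deletion): an event of at least 3 bp inside
#' the large window starting at `pos`, or an event of at most 10 bp inside
#' the small window. The two per-phase fractions are combined with
#' `phase_combine` (default `"max"`, so a variant carried by one haplotype
#' remains discoverable; `"min"` demands support from both).
#'
#' @param reads_by_phase list of two read lists (phase 1, phase 2).
#' @param pos 0-based site.
#' @param large_window,small_window window sizes (defaults 10 and 4).
#' @param phase_combine `"max"` or `"min"`.
#' @return named vector `c(insertion_frequency, deletion_frequency)`
#'   (`NA` if a phase has zero depth).
#' @export
indel_window_frequencies <- function(reads_by_phase, pos,
                                     large_window = 10L, small_window = 4L,
                                     phase_combine = c("max", "min")) {
  phase_combine <- match.arg(phase_combine)
  freq <- vapply(reads_by_phase, function(phase_reads) {
    cov <- vapply(phase_reads, function(r) pos >= r$ref_start &&
                    pos < r$ref_end, logical(1))
    if (!any(cov)) return(c(NA_real_, NA_real_))
    hits <- vapply(phase_reads[cov], read_has_indel, logical(2), pos = pos,
                   large_window = large_window, small_window = small_window)
    rowSums(matrix(hits, nrow = 2)) / sum(cov)
  }, numeric(2))
  comb <- if (phase_combine == "max") pmax else pmin
  c(insertion_frequency = comb(freq[1, 1], freq[1, 2]),
    deletion_frequency = comb(freq[2, 1], freq[2, 2]))
}

#' Select indel candidate sites in a region
#'
#' A position qualifies when both per-phase depths reach
#' `min_phase_depth` and the combined insertion frequency reaches
#' `ins_threshold` or the combined deletion frequency reaches
#' `del_threshold`. Reads without a haplotype assignment are ignored here
#' (they still contribute to the all-reads MSA set later).
#'
#' @param reads list of [aligned_read()] with haplotype assignments.
#' @param chrom contig name.
#' @param start,end 0-based half-open region.
#' @param min_phase_depth minimum per-phase depth (default 8).
#' @param ins_threshold,del_threshold frequency thresholds (ONT defaults
#'   0.4 and 0.6).
#' @param large_window,small_window window sizes.
#' @param phase_combine `"max"` or `"min"` across phases.
#' @return data.frame: `chrom`, `pos` (0-based), `depth_1`, `depth_2`,
#'   `ins_freq`, `del_freq`.
#' @export
select_indel_candidates <- function(reads, chrom, start, end,
                                    min_phase_depth = 8L,
                                    ins_threshold = 0.4, del_threshold = 0.6,
                                    large_window = 10L, small_window = 4L,
                                    phase_combine = c("max", "min")) {
  phase_combine <- match.arg(phase_combine)
  L <- end - start
  depth <- matrix(0L, nrow = 2, ncol = L)
  ins_cnt <- matrix(0L, nrow = 2, ncol = L)
  del_cnt <- matrix(0L, nrow = 2, ncol = L)
  clip <- function(x) pmin(pmax(x, start), end - 1L) - start + 1L

  for (r in reads) {
    h <- r$haplotype
    if (is.na(h) || !h %in% 1:2) next
    lo <- max(r$ref_start, start); hi <- min(r$ref_end, end)
    if (lo < hi) depth[h, (lo - start + 1L):(hi - start)] <-
        depth[h, (lo - start + 1L):(hi - start)] + 1L
    # candidate positions b whose windows catch this read's events
    ivs <- list()
    if (nrow(r$ins) > 0) {
      big <- r$ins[r$ins$len >= 3L, , drop = FALSE]
      small <- r$ins[r$ins$len <= 10L, , drop = FALSE]
      if (nrow(big) > 0)
        ivs <- c(ivs, list(cbind(big$pos - large_window + 1L, big$pos, 1L)))
      if (nrow(small) > 0)
        ivs <- c(ivs, list(cbind(small$pos - small_window + 1L, small$pos, 1L)))
    }
    if (nrow(r$del) > 0) {
      big <- r$del[r$del$len >= 3L, , drop = FALSE]
      small <- r$del[r$del$len <= 10L, , drop = FALSE]
      if (nrow(big) > 0)
        ivs <- c(ivs, list(cbind(big$pos - large_window + 1L,
                                 big$pos + big$len - 1L, 2L)))
      if (nrow(small) > 0)
        ivs <- c(ivs, list(cbind(small$pos - small_window + 1L,
                                 small$pos + small$len - 1L, 2L)))
    }
    if (length(ivs) == 0) next
    iv <- do.call(rbind, ivs)
    for (kind in 1:2) {
      rows <- iv[iv[, 3] == kind, , drop = FALSE]
      if (nrow(rows) == 0) next
      # union of intervals so the read is counted once per position
      mask <- logical(L)
      for (q in seq_len(nrow(rows))) {
        a <- clip(rows[q, 1]); bb <- clip(rows[q, 2])
        if (rows[q, 2] < start || rows[q, 1] > end - 1L) next
        mask[a:bb] <- TRUE
      }
      tgt <- if (kind == 1L) "ins" else "del"
      if (kind == 1L) ins_cnt[h, mask] <- ins_cnt[h, mask] + 1L
      else del_cnt[h, mask] <- del_cnt[h, mask] + 1L
    }
  }

  with_depth <- depth > 0
  insf <- matrix(NA_real_, 2, L); delf <- matrix(NA_real_, 2, L)
  insf[with_depth] <- ins_cnt[with_depth] / depth[with_depth]
  delf[with_depth] <- del_cnt[with_depth] / depth[with_depth]
  comb <- if (phase_combine == "max") pmax else pmin
  ins_c <- comb(insf[1, ], insf[2, ])
  del_c <- comb(delf[1, ], delf[2, ])
  keep <- which(depth[1, ] >= min_phase_depth & depth[2, ] >= min_phase_depth &
                  ((!is.na(ins_c) & ins_c >= ins_threshold) |
                   (!is.na(del_c) & del_c >= del_threshold)))
  data.frame(chrom = rep(chrom, length(keep)), pos = start + keep - 1L,
             depth_1 = depth[1, keep], depth_2 = depth[2, keep],
             ins_freq = ins_c[keep], del_freq = del_c[keep],
             stringsAsFactors = FALSE)
}

# read index (0-based) aligned at ref position pos, or the next aligned
# read base when the read is deleted at pos; NA when not spanning
read_index_at <- function(read, pos) {
  if (pos < read$ref_start || pos >= read$ref_end) return(NA_integer_)
  cg <- parse_cigar(read$cigar)
  ri <- 0L; fp <- read$ref_start
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]; len <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      if (pos < fp + len) return(ri + (pos - fp))
      ri <- ri + len; fp <- fp + len
    } else if (op == "I") {
      ri <- ri + len
    } else if (op %in% c("D", "N")) {
      if (pos < fp + len) return(ri)   # deleted here; next aligned base
      fp <- fp + len
    } else if (op == "S") {
      ri <- ri + len
    }
  }
  NA_integer_
}

#' Extract the MSA window sequences at a candidate
#'
#' The reference window of `window_length` starting at `pos`, and for each
#' read spanning `pos` the read subsequence starting at the read index
#' aligned to `pos`, truncated at the read end.
#'
#' @param reads list of [aligned_read()].
#' @param pos 0-based candidate position.
#' @param ref_window reference sequence of length `window_length` starting
#'   at `pos`.
#' @param window_length window size (160 for ONT, 260 for PacBio).
#' @return list with `ref` and named character vector `reads`.
#' @export
extract_window_sequences <- function(reads, pos, ref_window,
                                     window_length = 160L) {
  stopifnot(nchar(ref_window) == window_length)
  out <- character(0)
  for (r in reads) {
    idx <- read_index_at(r, pos)
    if (is.na(idx)) next
    s <- substr(r$sequence, idx + 1L, idx + window_length)
    if (nchar(s) > 0) out[r$read_id] <- s
  }
  list(ref = toupper(ref_window), reads = out)
}

nuc_submat <- function(match = 2, mismatch = -4) {
  m <- matrix(mismatch, 5, 5, dimnames = list(c(BASES, "N"), c(BASES, "N")))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

# pairwise overlap alignment of sequences against the window reference,
# vectorised over patterns; gap structure is read off the cheap indel
# ranges (alignment-column coordinates) instead of the gapped strings
pairwise_affine <- function(seqs, center, match = 2, mismatch = -4,
                            gap_open = 8, gap_ext = 1) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs), Biostrings::DNAString(center),
    type = "overlap", substitutionMatrix = nuc_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_ext)
  list(ps = IRanges::start(Biostrings::pattern(pa)),
       pe = IRanges::end(Biostrings::pattern(pa)),
       ss = IRanges::start(Biostrings::subject(pa)),
       se = IRanges::end(Biostrings::subject(pa)),
       ins = Biostrings::insertion(Biostrings::indel(pa)),
       del = Biostrings::deletion(Biostrings::indel(pa)))
}

# per-alignment column classification: is_ins (gap in centre), is_del
# (gap in read), centre/read index per column. Insertion ranges come in
# subject-relative coordinates and deletion ranges in pattern-relative
# coordinates (each unadjusted for the other's gaps), so the alignment is
# reconstructed by walking both sequences and firing each gap event when
# its sequence reaches the event position.
alignment_columns <- function(pa, i) {
  ins <- pa$ins[[i]]; del <- pa$del[[i]]
  wp <- pa$pe[i] - pa$ps[i] + 1L          # pattern bases in aligned region
  ws <- pa$se[i] - pa$ss[i] + 1L          # subject bases in aligned region
  ncols <- wp + sum(IRanges::width(del))
  stopifnot(ncols == ws + sum(IRanges::width(ins)))
  is_ins <- logical(ncols); is_del <- logical(ncols)
  es <- IRanges::start(ins); ew <- IRanges::width(ins)
  ds <- IRanges::start(del); dw <- IRanges::width(del)
  cp <- 0L; cs <- 0L; col <- 0L; ii <- 1L; di <- 1L
  while (col < ncols) {
    if (di <= length(ds) && cp == ds[di] - 1L) {
      is_del[col + seq_len(dw[di])] <- TRUE
      cs <- cs + dw[di]; col <- col + dw[di]; di <- di + 1L
    } else if (ii <= length(es) && cs == es[ii] - 1L) {
      is_ins[col + seq_len(ew[ii])] <- TRUE
      cp <- cp + ew[ii]; col <- col + ew[ii]; ii <- ii + 1L
    } else {
      nd <- if (di <= length(ds)) ds[di] - 1L - cp else wp - cp
      ni <- if (ii <= length(es)) es[ii] - 1L - cs else ws - cs
      step <- min(nd, ni)
      if (step <= 0L) stopf("alignment reconstruction failed")
      col <- col + step; cp <- cp + step; cs <- cs + step
    }
  }
  list(ncols = ncols, is_ins = is_ins, is_del = is_del,
       centre_idx = pa$ss[i] - 1L + cumsum(!is_ins),
       read_idx = pa$ps[i] - 1L + cumsum(!is_del))
}

# per-read star rows: read character over each centre base plus the
# insertion string after each centre position
star_rows <- function(pa, rchars_all, Lc, indices = seq_along(rchars_all)) {
  lapply(indices, function(i) {
    ac <- alignment_columns(pa, i)
    rchars <- rchars_all[[i]]
    aligned <- rep("-", Lc)
    mcols <- !ac$is_ins & !ac$is_del
    aligned[ac$centre_idx[mcols]] <- rchars[ac$read_idx[mcols]]
    ins_seq <- rep("", Lc + 1L)
    if (any(ac$is_ins)) {
      grp <- tapply(rchars[ac$read_idx[ac$is_ins]], ac$centre_idx[ac$is_ins],
                    function(x) paste(x, collapse = ""))
      ins_seq[as.integer(names(grp)) + 1L] <- unname(grp)
    }
    list(aligned = aligned, ins = ins_seq)
  })
}

# merge star rows into the alignment matrix (once-a-gap-always-a-gap)
star_assemble <- function(center, per_read) {
  Lc <- nchar(center)
  n <- length(per_read)
  ins_after <- integer(Lc + 1L)
  for (r in per_read) ins_after <- pmax(ins_after, nchar(r$ins))
  ncols <- Lc + sum(ins_after)
  aln <- matrix("-", nrow = n + 1L, ncol = ncols)
  col <- 0L
  for (i in 0:Lc) {
    if (ins_after[i + 1L] > 0) {
      w <- ins_after[i + 1L]
      for (r in seq_len(n)) {
        s <- per_read[[r]]$ins[i + 1L]
        if (nchar(s) > 0)
          aln[r + 1L, col + seq_len(nchar(s))] <-
            strsplit(s, "", fixed = TRUE)[[1]]
      }
      col <- col + w
    }
    if (i < Lc) {
      col <- col + 1L
      aln[1L, col] <- substr(center, i + 1L, i + 1L)
      for (r in seq_len(n)) aln[r + 1L, col] <- per_read[[r]]$aligned[i + 1L]
    }
  }
  aln
}

# centre-star MSA: align every read to the reference window and merge on
# the shared centre
centerstar_msa <- function(seqs) {
  center <- seqs[[1]]
  reads <- unlist(seqs[-1])
  pa <- pairwise_affine(reads, center)
  star_assemble(center,
                star_rows(pa, strsplit(reads, "", fixed = TRUE),
                          nchar(center)))
}

mafft_msa <- function(seqs) {
  exe <- Sys.which("mafft")
  if (!nzchar(exe))
    stopf("external MSA backend 'mafft' not found on PATH")
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste0(">s", seq_along(seqs), "\n", unlist(seqs)), fin)
  status <- system2(exe, c("--quiet", "--retree", "2", fin),
                    stdout = fout, stderr = FALSE)
  if (status != 0) stopf("mafft exited with status %d", status)
  x <- toupper(as.character(Biostrings::readBStringSet(fout)))
  do.call(rbind, strsplit(x, "", fixed = TRUE))
}

#' Realign window sequences with an MSA backend
#'
#' Realigns the reference window and the read windows, truncates the
#' alignment to `max_cols` columns (padding with gap columns when shorter)
#' and computes the per-column symbol count matrix `C`, frequency matrix
#' `M = C / n_reads` and the one-hot reference matrix `Q`, all over the
#' fixed symbol order A, G, T, C, gap.
#'
#' @param sequences list/vector of sequences, reference first.
#' @param backend `"internal"` (centre-star over affine-gap pairwise
#'   alignments) or `"mafft"` (external subprocess).
#' @param max_cols alignment columns kept (default 128).
#' @return object of class `msa_pileup`: `aln` (character matrix, reference
#'   in row 1), `C`, `M`, `Q` (5 x `max_cols`), `n_reads`.
#' @export
msa_realign <- function(sequences, backend = c("internal", "mafft"),
                        max_cols = 128L) {
  backend <- match.arg(backend)
  sequences <- toupper(unlist(sequences))
  if (length(sequences) < 2) stopf("MSA needs at least 2 sequences")
  aln <- if (backend == "internal") centerstar_msa(sequences)
         else mafft_msa(sequences)
  pileup_from_aln(aln, max_cols)
}

# count/frequency/reference matrices from an alignment matrix (ref row 1)
pileup_from_aln <- function(aln, max_cols = 128L) {
  if (ncol(aln) >= max_cols) {
    aln <- aln[, seq_len(max_cols), drop = FALSE]
  } else {
    aln <- cbind(aln, matrix("-", nrow(aln), max_cols - ncol(aln)))
  }
  n_reads <- nrow(aln) - 1L
  C <- matrix(0, 5L, max_cols, dimnames = list(MSA_SYMBOLS, NULL))
  for (s in seq_along(MSA_SYMBOLS))
    C[s, ] <- colSums(aln[-1L, , drop = FALSE] == MSA_SYMBOLS[s])
  M <- if (n_reads > 0) C / n_reads else C
  Q <- matrix(0, 5L, max_cols, dimnames = list(MSA_SYMBOLS, NULL))
  Q[cbind(match(aln[1L, ], MSA_SYMBOLS), seq_len(max_cols))] <- 1
  structure(list(aln = aln, C = C, M = M, Q = Q, n_reads = n_reads),
            class = "msa_pileup")
}

#' Build the indel feature tensor
#'
#' Stacks the three per-set 5 x 128 x 2 blocks (all reads, phase 1,
#' phase 2) into a 15 x 128 x 2 tensor: channel 1 is `M - Q`, channel 2 is
#' `Q`. A `NULL` pileup (empty read set) yields a zero block.
#'
#' @param pileup_all,pileup_phase1,pileup_phase2 [msa_realign()] pileups
#'   over the same candidate.
#' @return numeric array `c(15, 128, 2)`, with attribute `empty_sets`
#'   naming zeroed blocks.
#' @export
build_indel_feature_tensor <- function(pileup_all, pileup_phase1,
                                       pileup_phase2) {
  tensor <- array(0, dim = c(15L, 128L, 2L))
  pil <- list(pileup_all, pileup_phase1, pileup_phase2)
  empty <- character(0)
  nm <- c("all", "phase1", "phase2")
  for (i in 1:3) {
    p <- pil[[i]]
    if (is.null(p) || p$n_reads == 0) { empty <- c(empty, nm[i]); next }
    rows <- (i - 1L) * 5L + 1:5
    tensor[rows, , 1L] <- p$M - p$Q
    tensor[rows, , 2L] <- p$Q
  }
  attr(tensor, "empty_sets") <- empty
  tensor
}

#' Consensus sequence of an MSA pileup
#'
#' Per column the most frequent read symbol (the reference row is
#' excluded); ties prefer the reference symbol, then the smaller symbol in
#' the fixed order. Gap symbols are removed from the returned sequence.
#'
#' @param pileup an [msa_realign()] pileup.
#' @return character string.
#' @export
consensus_from_msa <- function(pileup) {
  if (pileup$n_reads == 0) stopf("consensus of an empty pileup")
  out <- character(ncol(pileup$C))
  for (j in seq_len(ncol(pileup$C))) {
    cnt <- pileup$C[, j]
    top <- which(cnt == max(cnt))
    ref_sym <- which(pileup$Q[, j] == 1)
    pick <- if (length(top) == 1) top
            else if (length(ref_sym) && ref_sym %in% top) ref_sym
            else top[which.min(match(MSA_SYMBOLS[top], c(BASES, "-")))]
    out[j] <- MSA_SYMBOLS[pick]
  }
  paste(out[out != "-"], collapse = "")
}

#' Infer an indel allele from consensus vs reference
#'
#' Global affine-gap alignment of the consensus against the reference
#' window; the first gap run yields a left-anchored VCF-style allele pair.
#' Returns `NULL` when the alignment has no gap.
#'
#' @param consensus consensus sequence (gaps removed).
#' @param ref_window reference window the consensus was built over.
#' @return `NULL` or list with `ref`, `alt` and `offset` (0-based offset of
#'   the allele's first base inside `ref_window`).
#' @export
infer_allele <- function(consensus, ref_window) {
  if (nchar(consensus) == 0 || nchar(ref_window) == 0)
    stopf("empty sequence")
  pa <- pairwise_affine(consensus, ref_window)
  ins <- pa$ins[[1]]; del <- pa$del[[1]]
  if (length(ins) == 0 && length(del) == 0) return(NULL)
  ac <- alignment_columns(pa, 1L)
  ins_first <- if (length(ins) > 0) IRanges::start(ins)[1] else Inf
  del_first <- if (length(del) > 0) IRanges::start(del)[1] else Inf
  if (ins_first < del_first) {              # insertion in consensus
    k <- IRanges::start(ins)[1]; w <- IRanges::width(ins)[1]
    seg <- substr(consensus, ac$read_idx[k], ac$read_idx[k + w - 1L])
    roff <- ac$centre_idx[k]                # ref base left of the gap
    if (roff >= 1) {
      anchor <- substr(ref_window, roff, roff)
      list(ref = anchor, alt = paste0(anchor, seg), offset = roff - 1L)
    } else {                                # no left base: anchor right
      anchor <- substr(ref_window, 1L, 1L)
      list(ref = anchor, alt = paste0(seg, anchor), offset = 0L)
    }
  } else {                                  # deletion in consensus
    k <- del_first; w <- IRanges::width(del)[1]
    dstart <- ac$centre_idx[k]              # first deleted ref base
    if (dstart >= 2) {
      list(ref = substr(ref_window, dstart - 1L, dstart + w - 1L),
           alt = substr(ref_window, dstart - 1L, dstart - 1L),
           offset = dstart - 2L)
    } else {                                # deletion at window start
      list(ref = substr(ref_window, 1L, w + 1L),
           alt = substr(ref_window, w + 1L, w + 1L),
           offset = 0L)
    }
  }
}

#' Combine per-phase indel alleles into a phased call
#'
#' Same allele on both phases is homozygous `1|1`; an allele on one phase
#' only is `1|0` / `0|1`; two different alleles give a multiallelic `1|2`
#' (with the reference allele extended to the longer of the two when they
#' differ in length).
#'
#' @param allele_phase1,allele_phase2 [infer_allele()] results (or `NULL`).
#' @param chrom contig name.
#' @param window_start 0-based position of the window the offsets refer to.
#' @param qual QUAL value for the record.
#' @return a [variant_calls()] table (possibly with 2 rows when the two
#'   phases yield alleles at different positions), or `NULL` if neither
#'   phase has an allele.
#' @export
combine_phase_calls <- function(allele_phase1, allele_phase2, chrom,
                                window_start, qual = 0) {
  a1 <- allele_phase1; a2 <- allele_phase2
  if (is.null(a1) && is.null(a2)) return(NULL)
  mkpos <- function(a) window_start + a$offset + 1L
  if (is.null(a2))
    return(variant_calls(chrom, mkpos(a1), a1$ref, a1$alt, "1|0", qual))
  if (is.null(a1))
    return(variant_calls(chrom, mkpos(a2), a2$ref, a2$alt, "0|1", qual))
  if (identical(a1[c("ref", "alt", "offset")], a2[c("ref", "alt", "offset")]))
    return(variant_calls(chrom, mkpos(a1), a1$ref, a1$alt, "1|1", qual))
  if (a1$offset == a2$offset) {
    # unify to the longer reference allele
    if (nchar(a1$ref) >= nchar(a2$ref)) { long <- a1; short <- a2 }
    else { long <- a2; short <- a1 }
    suffix <- substr(long$ref, nchar(short$ref) + 1L, nchar(long$ref))
    short_alt <- paste0(short$alt, suffix)
    alt1 <- if (identical(long, a1)) long$alt else short_alt
    alt2 <- if (identical(long, a1)) short_alt else long$alt
    if (alt1 == alt2)
      return(variant_calls(chrom, mkpos(a1), long$ref, alt1, "1|1", qual))
    return(variant_calls(chrom, mkpos(a1), long$ref,
                         paste(alt1, alt2, sep = ","), "1|2", qual))
  }
  # alleles at different positions: one phased record each
  sort_calls(rbind(
    variant_calls(chrom, mkpos(a1), a1$ref, a1$alt, "1|0", qual),
    variant_calls(chrom, mkpos(a2), a2$ref, a2$alt, "0|1", qual)))
}
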