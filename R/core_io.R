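# core_io: standard-format I/O and the per-position pileup contract.
#
# All internal coordinates are 0-based half-open; the single conversion to
# 1-based happens at the VCF boundary (write_vcf/read_vcf).

#' Construct an aligned read
#'
#' A lightweight record of one long read aligned to the reference: the
#' (already reverse-complemented, strand-agnostic) read sequence, its CIGAR
#' against the reference, and an optional haplotype assignment. On
#' construction the CIGAR is decoded into a per-reference-position base code
#' vector and per-read indel event tables, which all downstream pileup and
#' feature operations consume.
#'
#' @param read_id unique read name.
#' @param chrom contig name.
#' @param ref_start 0-based leftmost aligned reference position.
#' @param sequence read bases over A,C,G,T (aligned orientation).
#' @param cigar CIGAR string (M/=/X, I, D, N, S, H supported).
#' @param mapq mapping quality.
#' @param haplotype `1L`, `2L` or `NA` (unassigned).
#' @return an object of class `aligned_read`.
#' @export
aligned_read <- function(read_id, chrom, ref_start, sequence, cigar,
                         mapq = 60L, haplotype = NA_integer_) {
  sequence <- toupper(sequence)
  cg <- parse_cigar(cigar)
  read_codes <- base_to_code(strsplit(sequence, "", fixed = TRUE)[[1]])
  ref_len <- sum(cg$len[cg$op %in% c("M", "=", "X", "D", "N")])
  read_len_aln <- sum(cg$len[cg$op %in% c("M", "=", "X", "I", "S")])
  if (read_len_aln != nchar(sequence))
    stopf("CIGAR consumes %d read bases but sequence has %d (%s)",
          read_len_aln, nchar(sequence), read_id)

  ref_codes <- integer(ref_len)
  ins_pos <- integer(0); ins_len <- integer(0); ins_seq <- character(0)
  del_pos <- integer(0); del_len <- integer(0)
  ri <- 0L  # consumed read bases
  fi <- 0L  # consumed ref bases (offset from ref_start)
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]; len <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      ref_codes[(fi + 1L):(fi + len)] <- read_codes[(ri + 1L):(ri + len)]
      ri <- ri + len; fi <- fi + len
    } else if (op == "I") {
      ins_pos <- c(ins_pos, ref_start + fi)
      ins_len <- c(ins_len, len)
      ins_seq <- c(ins_seq, substr(sequence, ri + 1L, ri + len))
      ri <- ri + len
    } else if (op %in% c("D", "N")) {
      ref_codes[(fi + 1L):(fi + len)] <- DEL_CODE
      del_pos <- c(del_pos, ref_start + fi)
      del_len <- c(del_len, len)
      fi <- fi + len
    } else if (op == "S") {
      ri <- ri + len
    } # H consumes nothing
  }
  structure(list(
    read_id = read_id, chrom = chrom,
    ref_start = as.integer(ref_start),
    ref_end = as.integer(ref_start + ref_len),
    sequence = sequence, cigar = cigar,
    mapq = as.integer(mapq), haplotype = haplotype,
    ref_codes = ref_codes,
    ins = data.frame(pos = ins_pos, len = ins_len, seq = ins_seq,
                     stringsAsFactors = FALSE),
    del = data.frame(pos = del_pos, len = del_len)
  ), class = "aligned_read")
}

#' @export
print.aligned_read <- function(x, ...) {
  cat(sprintf("<aligned_read %s %s:%d-%d mapq=%d hap=%s cigar=%s>\n",
              x$read_id, x$chrom, x$ref_start, x$ref_end, x$mapq,
              ifelse(is.na(x$haplotype), ".", x$haplotype),
              if (nchar(x$cigar) > 30) paste0(substr(x$cigar, 1, 30), "...")
              else x$cigar))
  invisible(x)
}

#' Reference/read coordinate pairs of an aligned read
#'
#' Walks the CIGAR and returns one row per aligned column: matched bases have
#' both indices, insertions have `ref_pos = NA`, deletions have
#' `read_index = NA`. Both indices are 0-based.
#'
#' @param read an [aligned_read()].
#' @return data.frame with columns `read_index`, `ref_pos`.
#' @export
aligned_pairs <- function(read) {
  cg <- parse_cigar(read$cigar)
  ri <- 0L; fp <- read$ref_start
  out <- vector("list", length(cg$op))
  for (k in seq_along(cg$op)) {
    op <- cg$op[k]; len <- cg$len[k]
    if (op %in% c("M", "=", "X")) {
      out[[k]] <- data.frame(read_index = ri:(ri + len - 1L),
                             ref_pos = fp:(fp + len - 1L))
      ri <- ri + len; fp <- fp + len
    } else if (op == "I") {
      out[[k]] <- data.frame(read_index = ri:(ri + len - 1L),
                             ref_pos = NA_integer_)
      ri <- ri + len
    } else if (op %in% c("D", "N")) {
      out[[k]] <- data.frame(read_index = NA_integer_,
                             ref_pos = fp:(fp + len - 1L))
      fp <- fp + len
    } else if (op == "S") {
      ri <- ri + len
    }
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# base code of each read at a single 0-based position (0 if not covered)
base_codes_at <- function(reads, pos) {
  vapply(reads, function(r) {
    if (pos >= r$ref_start && pos < r$ref_end)
      r$ref_codes[pos - r$ref_start + 1L]
    else 0L
  }, integer(1))
}

# reads x positions base-code matrix over 0-based positions `positions`
read_base_matrix <- function(reads, positions) {
  n <- length(reads)
  m <- matrix(0L, nrow = n, ncol = length(positions))
  for (i in seq_len(n)) {
    r <- reads[[i]]
    sel <- positions >= r$ref_start & positions < r$ref_end
    if (any(sel)) m[i, sel] <- r$ref_codes[positions[sel] - r$ref_start + 1L]
  }
  m
}

#' Read a reference subsequence from an indexed FASTA
#'
#' @param fasta_path path to a FASTA file with a `.fai` index (created if
#'   missing).
#' @param chrom contig name.
#' @param start,end 0-based half-open range.
#' @return uppercase character string of length `end - start`.
#' @export
read_reference <- function(fasta_path, chrom, start, end) {
  if (!file.exists(paste0(fasta_path, ".fai"))) Rsamtools::indexFa(fasta_path)
  fa <- Rsamtools::FaFile(fasta_path)
  info <- Rsamtools::seqinfo(fa)
  if (!chrom %in% GenomeInfoDb::seqnames(info))
    stopf("contig '%s' not found in %s", chrom, fasta_path)
  clen <- GenomeInfoDb::seqlengths(info)[[chrom]]
  if (start < 0 || end > clen || start >= end)
    stopf("range [%d,%d) out of bounds for %s (length %d)",
          start, end, chrom, clen)
  rng <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  toupper(as.character(Rsamtools::scanFa(fa, rng)[[1]]))
}

#' Read primary alignments overlapping a region
#'
#' Returns all primary, non-duplicate, non-supplementary reads overlapping
#' `[start, end)` with mapping quality at least `min_mapq`, with coordinate
#' pairs reconstructed from the CIGAR. A haplotype tag (`HP`) is carried over
#' when present.
#'
#' @param bam_path indexed BAM file.
#' @param chrom contig name.
#' @param start,end 0-based half-open region.
#' @param min_mapq minimum mapping quality (default 0).
#' @return list of [aligned_read()] objects.
#' @export
read_alignments <- function(bam_path, chrom, start, end, min_mapq = 0L) {
  param <- Rsamtools::ScanBamParam(
    which = GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end)),
    what = c("qname", "pos", "mapq", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE),
    tag = "HP",
    mapqFilter = as.integer(min_mapq))
  res <- Rsamtools::scanBam(bam_path, param = param)[[1]]
  n <- length(res$qname)
  if (n == 0) return(list())
  hp <- res$tag$HP %||% rep(NA_integer_, n)
  seqs <- as.character(res$seq)
  lapply(seq_len(n), function(i) {
    aligned_read(read_id = res$qname[i], chrom = chrom,
                 ref_start = res$pos[i] - 1L, sequence = seqs[i],
                 cigar = res$cigar[i], mapq = res$mapq[i],
                 haplotype = hp[i])
  })
}

#' Pileup column at one position
#'
#' One entry per read whose alignment spans `pos`; reads with a deletion at
#' `pos` contribute the deletion marker `"-"`. Insertions adjacent to `pos`
#' are not represented in the column.
#'
#' @param reads list of [aligned_read()].
#' @param chrom contig name.
#' @param pos 0-based position.
#' @param ref_base reference base at `pos`.
#' @return object of class `pileup_column` with fields `chrom`, `pos`,
#'   `ref_base`, `per_read_base` (named character vector) and `depth`.
#' @export
pileup <- function(reads, chrom, pos, ref_base) {
  codes <- base_codes_at(reads, pos)
  keep <- codes > 0L
  prb <- code_to_base(codes[keep])
  names(prb) <- vapply(reads[keep], `[[`, character(1), "read_id")
  structure(list(chrom = chrom, pos = as.integer(pos),
                 ref_base = toupper(ref_base),
                 per_read_base = prb, depth = length(prb)),
            class = "pileup_column")
}

#' Build a table of variant calls
#'
#' The common call container: one row per record, `pos` 1-based (VCF
#' convention), `alt` a comma-separated allele list, `genotype` one of
#' `0/1, 1/1, 1/2` or their phased (`|`) forms.
#'
#' @param chrom,pos,ref,alt,genotype,qual vectors of equal length.
#' @return data.frame of class `variant_calls`.
#' @export
variant_calls <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          genotype = character(), qual = numeric()) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   genotype = as.character(genotype), qual = as.numeric(qual),
                   stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    alts <- strsplit(df$alt[i], ",", fixed = TRUE)[[1]]
    if (length(alts) < 1 || any(alts == df$ref[i]))
      stopf("invalid alt alleles '%s' for ref '%s'", df$alt[i], df$ref[i])
    gidx <- suppressWarnings(as.integer(strsplit(df$genotype[i], "[/|]")[[1]]))
    if (any(is.na(gidx)) || max(gidx) > length(alts))
      stopf("genotype '%s' inconsistent with %d alt allele(s)",
            df$genotype[i], length(alts))
  }
  class(df) <- c("variant_calls", "data.frame")
  df
}

sort_calls <- function(calls) {
  calls[order(calls$chrom, calls$pos), , drop = FALSE]
}

#' Classify a variant by its REF/ALT alleles
#'
#' Both alleles length 1 is a SNP; a longer ALT is an insertion; a longer REF
#' a deletion. Multiallelic records are classified per alternative allele.
#'
#' @param ref_allele,alt_allele single allele strings.
#' @return one of `"SNP"`, `"insertion"`, `"deletion"`.
#' @export
classify_variant <- function(ref_allele, alt_allele) {
  if (ref_allele == alt_allele) stopf("identical ref and alt allele '%s'", ref_allele)
  nr <- nchar(ref_allele); na <- nchar(alt_allele)
  if (nr == 1 && na == 1) return("SNP")
  if (nr < na) return("insertion")
  if (nr > na) return("deletion")
  stopf("cannot classify equal-length multi-base alleles %s>%s",
        ref_allele, alt_allele)
}

#' Write calls to a VCF 4.2 file
#'
#' @param calls a [variant_calls()] table, sorted by chrom then pos.
#' @param sample_name sample column name.
#' @param path output path.
#' @param phased if `TRUE` genotypes are written as given (expected to carry
#'   `|` separators); purely cosmetic, genotype strings are not altered.
#' @param contigs optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, sample_name, path, phased = FALSE,
                      contigs = NULL) {
  if (nrow(calls) > 0) {
    o <- order(calls$chrom, calls$pos)
    if (!identical(o, seq_len(nrow(calls))))
      stopf("calls must be sorted by chrom, pos before writing")
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=haplocall",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_name), collapse = "\t"))
  body <- character(0)
  if (nrow(calls) > 0) {
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%.2f\tPASS\t.\tGT\t%s",
                    calls$chrom, calls$pos, calls$ref, calls$alt,
                    calls$qual, calls$genotype)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF file into a call table
#'
#' Thin wrapper over a standard VCF parser; keeps the first sample's GT.
#'
#' @param path VCF file.
#' @return a [variant_calls()] table.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) return(variant_calls())
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- if (ncol(v@gt) >= 2) vcfR::extract.gt(v, element = "GT")[, 1]
        else rep("./.", nrow(fix))
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  qual[is.na(qual)] <- 0
  variant_calls(chrom = fix$CHROM, pos = as.integer(fix$POS),
                ref = fix$REF, alt = fix$ALT,
                genotype = unname(gt), qual = qual)
}

#' Read a BED file of regions
#'
#' @param path BED3+ file.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  data.frame(chrom = as.character(bed[[1]]), start = as.integer(bed[[2]]),
             end = as.integer(bed[[3]]), stringsAsFactors = FALSE)
}

#' Write a FASTA file with index
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  Rsamtools::indexFa(path)
  invisible(path)
}
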