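# evaluate: exact genotype-level comparison of call sets against truth and
# precision/recall/F1 reporting, with optional BED region restriction.

# canonical key of one record: normalised position/alleles plus a phase-
# insensitive genotype over sorted alternative alleles
call_keys <- function(calls) {
  if (nrow(calls) == 0) return(character(0))
  vapply(seq_len(nrow(calls)), function(i) {
    ref <- calls$ref[i]
    alts <- strsplit(calls$alt[i], ",", fixed = TRUE)[[1]]
    pos <- calls$pos[i]
    # trim shared suffix (keep >= 1 base per allele)
    repeat {
      all_len <- c(nchar(ref), nchar(alts))
      lasts <- c(substr(ref, nchar(ref), nchar(ref)),
                 vapply(alts, function(a) substr(a, nchar(a), nchar(a)), ""))
      if (all(all_len > 1) && length(unique(lasts)) == 1) {
        ref <- substr(ref, 1, nchar(ref) - 1)
        alts <- vapply(alts, function(a) substr(a, 1, nchar(a) - 1), "")
      } else break
    }
    # trim shared prefix (keep >= 1 base), advancing pos
    repeat {
      firsts <- c(substr(ref, 1, 1), vapply(alts, substr, "", 1, 1))
      if (all(c(nchar(ref), nchar(alts)) > 1) &&
          length(unique(firsts)) == 1) {
        ref <- substr(ref, 2, nchar(ref))
        alts <- vapply(alts, function(a) substr(a, 2, nchar(a)), "")
        pos <- pos + 1L
      } else break
    }
    gidx <- as.integer(strsplit(calls$genotype[i], "[/|]")[[1]])
    o <- order(alts)
    remap <- c(0L, match(seq_along(alts), o))      # old index -> new index
    gt <- paste(sort(remap[gidx + 1L]), collapse = "/")
    paste(calls$chrom[i], pos, ref, paste(alts[o], collapse = ","), gt,
          sep = ":")
  }, character(1))
}

call_types <- function(calls) {
  if (nrow(calls) == 0) return(character(0))
  vapply(seq_len(nrow(calls)), function(i) {
    alts <- strsplit(calls$alt[i], ",", fixed = TRUE)[[1]]
    if (nchar(calls$ref[i]) == 1 && all(nchar(alts) == 1)) "SNP"
    else if (max(nchar(alts)) > nchar(calls$ref[i])) "insertion"
    else "deletion"
  }, character(1))
}

in_regions <- function(calls, regions) {
  if (is.null(regions) || nrow(calls) == 0)
    return(rep(TRUE, nrow(calls)))
  vapply(seq_len(nrow(calls)), function(i) {
    sel <- regions$chrom == calls$chrom[i]
    any(calls$pos[i] - 1L >= regions$start[sel] &
          calls$pos[i] - 1L < regions$end[sel])
  }, logical(1))
}

#' Compare a call set against a truth set
#'
#' A call matches a truth record when chromosome, normalised position,
#' normalised alleles and unphased genotype all agree. Genotype mismatches
#' at a shared site count as one FP and one FN.
#'
#' @param calls,truth [variant_calls()] tables.
#' @param regions optional data.frame (`chrom`, `start`, `end`; 0-based
#'   half-open) restricting the comparison.
#' @return object of class `eval_counts`: `total` (TP/FP/FN) and `by_type`
#'   (3 x 3 matrix over SNP/insertion/deletion).
#' @export
compare_calls <- function(calls, truth, regions = NULL) {
  calls <- calls[in_regions(calls, regions), , drop = FALSE]
  truth <- truth[in_regions(truth, regions), , drop = FALSE]
  ck <- call_keys(calls); tk <- call_keys(truth)
  ct <- call_types(calls); tt <- call_types(truth)
  tp_call <- ck %in% tk
  fn_truth <- !(tk %in% ck)
  types <- c("SNP", "insertion", "deletion")
  by_type <- matrix(0L, 3, 3, dimnames = list(types, c("TP", "FP", "FN")))
  for (ty in types) {
    by_type[ty, "TP"] <- sum(tp_call & ct == ty)
    by_type[ty, "FP"] <- sum(!tp_call & ct == ty)
    by_type[ty, "FN"] <- sum(fn_truth & tt == ty)
  }
  structure(list(
    total = c(TP = sum(tp_call), FP = sum(!tp_call), FN = sum(fn_truth)),
    by_type = by_type,
    n_calls = nrow(calls), n_truth = nrow(truth)), class = "eval_counts")
}

#' @export
print.eval_counts <- function(x, ...) {
  m <- prf1(x)
  cat(sprintf("TP=%d FP=%d FN=%d  precision=%.4f recall=%.4f F1=%.4f\n",
              x$total["TP"], x$total["FP"], x$total["FN"],
              m["precision"], m["recall"], m["F1"]))
  invisible(x)
}

#' Precision, recall and F1
#'
#' `p = TP/(TP+FP)`, `r = TP/(TP+FN)`, `F1 = 2pr/(p+r)`. Degenerate 0/0
#' denominators yield 0, except the fully empty case (no truth, no calls)
#' which yields (1, 1, 1).
#'
#' @param counts an [compare_calls()] result or a numeric vector with
#'   named elements `TP`, `FP`, `FN`.
#' @return named vector `precision`, `recall`, `F1`.
#' @export
prf1 <- function(counts) {
  if (inherits(counts, "eval_counts")) counts <- counts$total
  tp <- counts[["TP"]]; fp <- counts[["FP"]]; fn <- counts[["FN"]]
  if (tp + fp + fn == 0)
    return(c(precision = 1, recall = 1, F1 = 1))
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, F1 = f1)
}
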