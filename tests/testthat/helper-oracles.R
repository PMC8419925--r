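# Independent brute-force oracles used by several test files. These
# deliberately avoid the package's decoded ref_codes path: bases are read
# off the raw sequence through the CIGAR coordinate pairs (computed once
# per read and memoised).

# per-read lookup table: 0-based ref position -> read base character
oracle_read_map <- function(read) {
  p <- aligned_pairs(read)
  p <- p[!is.na(p$ref_pos) & !is.na(p$read_index), , drop = FALSE]
  chars <- strsplit(read$sequence, "", fixed = TRUE)[[1]]
  list(pos = p$ref_pos, base = chars[p$read_index + 1L])
}

oracle_base_at_map <- function(map, pos) {
  hit <- match(pos, map$pos)
  if (is.na(hit)) NA_character_ else map$base[hit]
}

# naive double loop over (read, site) pairs reproducing the SNP tensor;
# each read's base at b and at every window site is looked up through its
# memoised coordinate map
snp_tensor_oracle <- function(nbr, reads, maps = lapply(reads,
                                                        oracle_read_map)) {
  bases <- c("A", "G", "T", "C")
  tns <- array(0, dim = c(5L, 41L, 5L))
  live <- which(!is.na(nbr$pos))
  # per read: base at b followed by bases at the window sites
  site_bases <- vapply(maps, function(m)
    m$base[match(c(nbr$b, nbr$pos[live]), m$pos)],
    character(1L + length(live)))
  at_b <- site_bases[1L, ]
  for (gi in seq_along(bases)) {
    grp <- site_bases[-1L, !is.na(at_b) & at_b == bases[gi], drop = FALSE]
    for (ci in seq_along(live)) {
      site_ref <- nbr$ref_base[live[ci]]
      for (di in seq_along(bases)) {
        cnt <- sum(!is.na(grp[ci, ]) & grp[ci, ] == bases[di])
        sgn <- if (bases[di] == site_ref) -1 else 1
        tns[gi, live[ci], di] <- cnt * sgn
      }
    }
  }
  tns[match(nbr$b_ref, bases), live, 5L] <- 1
  for (col in live)
    tns[5L, col, match(nbr$ref_base[col], bases)] <- 1
  tns
}

# literal restatement of the genotype decision rules
decide_genotype_oracle <- function(probs, ref_base) {
  nm <- names(probs)
  over <- nm[probs > 0.5]
  if (length(over) >= 2) {
    top2 <- nm[order(probs, decreasing = TRUE)][1:2]
    if (ref_base %in% top2)
      list(genotype = "0/1", alt = setdiff(top2, ref_base))
    else list(genotype = "1/2", alt = top2)
  } else {
    best <- nm[which.max(probs)]
    if (best == ref_base) NULL else list(genotype = "1/1", alt = best)
  }
}
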