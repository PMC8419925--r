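# Bundled fixture access.

#' Sanger-validated variant list
#'
#' A bundled list of 41 variants in HG002 validated by Sanger sequencing
#' (25 SNPs, 10 insertions, 6 deletions, including two multiallelic SNPs),
#' useful as a small real-world fixture for the variant classifier and the
#' VCF writer. Two indel rows are kept exactly as printed in the original
#' validation report and are therefore not left-anchored.
#'
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `genotype`.
#' @export
sanger_validated_variants <- function() {
  path <- system.file("extdata", "sanger_validated_variants.tsv",
                      package = "haplocall", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
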