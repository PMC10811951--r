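#' Extract a genotype matrix from a VCF file
#'
#' Minimal VCF ingestion for desk-scale analyses: rows are the biallelic
#' variants in file order, columns the samples in header order. Parsing goes
#' through \code{VariantAnnotation::readVcf}; multiallelic records are
#' skipped (with a reported count) and missing genotypes are set to 0
#' (reference) -- conservative for rare-variant binary matrices -- with a
#' per-site count reported so users can pre-filter.
#'
#' @param path path to a VCF file with GT fields.
#' @param mode \code{"dosage"}: alternate-allele count 0/1/2;
#'   \code{"binary"}: 1 iff any alternate allele is present.
#' @return a \code{\link{genotype_matrix}} (possibly with zero rows if every
#'   record was skipped) with attributes \code{skipped_multiallelic} (count)
#'   and \code{missing_per_site} (integer vector over kept variants).
#' @export
read_vcf_genotypes <- function(path, mode = c("dosage", "binary")) {
  mode <- match.arg(mode)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("the 'VariantAnnotation' package is required to read VCF",
         call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  gt <- tryCatch(VariantAnnotation::geno(vcf)$GT,
                 error = function(e) NULL)
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  n_alt <- lengths(VariantAnnotation::alt(vcf))
  keep <- n_alt <= 1L
  skipped <- sum(!keep)
  if (skipped > 0) {
    message(skipped, " multiallelic record(s) skipped")
  }
  gt <- gt[keep, , drop = FALSE]
  n <- nrow(gt)
  m <- ncol(gt)
  vals <- matrix(0L, n, m)
  missing_per_site <- integer(n)
  if (n > 0 && m > 0) {
    # GT strings like 0/1, 1|1, ., ./.; count "1" alleles, missing -> 0
    alleles <- strsplit(as.character(t(gt)), "[/|]")
    dos <- vapply(alleles, function(a) sum(a == "1"), integer(1L))
    miss <- vapply(alleles, function(a) any(a %in% c(".", "")), logical(1L))
    vals <- matrix(dos, n, m, byrow = TRUE)
    vals[matrix(miss, n, m, byrow = TRUE)] <- 0L
    missing_per_site <- rowSums(matrix(miss, n, m, byrow = TRUE))
    if (any(missing_per_site > 0)) {
      message(sum(missing_per_site), " missing genotype(s) set to 0 across ",
              sum(missing_per_site > 0), " site(s)")
    }
    if (mode == "binary") vals <- 1L * (vals > 0L)
  }
  out <- genotype_matrix(vals,
                         coding = if (mode == "binary") "binary"
                                  else "dosage012",
                         allow_empty = TRUE)
  attr(out, "skipped_multiallelic") <- skipped
  attr(out, "missing_per_site") <- missing_per_site
  out
}
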