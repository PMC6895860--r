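#' Canonical variant identifiers
#'
#' All tables in the pipeline identify a variant by the tuple
#' (chrom, pos, ref, alt) on GRCh37 with 1-based positions. `variant_id()`
#' collapses the tuple into a single string key used for joins and
#' de-duplication; `allele_set_id()` collapses it with the alleles in
#' lexicographic order, which is the key used for base-array manifest
#' matching (alleles compared as an unordered set, no strand flipping).
#'
#' @param chrom Chromosome label ("1".."22", "X", ...).
#' @param pos 1-based position (bp).
#' @param ref,alt Uppercase ACGT allele strings, `ref != alt`.
#' @return Character vector of keys.
#' @examples
#' variant_id("6", 29000000, "A", "G")
#' allele_set_id("6", 29000000, "G", "A") == allele_set_id("6", 29000000, "A", "G")
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' @rdname variant_id
#' @export
allele_set_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, pmin(ref, alt), pmax(ref, alt), sep = ":")
}

#' Validate a table of variant keys
#'
#' Checks the invariants every variant table must satisfy: positions >= 1,
#' non-empty uppercase ACGT alleles, ref different from alt. Returns the
#' input (as a tibble, with uppercased alleles) so it can sit inside a
#' pipe; aborts with the offending rows otherwise.
#'
#' @param x A data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param require_unique Abort if duplicated (chrom,pos,ref,alt) keys exist.
#' @return `x` as a tibble with an added `variant` key column.
#' @export
validate_variant_keys <- function(x, require_unique = FALSE) {
  x <- as_tibble(x)
  needed <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing variant key columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  x$chrom <- as.character(x$chrom)
  x$pos <- as.integer(x$pos)
  x$ref <- toupper(x$ref)
  x$alt <- toupper(x$alt)
  bad <- !is.finite(x$pos) | x$pos < 1L
  if (any(bad)) abort(paste0("positions must be >= 1; first bad row: ",
                             which(bad)[1]))
  ok_allele <- function(a) nzchar(a) & grepl("^[ACGT]+$", a)
  bad <- !ok_allele(x$ref) | !ok_allele(x$alt)
  if (any(bad)) abort(paste0("alleles must be non-empty ACGT strings; first bad row: ",
                             which(bad)[1]))
  if (any(x$ref == x$alt)) {
    abort(paste0("ref == alt at row ", which(x$ref == x$alt)[1]))
  }
  x$variant <- variant_id(x$chrom, x$pos, x$ref, x$alt)
  if (require_unique && anyDuplicated(x$variant) > 0) {
    abort(paste0("duplicate variant keys, e.g. ",
                 x$variant[duplicated(x$variant)][1]))
  }
  x
}
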