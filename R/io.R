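#' Read a reference genotype panel from VCF
#'
#' Parses a VCF 4.x file into a [genotype_panel] backing r-squared
#' computation for one population pool. Multi-allelic records are split
#' into one bi-allelic key per ALT allele (alleles other than the key's
#' ALT are coded as reference) and flagged `triallelic = TRUE`, so the
#' tri-allelic exclusion is an explicit downstream filter rather than a
#' silent drop. The panel is marked phased only if every genotype
#' separator in the file is `|`.
#'
#' @param path Path to a VCF file (plain text or bgzipped).
#' @param population_label Pool label, e.g. `"NFE"`, `"AMR"`, `"AA"`.
#' @return A [genotype_panel].
#' @export
read_panel_vcf <- function(path, population_label) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("malformed VCF '", path, "': ",
                                     conditionMessage(e))),
    warning = function(w) abort(paste0("malformed VCF '", path, "': ",
                                       conditionMessage(w)))
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) abort(paste0("VCF '", path, "' contains no records"))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) abort(paste0("VCF '", path, "' has no GT field"))
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  samples <- colnames(gt)

  gt_chr <- as.vector(gt)
  gt_chr[gt_chr %in% c(".", "./.", ".|.")] <- NA_character_
  non_missing <- gt_chr[!is.na(gt_chr)]
  has_pipe <- grepl("|", non_missing, fixed = TRUE)
  has_slash <- grepl("/", non_missing, fixed = TRUE)
  if (any(!has_pipe & !has_slash)) {
    abort(paste0("mixed ploidy in VCF '", path,
                 "': haploid genotype encountered (record ",
                 which(matrix(!has_pipe & !has_slash, nrow = nrow(gt)),
                       arr.ind = TRUE)[1, 1], ")"))
  }
  phased <- all(has_pipe) && !any(has_slash)

  parts <- strsplit(gt_chr, "[/|]")
  if (any(lengths(parts) != 2 & !is.na(gt_chr))) {
    bad <- which(lengths(parts) != 2 & !is.na(gt_chr))[1]
    abort(paste0("mixed ploidy in VCF '", path, "' at record ",
                 ((bad - 1) %% nrow(gt)) + 1))
  }
  a1 <- suppressWarnings(matrix(as.integer(vapply(
    parts, function(p) if (length(p) == 2) p[1] else NA_character_,
    character(1))), nrow = nrow(gt)))
  a2 <- suppressWarnings(matrix(as.integer(vapply(
    parts, function(p) if (length(p) == 2) p[2] else NA_character_,
    character(1))), nrow = nrow(gt)))

  alt_lists <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_keys <- sum(lengths(alt_lists))
  variants <- vector("list", n_keys)
  hap <- if (phased) matrix(NA_integer_, nrow = 2 * length(samples),
                            ncol = n_keys) else NULL
  geno <- matrix(NA_integer_, nrow = length(samples), ncol = n_keys)
  col <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- alt_lists[[i]]
    for (k in seq_along(alts)) {
      col <- col + 1L
      variants[[col]] <- tibble(
        chrom = as.character(fix[i, "CHROM"]),
        pos = as.integer(fix[i, "POS"]),
        ref = toupper(fix[i, "REF"]),
        alt = toupper(alts[k]),
        triallelic = length(alts) > 1L
      )
      d1 <- as.integer(a1[i, ] == k)
      d2 <- as.integer(a2[i, ] == k)
      geno[, col] <- d1 + d2
      if (phased) {
        hap[, col] <- as.vector(rbind(d1, d2))
      }
    }
  }
  variants <- validate_variant_keys(bind_rows(variants))
  genotype_panel(population = population_label, samples = samples,
                 variants = variants, geno = geno, hap = hap,
                 phased = phased)
}

#' Construct a genotype panel
#'
#' Container for one population pool's sample-by-variant genotype matrix,
#' plus the per-haplotype allele matrix when the data are phased. Built by
#' [read_panel_vcf()] or directly by the fixture generator.
#'
#' @param population Pool label.
#' @param samples Character vector of sample names.
#' @param variants Tibble of variant keys (chrom, pos, ref, alt, and an
#'   optional `triallelic` flag); one row per matrix column.
#' @param geno N x V integer matrix of ALT-allele dosages in {0,1,2,NA}.
#' @param hap 2N x V matrix of haplotype alleles in {0,1,NA}; haplotypes
#'   2i-1 and 2i belong to sample i. `NULL` for unphased panels.
#' @param phased Logical flag.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(population, samples, variants, geno,
                           hap = NULL, phased = !is.null(hap)) {
  variants <- validate_variant_keys(variants, require_unique = TRUE)
  if (!"triallelic" %in% names(variants)) variants$triallelic <- FALSE
  stopifnot(ncol(geno) == nrow(variants), nrow(geno) == length(samples))
  if (phased) {
    stopifnot(!is.null(hap), nrow(hap) == 2 * length(samples),
              ncol(hap) == nrow(variants))
  }
  colnames(geno) <- variants$variant
  if (!is.null(hap)) colnames(hap) <- variants$variant
  structure(
    list(population = population, samples = samples, variants = variants,
         geno = geno, hap = hap, phased = phased),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", x$population, ": ", length(x$samples),
      " samples, ", nrow(x$variants), " variants, ",
      if (x$phased) "phased" else "unphased", "\n", sep = "")
  invisible(x)
}

#' Number of samples and variants in a panel
#' @param panel A [genotype_panel].
#' @return Named integer vector with elements `samples` and `variants`.
#' @export
panel_dim <- function(panel) {
  c(samples = length(panel$samples), variants = nrow(panel$variants))
}

valid_effects <- c("nonsynonymous", "stopgain", "stoploss", "splicing",
                   "synonymous", "other")

#' Read a variant annotation table
#'
#' Tab-separated with header columns chrom, pos, ref, alt, effect, cadd,
#' regulome, afr_maf, amr_maf, nfe_maf, eas_maf (an optional `triallelic`
#' logical column is carried through). Empty cells become missing values;
#' a missing population frequency fails that population's threshold
#' downstream. Minor allele frequencies must lie in [0, 0.5].
#'
#' @param path Path to the TSV file.
#' @return Tibble of annotation records, one per input row.
#' @export
read_annotation_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       na = c("", "NA", "."),
                       col_types = readr::cols(
                         chrom = "c", ref = "c", alt = "c",
                         effect = "c", regulome = "c",
                         .default = readr::col_guess()))
  needed <- c("chrom", "pos", "ref", "alt", "effect", "cadd", "regulome",
              "afr_maf", "amr_maf", "nfe_maf", "eas_maf")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- validate_variant_keys(x)
  x$effect <- as.character(x$effect)
  bad <- !is.na(x$effect) & !x$effect %in% valid_effects
  if (any(bad)) {
    abort(paste0("unknown effect class '", x$effect[bad][1], "'"))
  }
  x$effect[is.na(x$effect)] <- "other"
  for (col in c("afr_maf", "amr_maf", "nfe_maf", "eas_maf")) {
    v <- x[[col]]
    if (any(!is.na(v) & (v < 0 | v > 0.5))) {
      abort(paste0(col, " outside [0, 0.5] at row ",
                   which(!is.na(v) & (v < 0 | v > 0.5))[1]))
    }
  }
  if (any(!is.na(x$cadd) & x$cadd < 0)) abort("negative CADD score")
  if (!"triallelic" %in% names(x)) x$triallelic <- FALSE
  x
}

#' Read an index-signal table
#'
#' One row per index association signal: the variant key, the discovery
#' effect direction (+1/-1), and per-population replication summary
#' statistics as (effect sign, two-sided p) for the Hispanic (AMR) and
#' African American (AA) samples. Missing replication cells are allowed
#' and never satisfy a replication test.
#'
#' @param path Path to a TSV with columns chrom, pos, ref, alt,
#'   discovery_direction, amr_beta_sign, amr_p2, aa_beta_sign, aa_p2.
#' @return Tibble of index signals.
#' @export
read_index_signals <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       na = c("", "NA", "."),
                       col_types = readr::cols(
                         chrom = "c", ref = "c", alt = "c",
                         .default = readr::col_guess()))
  needed <- c("chrom", "pos", "ref", "alt", "discovery_direction",
              "amr_beta_sign", "amr_p2", "aa_beta_sign", "aa_p2")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("index-signal table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- validate_variant_keys(x, require_unique = TRUE)
  for (col in c("discovery_direction", "amr_beta_sign", "aa_beta_sign")) {
    v <- x[[col]]
    if (any(!is.na(v) & !v %in% c(-1, 1))) {
      abort(paste0(col, " must be +1 or -1"))
    }
  }
  for (col in c("amr_p2", "aa_p2")) {
    v <- x[[col]]
    if (any(!is.na(v) & (v <= 0 | v > 1))) {
      abort(paste0(col, " must lie in (0, 1]"))
    }
  }
  x
}

#' Read a base-array manifest
#'
#' @param path TSV with columns chrom, pos, ref, alt and optionally
#'   `source` (array label).
#' @return Tibble of manifest entries with unique keys.
#' @export
read_manifest <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(chrom = "c", ref = "c", alt = "c",
                                               .default = readr::col_guess()))
  x <- validate_variant_keys(x, require_unique = TRUE)
  if (!"source" %in% names(x)) x$source <- "base"
  x
}

#' Read a designability-score table
#'
#' @param path TSV with columns chrom, pos, ref, alt, score (score in
#'   [0, 1], higher is more designable).
#' @return Tibble with a `score` column.
#' @export
read_designability <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       na = c("", "NA", "."),
                       col_types = readr::cols(chrom = "c", ref = "c", alt = "c",
                                               .default = readr::col_guess()))
  x <- validate_variant_keys(x, require_unique = TRUE)
  if (!"score" %in% names(x)) abort("designability table needs a 'score' column")
  x
}

#' Read precomputed imputation INFO scores
#'
#' @param path TSV with columns chrom, pos, ref, alt, info (info in [0, 1]).
#' @return Tibble with an `info` column.
#' @export
read_info_scores <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       na = c("", "NA", "."),
                       col_types = readr::cols(chrom = "c", ref = "c", alt = "c",
                                               .default = readr::col_guess()))
  x <- validate_variant_keys(x, require_unique = TRUE)
  if (!"info" %in% names(x)) abort("INFO table needs an 'info' column")
  if (any(!is.na(x$info) & (x$info < 0 | x$info > 1))) {
    abort("INFO scores must lie in [0, 1]")
  }
  x
}

#' Read per-sample genotype probabilities
#'
#' Long format: one row per variant per sample with the three genotype
#' probabilities (p0, p1, p2) summing to 1 within 1e-6. Input to
#' [compute_info_score()].
#'
#' @param path TSV with columns chrom, pos, ref, alt, sample_id, p0, p1, p2.
#' @return Tibble of genotype-probability records.
#' @export
read_genotype_probs <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(chrom = "c", ref = "c", alt = "c",
                                               .default = readr::col_guess()))
  needed <- c("chrom", "pos", "ref", "alt", "sample_id", "p0", "p1", "p2")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("genotype-probability table missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- validate_variant_keys(x)
  validate_prob_triples(x$p0, x$p1, x$p2)
  x
}

validate_prob_triples <- function(p0, p1, p2, tol = 1e-6) {
  if (any(p0 < 0 | p1 < 0 | p2 < 0, na.rm = TRUE)) {
    abort("genotype probabilities must be non-negative")
  }
  s <- p0 + p1 + p2
  if (any(abs(s - 1) > tol, na.rm = TRUE)) {
    abort(paste0("genotype probability triple does not sum to 1 (row ",
                 which(abs(s - 1) > tol)[1], ")"))
  }
  invisible(TRUE)
}

#' Write (and re-read) a selection table
#'
#' Writes selection records as TSV (key columns plus arm, criteria,
#' region id and bead count) together with a plain-text funnel summary in
#' a sibling `<path>.summary.txt`, mirroring the workflow's per-stage
#' counts. `read_selection()` round-trips the TSV.
#'
#' @param records Tibble of selection records with unique variant keys.
#' @param path Output TSV path.
#' @param funnel Optional funnel tibble (columns `stage`, `n_out`) from
#'   [run_design()]; when absent a minimal summary (per-arm and total
#'   counts) is written.
#' @return `path`, invisibly.
#' @export
write_selection <- function(records, path, funnel = NULL) {
  records <- validate_variant_keys(records, require_unique = TRUE)
  cols <- c("variant", "chrom", "pos", "ref", "alt", "arm", "criteria",
            "region_id", "bead_count")
  for (col in setdiff(cols, names(records))) records[[col]] <- NA
  readr::write_tsv(records[cols], path, progress = FALSE)

  summary_path <- paste0(path, ".summary.txt")
  lines <- c("custom-content selection funnel", "")
  if (!is.null(funnel)) {
    lines <- c(lines, sprintf("%-48s %10d", funnel$stage,
                              as.integer(funnel$n_out)))
  } else {
    by_arm <- records |> count(arm)
    lines <- c(lines,
               sprintf("%-48s %10d", paste0("arm: ", by_arm$arm), by_arm$n),
               sprintf("%-48s %10d", "total variants", nrow(records)),
               sprintf("%-48s %10d", "total bead types",
                       as.integer(sum(records$bead_count, na.rm = TRUE))))
  }
  writeLines(lines, summary_path)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(chrom = "c", ref = "c", alt = "c",
                                               .default = readr::col_guess()))
  validate_variant_keys(x, require_unique = TRUE)
}

#' Export variants or regions as BED
#'
#' Converts from the package's 1-based inclusive coordinates to BED's
#' 0-based half-open convention. For variant tables the interval covers
#' the reference allele; for region tables the full region span.
#'
#' @param x Tibble with either variant keys or `chrom`/`start`/`end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  if (all(c("start", "end") %in% names(x))) {
    bed <- tibble(chrom = x$chrom, start0 = x$start - 1L, end0 = x$end,
                  name = if ("region_id" %in% names(x)) x$region_id else ".")
  } else {
    x <- validate_variant_keys(x)
    bed <- tibble(chrom = x$chrom, start0 = x$pos - 1L,
                  end0 = x$pos - 1L + nchar(x$ref), name = x$variant)
  }
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
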