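# Small in-code fixtures shared across test files.

write_tiny_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

tiny_vcf_lines <- function(gts, chrom = "1", pos = NULL, ref = "A",
                           alt = "G", samples = NULL) {
  # gts: character matrix, rows = records, cols = samples
  gts <- as.matrix(gts)
  n_rec <- nrow(gts)
  if (is.null(pos)) pos <- seq(100, by = 100, length.out = n_rec)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(gts)))
  chrom <- rep_len(chrom, n_rec)
  ref <- rep_len(ref, n_rec)
  alt <- rep_len(alt, n_rec)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(n_rec), function(i) {
    paste(c(chrom[i], pos[i], ".", ref[i], alt[i], ".", "PASS", ".",
            "GT", gts[i, ]), collapse = "\t")
  }, character(1))
  c(header, body)
}

# a signal row as classify_replication_status() would emit it
status_signal <- function(status, pop = NA_character_, chrom = "1",
                          pos = 5000000L) {
  tibble::tibble(chrom = chrom, pos = pos, ref = "A", alt = "G",
                 variant = paste(chrom, pos, "A", "G", sep = ":"),
                 status = status, status_pop = pop)
}

# panel with exact planted haplotype structure: index plus candidates at
# given r2 values, one chromosome
planted_panel <- function(r2_targets, n_hap = 800, pop = "NFE", seed = 7,
                          chrom = "1", base_pos = 5000000L,
                          p_index = 0.5, p_cand = 0.5) {
  withr::with_seed(seed, {
    idx <- stats::rbinom(n_hap, 1, p_index)
    hap <- cbind(idx)
    keys <- tibble::tibble(chrom = chrom, pos = base_pos, ref = "A", alt = "G")
    for (k in seq_along(r2_targets)) {
      # conditional draw against the shared index haplotypes
      d <- sqrt(r2_targets[k] * p_index * (1 - p_index) * p_cand * (1 - p_cand))
      pb1 <- (p_index * p_cand + d) / p_index
      pb0 <- ((1 - p_index) * p_cand - d) / (1 - p_index)
      u <- stats::runif(n_hap)
      hap <- cbind(hap, as.integer(u < ifelse(idx == 1, pb1, pb0)))
      keys <- dplyr::bind_rows(keys, tibble::tibble(
        chrom = chrom, pos = base_pos + 1000L * k, ref = "A", alt = "G"))
    }
    geno <- hap[seq(1, n_hap, 2), , drop = FALSE] +
      hap[seq(2, n_hap, 2), , drop = FALSE]
    finearray::genotype_panel(
      population = pop,
      samples = paste0(pop, seq_len(n_hap / 2)),
      variants = keys, geno = geno, hap = hap, phased = TRUE)
  })
}
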