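#' Filter selection records by designability score
#'
#' Array probe design tools score each variant's design ability; records
#' scoring below `min_score` cannot be assayed reliably and are dropped.
#' Records with no score in the table are dropped with a warning.
#'
#' @param records Selection-record tibble.
#' @param scores Designability tibble (variant keys + `score`).
#' @param min_score Inclusive lower bound (default 0.5).
#' @return Filtered records (score column added).
#' @export
filter_designable <- function(records, scores, min_score = 0.5) {
  records <- validate_variant_keys(records)
  scores <- validate_variant_keys(scores, require_unique = TRUE)
  out <- records |>
    left_join(scores |> select(variant, score), by = "variant")
  n_missing <- sum(is.na(out$score))
  if (n_missing > 0) {
    warn(paste0(n_missing, " record(s) without designability score dropped"))
  }
  out |> filter(!is.na(score), score >= min_score)
}

#' Partition records into priority and prunable sets
#'
#' Priority content is kept unconditionally: everything from the
#' coding/regulatory arm plus fine-mapping records whose index signal
#' replicated in at least one sample (status BOTH or ONE). Fine-mapping
#' records for OPPOSITE or NONE signals form the prunable set subjected
#' to INFO-score pruning. The partition is exhaustive and disjoint.
#'
#' @param records Selection-record tibble with `arm` and, for
#'   fine-mapping records, `status`.
#' @return List with tibbles `priority` and `prunable`.
#' @export
partition_priority <- function(records) {
  if (nrow(records) == 0) {
    return(list(priority = records, prunable = records))
  }
  # arm may carry merged provenance like "coding_regulatory+fine_mapping"
  is_priority <- grepl("coding_regulatory", records$arm, fixed = TRUE) |
    (grepl("fine_mapping", records$arm, fixed = TRUE) &
       !is.na(records$status) & records$status %in% c("BOTH", "ONE"))
  list(priority = records |> filter(is_priority) |> mutate(priority = TRUE),
       prunable = records |> filter(!is_priority) |> mutate(priority = FALSE))
}

#' Imputation INFO score from genotype probabilities
#'
#' The ratio-of-variances imputation information measure. For each sample
#' i with genotype probabilities (p0, p1, p2), let e_i = p1 + 2 p2 (the
#' expected dosage) and f_i = p1 + 4 p2. With estimated allele frequency
#' theta = sum(e_i) / (2N):
#' \deqn{info = 1 - \frac{\sum_i (f_i - e_i^2)}{2N\,\theta(1-\theta)}}
#' info is 1 by convention when theta is 0 or 1, and is clamped to
#' [0, 1]. Hard-called genotypes (unit-vector triples) give exactly 1.
#'
#' @param probs Genotype-probability tibble (see [read_genotype_probs()]):
#'   columns chrom, pos, ref, alt, sample_id, p0, p1, p2.
#' @return Tibble of variant keys with an `info` column.
#' @export
compute_info_score <- function(probs) {
  probs <- validate_variant_keys(probs)
  validate_prob_triples(probs$p0, probs$p1, probs$p2)
  probs |>
    mutate(e = p1 + 2 * p2, f = p1 + 4 * p2) |>
    group_by(chrom, pos, ref, alt, variant) |>
    summarise(info = info_from_moments(e, f), .groups = "drop")
}

info_from_moments <- function(e, f) {
  n <- length(e)
  theta <- sum(e) / (2 * n)
  if (theta <= 0 || theta >= 1) return(1)
  info <- 1 - sum(f - e^2) / (2 * n * theta * (1 - theta))
  min(max(info, 0), 1)
}

#' Infinium bead-type count for a variant
#'
#' Strand-ambiguous SNPs (A/T or C/G allele pairs) and indels (either
#' allele longer than one base) need the two-bead Infinium I assay; all
#' other SNPs use one bead type (Infinium II).
#'
#' @param ref,alt Allele strings.
#' @return Integer vector of bead counts (1 or 2).
#' @export
count_bead_types <- function(ref, alt) {
  ambiguous <- (ref == "A" & alt == "T") | (ref == "T" & alt == "A") |
    (ref == "C" & alt == "G") | (ref == "G" & alt == "C")
  indel <- nchar(ref) != 1L | nchar(alt) != 1L
  ifelse(ambiguous | indel, 2L, 1L)
}

#' Search the INFO threshold meeting a bead budget
#'
#' The prunable set is reduced by excluding variants whose INFO score
#' exceeds a threshold t — well-imputed variants are the ones an array
#' can afford to leave off — so retained(t) = records with info <= t.
#' The threshold is searched on the grid of observed INFO values (plus a
#' retain-none sentinel, reported as 0) for the largest t such that
#' priority beads plus beads(retained(t)) fit the budget. Records with
#' missing INFO are treated as info = 0 (never excludable) with a
#' warning.
#'
#' @param prunable Prunable records with an `info` column and allele
#'   columns for bead accounting.
#' @param priority_beads Bead types already committed to priority content.
#' @param budget Maximum total bead types (positive integer).
#' @return List: `threshold`, `retained` (tibble), `n_retained`,
#'   `beads_retained`, `retain_all` flag.
#' @export
find_info_threshold <- function(prunable, priority_beads, budget) {
  stopifnot(budget > 0, priority_beads >= 0)
  if (priority_beads > budget) {
    abort(paste0("priority content alone needs ", priority_beads,
                 " bead types but the budget is ", budget))
  }
  if (nrow(prunable) == 0) {
    return(list(threshold = 0, retained = prunable, n_retained = 0L,
                beads_retained = 0L, retain_all = TRUE))
  }
  prunable <- validate_variant_keys(prunable)
  if (!"info" %in% names(prunable)) abort("prunable records need 'info'")
  if (anyNA(prunable$info)) {
    warn(paste0(sum(is.na(prunable$info)),
                " prunable record(s) without INFO treated as 0"))
    prunable$info[is.na(prunable$info)] <- 0
  }
  if (!"bead_count" %in% names(prunable)) {
    prunable$bead_count <- count_bead_types(prunable$ref, prunable$alt)
  }
  grid <- sort(unique(prunable$info))
  beads_at <- vapply(grid, function(t) {
    sum(prunable$bead_count[prunable$info <= t])
  }, numeric(1))
  fits <- priority_beads + beads_at <= budget
  if (!any(fits)) {
    return(list(threshold = 0, retained = prunable[0, ], n_retained = 0L,
                beads_retained = 0L, retain_all = FALSE))
  }
  t_best <- max(grid[fits])
  retained <- prunable |> filter(info <= t_best)
  list(threshold = t_best, retained = retained,
       n_retained = nrow(retained),
       beads_retained = sum(retained$bead_count),
       retain_all = t_best == max(grid))
}

#' Assemble the final custom content
#'
#' Union of the priority set and the INFO-retained prunable set, with
#' bead accounting. The two sets must be disjoint; counts and bead totals
#' are additive by construction and verified.
#'
#' @param priority,retained Selection-record tibbles.
#' @return List: `selection` (final tibble with `bead_count` and
#'   `priority` flag), `n_variants`, `n_bead_types`.
#' @export
assemble_final <- function(priority, retained) {
  if (length(intersect(priority$variant, retained$variant)) > 0) {
    abort("priority and retained sets overlap")
  }
  add_beads <- function(x, flag) {
    if (nrow(x) == 0) {
      x$bead_count <- integer(0)
      x$priority <- logical(0)
      return(x)
    }
    if (!"bead_count" %in% names(x)) {
      x$bead_count <- count_bead_types(x$ref, x$alt)
    }
    x$priority <- flag
    x
  }
  final <- bind_rows(add_beads(priority, TRUE), add_beads(retained, FALSE))
  stopifnot(nrow(final) == nrow(priority) + nrow(retained))
  list(selection = final, n_variants = nrow(final),
       n_bead_types = sum(final$bead_count))
}
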