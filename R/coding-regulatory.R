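#' Population frequency thresholds for the coding/regulatory arm
#'
#' The frequency gate keeps a variant when its minor allele frequency
#' strictly exceeds the threshold in at least one population: AFR > 0.01,
#' AMR > 0.01, NFE > 0.05 or EAS > 0.05 by default. The lower bound for
#' AFR and AMR reflects the design's focus on power in African American
#' and Hispanic samples. A missing frequency never satisfies a threshold.
#'
#' @param afr,amr,nfe,eas Strict lower MAF bounds, each in (0, 0.5).
#' @return Named list of thresholds.
#' @export
freq_thresholds <- function(afr = 0.01, amr = 0.01, nfe = 0.05, eas = 0.05) {
  th <- list(afr = afr, amr = amr, nfe = nfe, eas = eas)
  if (any(unlist(th) <= 0 | unlist(th) >= 0.5)) {
    abort("frequency thresholds must lie in (0, 0.5)")
  }
  th
}

#' Coding/regulatory selection predicates
#'
#' Vectorised predicates over annotation records:
#' `passes_frequency_filter()` is the disjunctive population-frequency
#' gate; `is_included_effect()` keeps nonsynonymous, stop-gain/loss and
#' splicing variants; `passes_cadd()` keeps CADD phred >= 30 (top 0.1%
#' most deleterious, inclusive bound); `passes_regulome()` keeps
#' RegulomeDB categories 1a-1e (eQTL plus transcription-factor-binding
#' evidence). Missing annotation never passes.
#'
#' @param annotations Annotation tibble (see [read_annotation_table()]).
#' @param thresholds A [freq_thresholds()] list.
#' @param min_cadd Inclusive CADD phred bound.
#' @param categories RegulomeDB categories counted as regulatory.
#' @return Logical vector, one element per annotation row.
#' @export
passes_frequency_filter <- function(annotations, thresholds = freq_thresholds()) {
  gt <- function(v, t) !is.na(v) & v > t
  gt(annotations$afr_maf, thresholds$afr) |
    gt(annotations$amr_maf, thresholds$amr) |
    gt(annotations$nfe_maf, thresholds$nfe) |
    gt(annotations$eas_maf, thresholds$eas)
}

#' @rdname passes_frequency_filter
#' @export
is_included_effect <- function(annotations) {
  annotations$effect %in% c("nonsynonymous", "stopgain", "stoploss", "splicing")
}

#' @rdname passes_frequency_filter
#' @export
passes_cadd <- function(annotations, min_cadd = 30) {
  !is.na(annotations$cadd) & annotations$cadd >= min_cadd
}

#' @rdname passes_frequency_filter
#' @export
passes_regulome <- function(annotations,
                            categories = c("1a", "1b", "1c", "1d", "1e")) {
  !is.na(annotations$regulome) & annotations$regulome %in% categories
}

#' Select coding/regulatory custom content
#'
#' The first arm of the design: within the fine-mapping regions and the
#' MHC, keep variants that pass the population frequency gate and meet at
#' least one of the three prioritisation criteria (included effect class,
#' CADD >= 30, RegulomeDB 1a-1e), then drop variants already on the base
#' array (matched by position plus unordered allele set) and tri-allelic
#' variants. A variant satisfying several criteria is emitted once with
#' multi-tag provenance, so per-criterion counts remain computable.
#'
#' @param annotations Annotation tibble.
#' @param regions Region tibble including the MHC row
#'   (`bind_rows(build_regions(signals), mhc_region())`).
#' @param manifest Base-array manifest tibble (or `NULL` for none).
#' @param thresholds [freq_thresholds()] list.
#' @param min_cadd,categories Criterion parameters, see
#'   [passes_frequency_filter()].
#' @return Tibble of selection records: variant keys, `region_id`,
#'   `arm = "coding_regulatory"`, logical columns `crit_effect`,
#'   `crit_cadd`, `crit_regulome` and a collapsed `criteria` tag.
#' @export
select_coding_regulatory <- function(annotations, regions, manifest = NULL,
                                     thresholds = freq_thresholds(),
                                     min_cadd = 30,
                                     categories = c("1a", "1b", "1c", "1d", "1e")) {
  annotations <- validate_variant_keys(annotations)
  if (!"triallelic" %in% names(annotations)) annotations$triallelic <- FALSE

  in_region <- annotations |>
    inner_join(regions |> select(region_id, chrom, start, end),
               by = join_by(chrom, between(pos, start, end))) |>
    distinct(variant, .keep_all = TRUE) |>
    select(-start, -end)

  hits <- in_region |>
    mutate(
      crit_effect = is_included_effect(in_region),
      crit_cadd = passes_cadd(in_region, min_cadd),
      crit_regulome = passes_regulome(in_region, categories),
      freq_ok = passes_frequency_filter(in_region, thresholds)
    ) |>
    filter(freq_ok, crit_effect | crit_cadd | crit_regulome, !triallelic) |>
    select(-freq_ok)

  if (!is.null(manifest) && nrow(manifest) > 0) {
    manifest <- validate_variant_keys(manifest)
    hits <- hits |>
      filter(!allele_set_id(chrom, pos, ref, alt) %in%
               allele_set_id(manifest$chrom, manifest$pos,
                             manifest$ref, manifest$alt))
  }

  hits |>
    mutate(
      arm = "coding_regulatory",
      criteria = pmap_chr_criteria(crit_effect, crit_cadd, crit_regulome)
    ) |>
    select(chrom, pos, ref, alt, variant, region_id, arm,
           crit_effect, crit_cadd, crit_regulome, criteria)
}

pmap_chr_criteria <- function(effect, cadd, regulome) {
  vapply(seq_along(effect), function(i) {
    paste(c("effect", "cadd", "regulome")[c(effect[i], cadd[i], regulome[i])],
          collapse = "+")
  }, character(1))
}
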