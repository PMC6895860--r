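#' Assemble a pipeline configuration
#'
#' Collects every input and threshold of the content-selection workflow.
#' Inputs may be given as file paths (read with the package's readers) or
#' as already-loaded objects (tibbles / [genotype_panel]s), which is how
#' the test-suite drives the pipeline. Every threshold defaults to the
#' design's published value; each is overridable because at least one
#' (the INFO bound) was by construction an arbitrary budget-matching
#' choice.
#'
#' @param signals Index-signal table (path or tibble).
#' @param panels Named list (NFE, AMR, AA) of VCF paths or
#'   [genotype_panel]s.
#' @param annotations Annotation table (path or tibble).
#' @param manifest Base-array manifest (path, tibble, or NULL).
#' @param designability Designability scores (path, tibble, or NULL to
#'   skip the filter).
#' @param info INFO scores (path, tibble, or NULL; needed only when the
#'   bead budget forces pruning).
#' @param bead_budget Maximum total bead types (`Inf` = no pruning).
#' @param flank Region flank in bp (1 Mb).
#' @param r2_threshold Inclusive LD bound (0.1).
#' @param freq [freq_thresholds()] list.
#' @param min_cadd Inclusive CADD phred bound (30).
#' @param regulome_categories RegulomeDB categories counted regulatory.
#' @param p_one_max,p_two_opposite_max Replication thresholds (0.05, 0.10).
#' @param designability_min Inclusive designability bound (0.5).
#' @param apply_frequency_filter_fine_mapping Also apply the population
#'   frequency gate to the fine-mapping arm (off by default: the gate
#'   belongs to the coding/regulatory arm).
#' @param precedence Replication-status precedence order.
#' @param ld_method `"auto"`, `"phased"` or `"em"`.
#' @return A `design_config` list.
#' @export
design_config <- function(signals, panels, annotations, manifest = NULL,
                          designability = NULL, info = NULL,
                          bead_budget = Inf, flank = 1e6,
                          r2_threshold = 0.1,
                          freq = freq_thresholds(), min_cadd = 30,
                          regulome_categories = c("1a", "1b", "1c", "1d", "1e"),
                          p_one_max = 0.05, p_two_opposite_max = 0.10,
                          designability_min = 0.5,
                          apply_frequency_filter_fine_mapping = FALSE,
                          precedence = c("BOTH", "OPPOSITE", "ONE", "NONE"),
                          ld_method = "auto") {
  structure(list(
    signals = signals, panels = panels, annotations = annotations,
    manifest = manifest, designability = designability, info = info,
    bead_budget = bead_budget, flank = flank, r2_threshold = r2_threshold,
    freq = freq, min_cadd = min_cadd,
    regulome_categories = regulome_categories,
    p_one_max = p_one_max, p_two_opposite_max = p_two_opposite_max,
    designability_min = designability_min,
    apply_frequency_filter_fine_mapping =
      isTRUE(apply_frequency_filter_fine_mapping),
    precedence = precedence, ld_method = ld_method
  ), class = "design_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [design_config()]; `panels` is a mapping
#' from pool label to VCF path.
#'
#' @param path YAML file.
#' @return A `design_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(design_config)))]
  if (!is.null(args$freq)) args$freq <- do.call(freq_thresholds, args$freq)
  do.call(design_config, args)
}

#' Validate a pipeline configuration
#'
#' @param config A `design_config`.
#' @return Tibble of violations (`field`, `constraint`); zero rows when
#'   the configuration is usable.
#' @export
validate_config <- function(config) {
  v <- list()
  bad <- function(field, constraint) {
    v[[length(v) + 1]] <<- tibble(field = field, constraint = constraint)
  }
  num_in <- function(x, lo, hi) is.numeric(x) && length(x) == 1 &&
    !is.na(x) && x >= lo && x <= hi
  if (!num_in(config$r2_threshold, 0, 1)) {
    bad("r2_threshold", "must lie in [0, 1]")
  }
  if (!num_in(config$p_one_max, 0, 1) || config$p_one_max == 0) {
    bad("p_one_max", "must lie in (0, 1]")
  }
  if (!num_in(config$p_two_opposite_max, 0, 1) ||
      config$p_two_opposite_max == 0) {
    bad("p_two_opposite_max", "must lie in (0, 1]")
  }
  if (!is.numeric(config$min_cadd) || config$min_cadd < 0) {
    bad("min_cadd", "must be non-negative")
  }
  if (!num_in(config$designability_min, 0, 1)) {
    bad("designability_min", "must lie in [0, 1]")
  }
  if (!(is.numeric(config$bead_budget) && config$bead_budget > 0)) {
    bad("bead_budget", "must be positive")
  }
  if (!is.numeric(config$flank) || config$flank <= 0) {
    bad("flank", "must be positive")
  }
  th <- tryCatch(do.call(freq_thresholds, config$freq), error = identity)
  if (inherits(th, "error")) bad("freq", conditionMessage(th))
  if (length(config$regulome_categories) == 0) {
    bad("regulome_categories", "must be non-empty")
  }
  if (!setequal(config$precedence, c("BOTH", "OPPOSITE", "ONE", "NONE"))) {
    bad("precedence", "must order BOTH, OPPOSITE, ONE, NONE")
  }
  if (is.null(config$panels) || is.null(names(config$panels)) ||
      !all(c("NFE", "AMR", "AA") %in% names(config$panels))) {
    bad("panels", "must name NFE, AMR and AA panels")
  } else {
    for (p in names(config$panels)) {
      x <- config$panels[[p]]
      if (is.character(x) && !file.exists(x)) {
        bad(paste0("panels$", p), paste0("file not found: ", x))
      }
    }
  }
  for (field in c("signals", "annotations", "manifest", "designability",
                  "info")) {
    x <- config[[field]]
    if (is.character(x) && !file.exists(x)) {
      bad(field, paste0("file not found: ", x))
    }
  }
  if (is.null(config$signals)) bad("signals", "required input")
  if (is.null(config$annotations)) bad("annotations", "required input")
  if (length(v) == 0) {
    tibble(field = character(), constraint = character())
  } else {
    bind_rows(v)
  }
}

load_input <- function(x, reader, ...) {
  if (is.null(x) || is.data.frame(x)) return(x)
  if (is.character(x)) return(reader(x, ...))
  x
}

load_panel_input <- function(x, label) {
  if (inherits(x, "genotype_panel")) return(x)
  read_panel_vcf(x, label)
}

#' Run the full content-selection workflow
#'
#' Executes the complete cascade: region building around index signals
#' (plus the fixed MHC window), the coding/regulatory arm, replication
#' classification and the status-conditional LD arm, union of the two
#' arms with merged provenance, designability filtering, priority
#' partitioning, INFO pruning against the bead budget, final assembly and
#' bead-type accounting. Per-stage in/out counts are recorded in a
#' nine-stage funnel. Deterministic given its inputs.
#'
#' @param config A `design_config` (see [design_config()]).
#' @return A `design_result`: list with `selection` (final records),
#'   `funnel` (stage counts), `regions`, `statuses`, `partition` sizes,
#'   `info_threshold`, `n_variants`, `n_bead_types`, `config`.
#' @export
run_design <- function(config) {
  violations <- validate_config(config)
  if (nrow(violations) > 0) {
    abort(paste0("invalid config: ", violations$field[1], " ",
                 violations$constraint[1]))
  }
  signals <- load_input(config$signals, read_index_signals)
  annotations <- load_input(config$annotations, read_annotation_table)
  manifest <- load_input(config$manifest, read_manifest)
  designability <- load_input(config$designability, read_designability)
  info <- load_input(config$info, read_info_scores)
  panels <- imap(config$panels, load_panel_input)

  funnel <- list()
  log_stage <- function(stage, n_in, n_out) {
    funnel[[length(funnel) + 1]] <<- tibble(stage = stage,
                                            n_in = as.integer(n_in),
                                            n_out = as.integer(n_out))
  }

  ## stage 1: regions
  regions <- build_regions(signals, flank = config$flank)
  regions_all <- bind_rows(regions, mhc_region())
  log_stage("regions built (incl. MHC)", nrow(signals), nrow(regions_all))

  ## stage 2: coding/regulatory arm
  cr <- tryCatch(
    select_coding_regulatory(annotations, regions_all, manifest,
                             thresholds = do.call(freq_thresholds,
                                                  config$freq),
                             min_cadd = config$min_cadd,
                             categories = config$regulome_categories),
    error = function(e) abort(paste0("coding/regulatory stage: ",
                                     conditionMessage(e)))
  )
  log_stage("coding/regulatory arm selected", nrow(annotations), nrow(cr))

  ## stage 3-4: fine-mapping arm (autosomal non-MHC signals only)
  statuses <- classify_replication_status(
    signals, p_one_max = config$p_one_max,
    p_two_opposite_max = config$p_two_opposite_max,
    precedence = config$precedence)
  mhc <- mhc_region()
  in_mhc <- statuses$chrom == mhc$chrom &
    statuses$pos >= mhc$start & statuses$pos <= mhc$end
  fm_signals <- statuses |> filter(!in_mhc)

  region_of <- assign_to_regions(fm_signals, regions) |>
    select(variant, region_id)
  fm_signals <- fm_signals |> left_join(region_of, by = "variant")

  candidate_keys <- unique(unlist(map(panels, function(p) {
    assign_to_regions(p$variants, regions) |>
      filter(!is.na(region_id)) |>
      pull(variant)
  })))
  log_stage("fine-mapping candidates in regions",
            sum(map_int(panels, ~ nrow(.x$variants))),
            length(candidate_keys))

  fm <- map(seq_len(nrow(fm_signals)), function(i) {
    sig <- fm_signals[i, ]
    reg <- regions |> filter(region_id == sig$region_id)
    select_fine_mapping_variants(sig, panels, reg, manifest,
                                 threshold = config$r2_threshold,
                                 method = config$ld_method)
  }) |> bind_rows()

  if (config$apply_frequency_filter_fine_mapping && nrow(fm) > 0) {
    ann2 <- validate_variant_keys(annotations)
    ann_pass <- ann2$variant[
      passes_frequency_filter(ann2, do.call(freq_thresholds, config$freq))]
    fm <- fm |> filter(variant %in% ann_pass)
  }
  # one record per variant per arm: a variant near two signals keeps the
  # record with the larger provenance (first occurrence after sorting)
  fm <- fm |> arrange(variant, signal) |> distinct(variant, .keep_all = TRUE)
  log_stage("fine-mapping arm selected (LD criteria)",
            length(candidate_keys), nrow(fm))

  ## stage 5: union of arms with merged provenance
  both <- bind_rows(
    cr |> mutate(signal = NA_character_, status = NA_character_,
                 status_pop = NA_character_, pools_held = NA_character_),
    fm |> mutate(crit_effect = NA, crit_cadd = NA, crit_regulome = NA,
                 criteria = NA_character_)
  )
  union_sel <- both |>
    group_by(chrom, pos, ref, alt, variant) |>
    summarise(
      arm = paste(sort(unique(arm)), collapse = "+"),
      region_id = first(region_id),
      criteria = first(stats::na.omit(criteria), default = NA_character_),
      crit_effect = any(crit_effect, na.rm = TRUE),
      crit_cadd = any(crit_cadd, na.rm = TRUE),
      crit_regulome = any(crit_regulome, na.rm = TRUE),
      signal = first(stats::na.omit(signal), default = NA_character_),
      status = first(stats::na.omit(status), default = NA_character_),
      status_pop = first(stats::na.omit(status_pop),
                         default = NA_character_),
      pools_held = first(stats::na.omit(pools_held),
                         default = NA_character_),
      .groups = "drop"
    ) |>
    mutate(criteria = ifelse(is.na(criteria) & !is.na(status),
                             paste0(status, ":", pools_held), criteria))
  log_stage("arms merged (unique variants)", nrow(both), nrow(union_sel))

  ## stage 6: designability
  designable <- if (is.null(designability)) {
    union_sel |> mutate(score = NA_real_)
  } else {
    filter_designable(union_sel, designability,
                      min_score = config$designability_min)
  }
  log_stage("designable variants", nrow(union_sel), nrow(designable))

  ## stage 7: priority partition
  parts <- partition_priority(designable)
  log_stage("priority content (coding/regulatory or replicated-signal LD)",
            nrow(designable), nrow(parts$priority))

  ## stage 8: INFO pruning of the remainder
  parts$priority <- parts$priority |>
    mutate(bead_count = count_bead_types(ref, alt))
  parts$prunable <- parts$prunable |>
    mutate(bead_count = count_bead_types(ref, alt))
  priority_beads <- sum(parts$priority$bead_count)
  pruning <- if (is.infinite(config$bead_budget)) {
    list(threshold = NA_real_, retained = parts$prunable,
         n_retained = nrow(parts$prunable),
         beads_retained = sum(parts$prunable$bead_count),
         retain_all = TRUE)
  } else {
    prunable <- parts$prunable
    if (!is.null(info)) {
      prunable <- prunable |>
        left_join(info |> select(variant, info), by = "variant")
    } else {
      prunable$info <- NA_real_
    }
    find_info_threshold(prunable, priority_beads, config$bead_budget)
  }
  log_stage("prunable variants retained after INFO pruning",
            nrow(parts$prunable), pruning$n_retained)

  ## stage 9: final assembly + bead accounting
  final <- assemble_final(parts$priority, pruning$retained)
  log_stage("final custom content (variants)",
            nrow(parts$priority) + pruning$n_retained, final$n_variants)

  structure(list(
    selection = final$selection |> arrange(chrom, pos, ref, alt),
    funnel = bind_rows(funnel),
    regions = regions_all,
    statuses = statuses,
    partition = c(priority = nrow(parts$priority),
                  prunable = nrow(parts$prunable),
                  retained = pruning$n_retained),
    info_threshold = pruning$threshold,
    n_variants = final$n_variants,
    n_bead_types = final$n_bead_types,
    config = config
  ), class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("<design_result> ", x$n_variants, " variants, ", x$n_bead_types,
      " bead types\n", sep = "")
  f <- x$funnel
  cat(sprintf("  %-52s %8d -> %8d\n", f$stage, f$n_in, f$n_out), sep = "")
  invisible(x)
}
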