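#' One-sided replication p-value
#'
#' Published replication statistics are typically two-sided; the
#' status classification works on a one-sided scale testing the
#' discovery direction. With a two-sided p and the replication effect
#' sign: p_one = p_two / 2 when the sign matches discovery, and
#' 1 - p_two / 2 when it is opposite.
#'
#' @param p_two Two-sided p-values in (0, 1] (NA allowed).
#' @param same_direction Logical: replication sign equals discovery sign.
#' @return One-sided p-values (NA where inputs are missing).
#' @export
one_sided_p <- function(p_two, same_direction) {
  ifelse(is.na(p_two) | is.na(same_direction), NA_real_,
         ifelse(same_direction, p_two / 2, 1 - p_two / 2))
}

#' Classify replication status of index signals
#'
#' Each signal is classed from its Hispanic (AMR) and African American
#' (AA) replication records:
#' * `BOTH` — one-sided p <= `p_one_max` in both populations;
#' * `OPPOSITE` — significant opposite-direction effect (two-sided
#'   p <= `p_two_opposite_max` with sign opposite to discovery) in a
#'   population;
#' * `ONE` — one-sided p <= `p_one_max` in exactly one population;
#' * `NONE` — otherwise.
#'
#' Precedence is BOTH > OPPOSITE > ONE > NONE (configurable): a signal
#' replicating in both samples is BOTH even if one record would also
#' qualify as opposite, and evidence of LD-structure divergence
#' (OPPOSITE) outranks single-sample replication because it triggers the
#' more permissive OR LD rule. Missing data in a population never
#' satisfies any test. If both populations qualify for the same
#' population-specific class, the one with the smaller p is recorded.
#'
#' @param signals Index-signal tibble (see [read_index_signals()]).
#' @param p_one_max One-sided replication threshold (default 0.05).
#' @param p_two_opposite_max Two-sided opposite-effect threshold (0.10).
#' @param precedence Order in which classes claim a signal.
#' @return `signals` with `status` (`"BOTH"`, `"OPPOSITE"`, `"ONE"`,
#'   `"NONE"`), `status_pop` (`"AMR"`/`"AA"`/NA), and the derived
#'   one-sided p columns `amr_p1`, `aa_p1`.
#' @export
classify_replication_status <- function(signals, p_one_max = 0.05,
                                        p_two_opposite_max = 0.10,
                                        precedence = c("BOTH", "OPPOSITE",
                                                       "ONE", "NONE")) {
  stopifnot(setequal(precedence, c("BOTH", "OPPOSITE", "ONE", "NONE")))
  signals <- validate_variant_keys(signals, require_unique = TRUE)
  amr_same <- signals$amr_beta_sign == signals$discovery_direction
  aa_same <- signals$aa_beta_sign == signals$discovery_direction
  amr_p1 <- one_sided_p(signals$amr_p2, amr_same)
  aa_p1 <- one_sided_p(signals$aa_p2, aa_same)

  rep_amr <- !is.na(amr_p1) & amr_p1 <= p_one_max
  rep_aa <- !is.na(aa_p1) & aa_p1 <= p_one_max
  opp_amr <- !is.na(signals$amr_p2) & !is.na(amr_same) & !amr_same &
    signals$amr_p2 <= p_two_opposite_max
  opp_aa <- !is.na(signals$aa_p2) & !is.na(aa_same) & !aa_same &
    signals$aa_p2 <= p_two_opposite_max

  n <- nrow(signals)
  status <- rep(NA_character_, n)
  status_pop <- rep(NA_character_, n)
  pick_pop <- function(q_amr, q_aa, p_amr, p_aa) {
    # both qualify -> smaller p wins; ties -> AMR (larger replication pool)
    ifelse(q_amr & q_aa,
           ifelse(!is.na(p_aa) & !is.na(p_amr) & p_aa < p_amr, "AA", "AMR"),
           ifelse(q_amr, "AMR", "AA"))
  }
  for (cls in precedence) {
    open <- is.na(status)
    hit <- switch(cls,
      BOTH = rep_amr & rep_aa,
      OPPOSITE = opp_amr | opp_aa,
      ONE = xor(rep_amr, rep_aa),
      NONE = rep(TRUE, n)
    )
    take <- open & hit
    status[take] <- cls
    if (cls == "OPPOSITE") {
      status_pop[take] <- pick_pop(opp_amr, opp_aa,
                                   signals$amr_p2, signals$aa_p2)[take]
    } else if (cls == "ONE") {
      status_pop[take] <- pick_pop(rep_amr, rep_aa, amr_p1, aa_p1)[take]
    }
  }
  signals |>
    mutate(amr_p1 = amr_p1, aa_p1 = aa_p1,
           status = status, status_pop = status_pop)
}

#' LD requirement implied by a replication status
#'
#' Maps a status class to the population pools in which r^2 >= `threshold`
#' with the index variant is required, and how the pools combine:
#' * BOTH: r^2 >= t in ALL of NFE, AMR, AA;
#' * ONE(pop): ALL of NFE and the replicating population;
#' * OPPOSITE(pop): ANY of NFE or the relevant population;
#' * NONE: NFE only.
#'
#' @param status Status class string.
#' @param population Relevant population for ONE/OPPOSITE.
#' @param threshold Inclusive r-squared bound (default 0.1).
#' @return List with `combinator` ("ALL"/"ANY"), `populations`, `threshold`.
#' @export
ld_requirement <- function(status, population = NA_character_,
                           threshold = 0.1) {
  stopifnot(length(status) == 1)
  if (status %in% c("ONE", "OPPOSITE") &&
      (is.na(population) || !population %in% c("AMR", "AA"))) {
    abort(paste0("status ", status, " needs a relevant population"))
  }
  req <- switch(status,
    BOTH = list(combinator = "ALL", populations = c("NFE", "AMR", "AA")),
    ONE = list(combinator = "ALL", populations = c("NFE", population)),
    OPPOSITE = list(combinator = "ANY", populations = c("NFE", population)),
    NONE = list(combinator = "ALL", populations = "NFE"),
    abort(paste0("unknown status ", status))
  )
  req$threshold <- threshold
  req
}

#' Select fine-mapping candidates for one index signal
#'
#' Applies the signal's status-conditional LD requirement to every
#' variant of its region: under an ALL combinator the candidate needs a
#' defined r^2 >= threshold with the index in every listed pool, under
#' ANY in at least one. Candidates on the base array (position plus
#' unordered allele set) and tri-allelic candidates are excluded.
#' If the index variant is absent from a required pool's panel, that
#' pool's requirement is unsatisfiable (a warning is issued): under ALL
#' the signal then yields nothing, under ANY the remaining pools may
#' still qualify.
#'
#' @param signal One row of [classify_replication_status()] output.
#' @param panels Named list of [genotype_panel]s, names containing
#'   `"NFE"`, `"AMR"`, `"AA"`.
#' @param region One-row region tibble containing the signal.
#' @param manifest Base-array manifest tibble or `NULL`.
#' @param threshold Inclusive r-squared bound.
#' @param method LD method passed to [pairwise_r2()].
#' @return Tibble of selection records: candidate keys, `region_id`,
#'   `arm = "fine_mapping"`, `signal` (index variant id), `status`,
#'   `status_pop`, `pools_held` (pools where the criterion held), and
#'   per-pool r2 columns.
#' @export
select_fine_mapping_variants <- function(signal, panels, region,
                                         manifest = NULL, threshold = 0.1,
                                         method = "auto") {
  stopifnot(nrow(signal) == 1)
  req <- ld_requirement(signal$status, signal$status_pop, threshold)
  pools <- req$populations
  missing_panels <- setdiff(pools, names(panels))
  if (length(missing_panels) > 0) {
    abort(paste0("no panel supplied for pool(s): ",
                 paste(missing_panels, collapse = ", ")))
  }

  per_pool <- map(setNames(pools, pools), function(p) {
    panel <- panels[[p]]
    if (!signal$variant %in% panel$variants$variant) {
      warn(paste0("index ", signal$variant, " absent from ", p,
                  " panel; requirement unsatisfiable in this pool"))
      return(NULL)
    }
    ld_neighbors(panel, signal$variant, region, threshold = threshold,
                 method = method)
  })

  qualified <- compact_pool_sets(per_pool, req$combinator)
  if (nrow(qualified) == 0) {
    return(empty_fine_mapping_records())
  }

  sig_variant <- signal$variant
  sig_status <- signal$status
  sig_pop <- signal$status_pop
  out <- qualified |>
    filter(!triallelic) |>
    mutate(region_id = region$region_id[1], arm = "fine_mapping",
           signal = sig_variant, status = sig_status,
           status_pop = sig_pop)
  if (!is.null(manifest) && nrow(manifest) > 0) {
    manifest <- validate_variant_keys(manifest)
    out <- out |>
      filter(!allele_set_id(chrom, pos, ref, alt) %in%
               allele_set_id(manifest$chrom, manifest$pos,
                             manifest$ref, manifest$alt))
  }
  out
}

compact_pool_sets <- function(per_pool, combinator) {
  tables <- imap(per_pool, function(tb, p) {
    if (is.null(tb) || nrow(tb) == 0) return(NULL)
    tb |>
      select(chrom, pos, ref, alt, variant, triallelic, r2) |>
      mutate(pool = p)
  })
  tables <- tables[!vapply(tables, is.null, logical(1))]
  if (length(tables) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), variant = character(),
                  triallelic = logical(), pools_held = character()))
  }
  long <- bind_rows(tables)
  wide <- long |>
    group_by(chrom, pos, ref, alt, variant, triallelic) |>
    summarise(pools_held = paste(sort(unique(pool)), collapse = "+"),
              n_pools = n_distinct(pool), .groups = "drop")
  r2_cols <- long |>
    mutate(col = paste0("r2_", tolower(pool))) |>
    select(variant, col, r2) |>
    tidyr::pivot_wider(names_from = col, values_from = r2)
  wide <- wide |> left_join(r2_cols, by = "variant")
  if (combinator == "ALL") {
    wide |> filter(n_pools == length(per_pool)) |> select(-n_pools)
  } else {
    wide |> select(-n_pools)
  }
}

empty_fine_mapping_records <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), variant = character(), triallelic = logical(),
         pools_held = character(), region_id = character(),
         arm = character(), signal = character(), status = character(),
         status_pop = character())
}
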