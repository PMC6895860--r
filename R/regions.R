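#' Build fine-mapping regions around index signals
#'
#' Each index signal defines a window extending `flank` bp on each side of
#' its position (2 Mb total by default), clipped at position 1. Windows on
#' the same chromosome that overlap or abut (gap of zero) are merged, so
#' several signals can share one region — the same arithmetic by which 200
#' index variants span 156 fine-mapping loci. Coordinates are GRCh37,
#' 1-based, inclusive on both ends.
#'
#' @param signals Tibble of index signals with variant key columns
#'   (unique keys required).
#' @param flank Flank size in bp on each side of the index position.
#' @return Tibble of regions: `region_id`, `chrom`, `start`, `end`,
#'   `is_mhc`, `n_signals`, and a list-column `index_keys` of the signal
#'   variant ids merged into each region.
#' @export
build_regions <- function(signals, flank = 1e6) {
  signals <- validate_variant_keys(signals, require_unique = TRUE)
  flank <- as.integer(flank)
  windows <- signals |>
    transmute(chrom, variant,
              start = pmax(1L, pos - flank),
              end = pos + flank) |>
    arrange(chrom, start, end)
  merged <- windows |>
    group_by(chrom) |>
    mutate(
      new_block = start > lag(cummax(end), default = -1L) + 1L,
      block = cumsum(new_block)
    ) |>
    group_by(chrom, block) |>
    summarise(start = min(start), end = max(end),
              n_signals = n(), index_keys = list(variant),
              .groups = "drop") |>
    arrange(chrom, start)
  merged |>
    mutate(region_id = paste0("R", sprintf("%03d", row_number())),
           is_mhc = FALSE) |>
    select(region_id, chrom, start, end, is_mhc, n_signals, index_keys)
}

#' The fixed MHC region
#'
#' The major histocompatibility complex window, chr6:27-34 Mb (GRCh37,
#' 1-based inclusive). This region participates only in the
#' coding/regulatory arm; LD-based fine-mapping content is not extracted
#' for signals inside it.
#'
#' @return One-row region tibble with `is_mhc = TRUE`.
#' @export
mhc_region <- function() {
  tibble(region_id = "MHC", chrom = "6", start = 27000000L, end = 34000000L,
         is_mhc = TRUE, n_signals = 0L, index_keys = list(character(0)))
}

#' Assign variant keys to regions
#'
#' Inclusive containment on both bounds. Regions must be non-overlapping
#' within each chromosome (as produced by [build_regions()]); keys falling
#' in no region get `NA`.
#'
#' @param keys Tibble with variant key columns.
#' @param regions Region tibble.
#' @return `keys` with a `region_id` column added.
#' @export
assign_to_regions <- function(keys, regions) {
  keys <- validate_variant_keys(keys)
  check_regions_disjoint(regions)
  keys |>
    left_join(
      regions |> select(region_id, chrom, start, end),
      by = join_by(chrom, between(pos, start, end))
    ) |>
    select(-start, -end)
}

check_regions_disjoint <- function(regions) {
  overlap <- regions |>
    arrange(chrom, start) |>
    group_by(chrom) |>
    filter(start <= lag(cummax(end), default = -1L)) |>
    ungroup()
  if (nrow(overlap) > 0) {
    abort(paste0("regions overlap within chromosome ", overlap$chrom[1]))
  }
  invisible(TRUE)
}
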