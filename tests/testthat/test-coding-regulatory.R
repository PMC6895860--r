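ann_row <- function(chrom = "1", pos = 5000000L, ref = "A", alt = "G",
                    effect = "other", cadd = NA_real_,
                    regulome = NA_character_, afr = NA_real_,
                    amr = NA_real_, nfe = NA_real_, eas = NA_real_,
                    triallelic = FALSE) {
  tibble::tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 effect = effect, cadd = cadd, regulome = regulome,
                 afr_maf = afr, amr_maf = amr, nfe_maf = nfe, eas_maf = eas,
                 triallelic = triallelic)
}

test_that("frequency gate is a strict disjunction over populations", {
  expect_true(passes_frequency_filter(ann_row(afr = 0.02)))
  # boundary is strict: MAF exactly at the threshold fails
  expect_false(passes_frequency_filter(
    ann_row(nfe = 0.05, afr = 0, amr = 0, eas = 0)))
  expect_true(passes_frequency_filter(ann_row(nfe = 0.050001)))
  expect_false(passes_frequency_filter(
    ann_row(afr = 0, amr = 0, nfe = 0, eas = 0)))
  expect_false(passes_frequency_filter(ann_row()))  # all missing
  # AFR/AMR use the lower bound
  expect_true(passes_frequency_filter(ann_row(amr = 0.02)))
  expect_false(passes_frequency_filter(ann_row(eas = 0.02)))
})

test_that("effect, CADD and RegulomeDB predicates match the inclusion rules", {
  expect_true(is_included_effect(ann_row(effect = "stopgain")))
  expect_true(is_included_effect(ann_row(effect = "splicing")))
  expect_false(is_included_effect(ann_row(effect = "synonymous")))

  expect_true(passes_cadd(ann_row(cadd = 30)))    # inclusive bound
  expect_false(passes_cadd(ann_row(cadd = 29.9)))
  expect_false(passes_cadd(ann_row()))            # missing

  expect_true(passes_regulome(ann_row(regulome = "1e")))
  expect_false(passes_regulome(ann_row(regulome = "1f")))
  expect_false(passes_regulome(ann_row(regulome = "2a")))
  expect_false(passes_regulome(ann_row()))
})

make_cr_fixture <- function(n = 100, seed = 99) {
  withr::with_seed(seed, {
    ann <- tibble::tibble(
      chrom = "1",
      pos = as.integer(4000000 + seq_len(n) * 1000),
      ref = "A", alt = "G",
      effect = sample(c("nonsynonymous", "stopgain", "synonymous", "other"),
                      n, replace = TRUE),
      cadd = ifelse(runif(n) < 0.2, runif(n, 28, 40), NA),
      regulome = sample(c("1a", "1e", "1f", "4", NA), n, replace = TRUE),
      afr_maf = ifelse(runif(n) < 0.8, runif(n, 0, 0.5), NA),
      amr_maf = runif(n, 0, 0.5),
      nfe_maf = runif(n, 0, 0.5),
      eas_maf = runif(n, 0, 0.5),
      triallelic = runif(n) < 0.1
    )
    manifest <- ann[sample.int(n, 15), c("chrom", "pos", "ref", "alt")]
    list(ann = ann, manifest = manifest)
  })
}

# predicate-by-predicate evaluation, independent of the selector pipeline
oracle_cr_select <- function(ann, regions, manifest, min_cadd = 30) {
  keep <- logical(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    in_reg <- any(ann$chrom[i] == regions$chrom &
                    ann$pos[i] >= regions$start &
                    ann$pos[i] <= regions$end)
    freq <- any(c(!is.na(ann$afr_maf[i]) && ann$afr_maf[i] > 0.01,
                  !is.na(ann$amr_maf[i]) && ann$amr_maf[i] > 0.01,
                  !is.na(ann$nfe_maf[i]) && ann$nfe_maf[i] > 0.05,
                  !is.na(ann$eas_maf[i]) && ann$eas_maf[i] > 0.05))
    crit <- ann$effect[i] %in% c("nonsynonymous", "stopgain", "stoploss",
                                 "splicing") ||
      (!is.na(ann$cadd[i]) && ann$cadd[i] >= min_cadd) ||
      (!is.na(ann$regulome[i]) &&
         ann$regulome[i] %in% c("1a", "1b", "1c", "1d", "1e"))
    in_man <- any(ann$chrom[i] == manifest$chrom &
                    ann$pos[i] == manifest$pos)
    keep[i] <- in_reg && freq && crit && !in_man && !ann$triallelic[i]
  }
  sort(variant_id(ann$chrom, ann$pos, ann$ref, ann$alt)[keep])
}

test_that("selector equals brute-force predicate evaluation on 100 variants", {
  fx <- make_cr_fixture()
  regions <- build_regions(tibble::tibble(chrom = "1", pos = 5000000L,
                                          ref = "C", alt = "T"))
  got <- select_coding_regulatory(fx$ann, regions, fx$manifest)
  expect_setequal(got$variant, oracle_cr_select(fx$ann, regions, fx$manifest))
  # every record carries at least one firing criterion tag
  expect_true(all(got$crit_effect | got$crit_cadd | got$crit_regulome))
})

test_that("manifest exclusion dominates and the region gate applies", {
  regions <- dplyr::bind_rows(
    build_regions(tibble::tibble(chrom = "1", pos = 5000000L,
                                 ref = "C", alt = "T")),
    mhc_region())
  in_mhc <- ann_row(chrom = "6", pos = 29000000L, afr = 0.02, cadd = 35)
  manifest <- in_mhc[, c("chrom", "pos", "ref", "alt")]
  expect_equal(nrow(select_coding_regulatory(in_mhc, regions, manifest)), 0L)
  expect_equal(nrow(select_coding_regulatory(in_mhc, regions, NULL)), 1L)
  # manifest matching is unordered on alleles
  swapped <- manifest |> dplyr::mutate(ref2 = alt, alt2 = ref) |>
    dplyr::select(chrom, pos, ref = ref2, alt = alt2)
  expect_equal(nrow(select_coding_regulatory(in_mhc, regions, swapped)), 0L)

  outside <- ann_row(chrom = "2", pos = 5000000L, effect = "stopgain",
                     afr = 0.3)
  expect_equal(nrow(select_coding_regulatory(outside, regions, NULL)), 0L)
})

test_that("selection is idempotent-monotone: union of single-criterion runs", {
  fx <- make_cr_fixture(seed = 123)
  regions <- build_regions(tibble::tibble(chrom = "1", pos = 5000000L,
                                          ref = "C", alt = "T"))
  full <- select_coding_regulatory(fx$ann, regions, fx$manifest)
  only_effect <- select_coding_regulatory(
    fx$ann |> dplyr::mutate(cadd = NA_real_, regulome = NA_character_),
    regions, fx$manifest)
  only_cadd <- select_coding_regulatory(
    fx$ann |> dplyr::mutate(effect = "other", regulome = NA_character_),
    regions, fx$manifest)
  only_reg <- select_coding_regulatory(
    fx$ann |> dplyr::mutate(effect = "other", cadd = NA_real_),
    regions, fx$manifest)
  expect_setequal(full$variant, unique(c(only_effect$variant,
                                         only_cadd$variant,
                                         only_reg$variant)))
})

test_that("raising thresholds never enlarges the selection", {
  fx <- make_cr_fixture(seed = 321)
  regions <- build_regions(tibble::tibble(chrom = "1", pos = 5000000L,
                                          ref = "C", alt = "T"))
  base <- select_coding_regulatory(fx$ann, regions, fx$manifest)
  higher_cadd <- select_coding_regulatory(fx$ann, regions, fx$manifest,
                                          min_cadd = 35)
  stricter_freq <- select_coding_regulatory(
    fx$ann, regions, fx$manifest,
    thresholds = freq_thresholds(afr = 0.05, amr = 0.05,
                                 nfe = 0.2, eas = 0.2))
  expect_true(all(higher_cadd$variant %in% base$variant))
  expect_true(all(stricter_freq$variant %in% base$variant))
})
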