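make_signal <- function(amr_sign = 1, amr_p2 = NA, aa_sign = 1, aa_p2 = NA,
                        disc = 1, chrom = "1", pos = 5000000L) {
  tibble::tibble(chrom = chrom, pos = pos, ref = "A", alt = "G",
                 discovery_direction = disc,
                 amr_beta_sign = amr_sign, amr_p2 = amr_p2,
                 aa_beta_sign = aa_sign, aa_p2 = aa_p2)
}

test_that("one-sided p conversion respects effect direction", {
  expect_equal(one_sided_p(0.04, TRUE), 0.02)
  expect_equal(one_sided_p(0.04, FALSE), 0.98)
  expect_equal(one_sided_p(1.0, TRUE), 0.5)
  expect_equal(one_sided_p(1.0, FALSE), 0.5)
  expect_true(is.na(one_sided_p(NA, TRUE)))
  expect_true(is.na(one_sided_p(0.04, NA)))
})

test_that("status classification reproduces the four classes", {
  # both one-sided p <= 0.05 even though two-sided p > 0.05
  s <- classify_replication_status(make_signal(1, 0.06, 1, 0.08))
  expect_equal(s$status, "BOTH")
  expect_equal(s$amr_p1, 0.03)
  expect_equal(s$aa_p1, 0.04)

  s <- classify_replication_status(make_signal(1, 0.04, 1, 0.80))
  expect_equal(s$status, "ONE")
  expect_equal(s$status_pop, "AMR")

  s <- classify_replication_status(make_signal(1, 0.60, -1, 0.09))
  expect_equal(s$status, "OPPOSITE")
  expect_equal(s$status_pop, "AA")

  s <- classify_replication_status(make_signal(1, 0.60, 1, 0.70))
  expect_equal(s$status, "NONE")
  expect_true(is.na(s$status_pop))

  # discovery direction -1: matching replication is also -1
  s <- classify_replication_status(make_signal(-1, 0.04, -1, 0.04,
                                               disc = -1))
  expect_equal(s$status, "BOTH")
  # opposite sign alone (large p) never triggers OPPOSITE
  s <- classify_replication_status(make_signal(-1, 0.50, 1, 0.70))
  expect_equal(s$status, "NONE")
})

test_that("missing replication data never satisfies any test", {
  s <- classify_replication_status(make_signal(1, NA, 1, 0.04))
  expect_equal(s$status, "ONE")
  expect_equal(s$status_pop, "AA")
  s <- classify_replication_status(make_signal(NA, NA, NA, NA))
  expect_equal(s$status, "NONE")
})

test_that("the classification truth table is total and exclusive", {
  # every combination of sign and p bucket maps to exactly one status
  grid <- tidyr::crossing(
    amr_sign = c(1, -1), aa_sign = c(1, -1),
    amr_p2 = c(0.04, 0.09, 0.5, NA), aa_p2 = c(0.04, 0.09, 0.5, NA)
  )
  signals <- purrr::pmap(grid, function(amr_sign, aa_sign, amr_p2, aa_p2) {
    make_signal(amr_sign, amr_p2, aa_sign, aa_p2)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(pos = 5000000L + dplyr::row_number() * 3000000L)
  out <- classify_replication_status(signals)
  expect_false(anyNA(out$status))
  expect_true(all(out$status %in% c("BOTH", "OPPOSITE", "ONE", "NONE")))
  expect_equal(is.na(out$status_pop),
               out$status %in% c("BOTH", "NONE"))
  # precedence: a signal qualifying as BOTH stays BOTH even if one
  # population's record would also pass the OPPOSITE p bound
  s <- classify_replication_status(make_signal(1, 0.04, 1, 0.05))
  expect_equal(s$status, "BOTH")
})

test_that("status maps to the documented LD requirement", {
  req <- ld_requirement("BOTH")
  expect_equal(req$combinator, "ALL")
  expect_setequal(req$populations, c("NFE", "AMR", "AA"))
  req <- ld_requirement("ONE", "AMR")
  expect_equal(req$combinator, "ALL")
  expect_setequal(req$populations, c("NFE", "AMR"))
  req <- ld_requirement("OPPOSITE", "AA")
  expect_equal(req$combinator, "ANY")
  expect_setequal(req$populations, c("NFE", "AA"))
  req <- ld_requirement("NONE")
  expect_equal(req$combinator, "ALL")
  expect_equal(req$populations, "NFE")
  expect_equal(req$threshold, 0.1)
  expect_error(ld_requirement("ONE"), "population")
})

# panels with pool-specific planted r2 against a shared layout
make_pool_panels <- function(r2_nfe, r2_amr, r2_aa, n_hap = 600, seed = 71) {
  list(NFE = planted_panel(r2_nfe, n_hap, "NFE", seed),
       AMR = planted_panel(r2_amr, n_hap, "AMR", seed + 1),
       AA = planted_panel(r2_aa, n_hap, "AA", seed + 2))
}

region1 <- tibble::tibble(region_id = "R001", chrom = "1",
                          start = 4000000L, end = 6000000L)

test_that("status-conditional selection follows ALL/ANY combinators", {
  # candidate 1 strong everywhere, candidate 2 strong except AA
  panels <- make_pool_panels(c(0.5, 0.5), c(0.5, 0.5), c(0.5, 0.02))
  idx <- panels$NFE$variants$variant[1]
  cand2 <- panels$NFE$variants$variant[3]

  sel_none <- select_fine_mapping_variants(
    status_signal("NONE"), panels, region1)
  expect_true(cand2 %in% sel_none$variant)  # NFE r2 = 0.5 suffices

  sel_both <- select_fine_mapping_variants(
    status_signal("BOTH"), panels, region1)
  expect_false(cand2 %in% sel_both$variant)  # AA pool fails under ALL
  expect_true(panels$NFE$variants$variant[2] %in% sel_both$variant)

  sel_opp <- select_fine_mapping_variants(
    status_signal("OPPOSITE", "AA"), panels, region1)
  expect_true(cand2 %in% sel_opp$variant)  # NFE suffices under ANY

  sel_one_aa <- select_fine_mapping_variants(
    status_signal("ONE", "AA"), panels, region1)
  expect_false(cand2 %in% sel_one_aa$variant)
})

test_that("selection respects the nesting of LD requirements", {
  withr::with_seed(61, {
    for (rep in 1:3) {
      r2s <- function() runif(4, 0, 0.6)
      panels <- make_pool_panels(r2s(), r2s(), r2s(), seed = 100 + rep)
      all3 <- select_fine_mapping_variants(status_signal("BOTH"),
                                           panels, region1)$variant
      all_nfe_aa <- select_fine_mapping_variants(status_signal("ONE", "AA"),
                                                 panels, region1)$variant
      nfe_only <- select_fine_mapping_variants(status_signal("NONE"),
                                               panels, region1)$variant
      any_nfe_aa <- select_fine_mapping_variants(
        status_signal("OPPOSITE", "AA"), panels, region1)$variant
      expect_true(all(all3 %in% all_nfe_aa))
      expect_true(all(all_nfe_aa %in% nfe_only))
      expect_true(all(nfe_only %in% any_nfe_aa))
    }
  })
})

test_that("manifest overlap and tri-allelic candidates are excluded", {
  panels <- make_pool_panels(0.5, 0.5, 0.5)
  cand <- panels$NFE$variants[2, ]
  manifest <- cand[, c("chrom", "pos", "ref", "alt")]
  sel <- select_fine_mapping_variants(status_signal("NONE"), panels,
                                      region1, manifest = manifest)
  expect_false(cand$variant %in% sel$variant)

  tri <- panels
  for (p in names(tri)) tri[[p]]$variants$triallelic[2] <- TRUE
  sel_tri <- select_fine_mapping_variants(status_signal("NONE"), tri, region1)
  expect_false(cand$variant %in% sel_tri$variant)
})

test_that("an index absent from a required pool warns and blocks ALL", {
  panels <- make_pool_panels(0.5, 0.5, 0.5)
  # drop the index from the AA panel
  keep <- panels$AA$variants$variant != panels$AA$variants$variant[1]
  panels$AA <- genotype_panel(
    "AA", panels$AA$samples, panels$AA$variants[keep, ],
    panels$AA$geno[, keep, drop = FALSE],
    panels$AA$hap[, keep, drop = FALSE], phased = TRUE)
  expect_warning(
    sel <- select_fine_mapping_variants(status_signal("BOTH"), panels,
                                        region1),
    "absent")
  expect_equal(nrow(sel), 0L)
  # under ANY the NFE pool still qualifies candidates
  expect_warning(
    sel_any <- select_fine_mapping_variants(
      status_signal("OPPOSITE", "AA"), panels, region1),
    "absent")
  expect_gt(nrow(sel_any), 0L)
})
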