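test_that("phased gamete counting matches direct tallies", {
  h <- haplotype_freqs_phased(rep(c(1, 0), c(5, 5)), rep(c(1, 0), c(5, 5)))
  expect_equal(unname(h$freqs), c(0.5, 0, 0, 0.5))

  h2 <- haplotype_freqs_phased(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unname(h2$freqs), rep(0.25, 4))

  withr::with_seed(5, {
    a <- rbinom(50, 1, 0.4)
    b <- rbinom(50, 1, 0.6)
  })
  h3 <- haplotype_freqs_phased(a, b)
  expect_equal(unname(h3$freqs["pAB"]), mean(a == 1 & b == 1))
  expect_equal(unname(h3$freqs["pab"]), mean(a == 0 & b == 0))
  expect_equal(sum(h3$freqs), 1)

  expect_error(haplotype_freqs_phased(c(NA, NA), c(0, 1)), "no haplotype")
})

test_that("r_squared matches closed-form evaluations", {
  expect_equal(r_squared(c(0.5, 0, 0, 0.5)), 1.0)
  # equilibrium: pAB = pA * pB exactly
  expect_equal(r_squared(c(0.12, 0.18, 0.28, 0.42)), 0.0)
  # D = 0.4 - 0.25 = 0.15, denominator 0.25 * 0.25
  expect_equal(r_squared(c(0.4, 0.1, 0.1, 0.4)), 0.36)
  # monomorphic locus -> undefined
  expect_true(is.na(r_squared(c(0.5, 0.5, 0, 0))))
})

test_that("EM equals closed-form counting when no double heterozygotes", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      tab <- random_genotype_table(80)
      tab[2, 2] <- 0
      if (sum(tab) == 0) next
      pA <- sum(tab * matrix(c(0, 1, 2), 3, 3)) / (2 * sum(tab))
      pB <- sum(tab * matrix(c(0, 1, 2), 3, 3, byrow = TRUE)) / (2 * sum(tab))
      if (pA %in% c(0, 1) || pB %in% c(0, 1)) next
      em <- em_haplotype_freqs(tab)
      expect_equal(unname(em$freqs), unname(oracle_counting_freqs(tab)),
                   tolerance = 1e-7)
    }
  })
})

test_that("EM attains the grid-search likelihood maximum", {
  withr::with_seed(87, {
    for (rep in 1:25) {
      tab <- random_genotype_table(150)
      em <- em_haplotype_freqs(tab)
      expect_true(em$defined)
      expect_gte(em$loglik, oracle_grid_max_loglik(tab) - 1e-6)
    }
  })
})

test_that("the fully ambiguous symmetric table resolves to full coupling", {
  tab <- matrix(0, 3, 3)
  tab[3, 3] <- 25; tab[2, 2] <- 50; tab[1, 1] <- 25
  em <- em_haplotype_freqs(tab)
  expect_equal(unname(em$freqs[c("pAB", "pab")]), c(0.5, 0.5),
               tolerance = 1e-6)
  expect_equal(r_squared(em), 1.0, tolerance = 1e-6)
  # grid search confirms this is a global maximum
  expect_gte(em$loglik, oracle_grid_max_loglik(tab) - 1e-6)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  withr::with_seed(53, {
    for (rep in 1:5) {
      tab <- random_genotype_table(60)
      lls <- c()
      # re-run EM step by step via decreasing iteration caps
      prev <- -Inf
      for (it in 1:12) {
        em <- em_haplotype_freqs(tab, tol = 0, max_iter = it)
        expect_gte(em$loglik, prev - 1e-8)
        prev <- em$loglik
      }
    }
  })
})

test_that("EM reports monomorphic loci as undefined", {
  tab <- matrix(0, 3, 3)
  tab[1, 1] <- 30; tab[1, 2] <- 40; tab[1, 3] <- 30
  em <- em_haplotype_freqs(tab)
  expect_false(em$defined)
  expect_true(is.na(r_squared(em)))
})

test_that("pairwise_r2: self-LD is 1, symmetry holds, monomorphic is NA", {
  panel <- planted_panel(c(0.5, 0.0), n_hap = 400, seed = 13)
  keys <- panel$variants$variant
  expect_equal(pairwise_r2(panel, keys[1], keys[1])$r2, 1.0)
  ab <- pairwise_r2(panel, keys[1], keys[2])$r2
  ba <- pairwise_r2(panel, keys[2], keys[1])$r2
  expect_equal(ab, ba)
  expect_error(pairwise_r2(panel, keys[1], "1:999:A:G"), "not in panel")

  # monomorphic variant: append an all-ref column
  v <- dplyr::bind_rows(panel$variants[, c("chrom", "pos", "ref", "alt")],
                        tibble::tibble(chrom = "1", pos = 9999999L,
                                       ref = "C", alt = "T"))
  mono <- genotype_panel("AA", panel$samples, v,
                         cbind(panel$geno, 0L),
                         cbind(panel$hap, 0L), phased = TRUE)
  expect_true(is.na(pairwise_r2(mono, keys[1], "1:9999999:C:T")$r2))
})

test_that("phased and EM estimates agree on planted panels", {
  # at n = 400 haplotypes the two estimators differ only through phase
  # uncertainty in double heterozygotes (sd of the difference is about
  # 0.02 at these frequencies); at large n they coincide
  panel <- planted_panel(c(0.6, 0.3, 0.1), n_hap = 400, seed = 17)
  keys <- panel$variants$variant
  for (k in keys[-1]) {
    ph <- pairwise_r2(panel, keys[1], k, method = "phased")$r2
    em <- pairwise_r2(panel, keys[1], k, method = "em")$r2
    expect_lt(abs(em - ph), 0.08)
    # phased route agrees with the plain squared correlation
    expect_equal(ph, oracle_hap_r2(panel$hap[, keys[1]], panel$hap[, k]),
                 tolerance = 1e-9)
  }
  big <- planted_panel(c(0.6, 0.3), n_hap = 20000, seed = 19)
  kb <- big$variants$variant
  for (k in kb[-1]) {
    ph <- pairwise_r2(big, kb[1], k, method = "phased")$r2
    em <- pairwise_r2(big, kb[1], k, method = "em")$r2
    expect_lt(abs(em - ph), 0.005)
  }
})

test_that("EM r2 converges to the phased value as N grows", {
  errs <- vapply(c(50, 200, 1000), function(n_hap) {
    panel <- planted_panel(0.4, n_hap = n_hap, seed = 29)
    keys <- panel$variants$variant
    abs(pairwise_r2(panel, keys[1], keys[2], method = "em")$r2 -
          pairwise_r2(panel, keys[1], keys[2], method = "phased")$r2)
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  expect_lte(errs[3], errs[1] + 1e-9)
})

test_that("ld_neighbors applies the inclusive threshold to planted r2", {
  # deterministic haplotype construction: index is half ALT, candidates
  # are allocated conditionally from rounded gamete counts so each pair's
  # r2 sits at (approximately) 0.05 / 0.10 / 0.50
  n <- 400
  a <- rep(c(1L, 0L), each = n / 2)
  hap <- cbind(a)
  vars <- tibble::tibble(chrom = "1", pos = 5000000L, ref = "A", alt = "G")
  targets <- c(0.05, 0.10, 0.50)
  for (k in seq_along(targets)) {
    d <- sqrt(targets[k] * 0.5^4)
    pb1 <- (0.25 + d) / 0.5
    pb0 <- (0.25 - d) / 0.5
    b <- integer(n)
    n_alt1 <- round((n / 2) * pb1)
    n_alt0 <- round((n / 2) * pb0)
    b[a == 1] <- rep(c(1L, 0L), c(n_alt1, n / 2 - n_alt1))
    b[a == 0] <- rep(c(1L, 0L), c(n_alt0, n / 2 - n_alt0))
    hap <- cbind(hap, b)
    vars <- dplyr::bind_rows(vars, tibble::tibble(
      chrom = "1", pos = 5000000L + 1000L * k, ref = "A", alt = "G"))
  }
  geno <- hap[seq(1, n, 2), ] + hap[seq(2, n, 2), ]
  panel <- genotype_panel("NFE", paste0("S", 1:(n / 2)), vars, geno, hap)
  keys <- panel$variants$variant
  r2s <- vapply(keys[-1], function(k2) {
    pairwise_r2(panel, keys[1], k2)$r2
  }, numeric(1))
  expect_true(all(abs(r2s - targets) < 0.01))

  region <- tibble::tibble(region_id = "R001", chrom = "1",
                           start = 4000000L, end = 6000000L)
  # threshold set to the middle pair's achieved r2: the bound is
  # inclusive, so that variant itself must be returned
  got <- ld_neighbors(panel, keys[1], region, threshold = unname(r2s[2]))
  expect_setequal(got$variant, c(keys[1], keys[3], keys[4]))

  all_defined <- ld_neighbors(panel, keys[1], region, threshold = 0)
  expect_setequal(all_defined$variant, keys)
  top <- ld_neighbors(panel, keys[1], region, threshold = 1 + 1e-9)
  expect_equal(nrow(top), 0L)
})
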