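#' Two-locus haplotype frequencies from phased haplotypes
#'
#' Direct gamete counting. Alleles are coded 0/1 (1 = ALT); haplotypes
#' with a missing allele at either locus are dropped pairwise. The four
#' gamete classes are named with A/B for the ALT allele at the first and
#' second locus: `pAB`, `pAb`, `paB`, `pab`.
#'
#' @param a,b Integer vectors of haplotype alleles (0/1/NA), same length.
#' @return List with `freqs` (named numeric of length 4 summing to 1),
#'   `n_haplotypes` used, and `method = "phased"`.
#' @export
haplotype_freqs_phased <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  n <- sum(keep)
  if (n == 0) abort("no haplotype has both alleles observed")
  a <- a[keep]; b <- b[keep]
  counts <- c(
    pAB = sum(a == 1 & b == 1),
    pAb = sum(a == 1 & b == 0),
    paB = sum(a == 0 & b == 1),
    pab = sum(a == 0 & b == 0)
  )
  list(freqs = counts / n, n_haplotypes = n, method = "phased")
}

#' Two-locus haplotype frequencies from unphased genotypes (EM)
#'
#' Maximum-likelihood gamete frequencies from a 3x3 table of two-locus
#' genotype counts (rows: ALT dosage at locus A; columns: dosage at locus
#' B). Only the double-heterozygote cell carries phase ambiguity; the EM
#' iteration splits it between the coupling (AB/ab) and repulsion (Ab/aB)
#' configurations by their expected share under the current frequencies.
#' Because the observed-data likelihood can be bimodal in D, the EM is
#' run from linkage equilibrium and from both feasibility extremes of
#' pAB, and the best mode is kept — deterministic, no random restarts.
#' Convergence: max frequency change < `tol` or `max_iter` iterations.
#' When two modes have equal likelihood (the table cannot identify the
#' phase), the equilibrium-basin solution is returned and flagged
#' `tied = TRUE`.
#'
#' @param counts 3x3 matrix of genotype counts (dosage 0/1/2 at each locus).
#' @param tol Convergence tolerance on haplotype frequencies.
#' @param max_iter Iteration cap.
#' @return List with `freqs` (pAB, pAb, paB, pab), `loglik`, `iterations`,
#'   `converged`, `tied`, `n_haplotypes`, `method = "em"`; or, when either
#'   locus is monomorphic in the table, a list with `freqs = NA` and
#'   `defined = FALSE`.
#' @export
em_haplotype_freqs <- function(counts, tol = 1e-12, max_iter = 2000) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)), all(counts >= 0))
  n <- sum(counts)
  if (n == 0) abort("empty genotype table")
  # ALT-allele counts at each locus
  nA <- sum(counts * matrix(c(0, 1, 2), 3, 3, byrow = FALSE))
  nB <- sum(counts * matrix(c(0, 1, 2), 3, 3, byrow = TRUE))
  pA <- nA / (2 * n)
  pB <- nB / (2 * n)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    return(list(freqs = c(pAB = NA_real_, pAb = NA_real_,
                          paB = NA_real_, pab = NA_real_),
                defined = FALSE, method = "em", n_haplotypes = 2 * n))
  }

  # phase-unambiguous gamete counts: cell (i,j) with dosages (dA,dB)
  # contributes known gametes except the double heterozygote (1,1)
  known <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (i in 1:3) for (j in 1:3) {
    if (i == 2 && j == 2) next
    m <- counts[i, j]
    if (m == 0) next
    dA <- i - 1L; dB <- j - 1L
    # each individual = two gametes; distribute dosages
    g1A <- min(dA, 1L); g2A <- dA - g1A
    g1B <- min(dB, 1L); g2B <- dB - g1B
    # for dA or dB == 1 with the other homozygous, phase is still known:
    # the single ALT allele sits on one gamete, the other carries ref
    lab <- function(xA, xB) paste0(if (xA == 1) "A" else "a",
                                   if (xB == 1) "B" else "b")
    known[lab(g1A, g1B)] <- known[lab(g1A, g1B)] + m
    known[lab(g2A, g2B)] <- known[lab(g2A, g2B)] + m
  }
  n_dh <- counts[2, 2]

  em_run <- function(pAB0) {
    f <- c(AB = pAB0, Ab = pA - pAB0, aB = pB - pAB0,
           ab = 1 - pA - pB + pAB0)
    iterations <- 0L
    converged <- FALSE
    while (iterations < max_iter) {
      iterations <- iterations + 1L
      denom <- f["AB"] * f["ab"] + f["Ab"] * f["aB"]
      coupling <- if (n_dh > 0 && denom > 0) {
        as.numeric(f["AB"] * f["ab"] / denom)
      } else 0.5
      e <- known
      e["AB"] <- e["AB"] + n_dh * coupling
      e["ab"] <- e["ab"] + n_dh * coupling
      e["Ab"] <- e["Ab"] + n_dh * (1 - coupling)
      e["aB"] <- e["aB"] + n_dh * (1 - coupling)
      f_new <- e / (2 * n)
      if (max(abs(f_new - f)) < tol) {
        f <- f_new
        converged <- TRUE
        break
      }
      f <- f_new
    }
    names(f) <- c("pAB", "pAb", "paB", "pab")
    list(freqs = f, loglik = two_locus_loglik(f, counts),
         iterations = iterations, converged = converged)
  }

  # the double-heterozygote likelihood can be bimodal in D; start from
  # linkage equilibrium plus the two feasibility extremes and keep the
  # best mode (equilibrium basin wins exact ties and is flagged)
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  eq <- pA * pB
  starts <- unique(c(eq, lo + 0.98 * (hi - lo), lo + 0.02 * (hi - lo)))
  runs <- lapply(starts, em_run)
  best <- runs[[1]]
  tied <- FALSE
  for (r in runs[-1]) {
    if (r$loglik > best$loglik + 1e-9) {
      best <- r
    } else if (abs(r$loglik - best$loglik) <= 1e-9 &&
               max(abs(r$freqs - best$freqs)) > 1e-6) {
      tied <- TRUE
    }
  }

  list(freqs = best$freqs, loglik = best$loglik,
       iterations = best$iterations, converged = best$converged,
       tied = tied, defined = TRUE, n_haplotypes = 2 * n, method = "em")
}

#' Multinomial log-likelihood of a two-locus genotype table
#'
#' Assumes random union of gametes (Hardy-Weinberg at the haplotype
#' level): the nine genotype-cell probabilities are products of gamete
#' frequencies, with the double heterozygote summing both phase
#' configurations.
#'
#' @param freqs Gamete frequencies (pAB, pAb, paB, pab).
#' @param counts 3x3 genotype count matrix.
#' @return Log-likelihood (constant terms omitted).
#' @export
two_locus_loglik <- function(freqs, counts) {
  p <- unname(freqs)
  pAB <- p[1]; pAb <- p[2]; paB <- p[3]; pab <- p[4]
  cell <- matrix(0, 3, 3)
  cell[1, 1] <- pab^2
  cell[1, 2] <- 2 * pab * paB
  cell[1, 3] <- paB^2
  cell[2, 1] <- 2 * pab * pAb
  cell[2, 2] <- 2 * pAB * pab + 2 * pAb * paB
  cell[2, 3] <- 2 * paB * pAB
  cell[3, 1] <- pAb^2
  cell[3, 2] <- 2 * pAb * pAB
  cell[3, 3] <- pAB^2
  nz <- counts > 0
  sum(counts[nz] * log(pmax(cell[nz], .Machine$double.xmin)))
}

#' Squared allelic correlation from gamete frequencies
#'
#' With pA = pAB + pAb, pB = pAB + paB and D = pAB - pA pB, returns
#' r^2 = D^2 / (pA (1 - pA) pB (1 - pB)). Undefined (NA) when either
#' locus is monomorphic.
#'
#' @param h Result of [haplotype_freqs_phased()] / [em_haplotype_freqs()],
#'   or a named numeric of the four gamete frequencies.
#' @return r-squared in [0, 1], or `NA` when undefined.
#' @export
r_squared <- function(h) {
  f <- if (is.list(h)) h$freqs else h
  if (any(is.na(f))) return(NA_real_)
  f <- unname(f)
  pA <- f[1] + f[2]
  pB <- f[1] + f[3]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(NA_real_)
  d <- f[1] - pA * pB
  r2 <- d^2 / (pA * (1 - pA) * pB * (1 - pB))
  min(max(r2, 0), 1)
}

geno_to_counts <- function(ga, gb) {
  keep <- !is.na(ga) & !is.na(gb)
  tab <- matrix(0, 3, 3)
  for (i in which(keep)) tab[ga[i] + 1L, gb[i] + 1L] <-
      tab[ga[i] + 1L, gb[i] + 1L] + 1
  tab
}

#' Pairwise r-squared between two variants in one panel
#'
#' Phased panels use direct gamete counting; unphased panels (or
#' `method = "em"`) use EM haplotype-frequency estimation from the 3x3
#' genotype table. Samples missing either genotype are dropped pairwise.
#'
#' @param panel A [genotype_panel].
#' @param key_a,key_b Variant id strings (`"chrom:pos:ref:alt"`) or
#'   one-row key tibbles.
#' @param method `"auto"` (phased path when available), `"phased"`, `"em"`.
#' @return One-row tibble: `population`, `key_a`, `key_b`, `r2`, `n_used`
#'   (haplotypes), `method`. `r2` is `NA` when either variant is
#'   monomorphic among the complete observations.
#' @export
pairwise_r2 <- function(panel, key_a, key_b, method = c("auto", "phased", "em")) {
  method <- match.arg(method)
  key_a <- as_key_string(key_a)
  key_b <- as_key_string(key_b)
  for (k in c(key_a, key_b)) {
    if (!k %in% panel$variants$variant) {
      abort(paste0("variant ", k, " not in panel ", panel$population))
    }
  }
  use_phased <- (method == "phased") ||
    (method == "auto" && isTRUE(panel$phased))
  if (use_phased && !isTRUE(panel$phased)) {
    abort("phased method requested on an unphased panel")
  }
  if (use_phased) {
    a <- panel$hap[, key_a]
    b <- panel$hap[, key_b]
    h <- haplotype_freqs_phased(a, b)
    tibble(population = panel$population, key_a = key_a, key_b = key_b,
           r2 = r_squared(h), n_used = h$n_haplotypes, method = "phased")
  } else {
    ga <- panel$geno[, key_a]
    gb <- panel$geno[, key_b]
    tab <- geno_to_counts(ga, gb)
    h <- em_haplotype_freqs(tab)
    tibble(population = panel$population, key_a = key_a, key_b = key_b,
           r2 = r_squared(h), n_used = h$n_haplotypes, method = "em")
  }
}

as_key_string <- function(key) {
  if (is.character(key) && length(key) == 1) return(key)
  if (is.data.frame(key)) {
    key <- validate_variant_keys(key)
    if (nrow(key) != 1) abort("expected a single variant key")
    return(key$variant)
  }
  abort("variant key must be a 'chrom:pos:ref:alt' string or one-row tibble")
}

#' LD neighbours of an index variant within a region
#'
#' All panel variants lying inside the region whose r-squared with the
#' index is defined and >= `threshold` (inclusive, matching the design's
#' r^2 >= 0.1 rule). An undefined r-squared — the variant or the index is
#' monomorphic in this pool — never qualifies: a variant cannot be in LD
#' where it does not vary.
#'
#' @param panel A [genotype_panel].
#' @param index_key Index variant id or one-row key tibble.
#' @param region One-row region tibble (`chrom`, `start`, `end`).
#' @param threshold Inclusive r-squared bound.
#' @param method Passed to [pairwise_r2()].
#' @return Tibble of qualifying variants with their `r2`.
#' @export
ld_neighbors <- function(panel, index_key, region, threshold = 0.1,
                         method = "auto") {
  index_key <- as_key_string(index_key)
  if (!index_key %in% panel$variants$variant) {
    abort(paste0("index variant ", index_key, " not in panel ",
                 panel$population))
  }
  cand <- panel$variants |>
    filter(chrom == region$chrom[1], pos >= region$start[1],
           pos <= region$end[1])
  if (nrow(cand) == 0) return(cand |> mutate(r2 = numeric(0)))
  r2s <- vapply(cand$variant, function(v) {
    pairwise_r2(panel, index_key, v, method = method)$r2
  }, numeric(1))
  cand |>
    mutate(r2 = unname(r2s)) |>
    filter(!is.na(r2), r2 >= threshold)
}
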