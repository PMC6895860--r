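# Independent oracles used across the suite. These deliberately re-derive
# quantities by enumeration / brute force, never by calling the package
# path they check.

# multinomial log-likelihood of a 3x3 two-locus genotype table, computed
# by enumerating the 16 ordered gamete pairs (independent of the
# package's closed-form cell probabilities)
oracle_loglik <- function(freqs, counts) {
  # freqs in order AB, Ab, aB, ab
  dosA <- c(1, 1, 0, 0)
  dosB <- c(1, 0, 1, 0)
  cell <- matrix(0, 3, 3)
  for (g1 in 1:4) for (g2 in 1:4) {
    i <- dosA[g1] + dosA[g2] + 1
    j <- dosB[g1] + dosB[g2] + 1
    cell[i, j] <- cell[i, j] + freqs[g1] * freqs[g2]
  }
  nz <- counts > 0
  sum(counts[nz] * log(pmax(cell[nz], .Machine$double.xmin)))
}

# grid search over pAB at fixed allele frequencies; returns the maximum
# log-likelihood over the feasible range
oracle_grid_max_loglik <- function(counts, resolution = 1e-4) {
  n <- sum(counts)
  pA <- sum(counts * matrix(c(0, 1, 2), 3, 3)) / (2 * n)
  pB <- sum(counts * matrix(c(0, 1, 2), 3, 3, byrow = TRUE)) / (2 * n)
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  grid <- seq(lo, hi, by = resolution)
  if (length(grid) == 0 || grid[length(grid)] < hi) grid <- c(grid, hi)
  best <- -Inf
  for (pAB in grid) {
    f <- c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
    if (any(f < -1e-12)) next
    best <- max(best, oracle_loglik(pmax(f, 0), counts))
  }
  best
}

# gamete counting when the double-heterozygote cell is empty: every
# individual's two gametes are phase-determined
oracle_counting_freqs <- function(counts) {
  stopifnot(counts[2, 2] == 0)
  tally <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (i in 1:3) for (j in 1:3) {
    m <- counts[i, j]
    if (m == 0) next
    dA <- i - 1; dB <- j - 1
    hapA <- c(min(dA, 1), dA - min(dA, 1))
    hapB <- c(min(dB, 1), dB - min(dB, 1))
    for (k in 1:2) {
      lab <- paste0(if (hapA[k] == 1) "A" else "a",
                    if (hapB[k] == 1) "B" else "b")
      tally[lab] <- tally[lab] + m
    }
  }
  tally / (2 * sum(counts))
}

# random two-locus genotype table with both loci guaranteed polymorphic
random_genotype_table <- function(n) {
  repeat {
    pA <- runif(1, 0.1, 0.9)
    pB <- runif(1, 0.1, 0.9)
    d_hi <- min(pA * (1 - pB), (1 - pA) * pB)
    d_lo <- -min(pA * pB, (1 - pA) * (1 - pB))
    d <- runif(1, d_lo, d_hi)
    f <- c(pA * pB + d, pA * (1 - pB) - d, (1 - pA) * pB - d,
           (1 - pA) * (1 - pB) + d)
    g <- sample.int(4, 2 * n, replace = TRUE, prob = pmax(f, 0))
    dosA <- c(1, 1, 0, 0)[g]
    dosB <- c(1, 0, 1, 0)[g]
    ga <- dosA[seq(1, 2 * n, 2)] + dosA[seq(2, 2 * n, 2)]
    gb <- dosB[seq(1, 2 * n, 2)] + dosB[seq(2, 2 * n, 2)]
    tab <- matrix(0, 3, 3)
    for (k in seq_len(n)) tab[ga[k] + 1, gb[k] + 1] <- tab[ga[k] + 1, gb[k] + 1] + 1
    pa <- sum(tab * matrix(c(0, 1, 2), 3, 3)) / (2 * n)
    pb <- sum(tab * matrix(c(0, 1, 2), 3, 3, byrow = TRUE)) / (2 * n)
    if (pa > 0 && pa < 1 && pb > 0 && pb < 1) return(tab)
  }
}

# brute-force r2 between two 0/1 haplotype vectors (plain correlation)
oracle_hap_r2 <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  suppressWarnings(stats::cor(a[keep], b[keep])^2)
}

# O(n*m) region assignment scan
oracle_assign <- function(keys, regions) {
  vapply(seq_len(nrow(keys)), function(i) {
    for (j in seq_len(nrow(regions))) {
      if (keys$chrom[i] == regions$chrom[j] &&
          keys$pos[i] >= regions$start[j] &&
          keys$pos[i] <= regions$end[j]) {
        return(regions$region_id[j])
      }
    }
    NA_character_
  }, character(1))
}

# vectorised variant of the grid oracle (same 16-pair enumeration,
# evaluated across the whole pAB grid at once)
oracle_grid_max_loglik_fast <- function(counts, resolution = 1e-4) {
  n <- sum(counts)
  pA <- sum(counts * matrix(c(0, 1, 2), 3, 3)) / (2 * n)
  pB <- sum(counts * matrix(c(0, 1, 2), 3, 3, byrow = TRUE)) / (2 * n)
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  grid <- unique(c(seq(lo, hi, by = resolution), hi))
  f <- cbind(grid, pA - grid, pB - grid, 1 - pA - pB + grid)
  f[f < 0] <- 0
  dosA <- c(1, 1, 0, 0)
  dosB <- c(1, 0, 1, 0)
  cell <- matrix(0, length(grid), 9)
  for (g1 in 1:4) for (g2 in 1:4) {
    idx <- (dosA[g1] + dosA[g2]) + 3 * (dosB[g1] + dosB[g2]) + 1
    cell[, idx] <- cell[, idx] + f[, g1] * f[, g2]
  }
  # counts laid out to match idx = dosageA + 3 * dosageB + 1
  cvec <- as.vector(counts)  # counts[i, j] with i = dosA + 1, j = dosB + 1
  ll <- cell
  ll[ll < .Machine$double.xmin] <- .Machine$double.xmin
  max(log(ll) %*% cvec)
}
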