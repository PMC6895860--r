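#' Specify a synthetic fine-mapping study
#'
#' Bundles every knob of the fixture generator: population pool sizes
#' (defaults match the 1000 Genomes pools backing the design: NFE 403,
#' AMR 338, AA 149 individuals), the replication-status mix over index
#' signals, per-candidate planted r-squared targets per pool, allele
#' frequencies, annotation criterion fractions, and the seed. The same
#' spec (including seed) always generates identical fixtures.
#'
#' @param statuses Character vector, one entry per index signal, from
#'   `"BOTH"`, `"ONE_AMR"`, `"ONE_AA"`, `"OPPOSITE_AMR"`,
#'   `"OPPOSITE_AA"`, `"NONE"`.
#' @param populations Named integer vector of diploid sample counts.
#' @param planted_r2 Tibble with one row per candidate slot and columns
#'   `r2_nfe`, `r2_amr`, `r2_aa`; every signal gets this candidate set.
#' @param maf_index,maf_candidate ALT-allele frequencies used when
#'   planting haplotypes.
#' @param fractions Named list of annotation fractions: `effect`, `cadd`,
#'   `regulome`, `freq_pass`, `manifest`. Allocation is deterministic and
#'   exact (`round(fraction * n)` keys).
#' @param n_mhc_variants Annotation-only variants placed inside the MHC
#'   window to exercise the coding/regulatory arm there.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(statuses = c("BOTH", "BOTH", "ONE_AMR", "ONE_AA",
                                      "OPPOSITE_AA", "NONE", "NONE"),
                         populations = c(NFE = 403L, AMR = 338L, AA = 149L),
                         planted_r2 = tibble(
                           r2_nfe = c(0.5, 0.2, 0.05),
                           r2_amr = c(0.5, 0.2, 0.05),
                           r2_aa = c(0.5, 0.2, 0.05)
                         ),
                         maf_index = 0.3, maf_candidate = 0.3,
                         fractions = list(effect = 0.10, cadd = 0.05,
                                          regulome = 0.05, freq_pass = 0.8,
                                          manifest = 0.2),
                         n_mhc_variants = 6L,
                         seed = 1L) {
  stopifnot(all(statuses %in% c("BOTH", "ONE_AMR", "ONE_AA", "OPPOSITE_AMR",
                                "OPPOSITE_AA", "NONE")),
            all(populations > 0),
            setequal(names(populations), c("NFE", "AMR", "AA")),
            all(unlist(fractions) >= 0 & unlist(fractions) <= 1))
  r2_cols <- c("r2_nfe", "r2_amr", "r2_aa")
  stopifnot(all(r2_cols %in% names(planted_r2)),
            all(unlist(planted_r2[r2_cols]) >= 0),
            all(unlist(planted_r2[r2_cols]) <= 1))
  structure(list(statuses = statuses, populations = populations,
                 planted_r2 = as_tibble(planted_r2),
                 maf_index = maf_index, maf_candidate = maf_candidate,
                 fractions = fractions, n_mhc_variants = n_mhc_variants,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

allele_cycle <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"),
                       ncol = 2, byrow = TRUE)

# derived seeds stay inside the 32-bit integer range whatever the base seed
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * salt + salt) %% 2147483647)
}

#' Lay out the synthetic variant map
#'
#' Index signals are spaced 10 Mb apart (cycling over autosomes 1-22) so
#' their 1-Mb-flank windows never merge; each signal's candidates sit at
#' 10-kb offsets inside its window. Deterministic, no randomness.
#'
#' @param spec A [fixture_spec()].
#' @return List of tibbles: `signals` (variant keys, one per status entry)
#'   and `candidates` (variant keys with `signal` id, `slot`, and the
#'   planted per-pool r-squared targets).
#' @export
fixture_layout <- function(spec) {
  n_sig <- length(spec$statuses)
  idx <- seq_len(n_sig) - 1L
  # one signal per chromosome per 10-Mb tier: windows never merge
  signals <- tibble(
    chrom = as.character((idx %% 22L) + 1L),
    pos = 20000000L + (idx %/% 22L) * 10000000L,
    ref = "A", alt = "G"
  )
  signals <- validate_variant_keys(signals, require_unique = TRUE)
  signals$signal_id <- signals$variant

  n_cand <- nrow(spec$planted_r2)
  candidates <- tidyr::crossing(signal = signals$variant,
                                slot = seq_len(n_cand)) |>
    left_join(signals |> select(signal = variant, chrom, sig_pos = pos),
              by = "signal") |>
    mutate(pos = sig_pos + 10000L * slot,
           ref = allele_cycle[(slot - 1L) %% 4L + 1L, 1],
           alt = allele_cycle[(slot - 1L) %% 4L + 1L, 2]) |>
    select(-sig_pos) |>
    left_join(spec$planted_r2 |> mutate(slot = row_number()), by = "slot")
  candidates <- validate_variant_keys(candidates, require_unique = TRUE)
  list(signals = signals, candidates = candidates)
}

#' Sample a haplotype pair with planted LD
#'
#' Draws `n_haplotypes` two-locus gametes from the exact four-gamete
#' distribution whose disequilibrium is D = sign * sqrt(r2 * pA(1-pA)
#' pB(1-pB)), so the expected sample r-squared equals the target. Errors
#' when the target is unattainable for the given allele frequencies,
#' reporting the attainable maximum.
#'
#' @param pA,pB ALT-allele frequencies at the two loci, in (0, 1).
#' @param target_r2 Desired r-squared in [0, 1].
#' @param n_haplotypes Number of gametes to draw.
#' @param seed Optional seed (local to this call).
#' @param sign Sign of D (+1 couples the two ALT alleles).
#' @return Integer matrix `n_haplotypes` x 2 of 0/1 alleles.
#' @export
plant_ld_pair <- function(pA, pB, target_r2, n_haplotypes, seed = NULL,
                          sign = 1) {
  freqs <- gamete_freqs_for_r2(pA, pB, target_r2, sign)
  draw <- function() {
    g <- sample.int(4, n_haplotypes, replace = TRUE, prob = freqs)
    # gamete order: AB, Ab, aB, ab
    cbind(a = as.integer(g <= 2), b = as.integer(g %in% c(1L, 3L)))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

gamete_freqs_for_r2 <- function(pA, pB, target_r2, sign = 1) {
  stopifnot(pA > 0, pA < 1, pB > 0, pB < 1, target_r2 >= 0, target_r2 <= 1)
  denom <- pA * (1 - pA) * pB * (1 - pB)
  d <- sign * sqrt(target_r2 * denom)
  d_max <- if (sign >= 0) min(pA * (1 - pB), (1 - pA) * pB)
           else min(pA * pB, (1 - pA) * (1 - pB))
  if (abs(d) > d_max + 1e-12) {
    abort(paste0("target r2 ", signif(target_r2, 4),
                 " infeasible for pA=", pA, ", pB=", pB,
                 "; attainable maximum is ", signif(d_max^2 / denom, 4)))
  }
  c(AB = pA * pB + d, Ab = pA * (1 - pB) - d,
    aB = (1 - pA) * pB - d, ab = (1 - pA) * (1 - pB) + d)
}

#' Generate phased genotype panels with planted LD
#'
#' For each population pool, index haplotypes are drawn Bernoulli(pA) and
#' each candidate's alleles are drawn conditionally on the index allele
#' from the gamete distribution matching that pool's planted r-squared
#' target. Haplotypes are independent across individuals (no
#' recombination map); realism beyond the planted pairwise structure is
#' not attempted.
#'
#' @param spec A [fixture_spec()].
#' @return Named list of phased [genotype_panel]s (NFE, AMR, AA).
#' @export
generate_panels <- function(spec) {
  layout <- fixture_layout(spec)
  pops <- names(spec$populations)
  panels <- setNames(vector("list", length(pops)), pops)
  for (pi in seq_along(pops)) {
    pop <- pops[pi]
    n_hap <- 2L * spec$populations[[pop]]
    panels[[pop]] <- withr::with_seed(derive_seed(spec$seed, 131) + pi, {
      build_population_panel(spec, layout, pop, n_hap)
    })
  }
  panels
}

build_population_panel <- function(spec, layout, pop, n_hap) {
  r2_col <- paste0("r2_", tolower(pop))
  variants <- bind_rows(
    layout$signals |> select(chrom, pos, ref, alt),
    layout$candidates |> select(chrom, pos, ref, alt)
  ) |> validate_variant_keys(require_unique = TRUE)
  hap <- matrix(NA_integer_, nrow = n_hap, ncol = nrow(variants))
  colnames(hap) <- variants$variant
  for (s in seq_len(nrow(layout$signals))) {
    sig <- layout$signals[s, ]
    idx_hap <- rbinom(n_hap, 1L, spec$maf_index)
    hap[, sig$variant] <- idx_hap
    cands <- layout$candidates |> filter(signal == sig$variant)
    for (ci in seq_len(nrow(cands))) {
      freqs <- gamete_freqs_for_r2(spec$maf_index, spec$maf_candidate,
                                   cands[[r2_col]][ci])
      pA <- spec$maf_index
      p_b_given_a1 <- freqs["AB"] / pA
      p_b_given_a0 <- freqs["aB"] / (1 - pA)
      u <- runif(n_hap)
      hap[, cands$variant[ci]] <- as.integer(
        u < ifelse(idx_hap == 1L, p_b_given_a1, p_b_given_a0))
    }
  }
  n_ind <- n_hap %/% 2L
  geno <- hap[seq(1, n_hap, by = 2), , drop = FALSE] +
    hap[seq(2, n_hap, by = 2), , drop = FALSE]
  genotype_panel(population = pop,
                 samples = sprintf("%s%04d", pop, seq_len(n_ind)),
                 variants = variants, geno = geno, hap = hap, phased = TRUE)
}

#' Write a genotype panel as a phased VCF
#'
#' @param panel A phased [genotype_panel].
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  stopifnot(isTRUE(panel$phased))
  v <- panel$variants
  n_ind <- length(panel$samples)
  gt <- matrix("", nrow = nrow(v), ncol = n_ind)
  for (j in seq_len(n_ind)) {
    h1 <- panel$hap[2L * j - 1L, ]
    h2 <- panel$hap[2L * j, ]
    gt[, j] <- paste0(ifelse(is.na(h1), ".", h1), "|",
                      ifelse(is.na(h2), ".", h2))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=finearray_fixture_", panel$population),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")
  )
  ord <- order(v$chrom, v$pos)
  body <- vapply(ord, function(i) {
    paste(c(v$chrom[i], v$pos[i], v$variant[i], v$ref[i], v$alt[i], ".",
            "PASS", ".", "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate fixture VCFs for every population
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of VCF paths.
#' @export
generate_panel_vcf <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  panels <- generate_panels(spec)
  paths <- vapply(names(panels), function(pop) {
    p <- file.path(dir, paste0("panel_", pop, ".vcf"))
    write_panel_vcf(panels[[pop]], p)
    p
  }, character(1))
  paths
}

#' Generate the index-signal replication table
#'
#' Draws effect signs and two-sided p-values so that
#' [classify_replication_status()] recovers each signal's intended class:
#' replicating records get a same-direction sign with two-sided p small
#' enough that the one-sided p is at most 0.05; OPPOSITE records get an
#' opposite-direction sign with two-sided p at most 0.10;
#' non-replicating records get large p-values. The intended class is
#' returned in `intended_status` (a ground-truth sidecar, not a pipeline
#' input column).
#'
#' @param spec A [fixture_spec()].
#' @return Index-signal tibble with `intended_status` / `intended_pop`.
#' @export
generate_replication_table <- function(spec) {
  layout <- fixture_layout(spec)
  n <- length(spec$statuses)
  withr::with_seed(derive_seed(spec$seed, 977), {
    disc <- sample(c(-1L, 1L), n, replace = TRUE)
    p_rep <- function(m) runif(m, 0.001, 0.08)    # one-sided <= 0.04
    p_opp <- function(m) runif(m, 0.001, 0.09)    # two-sided <= 0.10
    p_null <- function(m) runif(m, 0.5, 0.95)
    amr_sign <- disc; aa_sign <- disc
    amr_p2 <- p_null(n); aa_p2 <- p_null(n)
    st <- spec$statuses
    amr_p2[st %in% c("BOTH", "ONE_AMR")] <-
      p_rep(sum(st %in% c("BOTH", "ONE_AMR")))
    aa_p2[st %in% c("BOTH", "ONE_AA")] <-
      p_rep(sum(st %in% c("BOTH", "ONE_AA")))
    amr_p2[st == "OPPOSITE_AMR"] <- p_opp(sum(st == "OPPOSITE_AMR"))
    amr_sign[st == "OPPOSITE_AMR"] <- -disc[st == "OPPOSITE_AMR"]
    aa_p2[st == "OPPOSITE_AA"] <- p_opp(sum(st == "OPPOSITE_AA"))
    aa_sign[st == "OPPOSITE_AA"] <- -disc[st == "OPPOSITE_AA"]
    layout$signals |>
      select(chrom, pos, ref, alt, variant) |>
      mutate(discovery_direction = disc,
             amr_beta_sign = amr_sign, amr_p2 = amr_p2,
             aa_beta_sign = aa_sign, aa_p2 = aa_p2,
             intended_status = sub("_(AMR|AA)$", "", st),
             intended_pop = ifelse(grepl("_(AMR|AA)$", st),
                                   sub("^.*_", "", st), NA_character_))
  })
}

#' Generate annotation, manifest and designability fixtures
#'
#' Criterion flags are allocated deterministically and exactly:
#' `round(fraction * n)` of the keys (in a seed-shuffled order, one
#' independent shuffle per criterion) receive each property. Keys passing
#' the frequency gate get AFR MAF 0.2; the rest get frequencies below
#' every threshold. A ground-truth tibble of the planted flags is
#' returned alongside so tests never re-derive expectations from the
#' generator internals.
#'
#' @param spec A [fixture_spec()].
#' @param keys Tibble of variant keys to annotate; defaults to the full
#'   fixture layout plus `n_mhc_variants` MHC-only variants.
#' @return List of tibbles: `annotations`, `manifest`, `designability`,
#'   `truth`.
#' @export
generate_annotation_and_manifest <- function(spec, keys = NULL) {
  if (is.null(keys)) {
    layout <- fixture_layout(spec)
    mhc <- if (spec$n_mhc_variants > 0) {
      tibble(chrom = "6",
             pos = 28000000L + 100000L * seq_len(spec$n_mhc_variants),
             ref = "A", alt = "G")
    } else NULL
    keys <- bind_rows(
      layout$signals |> select(chrom, pos, ref, alt),
      layout$candidates |> select(chrom, pos, ref, alt),
      mhc
    )
  }
  keys <- validate_variant_keys(keys, require_unique = TRUE)
  n <- nrow(keys)
  fr <- spec$fractions
  withr::with_seed(derive_seed(spec$seed, 613), {
    pick <- function(frac) {
      chosen <- logical(n)
      chosen[sample.int(n, round(frac * n))] <- TRUE
      chosen
    }
    truth <- tibble(
      variant = keys$variant,
      effect_pass = pick(fr$effect),
      cadd_pass = pick(fr$cadd),
      regulome_pass = pick(fr$regulome),
      freq_pass = pick(fr$freq_pass),
      in_manifest = pick(fr$manifest)
    )
    effect_classes <- c("nonsynonymous", "stopgain", "stoploss", "splicing")
    regulome_cats <- c("1a", "1b", "1c", "1d", "1e")
    annotations <- keys |>
      select(chrom, pos, ref, alt) |>
      mutate(
        effect = ifelse(truth$effect_pass,
                        effect_classes[(row_number() %% 4L) + 1L],
                        "synonymous"),
        cadd = ifelse(truth$cadd_pass, runif(n, 30, 50), runif(n, 0, 25)),
        regulome = ifelse(truth$regulome_pass,
                          regulome_cats[(row_number() %% 5L) + 1L], "7"),
        afr_maf = ifelse(truth$freq_pass, 0.2, 0.005),
        amr_maf = ifelse(truth$freq_pass, 0.2, 0.005),
        nfe_maf = ifelse(truth$freq_pass, 0.2, 0.01),
        eas_maf = ifelse(truth$freq_pass, 0.2, 0.01)
      )
    manifest <- keys |>
      filter(truth$in_manifest) |>
      select(chrom, pos, ref, alt) |>
      mutate(source = "MEGA_EX")
    designability <- keys |>
      select(chrom, pos, ref, alt) |>
      mutate(score = runif(n, 0.6, 1.0))
    list(annotations = annotations, manifest = manifest,
         designability = designability, truth = truth)
  })
}

#' Generate a complete synthetic study on disk
#'
#' Writes every input the pipeline consumes — phased panel VCFs per
#' population, the index-signal TSV, annotation, manifest, designability
#' and INFO-score tables — plus ground-truth sidecars, all derived from
#' one seed.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @return Named list of file paths plus the `truth` tibbles.
#' @export
generate_study <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  panel_paths <- generate_panel_vcf(spec, dir)
  signals <- generate_replication_table(spec)
  ann <- generate_annotation_and_manifest(spec)
  info <- withr::with_seed(derive_seed(spec$seed, 389), {
    ann$annotations |>
      select(chrom, pos, ref, alt) |>
      mutate(info = round(runif(n()), 4))
  })
  paths <- list(
    panels = panel_paths,
    signals = file.path(dir, "index_signals.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    manifest = file.path(dir, "manifest.tsv"),
    designability = file.path(dir, "designability.tsv"),
    info = file.path(dir, "info_scores.tsv"),
    truth_signals = file.path(dir, "truth_signals.tsv"),
    truth_annotations = file.path(dir, "truth_annotations.tsv")
  )
  readr::write_tsv(signals |> select(-variant, -intended_status,
                                     -intended_pop),
                   paths$signals, progress = FALSE)
  readr::write_tsv(signals |> select(variant, intended_status, intended_pop),
                   paths$truth_signals, progress = FALSE)
  readr::write_tsv(ann$annotations, paths$annotations, progress = FALSE)
  readr::write_tsv(ann$manifest, paths$manifest, progress = FALSE)
  readr::write_tsv(ann$designability, paths$designability, progress = FALSE)
  readr::write_tsv(ann$truth, paths$truth_annotations, progress = FALSE)
  readr::write_tsv(info, paths$info, progress = FALSE)
  paths$truth <- list(signals = signals, annotations = ann$truth)
  paths
}
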