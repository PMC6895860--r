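#' Tidy a design result
#'
#' Returns the final selection as a tibble, one row per selected variant
#' with arm, criteria, replication status and bead-count provenance.
#'
#' @param x A `design_result` from [run_design()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy design_result
#' @export
tidy.design_result <- function(x, ...) {
  as_tibble(x$selection)
}

#' One-row summary of a design result
#'
#' @param x A `design_result`.
#' @param ... Unused.
#' @return One-row tibble: region, arm, partition and bead-type counts
#'   plus the INFO threshold used.
#' @method glance design_result
#' @export
glance.design_result <- function(x, ...) {
  tibble(
    n_regions = nrow(x$regions),
    n_coding_regulatory = sum(grepl("coding_regulatory", x$selection$arm)),
    n_fine_mapping = sum(grepl("fine_mapping", x$selection$arm)),
    n_priority = unname(x$partition["priority"]),
    n_retained = unname(x$partition["retained"]),
    info_threshold = x$info_threshold,
    n_variants = x$n_variants,
    n_bead_types = x$n_bead_types
  )
}

#' Funnel plot of a design run
#'
#' Per-stage output counts of the selection cascade, in pipeline order —
#' the plot mirrors the workflow's selection funnel.
#'
#' @param object A `design_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot design_result
#' @export
autoplot.design_result <- function(object, ...) {
  f <- object$funnel |>
    mutate(stage = factor(stage, levels = rev(stage)))
  ggplot2::ggplot(f, ggplot2::aes(x = n_out, y = stage)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_text(ggplot2::aes(label = n_out), hjust = -0.15,
                       size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(c(0, 0.15))) +
    ggplot2::labs(x = "variants out of stage", y = NULL,
                  title = "Custom-content selection funnel") +
    ggplot2::theme_minimal()
}

#' LD profile plot around an index variant
#'
#' Pairwise r-squared of every panel variant in a region against the
#' index, per population pool, with the inclusive selection threshold
#' drawn as a horizontal line.
#'
#' @param panels Named list of [genotype_panel]s.
#' @param index_key Index variant id.
#' @param region One-row region tibble.
#' @param threshold r-squared bound to draw.
#' @param method Passed to [pairwise_r2()].
#' @return A ggplot object.
#' @export
plot_ld_profile <- function(panels, index_key, region, threshold = 0.1,
                            method = "auto") {
  prof <- imap(panels, function(panel, pop) {
    cand <- panel$variants |>
      filter(chrom == region$chrom[1], pos >= region$start[1],
             pos <= region$end[1])
    if (nrow(cand) == 0) return(NULL)
    cand |>
      mutate(r2 = vapply(variant, function(v) {
        pairwise_r2(panel, index_key, v, method = method)$r2
      }, numeric(1)), population = pop)
  }) |> bind_rows()
  ggplot2::ggplot(prof, ggplot2::aes(x = pos / 1e6, y = r2,
                                     colour = population)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "position (Mb)", y = expression(r^2),
                  title = paste("LD with", index_key)) +
    ggplot2::theme_minimal()
}
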