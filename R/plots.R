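#' Q-Q plot of observed versus expected p-values
#'
#' @param rows An `rr_gwas` tibble, or a numeric vector of p-values.
#' @param layer Layer to plot when `rows` is a GWAS table.
#' @return A ggplot; the genomic inflation factor is annotated on the
#'   panel.
#' @export
plot_qq <- function(rows, layer = "joint") {
  if (is.numeric(rows)) {
    p <- rows[!is.na(rows)]
    lambda <- median(qchisq(p, 1, lower.tail = FALSE)) / qchisq(0.5, 1)
  } else {
    p <- rows[[paste0("p_", layer)]]
    p <- p[!is.na(p)]
    s <- gwas_summaries(rows)
    lambda <- s$lambda_per_layer[[layer]]
  }
  n <- length(p)
  df <- tibble(
    expected = -log10(stats::ppoints(n)),
    observed = -log10(sort(p))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
                      label = sprintf("lambda == %.2f", lambda),
                      parse = TRUE) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  title = sprintf("Q-Q plot (%s layer)",
                                  if (is.numeric(rows)) "p" else layer)) +
    ggplot2::theme_minimal()
}

#' Rectangular Manhattan plot for one layer
#'
#' @param rows An `rr_gwas` tibble.
#' @param layer Layer to display.
#' @param summary Optional [gwas_summaries()] object supplying thresholds.
#' @return A ggplot.
#' @export
plot_manhattan <- function(rows, layer = "joint", summary = NULL) {
  summary <- summary %||% gwas_summaries(rows)
  df <- manhattan_frame(rows)
  df$p <- rows[[paste0("p_", layer)]][match(df$snp_id, rows$snp_id)]
  df <- df[!is.na(df$p), ]
  df$neglog <- -log10(df$p)
  df$sig <- df$p < summary$suggestive_p
  ggplot2::ggplot(df, ggplot2::aes(.data$cumpos, .data$neglog,
                                   colour = .data$chrom_parity)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$sig), show.legend = FALSE) +
    ggplot2::scale_size_manual(values = c(`FALSE` = 0.7, `TRUE` = 2.2)) +
    ggplot2::scale_colour_manual(values = c(a = "grey30", b = "steelblue")) +
    ggplot2::geom_hline(yintercept = -log10(summary$suggestive_p),
                        linetype = 3, colour = "red") +
    ggplot2::scale_x_continuous(breaks = attr(df, "chrom_centers"),
                                labels = attr(df, "chrom_labels")) +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](p)),
                  title = sprintf("%s layer", layer)) +
    ggplot2::theme_minimal()
}

#' Circular Manhattan plot with the three GWAS layers
#'
#' Three concentric rings — outer: intercept ("baseline") layer, middle:
#' slope layer, inner: joint layer — each with its dotted suggestive
#' threshold circle; SNPs passing the threshold are enlarged.
#'
#' @param rows An `rr_gwas` tibble.
#' @param summary Optional [gwas_summaries()] supplying thresholds.
#' @return A ggplot built with polar coordinates.
#' @export
plot_manhattan_circular <- function(rows, summary = NULL) {
  summary <- summary %||% gwas_summaries(rows)
  base <- manhattan_frame(rows)
  rings <- list(joint = 0, slope = 1, intercept = 2)  # inner to outer
  ring_height <- 0.85
  dfs <- lapply(names(rings), function(l) {
    p <- rows[[paste0("p_", l)]][match(base$snp_id, rows$snp_id)]
    keep <- !is.na(p)
    neglog <- -log10(p[keep])
    top <- max(neglog, -log10(summary$suggestive_p)) * 1.05
    d <- base[keep, ]
    d$layer <- l
    d$radius <- 1 + rings[[l]] + ring_height * neglog / top
    d$sig <- p[keep] < summary$suggestive_p
    d$thr_radius <- 1 + rings[[l]] +
      ring_height * (-log10(summary$suggestive_p)) / top
    d
  })
  df <- bind_rows(dfs)
  thr <- distinct(df, .data$layer, .data$thr_radius)
  ggplot2::ggplot(df, ggplot2::aes(.data$cumpos, .data$radius)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chrom_parity,
                                     size = .data$sig),
                        show.legend = FALSE) +
    ggplot2::scale_size_manual(values = c(`FALSE` = 0.5, `TRUE` = 2.5)) +
    ggplot2::scale_colour_manual(values = c(a = "grey40", b = "steelblue")) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$thr_radius),
                        linetype = 3, colour = "red") +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::ylim(0, NA) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "intercept (outer), slope (middle), joint (inner)")
}

#' @method autoplot rr_gwas
#' @export
autoplot.rr_gwas <- function(object, type = c("circular", "manhattan", "qq"),
                             ...) {
  type <- match.arg(type)
  switch(type,
         circular = plot_manhattan_circular(object, ...),
         manhattan = plot_manhattan(object, ...),
         qq = plot_qq(object, ...))
}

#' Render the standard plot set to files
#'
#' Writes the circular Manhattan plot, a rectangular Manhattan plot per
#' layer and a Q-Q plot per layer as PNG files. Deterministic given fixed
#' inputs.
#'
#' @param rows An `rr_gwas` tibble.
#' @param summary Optional [gwas_summaries()].
#' @param out_dir Output directory (created if needed).
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return Invisibly, the paths written.
#' @export
render_plots <- function(rows, summary = NULL, out_dir,
                         width = 7, height = 6, dpi = 150) {
  summary <- summary %||% gwas_summaries(rows)
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create '%s'", out_dir))
  paths <- character()
  save_one <- function(plot, name) {
    path <- file.path(out_dir, name)
    ggplot2::ggsave(path, plot, width = width, height = height, dpi = dpi)
    paths <<- c(paths, path)
  }
  save_one(plot_manhattan_circular(rows, summary), "manhattan_circular.png")
  for (l in c("intercept", "slope", "joint")) {
    save_one(plot_manhattan(rows, l, summary),
             sprintf("manhattan_%s.png", l))
    save_one(plot_qq(rows, l), sprintf("qq_%s.png", l))
  }
  invisible(paths)
}

## cumulative positions + alternating chromosome shading
manhattan_frame <- function(rows) {
  df <- tibble(snp_id = rows$snp_id, chrom = rows$chrom, pos = rows$pos)
  df <- arrange(df, chrom_order(.data$chrom), .data$pos)
  offs <- df %>%
    group_by(.data$chrom) %>%
    summarise(len = max(.data$pos), .groups = "drop") %>%
    arrange(chrom_order(.data$chrom)) %>%
    mutate(offset = cumsum(dplyr::lag(.data$len, default = 0)),
           parity = rep(c("a", "b"), length.out = n()))
  df <- left_join(df, offs, by = "chrom")
  df$cumpos <- df$pos + df$offset
  df$chrom_parity <- df$parity
  centers <- df %>% group_by(.data$chrom) %>%
    summarise(c = mean(range(.data$cumpos)), .groups = "drop") %>%
    arrange(chrom_order(.data$chrom))
  attr(df, "chrom_centers") <- centers$c
  attr(df, "chrom_labels") <- centers$chrom
  df
}
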