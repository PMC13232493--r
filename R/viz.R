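# Locus-zoom and UpSet figures. Figures are by-products: every number they
# render comes from already-validated tables, and tests introspect track
# and bar structure rather than pixels.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_segment
#'   geom_hline geom_text labs theme_minimal theme element_blank
#'   scale_y_continuous scale_x_continuous scale_color_manual sym
NULL

#' Locus-zoom figure with association, haplotype, and gene tracks
#'
#' Renders the standard regional-association view for one locus as stacked
#' tracks: (1) the association track, one LOD trace per condition with the
#' permutation significance threshold as a dashed line (the threshold is an
#' input from the upstream mapping, never computed here); (2) founder
#' haplotype-effect trajectories, present only when supplied; (3) the gene
#' track, genes as strand-agnostic bars with highlighted genes visually
#' distinct.
#'
#' @param scan Scan tibble for the locus window: `marker`, `chrom`,
#'   `position`, one numeric LOD column per condition.
#' @param threshold Genome-wide significance LOD threshold (dashed line).
#' @param genes Optional gene table (`gene_symbol`, `start`, `end`).
#' @param haplotype_effects Optional [haplotype_effects()] restricted to
#'   the window.
#' @param highlight Character vector of gene symbols drawn in the
#'   highlight color.
#' @param palette Optional named condition -> color vector.
#' @param out_path Optional `.png`/`.pdf` path; written when given.
#' @param width,height,dpi Device settings for `out_path`.
#' @return An `lp_locus_zoom` object: `$figure` (patchwork), `$tracks`
#'   (ordered track labels), `$conditions`.
#' @export
plot_locus_zoom <- function(scan, threshold, genes = NULL,
                            haplotype_effects = NULL, highlight = character(),
                            palette = NULL, out_path = NULL,
                            width = 8, height = 7, dpi = 150) {
  validate_scan(scan)
  lp_assert(nrow(scan) > 0, "cannot draw a locus zoom from an empty scan")
  conditions <- setdiff(names(scan), c("marker", "chrom", "position"))
  window <- range(scan$position)
  if (!is.null(haplotype_effects)) {
    lp_assert(inherits(haplotype_effects, "lp_haplotype_effects"),
              "`haplotype_effects` must come from haplotype_effects()")
    inside <- haplotype_effects$positions >= window[1] &
      haplotype_effects$positions <= window[2]
    lp_assert(all(inside),
              "haplotype effect positions fall outside the scan window")
  }

  long <- tidyr::pivot_longer(scan, cols = dplyr::all_of(conditions),
                              names_to = "condition", values_to = "lod")
  p_assoc <- ggplot(long, aes(x = .data$position / 1e6, y = .data$lod,
                              color = .data$condition)) +
    geom_line() +
    geom_hline(yintercept = threshold, linetype = "dashed", color = "grey30") +
    labs(x = NULL, y = "LOD", color = NULL) +
    theme_minimal()
  if (!is.null(palette)) {
    p_assoc <- p_assoc + scale_color_manual(values = palette)
  }

  tracks <- list(association = p_assoc)
  if (!is.null(haplotype_effects)) {
    he <- haplotype_effects
    eff <- as_tibble(as.data.frame(he$effects))
    names(eff) <- he$founder_labels
    eff$position <- he$positions
    eff_long <- tidyr::pivot_longer(eff, cols = dplyr::all_of(he$founder_labels),
                                    names_to = "founder", values_to = "effect")
    tracks$haplotypes <- ggplot(eff_long, aes(x = .data$position / 1e6,
                                              y = .data$effect,
                                              color = .data$founder)) +
      geom_line() +
      labs(x = NULL, y = "haplotype effect", color = NULL) +
      theme_minimal()
  }

  gene_df <- if (is.null(genes) || nrow(genes) == 0) {
    tibble(gene_symbol = character(), start = numeric(), end = numeric(),
           y = numeric(), highlighted = logical())
  } else {
    g <- as_tibble(genes)[, c("gene_symbol", "start", "end")]
    g$y <- (seq_len(nrow(g)) - 1) %% 8  # stagger overlapping labels
    g$highlighted <- g$gene_symbol %in% highlight
    g
  }
  p_genes <- ggplot(gene_df) +
    geom_segment(aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                     y = .data$y, yend = .data$y,
                     color = .data$highlighted),
                 linewidth = 2, show.legend = FALSE) +
    scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                       drop = FALSE) +
    scale_x_continuous(limits = window / 1e6) +
    labs(x = "position (Mb)", y = NULL) +
    theme_minimal() +
    theme(axis.text.y = element_blank(), panel.grid = element_blank())
  if (nrow(gene_df) > 0) {
    p_genes <- p_genes +
      geom_text(aes(x = (.data$start + .data$end) / 2e6, y = .data$y + 0.35,
                    label = .data$gene_symbol), size = 2)
  }
  tracks$genes <- p_genes

  heights <- c(2, if (!is.null(haplotype_effects)) 1.5, 1.5)
  figure <- patchwork::wrap_plots(tracks, ncol = 1, heights = heights)
  out <- structure(
    list(figure = figure, tracks = names(tracks), conditions = conditions),
    class = "lp_locus_zoom"
  )
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, figure, width = width, height = height,
                    dpi = dpi)
  }
  out
}

#' @export
print.lp_locus_zoom <- function(x, ...) {
  print(x$figure)
  invisible(x)
}

#' UpSet figure of evidence-overlap classes
#'
#' Draws the standard UpSet view of an [overlap_counts()] partition:
#' intersection bars ordered by descending class count, with the
#' criterion-membership dot matrix below. Bar heights sum to the number of
#' screened genes by construction.
#'
#' @param counts An [overlap_counts()] result (non-empty).
#' @param highlight Optional named vector, class key -> color.
#' @param out_path Optional `.png`/`.pdf` path.
#' @param width,height,dpi Device settings for `out_path`.
#' @return An `lp_upset` object: `$figure`, `$bar_heights` (named,
#'   descending), `$criteria`.
#' @export
plot_upset <- function(counts, highlight = NULL, out_path = NULL,
                       width = 7, height = 5, dpi = 150) {
  lp_assert(inherits(counts, "lp_overlap_counts"),
            "`counts` must come from overlap_counts()")
  lp_assert(nrow(counts) > 0, "cannot draw an UpSet figure from empty counts")
  criteria <- attr(counts, "criteria_names")

  ord <- counts[order(-counts$count, counts$key), ]
  ord$class_idx <- seq_len(nrow(ord))
  ord$label <- ifelse(nzchar(ord$key), ord$key, "(none)")
  ord$fill <- "grey35"
  if (!is.null(highlight)) {
    hit <- match(ord$key, names(highlight))
    ord$fill[!is.na(hit)] <- unname(highlight[hit[!is.na(hit)]])
  }

  p_bars <- ggplot(ord, aes(x = .data$class_idx, y = .data$count)) +
    geom_col(fill = ord$fill) +
    geom_text(aes(label = .data$count), vjust = -0.4, size = 3) +
    scale_x_continuous(breaks = NULL) +
    labs(x = NULL, y = "genes") +
    theme_minimal()

  dots <- tidyr::expand_grid(class_idx = ord$class_idx, criterion = criteria)
  dots$member <- mapply(function(ci, cr) cr %in% ord$members[[ci]],
                        dots$class_idx, dots$criterion)
  dots$criterion <- factor(dots$criterion, levels = rev(criteria))
  p_dots <- ggplot(dots, aes(x = .data$class_idx, y = .data$criterion)) +
    geom_point(aes(alpha = .data$member), size = 3, show.legend = FALSE) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.15)) +
    scale_x_continuous(breaks = NULL) +
    labs(x = NULL, y = NULL) +
    theme_minimal()

  figure <- patchwork::wrap_plots(list(p_bars, p_dots), ncol = 1,
                                  heights = c(2, 1))
  out <- structure(
    list(figure = figure,
         bar_heights = setNames(ord$count, ord$label),
         criteria = criteria),
    class = "lp_upset"
  )
  if (!is.null(out_path)) {
    ggplot2::ggsave(out_path, figure, width = width, height = height,
                    dpi = dpi)
  }
  out
}

#' @export
print.lp_upset <- function(x, ...) {
  print(x$figure)
  invisible(x)
}
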