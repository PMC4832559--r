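#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_tile
#'   geom_hline labs scale_color_brewer facet_wrap theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot per-site validation statistics
#'
#' Minor allele frequency against observed heterozygosity, coloured by MAF
#' group, with point size tracking the Hardy-Weinberg deviation.
#'
#' @param object A [site_stats()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.site_stats <- function(object, ...) {
  df <- mutate(as_tibble(object),
               hwe_neglog10 = -log10(pmax(.data$p_hwe, 1e-12)))
  ggplot(df, aes(x = .data$maf, y = .data$het_obs,
                 color = .data$maf_group, size = .data$hwe_neglog10)) +
    geom_point(alpha = 0.8) +
    scale_color_brewer(palette = "Dark2", drop = FALSE) +
    labs(x = "minor allele frequency", y = "observed heterozygosity",
         color = "MAF group", size = expression(-log[10] * " P(HWE)")) +
    theme_minimal()
}

#' Plot association scan results
#'
#' Per-site `-log10` nominal P-values by method, with the Bonferroni
#' significance line at `alpha / m`.
#'
#' @param object An [assoc_scan()] tibble.
#' @param alpha Experiment-wide level for the significance line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assoc_scan <- function(object, alpha = 0.05, ...) {
  df <- filter(as_tibble(object), !is.na(.data$p_nominal))
  ggplot(df, aes(x = .data$site_id, y = -log10(.data$p_nominal),
                 fill = .data$method)) +
    geom_col(position = "dodge") +
    geom_hline(yintercept = -log10(alpha / max(df$m)), linetype = "dashed") +
    labs(x = NULL, y = expression(-log[10] * " P"), fill = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot an IBS kinship matrix
#'
#' @param object An [ibs_kinship()] matrix.
#' @param ... Unused.
#' @return A ggplot heatmap.
#' @export
autoplot.ibs_kinship <- function(object, ...) {
  k <- unclass(object)
  df <- tibble(
    a = factor(rep(rownames(k), times = ncol(k)), levels = rownames(k)),
    b = factor(rep(colnames(k), each = nrow(k)), levels = colnames(k)),
    ibs = as.vector(k)
  )
  ggplot(df, aes(x = .data$a, y = .data$b, fill = .data$ibs)) +
    geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "IBS") +
    theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Plot the screening filter cascade
#'
#' Bar chart of site counts surviving each screening stage, read from the
#' audit attached by [screen()].
#'
#' @param screened A [screen()] result.
#' @return A ggplot object.
#' @export
plot_filter_cascade <- function(screened) {
  audit <- attr(screened, "audit")
  if (is.null(audit)) abort("no audit attribute; pass a screen() result")
  df <- tibble(stage = factor(names(audit), levels = names(audit)),
               n = unlist(audit))
  ggplot(df, aes(x = .data$stage, y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "variant sites retained") +
    theme_minimal()
}
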