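#' Plot protein class counts and length distribution
#'
#' @param object Accessioned protein table (class `orf_proteins`).
#' @param ... Unused.
#' @return A ggplot: protein length distribution split by class.
#' @method autoplot orf_proteins
#' @export
autoplot.orf_proteins <- function(object, ...) {
  df <- tibble(class = object$class, length = object$length)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, fill = .data$class)) +
    ggplot2::geom_histogram(bins = 30, position = "stack") +
    ggplot2::labs(x = "protein length (aa)", y = "proteins",
                  title = "Predicted proteins by class") +
    ggplot2::theme_minimal()
}

#' Plot detection evidence by protein class
#'
#' @param object Evidence table (class `orf_evidence`).
#' @param ... Unused.
#' @return A ggplot bar chart of detected/undetected counts per class.
#' @method autoplot orf_evidence
#' @export
autoplot.orf_evidence <- function(object, ...) {
  df <- tibble(class = object$class, detected = object$detected)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, fill = .data$detected)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = NULL, y = "proteins",
                  title = "Expression evidence by class") +
    ggplot2::theme_minimal()
}

#' Plot variant impact tallies
#'
#' @param object Consequence table (class `orf_consequences`).
#' @param ... Unused.
#' @return A ggplot bar chart of calls per impact class.
#' @method autoplot orf_consequences
#' @export
autoplot.orf_consequences <- function(object, ...) {
  df <- tibble(impact = factor(object$impact, levels = IMPACT_LEVELS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$impact)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "impact", y = "calls",
                  title = "Variant consequences by impact") +
    ggplot2::theme_minimal()
}

#' Plot pLDDT confidence bins
#'
#' @param structure Tibble with `plddt` (and optionally `bin`).
#' @return A ggplot bar chart of proteins per confidence bin.
#' @export
plot_plddt_bins <- function(structure) {
  bins <- if ("bin" %in% names(structure)) structure$bin
          else bin_plddt(structure$plddt)
  df <- tibble(bin = factor(bins, levels = c("very_low", "medium", "high",
                                             "very_high")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "pLDDT bin", y = "proteins",
                  title = "Structure-prediction confidence") +
    ggplot2::theme_minimal()
}
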