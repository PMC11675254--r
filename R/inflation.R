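#' Genomic inflation factor (lambda)
#'
#' Median-based inflation factor: the median observed 1-df chi-square
#' statistic over informative SNPs, divided by the median of the 1-df
#' chi-square distribution (`qchisq(0.5, 1)`, about 0.4549). Values close to
#' one indicate the absence of systematic (structural) inflation.
#'
#' @param results Tibble from [tdt_scan()] (needs `chi2`, `n_informative`).
#' @return A single number.
#' @export
genomic_lambda <- function(results) {
  chi2 <- results$chi2[results$n_informative > 0]
  ptr_assert(length(chi2) > 0, "no informative SNPs for lambda",
             "pathtrio_no_informative")
  median(chi2) / qchisq(0.5, df = 1)
}

#' QQ-plot coordinates for TDT p-values
#'
#' Pairs the i-th smallest observed p-value with the uniform quantile
#' `i / (n + 1)` (which avoids `-log10(0)` at the extremes), both on the
#' `-log10` scale. Only informative SNPs enter.
#'
#' @param results Tibble from [tdt_scan()].
#' @return Tibble of class `trio_qq` with columns `expected`, `observed`
#'   (`-log10` p), sorted by `expected`.
#' @export
qq_coordinates <- function(results) {
  p <- sort(results$p[results$n_informative > 0])
  ptr_assert(length(p) > 0, "no informative SNPs for QQ coordinates",
             "pathtrio_no_informative")
  n <- length(p)
  out <- tibble::tibble(
    expected = -log10(seq_len(n) / (n + 1)),
    observed = -log10(p)
  )
  out <- dplyr::arrange(out, .data$expected)
  class(out) <- c("trio_qq", class(out))
  out
}

#' QQ plot of observed vs expected -log10 p
#'
#' @param object A `trio_qq` tibble from [qq_coordinates()], or a results
#'   tibble from [tdt_scan()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
plot_qq <- function(object, ...) {
  if (!inherits(object, "trio_qq")) object <- qq_coordinates(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_qq
#' @exportS3Method ggplot2::autoplot
autoplot.trio_qq <- function(object, ...) plot_qq(object, ...)
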