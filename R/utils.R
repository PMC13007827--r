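#' @keywords internal
"_PACKAGE"

#' @importFrom stats lm coef fft rnorm runif rbinom sd var median
#'   model.matrix plogis pnorm pchisq predict glm binomial quantile
#'   chisq.test kruskal.test complete.cases setNames aggregate
#' @importFrom utils read.csv write.csv head combn
NULL

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("epizmap_config_error", "error")))
}

stop_shape <- function(...) {
  stop(errorCondition(paste0(...), class = c("epizmap_shape_error", "error")))
}

# derive a reproducible child seed (< 2^31) from a base seed and a stage tag
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical frequency bands
#'
#' The five canonical iEEG frequency bands used throughout the package:
#' delta 1-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-80 Hz. Shared
#' edges belong to the upper band (half-open intervals).
#'
#' @return A data.frame with columns `band`, `lo`, `hi` (Hz).
#' @export
canonical_bands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    lo   = c(1, 4, 8, 13, 30),
    hi   = c(4, 8, 13, 30, 80),
    stringsAsFactors = FALSE
  )
}
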