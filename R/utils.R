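#' @keywords internal
"_PACKAGE"

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

#' Derive a child seed from a base seed
#'
#' One global seed fans out deterministically to per-stage seeds so that
#' partial reruns of a pipeline reproduce the full run.
#'
#' @param seed integer base seed.
#' @param offset integer stage offset (>= 0).
#' @return An integer seed below 2^31.
#' @export
child_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.double(seed) * 1009 + 97 * offset) %% 2147483629)
}

# stop() with a consistent prefix so pipeline stages are identifiable in logs
wc_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# quantile-based equal-tailed interval used throughout
eti <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  unname(stats::quantile(x, c(a, 1 - a), names = FALSE))
}
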