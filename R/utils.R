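#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n row_number across all_of
#' @importFrom stats median prcomp qbeta rpois rnorm rbinom rlnorm rnbinom
#'   rgamma runif setNames wilcox.test pnorm pbinom
#' @importFrom utils head tail
NULL

# run `expr` under a local RNG seed when `seed` is not NULL
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))
warnf <- function(fmt, ...) warn(sprintf(fmt, ...))

assert_that <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) stopf(fmt, ...)
  invisible(TRUE)
}

# deterministic JSON writer used for reports and truth tables
write_json_stable <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
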