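#' Callable-site masks
#'
#' A callable mask is a tibble of 0-based half-open intervals
#' (`chrom`, `start`, `end`) marking the sites where genotypes could have
#' been called (adequate depth in every sample). All mask arithmetic keeps
#' the BED convention.
#'
#' @param x a data frame with columns `chrom`, `start`, `end`.
#' @return A tibble of sorted, merged, non-overlapping intervals.
#' @export
callable_mask <- function(x) {
  x <- as_tibble(x)[, c("chrom", "start", "end")]
  assert_that(all(x$end > x$start), "mask intervals must have end > start")
  out <- lapply(split(x, x$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    tibble(chrom = d$chrom[1], start = IRanges::start(ir) - 1L,
           end = IRanges::end(ir))
  })
  out <- bind_rows(out)
  arrange(out, .data$chrom, .data$start)
}

mask_iranges <- function(mask) {
  lapply(split(mask, mask$chrom),
         function(d) IRanges::IRanges(d$start + 1L, d$end))
}

#' Total callable length of a mask
#' @param mask a [callable_mask()].
#' @param chrom optional chromosome to restrict to.
#' @return Integer number of callable sites.
#' @export
mask_length <- function(mask, chrom = NULL) {
  if (!is.null(chrom)) mask <- mask[mask$chrom %in% chrom, , drop = FALSE]
  sum(mask$end - mask$start)
}

#' Remove single positions from a callable mask
#'
#' Used when filtered-out SNPs are excised from the callable regions.
#'
#' @param mask a [callable_mask()].
#' @param positions tibble with `chrom` and `pos` (1-based site positions).
#' @return The reduced mask.
#' @export
mask_remove_positions <- function(mask, positions) {
  if (nrow(positions) == 0) return(mask)
  out <- lapply(split(mask, mask$chrom), function(d) {
    p <- positions$pos[positions$chrom == d$chrom[1]]
    ir <- IRanges::IRanges(d$start + 1L, d$end)
    if (length(p) > 0)
      ir <- IRanges::setdiff(ir, IRanges::IRanges(p, p))
    if (length(ir) == 0) return(NULL)
    tibble(chrom = d$chrom[1], start = IRanges::start(ir) - 1L,
           end = IRanges::end(ir))
  })
  arrange(bind_rows(out), .data$chrom, .data$start)
}

# TRUE for each (chrom, pos 1-based) that falls inside the mask
mask_covers <- function(mask, chrom, pos) {
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    d <- mask[mask$chrom == ch, , drop = FALSE]
    i <- which(chrom == ch)
    if (nrow(d) == 0) next
    ir <- IRanges::IRanges(d$start + 1L, d$end)
    out[i] <- IRanges::overlapsAny(IRanges::IRanges(pos[i], pos[i]), ir)
  }
  out
}

# callable sites of `mask` inside each window (0-based half-open windows)
mask_callable_in_windows <- function(mask, windows) {
  n <- nrow(windows)
  out <- integer(n)
  for (ch in unique(windows$chrom)) {
    d <- mask[mask$chrom == ch, , drop = FALSE]
    wi <- which(windows$chrom == ch)
    if (nrow(d) == 0) next
    ir <- IRanges::IRanges(d$start + 1L, d$end)
    wr <- IRanges::IRanges(windows$start[wi] + 1L, windows$end[wi])
    ov <- IRanges::findOverlaps(wr, ir)
    if (length(ov) == 0) next
    w <- IRanges::width(IRanges::pintersect(
      wr[S4Vectors::queryHits(ov)], ir[S4Vectors::subjectHits(ov)]))
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    out[wi[as.integer(names(agg))]] <- as.integer(agg)
  }
  out
}
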