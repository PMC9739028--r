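#' Block post-filter for predicted contact sequences
#'
#' Cleans a raw per-timestep classifier output in two run-length stages,
#' applied once in this order:
#' \enumerate{
#'   \item every maximal run of 0s strictly shorter than `max_gap` samples
#'     lying between two 1-blocks is set to 1 (adjacent blocks are combined);
#'   \item every remaining 1-block not strictly longer than `min_block`
#'     samples is set to 0 (only blocks longer than `min_block` are kept).
#' }
#' At 100 Hz the defaults merge gaps shorter than 0.2 s and keep only blocks
#' longer than 0.3 s.  Leading and trailing zero-runs are never filled: a gap
#' must separate two blocks to qualify.  The operation is idempotent.
#'
#' @param seq a [binary_phase] (or a plain 0/1 vector).
#' @param max_gap gaps of `< max_gap` zero samples between blocks are merged.
#' @param min_block blocks of `<= min_block` one samples are discarded.
#' @return Filtered sequence of the same type and length as the input.
#' @examples
#' x <- c(rep(1, 40), rep(0, 10), rep(1, 40), rep(0, 10))
#' table(filter_blocks(x))  # one merged 90-sample block
#' @export
filter_blocks <- function(seq, max_gap = 20L, min_block = 30L) {
  max_gap <- as.integer(max_gap)
  min_block <- as.integer(min_block)
  if (max_gap < 0L || min_block < 0L)
    stop("`max_gap` and `min_block` must be non-negative")
  if (inherits(seq, "binary_phase")) {
    out <- cpp_filter_blocks(seq$values, max_gap, min_block)
    return(binary_phase(out, seq$sample_rate, seq$effector))
  }
  v <- as.integer(seq)
  if (anyNA(v) || !all(v %in% c(0L, 1L)))
    stop("`seq` must contain only 0 and 1")
  cpp_filter_blocks(v, max_gap, min_block)
}
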