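# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

# All coordinates in the package are 1-based, fully closed intervals
# (UCSC browser display convention).  A probe at exactly a region's start or
# stop coordinate belongs to the region.
in_interval <- function(pos, start, stop) pos >= start & pos <= stop

# disjoint consecutive block index: 1,1,1,2,2,2,... for block size `size`
block_index <- function(n, size) (seq_len(n) - 1L) %/% size + 1L

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}
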