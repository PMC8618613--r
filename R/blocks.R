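# block averaging of scalar time series

#' Block-average a time series
#'
#' Partitions a `(time, value)` series into consecutive blocks of fixed
#' duration anchored at t = 0 (block k covers `[k*block, (k+1)*block)` ns)
#' and returns the per-block mean and standard deviation.  A trailing
#' partial block — one whose data do not extend to within one median
#' sampling interval of the block end — is dropped, so per-block statistics
#' stay comparable.
#'
#' @param time strictly increasing times, ns.
#' @param value scalar values, same length as `time`.
#' @param block block duration, ns.
#' @return A `block_series`: data.frame with columns `block`, `t_start`,
#'   `t_mid`, `n`, `mean`, `sd`, and attribute `block_duration`.
#' @export
block_average <- function(time, value, block) {
  if (!.is_number(block) || block <= 0)
    .stopf("parameter error: block duration must be a positive number")
  if (!length(time)) .stopf("parameter error: empty series")
  if (length(time) != length(value))
    .stopf("time and value lengths differ")
  if (is.unsorted(time, strictly = TRUE))
    .stopf("times must be strictly increasing")
  dt <- if (length(time) > 1L) median(diff(time)) else block
  k <- floor(time / block)
  keep_k <- k[(k + 1) * block - dt <= max(time) + 1e-12]
  sel <- k %in% keep_k
  if (!any(sel)) .stopf("series shorter than one block")
  kf <- factor(k[sel])
  out <- data.frame(
    block = as.integer(levels(kf)),
    t_start = as.integer(levels(kf)) * block,
    n = as.integer(tabulate(kf)),
    mean = as.numeric(tapply(value[sel], kf, mean)),
    sd = as.numeric(tapply(value[sel], kf, function(v)
      if (length(v) > 1L) sd(v) else 0)))
  out$t_mid <- out$t_start + block / 2
  out <- out[, c("block", "t_start", "t_mid", "n", "mean", "sd")]
  rownames(out) <- NULL
  structure(out, block_duration = block, class = c("block_series",
                                                   "data.frame"))
}

#' @export
print.block_series <- function(x, ...) {
  cat(sprintf("block_series: %d blocks of %g ns\n", nrow(x),
              attr(x, "block_duration")))
  print.data.frame(x, ...)
  invisible(x)
}
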