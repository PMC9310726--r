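#' Binarize an epoch around its linear trend
#'
#' Removes a least-squares linear trend from a real-valued signal and
#' thresholds the residual at zero: samples strictly above the trend map to
#' 1, samples at or below it map to 0. Ties at exactly zero (including
#' residuals that are zero up to numerical precision, as for a pure ramp)
#' deterministically map to 0. Binarizing around the trend makes the
#' resulting bit sequence invariant to amplifier gain and slow drift, which
#' is what a complexity measure of signal *diversity* should ignore.
#'
#' @param x Numeric vector, one epoch of signal (microvolts). Must be finite.
#' @param detrend `"linear"` (default) removes an ordinary least-squares
#'   linear fit; `"mean"` subtracts the epoch mean only.
#' @return Integer vector of 0/1 bits, same length as `x`.
#' @examples
#' binarize(c(1, -1, 2, -2))  # 1 0 1 0
#' @export
binarize <- function(x, detrend = c("linear", "mean")) {
  if (!is.numeric(x)) stop("epoch samples must be numeric")
  if (length(x) && !all(is.finite(x))) {
    stop("non-finite values in epoch (", sum(!is.finite(x)), " samples)")
  }
  detrend <- match.arg(detrend)
  if (length(x) == 0L) return(integer(0))
  if (detrend == "linear") {
    tt <- seq_along(x)
    r <- stats::.lm.fit(cbind(1, tt), x)$residuals
  } else {
    r <- x - mean(x)
  }
  # residuals that are zero up to numerical precision count as ties -> 0;
  # least-squares residual noise scales with the signal amplitude
  tol <- sqrt(.Machine$double.eps) * max(abs(x))
  if (!is.finite(tol)) tol <- 0
  as.integer(r > tol)
}

#' LZ78 dictionary phrase count
#'
#' Sequential word-dictionary (LZ78) parse of a binary sequence: the scanner
#' grows the current phrase while it matches a dictionary entry and, on the
#' first mismatch, inserts the extended phrase and restarts. A trailing
#' phrase that ends the sequence while still matching a dictionary entry
#' counts as one additional phrase. The phrase count L measures the
#' diversity of the sequence: a constant sequence yields the minimum
#' number of phrases, an i.i.d. random one close to the maximum.
#'
#' @param bits Integer (or numeric) vector of 0s and 1s.
#' @return Integer phrase count `L` (0 for an empty sequence).
#' @examples
#' lz78_phrase_count(c(0, 1))                      # 2
#' lz78_phrase_count(rep(0, 4))                    # 3: 0 | 00 | trailing 0
#' @export
lz78_phrase_count <- function(bits) {
  if (is.numeric(bits)) bits <- as.integer(bits)
  if (!is.integer(bits)) stop("bits must be an integer 0/1 vector")
  .lz78_count(bits)
}

#' Normalized LZ78 complexity
#'
#' Scales an LZ78 phrase count so values are comparable across sequence
#' lengths: `C = L * log2(L) / T`. A sequence of a single repeated symbol
#' has C near 0 at large T; i.i.d. binary noise approaches C ~ 0.7 at
#' T = 5120. By convention `L <= 1` (including the empty sequence) gives
#' `C = 0`.
#'
#' @param L Phrase count (non-negative integer).
#' @param T_len Sequence length in samples; must satisfy `L <= T_len`.
#' @return Normalized complexity `C` (unitless, non-negative).
#' @examples
#' normalized_complexity(7, 16)  # 7 * log2(7) / 16
#' @export
normalized_complexity <- function(L, T_len) {
  if (L < 0) stop("phrase count L must be non-negative")
  if (L > T_len) stop("impossible parse: L = ", L, " exceeds T = ", T_len)
  if (L <= 1) return(0)
  L * log2(L) / T_len
}

#' Complexity of a single epoch
#'
#' Composes [binarize()], [lz78_phrase_count()] and
#' [normalized_complexity()] for one epoch of signal.
#'
#' @inheritParams binarize
#' @return A list with elements `L`, `T` and `C`.
#' @export
epoch_lz <- function(x, detrend = c("linear", "mean")) {
  bits <- binarize(x, detrend)
  L <- lz78_phrase_count(bits)
  list(L = L, T = length(bits), C = normalized_complexity(L, max(length(bits), 1L)))
}

#' Complexity table for a set of epochs
#'
#' Applies [epoch_lz()] to every epoch in an epoch set (see
#' [segment_epochs()]) and returns the annotated long-format complexity
#' table that all downstream statistics consume.
#'
#' @param epochs An `lz_epochs` object.
#' @param detrend Detrending method passed to [binarize()].
#' @return A data frame with the epoch annotations (`cat`, `session`,
#'   `channel`, `state`, `dose`, `stim`, `epoch`) plus `T`, `L` and `C`.
#' @export
epochs_lz <- function(epochs, detrend = c("linear", "mean")) {
  stopifnot(inherits(epochs, "lz_epochs"))
  detrend <- match.arg(detrend)
  n <- length(epochs$samples)
  L <- integer(n)
  C <- numeric(n)
  T_len <- integer(n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      epoch_lz(epochs$samples[[i]], detrend),
      error = function(e) {
        stop("epoch ", i, " (", paste(unlist(epochs$meta[i, c("cat", "session", "channel")]),
                                      collapse = "/"), "): ", conditionMessage(e),
             call. = FALSE)
      }
    )
    L[i] <- res$L
    C[i] <- res$C
    T_len[i] <- res$T
  }
  out <- epochs$meta
  out$T <- T_len
  out$L <- L
  out$C <- C
  out
}
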