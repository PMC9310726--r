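# Naive reference implementations, deliberately independent of the package
# internals: the LZ78 oracle stores whole phrase strings in an environment
# and grows the current phrase by string concatenation, instead of the
# package's integer trie.

lz78_oracle <- function(bits) {
  n <- length(bits)
  if (n == 0L) return(0L)
  dict <- new.env(hash = TRUE, parent = emptyenv())
  L <- 0L
  w <- ""
  for (b in bits) {
    w2 <- paste0(w, b)
    if (exists(w2, envir = dict, inherits = FALSE)) {
      w <- w2
    } else {
      assign(w2, TRUE, envir = dict)
      L <- L + 1L
      w <- ""
    }
  }
  if (nzchar(w)) L <- L + 1L  # trailing phrase still matching the dictionary
  L
}

# all binary strings of length n as rows of a 0/1 matrix
bit_matrix <- function(n) {
  m <- outer(seq_len(2^n) - 1L, 2^(seq_len(n) - 1L),
             function(k, p) (k %/% p) %% 2L)
  storage.mode(m) <- "integer"
  m
}

bitstr <- function(s) as.integer(strsplit(s, "")[[1]])

# explicit least-squares detrend, used as the binarization oracle
detrend_oracle <- function(x) {
  tt <- seq_along(x)
  unname(stats::residuals(stats::lm(x ~ tt)))
}
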