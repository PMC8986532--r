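# internal helpers

# sample() without the length-1 surprise: draws k elements from the vector x
sample_int <- function(x, k) {
  if (length(x) == 1L) return(rep(x, length.out = k))
  x[sample.int(length(x), k)]
}
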