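# Internal helpers.

# sample() without the scalar-first-argument surprise: always samples from
# the elements of x, even when length(x) == 1.
resample <- function(x, n, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), n, replace = replace, prob = prob)]
}
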