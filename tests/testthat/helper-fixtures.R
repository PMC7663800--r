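# Reference coefficient sets as a list of mooney_rivlin objects keyed by
# composition label.
reference_materials <- function(temperature = 310.15) {
  tab <- pu_reference_params()
  out <- lapply(seq_len(nrow(tab)), function(i) {
    mooney_rivlin(tab$c10[i], tab$c01[i], tab$c11[i],
                  temperature = temperature)
  })
  names(out) <- tab$label
  out
}

# Random coefficient triples with a stress-stretch curve that stays
# monotone near lambda = 1 (positive small-strain slope); used by
# property-style tests.
random_params <- function() {
  repeat {
    p <- mooney_rivlin(runif(1, -2, 2), runif(1, -1, 3), runif(1, -0.3, 0.3))
    if (6 * (p$c10 + p$c01) > 0.1) return(p)
  }
}

# write a small curve CSV and return its path
write_tmp_curve <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

default_waveform <- function(freq = 1) pressure_waveform(180, 40, ps = 10, freq = freq)
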