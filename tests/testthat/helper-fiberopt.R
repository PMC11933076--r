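# Shared fixtures, all generated in code.

noiseless_truth <- function() {
  tr <- default_truth()
  for (lab in names(tr)) tr[[lab]]$noise_sd <- 0
  tr
}

# small complete dataset (no missing cells) for io / preprocessing tests
small_dataset <- function(n = 60, seed = 11, mode = "surface") {
  generate_dataset(synthetic_config(n_rows = n, seed = seed, mode = mode,
                                    n_missing = 0))$dataset
}

# per-dimension recovery error on the active features, linear [0,1] scaling
# of original units over the schema bounds
recovery_errors <- function(opt, x_star) {
  a <- default_anchors()
  vapply(names(x_star), function(f)
    abs(opt$x_opt[[f]] - x_star[[f]]) / (a[[f]][5L] - a[[f]][1L]),
    numeric(1))
}
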