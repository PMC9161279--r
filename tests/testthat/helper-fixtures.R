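# Programmatic fixtures: every dataset used by the tests is generated at
# test time into the session temp directory.

fixture_dataset <- function(n, dir_tag, n_leaves_range = c(1L, 8L),
                            image_size = 32L, background = "soil",
                            seed = 101L, ratio = 0.8, split_seed = 7L) {
  d <- file.path(tempdir(), paste0("leafseg-", dir_tag))
  if (!dir.exists(d)) {
    generate_dataset(n, rosette_sampler(image_size = image_size,
                                        n_leaves_range = n_leaves_range,
                                        background_mode = background),
                     seed = seed, out_dir = d)
  }
  m <- read_manifest(file.path(d, "manifest.csv"))
  split_dataset(m, ratio = ratio, seed = split_seed)
}

random_binary_mask <- function(h, w, p = 0.4) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}
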