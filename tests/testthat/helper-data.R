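# Shared fixtures built in code at test time.

tiny_seg_dataset <- function(n_train = 8L, n_test = 2L, size = 32L,
                             seed = 101L) {
  td <- file.path(tempfile("segdata"), "d")
  seed_everything(seed)
  generate_segmentation_dataset(blob_scene_params(size = size,
                                                  n_blobs = c(1L, 3L),
                                                  radius = c(3, 6)),
                                n_train = n_train, n_test = n_test,
                                outdir = td)
  td
}

tiny_unet <- function(...) build_unet(base_filters = 4L, depth = 2L, ...)

random_prob_map <- function(n = 16L) matrix(runif(n * n), n, n)

random_binary <- function(n = 8L) matrix(as.double(rbinom(n * n, 1L, 0.4)), n, n)
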