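# Shared fixtures: tiny network configuration and easy/hard synthetic specs.

tiny_cfg <- function(input_size = 64L)
  net_config(input_size = input_size, width_mult = 1 / 8, conv4_blocks = 2,
             edge_thickness = 1)

easy_spec <- function(seed, image_size = 64L)
  synth_spec(image_size = image_size, fuzziness = 0, contrast = 0.9,
             hair = FALSE, glue = FALSE, ruler = FALSE, noise_sd = 0.01,
             seed = seed)

hard_spec <- function(seed, image_size = 64L)
  synth_spec(image_size = image_size, fuzziness = 3, contrast = 0.25,
             hair = TRUE, glue = TRUE, ruler = FALSE, noise_sd = 0.05,
             seed = seed)

easy_samples <- function(seeds, image_size = 64L)
  lapply(seeds, function(s)
    generate_sample(easy_spec(s, image_size), edge_thickness = 1))

# central-difference gradient of a scalar function of an array
num_grad <- function(f, x, eps = 1e-5) {
  g <- if (is.null(dim(x))) numeric(length(x)) else array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

cc_ns <- asNamespace("cclseg")
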