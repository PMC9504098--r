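# Shared fixtures: tiny deterministic arrays and module builders.

rand_arr <- function(dims, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(prod(dims)), dims)
}

rand_mask <- function(H = 8, W = 8, p = 0.4, seed = 1) {
  set.seed(seed)
  matrix(as.integer(stats::runif(H * W) < p), H, W)
}

# a tiny three-level fusion fixture: levels at 2x2, 4x4, 8x8 spatial size
tiny_fusion_inputs <- function(seed = 3, s_dims = c(4L, 4L, 4L),
                               h_dims = c(4L, 4L, 4L)) {
  set.seed(seed)
  sizes <- c(2L, 4L, 8L)
  maps <- list(s0 = rand_arr(c(2, 2, s_dims[1]), seed),
               s1 = rand_arr(c(4, 4, s_dims[2]), seed + 1),
               s2 = rand_arr(c(8, 8, s_dims[3]), seed + 2))
  pyr <- list(h0 = rand_arr(c(2, 2, h_dims[1]), seed + 3),
              h1 = rand_arr(c(4, 4, h_dims[2]), seed + 4),
              h2 = rand_arr(c(8, 8, h_dims[3]), seed + 5))
  list(maps = maps, pyramid = pyr, sizes = sizes)
}

tiny_fusion_module <- function(seed = 4, s_dims = c(4L, 4L, 4L),
                               h_dims = c(4L, 4L, 4L)) {
  set.seed(seed)
  nn_mpf_fusion(fusion_config(s_dims = s_dims, h_dims = h_dims,
                              l_dims = c(4L, 4L, 4L), f_dims = c(4L, 4L, 4L),
                              gate_dim = 4L))
}

# set every trainable parameter of a module tree to zero
zero_all_params <- function(module) {
  for (p in nn_params(module)) p$value[] <- 0
  invisible(module)
}

# relative error used by gradient checks
rel_err <- function(a, b) {
  max(abs(a - b)) / max(max(abs(a)), max(abs(b)), 1e-8)
}
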