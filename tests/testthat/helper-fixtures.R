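# Shared fixture builders: everything is generated in code at test time.

# Small single-trait trial with explicit variance components.
tiny_trial <- function(n_lines = 60, n_markers = 200, n_env = 1, n_rep = 2,
                       n_testers = 2, vg = 80, vgxe = 0, venv = 0, vrep = 0,
                       vblk = 0, verr = 40, seed = 5, block_size = 4,
                       trait_kind = "gaussian", mu = 20) {
  cfg <- sim_config(n_lines = n_lines, n_markers = n_markers,
                    n_environments = n_env, n_replicates = n_rep,
                    block_size = block_size, n_testers = n_testers,
                    var_genetic = vg, var_gxe = vgxe, var_env = venv,
                    var_replicate = vrep, var_block = vblk, var_error = verr,
                    n_qtl = n_lines, trait_kind = trait_kind, mu = mu,
                    seed = seed)
  markers <- simulate_markers(cfg)
  sim <- simulate_trial(cfg, markers)
  list(config = cfg, markers = markers, plots = sim$plots, truth = sim$truth)
}

# Cell-level data (1 rep, 1 tester) plus kernel, the reaction-norm layout.
cell_level_data <- function(n_lines = 300, n_markers = 600, vg = 80,
                            vgxe = 23, verr = 160, venv = 10, seed = 1) {
  cfg <- sim_config(n_lines = n_lines, n_markers = n_markers,
                    n_environments = 3, n_replicates = 1, block_size = 5,
                    n_testers = 1, var_genetic = vg, var_gxe = vgxe,
                    var_env = venv, var_replicate = 0, var_block = 0,
                    var_error = verr, n_qtl = n_lines, mu = 20, seed = seed)
  markers <- simulate_markers(cfg)
  sim <- simulate_trial(cfg, markers)
  grm <- compute_grm(qc_markers(markers))
  blues <- data.frame(line = sim$plots$line, env = sim$plots$location,
                      value = sim$plots$y, stringsAsFactors = FALSE)
  list(config = cfg, blues = blues, grm = grm, truth = sim$truth)
}

# Random well-conditioned kernel with line IDs, for sampler-only tests.
random_kernel <- function(n, p = 4 * n, seed = 1) {
  set.seed(seed)
  S <- scale(matrix(rnorm(n * p), n, p))
  G <- tcrossprod(S) / p
  dimnames(G) <- list(sprintf("l%02d", seq_len(n)), sprintf("l%02d", seq_len(n)))
  G
}
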