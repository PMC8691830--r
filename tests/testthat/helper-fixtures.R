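# Shared fixtures: small, fast synthetic objects built in code.

fig2_schedule <- function() infusion_schedule(onset = 300, duration = 600,
                                              v_in = 0.107)

# a small uniform-activity phantom for preprocessing / fitting tests
small_phantom <- function(k = 0.01, noise_sd = 0, n_frames = 150,
                          frame_time = 10, A_true = 20, v_out_true = 0.3,
                          c_out_true = 1e-4, grid = c(8, 8, 1), seed = 1) {
  spec <- phantom_spec(grid_shape = grid, voxel_size = c(0.39, 0.39, 1),
                       frame_time = frame_time, n_frames = n_frames,
                       baseline = 100, A_true = A_true,
                       v_out_true = v_out_true, c_out_true = c_out_true,
                       infusion = infusion_schedule(300, 600, 0.0108),
                       noise_sd = noise_sd, seed = seed)
  spec$k_map <- array(k, grid)
  spec
}

# noiseless model trace for ROI fitting tests
model_trace <- function(k, A, v_out = 0, c_out = 0,
                        schedule = fig2_schedule(),
                        times = seq(0, 2400, by = 5)) {
  tr <- closed_form_concentrations(kinetic_params(k, v_out, c_out),
                                   schedule, times)
  signal_from_concentration(tr, A)
}
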