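# Shared builders for synthetic truths and traces.

single_gaussian_model <- function(center = 3.5, width = 0.3, depth = 0.3,
                                  rate = 0.05) {
  signal_model(distance_distribution(gaussian_component(center, width)),
               depth, background_model(rate))
}

bimodal_model <- function(c1 = 3.0, c2 = 4.5, w1 = 0.3, w2 = 0.35,
                          p1 = 0.5, depth = 0.3, rate = 0.08) {
  signal_model(
    distance_distribution(gaussian_component(c1, w1, p1),
                          gaussian_component(c2, w2, 1 - p1)),
    depth, background_model(rate))
}

# One ready-to-fit noiseless or noisy trace.
make_trace <- function(model = single_gaussian_model(), t_max = 3,
                       n_points = 300, snr = Inf, seed = 1,
                       condition_id = "c1", pair_id = "p") {
  sc <- synthetic_scenario(pair_id, setNames(list(model), condition_id),
                          t_max = t_max, n_points = n_points, snr = snr,
                          seed = seed)
  generate_traces(sc)[[1L]]
}

# Truth vector packed for a spec with a single trace and one component.
pack_single_truth <- function(spec, center, width, depth, rate,
                              condition_id = spec$conditions[1L]) {
  repack_parameters(list(
    rates = rate, depths = depth,
    components = setNames(list(matrix(c(center, width, 1), 3)),
                          condition_id)), spec)
}
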