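# Small panels shared across tests (all counts deterministic unless a test
# wants noise).

tiny_panel <- function(pop = 10) {
  transmitter_panel(c("A", "B"), c(10, 4), c(0, 0), population_mean = pop)
}

fixed_panel3 <- function() {
  transmitter_panel(c("X", "Y", "Z"), c(8, 12, 5), c(0, 0, 0),
                    population_mean = 20)
}

# published panel with deterministic counts (sd = 0) for exact-arithmetic
# tests
frozen_observed_panel <- function() {
  p <- observed_panel()
  transmitter_panel(p$transmitter, p$count_mean, rep(0, nrow(p)),
                    population_mean = 360)
}

# mean directed ratio X -> Y by exhaustive enumeration over all equally
# likely assignments of the two label sets (independent uniform subsets):
# by symmetry it is sufficient to enumerate Y-subsets against one fixed
# X-subset. Independent oracle for the Monte Carlo estimator.
enumerate_mean_ratio <- function(n_cells, n_x, n_y) {
  x_set <- seq_len(n_x)
  y_subsets <- utils::combn(n_cells, n_y, simplify = FALSE)
  mean(vapply(y_subsets, function(y) length(intersect(x_set, y)) / n_x,
              numeric(1)))
}
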