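## Tiny networks with closed-form solutions, shared across test files.

first_order_net <- function(k = 1e6) {
  build_network(c("A", "B"),
                list(list(id = "conv", reactants = c(A = 1), products = c(B = 1),
                          k = k)))
}

reversible_net <- function(kf = 2e5, kb = 1e5) {
  build_network(c("A", "B"),
                list(list(id = "f", reactants = c(A = 1), products = c(B = 1), k = kf),
                     list(id = "b", reactants = c(B = 1), products = c(A = 1), k = kb)))
}

second_order_net <- function(k = 3.1e9) {
  build_network(c("A", "B", "C"),
                list(list(id = "r", reactants = c(A = 1, B = 1),
                          products = c(C = 1), k = k)))
}

## minimal hand-built trajectory for observable tests
toy_trajectory <- function(time, conc_list) {
  conc <- do.call(cbind, conc_list)
  colnames(conc) <- names(conc_list)
  structure(list(time = time, conc = conc, fluxes = NULL,
                 network = NULL, solver_report = list()),
            class = "trajectory")
}

flash_grid <- function(n = 140, t_max = -3) c(0, 10^seq(-8, t_max, length.out = n))
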