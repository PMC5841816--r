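# small fixture networks built in code

# two regions, 50 mm apart, unit weight
two_node_net <- function(velocity = 5) {
  structural_network(rbind(c(0, 1), c(1, 0)),
                     rbind(c(0, 50), c(50, 0)), velocity = velocity)
}

# fully symmetric complete graph (all weights and distances equal):
# ISP converges to a spatially uniform solution on it
k4_net <- function(velocity = 5) {
  W <- matrix(1, 4, 4) - diag(4)
  D <- matrix(60, 4, 4) - diag(60, 4)
  structural_network(W, D, velocity = velocity)
}

# random symmetric zero-diagonal matrix with unit max
random_fc_template <- function(n, seed, scale = 0.5) {
  set.seed(seed)
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- stats::runif(n * (n - 1) / 2, 0, scale)
  M <- M + t(M)
  diag(M) <- 1
  M
}
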