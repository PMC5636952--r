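# Shared helpers: finite-difference force oracle and small random geometries.

fd_forces <- function(calc, cfg, h = 1e-5) {
  n <- n_atoms(cfg)
  F <- matrix(0, n, 3)
  for (a in seq_len(n)) {
    for (d in 1:3) {
      cp <- cfg; cp$positions[a, d] <- cp$positions[a, d] + h
      cm <- cfg; cm$positions[a, d] <- cm$positions[a, d] - h
      F[a, d] <- -(calc_evaluate(calc, cp, forces = FALSE)$energy -
                   calc_evaluate(calc, cm, forces = FALSE)$energy) / (2 * h)
    }
  }
  F
}

# Random small molecule with a minimum interatomic separation.
random_molecule <- function(n, elements = c("C", "H", "O"), min_dist = 0.9,
                            box = 3.5) {
  repeat {
    pos <- matrix(stats::runif(3 * n, 0, box), n, 3)
    if (n == 1 || min(stats::dist(pos)) > min_dist) break
  }
  atomic_config(sample(elements, n, replace = TRUE), pos)
}

# Reference forward pass written independently of the package internals.
oracle_forward <- function(net, x) {
  a <- x
  L <- length(net$W)
  for (l in seq_len(L)) {
    z <- net$W[[l]] %*% a + net$b[[l]]
    a <- if (l < L) tanh(z) else z
  }
  as.numeric(a)
}

zero_network <- function(net) {
  net_set_params <- getFromNamespace("net_set_params", "nnpir")
  n_params <- getFromNamespace("n_params", "nnpir")
  net_set_params(net, rep(0, n_params(net)))
}

zero_model <- function(model) {
  for (e in names(model$networks)) {
    model$networks[[e]] <- zero_network(model$networks[[e]])
  }
  model$energy_shifts[] <- 0
  model
}
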