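# Small dense feed-forward networks (tanh hidden layers, linear output) shared
# by all atoms of one element. Besides the forward pass we need three
# derivative objects:
#   * gradient w.r.t. parameters        (Kalman jacobian, energy rows)
#   * gradient w.r.t. inputs            (forces via descriptor jacobians)
#   * mixed jacobian d2y/(dtheta dx)    (Kalman jacobian, force rows)
# The mixed jacobian is computed with a forward-tangent / reverse-adjoint
# sweep; the tangent is seeded with the identity so all input directions are
# handled in one batched pass of small matrix products.

#' Create an elemental network
#'
#' Feed-forward network with tanh hidden units and a linear output node,
#' shared by all atoms of one element. Weights are initialized uniformly in
#' [-0.5, 0.5] scaled by 1/sqrt(fan-in); biases start at zero.
#'
#' @param element Element symbol the network serves.
#' @param n_input Input dimension (descriptor length).
#' @param hidden Integer vector of hidden-layer sizes, e.g. \code{c(35, 35)}.
#' @param seed Integer seed for reproducible initialization.
#' @return An object of class \code{elemental_network}.
#' @export
elemental_network <- function(element, n_input, hidden = c(35, 35),
                              seed = 1L) {
  sizes <- c(n_input, hidden, 1L)
  old <- .Random.seed_save()
  set.seed(seed)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]
    W[[l]] <- matrix(stats::runif(sizes[l + 1L] * fan_in, -0.5, 0.5) /
                       sqrt(fan_in), sizes[l + 1L], fan_in)
    b[[l]] <- numeric(sizes[l + 1L])
  }
  .Random.seed_restore(old)
  structure(list(element = element, sizes = sizes, W = W, b = b),
            class = "elemental_network")
}

# Preserve the caller's RNG stream around internally seeded draws.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

n_params <- function(net) {
  sum(vapply(seq_along(net$W),
             function(l) length(net$W[[l]]) + length(net$b[[l]]), 0))
}

# Flatten parameters (per layer: vec(W) column-major, then b).
net_get_params <- function(net) {
  unlist(lapply(seq_along(net$W),
                function(l) c(as.vector(net$W[[l]]), net$b[[l]])))
}

net_set_params <- function(net, theta) {
  pos <- 0L
  for (l in seq_along(net$W)) {
    nw <- length(net$W[[l]])
    net$W[[l]][] <- theta[pos + seq_len(nw)]
    pos <- pos + nw
    nb <- length(net$b[[l]])
    net$b[[l]][] <- theta[pos + seq_len(nb)]
    pos <- pos + nb
  }
  net
}

# Forward pass; returns scalar output and cached activations.
net_forward <- function(net, x) {
  L <- length(net$W)
  a <- vector("list", L + 1L)
  a[[1L]] <- x
  for (l in seq_len(L)) {
    z <- drop(net$W[[l]] %*% a[[l]]) + net$b[[l]]
    a[[l + 1L]] <- if (l < L) tanh(z) else z
  }
  list(y = a[[L + 1L]], a = a)
}

# Gradient of the scalar output w.r.t. flattened parameters (backprop) and,
# optionally, w.r.t. the input.
net_gradients <- function(net, x, params = TRUE, input = TRUE) {
  fwd <- net_forward(net, x)
  a <- fwd$a
  L <- length(net$W)
  delta <- 1  # adjoint at the linear output
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- outer(delta, a[[l]])
    gb[[l]] <- delta
    back <- drop(crossprod(net$W[[l]], delta))
    delta <- if (l > 1L) (1 - a[[l]]^2) * back else back
  }
  out <- list(y = fwd$y)
  if (params) {
    out$pgrad <- unlist(lapply(seq_len(L),
                               function(l) c(as.vector(gW[[l]]), gb[[l]])))
  }
  if (input) out$xgrad <- delta  # after final fold: dy/dx
  out
}

# Mixed jacobian M[theta, j] = d^2 y / (d theta d x_j), p x n_input.
# Forward tangent T seeded with identity (columns = input directions), then a
# reverse sweep carrying both the ordinary adjoint and the tangent adjoint.
net_mixed_jacobian <- function(net, x) {
  L <- length(net$W)
  nin <- net$sizes[1L]
  fwd <- net_forward(net, x)
  a <- fwd$a
  # forward tangents
  S <- vector("list", L); Tt <- vector("list", L + 1L)
  Tt[[1L]] <- diag(nin)
  for (l in seq_len(L)) {
    S[[l]] <- net$W[[l]] %*% Tt[[l]]
    Tt[[l + 1L]] <- if (l < L) (1 - a[[l + 1L]]^2) * S[[l]] else S[[l]]
  }
  # reverse sweep; per-layer parameter blocks, each a (nW+nb) x nin matrix
  Abar <- matrix(0, 1, nin)   # adjoint of a_L (columns = input directions)
  Tbar <- matrix(1, 1, nin)   # adjoint of t_L
  blocks <- vector("list", L)
  for (l in L:1) {
    if (l < L) {
      phi1 <- 1 - a[[l + 1L]]^2
      phi2 <- -2 * a[[l + 1L]] * phi1
      Zbar <- phi1 * Abar + (phi2 * S[[l]]) * Tbar
      Sbar <- phi1 * Tbar
    } else {  # linear output layer
      Zbar <- Abar
      Sbar <- Tbar
    }
    # d y_dot / d W_l per input direction j:
    #   Zbar[,j] %o% a_{l-1}  +  Sbar[,j] %o% T_{l-1}[,j]
    nr <- nrow(net$W[[l]]); nc <- ncol(net$W[[l]])
    Wblk <- matrix(0, nr * nc, nin)
    for (j in seq_len(nin)) {
      Wblk[, j] <- as.vector(outer(Zbar[, j], a[[l]]) +
                             outer(Sbar[, j], Tt[[l]][, j]))
    }
    blocks[[l]] <- rbind(Wblk, Zbar)
    Abar <- crossprod(net$W[[l]], Zbar)
    Tbar <- crossprod(net$W[[l]], Sbar)
  }
  do.call(rbind, blocks)
}
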