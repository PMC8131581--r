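# Deterministic force-driven 2-D layout: spring (elastic) attraction
# along edges, inverse-square (electric) repulsion between all node
# pairs, velocity damping, integrated with semi-implicit Euler from
# seeded random positions on the unit disc.

#' Parameters for the force-driven layout
#'
#' @param k_spring spring stiffness (scaled per edge by its weight).
#' @param rest_length spring rest length L.
#' @param q_repulse repulsion constant (force q / d^2 between any two
#'   nodes).
#' @param gamma_damp velocity damping coefficient; `dt * gamma_damp < 2`
#'   is required for stability.
#' @param dt integration step.
#' @param max_steps iteration cap; hitting it flags non-convergence.
#' @param tol_force termination threshold on the maximum per-node net
#'   (spring + repulsion) force.
#' @param seed seed for the initial positions (and any jitter).
#' @return List of class `layout_params`.
#' @export
layout_params <- function(k_spring = 1, rest_length = 1, q_repulse = 0.2,
                          gamma_damp = 1, dt = 0.05, max_steps = 20000L,
                          tol_force = 1e-4, seed = 1L) {
  if (k_spring <= 0 || q_repulse < 0 || gamma_damp <= 0 || dt <= 0 ||
      rest_length < 0) {
    stopf("layout constants must be positive (rest_length >= 0)")
  }
  if (dt * gamma_damp >= 2) stopf("unstable parameters: need dt * gamma_damp < 2")
  if (tol_force <= 0) stopf("tol_force must be positive")
  structure(list(k_spring = k_spring, rest_length = rest_length,
                 q_repulse = q_repulse, gamma_damp = gamma_damp, dt = dt,
                 max_steps = as.integer(max_steps), tol_force = tol_force,
                 seed = as.integer(seed)),
            class = "layout_params")
}

#' Force-driven graph layout
#'
#' Integrates under-damped dynamics — per edge a spring force
#' `-k w (|d| - L)` along the edge (w = edge weight), between every node
#' pair a repulsion `q / |d|^2`, and damping `-gamma v` — with
#' semi-implicit Euler until the maximum per-node net force drops below
#' `tol_force` or `max_steps` is reached. Initial positions are seeded
#' uniform draws on the unit disc; coincident nodes are jittered by 1e-6
#' in a seeded direction. Deterministic given seed, parameters and graph.
#'
#' @param graph a `bm_graph`, or a list with `nodes` (data.frame with
#'   `name`) and `edges` (data.frame source, target, weight).
#' @param params a [layout_params()] object.
#' @return data.frame (node, x, y) with attributes `converged`, `steps`,
#'   `max_force` and `kinetic_energy`.
#' @export
layout_graph <- function(graph, params = layout_params()) {
  stopifnot(inherits(params, "layout_params"))
  nodes <- graph$nodes$name
  n <- length(nodes)
  if (n < 2L) stopf("need >=2 nodes")
  ei <- match(graph$edges$source, nodes)
  ej <- match(graph$edges$target, nodes)
  ew <- graph$edges$weight
  if (anyNA(ei) || anyNA(ej)) stopf("edge endpoints missing from node table")

  pos <- with_seed(params$seed, {
    r <- sqrt(stats::runif(n))
    th <- 2 * pi * stats::runif(n)
    jit <- matrix(stats::rnorm(2L * n), n, 2L)   # reserved jitter directions
    p <- cbind(r * cos(th), r * sin(th))
    attr(p, "jitter") <- jit
    p
  })
  jitter_dir <- attr(pos, "jitter")
  attr(pos, "jitter") <- NULL
  vel <- matrix(0, n, 2L)

  net_force <- function(pos) {
    F <- matrix(0, n, 2L)
    dx <- outer(pos[, 1], pos[, 1], "-")
    dy <- outer(pos[, 2], pos[, 2], "-")
    d2 <- dx * dx + dy * dy
    coincident <- d2 < 1e-24
    diag(coincident) <- FALSE
    if (any(coincident)) {
      idx <- unique(which(coincident, arr.ind = TRUE)[, 1])
      pos[idx, ] <- pos[idx, ] + 1e-6 *
        jitter_dir[idx, , drop = FALSE] /
        sqrt(rowSums(jitter_dir[idx, , drop = FALSE]^2))
      dx <- outer(pos[, 1], pos[, 1], "-")
      dy <- outer(pos[, 2], pos[, 2], "-")
      d2 <- dx * dx + dy * dy
    }
    diag(d2) <- Inf
    inv3 <- d2^(-1.5)                       # q * dhat / d^2 = q * dvec / d^3
    F[, 1] <- params$q_repulse * rowSums(dx * inv3)
    F[, 2] <- params$q_repulse * rowSums(dy * inv3)
    d <- sqrt(d2)
    for (e in seq_along(ei)) {
      i <- ei[e]; j <- ej[e]
      dist_ij <- d[i, j]
      dirv <- c(dx[i, j], dy[i, j]) / dist_ij
      f <- -params$k_spring * ew[e] * (dist_ij - params$rest_length) * dirv
      F[i, ] <- F[i, ] + f
      F[j, ] <- F[j, ] - f
    }
    list(F = F, pos = pos)
  }

  converged <- FALSE
  steps <- 0L
  maxf <- Inf
  for (step in seq_len(params$max_steps)) {
    nf <- net_force(pos)
    pos <- nf$pos
    F <- nf$F
    maxf <- max(sqrt(rowSums(F^2)))
    steps <- step
    if (maxf < params$tol_force && max(abs(vel)) < params$tol_force) {
      converged <- TRUE
      break
    }
    vel <- vel + params$dt * (F - params$gamma_damp * vel)
    pos <- pos + params$dt * vel
    if (any(!is.finite(pos)) || max(abs(pos)) > 1e6) {
      stopf("layout diverged; reduce dt or increase damping")
    }
  }
  out <- data.frame(node = nodes, x = pos[, 1], y = pos[, 2],
                    stringsAsFactors = FALSE)
  attr(out, "converged") <- converged
  attr(out, "steps") <- steps
  attr(out, "max_force") <- maxf
  attr(out, "kinetic_energy") <- 0.5 * sum(vel^2)
  out
}
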