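#' Build sparse random (or spatially restricted) connectivity
#'
#' Each ordered pair of distinct neurons is connected independently with
#' probability eps = C/N, independent of neuron type (no autapses). When
#' `spatial_s` is given, the probability becomes eps * exp(-d^2/(2 s^2))
#' with d the Euclidean distance on the unit torus, so `C` then sets the
#' peak (zero-distance) probability scale. Neuron positions are uniform on
#' the torus and independent of the adjacency.
#'
#' @param N number of neurons (first 0.8*N excitatory).
#' @param C mean number of synapses per neuron (random case).
#' @param seed optional integer seed.
#' @param spatial_s connectivity range `s` on the unit torus (mm), or NULL
#'   for distance-independent connectivity.
#' @param L_mm physical side of the sheet (mm), used to place neurons.
#' @return a `connectivity` object: list with CSR adjacency by presynaptic
#'   neuron (`ptr`, 1-based cumulative; `post`, postsynaptic indices),
#'   positions `x`, `y` (mm), and `N`, `Ne`, `C`.
#' @export
build_connectivity <- function(N, C, seed = NULL, spatial_s = NULL,
                               L_mm = 1) {
  if (C < 0 || C >= N) stop("C must satisfy 0 <= C < N")
  if (!is.null(seed)) set.seed(seed)
  Ne <- as.integer(round(0.8 * N))
  x <- runif(N) * L_mm
  y <- runif(N) * L_mm
  eps <- C / N
  post_list <- vector("list", N)
  if (is.null(spatial_s)) {
    for (pre in seq_len(N)) {
      m <- rbinom(1, N - 1, eps)
      if (m > 0) {
        tgt <- sample.int(N - 1, m)
        tgt <- ifelse(tgt >= pre, tgt + 1L, tgt)  # skip autapse
        post_list[[pre]] <- tgt
      } else {
        post_list[[pre]] <- integer(0)
      }
    }
  } else {
    for (pre in seq_len(N)) {
      dx <- abs(x - x[pre]); dx <- pmin(dx, L_mm - dx)
      dy <- abs(y - y[pre]); dy <- pmin(dy, L_mm - dy)
      p <- eps * exp(-(dx^2 + dy^2) / (2 * spatial_s^2))
      p[pre] <- 0
      sel <- which(runif(N) < p)
      post_list[[pre]] <- sel
    }
  }
  deg <- lengths(post_list)
  conn <- list(ptr = cumsum(c(1L, deg)), post = unlist(post_list, use.names = FALSE),
               x = x, y = y, N = as.integer(N), Ne = Ne, C = C,
               spatial_s = spatial_s)
  if (is.null(conn$post)) conn$post <- integer(0)
  class(conn) <- "connectivity"
  conn
}

#' @export
print.connectivity <- function(x, ...) {
  m <- length(x$post)
  cat(sprintf("<connectivity> N = %d, %d edges, mean in-degree %.1f%s\n",
              x$N, m, m / x$N,
              if (is.null(x$spatial_s)) "" else
                sprintf(", spatial s = %g mm", x$spatial_s)))
  invisible(x)
}

#' Mean in-degree of a connectivity object
#' @param conn a `connectivity`.
#' @return average number of incoming synapses per neuron.
#' @export
mean_in_degree <- function(conn) length(conn$post) / conn$N

# Incoming E->E edge lists (reverse CSR), needed for STDP potentiation.
# Returns 0-based vectors for the C++ core.
reverse_ee_adjacency <- function(conn) {
  Ne <- conn$Ne
  pre_of_edge <- rep.int(seq_len(conn$N), diff(conn$ptr))
  ee <- which(pre_of_edge <= Ne & conn$post <= Ne)
  post_ee <- conn$post[ee]
  ord <- order(post_ee)
  ee <- ee[ord]
  post_ee <- post_ee[ord]
  cnt <- tabulate(post_ee, nbins = Ne)
  list(rev_ptr = as.integer(cumsum(c(0L, cnt))),
       rev_edge = as.integer(ee - 1L),
       rev_pre = as.integer(pre_of_edge[ee] - 1L))
}

# Per-edge conductance increments (nS): J_e for excitatory presynaptic
# neurons, J_i for inhibitory; E->E edges optionally redrawn for STDP runs.
edge_weights <- function(conn, cfg, stdp_init = FALSE, seed = NULL) {
  pre_of_edge <- rep.int(seq_len(conn$N), diff(conn$ptr))
  w <- ifelse(pre_of_edge <= conn$Ne, cfg$J_e, cfg$J_i)
  if (stdp_init) {
    if (!is.null(seed)) set.seed(seed)
    ee <- pre_of_edge <= conn$Ne & conn$post <= conn$Ne
    w[ee] <- pmin(pmax(rnorm(sum(ee), cfg$w0_mean, cfg$w0_sd), cfg$g_min),
                  cfg$g_max)
  }
  w
}
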