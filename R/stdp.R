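#' Additive STDP weight change for a nearest-neighbour spike pair
#'
#' For a pre/post spike pair separated by dt = t_pre - t_post:
#' potentiation A_plus * exp(dt/tau_plus) * g_max when dt < 0 (pre before
#' post), depression -A_minus * exp(-dt/tau_minus) * g_max when dt >= 0.
#' Updates are weight-independent; bounds are enforced at application time.
#'
#' @param dt_ms t_pre - t_post (ms); may be a vector.
#' @param A_plus,A_minus relative strengths of potentiation and depression.
#' @param tau_plus,tau_minus their time courses (ms).
#' @param g_max hard upper weight bound (nS).
#' @return weight change(s) in nS.
#' @export
stdp_delta_w <- function(dt_ms, A_plus = 0.025, A_minus = 0.0275,
                         tau_plus = 20, tau_minus = 20, g_max = 10) {
  ifelse(dt_ms < 0,
         A_plus * exp(dt_ms / tau_plus) * g_max,
         -A_minus * exp(-dt_ms / tau_minus) * g_max)
}

#' Shuffle synaptic weights across existing connections
#'
#' Permutes the weight values of the selected edges while leaving the
#' adjacency (degree structure) untouched. Used for the shuffled-weight
#' control: the weight histogram is invariant, but the per-neuron
#' composition of strong and weak synapses is randomized.
#'
#' @param weights per-edge weight vector.
#' @param which_edges indices of the edges to permute among themselves
#'   (default all).
#' @param seed optional integer seed.
#' @return permuted weight vector.
#' @export
shuffle_weights <- function(weights, which_edges = seq_along(weights),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  weights[which_edges] <- weights[sample(which_edges)]
  weights
}

#' Indices of plastic (E-to-E) edges
#'
#' @param conn a `connectivity`.
#' @return integer vector of edge indices with excitatory pre and post.
#' @export
ee_edges <- function(conn) {
  pre_of_edge <- rep.int(seq_len(conn$N), diff(conn$ptr))
  which(pre_of_edge <= conn$Ne & conn$post <= conn$Ne)
}

#' Fraction of weights saturated at the bounds
#'
#' @param w weight vector (nS).
#' @param g_max,g_min bounds (nS).
#' @param tol_frac how close to a bound (fraction of g_max) counts as
#'   saturated.
#' @return fraction of weights within `tol_frac*g_max` of either bound.
#' @export
weight_bimodality <- function(w, g_max = 10, g_min = 0, tol_frac = 0.05) {
  tol <- tol_frac * g_max
  mean(w <= g_min + tol | w >= g_max - tol)
}
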