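#' Transition probability matrix of the Mk1 model
#'
#' Under the Markov k-state one-parameter model every change between the k
#' unordered states occurs at the same instantaneous rate `alpha` (per Ma),
#' so the rate matrix Q has off-diagonals `alpha` and diagonals
#' `-(k-1) alpha`, and the transition probabilities have the closed form
#' \deqn{P_{ii}(t) = 1/k + \frac{k-1}{k} e^{-k \alpha t}, \qquad
#'       P_{ij}(t) = 1/k - \frac{1}{k} e^{-k \alpha t}.}
#'
#' @param alpha rate of change to each alternative state, per Ma, > 0.
#' @param t elapsed time (branch length), Ma, >= 0.
#' @param k number of states (>= 2).
#' @return a k-by-k row-stochastic matrix.
#' @examples
#' mk_transition_matrix(0.1, 5, k = 3)
#' @export
mk_transition_matrix <- function(alpha, t, k = 3) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (t < 0) stop("t must be >= 0")
  e <- exp(-k * alpha * t)
  P <- matrix((1 - e) / k, k, k)
  diag(P) <- 1 / k + (k - 1) * e / k
  P
}

# --- internal pruning machinery ---------------------------------------------
#
# All functions below index nodes the ape way: tips 1..ntip, root ntip+1,
# internals ntip+1..ntip+nnode.  States are integers 0..k-1.
#
# .mk_prep caches the traversal structure so the optimizer does not redo it
# on every likelihood evaluation.
.mk_prep <- function(tree, states, k) {
  ntip <- length(tree$tip.label)
  if (ntip < 1) stop("tree has no tips")
  s <- states[tree$tip.label]
  if (any(is.na(s)))
    stop("tip(s) without state: ",
         paste(tree$tip.label[is.na(s)], collapse = ", "))
  if (any(s < 0 | s >= k)) stop("tip states must be integers in [0, k)")
  edge <- tree$edge
  blen <- tree$edge.length
  if (is.null(blen)) stop("tree has no branch lengths")
  nn <- ntip + tree$Nnode
  # children[[v]] = child node ids of v; brlen[child] = length of its stem
  children <- vector("list", nn)
  brlen <- rep(NA_real_, nn)
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1]; c <- edge[i, 2]
    children[[p]] <- c(children[[p]], c)
    brlen[c] <- blen[i]
  }
  # postorder on internal nodes: ape "postorder" edge ordering lists every
  # edge after all edges in its child's subtree, so unique parents in that
  # order are a valid node postorder
  po_edge <- ape::reorder.phylo(tree, "postorder")$edge
  post_nodes <- unique(po_edge[, 1])         # internal nodes, children-first
  list(ntip = ntip, nn = nn, k = k, root = ntip + 1L,
       states = as.integer(s), children = children, brlen = brlen,
       post_nodes = post_nodes)
}

# message passed up one branch: (P(t) %*% L)(s) = e*L(s) + (1-e)*mean-part
.mk_msg <- function(L, e, k) e * L + (1 - e) * sum(L) / k

# down (pruning) pass with per-node scaling.
# Returns Lhat (nn x k, scaled conditional likelihoods), lsd (per-node
# cumulative log scalers: true L_v = Lhat_v * exp(lsd_v)), msg (nn x k,
# scaled message each non-root node sends to its parent), loglik.
.mk_down <- function(prep, alpha) {
  k <- prep$k
  Lhat <- matrix(0, prep$nn, k)
  Lhat[cbind(seq_len(prep$ntip), prep$states + 1L)] <- 1
  lsd <- numeric(prep$nn)
  msg <- matrix(NA_real_, prep$nn, k)
  for (v in prep$post_nodes) {
    L <- rep(1, k)
    for (ch in prep$children[[v]]) {
      e <- exp(-k * alpha * prep$brlen[ch])
      m <- .mk_msg(Lhat[ch, ], e, k)
      msg[ch, ] <- m
      L <- L * m
      lsd[v] <- lsd[v] + lsd[ch]
    }
    sc <- max(L)
    if (sc <= 0) return(NULL)  # impossible data under this alpha
    Lhat[v, ] <- L / sc
    lsd[v] <- lsd[v] + log(sc)
  }
  root <- prep$root
  loglik <- log(sum(Lhat[root, ] / k)) + lsd[root]
  list(Lhat = Lhat, lsd = lsd, msg = msg, loglik = loglik)
}

# up (outside) pass: Uhat_v carries the likelihood of everything outside the
# subtree of v (including the uniform root prior); marginal_v ~ Lhat_v*Uhat_v
.mk_up <- function(prep, alpha, down) {
  k <- prep$k
  Uhat <- matrix(NA_real_, prep$nn, k)
  lsu <- numeric(prep$nn)
  root <- prep$root
  Uhat[root, ] <- 1 / k
  for (v in rev(prep$post_nodes)) {       # preorder: parents before children
    kids <- prep$children[[v]]
    for (ch in kids) {
      A <- Uhat[v, ]
      for (w in kids) if (w != ch) {
        A <- A * down$msg[w, ]
        lsu[ch] <- lsu[ch] + down$lsd[w]
      }
      e <- exp(-k * alpha * prep$brlen[ch])
      U <- .mk_msg(A, e, k)               # P is symmetric: same kernel
      sc <- max(U)
      Uhat[ch, ] <- U / sc
      lsu[ch] <- lsu[ch] + lsu[v] + log(sc)
    }
  }
  list(Uhat = Uhat, lsu = lsu)
}

#' Pruning log-likelihood of tip states under the Mk1 model
#'
#' Felsenstein's pruning algorithm with per-node scaling and a uniform 1/k
#' prior on the root state.  Polytomies are handled natively (product over
#' all children).
#'
#' @param tree a `chronogram` (or `phylo`) with branch lengths in Ma.
#' @param states named integer vector of tip states (0..k-1), covering every
#'   tip (e.g. from [read_biome_coding()]).
#' @param alpha Mk1 rate, per Ma, > 0.
#' @param k number of states.
#' @return the log-likelihood (a scalar).
#' @export
mk_loglik <- function(tree, states, alpha, k = 3) {
  if (alpha <= 0) stop("alpha must be > 0")
  prep <- .mk_prep(tree, states, k)
  if (prep$ntip == 1) return(log(1 / k))  # one observed tip, uniform prior
  down <- .mk_down(prep, alpha)
  if (is.null(down)) return(-Inf)
  down$loglik
}

# bounded 1-D ML fit of alpha on the log scale
.mk_fit_alpha <- function(prep, lower = 1e-8, upper = 1e3) {
  mono <- length(unique(prep$states)) == 1
  if (mono) {
    warning("all tips share one state; likelihood is maximized as alpha -> 0, ",
            "returning the lower bound", call. = FALSE)
    d <- .mk_down(prep, lower)
    return(list(alpha = lower, loglik = d$loglik, boundary = TRUE))
  }
  f <- function(la) {
    d <- .mk_down(prep, exp(la))
    if (is.null(d)) return(-.Machine$double.xmax)
    d$loglik
  }
  opt <- stats::optimize(f, c(log(lower), log(upper)), maximum = TRUE,
                         tol = 1e-8)
  list(alpha = exp(opt$maximum), loglik = opt$objective, boundary = FALSE)
}
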