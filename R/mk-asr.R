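#' Maximum-likelihood ancestral-state reconstruction under the Mk1 model
#'
#' Fits the single rate of the Markov k-state one-parameter model to a set of
#' discrete tip states (habitat/biome categories) on a dated tree by
#' maximizing the pruning likelihood, then computes marginal posterior state
#' probabilities at every node by the up-down (outside) algorithm under a
#' uniform 1/k root prior.  Each node's ML state is the argmax of its
#' marginals; a node whose top two probabilities differ by less than
#' `tie_epsilon` is flagged ambiguous (and is excluded from downstream shift
#' counting).
#'
#' @param tree a `chronogram` (see [read_newick()]) or `phylo` with branch
#'   lengths in Ma.
#' @param states named integer vector of tip states in `0..k-1`, e.g. from
#'   [read_biome_coding()].
#' @param k number of states (default taken from the coding's `k` attribute,
#'   else 3).
#' @param alpha optional fixed rate; when `NULL` (default) the rate is
#'   estimated by bounded 1-D ML on the log scale, `alpha` in
#'   `[1e-8, 1e3]` per Ma.
#' @param tie_epsilon ambiguity threshold on the top-two marginal gap.
#' @return an object of class `mk_asr` with elements `tree`, `states`, `k`,
#'   `alpha`, `logLik`, `marginal` (node-by-k matrix over all nodes, tips
#'   included as point masses), `ml_state` (integer, `NA` when ambiguous),
#'   `ambiguous` (logical), `support` (per node; tips 1), `boundary`
#'   (TRUE when the rate estimate sits at the optimization bound), `call`.
#' @seealso [shift_test()], [mk_loglik()], [simulate.mk_asr()]
#' @examples
#' tr <- read_newick("((A:1,B:1)0.99:2,(C:2,D:2)0.7:1);")
#' st <- c(A = 0L, B = 0L, C = 2L, D = 2L)
#' fit <- mk_asr(tr, st, k = 3)
#' fit
#' @export
mk_asr <- function(tree, states, k = NULL, alpha = NULL,
                   tie_epsilon = 1e-6) {
  if (is.null(k)) k <- if (!is.null(attr(states, "k"))) attr(states, "k") else 3L
  tree <- as_chronogram(tree)
  prep <- .mk_prep(tree, states, k)
  if (prep$ntip < 2) stop("need at least 2 tips")
  if (is.null(alpha)) {
    fit <- .mk_fit_alpha(prep)
  } else {
    if (alpha <= 0) stop("alpha must be > 0")
    fit <- list(alpha = alpha, loglik = NULL, boundary = FALSE)
  }
  down <- .mk_down(prep, fit$alpha)
  up <- .mk_up(prep, fit$alpha, down)
  marg <- down$Lhat * up$Uhat
  marg <- marg / rowSums(marg)
  # tips are observed: point masses
  marg[seq_len(prep$ntip), ] <- 0
  marg[cbind(seq_len(prep$ntip), prep$states + 1L)] <- 1
  ml <- max.col(marg, ties.method = "first") - 1L
  sorted <- t(apply(marg, 1, sort, decreasing = TRUE))
  ambiguous <- (sorted[, 1] - sorted[, 2]) < tie_epsilon
  ml[ambiguous] <- NA_integer_
  structure(list(
    tree = tree, states = prep$states, k = k,
    alpha = fit$alpha, logLik = down$loglik,
    marginal = marg, ml_state = ml, ambiguous = ambiguous,
    support = if (!is.null(tree$support)) tree$support else
      c(rep(1, prep$ntip), rep(NA_real_, tree$Nnode)),
    boundary = isTRUE(fit$boundary),
    tie_epsilon = tie_epsilon,
    call = match.call()
  ), class = "mk_asr")
}

#' @export
print.mk_asr <- function(x, ...) {
  cat("Mk1 ancestral-state reconstruction\n")
  cat(sprintf("  %d tips, %d internal nodes, k = %d states\n",
              length(x$tree$tip.label), x$tree$Nnode, x$k))
  cat(sprintf("  fitted rate alpha = %.6g per Ma%s\n", x$alpha,
              if (x$boundary) " (at optimization bound)" else ""))
  cat(sprintf("  log-likelihood = %.6f  (uniform 1/%d root prior)\n",
              x$logLik, x$k))
  n_amb <- sum(x$ambiguous[-seq_len(length(x$tree$tip.label))])
  cat(sprintf("  ambiguous internal nodes: %d\n", n_amb))
  invisible(x)
}

#' @export
summary.mk_asr <- function(object, ...) {
  ntip <- length(object$tree$tip.label)
  idx <- ntip + seq_len(object$tree$Nnode)
  tab <- data.frame(
    node = idx,
    support = object$support[idx],
    object$marginal[idx, , drop = FALSE],
    ml_state = object$ml_state[idx],
    ambiguous = object$ambiguous[idx]
  )
  names(tab)[2 + seq_len(object$k)] <- paste0("P_state", seq_len(object$k) - 1)
  structure(list(alpha = object$alpha, logLik = object$logLik,
                 k = object$k, nodes = tab),
            class = "summary.mk_asr")
}

#' @export
print.summary.mk_asr <- function(x, ...) {
  cat(sprintf("Mk1 fit: alpha = %.6g, logLik = %.4f, k = %d\n",
              x$alpha, x$logLik, x$k))
  print(utils::head(x$nodes, 10), digits = 4, row.names = FALSE)
  if (nrow(x$nodes) > 10) cat("  ... (", nrow(x$nodes) - 10, " more nodes)\n")
  invisible(x)
}

#' @export
coef.mk_asr <- function(object, ...) c(alpha = object$alpha)

#' @export
logLik.mk_asr <- function(object, ...) {
  structure(object$logLik, df = 1, nobs = length(object$tree$tip.label),
            class = "logLik")
}

#' Simulate tip states under a fitted Mk1 model
#'
#' Forward-simulates the discrete character down the fitted tree from a
#' uniform root state, using the model's transition probabilities — the
#' parametric-bootstrap counterpart of [mk_asr()].
#'
#' @param object an `mk_asr` fit.
#' @param nsim number of replicate tip-state vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return a matrix (`nsim` rows, one column per tip) of simulated states.
#' @export
simulate.mk_asr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- t(vapply(seq_len(nsim), function(i) {
    sim <- simulate_character(object$tree, alpha = object$alpha, k = object$k)
    sim$tip_states
  }, integer(length(object$tree$tip.label))))
  colnames(out) <- object$tree$tip.label
  out
}

#' Plot a reconstruction: tree with marginal-probability pies at nodes
#'
#' @param x an `mk_asr` fit.
#' @param colors one colour per state (default white/green/black for the
#'   semi-arid/woodland/forest convention).
#' @param cex.pie pie size.
#' @param ... passed to [ape::plot.phylo()].
#' @export
plot.mk_asr <- function(x, colors = c("white", "darkgreen", "black"),
                        cex.pie = 0.5, ...) {
  if (length(colors) < x$k) colors <- grDevices::hcl.colors(x$k)
  ntip <- length(x$tree$tip.label)
  ape::plot.phylo(x$tree, ...)
  ape::nodelabels(pie = x$marginal[ntip + seq_len(x$tree$Nnode), ,
                                   drop = FALSE],
                  piecol = colors[seq_len(x$k)], cex = cex.pie)
  ape::tiplabels(pch = 21, bg = colors[x$states + 1L])
  invisible(x)
}

#' Write the per-node reconstruction table as TSV
#'
#' Header comment lines record the fitted rate and log-likelihood; the body
#' has one row per node with its support, marginal probabilities, ML state
#' and ambiguity flag.
#'
#' @param fit an `mk_asr` object.
#' @param file output path.
#' @export
write_asr_nodes <- function(fit, file) {
  s <- summary(fit)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# alpha = %.10g", fit$alpha), con)
  writeLines(sprintf("# logLik = %.10g", fit$logLik), con)
  utils::write.table(format(s$nodes, digits = 10, trim = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
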