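# Independent oracles used across the suite.  These deliberately avoid the
# package's own pruning/closed-form code paths: likelihoods by exhaustive
# enumeration of internal-state assignments with matrix-exponential
# transition probabilities, Mann-Whitney p-values by combinatorial
# enumeration of rank arrangements.

# transition matrix by matrix exponential of the Mk rate matrix
oracle_transition <- function(alpha, t, k) {
  Q <- matrix(alpha, k, k)
  diag(Q) <- -(k - 1) * alpha
  as.matrix(Matrix::expm(Q * t))
}

# likelihood (and per-node marginals) by brute-force sum over all internal
# state assignments, uniform 1/k root prior
oracle_enum <- function(tree, states, alpha, k) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  s <- states[tree$tip.label]
  ints <- (ntip + 1):nn
  grid <- as.matrix(expand.grid(rep(list(0:(k - 1)), length(ints))))
  Pcache <- lapply(seq_len(nrow(tree$edge)),
                   function(e) oracle_transition(alpha, tree$edge.length[e], k))
  tot <- 0
  pernode <- matrix(0, nn, k)
  for (g in seq_len(nrow(grid))) {
    asg <- rep(NA_integer_, nn)
    asg[seq_len(ntip)] <- s
    asg[ints] <- grid[g, ]
    lik <- 1 / k
    for (e in seq_len(nrow(tree$edge)))
      lik <- lik * Pcache[[e]][asg[tree$edge[e, 1]] + 1,
                               asg[tree$edge[e, 2]] + 1]
    tot <- tot + lik
    for (v in seq_len(nn))
      pernode[v, asg[v] + 1] <- pernode[v, asg[v] + 1] + lik
  }
  list(loglik = log(tot), marginal = pernode / tot)
}

# exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled sample to the two groups (tie-free data); two-sided p doubles the
# smaller tail, capped at 1 (the convention of the exact distribution)
oracle_mw_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  U_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  Us <- apply(idx, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  lo <- mean(Us <= U_obs)
  hi <- mean(Us >= U_obs)
  min(1, 2 * min(lo, hi))
}

# random tree with supports for quick fixtures
rand_chronogram <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as_chronogram(ape::rtree(n))
}

# write a minimal valid occurrence CSV and return its path
write_occ_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

make_occ_row <- function(record_id, unit, tmin, tmax, prec) {
  mm <- sprintf("%02d", 1:12)
  row <- data.frame(record_id = record_id, unit = unit, lat = 0, lon = 30)
  for (m in 1:12) row[[paste0("tmin_", mm[m])]] <- tmin[m]
  for (m in 1:12) row[[paste0("tmax_", mm[m])]] <- tmax[m]
  for (m in 1:12) row[[paste0("prec_", mm[m])]] <- prec[m]
  row
}
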