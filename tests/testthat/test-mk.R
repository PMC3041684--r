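test_that("transition matrix: identity at t = 0, uniform at stationarity", {
  expect_equal(mk_transition_matrix(0.3, 0, k = 3), diag(3))
  P <- mk_transition_matrix(2, 40, k = 4)   # k*alpha*t >> 40
  expect_true(all(abs(P - 0.25) < 1e-15))
  P3 <- mk_transition_matrix(0.1, 5, k = 3)
  expect_equal(P3[1, 1], 1 / 3 + 2 * exp(-1.5) / 3, tolerance = 1e-12)
  expect_equal(P3[1, 2], 1 / 3 - exp(-1.5) / 3, tolerance = 1e-12)
  expect_equal(round(P3[1, 1], 5), 0.48209)
  expect_equal(round(P3[1, 2], 5), 0.25896)
  expect_error(mk_transition_matrix(-1, 1), "alpha")
  expect_error(mk_transition_matrix(1, -1), "t")
})

test_that("transition matrix equals the matrix exponential across random cases", {
  set.seed(66)
  for (i in 1:20) {
    k <- sample(2:5, 1); a <- runif(1, 0.01, 2); t <- runif(1, 0, 10)
    expect_lt(max(abs(mk_transition_matrix(a, t, k) -
                      oracle_transition(a, t, k))), 1e-12)
    # rows sum to 1, off-diagonals symmetric
    P <- mk_transition_matrix(a, t, k)
    expect_equal(rowSums(P), rep(1, k))
    expect_equal(P, t(P))
  }
})

test_that("pruning log-likelihood equals the enumeration oracle", {
  set.seed(77)
  for (i in 1:30) {
    n <- sample(3:6, 1); k <- sample(2:3, 1)
    a <- runif(1, 0.02, 1.5)
    tr <- rand_chronogram(n)
    st <- sample(0:(k - 1), n, replace = TRUE)
    names(st) <- tr$tip.label
    expect_equal(mk_loglik(tr, st, a, k),
                 oracle_enum(tr, st, a, k)$loglik, tolerance = 1e-12)
  }
  # 4-tip, k = 2 spotlight case from the enumeration contract
  tr <- read_newick("((A:1,B:2):0.5,(C:1.5,D:0.7):1);")
  st <- c(A = 0L, B = 1L, C = 0L, D = 1L)
  expect_equal(mk_loglik(tr, st, 0.2, 2),
               oracle_enum(tr, st, 0.2, 2)$loglik, tolerance = 1e-12)
})

test_that("single observed tip has log-likelihood log(1/k)", {
  tr <- read_newick("(A:1);")
  expect_equal(mk_loglik(tr, c(A = 0L), 0.5, 3), log(1 / 3))
})

test_that("likelihood vanishes as alpha -> 0 with tips in >= 2 states", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  st <- c(A = 0L, B = 1L, C = 0L)
  lls <- sapply(c(1e-1, 1e-3, 1e-5), function(a) mk_loglik(tr, st, a, 3))
  expect_true(all(diff(lls) < 0))          # monotone decrease
  expect_lt(lls[3], -10)
})

test_that("likelihood is invariant to child order and zero-length degree-2 nodes", {
  tr <- read_newick("((A:1,B:2)0.9:0.5,(C:1.5,D:0.7)0.8:1);")
  st <- c(A = 0L, B = 1L, C = 2L, D = 1L)
  rot <- read_newick("((D:0.7,C:1.5)0.8:1,(B:2,A:1)0.9:0.5);")
  expect_equal(mk_loglik(tr, st, 0.3, 3), mk_loglik(rot, st, 0.3, 3),
               tolerance = 1e-12)
  # splice a zero-length degree-2 node into one branch
  spliced <- read_newick("((A:1,B:2)0.9:0.5,((C:1.5,D:0.7)0.8:0.0):1);")
  expect_equal(mk_loglik(tr, st, 0.3, 3), mk_loglik(spliced, st, 0.3, 3),
               tolerance = 1e-12)
})

test_that("rate fitting: optimality, boundary warning, oracle cross-check", {
  set.seed(88)
  tr <- rand_chronogram(40)
  sim <- simulate_character(tr, alpha = 0.3, k = 3)
  fit <- mk_asr(tr, sim$tip_states, k = 3)
  for (m in c(0.5, 2)) {
    expect_gte(fit$logLik, mk_loglik(tr, sim$tip_states, fit$alpha * m, 3))
  }
  # monomorphic tips sit at the lower bound with a warning
  mono <- rep(1L, 6); names(mono) <- letters[1:6]
  trm <- rand_chronogram(6)
  names(mono) <- trm$tip.label
  expect_warning(fitm <- mk_asr(trm, mono, k = 3), "lower bound")
  expect_equal(fitm$alpha, 1e-8)
  expect_true(fitm$boundary)
})

test_that("fit agrees with an independent ER-model implementation", {
  skip_if_not_installed("phytools")
  set.seed(99)
  tr <- rand_chronogram(30)
  sim <- simulate_character(tr, alpha = 0.4, k = 3)
  fit <- mk_asr(tr, sim$tip_states, k = 3)
  x <- factor(sim$tip_states, levels = 0:2)
  names(x) <- names(sim$tip_states)
  ref <- phytools::fitMk(tr, x, model = "ER", pi = "equal")
  expect_equal(fit$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
  expect_equal(fit$alpha, ref$rates, tolerance = 0.02)
})

test_that("marginal reconstruction matches the enumeration oracle", {
  set.seed(111)
  for (i in 1:15) {
    n <- sample(3:6, 1); k <- sample(2:3, 1)
    a <- runif(1, 0.05, 1)
    tr <- rand_chronogram(n)
    st <- sample(0:(k - 1), n, replace = TRUE)
    names(st) <- tr$tip.label
    fit <- mk_asr(tr, st, k = k, alpha = a)
    orc <- oracle_enum(tr, st, a, k)
    expect_lt(max(abs(fit$marginal - orc$marginal)), 1e-9)
    expect_equal(rowSums(fit$marginal), rep(1, nrow(fit$marginal)),
                 tolerance = 1e-9)
  }
})

test_that("marginal-based total likelihood agrees with pruning at every node", {
  set.seed(122)
  tr <- rand_chronogram(12)
  st <- sample(0:2, 12, replace = TRUE)
  names(st) <- tr$tip.label
  a <- 0.25
  prep <- biomeshift:::.mk_prep(tr, st, 3)
  down <- biomeshift:::.mk_down(prep, a)
  up <- biomeshift:::.mk_up(prep, a, down)
  for (v in seq_len(prep$nn)) {
    tot <- log(sum(down$Lhat[v, ] * up$Uhat[v, ])) + down$lsd[v] + up$lsu[v]
    expect_equal(tot, down$loglik, tolerance = 1e-9)
  }
})

test_that("two matching tips reconstruct their shared state at the root", {
  tr <- read_newick("(A:1,B:1);")
  fit <- mk_asr(tr, c(A = 2L, B = 2L), k = 3, alpha = 0.2)
  root <- length(tr$tip.label) + 1
  expect_equal(which.max(fit$marginal[root, ]) - 1, 2)
})

test_that("mk_asr object supports the standard model-object verbs", {
  set.seed(133)
  tr <- rand_chronogram(10)
  sim <- simulate_character(tr, 0.3, 3)
  fit <- mk_asr(tr, sim$tip_states)
  expect_named(coef(fit), "alpha")
  expect_s3_class(stats::logLik(fit), "logLik")
  expect_output(print(fit), "alpha")
  expect_output(print(summary(fit)), "logLik")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(3, 10))
  expect_true(all(sims %in% 0:2))
  tf <- tempfile(fileext = ".tsv")
  write_asr_nodes(fit, tf)
  expect_match(readLines(tf, n = 1), "alpha")
})
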