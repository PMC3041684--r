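test_that("expected shifts: constant, frequency-derived and degenerate nulls", {
  ex <- expected_shifts(27, null_constant(0.635))
  expect_equal(ex$E, 17.145)
  expect_equal(ex$E_rounded, 17L)

  expect_equal(suppressWarnings(
    expected_shifts(10, null_frequency(c(1, 0, 0)))$E), 0)
  ex3 <- expected_shifts(9, null_frequency(rep(1 / 3, 3)))
  expect_equal(ex3$p_rand, 2 / 3)
  expect_equal(ex3$E, 6)
  # frequencies derived from tip states when not supplied
  st <- c(a = 0L, b = 0L, c = 1L, d = 2L)
  ex4 <- expected_shifts(4, null_frequency(), states = st, k = 3)
  expect_equal(ex4$p_rand, 1 - sum((c(2, 1, 1) / 4)^2))
  expect_warning(expected_shifts(5, null_frequency(c(1, 0, 0)), k = 3),
                 "degenerate")
  expect_error(expected_shifts(0, null_constant(0.5)), "n")
  # round-half-up display convention
  expect_equal(expected_shifts(5, null_constant(0.5))$E_rounded, 3L)
})

test_that("G test matches the closed form and its symmetries", {
  # O = E exactly -> G = 0, p = 1
  g0 <- g_test(5, 10, 0.5)
  expect_equal(g0$G, 0)
  expect_equal(g0$p_value, 1)

  g <- g_test(6, 27, 0.635)
  E <- 27 * 0.635
  expect_equal(g$G, 2 * (6 * log(6 / E) + 21 * log(21 / (27 - E))),
               tolerance = 1e-12)
  expect_equal(g$G, 19.175, tolerance = 1e-3)
  expect_equal(g$p_value, stats::pchisq(g$G, 1, lower.tail = FALSE))

  # complementary framing symmetry
  g2 <- g_test(21, 27, 1 - 0.635)
  expect_equal(g$G, g2$G, tolerance = 1e-12)

  # O = 0 handled via 0 ln 0 = 0
  expect_equal(g_test(0, 10, 0.3)$G, 2 * 10 * log(10 / 7), tolerance = 1e-12)
  expect_error(g_test(11, 10, 0.3), "exceed")
})

test_that("shift counting respects support, ambiguity and monotonicity", {
  # 2-tip tree, unequal branch lengths: the root's ML state is the state of
  # the closer tip, so exactly one branch carries a shift
  tr <- read_newick("(A:1,B:2);")
  fit <- mk_asr(tr, c(A = 0L, B = 2L), k = 3, alpha = 0.2)
  cs <- count_shifts(fit, support_threshold = 0.98)
  expect_equal(cs$O_shift, 1)
  expect_equal(cs$n, 2)
  expect_equal(cs$shifts$child_label, "B")

  # equal branch lengths: the root marginals for the two observed states tie
  # exactly, the root is flagged ambiguous, and its branches are excluded
  trs <- read_newick("(A:1,B:1);")
  fits <- mk_asr(trs, c(A = 0L, B = 2L), k = 3, alpha = 0.2)
  expect_true(fits$ambiguous[3])
  css <- count_shifts(fits, support_threshold = 0.98)
  expect_equal(css$n, 0)

  # all tips one state -> no shifts at any rate
  tr4 <- rand_chronogram(6, seed = 9)
  st <- rep(2L, 6); names(st) <- tr4$tip.label
  fit4 <- suppressWarnings(mk_asr(tr4, st, k = 3))
  expect_equal(count_shifts(fit4)$O_shift, 0)

  # raising the threshold can only shrink n and O_shift
  set.seed(10)
  tr5 <- simulate_tree(sim_spec(n_tips = 30, alpha = 0.3))
  sim <- simulate_character(tr5, 0.3, 3)
  fit5 <- suppressWarnings(mk_asr(tr5, sim$tip_states))
  lo <- count_shifts(fit5, support_threshold = 0)
  hi <- count_shifts(fit5, support_threshold = 0.98)
  expect_lte(hi$n, lo$n)
  expect_lte(hi$O_shift, lo$O_shift)
  expect_error(count_shifts(fit5, support_threshold = 1.5), "threshold")

  # every listed shift branch differs in state and satisfies the filter
  sh <- lo$shifts
  if (nrow(sh)) {
    expect_true(all(sh$parent_state != sh$child_state))
    expect_true(all(sh$child_support >= 0))
  }
})

test_that("shift counting is invariant to tip reordering / Newick rotation", {
  tr <- read_newick("((A:1,B:1)0.99:1,(C:1,D:1)0.99:1);")
  rot <- read_newick("((D:1,C:1)0.99:1,(B:1,A:1)0.99:1);")
  st <- c(A = 0L, B = 0L, C = 2L, D = 2L)
  f1 <- mk_asr(tr, st, k = 3, alpha = 0.1)
  f2 <- mk_asr(rot, st, k = 3, alpha = 0.1)
  c1 <- count_shifts(f1); c2 <- count_shifts(f2)
  expect_equal(c1$n, c2$n)
  expect_equal(c1$O_shift, c2$O_shift)
})

test_that("basal-node exclusion removes the deepest internal nodes", {
  tr <- read_newick("(((A:1,B:1)0.99:1,C:2)0.99:1,D:3);")
  st <- c(A = 0L, B = 0L, C = 2L, D = 2L)
  fit <- mk_asr(tr, st, k = 3, alpha = 0.1)
  full <- count_shifts(fit, support_threshold = 0)
  drop1 <- count_shifts(fit, support_threshold = 0, drop_basal = 1)
  # dropping the root removes its two incident branches
  expect_equal(drop1$n, full$n - 2)
  drop_all <- count_shifts(fit, support_threshold = 0, drop_basal = 3)
  expect_equal(drop_all$n, 0)
})

test_that("permutation null is deterministic and degenerate cases behave", {
  set.seed(20)
  tr <- simulate_tree(sim_spec(n_tips = 25, alpha = 0.3))
  sim <- simulate_character(tr, 0.3, 3)
  fit <- suppressWarnings(mk_asr(tr, sim$tip_states))
  p1 <- permutation_null(fit, reps = 100, seed = 42)
  p2 <- permutation_null(fit, reps = 100, seed = 42)
  expect_identical(p1$O_null, p2$O_null)
  expect_error(permutation_null(fit, reps = 50), "100")

  # all tips one state: every replicate is shift-free, p = 1
  st1 <- rep(0L, 25); names(st1) <- tr$tip.label
  fit1 <- suppressWarnings(mk_asr(tr, st1, k = 3))
  pn <- permutation_null(fit1, reps = 100, seed = 7)
  expect_true(all(pn$O_null == 0))
  expect_equal(pn$p_empirical, 1)
})

test_that("shift_test composes the pieces and writes a valid report", {
  set.seed(30)
  tr <- simulate_tree(sim_spec(n_tips = 30, alpha = 0.2))
  sim <- simulate_character(tr, 0.2, 3)
  fit <- suppressWarnings(mk_asr(tr, sim$tip_states))
  st <- shift_test(fit, support_threshold = 0.9, null = null_frequency(),
                   permutations = 100, seed = 5)
  expect_gte(st$O_shift, 0)
  expect_lte(st$O_shift, st$n)
  expect_gte(st$G, 0)
  expect_equal(st$E, st$n * st$p_rand)
  expect_output(print(st), "Biome-shift")
  jf <- tempfile(fileext = ".json"); tf <- tempfile(fileext = ".tsv")
  write_shift_report(st, jf, tf)
  rep <- jsonlite::read_json(jf)
  expect_equal(rep$n, st$n)
  expect_equal(rep$O_shift, st$O_shift)
  expect_equal(rep$options$support_threshold, 0.9)
})
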