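#' Null models for the biome-shift test
#'
#' A shift null specifies the probability `p_rand` that a random branch
#' connects two different habitat states.  Three modes:
#' `null_constant(p)` supplies the probability directly (e.g. a published
#' constant); `null_frequency()` derives it from observed tip-state
#' frequencies as the pair-mismatch probability `1 - sum(f_i^2)`;
#' `null_permutation(reps, seed)` requests a Monte-Carlo null in which tip
#' states are shuffled without replacement, the rate refitted, and shifts
#' recounted per replicate.
#'
#' @param p shift probability in (0, 1).
#' @param freqs optional state frequencies (summing to 1); when `NULL` they
#'   are taken from the tip coding at test time.
#' @param reps number of permutation replicates (>= 100).
#' @param seed RNG seed for the permutation null.
#' @return a `shift_null` specification list.
#' @name shift_null
NULL

#' @rdname shift_null
#' @export
null_constant <- function(p) {
  if (p <= 0 || p >= 1) stop("p_rand must be in (0, 1)")
  structure(list(mode = "constant", p_rand = p), class = "shift_null")
}

#' @rdname shift_null
#' @export
null_frequency <- function(freqs = NULL) {
  if (!is.null(freqs)) {
    if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
    if (any(freqs < 0)) stop("negative frequency")
  }
  structure(list(mode = "frequency", freqs = freqs), class = "shift_null")
}

#' @rdname shift_null
#' @export
null_permutation <- function(reps = 1000, seed = NULL) {
  if (reps < 100) stop("need at least 100 permutation replicates")
  structure(list(mode = "permutation", reps = as.integer(reps), seed = seed),
            class = "shift_null")
}

.null_p_rand <- function(null, states, k) {
  if (null$mode == "constant") return(null$p_rand)
  f <- null$freqs
  if (is.null(f)) f <- tabulate(states + 1L, nbins = k) / length(states)
  p <- 1 - sum(f^2)
  if (p == 0) warning("degenerate state frequencies: p_rand = 0",
                      call. = FALSE)
  p
}

#' Count biome shifts on supported branches
#'
#' A branch is *eligible* when its child endpoint is a tip (observed, hence
#' certain) or an internal node with support at or above the threshold, and
#' both endpoints have unambiguous ML states.  A *shift* is an eligible
#' branch whose endpoint states differ; it is attributed to the child node.
#' With `drop_basal > 0`, the `drop_basal` internal nodes closest to the
#' root (by edge-count depth, ties broken by node id) and all branches
#' incident to them are excluded — the sensitivity analysis that removes the
#' most basal, ambiguously reconstructed nodes.
#'
#' @param asr an `mk_asr` fit.
#' @param support_threshold minimum posterior support for an internal child
#'   node to count, in `[0, 1]` (default 0.98).
#' @param drop_basal number of basal internal nodes to exclude.
#' @return list with `n` (eligible branch count), `O_shift` (shift count) and
#'   `shifts`, a data.frame of the shift branches (`parent`, `child`,
#'   `parent_state`, `child_state`, `child_support`, `child_label`).
#' @export
count_shifts <- function(asr, support_threshold = 0.98, drop_basal = 0) {
  if (support_threshold < 0 || support_threshold > 1)
    stop("support_threshold must be in [0, 1]")
  tree <- asr$tree
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  ml <- asr$ml_state
  sup <- asr$support
  sup[seq_len(ntip)] <- 1
  dropped <- integer(0)
  if (drop_basal > 0) {
    depth <- .node_depths(tree)
    internals <- ntip + seq_len(tree$Nnode)
    ord <- internals[order(depth[internals], internals)]
    dropped <- ord[seq_len(min(drop_basal, length(ord)))]
  }
  parent <- edge[, 1]; child <- edge[, 2]
  is_tip <- child <= ntip
  supported <- is_tip | (!is.na(sup[child]) & sup[child] >= support_threshold)
  unamb <- !is.na(ml[child]) & !is.na(ml[parent])
  keep <- supported & unamb &
    !(parent %in% dropped) & !(child %in% dropped)
  shift <- keep & ml[child] != ml[parent]
  shifts <- data.frame(
    parent = parent[shift], child = child[shift],
    parent_state = ml[parent[shift]], child_state = ml[child[shift]],
    child_support = sup[child[shift]],
    child_label = ifelse(child[shift] <= ntip,
                         tree$tip.label[pmin(child[shift], ntip)], ""),
    stringsAsFactors = FALSE
  )
  list(n = sum(keep), O_shift = sum(shift), shifts = shifts)
}

#' Expected number of shifts under random habitat assignment
#'
#' @param n number of eligible nodes/branches (>= 1).
#' @param null a `shift_null` from [null_constant()] or [null_frequency()]
#'   (a bare probability is also accepted).
#' @param states tip states, needed when the null derives `p_rand` from
#'   frequencies and none were supplied.
#' @param k number of states.
#' @return list with `E` (real expected count `n * p_rand`), `E_rounded`
#'   (round-half-up integer) and `p_rand`.
#' @examples
#' expected_shifts(27, null_constant(0.635))  # E = 17.145, rounds to 17
#' @export
expected_shifts <- function(n, null, states = NULL, k = 3) {
  if (n < 1) stop("n must be >= 1")
  if (is.numeric(null)) null <- null_constant(null)
  p <- .null_p_rand(null, states, k)
  E <- n * p
  list(E = E, E_rounded = as.integer(floor(E + 0.5)), p_rand = p)
}

#' Likelihood-ratio (G) goodness-of-fit test for the shift count
#'
#' Compares the observed split of `n` eligible branches into shift /
#' non-shift against the expectation under shift probability `p_rand`:
#' \deqn{G = 2\left[O \ln\frac{O}{E} + (n-O)\ln\frac{n-O}{n-E}\right]}
#' with `0 ln(0/E) = 0`, referred to a chi-square distribution with 1 df.
#'
#' @param O_shift observed shift count (0..n).
#' @param n eligible branch count.
#' @param p_rand null shift probability, in (0, 1).
#' @return list with `G`, `df` (= 1) and `p_value` (upper tail).
#' @export
g_test <- function(O_shift, n, p_rand) {
  if (O_shift > n) stop("O_shift cannot exceed n")
  if (O_shift < 0) stop("O_shift must be >= 0")
  if (p_rand <= 0 || p_rand >= 1) stop("p_rand must be in (0, 1)")
  if (n < 1) stop("n must be >= 1")
  E1 <- n * p_rand
  E0 <- n - E1
  term <- function(o, e) if (o == 0) 0 else o * log(o / e)
  G <- 2 * (term(O_shift, E1) + term(n - O_shift, E0))
  list(G = G, df = 1L,
       p_value = stats::pchisq(G, df = 1, lower.tail = FALSE))
}

#' Permutation null distribution of the shift count
#'
#' Shuffles the tip states without replacement, reconstructs ancestral
#' states and recounts shifts for each replicate, yielding the Monte-Carlo
#' analogue of the random-assignment null.  The empirical p-value is
#' lower-tailed (fraction of replicates with `O_shift` at or below the
#' observed count), matching the question "are there fewer shifts than
#' expected?".
#'
#' By default the Mk1 rate is held at the observed ML estimate across
#' replicates, so the null is "same tree, same evolutionary rate, habitats
#' assigned to tips at random" and every replicate counts shifts over a
#' comparable set of eligible branches.  Re-estimating the rate from each
#' shuffled data set (`refit_alpha = TRUE`) is offered for audit, but note
#' that shuffled tips push the rate estimate towards its upper bound, which
#' flattens the marginals, floods the tree with ambiguous nodes and shrinks
#' the eligible set, so null counts stop being comparable with the observed
#' count.
#'
#' @param asr an `mk_asr` fit (supplies tree, states, k and tie policy).
#' @param reps number of replicates (>= 100).
#' @param seed RNG seed; fixed seed gives an identical replicate sequence.
#' @param support_threshold,drop_basal as in [count_shifts()].
#' @param refit_alpha re-estimate the rate per replicate (default FALSE;
#'   see Details).
#' @return list with `O_null` (length-`reps` integer vector), `n_null`
#'   (eligible counts per replicate), `p_empirical`
#'   (`mean(O_null <= O_observed)`), `O_observed`, `n_observed`.
#' @export
permutation_null <- function(asr, reps = 1000, seed = NULL,
                             support_threshold = 0.98, drop_basal = 0,
                             refit_alpha = FALSE) {
  if (reps < 100) stop("need at least 100 permutation replicates")
  if (!is.null(seed)) set.seed(seed)
  obs <- count_shifts(asr, support_threshold, drop_basal)
  tips <- asr$tree$tip.label
  O_null <- integer(reps)
  n_null <- integer(reps)
  for (r in seq_len(reps)) {
    perm <- sample(asr$states)
    names(perm) <- tips
    attr(perm, "k") <- asr$k
    refit <- suppressWarnings(
      mk_asr(asr$tree, perm, k = asr$k,
             alpha = if (refit_alpha) NULL else asr$alpha,
             tie_epsilon = asr$tie_epsilon))
    cs <- count_shifts(refit, support_threshold, drop_basal)
    O_null[r] <- cs$O_shift
    n_null[r] <- cs$n
  }
  list(O_null = O_null, n_null = n_null,
       p_empirical = mean(O_null <= obs$O_shift),
       O_observed = obs$O_shift, n_observed = obs$n)
}

#' Test whether biome shifts are rarer than random expectation
#'
#' The headline analysis: counts shifts on supported branches of a
#' reconstruction, computes the expected count under a random-assignment
#' null, and tests the difference with a likelihood-ratio G test (df 1).
#' Optionally adds a permutation null ([permutation_null()]).
#'
#' @param asr an `mk_asr` fit.
#' @param support_threshold,drop_basal see [count_shifts()].
#' @param null a `shift_null`; default [null_frequency()] (the pair-mismatch
#'   probability from the tip-state frequencies).  Use
#'   `null_constant(0.635)`-style overrides to reproduce published
#'   constants.
#' @param permutations if > 0, also run a permutation null with this many
#'   replicates.
#' @param seed seed for the permutation null.
#' @return an object of class `shift_test`.
#' @export
shift_test <- function(asr, support_threshold = 0.98, drop_basal = 0,
                       null = null_frequency(), permutations = 0,
                       seed = NULL) {
  cs <- count_shifts(asr, support_threshold, drop_basal)
  ex <- expected_shifts(max(cs$n, 1), null, states = asr$states, k = asr$k)
  gt <- if (ex$p_rand > 0 && ex$p_rand < 1 && cs$n >= 1)
    g_test(cs$O_shift, cs$n, ex$p_rand)
  else list(G = NA_real_, df = 1L, p_value = NA_real_)
  perm <- NULL
  if (permutations > 0)
    perm <- permutation_null(asr, reps = permutations, seed = seed,
                             support_threshold = support_threshold,
                             drop_basal = drop_basal)
  structure(list(
    n = cs$n, O_shift = cs$O_shift, shifts = cs$shifts,
    p_rand = ex$p_rand, E = ex$E, E_rounded = ex$E_rounded,
    G = gt$G, df = gt$df, p_value = gt$p_value,
    permutation = perm,
    options = list(support_threshold = support_threshold,
                   drop_basal = drop_basal, null_mode = null$mode,
                   permutations = permutations, seed = seed)
  ), class = "shift_test")
}

#' @export
print.shift_test <- function(x, ...) {
  cat("Biome-shift conservatism test\n")
  cat(sprintf("  eligible branches n = %d (support >= %.2f%s)\n", x$n,
              x$options$support_threshold,
              if (x$options$drop_basal > 0)
                sprintf(", %d basal nodes removed", x$options$drop_basal)
              else ""))
  cat(sprintf("  observed shifts O = %d\n", x$O_shift))
  cat(sprintf("  null p_rand = %.4f (%s), expected E = %.3f (~%d)\n",
              x$p_rand, x$options$null_mode, x$E, x$E_rounded))
  cat(sprintf("  G = %.4f, df = %d, p = %.4g\n", x$G, x$df, x$p_value))
  if (!is.null(x$permutation))
    cat(sprintf("  permutation null (%d reps): mean O = %.2f, empirical p = %.4g\n",
                length(x$permutation$O_null), mean(x$permutation$O_null),
                x$permutation$p_empirical))
  invisible(x)
}

#' Write a shift-test report (JSON) and shift-branch list (TSV)
#'
#' @param test a `shift_test` object.
#' @param json_file path for the JSON report (`NULL` to skip).
#' @param tsv_file path for the shift-branch TSV (`NULL` to skip).
#' @export
write_shift_report <- function(test, json_file = NULL, tsv_file = NULL) {
  if (!is.null(json_file)) {
    rep <- list(
      n = test$n, O_shift = test$O_shift, p_rand = test$p_rand,
      E = test$E, E_rounded = test$E_rounded,
      G = test$G, df = test$df, p_value = test$p_value,
      options = test$options,
      shift_branches = test$shifts
    )
    if (!is.null(test$permutation))
      rep$permutation <- list(
        reps = length(test$permutation$O_null),
        mean_O_null = mean(test$permutation$O_null),
        p_empirical = test$permutation$p_empirical)
    jsonlite::write_json(rep, json_file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(tsv_file))
    utils::write.table(test$shifts, tsv_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(test)
}
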