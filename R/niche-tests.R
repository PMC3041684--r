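#' Two-sample Mann-Whitney U test
#'
#' Rank-based two-sided test of distributional difference between two
#' samples, the workhorse for pairwise niche comparisons.  The U statistic
#' is computed from midranks (ties share their average rank).  The p-value
#' is exact (network/enumeration distribution) when the pooled sample is
#' tie-free and `n_x * n_y <= exact_threshold`; otherwise a normal
#' approximation with tie correction and continuity correction is used,
#' matching common statistical-package behaviour.
#'
#' @param x,y numeric samples, each non-empty.
#' @param exact_threshold use the exact null distribution when
#'   `n_x * n_y` does not exceed this and there are no ties (default 400).
#' @return list with `U` (the U statistic for `x`), `p` (two-sided p-value,
#'   capped at 1), `method` (`"exact"` or `"normal"`), `n_x`, `n_y`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact_threshold = 400) {
  if (!length(x) || !length(y)) stop("empty sample")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && nx * ny <= exact_threshold
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  list(U = U, p = min(1, wt$p.value),
       method = if (use_exact) "exact" else "normal",
       n_x = nx, n_y = ny)
}

# significance marks at the conventional pairwise-table cutoffs
.sig_mark <- function(p) ifelse(p < 0.001, "**", ifelse(p < 0.05, "*", ""))

#' Pairwise Mann-Whitney U tests within a clade
#'
#' Runs [mann_whitney_u()] for every unordered pair of units in a clade for
#' one niche variable, as in a pairwise niche-difference table.  Raw
#' p-values are reported (no multiple-testing correction by default; set
#' `adjust = "holm"` for a Holm-corrected column).
#'
#' @param values named list mapping each unit to its numeric values (e.g.
#'   annual precipitation of its records), or an occurrence data.frame plus
#'   `variable`.
#' @param clade character vector of unit names to compare.
#' @param variable variable name used for labelling (and, when `values` is an
#'   occurrence data.frame, the column of [niche_values()] to test:
#'   `"annual_precip"` or `"arid_months"`).
#' @param adjust p-adjustment method passed to [stats::p.adjust()]
#'   (`"none"`, the default, reports raw p-values only).
#' @param exact_threshold see [mann_whitney_u()].
#' @return an object of class `pairwise_tests`: a data.frame with one row per
#'   unordered pair (`variable, unit_a, unit_b, n_a, n_b, U, p, method,
#'   mark`), plus symmetric `U` and `p` matrices in attributes `U_matrix`
#'   and `p_matrix`.  `U` is the statistic for `unit_a`;
#'   `U(a,b) + U(b,a) = n_a * n_b`.
#' @export
pairwise_matrix <- function(values, clade, variable = "annual_precip",
                            adjust = "none", exact_threshold = 400) {
  if (is.data.frame(values)) {
    nv <- niche_values(values)
    values <- split(nv[[variable]], nv$unit)
  }
  missing <- setdiff(clade, names(values))
  if (length(missing))
    stop("no records for unit(s): ", paste(missing, collapse = ", "))
  empty <- clade[vapply(values[clade], length, 1L) == 0]
  if (length(empty))
    stop("no records for unit(s): ", paste(empty, collapse = ", "))
  m <- length(clade)
  Um <- matrix(NA_real_, m, m, dimnames = list(clade, clade))
  Pm <- Um
  rows <- list()
  if (m >= 2) {
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
      a <- clade[i]; b <- clade[j]
      res <- mann_whitney_u(values[[a]], values[[b]], exact_threshold)
      Um[a, b] <- res$U
      Um[b, a] <- res$n_x * res$n_y - res$U
      Pm[a, b] <- Pm[b, a] <- res$p
      rows[[length(rows) + 1L]] <- data.frame(
        variable = variable, unit_a = a, unit_b = b,
        n_a = res$n_x, n_b = res$n_y, U = res$U, p = res$p,
        method = res$method, mark = .sig_mark(res$p),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(0), unit_a = character(0),
               unit_b = character(0), n_a = integer(0), n_b = integer(0),
               U = numeric(0), p = numeric(0), method = character(0),
               mark = character(0))
  if (adjust != "none" && nrow(out))
    out$p_adj <- stats::p.adjust(out$p, method = adjust)
  attr(out, "U_matrix") <- Um
  attr(out, "p_matrix") <- Pm
  class(out) <- c("pairwise_tests", "data.frame")
  out
}

#' @export
print.pairwise_tests <- function(x, ...) {
  cat("Pairwise Mann-Whitney U tests (", x$variable[1], ", ",
      nrow(x), " pairs)\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("marks: * p < 0.05, ** p < 0.001 (raw p-values)\n")
  invisible(x)
}

#' Write pairwise test tables as TSV
#' @param tests one `pairwise_tests` object or a list of them (e.g. one per
#'   clade and variable); blocks are concatenated.
#' @param file output path.
#' @export
write_pairwise_tests <- function(tests, file) {
  if (inherits(tests, "pairwise_tests")) tests <- list(tests)
  tab <- do.call(rbind, lapply(tests, as.data.frame))
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
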