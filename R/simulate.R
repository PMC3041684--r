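#' Default per-biome climate profiles for the occurrence simulator
#'
#' Annual precipitation is drawn log-normally per biome; the 12 monthly
#' weights split the annual total across months (one fixed seasonality per
#' biome, so arid-month counts are controllable given the annual total).
#' Defaults emulate the contrast between sub-Saharan semi-arid bushland
#' (~450 mm, long dry season), deciduous woodland (~950 mm, a few dry
#' months) and (rain-)forest (~1800 mm, essentially aseasonal): with a mean
#' temperature near 22 C a month is arid when it receives less than about
#' 44 mm, so the weight vectors put roughly 8, 4 and 1 months below that
#' line at the profile's median annual total.
#'
#' @return named list of profiles, each with `meanlog`, `sdlog` (log-mm) and
#'   `month_weights` (length 12, summing to 1).
#' @export
biome_profiles <- function() {
  list(
    semi_arid = list(meanlog = log(450), sdlog = 0.35,
                     month_weights = c(rep(0.025, 4), rep(0.2, 4),
                                       rep(0.025, 4))),
    woodland = list(meanlog = log(950), sdlog = 0.30,
                    month_weights = c(rep(0.03, 2), rep(0.11, 8),
                                      rep(0.03, 2))),
    forest = list(meanlog = log(1800), sdlog = 0.25,
                  month_weights = c(0.02, rep(0.98 / 11, 11)))
  )
}

#' Simulation specification
#'
#' Bundles the parameters of the synthetic study design: tree size and age,
#' Mk rate, number of states, per-biome climate profiles, sampling effort
#' and the node-support model.  Defaults mirror the kind of study the
#' pipeline targets: ~26 units on a crown group ~6.9 Ma old, ~45 collections
#' per unit (roughly 1189 records over 26 units), three biomes, and most
#' internal nodes well supported.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth Yule speciation rate per Ma (shape only; the tree is rescaled
#'   to `age`).
#' @param age root age in Ma.
#' @param alpha Mk1 rate per Ma for the simulated character.
#' @param k number of biome states.
#' @param profiles per-biome climate profiles (see [biome_profiles()]); the
#'   first `k` are used, in vocabulary order.
#' @param records_mean Poisson mean of records per unit.
#' @param prop_supported fraction of internal nodes drawn with support
#'   >= 0.98 (the rest are drawn in `[0.5, 0.98)`).
#' @param temp_mean,temp_amplitude mean and seasonal (sinusoidal) amplitude
#'   of monthly mean temperature, degrees C; `tmin`/`tmax` sit 5 C below and
#'   above the monthly mean.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_tips = 26, birth = 0.5, age = 6.9, alpha = 0.2,
                     k = 3, profiles = biome_profiles(), records_mean = 45,
                     prop_supported = 0.8, temp_mean = 22,
                     temp_amplitude = 3) {
  stopifnot(n_tips >= 2, birth > 0, age > 0, alpha > 0, k >= 2,
            records_mean >= 0)
  structure(list(n_tips = n_tips, birth = birth, age = age, alpha = alpha,
                 k = k, profiles = profiles, records_mean = records_mean,
                 prop_supported = prop_supported, temp_mean = temp_mean,
                 temp_amplitude = temp_amplitude),
            class = "sim_spec")
}

#' Simulate an ultrametric Yule chronogram with node supports
#'
#' Pure-birth tree conditioned on the number of tips, rescaled so the root
#' depth equals the target age, with posterior-style supports drawn for
#' internal nodes (`prop_supported` of them at or above 0.98).
#'
#' @param spec a [sim_spec()].
#' @param seed optional RNG seed (fixed seed, identical tree).
#' @return a `chronogram`.
#' @export
simulate_tree <- function(spec = sim_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rphylo(spec$n_tips, birth = spec$birth, death = 0)
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * spec$age / depth
  phy$tip.label <- sprintf("sp%02d", seq_len(spec$n_tips))
  nn <- phy$Nnode
  hi <- stats::runif(nn) < spec$prop_supported
  sup <- numeric(nn)
  sup[hi] <- stats::runif(sum(hi), 0.98, 1)
  sup[!hi] <- stats::runif(sum(!hi), 0.5, 0.98)
  as_chronogram(phy, support = c(rep(1, spec$n_tips), round(sup, 2)))
}

#' Forward-simulate a discrete character under the Mk1 model
#'
#' Root state uniform on `0..k-1`; along each branch the state evolves by
#' the Mk1 transition law (the same closed form used by the likelihood).
#' True internal states are returned for benchmarking reconstructions.
#'
#' @param tree a `chronogram`/`phylo` with branch lengths.
#' @param alpha Mk1 rate per Ma.
#' @param k number of states.
#' @param seed optional RNG seed.
#' @return list with `tip_states` (named integer vector, `k` attribute set)
#'   and `node_states` (all nodes, ape numbering).
#' @export
simulate_character <- function(tree, alpha, k = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  blen <- ape::reorder.phylo(tree, "cladewise")$edge.length
  state <- rep(NA_integer_, nn)
  state[ntip + 1L] <- sample.int(k, 1) - 1L
  for (i in seq_len(nrow(edge))) {
    s <- state[edge[i, 1]]
    P <- mk_transition_matrix(alpha, blen[i], k)
    state[edge[i, 2]] <- sample.int(k, 1, prob = P[s + 1L, ]) - 1L
  }
  tips <- state[seq_len(ntip)]
  names(tips) <- tree$tip.label
  attr(tips, "k") <- k
  list(tip_states = tips, node_states = state)
}

#' Simulate an occurrence table conditioned on a biome coding
#'
#' Per unit, a Poisson number of records; per record, annual precipitation
#' drawn log-normally from the unit's biome profile and spread over months
#' by the profile's fixed weight vector; monthly mean temperature follows a
#' sinusoid (tmin/tmax 5 C below/above).  Latitude/longitude are dummy
#' coordinates.
#'
#' @param coding named integer tip-state vector (see [read_biome_coding()]).
#' @param spec a [sim_spec()].
#' @param seed optional RNG seed.
#' @return occurrence data.frame in the [read_occurrences()] schema.
#' @export
simulate_occurrences <- function(coding, spec = sim_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prof_names <- names(spec$profiles)
  if (max(coding) + 1L > length(spec$profiles))
    stop("biome state without a climate profile")
  mm <- sprintf("%02d", 1:12)
  tmean <- spec$temp_mean +
    spec$temp_amplitude * sin(2 * pi * (0:11) / 12)
  rows <- list()
  rid <- 0L
  for (u in names(coding)) {
    prof <- spec$profiles[[coding[[u]] + 1L]]
    n <- stats::rpois(1, spec$records_mean)
    if (n == 0) {
      warning("unit ", u, " drew 0 records", call. = FALSE)
      next
    }
    A <- stats::rlnorm(n, prof$meanlog, prof$sdlog)
    prec <- round(outer(A, prof$month_weights), 1)
    df <- data.frame(record_id = sprintf("r%05d", rid + seq_len(n)),
                     unit = u,
                     lat = round(stats::runif(n, -25, 10), 4),
                     lon = round(stats::runif(n, 10, 40), 4),
                     stringsAsFactors = FALSE)
    for (m in 1:12) df[[paste0("tmin_", mm[m])]] <- round(tmean[m] - 5, 1)
    for (m in 1:12) df[[paste0("tmax_", mm[m])]] <- round(tmean[m] + 5, 1)
    for (m in 1:12) df[[paste0("prec_", mm[m])]] <- prec[, m]
    rid <- rid + n
    rows[[length(rows) + 1L]] <- df
  }
  if (!length(rows)) stop("no records simulated")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic data set
#'
#' Convenience wrapper: tree, Mk-evolved biome coding and occurrence table
#' from one spec and seed; optionally written to a directory
#' (`tree.nwk`, `biomes.csv`, `occurrences.csv`, `truth.json`).
#'
#' @param spec a [sim_spec()].
#' @param seed RNG seed governing all three stages.
#' @param dir optional output directory (created if needed).
#' @return list with `tree`, `coding`, `node_states` (truth), `occurrences`.
#' @export
simulate_dataset <- function(spec = sim_spec(), seed = NULL, dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- simulate_tree(spec)
  sim <- simulate_character(tree, spec$alpha, spec$k)
  occ <- simulate_occurrences(sim$tip_states, spec)
  out <- list(tree = tree, coding = sim$tip_states,
              node_states = sim$node_states, occurrences = occ)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_newick(tree, file.path(dir, "tree.nwk"))
    vocab <- names(biome_states)
    utils::write.csv(
      data.frame(unit = names(sim$tip_states),
                 biome = if (spec$k == 3) vocab[sim$tip_states + 1L]
                         else sim$tip_states),
      file.path(dir, "biomes.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(occ, file.path(dir, "occurrences.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(seed = seed, spec = spec[c("n_tips", "birth", "age", "alpha",
                                      "k", "records_mean")],
           node_states = sim$node_states),
      file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
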