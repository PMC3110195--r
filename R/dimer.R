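#' Build the dimer reference dataset from an isolated-dimer ensemble
#'
#' For each sampled frame of a two-chain ensemble, records (i) the number
#' of interpeptide sidechain contacts between C-terminal residues (31-42,
#' sidechain centre-of-mass distance below `contact_cutoff`) and (ii) the
#' interpeptide interaction energy. The default 5000 entries match the
#' size of the reference dataset the detection rule draws from; when the
#' ensemble holds more frames than `n_samples`, frames are subsampled
#' with the seed.
#'
#' @param dimer_traj two-chain `ab_trajectory` (see
#'   [make_isolated_dimer_ensemble()]).
#' @param n_samples reference-set size (default 5000).
#' @param contact_cutoff sidechain contact cutoff, Angstrom.
#' @param seed subsampling seed.
#' @param ... passed to [interpeptide_energy()].
#' @return An `ab_refset` tibble with columns `contacts`, `energy`, and
#'   attributes recording provenance (source frames, cutoff).
#' @export
build_reference_dataset <- function(dimer_traj, n_samples = 5000L,
                                    contact_cutoff = 6.0, seed = 1L, ...) {
  stopifnot(inherits(dimer_traj, "ab_trajectory"))
  chains <- unique(dimer_traj$topology$chain)
  if (length(chains) != 2) abort("reference dataset needs a two-chain trajectory")
  nf <- n_frames(dimer_traj)
  idx <- seq_len(nf)
  if (nf > n_samples) {
    idx <- withr::with_seed(seed, sort(sample.int(nf, n_samples)))
  }
  vals <- purrr::map(idx, function(i) {
    fr <- trajectory_frame(dimer_traj, i)
    list(contacts = cterm_contacts(fr, chains[1], chains[2], contact_cutoff),
         energy = interpeptide_energy(fr, chains[1], chains[2], ...))
  })
  out <- tibble(contacts = purrr::map_int(vals, "contacts"),
                energy = purrr::map_dbl(vals, "energy"))
  if (!all(is.finite(out$energy))) abort("reference energies must be finite")
  attr(out, "source_frames") <- idx
  attr(out, "contact_cutoff") <- contact_cutoff
  class(out) <- c("ab_refset", class(out))
  out
}

# number of interpeptide sidechain contacts restricted to C-terminal
# residues (31-42) of both chains
cterm_contacts <- function(atoms, chain_i, chain_j, contact_cutoff = 6.0) {
  sc <- sidechain_centres(atoms)
  sc <- sc[sc$resno >= 31 & sc$resno <= 42, ]
  a <- sc[sc$chain == chain_i, ]
  b <- sc[sc$chain == chain_j, ]
  if (nrow(a) == 0 || nrow(b) == 0) return(0L)
  d <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
              outer(a$z, b$z, "-")^2)
  sum(d < contact_cutoff)
}

#' The reference-comparison dimer rule
#'
#' A candidate chain pair is called a dimer when, over `n_draws` random
#' draws (with replacement) from the reference dataset, more than
#' `threshold` of the comparisons succeed, where a comparison succeeds
#' if the pair's C-terminal sidechain contacts exceed the drawn
#' reference contacts OR its interaction energy is strictly lower (more
#' favourable) than the drawn reference energy. Ties count as failures.
#' Deterministic given the seed; monotone in the pair's contacts
#' (increasing) and energy (decreasing).
#'
#' @param contacts candidate pair's C-terminal contact count.
#' @param energy candidate pair's interpeptide energy, kcal/mol.
#' @param refset an `ab_refset`.
#' @param n_draws number of reference comparisons (default 3000).
#' @param threshold success fraction required (default 0.75).
#' @param seed draw seed.
#' @return Logical; the realised success fraction is attached as
#'   attribute `"fraction"`.
#' @export
is_dimer <- function(contacts, energy, refset, n_draws = 3000L,
                     threshold = 0.75, seed = 1L) {
  if (n_draws <= 0) abort("n_draws must be positive")
  if (nrow(refset) == 0) abort("reference dataset is empty")
  frac <- withr::with_seed(seed, {
    k <- sample.int(nrow(refset), n_draws, replace = TRUE)
    mean(contacts > refset$contacts[k] | energy < refset$energy[k])
  })
  structure(frac > threshold, fraction = frac)
}

# closed-form per-draw success probability and call probability of the
# rule for given pair metrics (exact binomial)
dimer_call_probability <- function(contacts, energy, refset, n_draws = 3000L,
                                   threshold = 0.75) {
  p <- mean(contacts > refset$contacts | energy < refset$energy)
  k <- floor(threshold * n_draws)   # need successes > threshold * n_draws
  list(p_success = p, p_called = 1 - stats::pbinom(k, n_draws, p))
}

#' Count dimers along a trajectory
#'
#' Per frame, candidate chain pairs (all pairs, or only pairs whose
#' minimum heavy-atom distance is below `max_pair_dist`) are scored with
#' the reference rule; called pairs are resolved into a matching by
#' greedy selection on descending success fraction so that each chain
#' joins at most one dimer (a tetramer of two touching dimers therefore
#' reports as two pairs).
#'
#' @param traj assembly `ab_trajectory`.
#' @param refset an `ab_refset`.
#' @param n_draws,threshold,seed see [is_dimer()].
#' @param pairs `"proximal"` (default: pre-filter by `max_pair_dist`) or
#'   `"all"` (exhaustive chain pairs).
#' @param max_pair_dist proximity pre-filter, Angstrom.
#' @param contact_cutoff C-terminal contact cutoff, Angstrom.
#' @return An `ab_dimer_calls` object: list with `calls` (tibble
#'   `frame`, `chain_i`, `chain_j`, `contacts`, `energy`, `fraction`,
#'   `matched`) and `counts` (tibble `frame`, `n_dimers`). `tidy()`
#'   returns the counts time series.
#' @export
count_dimers <- function(traj, refset, n_draws = 3000L, threshold = 0.75,
                         seed = 1L, pairs = c("proximal", "all"),
                         max_pair_dist = 12, contact_cutoff = 6.0) {
  stopifnot(inherits(traj, "ab_trajectory"))
  pairs <- match.arg(pairs)
  chains <- sort(unique(traj$topology$chain))
  combos <- utils::combn(chains, 2)
  all_calls <- vector("list", n_frames(traj))
  counts <- integer(n_frames(traj))
  for (fi in seq_len(n_frames(traj))) {
    fr <- trajectory_frame(traj, fi)
    co <- coords_of(fr)
    rows <- list()
    for (k in seq_len(ncol(combos))) {
      ci <- combos[1, k]; cj <- combos[2, k]
      ii <- fr$chain == ci; jj <- fr$chain == cj
      if (pairs == "proximal") {
        dmin <- min(proxy_min_dist(co[ii, , drop = FALSE], co[jj, , drop = FALSE]))
        if (dmin >= max_pair_dist) next
      }
      ct <- cterm_contacts(fr, ci, cj, contact_cutoff)
      en <- interpeptide_energy(fr, ci, cj)
      call <- is_dimer(ct, en, refset, n_draws, threshold,
                       seed = seed + 7L * fi + k)
      rows[[length(rows) + 1]] <- tibble(frame = fi, chain_i = ci, chain_j = cj,
                                         contacts = ct, energy = en,
                                         fraction = attr(call, "fraction"),
                                         called = as.logical(call))
    }
    calls <- if (length(rows) > 0) bind_rows(rows) else
      tibble(frame = integer(), chain_i = character(), chain_j = character(),
             contacts = integer(), energy = numeric(), fraction = numeric(),
             called = logical())
    # greedy matching: best success fraction first, one chain one dimer
    calls$matched <- FALSE
    cand <- which(calls$called)
    cand <- cand[order(-calls$fraction[cand], calls$chain_i[cand], calls$chain_j[cand])]
    used <- character()
    for (r in cand) {
      if (calls$chain_i[r] %in% used || calls$chain_j[r] %in% used) next
      calls$matched[r] <- TRUE
      used <- c(used, calls$chain_i[r], calls$chain_j[r])
    }
    counts[fi] <- sum(calls$matched)
    all_calls[[fi]] <- calls
  }
  structure(list(calls = bind_rows(all_calls),
                 counts = tibble(frame = seq_along(counts), n_dimers = counts)),
            class = "ab_dimer_calls")
}

proxy_min_dist <- function(a, b) {
  # min distance between two coordinate sets without forming a huge matrix
  min(sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b), 0)))
}

#' @export
print.ab_dimer_calls <- function(x, ...) {
  cat(sprintf("<ab_dimer_calls: %d frames, mean %.2f dimers/frame>\n",
              nrow(x$counts), mean(x$counts$n_dimers)))
  invisible(x)
}

#' @rdname count_dimers
#' @param x an `ab_dimer_calls`.
#' @param ... unused.
#' @export
tidy.ab_dimer_calls <- function(x, ...) x$counts

#' @rdname count_dimers
#' @export
glance.ab_dimer_calls <- function(x, ...) {
  tibble(n_frames = nrow(x$counts), mean_dimers = mean(x$counts$n_dimers),
         max_dimers = max(x$counts$n_dimers))
}

#' PCA clustering of dimer configurations
#'
#' Superposes every configuration onto the first, projects the flattened
#' coordinates onto the first two principal components, groups them by
#' k-means (seeded initialisation), and reports the medoid of each
#' cluster (the configuration nearest its cluster mean in PC space).
#'
#' @param configs a list of congruent coordinate matrices (n_atoms x 3)
#'   or atom tables, or a two-chain `ab_trajectory`.
#' @param n_clusters number of groups (5 or 6 in the reference analysis).
#' @param seed k-means seed.
#' @return An `ab_dimer_clusters` object: `assignments` (tibble `config`,
#'   `cluster`, `pc1`, `pc2`), `medoids` (config index per cluster),
#'   `explained_variance` (per-component fractions, non-increasing).
#' @export
pca_cluster_dimers <- function(configs, n_clusters = 5L, seed = 1L) {
  if (inherits(configs, "ab_trajectory")) {
    configs <- lapply(seq_len(n_frames(configs)), function(i)
      coords_of(trajectory_frame(configs, i)))
  }
  configs <- lapply(configs, function(cf) {
    if (is.data.frame(cf)) coords_of(check_atom_table(cf)) else as.matrix(cf)
  })
  n <- length(configs)
  if (n < n_clusters) abort("need at least as many configurations as clusters")
  sizes <- vapply(configs, nrow, integer(1))
  if (length(unique(sizes)) != 1) abort("configurations must be congruent")
  ref <- configs[[1]]
  aligned <- lapply(configs, function(m) kabsch_fit(m, ref))
  X <- do.call(rbind, lapply(aligned, as.vector))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  if (ncol(scores) == 1) scores <- cbind(scores, 0)
  km <- withr::with_seed(seed, stats::kmeans(scores, centers = n_clusters,
                                             nstart = 10))
  medoids <- vapply(seq_len(n_clusters), function(k) {
    idx <- which(km$cluster == k)
    d2 <- rowSums(sweep(scores[idx, , drop = FALSE], 2, km$centers[k, ])^2)
    idx[which.min(d2)]
  }, integer(1))
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    assignments = tibble(config = seq_len(n), cluster = km$cluster,
                         pc1 = scores[, 1], pc2 = scores[, 2]),
    medoids = medoids,
    explained_variance = ev
  ), class = "ab_dimer_clusters")
}

#' @export
print.ab_dimer_clusters <- function(x, ...) {
  cat(sprintf("<ab_dimer_clusters: %d configs in %d clusters, PC1+2 variance %.1f%%>\n",
              nrow(x$assignments), length(x$medoids),
              100 * sum(x$explained_variance[1:2])))
  invisible(x)
}

#' @rdname pca_cluster_dimers
#' @param x an `ab_dimer_clusters`.
#' @param ... unused.
#' @export
tidy.ab_dimer_clusters <- function(x, ...) x$assignments
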