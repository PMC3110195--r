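# small reference set shared across tests
fixture_refset <- function() {
  if (is.null(the$refset)) {
    ens <- make_isolated_dimer_ensemble(fixture_dimer(), 300,
                                        noise_spec(sigma = 0.8, seed = 13))
    the$refset <- build_reference_dataset(ens, n_samples = 300, seed = 13)
  }
  the$refset
}

# a refset with an exact per-draw success probability for given metrics
synthetic_refset <- function(n_lose, n_win, pair_contacts = 10,
                             pair_energy = -5) {
  rs <- tibble::tibble(
    contacts = c(rep(0L, n_lose), rep(pair_contacts + 10L, n_win)),
    energy = c(rep(pair_energy + 5, n_lose), rep(pair_energy - 5, n_win))
  )
  class(rs) <- c("ab_refset", class(rs))
  rs
}

test_that("the reference dataset records one contact/energy pair per sampled frame", {
  rs <- fixture_refset()
  expect_equal(nrow(rs), 300)
  expect_true(all(is.finite(rs$energy)))
  expect_true(all(rs$contacts >= 0))

  # subsampling is seeded and sized
  ens <- make_isolated_dimer_ensemble(fixture_dimer(), 50,
                                      noise_spec(sigma = 0.5, seed = 2))
  rs1 <- build_reference_dataset(ens, n_samples = 20, seed = 5)
  rs2 <- build_reference_dataset(ens, n_samples = 20, seed = 5)
  expect_equal(nrow(rs1), 20)
  expect_equal(rs1, rs2)
})

test_that("contacts are counted only between C-terminal residues", {
  # two sidechain centres within contact range but in the N-terminal region
  nterm <- dplyr::bind_rows(
    toy_atoms(c(0, 0, 0), elety = "CB", chain = "A", resno = 19, resid = "PHE"),
    toy_atoms(c(4, 0, 0), elety = "CB", chain = "B", resno = 20, resid = "PHE")
  )
  expect_equal(globulomeR:::cterm_contacts(nterm, "A", "B"), 0)
  cterm <- dplyr::bind_rows(
    toy_atoms(c(0, 0, 0), elety = "CB", chain = "A", resno = 35, resid = "MET"),
    toy_atoms(c(4, 0, 0), elety = "CB", chain = "B", resno = 36, resid = "VAL")
  )
  expect_equal(globulomeR:::cterm_contacts(cterm, "A", "B"), 1)
})

test_that("the 75 percent rule behaves as the exact binomial predicts", {
  rs <- fixture_refset()
  # contacts beyond every reference: always a dimer
  expect_true(is_dimer(max(rs$contacts) + 5, 1e9, rs))
  # dominated pair: never a dimer
  expect_false(is_dimer(0, max(rs$energy) + 1, rs))

  # exactly 70 percent of references lose: called at 0.65, not at 0.75
  rs70 <- synthetic_refset(n_lose = 70, n_win = 30)
  expect_false(is_dimer(10, -5, rs70, n_draws = 3000, threshold = 0.75, seed = 1))
  expect_true(is_dimer(10, -5, rs70, n_draws = 3000, threshold = 0.65, seed = 1))
  # exact binomial: P(success fraction > 0.75 | p = 0.7) is negligible
  expect_lt(globulomeR:::dimer_call_probability(10, -5, rs70, 3000, 0.75)$p_called,
            1e-6)
  expect_gt(globulomeR:::dimer_call_probability(10, -5, rs70, 3000, 0.65)$p_called,
            1 - 1e-6)
})

test_that("the dimer call is monotone in contacts and energy", {
  rs <- fixture_refset()
  fr <- function(ct, en) attr(is_dimer(ct, en, rs, n_draws = 500, seed = 3),
                              "fraction")
  base <- fr(5, 500)
  expect_gte(fr(8, 500), base)
  expect_gte(fr(5, 100), base)
  expect_gte(fr(8, 100), fr(8, 500))
})

test_that("empirical call rates track the exact binomial within 3 standard errors", {
  rs73 <- synthetic_refset(n_lose = 73, n_win = 27)
  n_draws <- 300
  p_called <- globulomeR:::dimer_call_probability(10, -5, rs73, n_draws, 0.75)$p_called
  calls <- vapply(1:200, function(s)
    as.logical(is_dimer(10, -5, rs73, n_draws = n_draws, threshold = 0.75,
                        seed = s)), logical(1))
  se <- sqrt(p_called * (1 - p_called) / 200)
  expect_lt(abs(mean(calls) - p_called), 3 * se)
})

test_that("dimer counting matches constructed geometries and the greedy matching", {
  rs <- fixture_refset()
  dm <- fixture_dimer()
  # 12 chains as 6 well-separated native pairs
  six <- dplyr::bind_rows(lapply(0:5, function(k) {
    at <- dm$atoms
    at$chain <- LETTERS[2 * k + match(at$chain, c("A", "B"))]
    at$x <- at$x + 60 * k
    at
  }))
  calls <- count_dimers(new_trajectory(six), rs, n_draws = 300, seed = 2)
  expect_equal(calls$counts$n_dimers, 6)
  called_pairs <- calls$calls[calls$calls$matched, c("chain_i", "chain_j")]
  expect_setequal(paste(called_pairs$chain_i, called_pairs$chain_j),
                  paste(LETTERS[seq(1, 11, 2)], LETTERS[seq(2, 12, 2)]))

  # all chains mutually distant: nothing to call
  spread <- dm$atoms[dm$atoms$chain == "A", ]
  lonely <- dplyr::bind_rows(lapply(0:3, function(k) {
    at <- spread; at$chain <- LETTERS[k + 1]; at$x <- at$x + 100 * k; at
  }))
  expect_equal(count_dimers(new_trajectory(lonely), rs, n_draws = 300,
                            seed = 2)$counts$n_dimers, 0)

  # a tetramer of two touching dimers still reports as two pairs
  tet <- dplyr::bind_rows(
    dm$atoms,
    {
      at <- dm$atoms
      at$chain <- c(A = "C", B = "D")[at$chain]
      at$x <- at$x + 11
      at
    }
  )
  tcalls <- count_dimers(new_trajectory(tet), rs, n_draws = 300, seed = 2)
  expect_equal(tcalls$counts$n_dimers, 2)
  matched <- tcalls$calls[tcalls$calls$matched, ]
  expect_setequal(paste(matched$chain_i, matched$chain_j), c("A B", "C D"))
})

test_that("dimer counting is stable under chain relabeling", {
  rs <- fixture_refset()
  dm <- fixture_dimer()
  pairx <- dplyr::bind_rows(dm$atoms, {
    at <- dm$atoms
    at$chain <- c(A = "C", B = "D")[at$chain]
    at$x <- at$x + 60
    at
  })
  relab <- pairx
  relab$chain <- c(A = "D", B = "C", C = "B", D = "A")[relab$chain]
  n1 <- count_dimers(new_trajectory(pairx), rs, n_draws = 300, seed = 4)
  n2 <- count_dimers(new_trajectory(relab), rs, n_draws = 300, seed = 4)
  expect_equal(n1$counts$n_dimers, n2$counts$n_dimers)
})

test_that("PCA clustering recovers planted dimer modes and orders variance", {
  dm <- fixture_dimer()
  base <- as.matrix(dm$atoms[, c("x", "y", "z")])
  modes <- list(
    base,
    { m <- base; m[dm$atoms$chain == "B", 1] <- m[dm$atoms$chain == "B", 1] + 6; m },
    { m <- base; m[dm$atoms$chain == "B", 3] <- m[dm$atoms$chain == "B", 3] + 9; m }
  )
  set.seed(31)
  labels <- rep(1:3, each = 20)
  configs <- lapply(labels, function(k) modes[[k]] + rnorm(length(base), sd = 0.15))
  cl <- pca_cluster_dimers(configs, n_clusters = 3, seed = 7)

  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(labels, cl$assignments$cluster)
  expect_gt(ari, 0.9)
  # eigenvalue ordering: explained variance is non-increasing
  expect_true(all(diff(cl$explained_variance) <= 1e-12))
  # medoids carry the label of their own cluster
  expect_equal(cl$assignments$cluster[cl$medoids], seq_len(3))

  same <- pca_cluster_dimers(rep(list(base), 8), n_clusters = 1, seed = 1)
  expect_equal(var(same$assignments$pc1), 0, tolerance = 1e-12)
})
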