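poisson <- substitution_model("Poisson")
lg <- substitution_model("LG")

aln1 <- function(chars, groups = NULL) {
  if (is.null(groups)) groups <- setNames(rep("FRL", length(chars)),
                                          names(chars))
  grouped_alignment(chars, groups)
}

test_that("transition matrices are stochastic and satisfy the semigroup laws", {
  for (m in list(poisson, lg)) {
    set.seed(13)
    for (t in c(0, 1e-4, 0.05, 0.7, 4)) {
      P <- transition_matrix(m, t)
      expect_true(all(P >= 0))
      expect_equal(unname(rowSums(P)), rep(1, 20), tolerance = 1e-10)
    }
    # Chapman-Kolmogorov on random branch-length pairs
    for (i in 1:5) {
      t1 <- runif(1, 0, 1); t2 <- runif(1, 0, 1)
      expect_equal(transition_matrix(m, t1) %*% transition_matrix(m, t2),
                   transition_matrix(m, t1 + t2), tolerance = 1e-9)
    }
    # detailed balance: pi_i P_ij = pi_j P_ji
    P <- transition_matrix(m, 0.3)
    F <- diag(m$pi) %*% P
    expect_equal(unname(F), unname(t(F)), tolerance = 1e-9)
    # unit expected rate
    Q <- m$Q
    expect_equal(-sum(m$pi * diag(Q)), 1, tolerance = 1e-12)
  }
  expect_error(transition_matrix(lg, -0.1), "non-negative")
})

test_that("degenerate trees give closed-form likelihoods", {
  # single leaf: log pi_A whatever the branch length
  tr <- ape::read.tree(text = "(a:0.37);")
  a <- aln1(c(a = "A"))
  expect_equal(site_likelihood(tr, a, lg, 1), log(lg$pi[["A"]]),
               tolerance = 1e-12)
  # two identical leaves joined by zero-length branches
  tr2 <- ape::read.tree(text = "(a:0,b:0);")
  a2 <- aln1(c(a = "A", b = "A"))
  expect_equal(site_likelihood(tr2, a2, lg, 1), log(lg$pi[["A"]]),
               tolerance = 1e-12)
})

test_that("pruning equals exhaustive state enumeration", {
  tr <- ape::read.tree(text = "((a:0.12,b:0.08):0.2,c:0.3);")
  set.seed(61)
  for (rep in 1:5) {
    chars <- setNames(sample(AA, 3, replace = TRUE), c("a", "b", "c"))
    oracle <- brute_site_likelihood(tr, chars, poisson)
    got <- site_likelihood(tr, aln1(chars), poisson, 1)
    expect_equal(got, oracle$loglik, tolerance = 1e-10)
  }
  # missing data: a gap leaf contributes nothing
  chars <- c(a = "A", b = "-", c = "W")
  expect_equal(site_likelihood(tr, aln1(chars), poisson, 1),
               brute_site_likelihood(tr, chars, poisson)$loglik,
               tolerance = 1e-10)
})

test_that("marginal posteriors equal brute-force Bayes enumeration", {
  tr <- ape::read.tree(text = "((a:0.15,b:0.25):0.1,c:0.4);")
  set.seed(71)
  for (m in list(poisson, lg)) {
    chars <- setNames(sample(AA, 3, replace = TRUE), c("a", "b", "c"))
    oracle <- brute_site_likelihood(tr, chars, m)
    for (node in c(4L, 5L)) {           # root and the (a,b) ancestor
      rec <- reconstruct_marginal(tr, aln1(chars), m, node)
      expect_equal(as.numeric(rec$posterior[1, ]),
                   oracle$posterior[node - 3L, ], tolerance = 1e-10)
      expect_equal(sum(rec$posterior[1, ]), 1, tolerance = 1e-9)
    }
  }
})

test_that("near-identical leaves reconstruct with near-certain posterior", {
  tr <- ape::read.tree(text = "((a:0.01,b:0.01):0.01,(c:0.01,d:0.01):0.01);")
  chars <- setNames(rep("W", 4), letters[1:4])
  rec <- reconstruct_marginal(tr, aln1(chars), poisson, 5L)
  expect_equal(rec$map_sequence, "W")
  expect_gt(rec$posterior[1, "W"], 0.99)
})

test_that("likelihood is invariant to re-rooting (pulley principle)", {
  skip_if_not_installed("phytools")
  set.seed(83)
  for (rep in 1:3) {
    tr <- ape::rtree(8)
    chars <- setNames(sample(AA, 8, replace = TRUE), tr$tip.label)
    a <- aln1(chars)
    base <- tree_loglik(tr, a, lg)
    for (node in sample(setdiff(2:14, 9), 3)) {
      blen <- tr$edge.length[tr$edge[, 2] == node]
      rr <- phytools::reroot(tr, node, position = 0.5 * blen)
      expect_equal(tree_loglik(rr, a, lg), base, tolerance = 1e-8)
    }
  }
})

test_that("total log-likelihood matches the phangorn oracle", {
  g <- generate_tree_and_sequences(n_leaves = 8, n_sites = 60, seed = 5)
  chm <- t(vapply(strsplit(g$aln$seq, ""), identity,
                  character(g$aln$n_columns)))
  fit <- phangorn::pml(g$tree, phangorn::phyDat(chm, type = "AA"),
                       model = "LG")
  expect_equal(tree_loglik(g$tree, g$aln, lg), fit$logLik,
               tolerance = 1e-6)
})

test_that("simulation respects the model: equilibrium and zero branches", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  sim <- simulate_evolution(tr, lg, 50, seed = 4)
  expect_equal(sim$leaf_seqs[["a"]], sim$root_sequence)
  expect_equal(sim$leaf_seqs[["c"]], sim$root_sequence)
  expect_error(simulate_evolution(tr, lg, 0), "n_sites")

  # root draws follow the equilibrium frequencies (3 sigma multinomial)
  tr1 <- ape::read.tree(text = "(a:0.1);")
  sim2 <- simulate_evolution(tr1, lg, 10000, seed = 9)
  obs <- table(factor(strsplit(sim2$root_sequence, "")[[1]], AA)) / 10000
  sigma <- sqrt(lg$pi * (1 - lg$pi) / 10000)
  expect_true(all(abs(obs - lg$pi) < 3 * sigma + 1e-9))
})

test_that("posterior mass at the truth grows as branches shrink", {
  # deterministic: concordant leaves at ever shorter branches
  tr_txt <- "((a:%1$g,b:%1$g):%1$g,(c:%1$g,d:%1$g):%1$g);"
  chars <- setNames(c("W", "W", "W", "A"), letters[1:4])
  mass <- vapply(c(0.5, 0.2, 0.05), function(bl) {
    tr <- ape::read.tree(text = sprintf(tr_txt, bl))
    reconstruct_marginal(tr, aln1(chars), lg, 5L)$posterior[1, "W"]
  }, numeric(1L))
  expect_true(all(diff(mass) > 0))

  # simulated: mean posterior at the true root state, 3-point sweep
  means <- vapply(c(1, 0.4, 0.1), function(scale) {
    g <- generate_tree_and_sequences(n_leaves = 8, n_sites = 150,
                                     branch_range = scale * c(0.05, 0.3),
                                     seed = 77)
    rec <- reconstruct_marginal(g$tree, g$aln, lg, 9L)
    truth <- match(strsplit(g$root_sequence, "")[[1]], AA)
    mean(rec$posterior[cbind(seq_along(truth), truth)])
  }, numeric(1L))
  expect_true(all(diff(means) > 0))
})

test_that("the FRL ancestor node is found by label, and errors are clear", {
  g <- generate_tree_and_sequences(n_leaves = 6, n_sites = 10, seed = 2)
  # relabel half the leaves VL
  grp <- g$aln$group
  grp[1:2] <- "VL"
  aln <- grouped_alignment(g$aln$seq, grp)
  node <- mrca_of_group(g$tree, aln, "FRL")
  expect_true(node > 6)
  expect_error(reconstruct_marginal(g$tree, aln, lg, node = 3L),
               "not an internal node")
  bad <- grouped_alignment(setNames(g$aln$seq, paste0("z", 1:6)),
                           setNames(grp, paste0("z", 1:6)))
  expect_error(tree_loglik(g$tree, bad, lg), "mismatch")
})

test_that("discrete gamma rates have unit mean and spread with shape", {
  r4 <- discrete_gamma_rates(0.5, 4)
  expect_equal(mean(r4), 1, tolerance = 1e-12)
  expect_true(all(diff(r4) > 0))
  expect_lt(diff(range(discrete_gamma_rates(20, 4))),
            diff(range(r4)))
  # gamma-aware likelihood still matches enumeration averaged over rates
  tr <- ape::read.tree(text = "((a:0.12,b:0.08):0.2,c:0.3);")
  chars <- c(a = "A", b = "R", c = "A")
  mg <- substitution_model("Poisson", gamma_shape = 0.8,
                           n_rate_categories = 3L)
  rates <- discrete_gamma_rates(0.8, 3)
  per_rate <- vapply(rates, function(r) {
    trs <- tr; trs$edge.length <- tr$edge.length * r
    brute_site_likelihood(trs, chars, poisson)$loglik
  }, numeric(1L))
  oracle <- log(mean(exp(per_rate)))
  expect_equal(site_likelihood(tr, aln1(chars), mg, 1), oracle,
               tolerance = 1e-10)
})
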