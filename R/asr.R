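# Marginal ancestral sequence reconstruction on a fixed rooted tree under
# an empirical amino-acid substitution model, via the pruning algorithm.

# fetch an empirical model's exchangeabilities (lower triangle, PAML
# order) and equilibrium frequencies from phangorn's model collection
.empirical_aa_model <- function(name) {
  Q <- NULL; bf <- NULL
  fun <- get("getModelAA", envir = asNamespace("phangorn"))
  fun(name, bf = TRUE, Q = TRUE)
  list(rates = Q, freq = bf)
}

#' Build an amino-acid substitution model
#'
#' Constructs a reversible 20-state model from symmetric exchangeabilities
#' `s_ij` and equilibrium frequencies `pi`: `q_ij = s_ij * pi_j`, rows
#' summing to zero, scaled to one expected substitution per site. The
#' transition matrix `P(t) = exp(Qt)` is obtained by symmetric
#' eigendecomposition of `diag(sqrt(pi)) Q diag(1/sqrt(pi))`.
#'
#' `"Poisson"` (equal exchangeabilities, uniform frequencies) is useful for
#' closed-form oracles; the empirical models (`"LG"`, `"WAG"`, `"JTT"`) are
#' taken from the collection shipped with phangorn.
#'
#' @param name Model name: `"LG"` (default), `"WAG"`, `"JTT"`, or
#'   `"Poisson"`.
#' @param frequencies Optional length-20 equilibrium frequency vector (PAML
#'   amino-acid order), overriding the model's own.
#' @param gamma_shape Optional shape of a discrete-gamma distribution of
#'   among-site rate variation; `NULL` (default) disables rate variation.
#' @param n_rate_categories Number of equal-probability gamma categories
#'   (default 4).
#' @return An object of class `substitution_model`.
#' @examples
#' m <- substitution_model("Poisson")
#' rowSums(transition_matrix(m, 0.5))
#' @export
substitution_model <- function(name = c("LG", "WAG", "JTT", "Poisson"),
                               frequencies = NULL,
                               gamma_shape = NULL,
                               n_rate_categories = 4L) {
  name <- match.arg(name)
  if (name == "Poisson") {
    S <- matrix(1, 20, 20); diag(S) <- 0
    pi <- rep(1 / 20, 20)
  } else {
    em <- .empirical_aa_model(name)
    S <- matrix(0, 20, 20)
    S[lower.tri(S)] <- em$rates
    S <- S + t(S)
    pi <- em$freq
  }
  if (!is.null(frequencies)) {
    stopifnot(length(frequencies) == 20, all(frequencies >= 0))
    pi <- frequencies / sum(frequencies)
  }
  dimnames(S) <- list(AA20, AA20)
  names(pi) <- AA20
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))           # expected rate before scaling
  Q <- Q / mu
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  B <- (B + t(B)) / 2                # enforce exact symmetry
  eig <- eigen(B, symmetric = TRUE)
  V <- diag(1 / sp) %*% eig$vectors
  Vinv <- t(eig$vectors) %*% diag(sp)
  if (!is.null(gamma_shape) && (!is.finite(gamma_shape) || gamma_shape <= 0))
    stop("gamma_shape must be a positive real")
  structure(list(name = name, S = S, pi = pi, Q = Q,
                 eigenvalues = eig$values, V = V, Vinv = Vinv,
                 gamma_shape = gamma_shape,
                 n_rate_categories = as.integer(n_rate_categories)),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("Amino-acid substitution model:", x$name)
  if (!is.null(x$gamma_shape))
    cat(sprintf(" +G(shape=%.3g, %d categories)",
                x$gamma_shape, x$n_rate_categories))
  cat("\n")
  invisible(x)
}

#' Transition probability matrix P(t)
#'
#' @param model A [substitution_model()].
#' @param t Branch length (expected substitutions per site), `>= 0`.
#' @param rate Rate multiplier (used for gamma categories).
#' @return Stochastic 20 x 20 matrix.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  if (t < 0) stop("branch length must be non-negative")
  P <- model$V %*% diag(exp(model$eigenvalues * t * rate)) %*% model$Vinv
  P[P < 0] <- 0                      # clip eigen round-off
  P <- P / rowSums(P)
  dimnames(P) <- list(AA20, AA20)
  P
}

#' Discrete-gamma rate categories
#'
#' Mean rates of `k` equal-probability categories of a Gamma(shape, shape)
#' distribution (mean 1), the standard discretization of among-site rate
#' variation.
#'
#' @param shape Gamma shape parameter (> 0).
#' @param k Number of categories.
#' @return Numeric vector of k rates with mean 1.
#' @export
discrete_gamma_rates <- function(shape, k = 4L) {
  if (is.null(shape)) return(1)
  q <- qgamma(seq(0, 1, length.out = k + 1L), shape = shape, rate = shape)
  # mean within each interval via the incomplete-gamma identity
  cdf1 <- pgamma(q, shape = shape + 1, rate = shape)
  r <- k * diff(cdf1)
  r / mean(r)
}

.model_rates <- function(model) {
  if (is.null(model$gamma_shape)) return(1)
  discrete_gamma_rates(model$gamma_shape, model$n_rate_categories)
}

# encode a character matrix of residues (rows = taxa) into a list of
# 20 x n_sites conditional-likelihood matrices; gaps and unknowns are
# missing data (all-ones vectors)
.leaf_conditionals <- function(chars) {
  n_sites <- ncol(chars)
  lapply(seq_len(nrow(chars)), function(i) {
    L <- matrix(1, 20, n_sites)
    idx <- match(chars[i, ], AA20)
    known <- which(!is.na(idx))
    L[, known] <- 0
    L[cbind(idx[known], known)] <- 1
    L
  })
}

.check_tree_alignment <- function(tree, aln) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  missing_in_aln <- setdiff(tree$tip.label, names(aln$seq))
  missing_in_tree <- setdiff(names(aln$seq), tree$tip.label)
  if (length(missing_in_aln) || length(missing_in_tree))
    stop("leaf/alignment mismatch; in tree only: [",
         paste(missing_in_aln, collapse = ", "), "]; in alignment only: [",
         paste(missing_in_tree, collapse = ", "), "]")
  invisible(TRUE)
}

# post-order (pruning) pass for one rate category.
# returns list(cond = per-node 20 x n_sites conditionals, logscale = per-node
# per-site log scaling factors)
.prune <- function(tree, leaf_cond, model, rate) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  n_sites <- ncol(leaf_cond[[1L]])
  cond <- vector("list", n_node)
  logscale <- matrix(0, n_node, n_sites)
  cond[seq_len(n_tip)] <- leaf_cond
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  elen <- ape::reorder.phylo(tree, "postorder")$edge.length
  Pcache <- new.env(hash = TRUE)
  for (k in seq_len(nrow(edge))) {
    parent <- edge[k, 1L]; child <- edge[k, 2L]
    key <- format(elen[k], digits = 17)
    P <- Pcache[[key]]
    if (is.null(P)) {
      P <- transition_matrix(model, elen[k], rate)
      Pcache[[key]] <- P
    }
    contrib <- P %*% cond[[child]]
    if (is.null(cond[[parent]])) {
      cond[[parent]] <- contrib
      logscale[parent, ] <- logscale[child, ]
    } else {
      cond[[parent]] <- cond[[parent]] * contrib
      logscale[parent, ] <- logscale[parent, ] + logscale[child, ]
    }
    mx <- apply(cond[[parent]], 2, max)
    mx[mx == 0] <- 1
    cond[[parent]] <- sweep(cond[[parent]], 2, mx, "/")
    logscale[parent, ] <- logscale[parent, ] + log(mx)
  }
  list(cond = cond, logscale = logscale)
}

.aln_char_matrix <- function(aln) {
  mat <- do.call(rbind, strsplit(aln$seq, "", fixed = TRUE))
  rownames(mat) <- names(aln$seq)
  mat
}

# per-site log-likelihoods for all sites, averaged over rate categories
.site_logliks <- function(tree, aln, model) {
  .check_tree_alignment(tree, aln)
  mat <- .aln_char_matrix(aln)[tree$tip.label, , drop = FALSE]
  leaf_cond <- .leaf_conditionals(mat)
  root <- length(tree$tip.label) + 1L
  rates <- .model_rates(model)
  per_cat <- sapply(rates, function(r) {
    pr <- .prune(tree, leaf_cond, model, r)
    log(colSums(model$pi * pr$cond[[root]])) + pr$logscale[root, ]
  })
  per_cat <- matrix(per_cat, ncol = length(rates))
  # log mean over equal-weight categories, stably
  m <- apply(per_cat, 1, max)
  m + log(rowMeans(exp(per_cat - m)))
}

#' Log-likelihood of a single alignment site
#'
#' Felsenstein pruning on the rooted tree; gaps and `X` are missing data.
#'
#' @param tree A rooted `phylo` tree whose tips match the alignment ids.
#' @param aln A [grouped_alignment()].
#' @param model A [substitution_model()].
#' @param site 1-based site (column) index.
#' @return Log-likelihood (averaged over gamma categories when enabled).
#' @export
site_likelihood <- function(tree, aln, model, site) {
  stopifnot(site >= 1, site <= aln$n_columns)
  .site_logliks(tree, aln, model)[site]
}

#' Total log-likelihood of an alignment on a tree
#'
#' @inheritParams site_likelihood
#' @return Sum of per-site log-likelihoods.
#' @export
tree_loglik <- function(tree, aln, model) {
  sum(.site_logliks(tree, aln, model))
}

#' Most recent common ancestor of a labelled group
#'
#' Finds the internal node subtending all leaves carrying a given group
#' label — e.g. the FRL (FaRLiP) ancestor as the MRCA of all FRL-labelled
#' sequences.
#'
#' @param tree Rooted `phylo`.
#' @param aln A [grouped_alignment()] supplying the labels.
#' @param group Group label, default `"FRL"`.
#' @return Internal node number.
#' @export
mrca_of_group <- function(tree, aln, group = "FRL") {
  tips <- names(aln$seq)[aln$group == group]
  tips <- intersect(tips, tree$tip.label)
  if (length(tips) == 0L) stop("no leaves labelled ", group, " in the tree")
  if (length(tips) == 1L) stop("group ", group, " has a single leaf; ",
                               "its ancestor is its parent edge, not a MRCA")
  ape::getMRCA(tree, tips)
}

# resolve a node specifier (number or label) to an internal node number
.resolve_node <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  if (is.numeric(node)) {
    node <- as.integer(node)
    if (node <= n_tip || node > n_node)
      stop("node ", node, " is not an internal node (valid: ",
           n_tip + 1L, "..", n_node, ")")
    return(node)
  }
  labs <- tree$node.label
  if (is.null(labs))
    stop("tree has no node labels; available internal nodes: ",
         n_tip + 1L, "..", n_node)
  hit <- which(labs == node)
  if (length(hit) != 1L)
    stop("node label '", node, "' not found or ambiguous; available: ",
         paste(labs[labs != ""], collapse = ", "))
  n_tip + hit
}

#' Marginal ancestral sequence reconstruction at an internal node
#'
#' Computes, for every alignment site, the posterior distribution over the
#' 20 amino acids at the chosen internal node, conditional on all leaf
#' data, by combining the post-order (pruning) conditionals below the node
#' with a pre-order "outside" pass through the rest of the tree. The MAP
#' sequence takes the highest-posterior state at each site, ties broken
#' alphabetically.
#'
#' @inheritParams site_likelihood
#' @param node Internal node number, node label, or `"mrca_frl"` for the
#'   MRCA of the FRL-labelled leaves.
#' @return Object of class `ancestral_reconstruction`: `node`,
#'   `posterior` (n_sites x 20 matrix, rows summing to 1), `map_sequence`,
#'   `site_count`.
#' @export
reconstruct_marginal <- function(tree, aln, model, node = "mrca_frl") {
  .check_tree_alignment(tree, aln)
  if (identical(node, "mrca_frl")) node <- mrca_of_group(tree, aln, "FRL")
  node <- .resolve_node(tree, node)
  mat <- .aln_char_matrix(aln)[tree$tip.label, , drop = FALSE]
  leaf_cond <- .leaf_conditionals(mat)
  n_tip <- length(tree$tip.label)
  n_sites <- ncol(leaf_cond[[1L]])
  root <- n_tip + 1L
  rates <- .model_rates(model)

  joint <- matrix(0, n_sites, 20)       # sum over categories of joint
  sitelik <- numeric(n_sites)           # sum over categories of site lik
  # per-site normalization is by the same max-scaled quantities across
  # categories, so accumulate on a common log scale per category
  logZ <- NULL
  per_cat_joint <- vector("list", length(rates))
  per_cat_ll <- matrix(0, n_sites, length(rates))
  for (ci in seq_along(rates)) {
    r <- rates[ci]
    pr <- .prune(tree, leaf_cond, model, r)
    # outside pass: out[[v]] is 20 x n_sites, with its own log scale
    edge <- tree$edge
    children <- split(seq_len(nrow(edge)), edge[, 1L])
    out <- vector("list", n_tip + tree$Nnode)
    out_scale <- matrix(0, n_tip + tree$Nnode, n_sites)
    out[[root]] <- matrix(model$pi, 20, n_sites)
    # pre-order: parents before children
    preorder <- rev(ape::reorder.phylo(tree, "postorder")$edge[, 2L])
    preorder <- c(root, preorder)
    elen_of <- setNames(tree$edge.length, edge[, 2L])
    for (v in preorder) {
      kids <- children[[as.character(v)]]
      if (is.null(kids)) next
      for (k in kids) {
        child <- edge[k, 2L]
        sib_prod <- matrix(1, 20, n_sites)
        sib_scale <- rep(0, n_sites)
        for (k2 in setdiff(kids, k)) {
          sib <- edge[k2, 2L]
          P2 <- transition_matrix(model, elen_of[[as.character(sib)]], r)
          sib_prod <- sib_prod * (P2 %*% pr$cond[[sib]])
          sib_scale <- sib_scale + pr$logscale[sib, ]
        }
        up <- out[[v]] * sib_prod
        P <- transition_matrix(model, elen_of[[as.character(child)]], r)
        out[[child]] <- t(P) %*% up
        out_scale[child, ] <- out_scale[v, ] + sib_scale
        mx <- apply(out[[child]], 2, max)
        mx[mx == 0] <- 1
        out[[child]] <- sweep(out[[child]], 2, mx, "/")
        out_scale[child, ] <- out_scale[child, ] + log(mx)
      }
    }
    jo <- t(pr$cond[[node]] * out[[node]])   # n_sites x 20
    jsc <- pr$logscale[node, ] + out_scale[node, ]
    per_cat_joint[[ci]] <- list(jo = jo, jsc = jsc)
    per_cat_ll[, ci] <- log(rowSums(jo)) + jsc
  }
  # combine categories: posterior = sum_c jo_c*exp(jsc_c) / sum_c lik_c
  m <- apply(per_cat_ll, 1, max)
  post <- matrix(0, n_sites, 20)
  for (ci in seq_along(rates)) {
    w <- exp(per_cat_joint[[ci]]$jsc - m)
    post <- post + per_cat_joint[[ci]]$jo * w
  }
  post <- post / rowSums(post)
  colnames(post) <- AA20
  # MAP with alphabetical tie-break
  map_seq <- apply(post, 1, function(p) {
    mx <- max(p)
    cand <- AA20[abs(p - mx) < 1e-12]
    sort(cand)[1L]
  })
  structure(list(node = node, posterior = post,
                 map_sequence = paste(map_seq, collapse = ""),
                 site_count = n_sites),
            class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat("Marginal ancestral reconstruction at node", x$node, "over",
      x$site_count, "sites\n")
  cat("MAP sequence:",
      if (nchar(x$map_sequence) > 60)
        paste0(substr(x$map_sequence, 1, 60), "...")
      else x$map_sequence, "\n")
  invisible(x)
}

#' Write an ancestral reconstruction to disk
#'
#' Writes the MAP sequence as FASTA and, optionally, the per-site posterior
#' distributions as TSV (site + 20 amino-acid columns).
#'
#' @param anc An `ancestral_reconstruction`.
#' @param fasta_path Output FASTA path.
#' @param posterior_path Optional TSV path.
#' @param name Sequence name in the FASTA record.
#' @export
write_reconstruction <- function(anc, fasta_path, posterior_path = NULL,
                                 name = "ancestor") {
  write_alignment(setNames(anc$map_sequence, name), fasta_path)
  if (!is.null(posterior_path)) {
    tab <- data.frame(site = seq_len(anc$site_count),
                      round(anc$posterior, 6))
    write.table(tab, posterior_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Simulate sequence evolution down a tree
#'
#' Draws the root sequence from the model's equilibrium frequencies and
#' each descendant state from `P(branch length)`; with a gamma model each
#' site first draws a rate category. Deterministic under a fixed seed.
#'
#' @inheritParams site_likelihood
#' @param n_sites Number of sites (>= 1).
#' @param seed Optional RNG seed.
#' @return List with `leaf_seqs` and `node_seqs` (named character vectors;
#'   internal nodes are named `node<N>`), `root_sequence`, and `site_rates`.
#' @export
simulate_evolution <- function(tree, model, n_sites, seed = NULL) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!is.null(seed)) set.seed(seed)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  rates <- .model_rates(model)
  site_rate <- sample(rates, n_sites, replace = TRUE)
  states <- matrix(NA_integer_, n_node, n_sites)
  states[root, ] <- sample.int(20, n_sites, replace = TRUE, prob = model$pi)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  elen <- ape::reorder.phylo(tree, "postorder")$edge.length
  for (k in rev(seq_len(nrow(edge)))) {     # preorder
    parent <- edge[k, 1L]; child <- edge[k, 2L]
    for (r in unique(site_rate)) {
      sel <- which(site_rate == r)
      P <- transition_matrix(model, elen[k], r)
      ps <- states[parent, sel]
      states[child, sel] <- vapply(ps, function(s)
        sample.int(20, 1L, prob = P[s, ]), integer(1L))
    }
  }
  to_seq <- function(i) paste(AA20[states[i, ]], collapse = "")
  leaf_seqs <- setNames(vapply(seq_len(n_tip), to_seq, character(1L)),
                        tree$tip.label)
  internal <- (n_tip + 1L):n_node
  node_seqs <- setNames(vapply(internal, to_seq, character(1L)),
                        paste0("node", internal))
  list(leaf_seqs = leaf_seqs, node_seqs = node_seqs,
       root_sequence = node_seqs[[1L]], site_rates = site_rate)
}
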