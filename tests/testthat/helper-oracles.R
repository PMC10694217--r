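# Independent oracles and small fixture builders used across the suite.

AA <- frlpsi:::AA20

random_seq <- function(n, freqs = NULL) {
  paste(sample(AA, n, replace = TRUE, prob = freqs), collapse = "")
}

# --- brute-force tree likelihood / posterior by state enumeration --------

# enumerate all internal-node state assignments of a small rooted tree and
# sum the joint probability; leaf_chars is a named character vector of
# single residues ("-" = missing)
brute_site_likelihood <- function(tree, leaf_chars, model) {
  n_tip <- length(tree$tip.label)
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  leaf_idx <- match(leaf_chars[tree$tip.label], AA)
  Pm <- lapply(seq_len(nrow(tree$edge)), function(k)
    transition_matrix(model, tree$edge.length[k]))
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  total <- 0
  joint <- matrix(0, length(internal), 20)
  for (g in seq_len(nrow(grid))) {
    st <- integer(n_tip + tree$Nnode)
    st[internal] <- grid[g, ]
    p <- model$pi[st[n_tip + 1L]]
    for (k in seq_len(nrow(tree$edge))) {
      par <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
      if (ch <= n_tip) {
        if (is.na(leaf_idx[ch])) next            # missing leaf: sum to 1
        p <- p * Pm[[k]][st[par], leaf_idx[ch]]
      } else {
        p <- p * Pm[[k]][st[par], st[ch]]
      }
    }
    total <- total + p
    for (i in seq_along(internal))
      joint[i, grid[g, i]] <- joint[i, grid[g, i]] + p
  }
  list(loglik = unname(log(total)),
       posterior = unname(joint / total))        # rows: internal nodes
}

# --- quaternion (Horn) superposition oracle ------------------------------

quaternion_superpose <- function(ref, mobile) {
  A <- sweep(as.matrix(ref), 2, colMeans(ref))
  B <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  S <- t(B) %*% A
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1],
    S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[1,3]+S[3,1],
    S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1], S[1,3]+S[3,1], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  ev <- eigen(K, symmetric = TRUE)
  lam <- ev$values[1L]
  q <- ev$vectors[, 1L]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    w^2+x^2-y^2-z^2, 2*(x*y-w*z), 2*(x*z+w*y),
    2*(x*y+w*z), w^2-x^2+y^2-z^2, 2*(y*z-w*x),
    2*(x*z-w*y), 2*(y*z+w*x), w^2-x^2-y^2+z^2), 3, 3, byrow = TRUE)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  list(rotation = R, rmsd = sqrt(max(0, msd)))
}

# --- connected-components clustering oracle ------------------------------

connected_components <- function(positions, cutoff) {
  n <- nrow(positions)
  d <- as.matrix(dist(positions))
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(d[v, ] <= cutoff & comp == 0L))
    }
  }
  comp
}

# partitions equal up to label renaming
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# --- structure fixtures --------------------------------------------------

# CA-trace structure for a one-letter sequence, author numbering from
# `start`
make_chain_structure <- function(seq1, chain = "A", start = 1L,
                                 id = "synthetic_chain") {
  res3 <- bio3d::aa123(strsplit(seq1, "")[[1L]])
  n <- length(res3)
  at <- data.frame(chain = chain, resno = start + seq_len(n) - 1L,
                   insert = "", resid = res3, elety = "CA",
                   x = 3.8 * seq_len(n), y = rep(c(0, 1), length.out = n),
                   z = 0, het = FALSE, stringsAsFactors = FALSE)
  frlpsi:::.make_structure(at, id)
}

# apply a rigid motion to every atom of a structure_model
transform_structure <- function(struct, R, t) {
  xyz <- as.matrix(struct$atoms[, c("x", "y", "z")])
  struct$atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2, t, "+")
  struct
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w^2+x^2-y^2-z^2, 2*(x*y-w*z), 2*(x*z+w*y),
    2*(x*y+w*z), w^2-x^2+y^2-z^2, 2*(y*z-w*x),
    2*(x*z-w*y), 2*(y*z+w*x), w^2-x^2-y^2+z^2), 3, 3, byrow = TRUE)
}
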