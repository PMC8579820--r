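# Small trees and independent oracles used across the suite.

cherry_tree <- function(t = 1) {
  parse_newick(sprintf("(A:%g,B:%g);", t, t))
}

three_tip_tree <- function() {
  parse_newick("((A:1,B:1):1,C:2);")
}

# Random ultrametric tree whose node ages are exact 4-decimal numbers, so
# a 6-decimal Newick writer represents it losslessly.
round_aged_tree <- function(n, root_age = 10, seed = 1, digits = 4) {
  tr <- random_dated_tree(n, root_age, seed)
  ages <- round(tr$ages, digits)
  phy <- tr$phy
  phy$edge.length <- ages[phy$edge[, 1]] - ages[phy$edge[, 2]]
  dated_tree(phy)
}

balanced_tree <- function(n = 64) {
  phy <- ape::stree(n, type = "balanced")
  phy$edge.length <- rep(1, nrow(phy$edge))
  dated_tree(phy)
}

# Brute-force shared-path-length walker: path from the root to the MRCA of
# two tips, summing edge lengths explicitly. Independent of ape::vcv.
walk_shared_path <- function(tree, tip_a, tip_b) {
  phy <- tree$phy
  path_to_root <- function(node) {
    p <- integer(0)
    while (TRUE) {
      row <- which(phy$edge[, 2] == node)
      if (length(row) == 0) break
      p <- c(p, row)
      node <- phy$edge[row, 1]
    }
    p
  }
  ia <- match(tip_a, phy$tip.label); ib <- match(tip_b, phy$tip.label)
  ea <- path_to_root(ia); eb <- path_to_root(ib)
  shared <- intersect(ea, eb)
  sum(phy$edge.length[shared])
}

# Dense-algebra Gaussian log-density via explicit inverse and determinant.
dense_mvn_loglik <- function(x, mean, V) {
  n <- length(x)
  r <- x - mean
  -0.5 * (n * log(2 * pi) + log(det(V)) + as.numeric(t(r) %*% solve(V) %*% r))
}

# 2-D segment intersection test (proper crossings only), for the
# traitgram no-crossing property.
segments_cross <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  (o1 * o2 < 0) && (o3 * o4 < 0)
}

# Brute-force biogeography likelihood: explicit sum over every assignment
# of states to internal nodes, with per-branch transition probabilities
# from Matrix::expm (not the package's eigen propagator) and cladogenesis
# weights. Single-epoch only; independent of the pruning recursion.
enum_biogeo_loglik <- function(tree, tips, kind, params, epochs) {
  space <- build_state_space(epochs$areas)
  j <- if (grepl("\\+J$", kind)) unname(params["j"]) else 0
  Q <- anagenetic_rate_matrix(space, unname(params["d"]), unname(params["e"]),
                              epochs$multipliers[[1]])
  phy <- tree$phy
  n <- ape::Ntip(phy)
  m <- phy$Nnode
  nonnull <- which(vapply(space$states, length, integer(1)) > 0)
  tipst <- vapply(phy$tip.label, function(sp) {
    a <- match(tips[[sp]], space$areas)
    which(vapply(space$states, function(s)
      length(s) == length(a) && all(sort(s) == sort(a)), logical(1)))
  }, integer(1))
  Pedge <- lapply(seq_len(nrow(phy$edge)), function(i)
    as.matrix(Matrix::expm(Q * phy$edge.length[i])))
  clado <- lapply(seq_len(space$n_states), function(s)
    if (length(space$states[[s]]) == 0) NULL
    else cladogenesis_distribution(space, kind, s, j))
  grids <- rep(list(nonnull), m)
  asn <- as.matrix(expand.grid(grids))
  total <- 0
  child_rows <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  for (g in seq_len(nrow(asn))) {
    st <- c(tipst, asn[g, ])          # states indexed by ape node number
    term <- 1 / length(nonnull)       # flat root prior over non-null states
    for (v in (n + 1):(n + m)) {
      rows <- child_rows[[as.character(v)]]
      c1 <- phy$edge[rows[1], 2]; c2 <- phy$edge[rows[2], 2]
      tab <- clado[[st[v]]]
      s <- sum(tab$prob *
               Pedge[[rows[1]]][tab$left, st[c1]] *
               Pedge[[rows[2]]][tab$right, st[c2]])
      term <- term * s
      if (term == 0) break
    }
    total <- total + term
  }
  log(total)
}

# Single-epoch spec covering a tree, with all-ones multipliers.
flat_epochs <- function(tree, areas, oldest = NULL) {
  if (is.null(oldest)) oldest <- ceiling(tree$root_age + 1)
  epoch_spec(c(oldest, 0), areas = areas)
}
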