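# Propagator factory: repeated evaluation of expm(Q t) for many t.
# Diagonalises Q once and reuses the eigenbasis; falls back to
# Matrix::expm (scaling-and-squaring) when the eigenbasis is
# ill-conditioned. Tiny negative entries from roundoff are clamped.
make_propagator <- function(Q) {
  n <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  ok <- FALSE
  if (!is.null(eg)) {
    sv <- tryCatch(svd(eg$vectors, nu = 0, nv = 0)$d, error = function(e) NULL)
    if (!is.null(sv) && min(sv) / max(sv) > 1e-10) {
      Vinv <- solve(eg$vectors)
      ok <- TRUE
    }
  }
  if (ok) {
    V <- eg$vectors; lam <- eg$values
    function(t) {
      P <- Re(V %*% (exp(lam * t) * Vinv))
      P[P < 0] <- 0
      P
    }
  } else {
    function(t) {
      P <- as.matrix(Matrix::expm(Q * t))
      P[P < 0] <- 0
      P
    }
  }
}

# Parameter-independent part of the pruning machinery: state space, tip
# state indices, epoch-sliced branch segments (pre-sorted oldest first,
# per edge) and the j-independent cladogenesis event tables. Built once
# per data set and reused across all optimizer evaluations.
biogeo_skeleton <- function(tree, tips, kind, epochs, space = NULL) {
  stopifnot(inherits(tree, "dated_tree"), inherits(epochs, "epoch_spec"))
  if (!ape::is.binary(tree$phy))
    stop("cladogenesis models require a fully bifurcating tree")
  if (is.null(space))
    space <- build_state_space(epochs$areas)
  labs <- tree$phy$tip.label
  missing <- setdiff(labs, names(tips))
  if (length(missing))
    stop("no range coding for tip(s): ", paste(missing, collapse = ", "))
  tip_idx <- tip_state_indices(space, tips[labs])
  segs <- slice_branches(tree, epochs)
  n_edge <- nrow(tree$phy$edge)
  edge_segs <- lapply(seq_len(n_edge), function(i) {
    si <- segs[segs$edge == i, , drop = FALSE]
    si[order(-si$start), , drop = FALSE]
  })
  mult_keys <- vapply(epochs$multipliers, function(m)
    paste(m, collapse = ","), character(1))
  list(tree = tree, kind = kind, epochs = epochs, space = space,
       tip_idx = tip_idx, segs = segs, edge_segs = edge_segs,
       mult_keys = mult_keys,
       clado_skel = clado_skeleton(space, kind))
}

# Assemble the full pruning context shared by the likelihood, the
# marginals and stochastic mapping: per-edge transition matrices (product
# of per-epoch segment propagators, oldest segment first), tip state
# indices and cladogenesis tables.
biogeo_context <- function(tree, tips, kind, d, e, j, epochs, space = NULL,
                           skel = NULL) {
  if (is.null(skel))
    skel <- biogeo_skeleton(tree, tips, kind, epochs, space)
  space <- skel$space
  epochs <- skel$epochs
  Qs <- lapply(seq_len(epochs$n_epochs), function(k)
    anagenetic_rate_matrix(space, d, e, epochs$multipliers[[k]]))
  # identical multiplier matrices share one propagator
  props <- vector("list", epochs$n_epochs)
  for (k in seq_len(epochs$n_epochs)) {
    prev <- match(skel$mult_keys[k], skel$mult_keys[seq_len(k - 1L)])
    props[[k]] <- if (!is.na(prev) && length(prev)) props[[prev]]
                  else make_propagator(Qs[[k]])
  }
  n_edge <- nrow(skel$tree$phy$edge)
  Pedge <- vector("list", n_edge)
  for (i in seq_len(n_edge)) {
    si <- skel$edge_segs[[i]]
    P <- diag(space$n_states)
    for (r in seq_len(nrow(si)))
      if (si$duration[r] > 0)
        P <- P %*% props[[si$epoch[r]]](si$duration[r])
    Pedge[[i]] <- P
  }
  list(tree = skel$tree, space = space, kind = skel$kind,
       params = c(d = d, e = e, j = j),
       tip_idx = skel$tip_idx, Pedge = Pedge, segs = skel$segs, Qs = Qs,
       props = props,
       clado = clado_tables(space, skel$kind, j, skel$clado_skel),
       epochs = epochs)
}

# Pruning pass: conditional likelihoods D[v, s] of the data in the clade
# of v given state s at node v, with per-node rescaling. Returns D, the
# per-edge "branch-top" likelihood vectors, and the total lnL.
biogeo_prune <- function(ctx) {
  phy <- ctx$tree$phy
  n <- ctx$tree$n_tips
  N <- n + phy$Nnode
  ns <- ctx$space$n_states
  po <- ape::reorder.phylo(phy, "postorder")
  eo <- match(po$edge[, 2], phy$edge[, 2])  # child node identifies the edge
  D <- matrix(0, N, ns)
  for (i in seq_len(n)) D[i, ctx$tip_idx[i]] <- 1
  logscale <- 0
  Dbranch <- vector("list", nrow(phy$edge))   # indexed by original edge row
  child_edges <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  for (r in seq_len(nrow(po$edge))) {
    ei <- eo[r]
    child <- phy$edge[ei, 2]
    Dbranch[[ei]] <- as.vector(ctx$Pedge[[ei]] %*% D[child, ])
    parent <- phy$edge[ei, 1]
    kids <- child_edges[[as.character(parent)]]
    if (all(!vapply(Dbranch[kids], is.null, logical(1)))) {
      db1 <- Dbranch[[kids[1]]]; db2 <- Dbranch[[kids[2]]]
      dv <- numeric(ns)
      for (s in seq_len(ns)) {
        tab <- ctx$clado[[s]]
        if (is.null(tab)) next
        dv[s] <- sum(tab$prob * db1[tab$left] * db2[tab$right])
      }
      f <- sum(dv)
      if (f <= 0) {
        D[parent, ] <- 0
      } else {
        D[parent, ] <- dv / f
        logscale <- logscale + log(f)
      }
    }
  }
  root <- n + 1L
  nonnull <- setdiff(seq_len(ns),
                     if (is.na(ctx$space$null_index)) integer(0)
                     else ctx$space$null_index)
  tot <- sum(D[root, nonnull])
  lnL <- if (tot <= 0) -Inf else log(tot / length(nonnull)) + logscale
  prior <- numeric(ns)
  prior[nonnull] <- 1 / length(nonnull)
  list(D = D, Dbranch = Dbranch, lnL = lnL, prior = prior,
       child_edges = child_edges)
}

#' Time-stratified range-evolution log-likelihood
#'
#' Felsenstein pruning over the range state space: along every branch
#' segment the matrix exponential of that epoch's anagenetic rate matrix
#' is applied; at internal nodes daughter likelihoods are combined through
#' the model's cladogenesis distribution; the root likelihood averages the
#' conditional likelihoods under a prior uniform over the non-null states
#' with nonzero conditional likelihood.
#'
#' @param tree a [dated_tree] (fully bifurcating).
#' @param tips named list mapping each tip label to a character vector of
#'   occupied areas.
#' @param kind model kind (see [cladogenesis_distribution()]).
#' @param params named numeric with `d`, `e` and (for +J models) `j`.
#' @param epochs an [epoch_spec] with `areas` covering the tree span.
#' @param space optional pre-built state space.
#' @return the log-likelihood in nats.
#' @export
stratified_loglik <- function(tree, tips, kind, params, epochs, space = NULL) {
  j <- if (is_jump_model(kind)) unname(params["j"]) else 0
  if (is.na(j)) stop("+J model needs a 'j' parameter")
  ctx <- biogeo_context(tree, tips, kind, unname(params["d"]),
                        unname(params["e"]), j, epochs, space)
  biogeo_prune(ctx)$lnL
}

# Outside pass: per-node marginal state probabilities at the given
# parameters (conditional x outside normalisation).
biogeo_marginals <- function(ctx, pr) {
  phy <- ctx$tree$phy
  n <- ctx$tree$n_tips
  N <- n + phy$Nnode
  ns <- ctx$space$n_states
  U <- matrix(0, N, ns)
  root <- n + 1L
  U[root, ] <- pr$prior
  M <- matrix(0, N, ns, dimnames = list(NULL, ctx$space$labels))
  # internal nodes oldest-first: every parent is visited before its children
  internal <- (n + 1L):N
  nodes_pre <- internal[order(ctx$tree$ages[internal], decreasing = TRUE)]
  for (v in nodes_pre) {
    kids <- pr$child_edges[[as.character(v)]]
    db1 <- pr$Dbranch[[kids[1]]]; db2 <- pr$Dbranch[[kids[2]]]
    uv <- U[v, ]
    A1 <- numeric(ns); A2 <- numeric(ns)
    for (s in which(uv > 0)) {
      tab <- ctx$clado[[s]]
      if (is.null(tab)) next
      w1 <- uv[s] * tab$prob * db2[tab$right]
      w2 <- uv[s] * tab$prob * db1[tab$left]
      A1[tab$left] <- A1[tab$left] + w1
      A2[tab$right] <- A2[tab$right] + w2
    }
    for (kk in 1:2) {
      ei <- kids[kk]
      child <- phy$edge[ei, 2]
      a <- if (kk == 1) A1 else A2
      u <- as.vector(crossprod(ctx$Pedge[[ei]], a))
      if (sum(u) > 0) u <- u / sum(u)
      U[child, ] <- u
    }
  }
  for (v in seq_len(N)) {
    m <- pr$D[v, ] * U[v, ]
    tot <- sum(m)
    M[v, ] <- if (tot > 0) m / tot else 0
  }
  M
}

#' Fit a range-evolution model by maximum likelihood
#'
#' Maximises the time-stratified likelihood over the dispersal rate d, the
#' extinction rate e and, for +J models, the founder-event weight j, using
#' bounded quasi-Newton optimisation from several log-spaced starting
#' points. Node marginal range probabilities are computed at the ML point
#' by the standard conditional-times-outside two-pass marginalisation.
#'
#' @inheritParams stratified_loglik
#' @param d_bounds,e_bounds rate bounds per Ma.
#' @param j_bounds founder-weight bounds (open above at 3).
#' @param n_starts number of starting points.
#' @return object of class `biogeo_fit`: `kind`, `params` (d, e, j),
#'   `lnL`, `k` (2 or 3), `AIC`, `marginals` (nodes x states matrix of
#'   marginal range probabilities), `space`, and the pruning context used
#'   by [sample_history()].
#' @export
fit_biogeo <- function(tree, tips, kind, epochs, space = NULL,
                       d_bounds = c(1e-12, 5), e_bounds = c(1e-12, 5),
                       j_bounds = c(1e-6, 3 - 1e-6), n_starts = 5) {
  if (!kind %in% biogeo_model_kinds)
    stop("unknown model kind '", kind, "'; valid kinds: ",
         paste(biogeo_model_kinds, collapse = ", "))
  if (is.null(space)) space <- build_state_space(epochs$areas)
  jump <- is_jump_model(kind)
  skel <- biogeo_skeleton(tree, tips, kind, epochs, space)
  negll <- function(par) {
    d <- exp(par[1]); e <- exp(par[2])
    j <- if (jump) par[3] else 0
    ctx <- biogeo_context(tree, tips, kind, d, e, j, epochs, space, skel)
    ll <- biogeo_prune(ctx)$lnL
    if (!is.finite(ll)) 1e10 else -ll
  }
  d_starts <- exp(seq(log(1e-3), log(0.3), length.out = n_starts))
  e_starts <- exp(seq(log(3e-4), log(0.1), length.out = n_starts))
  j_starts <- seq(0.05, 2.0, length.out = n_starts)
  lower <- c(log(d_bounds[1]), log(e_bounds[1]), if (jump) j_bounds[1])
  upper <- c(log(d_bounds[2]), log(e_bounds[2]), if (jump) j_bounds[2])
  best <- NULL
  for (i in seq_len(n_starts)) {
    p0 <- c(log(d_starts[i]), log(e_starts[i]), if (jump) j_starts[i])
    o <- tryCatch(
      stats::optim(p0, negll, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("optimizer failed to converge from any start")
  d <- exp(best$par[1]); e <- exp(best$par[2])
  j <- if (jump) best$par[3] else 0
  ctx <- biogeo_context(tree, tips, kind, d, e, j, epochs, space, skel)
  pr <- biogeo_prune(ctx)
  M <- biogeo_marginals(ctx, pr)
  k <- if (jump) 3L else 2L
  fit <- list(kind = kind, params = c(d = d, e = e, j = j),
              lnL = pr$lnL, k = k, AIC = 2 * k - 2 * pr$lnL,
              marginals = M, space = space,
              context = ctx, prune = pr)
  class(fit) <- "biogeo_fit"
  fit
}

#' Evaluate a range-evolution model at fixed parameters
#'
#' Builds the same fitted-model object as [fit_biogeo()] but at
#' user-supplied parameter values, without optimisation: useful for
#' likelihood profiling, simulation studies and stochastic mapping under
#' known parameters.
#'
#' @inheritParams stratified_loglik
#' @return a `biogeo_fit` (see [fit_biogeo()]); `k` counts the model's
#'   free parameters even though none were estimated here.
#' @export
biogeo_fit_at <- function(tree, tips, kind, params, epochs, space = NULL) {
  jump <- is_jump_model(kind)
  j <- if (jump) unname(params["j"]) else 0
  if (jump && is.na(j)) stop("+J model needs a 'j' parameter")
  ctx <- biogeo_context(tree, tips, kind, unname(params["d"]),
                        unname(params["e"]), j, epochs, space)
  pr <- biogeo_prune(ctx)
  M <- biogeo_marginals(ctx, pr)
  k <- if (jump) 3L else 2L
  fit <- list(kind = kind,
              params = c(d = unname(params["d"]), e = unname(params["e"]),
                         j = j),
              lnL = pr$lnL, k = k, AIC = 2 * k - 2 * pr$lnL,
              marginals = M, space = ctx$space, context = ctx, prune = pr)
  class(fit) <- "biogeo_fit"
  fit
}

#' @export
print.biogeo_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, k = %d, AIC = %.4f\n",
              x$kind, x$lnL, x$k, x$AIC))
  cat(sprintf("  d = %.5g, e = %.5g, j = %.4g per Ma\n",
              x$params["d"], x$params["e"], x$params["j"]))
  n <- x$context$tree$n_tips
  root <- n + 1L
  top <- sort(x$marginals[root, ], decreasing = TRUE)[1:3]
  cat("  root state probabilities:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Compare nested range-evolution models
#'
#' For each (base, +J) pair: chi-squared(1) likelihood-ratio p (truncated
#' to 1 when the +J fit is no better) and pairwise Akaike weights from
#' `exp(-0.5 dAIC)`.
#'
#' @param fits list of [fit_biogeo()] results (or lists with `kind`,
#'   `lnL`, `k`).
#' @param pairs optional list of `c(alternative, null)` kind pairs;
#'   defaults to every +J model present paired with its base model.
#' @return data frame mirroring the usual published layout: one row per
#'   pair with lnL, p, AIC and pairwise AIC weights of both models.
#' @export
compare_biogeo_models <- function(fits, pairs = NULL) {
  kinds <- vapply(fits, function(f) f$kind, character(1))
  names(fits) <- kinds
  if (is.null(pairs)) {
    alts <- kinds[grepl("\\+J$", kinds)]
    pairs <- lapply(alts, function(a) c(a, base_model(a)))
    pairs <- Filter(function(p) p[2] %in% kinds, pairs)
  }
  rows <- lapply(pairs, function(p) {
    alt <- fits[[p[1]]]; nul <- fits[[p[2]]]
    if (is.null(alt) || is.null(nul)) stop("missing fit for pair ",
                                           paste(p, collapse = " vs "))
    stat <- 2 * (alt$lnL - nul$lnL)
    pval <- if (stat <= 0) 1 else stats::pchisq(stat, 1, lower.tail = FALSE)
    aic_alt <- 2 * alt$k - 2 * alt$lnL
    aic_nul <- 2 * nul$k - 2 * nul$lnL
    w <- exp(-0.5 * (c(aic_alt, aic_nul) - min(aic_alt, aic_nul)))
    w <- w / sum(w)
    data.frame(alternative = p[1], null = p[2],
               lnL_alt = alt$lnL, lnL_null = nul$lnL,
               p = pval, AIC_alt = aic_alt, AIC_null = aic_nul,
               AICw_alt = w[1], AICw_null = w[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
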