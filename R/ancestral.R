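# Shared path-length matrix among ALL nodes (tips + internal), in Ma:
# entry (u, v) = time from the root to the MRCA of u and v.
full_shared_time <- function(tree) {
  phy <- tree$phy
  n <- tree$n_tips
  m <- phy$Nnode
  N <- n + m
  depths <- tree$root_age - tree$ages      # time from root to each node
  mr <- ape::mrca(phy, full = TRUE)        # N x N node numbers
  S <- matrix(depths[mr], N, N)
  S
}

#' Ancestral state reconstruction under Brownian motion
#'
#' Joint maximum-likelihood (equivalently GLS) estimates of the trait value
#' at every internal node, with confidence intervals. The estimate at node
#' k is the conditional expectation of a Brownian motion given the tip
#' values, with the root state replaced by its GLS estimate; each estimate
#' is a convex combination of the tip values. Variances come from the
#' conditional-normal formula plus the root-estimation term, scaled by the
#' unbiased rate estimate (divisor n - 1); intervals use the Student-t
#' quantile with n - 1 degrees of freedom, which gives exact nominal
#' coverage for the root state.
#'
#' @param tree a [dated_tree].
#' @param x named numeric trait vector.
#' @param level confidence level for the intervals.
#' @return data frame with one row per node (tips included, post-order ape
#'   numbering): `node`, `age`, `estimate`, `variance`, `lo`, `hi`. Tip
#'   rows have variance 0 and estimate equal to the observation.
#' @export
bm_ancestral_states <- function(tree, x, level = 0.95) {
  x <- align_traits(tree, x)
  n <- tree$n_tips
  N <- n + tree$phy$Nnode
  S <- full_shared_time(tree)
  Ct <- S[seq_len(n), seq_len(n)]          # tip covariance structure
  L <- chol(Ct)
  one <- rep(1, n)
  Cinv1 <- backsolve(L, backsolve(L, one, transpose = TRUE))
  denom <- sum(Cinv1)
  z0 <- sum(Cinv1 * x) / denom
  r <- x - z0
  Cinvr <- backsolve(L, backsolve(L, r, transpose = TRUE))
  sig2_hat <- sum(r * Cinvr) / (n - 1)     # unbiased rate estimate

  est <- numeric(N); vvar <- numeric(N)
  est[seq_len(n)] <- x
  internal <- (n + 1L):N
  for (k in internal) {
    ck <- S[k, seq_len(n)]
    w <- backsolve(L, backsolve(L, ck, transpose = TRUE))
    est[k] <- z0 + sum(w * r)
    h <- 1 - sum(w)                        # weight routed through z0-hat
    cond <- S[k, k] - sum(ck * w)
    vvar[k] <- sig2_hat * (cond + h^2 / denom)
    vvar[k] <- max(vvar[k], 0)
  }
  q <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  data.frame(node = seq_len(N), age = tree$ages,
             estimate = est, variance = vvar,
             lo = est - q * sqrt(vvar), hi = est + q * sqrt(vvar))
}

#' Traitgram coordinates
#'
#' Projects the tree into (time before present, trait value) space: tip
#' y-coordinates are the observed values, internal-node y-coordinates the
#' Brownian-motion ancestral estimates, x-coordinates the node ages (root
#' at the left / oldest age).
#'
#' @inheritParams bm_ancestral_states
#' @return list with `nodes` (node, age, value) and `edges`
#'   (parent/child node numbers and their coordinate pairs).
#' @export
traitgram <- function(tree, x) {
  anc <- bm_ancestral_states(tree, x)
  nodes <- data.frame(node = anc$node, age = anc$age, value = anc$estimate)
  e <- tree$phy$edge
  edges <- data.frame(
    parent = e[, 1], child = e[, 2],
    age_parent = nodes$age[e[, 1]], value_parent = nodes$value[e[, 1]],
    age_child = nodes$age[e[, 2]], value_child = nodes$value[e[, 2]])
  list(nodes = nodes, edges = edges)
}

#' Ancestral reconstruction with PNO uncertainty propagation
#'
#' Propagates niche-model uncertainty to interior nodes: on each of
#' `n_samples` replicates, one value per species is drawn from that
#' species' predicted niche occupancy profile and a full Brownian-motion
#' ancestral reconstruction is run (the rate is re-estimated on every
#' draw). Per node the mean estimate and percentile interval across
#' replicates are reported.
#'
#' @param tree a [dated_tree].
#' @param profiles named list of [pno_profile] objects, one per tip.
#' @param n_samples number of resampling replicates (>= 100).
#' @param seed integer seed for reproducibility.
#' @return data frame: `node`, `age`, `estimate` (mean across replicates),
#'   `lo`, `hi` (2.5/97.5 percentiles).
#' @export
pno_ancestral <- function(tree, profiles, n_samples = 1000, seed = 1) {
  labs <- tree$phy$tip.label
  missing <- setdiff(labs, names(profiles))
  if (length(missing))
    stop("no PNO profile for: ", paste(missing, collapse = ", "))
  if (n_samples < 100) stop("n_samples must be >= 100")
  for (sp in labs)
    if (length(profiles[[sp]]$weights) == 0 ||
        sum(profiles[[sp]]$weights) == 0)
      stop("empty PNO profile for ", sp)
  set.seed(seed)
  N <- tree$n_tips + tree$phy$Nnode
  draws <- matrix(NA_real_, n_samples, N)
  for (i in seq_len(n_samples)) {
    x <- vapply(labs, function(sp) pno_sample(profiles[[sp]], 1), numeric(1))
    names(x) <- labs
    draws[i, ] <- bm_ancestral_states(tree, x)$estimate
  }
  data.frame(node = seq_len(N), age = tree$ages,
             estimate = colMeans(draws),
             lo = apply(draws, 2, stats::quantile, probs = 0.025),
             hi = apply(draws, 2, stats::quantile, probs = 0.975))
}
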