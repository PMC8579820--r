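#' Classify a cladogenetic event from its state triple
#'
#' @param parent,left,right character vectors of area labels (or integer
#'   index vectors), parent and daughter ranges at a speciation event.
#' @return one of `"speciation"` (within-area speciation, including
#'   BAYAREALIKE-style copy events at widespread parents), `"subset"`
#'   (subset speciation), `"founder"` (jump dispersal to a new area),
#'   `"vicariance"` (disjoint split of the parent range).
#' @export
classify_cladogenetic_event <- function(parent, left, right) {
  p <- sort(parent); l <- sort(left); r <- sort(right)
  same <- function(a, b) length(a) == length(b) && all(a == b)
  if (same(l, p) && same(r, p)) return("speciation")
  for (o in list(list(k = l, oth = r), list(k = r, oth = l))) {
    if (same(o$k, p)) {
      if (length(o$oth) >= 1 && all(o$oth %in% p) && length(o$oth) < length(p))
        return("subset")
      if (any(!o$oth %in% p)) return("founder")
    }
  }
  if (length(intersect(l, r)) == 0 && same(sort(c(l, r)), p))
    return("vicariance")
  stop("inconsistent cladogenetic state triple: ",
       paste(p, collapse = ""), " -> (", paste(l, collapse = ""), ", ",
       paste(r, collapse = ""), ")")
}

# Simulate one unconditioned CTMC path along a branch (old -> young)
# through its epoch segments; returns final state index and event log.
ctmc_forward_path <- function(ctx, state, segments) {
  events <- list()
  for (r in seq_len(nrow(segments))) {
    Q <- ctx$Qs[[segments$epoch[r]]]
    t_now <- segments$start[r]; t_end <- segments$end[r]
    repeat {
      rate <- -Q[state, state]
      if (rate <= 0) break
      wait <- stats::rexp(1, rate)
      if (t_now - wait <= t_end) break
      t_now <- t_now - wait
      probs <- Q[state, ]; probs[state] <- 0
      new <- sample.int(length(probs), 1, prob = probs)
      events[[length(events) + 1L]] <- list(time = t_now, from = state, to = new)
      state <- new
    }
  }
  list(state = state, events = events)
}

#' Sample one biogeographic stochastic map
#'
#' Draws a complete range-evolution history consistent with the fitted
#' model and the tip data: node states come from the joint smoothed
#' distribution (root from its marginal, then each node conditionally on
#' its parent), and branch histories are drawn conditional on their
#' endpoint states by rejection sampling of forward CTMC paths.
#'
#' @param fit a [fit_biogeo()] result.
#' @param seed optional integer seed.
#' @param max_rejections per-branch cap on rejection-sampling attempts.
#' @return object of class `range_history`: `node_states` (state index per
#'   node), `clado_events` (data frame: node, parent/left/right state
#'   labels, type), `branch_events` (data frame: edge, time Ma, type
#'   `"expansion"`/`"contraction"`, from/to state labels).
#' @export
sample_history <- function(fit, seed = NULL, max_rejections = 1e5) {
  stopifnot(inherits(fit, "biogeo_fit"))
  if (!is.null(seed)) set.seed(seed)
  ctx <- fit$context; pr <- fit$prune
  phy <- ctx$tree$phy
  n <- ctx$tree$n_tips
  N <- n + phy$Nnode
  ns <- ctx$space$n_states
  root <- n + 1L
  node_states <- integer(N)
  node_tops <- integer(N)   # state at the *top* (old end) of each node's branch
  rootm <- pr$prior * pr$D[root, ]
  node_states[root] <- sample.int(ns, 1, prob = rootm)
  clado <- list(); branch <- list()
  internal <- (n + 1L):N
  nodes_pre <- internal[order(ctx$tree$ages[internal], decreasing = TRUE)]
  for (v in nodes_pre) {
    s <- node_states[v]
    kids <- pr$child_edges[[as.character(v)]]
    tab <- ctx$clado[[s]]
    db1 <- pr$Dbranch[[kids[1]]]; db2 <- pr$Dbranch[[kids[2]]]
    wts <- tab$prob * db1[tab$left] * db2[tab$right]
    if (sum(wts) <= 0) stop("no consistent cladogenetic event at node ", v)
    row <- sample.int(nrow(tab), 1, prob = wts)
    lab <- ctx$space$labels
    clado[[length(clado) + 1L]] <- data.frame(
      node = v, parent = lab[s], left = lab[tab$left[row]],
      right = lab[tab$right[row]],
      type = classify_cladogenetic_event(
        ctx$space$states[[s]],
        ctx$space$states[[tab$left[row]]],
        ctx$space$states[[tab$right[row]]]),
      stringsAsFactors = FALSE)
    tops <- c(tab$left[row], tab$right[row])
    for (kk in 1:2) {
      ei <- kids[kk]
      child <- phy$edge[ei, 2]
      top <- tops[kk]
      node_tops[child] <- top
      w <- ctx$Pedge[[ei]][top, ] * pr$D[child, ]
      if (sum(w) <= 0) stop("no consistent endpoint state on edge ", ei)
      node_states[child] <- sample.int(ns, 1, prob = w)
    }
  }
  # branch histories by rejection sampling of forward paths
  lab <- ctx$space$labels
  for (ei in seq_len(nrow(phy$edge))) {
    child <- phy$edge[ei, 2]
    si <- ctx$segs[ctx$segs$edge == ei, , drop = FALSE]
    si <- si[order(-si$start), , drop = FALSE]
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      path <- ctmc_forward_path(ctx, node_tops[child], si)
      if (path$state == node_states[child]) break
      if (attempt >= max_rejections)
        stop("rejection cap (", max_rejections, ") exceeded on edge ", ei,
             "; consider a uniformization-based sampler for these rates")
    }
    for (ev in path$events) {
      gain <- length(ctx$space$states[[ev$to]]) >
              length(ctx$space$states[[ev$from]])
      branch[[length(branch) + 1L]] <- data.frame(
        edge = ei, time = ev$time,
        type = if (gain) "expansion" else "contraction",
        from = lab[ev$from], to = lab[ev$to], stringsAsFactors = FALSE)
    }
  }
  structure(list(
    node_states = node_states,
    clado_events = do.call(rbind, clado),
    branch_events = if (length(branch)) do.call(rbind, branch)
                    else data.frame(edge = integer(), time = numeric(),
                                    type = character(), from = character(),
                                    to = character())),
    class = "range_history")
}

#' Summarise stochastic maps by event type
#'
#' Counts each history's events by type -- cladogenetic: within-area
#' speciation (copy events included), subset speciation, founder event,
#' vicariance; anagenetic: range expansion (area gain) and range
#' contraction (area loss) -- and reports the mean, standard deviation and
#' percentage of the grand-total mean per type. Every history contributes
#' exactly one cladogenetic event per internal node.
#'
#' @param histories list of [sample_history()] results (>= 2).
#' @return data frame: `type`, `mean`, `sd`, `pct` (percentages sum
#'   to 100).
#' @export
bsm_summary <- function(histories) {
  if (length(histories) < 2) stop("need at least 2 histories")
  types <- c("speciation", "subset", "founder", "expansion", "contraction",
             "vicariance")
  counts <- t(vapply(histories, function(h) {
    cl <- table(factor(h$clado_events$type,
                       levels = c("speciation", "subset", "founder",
                                  "vicariance")))
    br <- table(factor(h$branch_events$type,
                       levels = c("expansion", "contraction")))
    c(speciation = unname(cl["speciation"]), subset = unname(cl["subset"]),
      founder = unname(cl["founder"]), expansion = unname(br["expansion"]),
      contraction = unname(br["contraction"]),
      vicariance = unname(cl["vicariance"]))
  }, numeric(6)))
  mu <- colMeans(counts)
  sdv <- apply(counts, 2, stats::sd)
  total <- sum(mu)
  data.frame(type = types, mean = mu[types], sd = sdv[types],
             pct = if (total > 0) 100 * mu[types] / total else 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run many stochastic maps and summarise them
#'
#' @param fit a [fit_biogeo()] result.
#' @param n number of maps.
#' @param seed integer seed (each map uses an offset of it).
#' @return list: `summary` (see [bsm_summary()]), `histories`.
#' @export
run_bsm <- function(fit, n = 50, seed = 1) {
  set.seed(seed)
  histories <- lapply(seq_len(n), function(i) sample_history(fit))
  list(summary = bsm_summary(histories), histories = histories)
}
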