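#' Simulate continuous traits on a dated tree
#'
#' Draws one trait vector from the generating distribution of the chosen
#' model: BM is multivariate normal with covariance `sigma2 * C` around the
#' root state; OU uses the fixed-root OU covariance; WN is iid normal;
#' LAMBDA is BM on the lambda-transformed covariance.
#'
#' @param tree a [dated_tree].
#' @param kind one of `"BM"`, `"OU"`, `"WN"`, `"LAMBDA"`.
#' @param params named numeric: `sigma2` and `z0` (all kinds), plus
#'   `alpha` (OU) or `lambda` (LAMBDA).
#' @param seed optional integer seed.
#' @return named numeric vector of tip values, with attributes `kind`,
#'   `params` and `seed`.
#' @export
simulate_traits <- function(tree, kind = c("BM", "OU", "WN", "LAMBDA"),
                            params = c(sigma2 = 1, z0 = 0), seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  s2 <- unname(params["sigma2"]); z0 <- unname(params["z0"])
  if (is.na(s2) || is.na(z0)) stop("params must include sigma2 and z0")
  if (s2 < 0) stop("sigma2 must be >= 0")
  n <- tree$n_tips
  C <- vcv_matrix(tree)
  V <- switch(kind,
    BM = s2 * C,
    OU = {
      a <- unname(params["alpha"])
      if (is.na(a) || a <= 0) stop("OU needs alpha > 0")
      s2 * ou_covariance(C, a)
    },
    WN = s2 * diag(n),
    LAMBDA = {
      lam <- unname(params["lambda"])
      if (is.na(lam) || lam < 0) stop("LAMBDA needs lambda >= 0")
      s2 * lambda_covariance(C, lam)
    })
  x <- if (s2 == 0) rep(z0, n)
       else as.vector(z0 + t(chol(V + 1e-12 * diag(n))) %*% stats::rnorm(n))
  names(x) <- tree$phy$tip.label
  attr(x, "kind") <- kind; attr(x, "params") <- params; attr(x, "seed") <- seed
  x
}

#' Forward-simulate a range-evolution history
#'
#' The root state is drawn uniformly from the single-area states; along
#' each branch segment the anagenetic CTMC runs with that epoch's rate
#' matrix; at every internal node a cladogenetic event is drawn from the
#' model's cladogenesis distribution. The complete event log (the true
#' history) is retained so that simulator bookkeeping can serve as an
#' oracle for event-count summaries.
#'
#' @param tree a [dated_tree] (bifurcating).
#' @param kind model kind (see [cladogenesis_distribution()]).
#' @param params named numeric with `d`, `e` and (for +J models) `j`.
#' @param epochs an [epoch_spec].
#' @param seed optional integer seed.
#' @param require_extant_tips redraw the history (up to `max_tries` times)
#'   if any tip ends in the null range, so the result is usable as input
#'   to the fitting functions.
#' @param max_tries cap on redraws.
#' @return list of class `simulated_ranges`: `tips` (named list of area
#'   vectors), `history` (a `range_history`), `params`, `seed`.
#' @export
simulate_range_history <- function(tree, kind, params, epochs, seed = NULL,
                                   require_extant_tips = TRUE,
                                   max_tries = 1000) {
  if (!is.null(seed)) set.seed(seed)
  space <- build_state_space(epochs$areas)
  j <- if (is_jump_model(kind)) unname(params["j"]) else 0
  if (is.na(j)) stop("+J model needs a 'j' parameter")
  dummy_tips <- stats::setNames(
    rep(list(epochs$areas[1]), tree$n_tips), tree$phy$tip.label)
  ctx <- biogeo_context(tree, dummy_tips, kind, unname(params["d"]),
                        unname(params["e"]), j, epochs, space)
  phy <- tree$phy
  n <- tree$n_tips
  N <- n + phy$Nnode
  singles <- which(vapply(space$states, length, integer(1)) == 1L)
  child_edges <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  lab <- space$labels
  for (try in seq_len(max_tries)) {
    node_states <- integer(N)
    root <- n + 1L
    node_states[root] <- sample(singles, 1)
    clado <- list(); branch <- list()
    internal <- (n + 1L):N
    nodes_pre <- internal[order(tree$ages[internal], decreasing = TRUE)]
    dead <- FALSE
    for (v in nodes_pre) {
      s <- node_states[v]
      if (length(space$states[[s]]) == 0) { dead <- TRUE; break }
      tab <- ctx$clado[[s]]
      row <- sample.int(nrow(tab), 1, prob = tab$prob)
      clado[[length(clado) + 1L]] <- data.frame(
        node = v, parent = lab[s], left = lab[tab$left[row]],
        right = lab[tab$right[row]],
        type = classify_cladogenetic_event(
          space$states[[s]], space$states[[tab$left[row]]],
          space$states[[tab$right[row]]]),
        stringsAsFactors = FALSE)
      kids <- child_edges[[as.character(v)]]
      tops <- c(tab$left[row], tab$right[row])
      for (kk in 1:2) {
        ei <- kids[kk]
        child <- phy$edge[ei, 2]
        si <- ctx$segs[ctx$segs$edge == ei, , drop = FALSE]
        si <- si[order(-si$start), , drop = FALSE]
        path <- ctmc_forward_path(ctx, tops[kk], si)
        node_states[child] <- path$state
        for (ev in path$events) {
          gain <- length(space$states[[ev$to]]) > length(space$states[[ev$from]])
          branch[[length(branch) + 1L]] <- data.frame(
            edge = ei, time = ev$time,
            type = if (gain) "expansion" else "contraction",
            from = lab[ev$from], to = lab[ev$to], stringsAsFactors = FALSE)
        }
      }
    }
    tip_null <- any(node_states[seq_len(n)] == space$null_index)
    if (!dead && (!tip_null || !require_extant_tips)) {
      tips <- lapply(node_states[seq_len(n)], function(s)
        space$areas[space$states[[s]]])
      names(tips) <- phy$tip.label
      history <- structure(list(
        node_states = node_states,
        clado_events = do.call(rbind, clado),
        branch_events = if (length(branch)) do.call(rbind, branch)
                        else data.frame(edge = integer(), time = numeric(),
                                        type = character(), from = character(),
                                        to = character())),
        class = "range_history")
      return(structure(list(tips = tips, history = history,
                            params = c(d = unname(params["d"]),
                                       e = unname(params["e"]), j = j),
                            seed = seed, kind = kind),
                       class = "simulated_ranges"))
    }
  }
  stop("could not simulate a history with all tips extant in ", max_tries,
       " tries; lower e or allow extinct tips")
}

#' Gaussian-response suitability surface over a climate grid
#'
#' Suitability of each valid cell is `exp(-(clim - optimum)^2 /
#' (2 breadth^2))`: a stand-in habitat-suitability model with a known
#' climatic optimum, used to validate the PNO machinery.
#'
#' @param clim climate grid (`ascii_grid` or matrix).
#' @param optimum climatic optimum (climate units).
#' @param breadth niche breadth (> 0, same units).
#' @return a suitability matrix (or `ascii_grid` if the input was one).
#' @export
make_gaussian_raster <- function(clim, optimum, breadth) {
  if (breadth <= 0) stop("breadth must be > 0")
  m <- as_grid_matrix(clim)
  s <- exp(-(m - optimum)^2 / (2 * breadth^2))
  if (inherits(clim, "ascii_grid")) {
    out <- clim; out$data <- s; out
  } else s
}

#' Random ultrametric test tree
#'
#' Coalescent tree rescaled to a given root age; convenience generator for
#' simulation studies.
#'
#' @param n_tips number of tips.
#' @param root_age target root age in Ma.
#' @param seed optional integer seed.
#' @return a [dated_tree].
#' @export
random_dated_tree <- function(n_tips, root_age = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rcoal(n_tips)
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * root_age / depth
  dated_tree(phy)
}
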