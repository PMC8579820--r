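#' Discrete geographic range state space
#'
#' States are the non-empty subsets of the area set up to `max_range_size`,
#' canonically ordered by subset size then lexicographically (in the order
#' the areas are given), optionally preceded by the null (empty) range used
#' for extinction bookkeeping. Each state is stored as an integer vector of
#' area indices; labels concatenate area labels (`"BC"`), the null range is
#' labelled `"_"`.
#'
#' @param areas character vector of distinct area labels.
#' @param max_range_size largest allowed range size (default: all areas).
#' @param include_null include the empty range as an absorbing state.
#' @return object of class `range_state_space`: `areas`, `states` (list of
#'   integer vectors), `labels`, `n_states`, `null_index` (or `NA`),
#'   `max_range_size`.
#' @export
build_state_space <- function(areas, max_range_size = length(areas),
                              include_null = TRUE) {
  if (anyDuplicated(areas)) stop("duplicate area labels")
  K <- length(areas)
  if (max_range_size < 1 || max_range_size > K)
    stop("max_range_size must be in [1, n_areas]")
  states <- list()
  if (include_null) states[[1]] <- integer(0)
  for (sz in seq_len(max_range_size))
    for (cmb in utils::combn(K, sz, simplify = FALSE))
      states[[length(states) + 1L]] <- cmb
  labels <- vapply(states, function(s)
    if (length(s) == 0) "_" else paste(areas[s], collapse = ""), character(1))
  bitmask <- vapply(states, function(s) sum(bitwShiftL(1L, s - 1L)), integer(1))
  structure(list(areas = areas, states = states, labels = labels,
                 bitmask = bitmask, n_states = length(states),
                 null_index = if (include_null) 1L else NA_integer_,
                 max_range_size = max_range_size),
            class = "range_state_space")
}

# Index of the state with exactly these area indices, or NA (bitmask lookup).
state_index <- function(space, area_idx) {
  match(sum(bitwShiftL(1L, as.integer(area_idx) - 1L)), space$bitmask)
}

# Map a named list of area-label vectors (tip ranges) to state indices.
tip_state_indices <- function(space, ranges) {
  vapply(names(ranges), function(sp) {
    a <- match(ranges[[sp]], space$areas)
    if (any(is.na(a)))
      stop("tip ", sp, " uses unknown area(s): ",
           paste(ranges[[sp]][is.na(a)], collapse = ", "))
    i <- state_index(space, a)
    if (is.na(i))
      stop("tip ", sp, " has range outside the state space (size limit?)")
    i
  }, integer(1))
}

#' Anagenetic dispersal-extinction rate matrix
#'
#' Continuous-time rates between range states along branches: a range
#' gains area k at rate `d * sum over occupied areas a of multipliers[a, k]`
#' (single-area gains only, respecting the range-size limit), and loses any
#' one occupied area at rate `e` (a single-area range collapses to the null
#' range, which is absorbing). Rows sum to zero.
#'
#' @param space a [build_state_space()] result.
#' @param d dispersal rate per area pair per Ma (>= 0).
#' @param e extinction (area loss) rate per Ma (>= 0).
#' @param multipliers non-negative areas x areas dispersal multiplier
#'   matrix (diagonal ignored); defaults to all ones.
#' @return dense `n_states x n_states` rate matrix (states in canonical
#'   order, labelled).
#' @export
anagenetic_rate_matrix <- function(space, d, e, multipliers = NULL) {
  K <- length(space$areas)
  if (is.null(multipliers)) multipliers <- matrix(1, K, K)
  multipliers <- as.matrix(multipliers)
  if (any(multipliers < 0)) stop("multipliers must be >= 0")
  n <- space$n_states
  Q <- matrix(0, n, n, dimnames = list(space$labels, space$labels))
  for (i in seq_len(n)) {
    S <- space$states[[i]]
    if (length(S) == 0) next                      # null range is absorbing
    if (length(S) < space$max_range_size) {
      for (k in setdiff(seq_len(K), S)) {
        rate <- d * sum(multipliers[S, k])
        if (rate > 0) {
          jdx <- state_index(space, c(S, k))
          Q[i, jdx] <- Q[i, jdx] + rate
        }
      }
    }
    if (e > 0) {
      for (a in S) {
        tgt <- setdiff(S, a)
        jdx <- if (length(tgt) == 0) space$null_index
               else state_index(space, tgt)
        if (!is.na(jdx)) Q[i, jdx] <- Q[i, jdx] + e
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

biogeo_model_kinds <- c("DEC", "DEC+J", "DIVALIKE", "DIVALIKE+J",
                        "BAYAREALIKE", "BAYAREALIKE+J")

base_model <- function(kind) sub("\\+J$", "", kind)
is_jump_model <- function(kind) grepl("\\+J$", kind)

# All non-empty proper subsets of an index set, as a list.
proper_subsets <- function(S) {
  out <- list()
  for (sz in seq_len(length(S) - 1L))
    for (cmb in utils::combn(S, sz, simplify = FALSE))
      out[[length(out) + 1L]] <- cmb
  out
}

#' Cladogenetic range-inheritance distribution
#'
#' Enumerates the ordered daughter-range pairs allowed at a speciation
#' event for a given parent range, with normalised probabilities. Event
#' classes by model family:
#' \itemize{
#'   \item sympatry: both daughters equal a single-area parent (all models);
#'   \item subset sympatry: one daughter keeps the widespread parent range,
#'     the other is one area within it (DEC family only);
#'   \item vicariance: the daughters split the parent disjointly -- one side
#'     restricted to a single area in the DEC family, any disjoint
#'     bipartition in the DIVALIKE family;
#'   \item copy: both daughters inherit the widespread parent range
#'     unchanged (BAYAREALIKE family only);
#'   \item jump (founder event): one daughter keeps the parent range, the
#'     other colonises a single area outside it (+J models only).
#' }
#' Per-event weights: every allowed non-jump event carries weight
#' `(3 - j)/3`, every jump event carries weight `j`; probabilities are the
#' weights normalised over all allowed ordered pairs, so `j = 0` recovers
#' the base model exactly.
#'
#' @param space a [build_state_space()] result.
#' @param kind one of `r paste(biogeo_model_kinds, collapse=", ")`.
#' @param parent index of the (non-null) parent state in `space`.
#' @param j founder-event weight, `0 <= j < 3`; must be 0 for non-J models.
#' @return data frame with columns `left`, `right` (state indices),
#'   `type` and `prob` (sums to 1).
#' @export
cladogenesis_distribution <- function(space, kind, parent, j = 0) {
  ev <- clado_events(space, kind, parent)
  clado_weight(ev, kind, j)
}

# Enumerate the allowed ordered daughter pairs and their event classes
# for one parent state; independent of j (jump rows are included for +J
# kinds and weighted later).
clado_events <- function(space, kind, parent) {
  if (!kind %in% biogeo_model_kinds)
    stop("unknown model kind '", kind, "'; valid kinds: ",
         paste(biogeo_model_kinds, collapse = ", "))
  P <- space$states[[parent]]
  if (length(P) == 0) stop("parent state must be non-null")
  base <- base_model(kind)
  left <- integer(0); right <- integer(0); type <- character(0)
  add <- function(l, r, ty) {
    left <<- c(left, l); right <<- c(right, r); type <<- c(type, ty)
  }
  if (length(P) == 1L) {
    add(parent, parent, "sympatry")
  } else if (base == "DEC") {
    for (a in P) {
      ai <- state_index(space, a)
      add(parent, ai, "subset"); add(ai, parent, "subset")
      rest <- state_index(space, setdiff(P, a))
      add(ai, rest, "vicariance")
      if (length(P) > 2L) add(rest, ai, "vicariance")
    }
  } else if (base == "DIVALIKE") {
    for (sub in proper_subsets(P)) {
      li <- state_index(space, sub)
      ri <- state_index(space, setdiff(P, sub))
      add(li, ri, "vicariance")
    }
  } else {  # BAYAREALIKE: ranges are copied unchanged at speciation
    add(parent, parent, "copy")
  }
  if (is_jump_model(kind)) {
    for (a in setdiff(seq_along(space$areas), P)) {
      ai <- state_index(space, a)
      add(parent, ai, "jump"); add(ai, parent, "jump")
    }
  }
  data.frame(left = left, right = right, type = type,
             stringsAsFactors = FALSE)
}

# Apply the +J per-event weighting to an event table and normalise.
clado_weight <- function(ev, kind, j) {
  if (!is_jump_model(kind) && j != 0)
    stop("j must be 0 for model ", kind)
  if (j < 0 || j >= 3) stop("j must lie in [0, 3)")
  wt <- ifelse(ev$type == "jump", j, (3 - j) / 3)
  keep <- wt > 0
  ev <- ev[keep, , drop = FALSE]
  ev$prob <- wt[keep] / sum(wt[keep])
  rownames(ev) <- NULL
  ev
}

# Precompute cladogenesis tables for every non-null parent state.
clado_tables <- function(space, kind, j, skeleton = NULL) {
  if (is.null(skeleton)) skeleton <- clado_skeleton(space, kind)
  lapply(skeleton, function(ev)
    if (is.null(ev)) NULL else clado_weight(ev, kind, j))
}

# j-independent event tables for every non-null parent state.
clado_skeleton <- function(space, kind) {
  lapply(seq_len(space$n_states), function(i)
    if (length(space$states[[i]]) == 0) NULL
    else clado_events(space, kind, i))
}
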