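test_that("state spaces enumerate canonical subsets", {
  s4 <- build_state_space(LETTERS[1:4], include_null = FALSE)
  expect_equal(s4$n_states, 15)
  s42 <- build_state_space(LETTERS[1:4], max_range_size = 2,
                           include_null = FALSE)
  expect_equal(s42$n_states, 10)
  s3n <- build_state_space(LETTERS[1:3], include_null = TRUE)
  expect_equal(s3n$n_states, 8)
  expect_equal(s3n$labels[1], "_")
  # ordered by size then lexicographically
  expect_equal(s4$labels[1:7], c("A", "B", "C", "D", "AB", "AC", "AD"))
  expect_error(build_state_space(c("A", "A")), "duplicate")
})

test_that("anagenetic rates implement single-area gains and losses", {
  sp <- build_state_space(LETTERS[1:4])
  Q <- anagenetic_rate_matrix(sp, d = 0.3, e = 0.07)
  expect_equal(Q["B", "AB"], 0.3)
  expect_equal(Q["B", "BC"], 0.3)
  expect_equal(Q["B", "BD"], 0.3)
  expect_equal(Q["B", "_"], 0.07)
  expect_equal(Q["AB", "A"], 0.07)
  expect_equal(Q["AB", "ABC"], 0.6)   # both occupied areas feed the gain
  expect_equal(Q["B", "AC"], 0)       # only single-area changes
  expect_true(all(abs(rowSums(Q)) < 1e-12))
  expect_equal(anagenetic_rate_matrix(sp, 0, 0), 0 * Q)
  m <- matrix(1, 4, 4); m[2, 4] <- 0   # dispersal B -> D shut off
  Qm <- anagenetic_rate_matrix(sp, 0.3, 0, m)
  expect_equal(Qm["B", "BD"], 0)
  expect_gt(Qm["BC", "BCD"], 0)        # C -> D still open
  # transition probabilities are proper for a range of durations
  for (t in c(0.1, 1, 10)) {
    P <- as.matrix(Matrix::expm(Q * t))
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-9)
    expect_true(all(P >= -1e-12))
  }
})

test_that("the eigen propagator agrees with scaling-and-squaring", {
  sp <- build_state_space(LETTERS[1:4])
  for (pars in list(c(0.1, 0.02), c(1.5, 0.9), c(1e-6, 1e-8))) {
    Q <- anagenetic_rate_matrix(sp, pars[1], pars[2])
    prop <- nicherange:::make_propagator(Q)
    for (t in c(0.01, 1, 7.5))
      expect_equal(prop(t), as.matrix(Matrix::expm(Q * t)),
                   tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("cladogenesis distributions follow each model's event rules", {
  sp <- build_state_space(LETTERS[1:4])
  b <- function(lbl) match(lbl, sp$labels)
  # single-area parent, no jumps: pure sympatry
  d1 <- cladogenesis_distribution(sp, "DEC", b("B"), j = 0)
  expect_equal(nrow(d1), 1)
  expect_equal(d1$type, "sympatry")
  expect_equal(d1$prob, 1)
  # BAYAREALIKE widespread parent: the range is copied unchanged
  d2 <- cladogenesis_distribution(sp, "BAYAREALIKE", b("BC"), j = 0)
  expect_equal(nrow(d2), 1)
  expect_equal(d2$type, "copy")
  expect_equal(sp$labels[d2$left], "BC")
  # DEC widespread parent: subset sympatry + narrow vicariance only
  d3 <- cladogenesis_distribution(sp, "DEC", b("BCD"), j = 0)
  expect_setequal(unique(d3$type), c("subset", "vicariance"))
  expect_true(all(vapply(seq_len(nrow(d3)), function(i) {
    l <- sp$states[[d3$left[i]]]; r <- sp$states[[d3$right[i]]]
    min(length(l), length(r)) == 1
  }, logical(1))))
  # DIVALIKE allows widespread vicariance but no subset sympatry
  d4 <- cladogenesis_distribution(sp, "DIVALIKE", b("ABCD"), j = 0)
  expect_equal(unique(d4$type), "vicariance")
  sizes <- vapply(seq_len(nrow(d4)), function(i)
    min(length(sp$states[[d4$left[i]]]), length(sp$states[[d4$right[i]]])),
    integer(1))
  expect_true(any(sizes == 2))
  # probabilities always normalise, with and without jumps
  for (kind in c("DEC", "DEC+J", "DIVALIKE+J", "BAYAREALIKE+J"))
    for (parent in c("B", "BC", "ABD"))
      for (j in if (grepl("J", kind)) c(0, 0.1, 1, 2.9) else 0) {
        dd <- cladogenesis_distribution(sp, kind, b(parent), j)
        expect_equal(sum(dd$prob), 1, tolerance = 1e-12)
      }
  # j = 0 in a +J model collapses to the base model's table
  dj0 <- cladogenesis_distribution(sp, "DEC+J", b("BC"), j = 0)
  dbase <- cladogenesis_distribution(sp, "DEC", b("BC"), j = 0)
  expect_equal(dj0[order(dj0$left, dj0$right), c("left", "right", "prob")],
               dbase[order(dbase$left, dbase$right),
                     c("left", "right", "prob")],
               ignore_attr = TRUE)
  expect_error(cladogenesis_distribution(sp, "FOO", 2), "unknown model")
  expect_error(cladogenesis_distribution(sp, "DEC", 2, j = 0.5), "must be 0")
})

test_that("pruning likelihood matches brute-force enumeration on small cases", {
  # representative subset here; the exhaustive sweep runs in the
  # acceptance suite
  set.seed(4)
  for (case in list(
    list(n = 2, areas = 2, kind = "DEC", j = 0),
    list(n = 3, areas = 3, kind = "DIVALIKE+J", j = 1),
    list(n = 4, areas = 2, kind = "BAYAREALIKE+J", j = 1))) {
    tr <- random_dated_tree(case$n, root_age = 5, seed = case$n + 10)
    areas <- LETTERS[seq_len(case$areas)]
    ep <- flat_epochs(tr, areas)
    tips <- lapply(seq_len(case$n), function(i)
      sample(areas, sample(seq_len(case$areas), 1)))
    names(tips) <- tr$phy$tip.label
    pars <- c(d = 0.08, e = 0.03, j = case$j)
    ours <- stratified_loglik(tr, tips, case$kind, pars, ep)
    ref <- enum_biogeo_loglik(tr, tips, case$kind, pars, ep)
    expect_equal(ours, ref, tolerance = 1e-8)
  }
})

test_that("likelihood respects nesting, stratification scaling and determinism", {
  fx <- argylia_fx()
  pars <- c(d = 0.01, e = 0.005)
  base <- stratified_loglik(fx$tree, fx$ranges, "DEC", pars, fx$epochs)
  nested <- stratified_loglik(fx$tree, fx$ranges, "DEC+J",
                              c(pars, j = 0), fx$epochs)
  expect_equal(base, nested, tolerance = 1e-10)
  # multiplying multipliers by c and dividing d by c leaves lnL unchanged
  scaled <- epoch_spec(fx$epochs$boundaries,
                       lapply(fx$epochs$multipliers, function(m) 4 * m),
                       areas = fx$epochs$areas)
  lnl_scaled <- stratified_loglik(fx$tree, fx$ranges, "DEC",
                                  c(d = 0.01 / 4, e = 0.005), scaled)
  expect_equal(lnl_scaled, base, tolerance = 1e-8)
  # two runs are deterministic to full precision
  again <- stratified_loglik(fx$tree, fx$ranges, "DEC", pars, fx$epochs)
  expect_equal(base, again, tolerance = 1e-12)
  # lnL is continuous in the parameters
  for (dd in c(1e-8, -1e-8)) {
    pert <- stratified_loglik(fx$tree, fx$ranges, "DEC",
                              c(d = 0.01 + dd, e = 0.005), fx$epochs)
    expect_lt(abs(pert - base), 1e-4)
  }
  expect_error(stratified_loglik(fx$tree, fx$ranges[-1], "DEC", pars,
                                 fx$epochs), "no range coding")
})

test_that("fitting recovers nested-model dominance and the ancestral area", {
  fx <- argylia_fx()
  fit <- argylia_bayareaj_fit()
  expect_identical(fit$k, 3L)
  expect_equal(fit$AIC, 2 * fit$k - 2 * fit$lnL)
  # every marginal row is a probability vector
  rs <- rowSums(fit$marginals)
  expect_equal(unname(rs), rep(1, length(rs)), tolerance = 1e-6)
  # the most probable root state is the Central Andes B
  root <- fit$marginals[fx$tree$n_tips + 1L, ]
  expect_equal(names(which.max(root)), "B")
  # +J contains the base model: its optimum cannot be worse
  base <- fit_biogeo(fx$tree, fx$ranges, "BAYAREALIKE", fx$epochs)
  expect_gte(fit$lnL, base$lnL - 1e-6)
})

test_that("model comparison reports LRTs and pairwise weights", {
  mk <- function(kind, lnL, k) list(kind = kind, lnL = lnL, k = k)
  fits <- list(mk("DIVALIKE+J", -20.11, 3), mk("DIVALIKE", -20.61, 2),
               mk("DEC+J", -20.73, 3), mk("DEC", -19.55, 2))
  cmp <- compare_biogeo_models(fits)
  diva <- cmp[cmp$alternative == "DIVALIKE+J", ]
  expect_equal(round(diva$p, 2), 0.32)
  dec <- cmp[cmp$alternative == "DEC+J", ]
  expect_equal(dec$p, 1)                     # alternative worse than null
  eq <- compare_biogeo_models(list(mk("DEC+J", -5, 3), mk("DEC", -5, 2)))
  expect_equal(eq$p, 1)
  expect_gt(eq$AICw_null, eq$AICw_alt)       # k penalty favours the base
})
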