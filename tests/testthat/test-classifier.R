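test_that("region membership matches its vertices, edges, and examples", {
  expect_true(in_region(0, 0))    # apex, closed boundary
  expect_true(in_region(5, 3))    # upper vertex
  expect_true(in_region(5, -3))   # lower vertex
  expect_true(in_region(2.5, 1.5))  # on the upper edge
  expect_false(in_region(2.5, 2))   # 0.6 * 2.5 = 1.5 < 2
  expect_false(in_region(-1, 0))    # negative valence
  expect_false(in_region(-0.5, 0))
})

test_that("region membership agrees with the barycentric oracle on the full lattice", {
  grid <- expand.grid(v = seq(-5, 5, by = 0.5), a = seq(-5, 5, by = 0.5))
  expect_equal(nrow(grid), 441)
  ours <- in_region(grid$v, grid$a)
  oracle <- mapply(barycentric_in_triangle, grid$v, grid$a)
  expect_identical(unname(ours), unname(oracle))
})

test_that("classification rules fire in priority order", {
  cfg <- classification_config()
  # all inside, no episodes -> S via majority rule
  r <- classify_dyad(make_consensus(uniform_scores(3, 1)))
  expect_equal(r$class, "S")
  expect_equal(r$rules, "R4_majority_inside")
  expect_equal(r$inside_fraction, 1)
  # all outside with negative median valence -> U
  r <- classify_dyad(make_consensus(uniform_scores(-3, 2)))
  expect_equal(r$class, "U")
  expect_equal(r$rules, "R6_majority_outside_negative_valence")
  # food exemption: everything inside except b, overall valence positive -> S
  r <- classify_dyad(make_consensus(uniform_scores(3, 1, list(b = c(-2, 0)))))
  expect_equal(r$class, "S")
  expect_equal(r$rules, "R3_food_exemption")
  # high-arousal episodes with a majority inside -> P
  r <- classify_dyad(make_consensus(uniform_scores(3, 1, list(
    g = c(4, 5), t = c(4, 5), a = c(-1, 0), c = c(-1, 0)))))
  expect_equal(r$class, "P")
  expect_equal(r$rules, "R5_high_arousal_episodes")
  expect_equal(r$n_episodes, 2)
  # aggression anywhere -> U, before any other rule can fire
  sc <- uniform_scores(3, 1)
  sc$aggression[sc$subphase == "m"] <- TRUE
  r <- classify_dyad(make_consensus(sc))
  expect_equal(r$class, "U")
  expect_equal(r$rules, "R1_aggression")
  # valence floor in a critical sub-phase -> U even with a good majority
  r <- classify_dyad(make_consensus(uniform_scores(3, 1, list(e = c(-5, 2)))))
  expect_equal(r$class, "U")
  expect_equal(r$rules, "R2_critical_valence_floor")
  # mildly negative critical sub-phase demotes S to P, not U
  r <- classify_dyad(make_consensus(uniform_scores(3, 1, list(e = c(-1, 0)))))
  expect_equal(r$class, "P")
  expect_equal(r$rules, "R5_critical_negative_valence")
  # borderline: majority outside with non-negative median valence
  r <- classify_dyad(make_consensus(uniform_scores(2, 4)))
  expect_equal(r$class, "U")
  expect_equal(r$rules, "R7_borderline_policy")
  r <- classify_dyad(make_consensus(uniform_scores(2, 4)),
                     classification_config(borderline = "pending"))
  expect_equal(r$class, "P")
  expect_error(classify_dyad(uniform_scores(1, 1)[0, ]), "empty")
})

test_that("rule priority matches an explicit rule-enumeration oracle", {
  # Oracle: evaluate each rule predicate independently and take the first
  # that holds, mirroring the documented priority order.
  oracle <- function(sheet, cfg = classification_config()) {
    inside <- in_region(sheet$valence, sheet$arousal, cfg$region)
    frac <- mean(inside)
    med_v <- median(sheet$valence)
    crit <- sheet$subphase %in% cfg$critical
    episode <- sheet$valence > 0 &
      (sheet$arousal > cfg$high_arousal_cutoff |
         sheet$arousal > cfg$region$slope * sheet$valence)
    if (any(sheet$aggression)) return("U")
    if (any(crit & sheet$valence <= -5)) return("U")
    if (all(inside[sheet$subphase != cfg$food_exempt]) && !all(inside) &&
        med_v > 0) return("S")
    if (frac > 0.5 && sum(episode) < cfg$episode_k &&
        !any(crit & sheet$valence < 0)) return("S")
    if (frac > 0.5) return("P")
    if (med_v < 0) return("U")
    if (cfg$borderline == "unsuitable") "U" else "P"
  }
  set.seed(11)
  for (i in 1:200) {
    sc <- uniform_scores(0, 0)
    sc$valence <- snap_to_grid(rnorm(24, 1, 2.5))
    sc$arousal <- snap_to_grid(rnorm(24, 1, 2))
    sc$aggression <- runif(24) < 0.02
    cons <- make_consensus(sc)
    expect_equal(classify_dyad(cons)$class, oracle(cons))
  }
})

test_that("classification is deterministic and insertion-order invariant", {
  set.seed(3)
  sc <- uniform_scores(0, 0)
  sc$valence <- snap_to_grid(rnorm(24, 2, 2))
  sc$arousal <- snap_to_grid(rnorm(24, 1, 2))
  base <- classify_dyad(make_consensus(sc))
  for (i in 1:5) {
    perm <- sc[sample(nrow(sc)), ]
    expect_equal(classify_dyad(make_consensus(perm))$class, base$class)
  }
})

test_that("moving a score into the region never decreases the inside fraction", {
  set.seed(5)
  for (i in 1:20) {
    sc <- uniform_scores(0, 0)
    sc$valence <- snap_to_grid(rnorm(24, 0.5, 2.5))
    sc$arousal <- snap_to_grid(rnorm(24, 1, 2))
    before <- classify_dyad(make_consensus(sc))
    out_idx <- which(!before$membership$inside)
    if (!length(out_idx)) next
    j <- out_idx[1L]
    sc$valence[j] <- 3; sc$arousal[j] <- 1  # move into the region
    after <- classify_dyad(make_consensus(sc))
    expect_gte(after$inside_fraction, before$inside_fraction)
  }
})
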