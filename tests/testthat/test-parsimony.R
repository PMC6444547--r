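test_that("constant and near-constant patterns score as expected", {
  tree <- fixture_tree8()
  tips <- tree$tip.label
  all_present <- setNames(rep("present", 8), tips)
  expect_equal(site_score(all_present, tree), 0)
  one <- setNames(c("present", rep("absent", 7)), tips)
  expect_equal(site_score(one, tree), 1)
  all_unknown <- setNames(rep("unknown", 8), tips)
  s <- site_score(all_unknown, tree)
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "degenerate"))
})

test_that("DP score and scenario set equal brute force on random cases", {
  set.seed(101)
  for (rep in 1:60) {
    nt <- sample(3:7, 1)
    tree <- random_rooted_tree(nt)
    states <- setNames(sample(c("present", "absent", "unknown"), nt,
                              replace = TRUE, prob = c(.4, .4, .2)),
                       tree$tip.label)
    if (all(states == "unknown")) next
    gc <- sample(c(1, 1, 2), 1)
    lc <- sample(c(1, 1, 3), 1)
    b <- brute_parsimony(states, tree, gc, lc)
    costs <- cost_scheme(gc, lc)
    expect_equal(site_score(states, tree, costs), b$score)
    en <- enumerate_scenarios(states, tree, costs)
    expect_equal(en$n_scenarios, nrow(b$labs))
    expect_setequal(apply(en$labelings, 1, paste, collapse = ""),
                    apply(b$labs, 1, paste, collapse = ""))
  }
})

test_that("polytomies are handled natively by the DP", {
  tree <- validate_species_tree(ape::read.tree(text = "((A:1,B:1,C:1):1,(D:1,E:1):1);"))
  states <- c(A = "present", B = "present", C = "absent",
              D = "absent", E = "absent")
  b <- brute_parsimony(states, tree)
  expect_equal(site_score(states, tree), b$score)
  en <- enumerate_scenarios(states, tree)
  expect_equal(en$n_scenarios, nrow(b$labs))
})

test_that("score respects the min(#present, #absent) bound", {
  set.seed(55)
  for (rep in 1:40) {
    nt <- sample(4:8, 1)
    tree <- random_rooted_tree(nt)
    states <- setNames(sample(c("present", "absent"), nt, replace = TRUE),
                       tree$tip.label)
    s <- site_score(states, tree)
    bound <- min(sum(states == "present"), sum(states == "absent"))
    expect_gte(s, 0)
    expect_lte(s, bound)
    expect_identical(s == 0, bound == 0)
  }
})

test_that("turning a tip unknown never increases the score", {
  set.seed(77)
  for (rep in 1:40) {
    nt <- sample(4:8, 1)
    tree <- random_rooted_tree(nt)
    states <- setNames(sample(c("present", "absent"), nt, replace = TRUE),
                       tree$tip.label)
    s0 <- site_score(states, tree)
    states2 <- states
    states2[sample.int(nt, 1)] <- "unknown"
    expect_lte(site_score(states2, tree), s0)
  }
})

test_that("edge-marginal branch ranges agree with capped enumeration", {
  set.seed(202)
  for (rep in 1:40) {
    nt <- sample(4:7, 1)
    tree <- random_rooted_tree(nt)
    states <- setNames(sample(c("present", "absent", "unknown"), nt,
                              replace = TRUE, prob = c(.45, .45, .1)),
                       tree$tip.label)
    if (all(states == "unknown")) next
    sm <- toy_site_matrix(matrix(states, ncol = 1,
                                 dimnames = list(tree$tip.label, "c5p0")))
    rec <- summarize_family(sm, tree)
    b <- brute_parsimony(states, tree)
    rng <- brute_branch_ranges(b, tree)
    got <- rec$branch_events[match(rng$branch, rec$branch_events$branch), ]
    expect_equal(got$gain_min, rng$gain_min)
    expect_equal(got$gain_max, rng$gain_max)
    expect_equal(got$loss_min, rng$loss_min)
    expect_equal(got$loss_max, rng$loss_max)
    # root-presence range against the oracle's optimal labellings
    ti <- intronevo:::.tree_index(tree)
    root_states <- b$labs[, ti$root]
    expect_equal(unname(rec$root_present["min"]), as.numeric(all(root_states == 1)))
    expect_equal(unname(rec$root_present["max"]), as.numeric(any(root_states == 1)))
  }
})

test_that("the quartet tie yields ranges and an ambiguous root", {
  tree <- tree_quartet()
  # spec'd tie: present in A and C only
  sm <- toy_site_matrix(matrix(c("present", "absent", "present", "absent"),
                               ncol = 1,
                               dimnames = list(c("A", "B", "C", "D"), "c7p0")))
  rec <- summarize_family(sm, tree)
  expect_equal(rec$totals$n_changes, 2)
  expect_equal(unname(rec$root_present), c(0, 1))
  be <- rec$branch_events
  expect_true(any(be$gain_min < be$gain_max | be$loss_min < be$loss_max))
  # parallel in every optimal scenario: gains on A,C or losses on B,D
  expect_length(rec$parallel_events, 1L)
  en <- enumerate_scenarios(setNames(sm$states[, 1], rownames(sm$states)), tree)
  expect_equal(en$n_scenarios, 2)
})

test_that("shared presence in one cherry gives one change with root range [0,1]", {
  tree <- tree_quartet()
  sm <- toy_site_matrix(matrix(c("present", "present", "absent", "absent"),
                               ncol = 1,
                               dimnames = list(c("A", "B", "C", "D"), "c7p0")))
  rec <- summarize_family(sm, tree)
  expect_equal(rec$totals$n_changes, 1)
  expect_equal(unname(rec$root_present), c(0, 1))
  # brute force: two optimal scenarios — root absent with a gain on the AB
  # stem, or root present with a loss on the CD stem
  b <- brute_parsimony(setNames(sm$states[, 1], rownames(sm$states)), tree)
  expect_identical(nrow(b$labs), 2L)
  rng <- brute_branch_ranges(b, tree)
  be <- rec$branch_events[match(rng$branch, rec$branch_events$branch), ]
  expect_equal(be$gain_max, rng$gain_max)
  expect_equal(be$loss_max, rng$loss_max)
  expect_equal(c(be$gain_max[be$branch == "AB"], be$loss_max[be$branch == "CD"]),
               c(1L, 1L))
  expect_true(all(be$gain_min == 0L & be$loss_min == 0L))
  expect_true(all(be$gain_max[!(be$branch %in% c("AB"))] == 0L))
  expect_true(all(be$loss_max[!(be$branch %in% c("CD"))] == 0L))
})

test_that("family summaries handle the constructed fixture cases", {
  d <- withr::local_tempdir()
  sx <- generate_fixture_suite("cases", d, seed = 3)
  tree <- sx$tree
  rec_of <- function(nm) {
    fr <- read_family(file.path(d, "families", nm), tree, family_id = nm)
    summarize_family(fr$matrix, tree)
  }
  zero <- rec_of("zero_change")
  expect_equal(zero$totals$n_changes, 0)
  expect_equal(unname(zero$root_present), c(3, 3))
  expect_equal(zero$retained_all, 3)
  expect_true(all(zero$branch_events$gain_max == 0) &&
                all(zero$branch_events$loss_max == 0))

  sg <- rec_of("single_gain")
  expect_equal(sg$totals$n_changes, 1)
  sl <- rec_of("single_loss")
  be <- sl$branch_events
  expect_equal(be$loss_min[be$branch == "D"], 1L)
  expect_equal(be$loss_max[be$branch == "D"], 1L)
  expect_equal(sum(be$gain_max) + sum(be$loss_max[be$branch != "D"]), 0L)

  tie <- rec_of("tie")
  expect_true(any(tie$branch_events$gain_min < tie$branch_events$gain_max |
                    tie$branch_events$loss_min < tie$branch_events$loss_max))

  par <- rec_of("parallel_loss")
  expect_length(par$parallel_events, 1L)

  gap <- rec_of("gap_containing")
  expect_identical(unname(gap$sites$score), 1)
  expect_identical(sum(gap$sites$truncated), 0L)
})

test_that("aggregation adds family totals and rejects duplicate ids", {
  tree <- tree_quartet()
  mk <- function(id, cols) {
    sm <- toy_site_matrix(cols, family_id = id)
    summarize_family(sm, tree)
  }
  sp <- c("A", "B", "C", "D")
  # family totals (sites, changes): (2, 2), (1, 1), (3, 4)
  f1 <- mk("f1", matrix(c("present", "absent", "absent", "absent",
                          "absent", "present", "absent", "absent"),
                        ncol = 2, dimnames = list(sp, c("c1p0", "c2p0"))))
  f2 <- mk("f2", matrix(c("absent", "absent", "absent", "present"),
                        ncol = 1, dimnames = list(sp, "c3p0")))
  f3 <- mk("f3", matrix(c("present", "absent", "present", "absent",
                          "absent", "absent", "absent", "present",
                          "present", "present", "absent", "absent"),
                        ncol = 3, dimnames = list(sp, c("c4p0", "c5p0", "c6p1"))))
  expect_equal(f1$totals$n_changes, 2)
  expect_equal(f2$totals$n_changes, 1)
  expect_equal(f3$totals$n_changes, 4)
  agg <- aggregate_families(list(f1, f2, f3))
  expect_equal(agg$n_variable_sites, 6)
  expect_equal(agg$n_changes, 7)
  expect_equal(agg$root_present,
               c(min = sum(f1$root_present["min"], f2$root_present["min"],
                           f3$root_present["min"]),
                 max = sum(f1$root_present["max"], f2$root_present["max"],
                           f3$root_present["max"])))
  one <- aggregate_families(list(f2))
  expect_equal(one$n_changes, f2$totals$n_changes)
  expect_error(aggregate_families(list(f1, f1)), "duplicate")
})

test_that("species-specific changes sum terminal-branch events", {
  tree <- tree_quartet()
  sm <- toy_site_matrix(matrix(c("absent", "present", "present", "present"),
                               ncol = 1,
                               dimnames = list(c("A", "B", "C", "D"), "c2p1")),
                        family_id = "f")
  agg <- aggregate_families(list(summarize_family(sm, tree)))
  sc <- agg$species_changes
  expect_equal(sc$change_min[sc$species == "A"], 1)
  expect_equal(sc$change_max[sc$species == "A"], 1)
  expect_true(all(sc$change_max[sc$species != "A"] == 0))
})

test_that("Dollo-like costs forbid repeated gains", {
  tree <- tree_quartet()
  states <- c(A = "present", B = "absent", C = "present", D = "absent")
  en <- enumerate_scenarios(states, tree, cost_scheme(gain_cost = 100))
  # all optimal scenarios have exactly one gain (at the root) and two losses
  for (ev in en$events) {
    expect_lte(sum(ev$direction == "gain"), 1)
  }
  expect_equal(en$score, 2)  # root present: losses on B and D
})

test_that("rank correlation matches the closed-form Spearman formula", {
  x <- c(2, 8, 1, 9, 5)
  names(x) <- paste0("s", 1:5)
  y_conc <- rank(x); names(y_conc) <- names(x)
  expect_equal(genome_size_correlation(x, y_conc)$estimate, 1)
  y_rev <- max(rank(x)) + 1 - rank(x); names(y_rev) <- names(x)
  expect_equal(genome_size_correlation(x, y_rev)$estimate, -1)

  set.seed(13)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    a <- sample(100L, n); b <- sample(100L, n)  # untied
    names(a) <- names(b) <- paste0("s", seq_len(n))
    res <- genome_size_correlation(a, b)
    d <- rank(a) - rank(b)
    expect_equal(res$estimate, 1 - 6 * sum(d^2) / (n * (n^2 - 1)))
    # exact permutation p agrees with the reference implementation
    ref <- suppressWarnings(cor.test(a, b, method = "spearman", exact = TRUE))
    expect_equal(res$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("ties get average ranks and a finite permutation p", {
  x <- c(s1 = 4, s2 = 4, s3 = 10, s4 = 12, s5 = 1)
  y <- c(s1 = 7, s2 = 9, s3 = 9, s4 = 20, s5 = 2)
  res <- genome_size_correlation(x, y)
  expect_equal(res$estimate, cor(rank(x), rank(y)))
  expect_true(res$p.value > 0 && res$p.value <= 1)
  expect_match(res$method, "exact permutation")
  expect_error(genome_size_correlation(x[1:2], y[1:2]), "3 species")
})
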