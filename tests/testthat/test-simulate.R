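test_that("zero rates leave every tip with exactly the ancestral sites", {
  tree <- fixture_tree8()
  h <- simulate_history(tree, simulation_params(
    n_ancestral_sites = 5L, gain_rate = 0, loss_rate = 0,
    protein_length = 100L, seed = 11))
  expect_identical(nrow(h$events), 0L)
  expect_identical(ncol(h$tip_matrix), 5L)
  expect_true(all(h$tip_matrix))
  expect_identical(sort(colnames(h$tip_matrix)), sort(h$root_sites$site))
})

test_that("infinite loss rate strips every site on every branch", {
  tree <- fixture_tree8()
  h <- simulate_history(tree, simulation_params(
    n_ancestral_sites = 3L, gain_rate = 0, loss_rate = Inf,
    protein_length = 100L, seed = 7))
  expect_false(any(h$tip_matrix))
  # each ancestral site is lost once on each of the root's two child branches
  expect_identical(sum(h$events$direction == "loss"), 6L)
})

test_that("a fixed seed yields the logged single terminal gain", {
  tree <- validate_species_tree(ape::read.tree(text = "(A:1,B:1);"))
  p <- simulation_params(n_ancestral_sites = 0L, gain_rate = 0.5,
                         loss_rate = 0, protein_length = 50L, seed = 2)
  h <- simulate_history(tree, p)
  # independent replay of the Poisson draw log in simulation order
  ti <- intronevo:::.tree_index(tree)
  expected <- withr::with_seed(2, {
    invisible(sample.int(150L, 0L))  # ancestral-site draw
    log <- list()
    cur <- integer(0)
    for (v in ti$pre) {
      if (v == ti$root) next
      g <- rpois(1, 0.5 * ti$blen[v])
      gained <- integer(0)
      if (g > 0) {
        free <- setdiff(1:150, cur)
        gained <- free[sample.int(length(free), g)]
      }
      if (length(c(cur, gained)) > 0) invisible(rpois(1, 0))  # loss draw
      log[[ti$node_name[v]]] <- gained
    }
    log
  })
  drawn <- unlist(lapply(names(expected), function(b)
    if (length(expected[[b]])) setNames(expected[[b]], b)))
  expect_identical(length(drawn), 1L)
  expect_identical(nrow(h$events), 1L)
  expect_identical(h$events$branch, names(drawn))
  expect_identical(h$events$site, intronevo:::.slot_id(unname(drawn)))
  # one site, present in exactly one species
  expect_identical(ncol(h$tip_matrix), 1L)
  expect_identical(sum(h$tip_matrix), 1L)
})

test_that("identical seeds give identical histories and byte-identical files", {
  tree <- fixture_tree8()
  p <- simulation_params(n_ancestral_sites = 6L, gain_rate = 0.7,
                         loss_rate = 0.1, protein_length = 120L, seed = 99)
  h1 <- simulate_history(tree, p)
  h2 <- simulate_history(tree, p)
  expect_identical(h1$events, h2$events)
  expect_identical(h1$tip_matrix, h2$tip_matrix)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_gene_models(h1, d1, family_id = "f")
  emit_gene_models(h2, d2, family_id = "f")
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("per-branch gain counts are Poisson with mean rate x length", {
  tree <- validate_species_tree(ape::read.tree(text = "(A:2,B:2);"))
  rate <- 1.2
  gains_on_A <- vapply(1:1000, function(s) {
    h <- simulate_history(tree, simulation_params(
      n_ancestral_sites = 0L, gain_rate = rate, loss_rate = 0,
      protein_length = 100L, seed = s))
    sum(h$events$branch == "A" & h$events$direction == "gain")
  }, numeric(1))
  mu <- rate * 2
  se <- sqrt(mu / 1000)
  expect_lt(abs(mean(gains_on_A) - mu), 3 * se)
})

test_that("degenerate inputs are rejected", {
  expect_error(simulation_params(protein_length = 5), "protein_length")
  expect_error(simulation_params(n_ancestral_sites = 40, protein_length = 10),
               "slots")
  empty <- structure(list(edge = matrix(integer(0), 0, 2),
                          tip.label = character(0), Nnode = 0L),
                     class = "phylo")
  expect_error(validate_species_tree(empty), "no tips")
  # slot exhaustion during gains
  tree <- validate_species_tree(ape::read.tree(text = "(A:50,B:50);"))
  expect_error(simulate_history(tree, simulation_params(
    n_ancestral_sites = 25L, gain_rate = 3, loss_rate = 0,
    protein_length = 10L, seed = 1)), "exhausted")
})

test_that("history consistency checking catches corrupted histories", {
  tree <- tree_quartet()
  h <- simulate_history(tree, simulation_params(
    n_ancestral_sites = 3L, gain_rate = 0.5, loss_rate = 0.1,
    protein_length = 60L, seed = 5))
  expect_true(check_history(h))
  broken <- h
  broken$tip_matrix[1L, 1L] <- !broken$tip_matrix[1L, 1L]
  expect_error(check_history(broken), "inconsistent")
  # gain on a branch where the site is already present
  bad_ev <- rbind(h$events, data.frame(branch = "A",
                                       site = h$root_sites$site[1L],
                                       direction = "gain"))
  broken2 <- h
  broken2$events <- bad_ev
  expect_error(check_history(broken2), "gain of present|inconsistent")
})

test_that("planted histories realise their event plans exactly", {
  tree <- tree_quartet()
  p <- simulation_params(n_ancestral_sites = 0L, gain_rate = 0, loss_rate = 0,
                         protein_length = 60L, seed = 1)
  ev <- data.frame(branch = c("AB", "A"), site = c("r5p1", "r5p1"),
                   direction = c("gain", "loss"))
  h <- plant_history(tree, p, root_slots = integer(0), events = ev)
  expect_identical(unname(h$tip_matrix[, "r5p1"]),
                   c(FALSE, TRUE, FALSE, FALSE))  # gained in AB clade, re-lost in A
  expect_error(plant_history(tree, p, root_slots = integer(0),
                             events = data.frame(branch = "A", site = "r5p1",
                                                 direction = "loss")),
               "absent")
})
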