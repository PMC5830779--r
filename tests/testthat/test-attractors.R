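# attractor engine: walks, forward sets, terminal-SCC validation, search in
# both updating modes, basins — checked against explicit small-model oracles

test_that("forward_set computes the asynchronous closure", {
  m <- parse_model(c("a = b", "b = a"))
  # fixed point -> itself
  expect_equal(nrow(forward_set(m, c(a = 0L, b = 0L))), 1)
  # transient state reaches both fixed points (but not its mirror transient)
  fs <- forward_set(m, c(a = 0L, b = 1L))
  expect_equal(nrow(fs), 3)
  expect_setequal(apply(fs, 1, paste, collapse = ""), c("00", "01", "11"))
  # constant 1-node model
  m1 <- parse_model("c = 1")
  expect_equal(nrow(forward_set(m1, c(c = 0L))), 2)
  expect_equal(nrow(forward_set(m1, c(c = 1L))), 1)
  # cap triggers the candidate-too-large error
  expect_error(forward_set(m, c(a = 0L, b = 1L), cap = 2), "cap")
})

test_that("validate_terminal_scc accepts attractors and rejects closed transients", {
  m <- parse_model(c("a = b", "b = a"))
  expect_true(validate_terminal_scc(m, matrix(c(0L, 0L), 1)))
  expect_true(validate_terminal_scc(m, matrix(c(1L, 1L), 1)))
  # the closure of a transient is closed but not strongly connected
  fs <- forward_set(m, c(a = 0L, b = 1L))
  expect_false(validate_terminal_scc(m, fs))
  # a strict subset that leaks is rejected by the closure condition
  expect_false(validate_terminal_scc(m, matrix(c(0L, 1L), 1)))
  # printed physiological fixed point of the example network
  ex <- example_network()
  s5 <- c(do = 1L, factory = 1L, energy = 1L, locker = 0L, releaser = 1L,
          sequester = 0L, activator = 1L, effector = 1L, task = 1L)
  expect_true(validate_terminal_scc(ex$physio, matrix(s5, 1)))
})

test_that("random_walk honours maxk, fixed points, and early stopping", {
  ex <- example_network()
  s <- c(do = 1L, factory = 0L, energy = 1L, locker = 1L, releaser = 0L,
         sequester = 1L, activator = 0L, effector = 1L, task = 0L)
  expect_identical(random_walk(ex$patho, s, maxk = 0), s)
  fp <- c(do = 0L, factory = 0L, energy = 0L, locker = 1L, releaser = 0L,
          sequester = 1L, activator = 0L, effector = 0L, task = 0L)
  set.seed(4)
  expect_identical(random_walk(ex$physio, fp, maxk = 500), fp)
  # pathological variant: any do=1, factory=0 start ends in the heavily
  # pathological fixed point (its forward set is that single state)
  set.seed(8)
  a_patho2 <- c(do = 1L, factory = 0L, energy = 0L, locker = 0L, releaser = 1L,
                sequester = 0L, activator = 1L, effector = 1L, task = 1L)
  for (i in 1:5) {
    start <- c(1L, 0L, sample(0:1, 7, replace = TRUE))
    names(start) <- ex$patho$model$nodes
    final <- random_walk(ex$patho, start, maxk = 1000)
    fs <- forward_set(ex$patho, final)
    expect_equal(nrow(fs), 1)
    expect_identical(fs[1, ], a_patho2)
  }
})

test_that("async search equals the exhaustive terminal-SCC oracle", {
  for (i in 1:20) {
    h <- if (i %% 4 == 0) 3L else 2L
    n <- sample(3:6, 1)
    m <- random_model(n, h = h, depth = 2, seed = 500 + i)
    cfg <- search_config("async", max_states = h^n, max_walk = 300,
                         seed = 600 + i, retries = 5)
    aset <- find_attractors(m, cfg)
    expect_identical(aset_keys(aset), oracle_async_attractors(m),
                     label = sprintf("model seed %d", 500 + i))
    # definitional predicate holds for every returned attractor
    for (a in aset$attractors)
      expect_true(validate_terminal_scc(m, a$states))
    # attractor state sets are pairwise disjoint
    all_keys <- unlist(lapply(aset$attractors, function(a)
      apply(a$states, 1, paste, collapse = "")))
    expect_equal(anyDuplicated(all_keys), 0)
  }
})

test_that("sync search equals brute-force cycle enumeration", {
  # a 3-node rotation has two fixed points and two 3-cycles
  m <- parse_model(c("a = b", "b = c", "c = a"))
  aset <- find_attractors(m, search_config("sync", max_states = 8))
  expect_equal(length(aset$attractors), 4)
  expect_identical(aset_keys(aset), oracle_sync_attractors(m))
  lens <- sort(vapply(aset$attractors, function(a) nrow(a$states), integer(1)))
  expect_equal(lens, c(1L, 1L, 3L, 3L))
  # random models
  for (i in 1:10) {
    m <- random_model(sample(3:6, 1), h = 2, depth = 2, seed = 700 + i)
    aset <- find_attractors(m, search_config("sync", max_states = 2^6))
    expect_identical(aset_keys(aset), oracle_sync_attractors(m))
  }
})

test_that("sync cycles are canonical rotations starting at the smallest state", {
  m <- parse_model(c("a = b", "b = c", "c = a"))
  aset <- find_attractors(m, search_config("sync", max_states = 8))
  cyc <- Filter(function(a) nrow(a$states) == 3, aset$attractors)[[1]]
  keys <- apply(cyc$states, 1, paste, collapse = "")
  expect_equal(keys[1], min(keys))
  # consecutive rows follow the synchronous map
  for (i in 1:2)
    expect_identical(unname(sync_update(m, cyc$states[i, ])),
                     unname(cyc$states[i + 1, ]))
})

test_that("basin percentages are exact for deterministic partitions", {
  # two isolated fixed points split the space evenly
  m <- parse_model("a = a")
  aset <- find_attractors(m, search_config("async", max_states = 2,
                                           max_walk = 10, seed = 1))
  expect_equal(unname(basin_percentages(aset)), c(50, 50))
  expect_equal(sum(basin_percentages(aset)), 100)
  m2 <- parse_model("b = 1")
  aset2 <- find_attractors(m2, search_config("async", max_states = 2,
                                             max_walk = 10, seed = 1))
  expect_equal(unname(basin_percentages(aset2)), 100)
})

test_that("walk failures are retried, counted unresolved, or escalate", {
  m <- parse_model(c("a = b", "b = a"))
  # maxk = 0: transient starts can never validate; fixed points still resolve
  cfg <- search_config("async", max_states = 4, max_walk = 0, seed = 2,
                       retries = 2)
  expect_warning(aset <- find_attractors(m, cfg), "2 of 4 start states unresolved")
  expect_equal(aset$unresolved, 2)
  expect_equal(aset$total, 4)
  expect_equal(unname(basin_percentages(aset)), c(50, 50)) # over resolved only
  # all starts failing is a hard error
  m_only_transient <- parse_model(c("a = b", "b = a"))
  starts <- matrix(c(0L, 1L, 1L, 0L), 2, byrow = TRUE)
  cm <- bnscreen:::compile_variant(as_variant(m_only_transient))
  res <- bnscreen:::cpp_find_attractors_async(cm$programs, starts, 2L, 0L, 1L, 1e6)
  expect_true(all(res$credits == 0))
})

test_that("search is reproducible under a fixed seed", {
  ex <- example_network()
  cfg <- search_config("async", max_states = 512, max_walk = 1000, seed = 33)
  a1 <- find_attractors(ex$patho, cfg)
  a2 <- find_attractors(ex$patho, cfg)
  expect_identical(aset_keys(a1), aset_keys(a2))
  expect_identical(a1$counts, a2$counts)
})

test_that("projection strings collapse attractor state sets per node", {
  ex <- example_network()
  aset <- find_attractors(ex$physio, example_search(21))
  proj <- project_attractors(aset, EXAMPLE_PROJ)
  expect_setequal(proj, EXAMPLE_PHYSIO_PROJ)
  expect_error(project_attractors(aset, "nosuch"), "unknown projection")
})

test_that("walk-based basin estimates match exact absorption probabilities", {
  # Ground truth for the one-walk-per-start crediting scheme: the absorption
  # probabilities of the uniform single-node-update chain, solved exactly.
  ex <- example_network()
  exact <- exact_absorption_basins(ex$patho)
  physio_keys <- names(exact_absorption_basins(ex$physio))
  # exact physiological part of the pathological space (the screen's x)
  x_exact <- sum(exact[names(exact) %in% physio_keys])
  expect_equal(x_exact, 56.85, tolerance = 1e-3)
  # engine estimates, averaged over replicate searches, converge on it
  est <- rowMeans(vapply(1:12, function(k) {
    aset <- find_attractors(ex$patho, example_search(8200 + k))
    keys <- vapply(aset$attractors, `[[`, character(1), "key")
    basin_percentages(aset)[match(names(exact), keys)]
  }, numeric(length(exact))))
  expect_true(all(abs(est - exact) < 1.5))
  # the borderline bullet do[0]: expected gain barely above delta = 5
  tv <- apply_bullet(ex$patho, bullet("do", 0))
  exact_test <- exact_absorption_basins(tv)
  y_exact <- sum(exact_test[names(exact_test) %in% physio_keys])
  expect_equal(y_exact - x_exact, 5.68, tolerance = 1e-2)
})
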