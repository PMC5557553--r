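small_naming_cfg <- function(repeats = 2, phase2 = "none", master_seed = 1,
                             n_agents = 4, iterations_per_node = 50) {
  pair <- make_discrete_environment_pair(8, 3, seed = 2)
  experiment_config(
    game_kind = "naming",
    topology = build_complete(n_agents),
    environment = pair$A,
    environment2 = if (phase2 == "environment-A-to-B") pair$B else NULL,
    iterations_per_node = iterations_per_node,
    phase2 = phase2,
    repeats = repeats,
    probe_interval = 100,
    probe_games = 40,
    master_seed = master_seed
  )
}

test_that("interaction edges are drawn uniformly and reproducibly", {
  t4 <- build_complete(4)
  set.seed(2)
  draws <- replicate(12000, paste(sort(select_interaction(t4)), collapse = "-"))
  freq <- table(draws) / 12000
  expect_length(freq, 6)
  expect_true(all(abs(freq - 1 / 6) < 0.02))

  star <- build_star(5)
  set.seed(3)
  for (i in 1:50) expect_true(1L %in% select_interaction(star))

  set.seed(7); e1 <- replicate(20, select_interaction(t4))
  set.seed(7); e2 <- replicate(20, select_interaction(t4))
  expect_identical(e1, e2)
})

test_that("run_phase is deterministic, sized correctly, and guards inputs", {
  denv <- make_discrete_environment_pair(8, 3, seed = 2)$A
  t4 <- build_complete(4)
  mk_pop <- function() lapply(1:4, function(i) new_naming_agent())

  pop <- mk_pop()
  reset_word_counter(); set.seed(11)
  r1 <- run_phase(pop, t4, denv, 300, "naming",
                  probe_specs = list(CS_S = "window",
                                     CS_G = list(pairs = "all-pairs", env = denv)),
                  probe_interval = 100, probe_games = 30)
  expect_equal(sort(unique(r1$iteration)), c(100, 200, 300))
  expect_setequal(unique(r1$series), c("CS_S", "CS_G"))
  final1 <- agent_to_json(pop[[1]])

  pop2 <- mk_pop()
  reset_word_counter(); set.seed(11)
  r2 <- run_phase(pop2, t4, denv, 300, "naming",
                  probe_specs = list(CS_S = "window",
                                     CS_G = list(pairs = "all-pairs", env = denv)),
                  probe_interval = 100, probe_games = 30)
  expect_identical(r1, r2)
  expect_identical(as.character(agent_to_json(pop2[[1]])),
                   as.character(final1))

  # zero iterations: empty fragment, agents untouched
  pop3 <- mk_pop()
  before <- agent_to_json(pop3[[2]])
  r0 <- run_phase(pop3, t4, denv, 0, "naming")
  expect_equal(nrow(r0), 0)
  expect_identical(as.character(agent_to_json(pop3[[2]])),
                   as.character(before))

  expect_error(run_phase(mk_pop(), build_complete(5), denv, 10, "naming"),
               "population size")
})

test_that("frozen probes measure without perturbing the population", {
  denv <- make_discrete_environment_pair(8, 0, seed = 5)$A
  pop <- lapply(1:4, function(i) new_naming_agent())
  set.seed(4)
  expect_equal(probe_cs(pop, "all-pairs", denv, 50, "naming"), 0)

  # converged identical agents: every probe succeeds
  reset_word_counter()
  words <- lapply(as.character(denv), function(s) new_word())
  for (a in pop) {
    for (i in seq_along(denv)) {
      naming_update_association(a, as.character(denv)[i], words[[i]], 0.9)
    }
  }
  state <- vapply(pop, function(a) as.character(agent_to_json(a)), character(1))
  expect_equal(probe_cs(pop, "all-pairs", denv, 100, "naming"), 1)
  t4 <- build_complete(4)
  expect_equal(probe_cs(pop, "edges", denv, 50, "naming", topology = t4), 1)
  after <- vapply(pop, function(a) as.character(agent_to_json(a)), character(1))
  expect_identical(after, state)
})

test_that("experiments produce tidy per-replicate trajectories deterministically", {
  cfg <- small_naming_cfg(repeats = 3)
  traj <- run_experiment(cfg)
  expect_setequal(names(traj),
                  c("replicate", "iteration", "series", "value", "phase"))
  expect_setequal(unique(traj$replicate), 1:3)
  expect_true(all(traj$value >= 0 & traj$value <= 1))
  expect_true(all(traj$phase == 1L))

  traj2 <- run_experiment(cfg)
  expect_identical(traj, traj2)

  # distinct replicate seeds give distinct trajectories
  v1 <- traj$value[traj$replicate == 1]
  v2 <- traj$value[traj$replicate == 2]
  expect_false(identical(v1, v2))
})

test_that("phase-2 designs switch topology or environment mid-run", {
  cfg <- small_naming_cfg(repeats = 1, phase2 = "topology-to-complete")
  traj <- run_experiment(cfg)
  expect_setequal(unique(traj$phase), c(1L, 2L))
  expect_equal(max(traj$iteration), 2 * 50 * 4)

  cfge <- small_naming_cfg(repeats = 1, phase2 = "environment-A-to-B")
  traje <- run_experiment(cfge)
  expect_setequal(unique(traje$series), c("CS_A", "CS_B"))
  expect_setequal(unique(traje$phase), c(1L, 2L))
})

test_that("population checkpoints restore exact state for phase-2 restarts", {
  denv <- make_discrete_environment_pair(8, 3, seed = 2)$A
  t4 <- build_complete(4)
  run1 <- function() {
    pop <- lapply(1:4, function(i) new_naming_agent())
    reset_word_counter(); set.seed(21)
    run_phase(pop, t4, denv, 200, "naming", probe_interval = 200)
    pop
  }
  # uninterrupted: phase 1 then phase 2 under a fresh seed
  pop_a <- run1()
  set.seed(99)
  rec_a <- run_phase(pop_a, t4, denv, 200, "naming", probe_interval = 100)
  # checkpointed: phase 1, save, restore, same phase-2 seed
  pop_b <- run1()
  path <- withr::local_tempfile(fileext = ".json")
  write_population(pop_b, path)
  pop_c <- read_population(path)
  set.seed(99)
  rec_c <- run_phase(pop_c, t4, denv, 200, "naming", probe_interval = 100)
  expect_identical(rec_a, rec_c)
  expect_identical(
    vapply(pop_c, function(a) as.character(agent_to_json(a)), character(1)),
    vapply(pop_a, function(a) as.character(agent_to_json(a)), character(1)))
})

test_that("config files drive experiments end to end", {
  cfg_yaml <- paste(
    "game_kind: naming",
    "topology: {kind: complete, n_nodes: 4}",
    "environment: {type: discrete-pair, n_stimuli: 8, n_shared: 3, seed: 2}",
    "iterations_per_node: 25",
    "phase2: none",
    "repeats: 2",
    "probe_interval: 50",
    "probe_games: 20",
    "master_seed: 5",
    sep = "\n")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(cfg_yaml, path)
  traj <- run_experiment_config(path)
  expect_setequal(unique(traj$replicate), 1:2)
  expect_true(all(traj$value >= 0 & traj$value <= 1))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(traj, csv)
  back <- read_trajectories(csv)
  expect_equal(back$value, traj$value)
})

test_that("per-game event logs capture one JSON line per game", {
  denv <- make_discrete_environment_pair(8, 3, seed = 2)$A
  pop <- lapply(1:4, function(i) new_naming_agent())
  log <- withr::local_tempfile(fileext = ".jsonl")
  reset_word_counter(); set.seed(2)
  run_phase(pop, build_complete(4), denv, 30, "naming", probe_interval = 30,
            log_file = log)
  lines <- readLines(log)
  expect_length(lines, 30)
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("iteration", "speaker", "hearer", "branch", "success")
                  %in% names(rec)))
})
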