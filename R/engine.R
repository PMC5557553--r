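#' Select an interaction edge
#'
#' Uniform draw over the topology's edges, using the current RNG stream.
#'
#' @param t A `topology`.
#' @return Integer pair of adjacent nodes.
#' @export
select_interaction <- function(t) {
  t$edges[sample.int(nrow(t$edges), 1L), ]
}

play_game <- function(game_kind, speaker, hearer, ctx, learn = TRUE) {
  if (game_kind == "guessing") guessing_game(speaker, hearer, ctx, learn)
  else naming_game(speaker, hearer, ctx, learn)
}

sample_any_context <- function(game_kind, env) {
  if (game_kind == "guessing") sample_context(env)
  else sample_discrete_context(env)
}

#' Measure communicative success with frozen probe games
#'
#' Plays `n_probe_games` evaluation games with `learn = FALSE` -- agent
#' state, including success windows, is untouched -- and returns the success
#' fraction. Pairs come either from the full set of agent pairs
#' (`"all-pairs"`, the global measure) or from the edges of a topology
#' (`"edges"`, the network-specific measure); roles within a probe pair are
#' assigned uniformly.
#'
#' @param population List of agents.
#' @param pair_source `"all-pairs"` or `"edges"`.
#' @param env Environment to draw probe stimuli from.
#' @param n_probe_games Number of evaluation games (>= 1).
#' @param game_kind `"guessing"` or `"naming"`.
#' @param topology Required when `pair_source = "edges"`.
#' @return Success fraction in \[0, 1\].
#' @export
probe_cs <- function(population, pair_source = c("all-pairs", "edges"), env,
                     n_probe_games, game_kind = c("guessing", "naming"),
                     topology = NULL) {
  pair_source <- match.arg(pair_source)
  game_kind <- match.arg(game_kind)
  if (n_probe_games < 1) stop("n_probe_games must be >= 1", call. = FALSE)
  n <- length(population)
  wins <- 0L
  for (g in seq_len(n_probe_games)) {
    if (pair_source == "all-pairs") {
      pair <- sample.int(n, 2L)
    } else {
      e <- select_interaction(topology)
      pair <- if (stats::runif(1) < 0.5) e else rev(e)
    }
    ctx <- sample_any_context(game_kind, env)
    out <- play_game(game_kind, population[[pair[1]]], population[[pair[2]]],
                     ctx, learn = FALSE)
    if (out$success) wins <- wins + 1L
  }
  wins / n_probe_games
}

# one probe specification: either "window" (mean trailing CS over agents) or
# list(pairs = "all-pairs"/"edges", env = <environment>)
eval_probe <- function(spec, population, t, game_kind, probe_games) {
  if (identical(spec, "window")) {
    return(mean(vapply(population, agent_cs, numeric(1))))
  }
  probe_cs(population, spec$pairs, spec$env, probe_games, game_kind,
           topology = t)
}

#' Run one training phase
#'
#' Plays `n_iterations` games, one per iteration: an edge is drawn uniformly,
#' roles are assigned by the topology's role-bias policy, a context is
#' sampled from the environment, and the game is played with learning on.
#' At every `probe_interval`-th iteration (and at the last one) each probe
#' series in `probe_specs` is measured.
#'
#' @param population List of agents, one per topology node.
#' @param t A `topology` with `length(population)` nodes.
#' @param env Training environment.
#' @param n_iterations Number of games.
#' @param game_kind `"guessing"` or `"naming"`.
#' @param probe_specs Named list of probe specifications: the string
#'   `"window"` (mean trailing per-agent CS) or
#'   `list(pairs = "all-pairs"|"edges", env = <environment>)` for frozen
#'   probe games.
#' @param probe_interval Iterations between probe points (default 100).
#' @param probe_games Probe games per probe point (default `20 * n` agents).
#' @param log_file Optional path: per-game JSON-lines event log (iteration,
#'   speaker, hearer, branch, word, success).
#' @return data.frame with columns `iteration`, `series`, `value`.
#' @export
run_phase <- function(population, t, env, n_iterations,
                      game_kind = c("guessing", "naming"),
                      probe_specs = list(CS_S = "window"),
                      probe_interval = 100, probe_games = NULL,
                      log_file = NULL) {
  game_kind <- match.arg(game_kind)
  if (length(population) != t$n_nodes)
    stop("population size must equal the number of topology nodes",
         call. = FALSE)
  if (is.null(probe_games)) probe_games <- 20L * length(population)
  log_con <- if (!is.null(log_file)) file(log_file, open = "a") else NULL
  on.exit(if (!is.null(log_con)) close(log_con))
  rec_it <- integer(0); rec_series <- character(0); rec_val <- numeric(0)
  if (n_iterations < 1)
    return(data.frame(iteration = integer(0), series = character(0),
                      value = numeric(0)))
  for (it in seq_len(n_iterations)) {
    e <- select_interaction(t)
    roles <- assign_roles(t, e)
    ctx <- sample_any_context(game_kind, env)
    out <- play_game(game_kind, population[[roles[[1]]]],
                     population[[roles[[2]]]], ctx, learn = TRUE)
    if (!is.null(log_con)) {
      writeLines(jsonlite::toJSON(list(
        iteration = it, speaker = roles[[1]], hearer = roles[[2]],
        branch = out$failure_branch, word = out$word, success = out$success
      ), auto_unbox = TRUE), log_con)
    }
    if (it %% probe_interval == 0 || it == n_iterations) {
      for (s in names(probe_specs)) {
        rec_it <- c(rec_it, it)
        rec_series <- c(rec_series, s)
        rec_val <- c(rec_val, eval_probe(probe_specs[[s]], population, t,
                                         game_kind, probe_games))
      }
    }
  }
  data.frame(iteration = rec_it, series = rec_series, value = rec_val)
}

#' Experiment configuration
#'
#' Bundles everything [run_experiment()] needs. The three canonical designs:
#' static agreement (`phase2 = "none"`, probes `CS_S` + `CS_G`), topology
#' change (`phase2 = "topology-to-complete"`: phase 2 retrains the same
#' agents on a complete graph), and environment change
#' (`phase2 = "environment-A-to-B"`: same topology, stimuli switch from
#' `environment` to `environment2`; probes `CS_A` + `CS_B` on the training
#' topology's edges).
#'
#' @param game_kind `"guessing"` or `"naming"`.
#' @param topology A `topology`, or a function `function(seed)` returning one
#'   (rebuilt per replicate with a derived seed).
#' @param environment Training environment (phase-1 environment for the
#'   environment-change design).
#' @param environment2 Phase-2 environment (environment-change design only).
#' @param iterations_per_node Training iterations per node per phase
#'   (default 625); total per phase is `iterations_per_node * n_nodes`.
#' @param phase2 `"none"`, `"topology-to-complete"` or
#'   `"environment-A-to-B"`.
#' @param repeats Number of replicates (default 10).
#' @param probe_interval Iterations between probe points (default 100).
#' @param probe_games Probe games per probe point (default `20 * n_nodes`).
#' @param master_seed Master seed; per-replicate seeds are derived from it.
#' @param agent_params Named list passed to [new_agent()] /
#'   [new_naming_agent()].
#' @return An `experiment_config`.
#' @export
experiment_config <- function(game_kind = c("guessing", "naming"),
                              topology, environment, environment2 = NULL,
                              iterations_per_node = 625,
                              phase2 = c("none", "topology-to-complete",
                                         "environment-A-to-B"),
                              repeats = 10, probe_interval = 100,
                              probe_games = NULL, master_seed = 1,
                              agent_params = list()) {
  game_kind <- match.arg(game_kind)
  phase2 <- match.arg(phase2)
  if (iterations_per_node < 1) stop("iterations_per_node must be positive",
                                    call. = FALSE)
  if (repeats < 1) stop("repeats must be >= 1", call. = FALSE)
  if (phase2 == "environment-A-to-B" && is.null(environment2))
    stop("environment-A-to-B requires environment2", call. = FALSE)
  structure(list(game_kind = game_kind, topology = topology,
                 environment = environment, environment2 = environment2,
                 iterations_per_node = iterations_per_node, phase2 = phase2,
                 repeats = repeats, probe_interval = probe_interval,
                 probe_games = probe_games, master_seed = master_seed,
                 agent_params = agent_params),
            class = "experiment_config")
}

make_population <- function(n, game_kind, agent_params) {
  maker <- if (game_kind == "guessing") new_agent else new_naming_agent
  lapply(seq_len(n), function(i) do.call(maker, agent_params))
}

#' Run a full experiment
#'
#' For each replicate (with a seed derived deterministically from the master
#' seed): build the topology and a fresh population, run phase 1 for
#' `iterations_per_node * n_nodes` games, then -- depending on `phase2` --
#' either stop, swap the topology for a complete graph over the same agents,
#' or swap the environment, and run phase 2 for the same number of games.
#' Probe series are chosen by design: `CS_S` (mean trailing per-agent CS) and
#' `CS_G` (frozen all-pairs probes) for the static and topology-change
#' designs; `CS_A` and `CS_B` (frozen probes on the training topology's
#' edges, stimuli from the respective environment) for the environment-change
#' design.
#'
#' @param cfg An [experiment_config()].
#' @return Tidy data.frame of trajectories: `replicate`, `iteration`
#'   (cumulative across phases), `series`, `value`, `phase`.
#' @export
run_experiment <- function(cfg) {
  seeds <- with_seed(cfg$master_seed,
                     sample.int(.Machine$integer.max, cfg$repeats))
  out <- vector("list", cfg$repeats)
  for (r in seq_len(cfg$repeats)) {
    out[[r]] <- run_replicate(cfg, seeds[r], r)
  }
  do.call(rbind, out)
}

run_replicate <- function(cfg, seed, replicate_id) {
  reset_word_counter()
  set.seed(seed)
  t1 <- if (is.function(cfg$topology)) cfg$topology(seed) else cfg$topology
  n <- t1$n_nodes
  population <- make_population(n, cfg$game_kind, cfg$agent_params)
  n_iter <- cfg$iterations_per_node * n
  env1 <- cfg$environment
  probes <- if (cfg$phase2 == "environment-A-to-B") {
    list(CS_A = list(pairs = "edges", env = env1),
         CS_B = list(pairs = "edges", env = cfg$environment2))
  } else {
    list(CS_S = "window", CS_G = list(pairs = "all-pairs", env = env1))
  }
  ph1 <- run_phase(population, t1, env1, n_iter, cfg$game_kind, probes,
                   cfg$probe_interval, cfg$probe_games)
  ph1$phase <- 1L
  if (cfg$phase2 == "none") {
    ph1$replicate <- replicate_id
    return(ph1[, c("replicate", "iteration", "series", "value", "phase")])
  }
  if (cfg$phase2 == "topology-to-complete") {
    t2 <- build_complete(n)
    env2 <- env1
  } else {
    t2 <- t1
    env2 <- cfg$environment2
  }
  ph2 <- run_phase(population, t2, env2, n_iter, cfg$game_kind, probes,
                   cfg$probe_interval, cfg$probe_games)
  ph2$phase <- 2L
  ph2$iteration <- ph2$iteration + n_iter
  res <- rbind(ph1, ph2)
  res$replicate <- replicate_id
  res[, c("replicate", "iteration", "series", "value", "phase")]
}

#' Write / read trajectory tables as CSV
#'
#' @param traj Tidy trajectory data.frame from [run_experiment()].
#' @param path CSV path.
#' @return `write_trajectories`: invisibly `path`; `read_trajectories`: the
#'   data.frame.
#' @export
write_trajectories <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run an experiment described by a YAML or JSON config file
#'
#' The file mirrors [experiment_config()] fields, with `topology` and
#' `environment` given declaratively, e.g.:
#' \preformatted{
#' game_kind: naming
#' topology: {kind: complete, n_nodes: 16}
#' environment: {type: discrete-pair, n_stimuli: 16, n_shared: 5, seed: 1}
#' iterations_per_node: 625
#' phase2: none
#' repeats: 10
#' master_seed: 1
#' }
#' Topology kinds: `complete` (`n_nodes`), `star` (`n_leaves`, `mode`),
#' `regular-optimized` (`n_nodes`, `objective`, `direction`, `seed`,
#' `n_steps`).
#' Environment types: `base` (`n_chips`, `seed`), `weighted-pair`
#' (`n_chips`, `n_env`, `seed`; yields A as `environment` and B as
#' `environment2`), `discrete-pair` (`n_stimuli`, `n_shared`, `seed`).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return Tidy trajectory data.frame (see [run_experiment()]).
#' @export
run_experiment_config <- function(path) {
  cfg_list <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
              else jsonlite::read_json(path, simplifyVector = TRUE)
  ts <- cfg_list$topology
  # note: the key is n_nodes, not n -- YAML 1.1 parses a bare `n` as boolean
  topo <- switch(ts$kind,
    "complete" = build_complete(ts$n_nodes),
    "star" = build_star(ts$n_leaves, mode = ts$mode %||% "balanced"),
    "regular-optimized" = optimize_regular_topology(
      ts$n_nodes, ts$degree %||% 3, ts$objective %||% "avg-betweenness",
      ts$direction %||% "minimize", seed = ts$seed %||% 1,
      n_steps = ts$n_steps %||% 2e5),
    stop("unknown topology kind: ", ts$kind, call. = FALSE)
  )
  es <- cfg_list$environment
  env2 <- NULL
  env <- switch(es$type,
    "base" = base_environment(
      generate_base_chipset(es$n_chips %||% 1269, es$seed %||% 1)),
    "weighted-pair" = {
      base <- generate_base_chipset(es$n_chips %||% 1269, es$seed %||% 1)
      pair <- make_environment_pair(base, n_env = es$n_env %||% 600,
                                    seed = es$seed %||% 1)
      env2 <- pair$B
      pair$A
    },
    "discrete-pair" = {
      pair <- make_discrete_environment_pair(es$n_stimuli %||% 16,
                                             es$n_shared %||% 5,
                                             es$seed %||% 1)
      env2 <- pair$B
      pair$A
    },
    stop("unknown environment type: ", es$type, call. = FALSE)
  )
  cfg <- experiment_config(
    game_kind = cfg_list$game_kind %||% "guessing",
    topology = topo, environment = env, environment2 = env2,
    iterations_per_node = cfg_list$iterations_per_node %||% 625,
    phase2 = cfg_list$phase2 %||% "none",
    repeats = cfg_list$repeats %||% 10,
    probe_interval = cfg_list$probe_interval %||% 100,
    probe_games = cfg_list$probe_games,
    master_seed = cfg_list$master_seed %||% 1
  )
  run_experiment(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
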