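# chronological history extraction (oldest first) from the circular buffer
history_vector <- function(agent) {
  n <- agent$hist_n
  if (n == 0L) return(integer(0))
  len <- agent$history_len
  pos <- agent$hist_pos
  if (n < len) return(agent$hist[seq_len(n)])
  idx <- ((pos + seq_len(len) - 1L) %% len) + 1L
  agent$hist[idx]
}

agent_to_list <- function(agent) {
  if (inherits(agent, "lg_naming_agent")) {
    return(list(
      type = "naming_agent",
      history_len = agent$history_len,
      lexicon = list(stimulus = agent$lex_stim, word = agent$lex_word,
                     strength = agent$lex_s),
      history = history_vector(agent)
    ))
  }
  n <- agent$n_units
  list(
    type = "agent",
    params = list(sigma = agent$sigma, beta = agent$beta, delta = agent$delta,
                  init_weight = agent$init_weight,
                  history_len = agent$history_len, dim = agent$dim),
    n_categories = agent$n_cat,
    units = list(
      center = if (n) unname(agent$centers[seq_len(n), , drop = FALSE])
               else matrix(numeric(0), 0, agent$dim),
      weight = agent$w[seq_len(n)],
      category = agent$ucat[seq_len(n)]
    ),
    lexicon = list(category = agent$lex_cat, word = agent$lex_word,
                   strength = agent$lex_s),
    history = history_vector(agent)
  )
}

agent_from_list <- function(x) {
  if (identical(x$type, "naming_agent")) {
    a <- new_naming_agent(history_len = x$history_len)
    a$lex_stim <- as.character(x$lexicon$stimulus)
    a$lex_word <- as.integer(x$lexicon$word)
    a$lex_s <- as.numeric(x$lexicon$strength)
  } else {
    p <- x$params
    a <- new_agent(sigma = p$sigma, beta = p$beta, delta = p$delta,
                   init_weight = p$init_weight, history_len = p$history_len,
                   dim = p$dim)
    n <- length(x$units$weight)
    cm <- x$units$center
    if (!is.matrix(cm)) cm <- matrix(unlist(cm), ncol = p$dim, byrow = TRUE)
    for (i in seq_len(n)) add_unit(a, cm[i, ], x$units$category[i])
    a$w[seq_len(n)] <- as.numeric(x$units$weight)
    a$n_cat <- as.integer(x$n_categories)
    a$lex_cat <- as.integer(x$lexicon$category)
    a$lex_word <- as.integer(x$lexicon$word)
    a$lex_s <- as.numeric(x$lexicon$strength)
  }
  for (h in x$history) record_outcome(a, as.logical(h))
  a
}

#' Serialize an agent to JSON
#'
#' Full-precision JSON snapshot of an agent's categories (unit centers,
#' weights), lexicon and chronological outcome history; used for
#' checkpointing between experiment phases and for exact state comparison
#' (frozen probes must leave the serialized form byte-identical).
#'
#' @param agent An `lg_agent` or `lg_naming_agent`.
#' @return A JSON string (class `json`).
#' @export
agent_to_json <- function(agent) {
  # I(17) significant digits: doubles survive the text round-trip exactly
  jsonlite::toJSON(agent_to_list(agent), auto_unbox = TRUE, digits = I(17),
                   null = "null")
}

#' Restore an agent from JSON
#'
#' @param json A JSON string from [agent_to_json()].
#' @return The restored agent.
#' @export
agent_from_json <- function(json) {
  agent_from_list(jsonlite::fromJSON(json, simplifyVector = TRUE))
}

#' Checkpoint a population to a JSON file
#'
#' Stores every agent plus the global word counter, so a phase-2 run
#' restarted from the checkpoint (with the RNG re-seeded identically)
#' reproduces an uninterrupted run exactly.
#'
#' @param population List of agents.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_population <- function(population, path) {
  obj <- list(word_counter = .lingnet_state$word_counter,
              agents = lapply(population, agent_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Restore a population checkpoint
#'
#' @param path Path written by [write_population()].
#' @return List of agents (the global word counter is restored as a side
#'   effect).
#' @export
read_population <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  reset_word_counter(obj$word_counter)
  lapply(obj$agents, agent_from_list)
}
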