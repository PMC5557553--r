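#' Create a categorizing agent
#'
#' An agent holds (i) a categorization system: a set of categories, each an
#' adaptive network of Gaussian reactive units (a unit has a center `m` in
#' stimulus space and a non-negative importance weight `w_u`), and (ii) an
#' associative lexicon mapping its private categories to shared word tokens
#' with strengths in \[0, 1\], plus a bounded queue of game outcomes from
#' which its trailing communicative success is computed.
#'
#' Agents are mutable (implemented as environments): the game protocols
#' update them in place.
#'
#' @param sigma Gaussian kernel scale of reactive units (default 1).
#' @param beta Learning rate of unit-weight reinforcement (default 1).
#' @param delta Forgetting rate: every forgetting event multiplies all unit
#'   weights by `1 - delta` (default 0.01).
#' @param init_weight Weight assigned to a newly created reactive unit
#'   (default 1).
#' @param history_len Capacity of the game-outcome window (default 50).
#' @param dim Stimulus dimensionality (default 3, for CIE LAB).
#' @return An object of class `lg_agent`.
#' @export
new_agent <- function(sigma = 1, beta = 1, delta = 0.01, init_weight = 1,
                      history_len = 50L, dim = 3L) {
  stopifnot(sigma > 0, beta >= 0, delta >= 0, delta < 1, init_weight > 0)
  a <- new.env(parent = emptyenv())
  a$centers <- matrix(NA_real_, 16L, dim)
  a$w <- numeric(16L)
  a$ucat <- integer(16L)
  a$n_units <- 0L
  a$n_cat <- 0L
  a$lex_cat <- integer(0)
  a$lex_word <- integer(0)
  a$lex_s <- numeric(0)
  a$hist <- integer(history_len)
  a$hist_n <- 0L
  a$hist_pos <- 0L
  a$sigma <- sigma
  a$beta <- beta
  a$delta <- delta
  a$init_weight <- init_weight
  a$history_len <- as.integer(history_len)
  a$dim <- as.integer(dim)
  class(a) <- "lg_agent"
  a
}

#' @export
print.lg_agent <- function(x, ...) {
  cat(sprintf("<agent: %d categories, %d units, %d lexicon entries, CS=%.2f>\n",
              x$n_cat, x$n_units, length(x$lex_s), agent_cs(x)))
  invisible(x)
}

#' Number of categories of an agent
#' @param agent An `lg_agent`.
#' @return Integer count.
#' @export
n_categories <- function(agent) agent$n_cat

# append a reactive unit, growing storage by doubling
add_unit <- function(agent, center, cat_id) {
  n <- agent$n_units + 1L
  if (n > nrow(agent$centers)) {
    cap <- 2L * nrow(agent$centers)
    cm <- matrix(NA_real_, cap, agent$dim)
    cm[seq_len(n - 1L), ] <- agent$centers[seq_len(n - 1L), ]
    agent$centers <- cm
    agent$w <- c(agent$w, numeric(cap - length(agent$w)))
    agent$ucat <- c(agent$ucat, integer(cap - length(agent$ucat)))
  }
  agent$centers[n, ] <- center
  agent$w[n] <- agent$init_weight
  agent$ucat[n] <- as.integer(cat_id)
  agent$n_units <- n
  invisible(agent)
}

#' Gaussian reactive-unit activation
#'
#' `z_u(x) = exp(-||x - m||^2 / (2 sigma^2))`: 1 when the stimulus sits on
#' the unit's center, decreasing monotonically with Euclidean distance. With
#' `sigma = 1` and LAB-scale distances, cross-stimulus activations underflow
#' to exactly 0 in double precision: each unit then responds only to the
#' stimulus it memorized (and numerically identical ones), which is the
#' intended single-stimulus specialization.
#'
#' @param center Unit center (numeric vector `m`).
#' @param x Stimulus vector, same length as `center`.
#' @param sigma Kernel scale (> 0).
#' @return Activation in (0, 1\].
#' @export
activation <- function(center, x, sigma = 1) {
  if (length(center) != length(x))
    stop("stimulus and unit center have different dimensions", call. = FALSE)
  exp(-sum((x - center)^2) / (2 * sigma^2))
}

# squared distances of stimulus x to the first n unit centers
.unit_d2 <- function(agent, x, n) {
  d2 <- numeric(n)
  cm <- agent$centers
  for (j in seq_len(agent$dim)) {
    dj <- cm[seq_len(n), j] - x[j]
    d2 <- d2 + dj * dj
  }
  d2
}

#' Response of one category's adaptive network
#'
#' `f_C(x) = sum_{u in C} w_u z_u(x)`: the weighted sum of the activations of
#' the category's reactive units.
#'
#' @param agent An `lg_agent`.
#' @param cat_id Category identifier (creation-ordered integer).
#' @param x Stimulus vector.
#' @return Non-negative response.
#' @export
category_response <- function(agent, cat_id, x) {
  if (cat_id < 1 || cat_id > agent$n_cat)
    stop("unknown category", call. = FALSE)
  idx <- which(agent$ucat[seq_len(agent$n_units)] == cat_id)
  if (length(x) != agent$dim)
    stop("stimulus dimension mismatch", call. = FALSE)
  cm <- agent$centers[idx, , drop = FALSE]
  d2 <- colSums((t(cm) - x)^2)
  sum(agent$w[idx] * exp(-d2 / (2 * agent$sigma^2)))
}

#' Classify a stimulus
#'
#' Assigns `x` to the category with the largest adaptive-network response.
#' Ties -- including the all-zero response that arises when every activation
#' underflows -- are broken in favor of the earliest-created category.
#'
#' @param agent An `lg_agent`.
#' @param x Stimulus vector.
#' @return Integer category id, or `NA_integer_` if the agent has no
#'   categories yet.
#' @export
classify <- function(agent, x) {
  if (agent$n_cat == 0L) return(NA_integer_)
  n <- agent$n_units
  z <- exp(-.unit_d2(agent, x, n) / (2 * agent$sigma^2))
  resp <- rowsum(agent$w[seq_len(n)] * z, agent$ucat[seq_len(n)])
  # every category owns >= 1 unit, so rowsum groups are exactly 1..n_cat in
  # order and which.max resolves ties toward the earliest category
  as.integer(which.max(resp))
}

#' Learn from a topic stimulus after a discrimination failure
#'
#' If the agent's trailing communicative success exceeds 0.95 (strictly) and
#' a classification exists, the topic is appended as a new reactive unit to
#' the category it classifies into; otherwise a brand-new category holding a
#' single unit centered at the topic is created. The success window is read
#' in its pre-game state (the current game's outcome is recorded afterwards).
#'
#' @param agent An `lg_agent`.
#' @param topic Stimulus vector.
#' @return The affected category id.
#' @export
learn_topic <- function(agent, topic) {
  cs <- agent_cs(agent)
  if (cs > 0.95 && agent$n_cat > 0L) {
    cat_id <- classify(agent, topic)
    add_unit(agent, topic, cat_id)
  } else {
    cat_id <- agent$n_cat + 1L
    agent$n_cat <- cat_id
    add_unit(agent, topic, cat_id)
  }
  cat_id
}

#' Reinforce a category toward a topic
#'
#' Every reactive unit `u` of category `cat_id` has its weight increased by
#' `beta * z_u(topic)`.
#'
#' @param agent An `lg_agent`.
#' @param cat_id Category id owned by `agent`.
#' @param topic Stimulus vector.
#' @return Invisibly, the agent.
#' @export
reinforce_category <- function(agent, cat_id, topic) {
  if (cat_id < 1 || cat_id > agent$n_cat)
    stop("category does not belong to this agent", call. = FALSE)
  n <- agent$n_units
  idx <- which(agent$ucat[seq_len(n)] == cat_id)
  cm <- agent$centers[idx, , drop = FALSE]
  d2 <- colSums((t(cm) - topic)^2)
  agent$w[idx] <- agent$w[idx] + agent$beta * exp(-d2 / (2 * agent$sigma^2))
  invisible(agent)
}

#' Apply forgetting to all reactive units
#'
#' Multiplies every unit weight by `1 - delta`. Multiplicative decay keeps
#' weights non-negative and preserves the within-category response ordering.
#'
#' @param agent An `lg_agent`.
#' @return Invisibly, the agent.
#' @export
decay_units <- function(agent) {
  if (agent$n_units > 0L) {
    idx <- seq_len(agent$n_units)
    agent$w[idx] <- agent$w[idx] * (1 - agent$delta)
  }
  invisible(agent)
}

#' Lexicon lookups
#'
#' `strongest_word` returns the word most strongly associated with a
#' category; `strongest_category` the category most strongly associated with
#' a word. Ties are broken toward the earliest-created token / category;
#' `NA` signals no association.
#'
#' @param agent An `lg_agent`.
#' @param cat_id Category id.
#' @param word Word token.
#' @return Integer token / category id, or `NA_integer_`.
#' @name lexicon-lookup
NULL

#' @rdname lexicon-lookup
#' @export
strongest_word <- function(agent, cat_id) {
  idx <- which(agent$lex_cat == cat_id)
  if (length(idx) == 0L) return(NA_integer_)
  idx <- idx[order(agent$lex_word[idx])]
  agent$lex_word[idx[which.max(agent$lex_s[idx])]]
}

#' @rdname lexicon-lookup
#' @export
strongest_category <- function(agent, word) {
  idx <- which(agent$lex_word == word)
  if (length(idx) == 0L) return(NA_integer_)
  idx <- idx[order(agent$lex_cat[idx])]
  agent$lex_cat[idx[which.max(agent$lex_s[idx])]]
}

#' Update a category--word association strength
#'
#' Adds `delta` to the association (missing pairs count as strength 0) and
#' clamps the result into \[0, 1\]. A missing pair whose updated strength
#' would be <= 0 is left absent, so lateral inhibition never creates ghost
#' associations.
#'
#' @param agent An `lg_agent`.
#' @param cat_id Category id.
#' @param word Word token.
#' @param delta Increment (the game protocols use +0.1 / -0.1; +0.5 for a
#'   newly adopted word).
#' @return Invisibly, the new strength.
#' @export
update_association <- function(agent, cat_id, word, delta) {
  idx <- which(agent$lex_cat == cat_id & agent$lex_word == word)
  if (length(idx) == 0L) {
    s <- min(max(delta, 0), 1)
    if (s > 0) {
      agent$lex_cat <- c(agent$lex_cat, as.integer(cat_id))
      agent$lex_word <- c(agent$lex_word, as.integer(word))
      agent$lex_s <- c(agent$lex_s, s)
    }
    return(invisible(s))
  }
  s <- min(max(agent$lex_s[idx] + delta, 0), 1)
  agent$lex_s[idx] <- s
  invisible(s)
}

# decrement by `delta` every existing association of `word` except with
# `keep_cat` (speaker-side lateral inhibition)
inhibit_other_categories <- function(agent, word, keep_cat, delta = 0.1) {
  idx <- which(agent$lex_word == word & agent$lex_cat != keep_cat)
  if (length(idx)) agent$lex_s[idx] <- pmax(agent$lex_s[idx] - delta, 0)
  invisible(agent)
}

# decrement every existing association of `cat_id` except with `keep_word`
# (hearer-side lateral inhibition)
inhibit_other_words <- function(agent, cat_id, keep_word, delta = 0.1) {
  idx <- which(agent$lex_cat == cat_id & agent$lex_word != keep_word)
  if (length(idx)) agent$lex_s[idx] <- pmax(agent$lex_s[idx] - delta, 0)
  invisible(agent)
}

#' Record a game outcome in an agent's success window
#'
#' @param agent An `lg_agent` or `lg_naming_agent`.
#' @param success Logical.
#' @return Invisibly, the agent.
#' @export
record_outcome <- function(agent, success) {
  pos <- agent$hist_pos %% agent$history_len + 1L
  agent$hist[pos] <- as.integer(success)
  agent$hist_pos <- pos
  if (agent$hist_n < agent$history_len) agent$hist_n <- agent$hist_n + 1L
  invisible(agent)
}

#' Trailing communicative success of an agent
#'
#' Fraction of successful games over the agent's most recent
#' `min(history_len, games played)` outcomes; 0 for an agent that has not
#' played yet (which routes a fresh agent into the new-category branch of
#' [learn_topic()]).
#'
#' @param agent An `lg_agent` or `lg_naming_agent`.
#' @return Value in \[0, 1\].
#' @export
agent_cs <- function(agent) {
  if (agent$hist_n == 0L) return(0)
  sum(agent$hist[seq_len(agent$hist_n)]) / agent$hist_n
}

#' Create a naming-game agent
#'
#' A lexical-layer-only agent: its lexicon associates discrete stimulus
#' identifiers directly with word tokens (no categorization system).
#'
#' @param history_len Capacity of the game-outcome window (default 50).
#' @return An object of class `lg_naming_agent`.
#' @export
new_naming_agent <- function(history_len = 50L) {
  a <- new.env(parent = emptyenv())
  a$lex_stim <- character(0)
  a$lex_word <- integer(0)
  a$lex_s <- numeric(0)
  a$hist <- integer(history_len)
  a$hist_n <- 0L
  a$hist_pos <- 0L
  a$history_len <- as.integer(history_len)
  class(a) <- "lg_naming_agent"
  a
}

#' @export
print.lg_naming_agent <- function(x, ...) {
  cat(sprintf("<naming agent: %d lexicon entries, CS=%.2f>\n",
              length(x$lex_s), agent_cs(x)))
  invisible(x)
}

#' Naming-agent lexicon operations
#'
#' Stimulus--word analogues of the categorizing agent's lexicon: argmax
#' lookups with earliest-token tie-breaks and clamped \[0, 1\] strength
#' updates.
#'
#' @param agent An `lg_naming_agent`.
#' @param stimulus Stimulus identifier (character).
#' @param word Word token.
#' @param delta Strength increment.
#' @return Lookups return a token / strength or `NA`; updates return the new
#'   strength invisibly.
#' @name naming-lexicon
NULL

#' @rdname naming-lexicon
#' @export
naming_strongest_word <- function(agent, stimulus) {
  idx <- which(agent$lex_stim == stimulus)
  if (length(idx) == 0L) return(NA_integer_)
  idx <- idx[order(agent$lex_word[idx])]
  agent$lex_word[idx[which.max(agent$lex_s[idx])]]
}

#' @rdname naming-lexicon
#' @export
naming_association <- function(agent, stimulus, word) {
  idx <- which(agent$lex_stim == stimulus & agent$lex_word == word)
  if (length(idx) == 0L) return(NA_real_)
  agent$lex_s[idx]
}

#' @rdname naming-lexicon
#' @export
naming_update_association <- function(agent, stimulus, word, delta) {
  idx <- which(agent$lex_stim == stimulus & agent$lex_word == word)
  if (length(idx) == 0L) {
    s <- min(max(delta, 0), 1)
    if (s > 0) {
      agent$lex_stim <- c(agent$lex_stim, stimulus)
      agent$lex_word <- c(agent$lex_word, as.integer(word))
      agent$lex_s <- c(agent$lex_s, s)
    }
    return(invisible(s))
  }
  s <- min(max(agent$lex_s[idx] + delta, 0), 1)
  agent$lex_s[idx] <- s
  invisible(s)
}

naming_knows_word <- function(agent, word) any(agent$lex_word == word)

# among context stimuli, the one with the strongest association with `word`
# (absent associations count 0; ties toward the lowest-index stimulus)
naming_point <- function(agent, word, stimuli) {
  s <- vapply(stimuli, function(st) {
    v <- naming_association(agent, st, word)
    if (is.na(v)) 0 else v
  }, numeric(1))
  which.max(s)
}
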