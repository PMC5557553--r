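new_outcome <- function(success, branch = "none", word = NA_integer_,
                        speaker_category = NA_integer_,
                        hearer_category = NA_integer_) {
  structure(list(success = success, failure_branch = branch, word = word,
                 speaker_category = speaker_category,
                 hearer_category = hearer_category),
            class = "game_outcome")
}

#' Discrimination game
#'
#' The agent classifies all four context stimuli; the game succeeds iff the
#' topic lands in a category different from every distractor's category (an
#' agent with no categories fails). On failure with `learn = TRUE` the agent
#' applies [learn_topic()] and, when `decay = TRUE` (the default, matching
#' the stand-alone failure consequences), one forgetting event.
#'
#' @param agent An `lg_agent`.
#' @param ctx A `game_context` over continuous stimuli.
#' @param learn Apply learning updates on failure?
#' @param decay Apply forgetting along with the failure update? (The guessing
#'   game's hearer-unknown-word branch runs the embedded discrimination game
#'   with `decay = FALSE` and applies its single listed forgetting event
#'   afterwards.)
#' @return List with `success` and `category` (the topic's category after any
#'   learning; `NA` for an unlearned failure of a category-less agent).
#' @export
discrimination_game <- function(agent, ctx, learn = TRUE, decay = TRUE) {
  s <- ctx$stimuli
  cats <- integer(4)
  for (i in 1:4) cats[i] <- classify(agent, s[i, ])
  tc <- cats[ctx$topic_index]
  success <- !is.na(tc) && all(cats[-ctx$topic_index] != tc)
  if (success) return(list(success = TRUE, category = tc))
  if (learn) {
    tc <- learn_topic(agent, s[ctx$topic_index, ])
    if (decay) decay_units(agent)
  }
  list(success = FALSE, category = tc)
}

#' Guessing game
#'
#' The full grounded interaction protocol between a speaker and a hearer over
#' a 4-stimulus context:
#'
#' 1. The speaker plays a discrimination game. On failure it learns the topic
#'    and forgets (weight decay), the game aborts as a
#'    `speaker-discrimination` failure, and the hearer is untouched.
#' 2. Otherwise `C_s` is the topic's category and `v` its strongest word (a
#'    fresh word, adopted at strength 0.5, if the category is unnamed). The
#'    hearer maps `v` to its strongest category `C_h` and points at the
#'    context stimulus with the highest `C_h` response (ties and all-zero
#'    responses resolve to the lowest-index stimulus).
#' 3. Success (the hearer pointed at the topic): both agents raise the used
#'    association by 0.1 with lateral inhibition (speaker: `v` against
#'    categories other than `C_s`; hearer: `C_h` against words other than
#'    `v`), and both reinforce their topic category's units by
#'    `beta * z_u(topic)`.
#' 4. Failures: `hearer-unknown-word` -- the hearer plays an embedded
#'    discrimination game (learning on its failure), associates the topic's
#'    category with `v` at strength 0.5, and forgets once;
#'    `hearer-wrong-point` -- both agents lower the used association by 0.1
#'    and the hearer learns the topic and forgets.
#'
#' Both participants record the outcome in their success windows, except the
#' hearer in the aborted speaker-discrimination branch. With `learn = FALSE`
#' the game is a pure probe: no agent state (including histories) changes,
#' and a speaker with no word for its topic category fails with the internal
#' branch tag `"speaker-no-word"`.
#'
#' @param speaker,hearer `lg_agent`s.
#' @param ctx A `game_context`.
#' @param learn Apply learning updates? (`FALSE` = frozen probe.)
#' @return A `game_outcome`: `success`, `failure_branch`, `word`,
#'   `speaker_category`, `hearer_category`.
#' @export
guessing_game <- function(speaker, hearer, ctx, learn = TRUE) {
  topic <- ctx$stimuli[ctx$topic_index, ]
  d <- discrimination_game(speaker, ctx, learn = learn, decay = TRUE)
  if (!d$success) {
    if (learn) record_outcome(speaker, FALSE)
    return(new_outcome(FALSE, "speaker-discrimination",
                       speaker_category = d$category))
  }
  cs <- d$category
  v <- strongest_word(speaker, cs)
  if (is.na(v)) {
    if (!learn) return(new_outcome(FALSE, "speaker-no-word",
                                   speaker_category = cs))
    v <- new_word()
    update_association(speaker, cs, v, 0.5)
  }
  ch <- strongest_category(hearer, v)
  if (is.na(ch)) {
    if (learn) {
      hd <- discrimination_game(hearer, ctx, learn = TRUE, decay = FALSE)
      update_association(hearer, hd$category, v, 0.5)
      decay_units(hearer)
      record_outcome(speaker, FALSE)
      record_outcome(hearer, FALSE)
    }
    return(new_outcome(FALSE, "hearer-unknown-word", word = v,
                       speaker_category = cs))
  }
  resp <- numeric(4)
  for (i in 1:4) resp[i] <- category_response(hearer, ch, ctx$stimuli[i, ])
  point <- which.max(resp)
  if (point == ctx$topic_index) {
    if (learn) {
      update_association(speaker, cs, v, 0.1)
      inhibit_other_categories(speaker, v, cs, 0.1)
      update_association(hearer, ch, v, 0.1)
      inhibit_other_words(hearer, ch, v, 0.1)
      reinforce_category(speaker, cs, topic)
      reinforce_category(hearer, ch, topic)
      record_outcome(speaker, TRUE)
      record_outcome(hearer, TRUE)
    }
    return(new_outcome(TRUE, word = v, speaker_category = cs,
                       hearer_category = ch))
  }
  if (learn) {
    update_association(speaker, cs, v, -0.1)
    update_association(hearer, ch, v, -0.1)
    learn_topic(hearer, topic)
    decay_units(hearer)
    record_outcome(speaker, FALSE)
    record_outcome(hearer, FALSE)
  }
  new_outcome(FALSE, "hearer-wrong-point", word = v, speaker_category = cs,
              hearer_category = ch)
}

#' Naming game
#'
#' Lexical-layer-only interaction over four distinct discrete stimuli: the
#' speaker utters the word most strongly associated with the topic (adopting
#' a fresh word at strength 0.5 if it has none), the hearer points at the
#' context stimulus most strongly associated with that word. On success both
#' raise the topic--word association by 0.1 with lateral inhibition (speaker:
#' the word against other stimuli; hearer: the topic against other words).
#' On failure: an unknown word is adopted by the hearer at strength 0.5; a
#' wrong point lowers both agents' topic--word association by 0.1. Both
#' agents record the outcome; `learn = FALSE` evaluates without any state
#' change.
#'
#' @param speaker,hearer `lg_naming_agent`s.
#' @param ctx A `game_context` over discrete stimuli (character 4-vector).
#' @return A `game_outcome` (category fields unused).
#' @export
naming_game <- function(speaker, hearer, ctx, learn = TRUE) {
  stimuli <- ctx$stimuli
  topic <- stimuli[ctx$topic_index]
  v <- naming_strongest_word(speaker, topic)
  if (is.na(v)) {
    if (!learn) return(new_outcome(FALSE, "speaker-no-word"))
    v <- new_word()
    naming_update_association(speaker, topic, v, 0.5)
  }
  if (!naming_knows_word(hearer, v)) {
    if (learn) {
      naming_update_association(hearer, topic, v, 0.5)
      record_outcome(speaker, FALSE)
      record_outcome(hearer, FALSE)
    }
    return(new_outcome(FALSE, "hearer-unknown-word", word = v))
  }
  point <- naming_point(hearer, v, stimuli)
  if (point == ctx$topic_index) {
    if (learn) {
      naming_update_association(speaker, topic, v, 0.1)
      idx <- which(speaker$lex_word == v & speaker$lex_stim != topic)
      if (length(idx)) speaker$lex_s[idx] <- pmax(speaker$lex_s[idx] - 0.1, 0)
      naming_update_association(hearer, topic, v, 0.1)
      idx <- which(hearer$lex_stim == topic & hearer$lex_word != v)
      if (length(idx)) hearer$lex_s[idx] <- pmax(hearer$lex_s[idx] - 0.1, 0)
      record_outcome(speaker, TRUE)
      record_outcome(hearer, TRUE)
    }
    return(new_outcome(TRUE, word = v))
  }
  if (learn) {
    naming_update_association(speaker, topic, v, -0.1)
    naming_update_association(hearer, topic, v, -0.1)
    record_outcome(speaker, FALSE)
    record_outcome(hearer, FALSE)
  }
  new_outcome(FALSE, "hearer-wrong-point", word = v)
}
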