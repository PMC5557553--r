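# a context over 4 far-apart LAB points, topic first by default
ctx4 <- function(topic_index = 1L) {
  make_context(rbind(c(0, 0, 0), c(60, 0, 0), c(120, 0, 0), c(180, 0, 0)),
               topic_index)
}

test_that("discrimination game separates topic from distractors", {
  ctx <- ctx4()
  apart <- agent_with_categories(ctx$stimuli)     # one category per stimulus
  expect_true(discrimination_game(apart, ctx)$success)

  fresh <- new_agent()
  res <- discrimination_game(fresh, ctx, learn = TRUE)
  expect_false(res$success)
  expect_equal(n_categories(fresh), 1L)           # learned the topic
  expect_equal(fresh$w[1], 1.0 * 0.99)            # and forgot once

  lumper <- agent_with_categories(matrix(c(0, 0, 0), 1))
  expect_false(discrimination_game(lumper, ctx, learn = FALSE)$success)
  expect_equal(n_categories(lumper), 1L)          # probe: untouched
})

test_that("guessing game between fresh agents aborts at speaker discrimination", {
  reset_word_counter()
  s <- new_agent(); h <- new_agent()
  h_before <- agent_to_json(h)
  out <- guessing_game(s, h, ctx4())
  expect_false(out$success)
  expect_identical(out$failure_branch, "speaker-discrimination")
  expect_equal(n_categories(s), 1L)
  expect_identical(as.character(agent_to_json(h)), as.character(h_before))
  expect_equal(s$hist_n, 1L)                      # speaker records the loss
})

test_that("unknown words are adopted by the hearer at strength 0.5", {
  reset_word_counter()
  ctx <- ctx4()
  s <- agent_with_categories(ctx$stimuli)
  h <- new_agent()
  out <- guessing_game(s, h, ctx)
  expect_false(out$success)
  expect_identical(out$failure_branch, "hearer-unknown-word")
  v <- out$word
  expect_false(is.na(v))
  # speaker adopted its fresh word at 0.5 as well
  expect_equal(s$lex_s[s$lex_word == v], 0.5)
  hc <- strongest_category(h, v)
  expect_false(is.na(hc))
  expect_equal(h$lex_s[h$lex_word == v], 0.5)
  expect_equal(h$hist_n, 1L)
})

test_that("successful guessing games reinforce lexicon and categories", {
  reset_word_counter()
  ctx <- ctx4()
  topic <- ctx$stimuli[1, ]
  v <- new_word()
  s <- agent_with_categories(ctx$stimuli)
  h <- agent_with_categories(ctx$stimuli)
  update_association(s, 1, v, 0.5)
  update_association(h, 1, v, 0.5)
  w_before <- c(s$w[1], h$w[1])
  out <- guessing_game(s, h, ctx)
  expect_true(out$success)
  expect_identical(out$failure_branch, "none")
  expect_equal(out$word, v)
  expect_equal(s$lex_s[s$lex_word == v], 0.6)
  expect_equal(h$lex_s[h$lex_word == v], 0.6)
  # unit centered at the topic: z_u(topic) = 1, beta = 1
  expect_equal(c(s$w[1], h$w[1]), w_before + 1)
  expect_equal(s$hist[1], 1L)
  expect_equal(h$hist[1], 1L)
})

test_that("wrong pointing penalizes the used association on both sides", {
  reset_word_counter()
  ctx <- ctx4()
  v <- new_word()
  s <- agent_with_categories(ctx$stimuli)
  h <- agent_with_categories(ctx$stimuli)
  update_association(s, 1, v, 0.5)
  update_association(h, 2, v, 0.5)   # hearer maps v to a distractor category
  n_cat_before <- n_categories(h)
  out <- guessing_game(s, h, ctx)
  expect_false(out$success)
  expect_identical(out$failure_branch, "hearer-wrong-point")
  expect_equal(s$lex_s[s$lex_word == v], 0.4)
  expect_equal(h$lex_s[h$lex_word == v], 0.4)
  # hearer learned the topic (fresh window: new category) and decayed
  expect_equal(n_categories(h), n_cat_before + 1L)
})

test_that("naming game follows the unknown-word / replay / wrong-point traces", {
  reset_word_counter()
  dctx <- make_context(c("s1", "s2", "s3", "s4"), 1L)
  s <- new_naming_agent(); h <- new_naming_agent()
  out <- naming_game(s, h, dctx)
  expect_false(out$success)
  expect_identical(out$failure_branch, "hearer-unknown-word")
  v <- out$word
  expect_equal(naming_association(h, "s1", v), 0.5)
  expect_equal(naming_association(s, "s1", v), 0.5)

  replay <- naming_game(s, h, dctx)
  expect_true(replay$success)
  expect_equal(naming_association(s, "s1", v), 0.6)
  expect_equal(naming_association(h, "s1", v), 0.6)

  # hearer knowing v only for a distractor points wrong
  s2 <- new_naming_agent(); h2 <- new_naming_agent()
  w <- new_word()
  naming_update_association(s2, "s1", w, 0.5)
  naming_update_association(h2, "s3", w, 0.5)
  out2 <- naming_game(s2, h2, dctx)
  expect_false(out2$success)
  expect_identical(out2$failure_branch, "hearer-wrong-point")
  expect_equal(naming_association(s2, "s1", w), 0.4)
  expect_identical(naming_association(h2, "s1", w), NA_real_)  # no ghost
})

test_that("probe games leave both agents byte-identical", {
  reset_word_counter()
  set.seed(3)
  env <- far_apart_env(8, spacing = 70)
  s <- new_agent(); h <- new_agent()
  for (i in 1:80) {                       # some real training first
    ctx <- sample_context(env)
    guessing_game(s, h, ctx)
  }
  before <- c(agent_to_json(s), agent_to_json(h))
  for (i in 1:30) {
    ctx <- sample_context(env)
    guessing_game(s, h, ctx, learn = FALSE)
  }
  expect_identical(as.character(agent_to_json(s)), as.character(before[1]))
  expect_identical(as.character(agent_to_json(h)), as.character(before[2]))

  ns <- new_naming_agent(); nh <- new_naming_agent()
  denv <- make_discrete_environment_pair(8, 0, seed = 2)$A
  for (i in 1:60) naming_game(ns, nh, sample_discrete_context(denv))
  nbefore <- c(agent_to_json(ns), agent_to_json(nh))
  for (i in 1:30) naming_game(ns, nh, sample_discrete_context(denv),
                              learn = FALSE)
  expect_identical(as.character(agent_to_json(ns)), as.character(nbefore[1]))
  expect_identical(as.character(agent_to_json(nh)), as.character(nbefore[2]))
})

test_that("outcomes carry exactly one failure branch and bounded state", {
  reset_word_counter()
  set.seed(17)
  env <- far_apart_env(10, spacing = 60)
  pop <- list(new_agent(), new_agent(), new_agent())
  branches <- c("speaker-discrimination", "hearer-unknown-word",
                "hearer-wrong-point")
  for (i in 1:400) {
    pair <- sample(3, 2)
    out <- guessing_game(pop[[pair[1]]], pop[[pair[2]]], sample_context(env))
    if (out$success) expect_identical(out$failure_branch, "none")
    else expect_true(out$failure_branch %in% branches)
  }
  for (a in pop) {
    expect_true(all(a$lex_s >= 0 & a$lex_s <= 1))
    expect_true(all(a$w[seq_len(a$n_units)] >= 0))
    expect_true(a$hist_n <= 50)
  }
})

test_that("two agents on a fixed tiny environment reach sustained success", {
  reset_word_counter()
  set.seed(5)
  env <- far_apart_env(4, spacing = 60)   # the only admissible context set
  a <- new_agent(); b <- new_agent()
  for (i in 1:400) {
    ctx <- sample_context(env)
    if (i %% 2 == 0) guessing_game(a, b, ctx) else guessing_game(b, a, ctx)
  }
  expect_gt(agent_cs(a), 0.9)
  expect_gt(agent_cs(b), 0.9)
})

test_that("naming on a complete graph converges to one word per stimulus", {
  reset_word_counter()
  set.seed(8)
  denv <- make_discrete_environment_pair(8, 0, seed = 4)$A
  pop <- lapply(1:6, function(i) new_naming_agent())
  for (i in 1:4000) {
    pair <- sample(6, 2)
    naming_game(pop[[pair[1]]], pop[[pair[2]]], sample_discrete_context(denv))
  }
  for (st in as.character(denv)) {
    words <- vapply(pop, naming_strongest_word, integer(1), stimulus = st)
    expect_equal(length(unique(words)), 1)
  }
})
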