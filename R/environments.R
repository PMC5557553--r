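#' Default focal points of the two color environments
#'
#' Focal points in CIE LAB space around which the family-resemblance
#' environments A and B concentrate their stimulus frequencies.
#'
#' @return A list with numeric vectors `A` and `B`, each `c(L, a, b)`.
#' @export
focal_points <- function() {
  list(
    A = c(L = 66.97, a = 18.65, b = 38.36),
    B = c(L = 46.24, a = -16.46, b = -1.41)
  )
}

# LAB box covered by the generated chip set
.lab_box <- list(L = c(10, 95), a = c(-80, 80), b = c(-80, 80))

#' Generate a base set of color chips in CIE LAB space
#'
#' Produces `n_chips` distinct chips on a jittered grid covering
#' L in \[10, 95\], a in \[-80, 80\], b in \[-80, 80\]. This is a generated
#' stand-in for a Munsell chip table with the same coverage of color space;
#' a real chip table can be supplied instead via [read_chipset()].
#'
#' @param n_chips Number of chips (>= 4). The classic chip universe has 1269.
#' @param seed Integer seed; output is byte-identical for equal seeds.
#' @return A `chip_set`: a data.frame with columns `L`, `a`, `b` and a
#'   `provenance` attribute (`"generated"`).
#' @export
generate_base_chipset <- function(n_chips = 1269, seed = 1) {
  if (!is.numeric(n_chips) || length(n_chips) != 1 || n_chips < 4)
    stop("n_chips must be a single integer >= 4", call. = FALSE)
  n_chips <- as.integer(n_chips)
  with_seed(seed, {
    m <- ceiling(n_chips^(1 / 3))
    gl <- seq(.lab_box$L[1], .lab_box$L[2], length.out = m)
    ga <- seq(.lab_box$a[1], .lab_box$a[2], length.out = m)
    gb <- seq(.lab_box$b[1], .lab_box$b[2], length.out = m)
    grid <- expand.grid(L = gl, a = ga, b = gb, KEEP.OUT.ATTRS = FALSE)
    keep <- sort(sample.int(nrow(grid), n_chips))
    chips <- grid[keep, , drop = FALSE]
    # jitter within +/- 30% of a cell so neighbours cannot collide
    half <- vapply(list(gl, ga, gb), function(g) {
      if (length(g) > 1) diff(g[1:2]) * 0.3 else 1
    }, numeric(1))
    for (j in 1:3) {
      chips[[j]] <- chips[[j]] + stats::runif(n_chips, -half[j], half[j])
    }
    rownames(chips) <- NULL
    as_chipset(chips, provenance = "generated")
  })
}

as_chipset <- function(df, provenance) {
  stopifnot(all(c("L", "a", "b") %in% names(df)))
  df <- df[, c("L", "a", "b")]
  if (nrow(df) < 1) stop("chip set must be non-empty", call. = FALSE)
  if (anyDuplicated(df)) stop("chip set contains duplicate chips", call. = FALSE)
  if (!all(vapply(df, function(x) all(is.finite(x)), logical(1))))
    stop("chip coordinates must be finite", call. = FALSE)
  structure(df, class = c("chip_set", "data.frame"), provenance = provenance)
}

#' Read a chip table from CSV
#'
#' Expects a header `L,a,b` and one chip per row.
#'
#' @param path Path to a CSV file.
#' @return A `chip_set` with provenance `"user-supplied"`.
#' @export
read_chipset <- function(path) {
  df <- utils::read.csv(path)
  as_chipset(df, provenance = "user-supplied")
}

#' Write a chip table to CSV
#'
#' @param chips A `chip_set` or data.frame with columns `L`, `a`, `b`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_chipset <- function(chips, path) {
  utils::write.csv(as.data.frame(chips)[, c("L", "a", "b")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Build a frequency-weighted environment around a focal point
#'
#' Resamples `n_env` chips (with replacement) from a base chip set, with the
#' probability of chip `c` proportional to
#' `exp(-sum_d (c_d - focal_d)^2 / (2 sigma_d^2))` -- a trivariate normal
#' (uncorrelated) family-resemblance weighting centered on `focal`.
#' Alternatively (`resample = FALSE`) chips are drawn fresh from the normal
#' distribution itself, without reference to the base set.
#'
#' @param base A `chip_set`.
#' @param focal Numeric `c(L, a, b)` focal point.
#' @param sigma_per_dim Positive scale per dimension. The default used for the
#'   canonical A/B pair is 10 times the per-dimension difference between the
#'   two focal points; see [make_environment_pair()].
#' @param n_env Number of chips in the environment (default 600).
#' @param seed Integer seed.
#' @param label Environment label (e.g. `"A"`, `"B"`, `"base"`).
#' @param resample If `TRUE` (default) resample from `base`; if `FALSE` draw
#'   fresh from the trivariate normal.
#' @return An object of class `lab_environment`: list with `chips` (numeric
#'   matrix, columns L, a, b), `focal`, `sigma`, `label`, `seed`.
#' @export
make_weighted_environment <- function(base, focal, sigma_per_dim,
                                      n_env = 600, seed = 1, label = "A",
                                      resample = TRUE) {
  if (!resample) {
    chips <- with_seed(seed, {
      m <- matrix(stats::rnorm(3 * n_env), ncol = 3)
      sweep(m, 2, sigma_per_dim, `*`) + matrix(focal, n_env, 3, byrow = TRUE)
    })
    colnames(chips) <- c("L", "a", "b")
    return(structure(list(chips = chips, focal = focal, sigma = sigma_per_dim,
                          label = label, seed = seed),
                     class = "lab_environment"))
  }
  bm <- as.matrix(as.data.frame(base)[, c("L", "a", "b")])
  if (nrow(bm) < 1) stop("base chip set is empty", call. = FALSE)
  if (any(sigma_per_dim <= 0)) stop("sigma components must be > 0", call. = FALSE)
  # log-weights, stabilized before exponentiation
  lw <- -((bm[, 1] - focal[1])^2 / (2 * sigma_per_dim[1]^2) +
          (bm[, 2] - focal[2])^2 / (2 * sigma_per_dim[2]^2) +
          (bm[, 3] - focal[3])^2 / (2 * sigma_per_dim[3]^2))
  w <- exp(lw - max(lw))
  idx <- with_seed(seed, sample.int(nrow(bm), n_env, replace = TRUE, prob = w))
  chips <- bm[idx, , drop = FALSE]
  rownames(chips) <- NULL
  structure(list(chips = chips, focal = focal, sigma = sigma_per_dim,
                 label = label, seed = seed, chip_index = idx),
            class = "lab_environment")
}

#' Build the canonical environment pair A/B
#'
#' Environment A is centered at (L = 66.97, a = 18.65, b = 38.36), environment
#' B at (L = 46.24, a = -16.46, b = -1.41). By default the per-dimension
#' normal scale is 10 times the per-dimension difference between the two
#' focal points (`sigma_mode = "per-dim"`); `sigma_mode = "euclidean"` instead
#' uses 10 times the Euclidean distance between the focal points in all three
#' dimensions.
#'
#' @param base A `chip_set` (e.g. from [generate_base_chipset()]).
#' @param n_env Chips per environment (default 600).
#' @param seed Integer seed (A and B use derived sub-seeds).
#' @param sigma_mode `"per-dim"` (default) or `"euclidean"`.
#' @param resample Passed to [make_weighted_environment()].
#' @return List with `lab_environment`s `A` and `B`.
#' @export
make_environment_pair <- function(base, n_env = 600, seed = 1,
                                  sigma_mode = c("per-dim", "euclidean"),
                                  resample = TRUE) {
  sigma_mode <- match.arg(sigma_mode)
  fp <- focal_points()
  sigma <- switch(sigma_mode,
    "per-dim" = 10 * abs(fp$A - fp$B),
    "euclidean" = rep(10 * sqrt(sum((fp$A - fp$B)^2)), 3)
  )
  list(
    A = make_weighted_environment(base, fp$A, sigma, n_env, seed = seed * 2L + 1L,
                                  label = "A", resample = resample),
    B = make_weighted_environment(base, fp$B, sigma, n_env, seed = seed * 2L + 2L,
                                  label = "B", resample = resample)
  )
}

#' Make a uniform environment from a chip set
#'
#' Wraps the full base chip set as an environment with uniform stimulus
#' frequencies (the single-environment training condition).
#'
#' @param base A `chip_set`.
#' @param label Environment label (default `"base"`).
#' @return A `lab_environment` whose chips are the base set.
#' @export
base_environment <- function(base, label = "base") {
  bm <- as.matrix(as.data.frame(base)[, c("L", "a", "b")])
  structure(list(chips = bm, focal = NULL, sigma = NULL, label = label,
                 seed = NULL),
            class = "lab_environment")
}

#' Sample a 4-stimulus game context from an environment
#'
#' Rejection-samples 4 chips uniformly from the environment until every
#' pairwise Euclidean distance exceeds 50 (so the stimuli are perceptually
#' discriminable), then marks one of them, uniformly at random, as the topic.
#' Uses the current RNG stream.
#'
#' @param env A `lab_environment`.
#' @param max_attempts Attempts before declaring the environment degenerate
#'   (default 10000).
#' @return A `game_context`: list with `stimuli` (4 x 3 matrix) and
#'   `topic_index` in 1..4.
#' @export
sample_context <- function(env, max_attempts = 10000) {
  chips <- env$chips
  n <- nrow(chips)
  if (n < 4) stop("environment has fewer than 4 chips", call. = FALSE)
  for (att in seq_len(max_attempts)) {
    idx <- sample.int(n, 4)
    s <- chips[idx, , drop = FALSE]
    if (min_pair_dist2(s) > 2500) {
      return(structure(list(stimuli = s,
                            topic_index = sample.int(4, 1)),
                       class = "game_context"))
    }
  }
  stop("degenerate environment: no 4-stimulus context with pairwise ",
       "distance > 50 found in ", max_attempts, " attempts", call. = FALSE)
}

# squared minimum pairwise distance among the rows of a small matrix
min_pair_dist2 <- function(s) {
  d2 <- Inf
  for (i in 1:3) for (j in (i + 1):4) {
    d <- s[i, ] - s[j, ]
    d2 <- min(d2, sum(d * d))
  }
  d2
}

#' Generate the discrete naming-game environment pair
#'
#' Two environments of `n_stimuli` opaque stimulus identifiers sharing exactly
#' `n_shared` identifiers. Stimuli have no internal structure; only identity
#' matters.
#'
#' @param n_stimuli Stimuli per environment (default 16).
#' @param n_shared Shared stimuli (default 5); must not exceed `n_stimuli`.
#' @param seed Integer seed.
#' @return List with `discrete_environment`s `A` and `B` (character vectors of
#'   identifiers with a `label` attribute).
#' @export
make_discrete_environment_pair <- function(n_stimuli = 16, n_shared = 5,
                                           seed = 1) {
  if (n_shared < 0 || n_shared > n_stimuli)
    stop("n_shared must be between 0 and n_stimuli", call. = FALSE)
  total <- 2L * n_stimuli - n_shared
  ids <- sprintf("s%03d", seq_len(total))
  with_seed(seed, {
    ids <- sample(ids)          # identifier assignment is arbitrary
    shared <- ids[seq_len(n_shared)]
    rest <- if (n_shared > 0) ids[-seq_len(n_shared)] else ids
    a_only <- rest[seq_len(n_stimuli - n_shared)]
    b_only <- rest[(n_stimuli - n_shared) + seq_len(n_stimuli - n_shared)]
    list(
      A = structure(c(shared, a_only), label = "A", class = "discrete_environment"),
      B = structure(c(shared, b_only), label = "B", class = "discrete_environment")
    )
  })
}

#' Sample a 4-stimulus context from a discrete environment
#'
#' Draws 4 distinct identifiers uniformly and marks one as the topic.
#' Uses the current RNG stream.
#'
#' @param env A `discrete_environment` (character vector of identifiers).
#' @return A `game_context` with `stimuli` (character 4-vector) and
#'   `topic_index`.
#' @export
sample_discrete_context <- function(env) {
  ids <- as.character(env)
  if (length(ids) < 4) stop("discrete environment has fewer than 4 stimuli",
                            call. = FALSE)
  structure(list(stimuli = sample(ids, 4), topic_index = sample.int(4, 1)),
            class = "game_context")
}

#' Serialize an environment to CSV plus JSON sidecar
#'
#' The chips go to `<path>` as CSV (`L,a,b`); label, focal point, sigma and
#' seed go to `<path>.json`.
#'
#' @param env A `lab_environment`.
#' @param path CSV output path.
#' @return Invisibly, `path`.
#' @export
write_environment <- function(env, path) {
  utils::write.csv(as.data.frame(env$chips), path, row.names = FALSE)
  meta <- list(label = env$label, focal = env$focal, sigma = env$sigma,
               seed = env$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an environment written by [write_environment()]
#'
#' @param path CSV path (the `<path>.json` sidecar must exist alongside).
#' @return A `lab_environment`.
#' @export
read_environment <- function(path) {
  chips <- as.matrix(utils::read.csv(path))
  colnames(chips) <- c("L", "a", "b")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(chips = chips,
                 focal = if (length(meta$focal)) unlist(meta$focal) else NULL,
                 sigma = if (length(meta$sigma)) unlist(meta$sigma) else NULL,
                 label = meta$label, seed = meta$seed),
            class = "lab_environment")
}

#' Write / read a discrete environment as plain text
#'
#' One identifier per line.
#'
#' @param env A `discrete_environment`.
#' @param path Output path.
#' @return `write_discrete_environment`: invisibly `path`;
#'   `read_discrete_environment`: a `discrete_environment`.
#' @export
write_discrete_environment <- function(env, path) {
  writeLines(as.character(env), path)
  invisible(path)
}

#' @rdname write_discrete_environment
#' @param label Label to attach on read (default `"A"`).
#' @export
read_discrete_environment <- function(path, label = "A") {
  structure(readLines(path), label = label, class = "discrete_environment")
}
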