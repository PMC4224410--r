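# Stimulus generation: digit-exclusion rules, stimulus sets, and
# pseudorandomized session schedules.

# Evaluate expr under a temporary seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Valid upper digit pairs
#'
#' All increasing pairs `(a, b)` of digits 1-9 with difference at least two
#' (excluding trivial constant-difference-one progressions) and `b != 2a`
#' (excluding ubiquitous doubling pairs such as 2-4, 3-6, 4-8).
#'
#' @return Integer matrix with columns `a`, `b`, one row per valid pair.
#' @export
valid_upper_pairs <- function() {
  g <- expand.grid(a = 1:9, b = 1:9)
  g <- g[g$b - g$a >= 2 & g$b != 2 * g$a, ]
  m <- as.matrix(g[order(g$a, g$b), , drop = FALSE])
  rownames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Valid lower digit triples for a given upper pair
#'
#' All increasing triples `(c, d, e)` of digits 1-9 disjoint from the upper
#' pair whose second difference `(e - d) - (d - c)` is at least two, so the
#' subordinate linear sequence is never trivial (constant or
#' difference-one).
#'
#' @param upper Length-2 integer vector, a valid upper pair.
#' @return Integer matrix with columns `c`, `d`, `e`.
#' @export
valid_lower_triples <- function(upper) {
  upper <- as.integer(upper)
  ok_pair <- apply(valid_upper_pairs(), 1, function(p) all(p == upper))
  if (length(upper) != 2L || !any(ok_pair))
    stop("not a valid upper pair: ", paste(upper, collapse = ","),
         call. = FALSE)
  pool <- setdiff(1:9, upper)
  g <- expand.grid(c = pool, d = pool, e = pool)
  g <- g[g$c < g$d & g$d < g$e & (g$e - g$d) - (g$d - g$c) >= 2, ]
  m <- as.matrix(g[order(g$c, g$d, g$e), , drop = FALSE])
  rownames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Enumerate the full valid stimulus space
#'
#' Every five-digit arrangement (upper pair, lower triple) that passes both
#' exclusion rules.
#'
#' @return List of integer vectors `c(a, b, c, d, e)`.
#' @export
all_valid_stimuli <- function() {
  if (!is.null(.domarith_cache$stimuli)) return(.domarith_cache$stimuli)
  up <- valid_upper_pairs()
  out <- list()
  for (i in seq_len(nrow(up))) {
    lows <- valid_lower_triples(up[i, ])
    for (j in seq_len(nrow(lows)))
      out[[length(out) + 1L]] <- c(up[i, ], lows[j, ])
  }
  out <- lapply(out, unname)
  .domarith_cache$stimuli <- out
  out
}

#' Generate the experiment's stimulus set
#'
#' Draws `n_arith` distinct valid arrangements for the arithmetic task
#' (each later presented under all three arithmetic cues with physically
#' identical digits) and `n_match` arrangements for the Match task that
#' include all arithmetic ones.
#'
#' @param n_arith Number of arithmetic arrangements (study design: 48).
#' @param n_match Number of Match arrangements (study design: 72),
#'   superset of the arithmetic set.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return List with elements `arith` and `match`, each a list of
#'   five-digit integer vectors.
#' @export
generate_stimulus_set <- function(n_arith = 48L, n_match = 72L, seed = 1L) {
  space <- all_valid_stimuli()
  if (n_arith > length(space))
    stop(sprintf("only %d valid arrangements exist, %d requested",
                 length(space), n_arith), call. = FALSE)
  if (n_match < n_arith)
    stop("the Match set must contain the arithmetic set", call. = FALSE)
  if (n_match > length(space))
    stop(sprintf("only %d valid arrangements exist, %d requested",
                 length(space), n_match), call. = FALSE)
  with_seed(seed, {
    match_idx <- sample(length(space), n_match)
    arith_idx <- sample(match_idx, n_arith)
    list(arith = space[arith_idx], match = space[match_idx])
  })
}

#' Draw the white matching digit for a trial
#'
#' On match trials a uniform draw from the stored digits; on mismatch
#' trials a uniform draw from the remaining digits 0-9.
#'
#' @param stored Integer vector of stored digits.
#' @param is_match Logical.
#' @param seed Optional seed (usually drawn inside a seeded schedule).
#' @return A digit 0-9.
#' @export
assign_white_digit <- function(stored, is_match, seed = NULL) {
  stored <- unique(as.integer(stored))
  if (length(stored) == 0L) stop("empty stored-digit set", call. = FALSE)
  pool <- if (is_match) stored else setdiff(0:9, stored)
  if (length(pool) == 0L)
    stop("no candidate white digit: stored set covers all digits",
         call. = FALSE)
  with_seed(seed, pool[sample.int(length(pool), 1L)])
}

# 18 condition labels (6 each) shuffled so no condition runs 3+ in a row.
shuffle_max_run2 <- function(labels, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    cand <- sample(labels)
    runs <- rle(cand)$lengths
    if (max(runs) <= 2L) return(cand)
  }
  stop("could not satisfy the pseudorandomization constraint", call. = FALSE)
}

#' Build the pseudorandomized session schedule
#'
#' Eight sessions of 36 trials: arithmetic and Match trials alternate;
#' each session holds six trials per arithmetic condition and 18 Match
#' trials; arithmetic condition order is constrained-shuffled (no condition
#' more than twice in a row); exactly half of each condition's trials are
#' matches; no arithmetic stimulus (arrangement x cue) repeats across
#' sessions and every Match arrangement appears exactly twice.
#'
#' @param stimset Output of [generate_stimulus_set()] with the default
#'   48 / 72 sizes (other sizes work if divisible by the session counts).
#' @param seed Integer seed.
#' @param n_sessions Number of sessions (study design: 8).
#' @return A `session_schedule` data.frame, one row per trial: `session`,
#'   `trial`, `task`, `condition`, `cue`, `d1`-`d5`, `white`, `is_match`.
#' @export
build_sessions <- function(stimset, seed = 1L, n_sessions = 8L) {
  n_arith <- length(stimset$arith)
  n_match <- length(stimset$match)
  per_cond <- n_arith / n_sessions            # arithmetic trials per condition
  per_match <- 2L * n_match / n_sessions      # Match trials per session
  if (per_cond != round(per_cond) || per_match != round(per_match))
    stop("stimulus-set sizes are not divisible across sessions",
         call. = FALSE)
  if (per_cond %% 2 != 0 || per_match %% 2 != 0)
    stop("per-session trial counts must be even to balance match trials",
         call. = FALSE)
  cues <- c(Simple = "±", Linear = "a_n", Quad = "b_n", Match = "m")
  with_seed(seed, {
    # deal arrangements to sessions, independently per arithmetic cue
    deal <- lapply(CONDITIONS[1:3], function(cond) {
      idx <- sample(n_arith)
      split(idx, rep(seq_len(n_sessions), each = per_cond))
    })
    names(deal) <- CONDITIONS[1:3]
    match_pool <- sample(rep(seq_len(n_match), 2L))
    match_deal <- split(match_pool, rep(seq_len(n_sessions), each = per_match))
    rows <- list()
    for (s in seq_len(n_sessions)) {
      cond_order <- shuffle_max_run2(rep(CONDITIONS[1:3], per_cond))
      taken <- c(Simple = 0L, Linear = 0L, Quad = 0L)
      # balanced match flags per condition, shuffled within session
      flags <- lapply(c(CONDITIONS[1:3], "Match"), function(cond) {
        k <- if (cond == "Match") per_match else per_cond
        sample(rep(c(TRUE, FALSE), k / 2))
      })
      names(flags) <- c(CONDITIONS[1:3], "Match")
      used <- c(Simple = 0L, Linear = 0L, Quad = 0L, Match = 0L)
      for (t in seq_len(2L * length(cond_order))) {
        if (t %% 2L == 1L) {                  # arithmetic slot
          cond <- cond_order[(t + 1L) %/% 2L]
          taken[cond] <- taken[cond] + 1L
          digits <- stimset$arith[[deal[[cond]][[s]][taken[cond]]]]
        } else {                              # Match slot
          cond <- "Match"
          digits <- stimset$match[[match_deal[[s]][t %/% 2L]]]
        }
        used[cond] <- used[cond] + 1L
        is_match <- flags[[cond]][used[cond]]
        stored <- build_trial_forest(cond, digits)$stored_digits
        white <- assign_white_digit(stored, is_match)
        rows[[length(rows) + 1L]] <- data.frame(
          session = s, trial = t,
          task = if (cond == "Match") "match" else "arithmetic",
          condition = cond, cue = cues[[cond]],
          d1 = digits[1], d2 = digits[2], d3 = digits[3],
          d4 = digits[4], d5 = digits[5],
          white = white, is_match = is_match)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "n_sessions") <- n_sessions
    class(out) <- c("session_schedule", "data.frame")
    out
  })
}

#' Write / read a session schedule as CSV
#'
#' @param schedule A `session_schedule`.
#' @param path File path.
#' @return `read_schedule_csv` returns a `session_schedule`.
#' @export
write_schedule_csv <- function(schedule, path) {
  write.csv(as.data.frame(schedule), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  out <- read.csv(path, check.names = FALSE)
  out$is_match <- as.logical(out$is_match)
  attr(out, "n_sessions") <- max(out$session)
  class(out) <- c("session_schedule", "data.frame")
  out
}

# five digits of one schedule row
schedule_digits <- function(schedule, i) {
  as.integer(schedule[i, c("d1", "d2", "d3", "d4", "d5")])
}
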