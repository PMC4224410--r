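# Independent oracles used across test files. Each is written as a direct
# restatement of the definition, independent of the package's code paths.

# longest root-to-node path by plain recursion over the node lists
oracle_max_depth <- function(forest) {
  walk <- function(node, depth) {
    if (length(node$children) == 0L) return(depth)
    max(vapply(node$children, walk, numeric(1), depth = depth + 1))
  }
  max(vapply(forest$roots, walk, numeric(1), depth = 0))
}

# multiset of elementary (op, a, b, result) calculations, as sorted strings
oracle_calc_multiset <- function(forest) {
  out <- character(0)
  walk <- function(node) {
    if (node$kind == "terminal") return(invisible(NULL))
    for (ch in node$children) walk(ch)
    out <<- c(out, paste(node$op, node$children[[1]]$value,
                         node$children[[2]]$value, node$value))
  }
  for (r in forest$roots) walk(r)
  sort(out)
}

# collect every node of a forest into a flat list
oracle_all_nodes <- function(forest) {
  acc <- list()
  walk <- function(node) {
    acc[[length(acc) + 1L]] <<- node
    for (ch in node$children) walk(ch)
  }
  for (r in forest$roots) walk(r)
  acc
}

# brute-force enumeration of the digit-exclusion rules
oracle_upper_pairs <- function() {
  out <- list()
  for (a in 1:9) for (b in 1:9) {
    if (a < b && b - a >= 2 && b != 2 * a)
      out[[length(out) + 1L]] <- c(a, b)
  }
  out
}

oracle_lower_triples <- function(upper) {
  out <- list()
  for (cc in 1:9) for (d in 1:9) for (e in 1:9) {
    if (cc < d && d < e && !any(c(cc, d, e) %in% upper) &&
        (e - d) - (d - cc) >= 2)
      out[[length(out) + 1L]] <- c(cc, d, e)
  }
  out
}

# least-squares scale by grid search
oracle_grid_scale <- function(y, x, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  rss <- vapply(grid, function(s) sum((y - s * x)^2), numeric(1))
  grid[which.min(rss)]
}

# independent Dirichlet exceedance estimate (plain loop-free sampler)
oracle_exceedance <- function(alpha, n_draws, seed) {
  set.seed(seed)
  m <- length(alpha)
  draws <- matrix(rgamma(n_draws * m, shape = rep(alpha, each = n_draws)),
                  n_draws, m)
  tabulate(apply(draws, 1, which.max), m) / n_draws
}

# a small sample of valid five-digit stimuli, fixed across test runs
sample_stimuli <- function(k = 25, seed = 404) {
  space <- all_valid_stimuli()
  set.seed(seed)
  space[sample(length(space), k)]
}
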