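# Complexity factors computed from calculation forests, and the
# condition-level estimate table used for parametric model fitting.

FACTORS <- c("dom_hier", "nodes_hier", "dom_flat", "nodes_flat",
             "verbal_encoding", "n_operations", "n_generated", "n_stored")

#' Degree of Merger of a calculation forest
#'
#' The maximum node depth over all trees of the forest, with each top node
#' as the reference point at depth zero. An all-terminal forest (the Match
#' task) has degree zero; every flat arithmetic forest has degree one.
#'
#' @param forest A `calc_forest`.
#' @return Non-negative integer.
#' @export
#' @examples
#' degree_of_merger(build_quad(2, 4, 9))  # 3
degree_of_merger <- function(forest) {
  stopifnot(inherits(forest, "calc_forest"))
  depth <- function(node) {
    if (node$kind == "terminal") return(0L)
    1L + max(vapply(node$children, depth, integer(1)))
  }
  max(vapply(forest$roots, depth, integer(1)))
}

#' Total number of digit tokens in a forest
#'
#' Counts every terminal and nonterminal node over all roots: the total
#' number of digits that appear in the tree structure (a reused generated
#' digit is one additional terminal token).
#'
#' @param forest A `calc_forest`.
#' @return Positive integer.
#' @export
count_nodes <- function(forest) {
  stopifnot(inherits(forest, "calc_forest"))
  n_in <- function(node) {
    if (node$kind == "terminal") return(1L)
    1L + sum(vapply(node$children, n_in, integer(1)))
  }
  sum(vapply(forest$roots, n_in, integer(1)))
}

#' Number of operations (number of Merge)
#'
#' The total number of binary branches, i.e. nonterminal nodes. Identical
#' for the hierarchical and flat representations of the same trial.
#'
#' @param forest A `calc_forest`.
#' @return Non-negative integer.
#' @export
count_operations <- function(forest) {
  stopifnot(inherits(forest, "calc_forest"))
  n_op <- function(node) {
    if (node$kind == "terminal") return(0L)
    1L + sum(vapply(node$children, n_op, integer(1)))
  }
  sum(vapply(forest$roots, n_op, integer(1)))
}

#' Number of generated digits used in a calculation
#'
#' Occurrences of temporarily generated digits (results not available on
#' screen) re-entering as operands of later calculations: nonterminal
#' children of nonterminals, plus reused-value terminals. Counted on the
#' calculation process, i.e. the hierarchical representation; occurrences,
#' not distinct values (the Quad worked example counts its twice-used
#' subordinate second term twice).
#'
#' @param forest A hierarchical `calc_forest`.
#' @return Non-negative integer.
#' @export
count_generated_digits <- function(forest) {
  stopifnot(inherits(forest, "calc_forest"))
  if (forest$representation != "hierarchical")
    stop("generated digits are defined on the hierarchical calculation process",
         call. = FALSE)
  n_gen <- function(node) {
    if (node$kind == "terminal") return(as.integer(!is.null(node$reuse_of)))
    sum(vapply(node$children, function(ch) {
      (ch$kind == "nonterminal") + n_gen(ch)
    }, integer(1)))
  }
  sum(vapply(forest$roots, n_gen, integer(1)))
}

#' Number of digits stored in memory for matching
#'
#' Two for each arithmetic condition (the two calculation results), five
#' for the Match task (all presented digits).
#'
#' @param condition Condition name.
#' @return 2 or 5.
#' @export
count_stored_digits <- function(condition) {
  condition <- match.arg(condition, CONDITIONS)
  if (condition == "Match") 5L else 2L
}

#' Verbal-encoding load of a trial
#'
#' The total number of digits and operations that would be verbalized when
#' covertly speaking each elementary calculation: the number of nodes of
#' the flat representation plus the number of operations.
#'
#' @param forest A `calc_forest` (flattened internally if hierarchical).
#' @return Non-negative integer.
#' @export
verbal_encoding <- function(forest) {
  stopifnot(inherits(forest, "calc_forest"))
  flat <- if (forest$representation == "hierarchical") flatten(forest) else forest
  count_nodes(flat) + count_operations(flat)
}

# All eight per-trial factor values for one stimulus (five digits).
trial_factors <- function(digits) {
  vals <- integer(length(FACTORS))
  names(vals) <- FACTORS
  out <- list()
  for (cond in CONDITIONS) {
    hier <- build_trial_forest(cond, digits)
    flat <- flatten(hier)
    out[[cond]] <- c(
      dom_hier = degree_of_merger(hier),
      nodes_hier = count_nodes(hier),
      dom_flat = degree_of_merger(flat),
      nodes_flat = count_nodes(flat),
      verbal_encoding = verbal_encoding(hier),
      n_operations = count_operations(hier),
      n_generated = count_generated_digits(hier),
      n_stored = count_stored_digits(cond))
  }
  out
}

#' Condition-level factor estimate table
#'
#' The estimate of a factor for a condition is the largest value the
#' factor can take over the valid stimulus space, so that its unit load is
#' invariable among conditions and estimates of the same factor can be
#' subtracted independently. Computed by enumerating valid stimuli (the
#' per-trial metrics are in fact constant over the space, so the maximum
#' equals the common value).
#'
#' @param stimuli Optional list of five-digit stimuli to enumerate; by
#'   default the full valid stimulus space.
#' @return A `factor_estimates` data.frame: one row per factor, one column
#'   per condition.
#' @export
estimates_table <- function(stimuli = NULL) {
  if (is.null(stimuli)) stimuli <- all_valid_stimuli()
  est <- matrix(0L, length(FACTORS), length(CONDITIONS),
                dimnames = list(FACTORS, CONDITIONS))
  for (dg in stimuli) {
    tf <- trial_factors(dg)
    for (cond in CONDITIONS)
      est[, cond] <- pmax(est[, cond], tf[[cond]][FACTORS])
  }
  out <- as.data.frame(est)
  class(out) <- c("factor_estimates", "data.frame")
  out
}

# cache: the table is constant, enumeration only needs to happen once
.domarith_cache <- new.env(parent = emptyenv())

default_estimates <- function() {
  if (is.null(.domarith_cache$estimates))
    .domarith_cache$estimates <- estimates_table()
  .domarith_cache$estimates
}

#' Contrast (subtracted) factor estimates
#'
#' Componentwise difference of two conditions' estimate columns; positive
#' and negative values correspond to predicted activations and
#' deactivations relative to the reference condition.
#'
#' @param table A `factor_estimates` table.
#' @param contrast Length-2 character vector `c(A, B)` for the contrast
#'   `A - B`, or a string like `"Linear - Simple"`.
#' @return Named integer vector, one entry per factor.
#' @export
#' @examples
#' contrast_estimates(estimates_table(), "Linear - Simple")
contrast_estimates <- function(table, contrast) {
  if (is.character(contrast) && length(contrast) == 1L)
    contrast <- strsplit(contrast, "\\s*-\\s*")[[1]]
  if (length(contrast) != 2L || !all(contrast %in% colnames(table)))
    stop("contrast must name two conditions present in the table",
         call. = FALSE)
  v <- as.integer(table[[contrast[1]]] - table[[contrast[2]]])
  names(v) <- rownames(table)
  v
}

# The three activation contrasts of the region-of-interest analysis.
PSC_CONTRASTS <- c("Simple - Match", "Linear - Match", "Quad - Match")

# factor -> 3-vector of subtracted estimates for the three contrasts vs Match
factor_contrast_vector <- function(factor,
                                   table = default_estimates(),
                                   contrasts = PSC_CONTRASTS) {
  if (!factor %in% rownames(table))
    stop("unknown factor: ", factor, call. = FALSE)
  vapply(contrasts, function(ct) contrast_estimates(table, ct)[[factor]],
         numeric(1))
}

#' Write / read a factor estimate table as CSV
#'
#' Factors as rows, conditions as columns.
#'
#' @param table A `factor_estimates` table.
#' @param path File path.
#' @return `read_estimates_csv` returns a `factor_estimates` table.
#' @export
write_estimates_csv <- function(table, path) {
  write.csv(cbind(factor = rownames(table), table), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_estimates_csv
#' @export
read_estimates_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  rownames(df) <- df$factor
  df$factor <- NULL
  class(df) <- c("factor_estimates", "data.frame")
  df
}
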