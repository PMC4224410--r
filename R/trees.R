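#' @useDynLib domarith, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats ave convolve dgamma digamma optim optimize rgamma rnorm
#'   sd setNames t.test
#' @importFrom utils read.csv write.csv
"_PACKAGE"

CONDITIONS <- c("Simple", "Linear", "Quad", "Match")

check_digit <- function(x, lo = 0L, hi = 9L, what = "digit") {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) ||
      x < lo || x > hi) {
    stop(sprintf("%s must be a single integer in %d-%d, got: %s",
                 what, lo, hi, paste(format(x), collapse = ",")), call. = FALSE)
  }
  as.integer(x)
}

#' Create a calculation-tree node
#'
#' A node of a calculation tree. Terminal nodes hold a digit that is (or
#' re-enters as) an operand; nonterminal nodes hold the full result of one
#' binary arithmetic operation (a Merge), which may exceed 9 — the mod-10
#' storage rule applies only to digits kept in memory for matching, not to
#' the node value itself.
#'
#' @param value Integer node value (full arithmetic result for nonterminals).
#' @param kind `"terminal"` or `"nonterminal"`.
#' @param op Operation producing the value: `"add"`, `"abs_sub"`, or `"none"`
#'   (terminals only).
#' @param children For nonterminals, a list of exactly two child nodes
#'   (binary Merge); empty for terminals.
#' @param reuse_of Optional id of an earlier nonterminal whose value this
#'   terminal re-enters (a generated digit used again later in the same
#'   calculation).
#' @param id Optional node id (nonterminals are labelled `m1`, `m2`, ... in
#'   execution order by the builders).
#' @return A `calc_node`.
#' @export
calc_node <- function(value, kind = c("terminal", "nonterminal"),
                      op = c("none", "add", "abs_sub"),
                      children = list(), reuse_of = NULL, id = NULL) {
  kind <- match.arg(kind)
  op <- match.arg(op)
  value <- check_digit(value, 0L, .Machine$integer.max, "node value")
  if (kind == "nonterminal" && (op == "none" || length(children) != 2L))
    stop("a nonterminal node needs an operation and exactly 2 children",
         call. = FALSE)
  if (kind == "terminal" && (op != "none" || length(children) != 0L))
    stop("a terminal node has no operation and no children", call. = FALSE)
  structure(list(value = value, display_digit = value %% 10L, kind = kind,
                 op = op, children = children, reuse_of = reuse_of, id = id),
            class = "calc_node")
}

new_forest <- function(condition, representation, roots, screen_digits,
                       stored_digits) {
  structure(list(condition = condition, representation = representation,
                 roots = roots,
                 screen_digits = as.integer(screen_digits),
                 stored_digits = sort(as.integer(stored_digits))),
            class = "calc_forest")
}

#' @export
print.calc_forest <- function(x, ...) {
  cat(sprintf("<calc_forest> %s (%s): %d root(s)\n",
              x$condition, x$representation, length(x$roots)))
  cat("  screen digits:", paste(x$screen_digits, collapse = " "), "\n")
  cat("  stored digits:", paste(x$stored_digits, collapse = " "), "\n")
  for (r in x$roots) cat("  ", deparse_node(r), "\n", sep = "")
  invisible(x)
}

deparse_node <- function(node) {
  if (node$kind == "terminal") {
    if (!is.null(node$reuse_of))
      sprintf("%d@%s", node$display_digit, node$reuse_of)
    else as.character(node$display_digit)
  } else {
    sprintf("(%s %s %s -> %d)",
            deparse_node(node$children[[1]]),
            if (node$op == "add") "+" else "|-|",
            deparse_node(node$children[[2]]), node$value)
  }
}

#' Addition with the last-digit storage rule
#'
#' Adds two digits; when the result is a two-figure number only its last
#' digit (the one's place) is kept in memory for the matching judgement.
#'
#' @param a,b Digits 0-9.
#' @return List with `value` (the full sum) and `stored` (the digit kept).
#' @export
#' @examples
#' add_with_carry_rule(3, 7)  # value 10, stored 0
add_with_carry_rule <- function(a, b) {
  a <- check_digit(a); b <- check_digit(b)
  v <- a + b
  list(value = v, stored = v %% 10L)
}

#' Absolute-difference subtraction
#'
#' The task's single subtraction rule: always subtract the smaller value
#' from the larger, so the result is never negative.
#'
#' @param a,b Digits 0-9.
#' @return `|a - b|`.
#' @export
abs_sub <- function(a, b) {
  a <- check_digit(a); b <- check_digit(b)
  abs(a - b)
}

# internal: terminal leaf for a screen digit
leaf <- function(d) calc_node(d, "terminal")

#' Build the hierarchical forest for the Simple condition
#'
#' Addition and subtraction of the upper two digits form two independent
#' depth-1 trees, drawn side by side and counted as a single two-root
#' forest. Stored digits: the last digit of the sum and the absolute
#' difference.
#'
#' @param d1,d2 The upper pair of screen digits (`d1 < d2`, both 1-9).
#' @return A hierarchical `calc_forest` with two roots.
#' @export
#' @examples
#' build_simple(3, 7)  # roots 10 and 4, stored {0, 4}
build_simple <- function(d1, d2) {
  d1 <- check_digit(d1, 1L, 9L); d2 <- check_digit(d2, 1L, 9L)
  if (d1 >= d2) stop("upper pair must be increasing", call. = FALSE)
  s <- add_with_carry_rule(d1, d2)
  root_add <- calc_node(s$value, "nonterminal", "add",
                        list(leaf(d1), leaf(d2)), id = "m1")
  root_sub <- calc_node(abs_sub(d1, d2), "nonterminal", "abs_sub",
                        list(leaf(d1), leaf(d2)), id = "m2")
  new_forest("Simple", "hierarchical", list(root_add, root_sub),
             c(d1, d2), c(s$stored, abs_sub(d1, d2)))
}

#' Build the hierarchical tree for the Linear condition
#'
#' The upper pair starts an increasing arithmetic progression; the third
#' term is the constant difference (a subtraction) added to the second term,
#' which re-enters the tree as a terminal. Stored digits: the constant
#' difference and the last digit of the third term.
#'
#' @inheritParams build_simple
#' @return A hierarchical single-root `calc_forest`.
#' @export
#' @examples
#' build_linear(3, 7)  # [|3-7| + 7] = 11, stored {4, 1}
build_linear <- function(d1, d2) {
  d1 <- check_digit(d1, 1L, 9L); d2 <- check_digit(d2, 1L, 9L)
  if (d1 >= d2) stop("upper pair must be increasing", call. = FALSE)
  diff_node <- calc_node(abs_sub(d1, d2), "nonterminal", "abs_sub",
                         list(leaf(d1), leaf(d2)), id = "m1")
  third <- add_with_carry_rule(diff_node$value, d2)
  root <- calc_node(third$value, "nonterminal", "add",
                    list(diff_node, leaf(d2)), id = "m2")
  new_forest("Linear", "hierarchical", list(root),
             c(d1, d2), c(diff_node$value, third$stored))
}

#' Build the hierarchical tree for the Quad condition
#'
#' The lower triple starts an increasing quadratic sequence. Two
#' subtractions give the first two terms of the subordinate linear
#' sequence; their difference is its constant difference, which is added to
#' the subordinate second term (re-entering as a terminal carrying
#' `reuse_of`) to give the subordinate third term. Stored digits: the
#' constant difference and the last digit of the answer.
#'
#' @param c1,d,e The lower triple of screen digits (`c1 < d < e`, all 1-9).
#' @return A hierarchical single-root `calc_forest`.
#' @export
#' @examples
#' build_quad(2, 4, 9)  # [||2-4| - |4-9|| + 5] = 8, stored {3, 8}
build_quad <- function(c1, d, e) {
  c1 <- check_digit(c1, 1L, 9L); d <- check_digit(d, 1L, 9L)
  e <- check_digit(e, 1L, 9L)
  if (!(c1 < d && d < e)) stop("lower triple must be increasing", call. = FALSE)
  s1 <- calc_node(abs_sub(c1, d), "nonterminal", "abs_sub",
                  list(leaf(c1), leaf(d)), id = "m1")
  s2 <- calc_node(abs_sub(d, e), "nonterminal", "abs_sub",
                  list(leaf(d), leaf(e)), id = "m2")
  cd <- calc_node(abs_sub(s1$value, s2$value), "nonterminal", "abs_sub",
                  list(s1, s2), id = "m3")
  reused <- calc_node(s2$value, "terminal", reuse_of = "m2")
  ans <- add_with_carry_rule(cd$value, s2$value)
  root <- calc_node(ans$value, "nonterminal", "add",
                    list(cd, reused), id = "m4")
  new_forest("Quad", "hierarchical", list(root),
             c(c1, d, e), c(cd$value, ans$stored))
}

#' Build the (trivially flat) forest for the Match task
#'
#' All five presented digits are simply stored; the forest has five
#' terminal roots and no Merge.
#'
#' @param digits Five distinct digits 1-9.
#' @return A hierarchical `calc_forest` of five terminal roots.
#' @export
build_match <- function(digits) {
  digits <- vapply(digits, check_digit, integer(1), lo = 1L, hi = 9L)
  if (length(digits) != 5L || anyDuplicated(digits))
    stop("Match needs five distinct digits 1-9", call. = FALSE)
  new_forest("Match", "hierarchical", lapply(digits, leaf), digits, digits)
}

#' Build the forest for one trial of a given condition
#'
#' @param condition One of `"Simple"`, `"Linear"`, `"Quad"`, `"Match"`.
#' @param digits The five screen digits, upper pair first then lower triple.
#' @return A hierarchical `calc_forest`.
#' @export
build_trial_forest <- function(condition, digits) {
  condition <- match.arg(condition, CONDITIONS)
  if (length(digits) != 5L) stop("need the five screen digits", call. = FALSE)
  f <- switch(condition,
              Simple = build_simple(digits[1], digits[2]),
              Linear = build_linear(digits[1], digits[2]),
              Quad = build_quad(digits[3], digits[4], digits[5]),
              Match = build_match(digits))
  f$screen_digits <- as.integer(digits)  # record the full five-digit display
  f
}

# Elementary calculations of a hierarchical forest, in execution order
# (left-to-right post-order: each Merge fires after its operands exist).
elementary_calcs <- function(forest) {
  out <- list()
  rec <- function(node) {
    if (node$kind == "terminal") return(invisible(NULL))
    rec(node$children[[1]])
    rec(node$children[[2]])
    out[[length(out) + 1L]] <<- list(
      op = node$op,
      a = node$children[[1]]$value,
      b = node$children[[2]]$value,
      result = node$value)
  }
  for (r in forest$roots) rec(r)
  out
}

#' Flatten a hierarchical forest into independent depth-1 calculations
#'
#' The flat representation models covert verbalization of each elementary
#' calculation: one depth-1 tree per Merge, in execution order, with every
#' operand and result re-listed as a fresh token (generated digits are
#' spoken again for each calculation that uses them). A Match forest is
#' unchanged apart from the representation label.
#'
#' @param forest A hierarchical `calc_forest`.
#' @return A flat `calc_forest`.
#' @export
flatten <- function(forest) {
  stopifnot(inherits(forest, "calc_forest"))
  if (forest$representation != "hierarchical")
    stop("flatten expects a hierarchical forest", call. = FALSE)
  calcs <- elementary_calcs(forest)
  roots <- lapply(seq_along(calcs), function(i) {
    cl <- calcs[[i]]
    calc_node(cl$result, "nonterminal", cl$op,
              list(leaf(cl$a), leaf(cl$b)), id = paste0("m", i))
  })
  if (length(roots) == 0L) roots <- forest$roots  # Match: no calculations
  new_forest(forest$condition, "flat", roots, forest$screen_digits,
             forest$stored_digits)
}

#' Terms of the arithmetic (linear) progression started by a digit pair
#'
#' @param a,b First two terms, `a < b`.
#' @param n Number of terms to return.
#' @return Integer vector of the first `n` terms.
#' @export
#' @examples
#' linear_terms(3, 7, 5)  # 3 7 11 15 19
linear_terms <- function(a, b, n = 3L) {
  stopifnot(n >= 2L)
  a + (b - a) * (seq_len(n) - 1L)
}

#' Terms of the quadratic sequence started by a digit triple
#'
#' The adjacent-term differences form the subordinate linear sequence; each
#' further term adds the next subordinate term.
#'
#' @param c1,d,e First three terms, increasing.
#' @param n Number of terms to return.
#' @return Integer vector of the first `n` terms.
#' @export
#' @examples
#' quadratic_terms(2, 4, 9, 5)  # 2 4 9 17 28
quadratic_terms <- function(c1, d, e, n = 4L) {
  stopifnot(n >= 3L)
  diffs <- linear_terms(d - c1, e - d, max(n - 1L, 2L))
  cumsum(c(c1, diffs))[seq_len(n)]
}

#' One-trial record for downstream export
#'
#' @param forest A `calc_forest`.
#' @return List with condition, screen digits, stored digits, and the
#'   condition's answer (root value of the final calculation; `NA` for Match).
#' @export
trial_record <- function(forest) {
  stopifnot(inherits(forest, "calc_forest"))
  nonterm <- Filter(function(r) r$kind == "nonterminal", forest$roots)
  answer <- if (length(nonterm)) nonterm[[length(nonterm)]]$value else NA_integer_
  list(condition = forest$condition,
       digits = forest$screen_digits,
       stored = forest$stored_digits,
       answer = answer)
}
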