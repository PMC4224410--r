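# Forest serialization: a small Newick dialect and a JSON structured-text
# form. Both round-trip exactly (parse(serialize(f)) reproduces f).

node_to_newick <- function(node) {
  if (node$kind == "terminal") {
    if (!is.null(node$reuse_of))
      sprintf("%d@%s", node$display_digit, node$reuse_of)
    else as.character(node$display_digit)
  } else {
    sprintf("(%s,%s)%d:%s#%s",
            node_to_newick(node$children[[1]]),
            node_to_newick(node$children[[2]]),
            node$value, node$op, node$id)
  }
}

node_to_list <- function(node) {
  out <- list(value = node$value, kind = node$kind, op = node$op)
  if (!is.null(node$id)) out$id <- node$id
  if (!is.null(node$reuse_of)) out$reuse_of <- node$reuse_of
  if (node$kind == "nonterminal")
    out$children <- lapply(node$children, node_to_list)
  out
}

list_to_node <- function(x) {
  calc_node(x$value, x$kind, x$op,
            children = if (is.null(x$children)) list()
                       else lapply(x$children, list_to_node),
            reuse_of = x$reuse_of, id = x$id)
}

#' Serialize a calculation forest to text
#'
#' `"newick"` writes a header comment line (`[&condition=...,...]`) followed
#' by one tree per line; internal nodes are labelled `value:op#id`, leaves
#' with their display digit, reused generated digits as `digit@id`.
#' `"json"` writes the full nested structure via jsonlite.
#'
#' @param forest A `calc_forest`.
#' @param format `"newick"` or `"json"`.
#' @return A single character string.
#' @seealso [parse_forest()]
#' @export
serialize_forest <- function(forest, format = c("newick", "json")) {
  stopifnot(inherits(forest, "calc_forest"))
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(condition = forest$condition,
                    representation = forest$representation,
                    screen_digits = forest$screen_digits,
                    stored_digits = forest$stored_digits,
                    roots = lapply(forest$roots, node_to_list))
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE)))
  }
  header <- sprintf("[&condition=%s,representation=%s,screen=%s,stored=%s]",
                    forest$condition, forest$representation,
                    paste(forest$screen_digits, collapse = "."),
                    paste(forest$stored_digits, collapse = "."))
  trees <- vapply(forest$roots,
                  function(r) paste0(node_to_newick(r), ";"), character(1))
  paste(c(header, trees), collapse = "\n")
}

parse_newick_node <- function(s) {
  pos <- 1L
  n <- nchar(s)
  peek <- function() substr(s, pos, pos)
  take_while <- function(chars_re) {
    start <- pos
    while (pos <= n && grepl(chars_re, substr(s, pos, pos))) pos <<- pos + 1L
    substr(s, start, pos - 1L)
  }
  parse_node <- function() {
    if (peek() == "(") {
      pos <<- pos + 1L
      left <- parse_node()
      if (peek() != ",") stop("newick parse error: expected ','", call. = FALSE)
      pos <<- pos + 1L
      right <- parse_node()
      if (peek() != ")") stop("newick parse error: expected ')'", call. = FALSE)
      pos <<- pos + 1L
      label <- take_while("[^,();]")
      m <- regmatches(label, regexec("^([0-9]+):([a-z_]+)#([A-Za-z0-9]+)$", label))[[1]]
      if (length(m) != 4L)
        stop("newick parse error: bad internal label: ", label, call. = FALSE)
      calc_node(as.integer(m[2]), "nonterminal", m[3],
                list(left, right), id = m[4])
    } else {
      label <- take_while("[^,();]")
      m <- regmatches(label, regexec("^([0-9]+)(@([A-Za-z0-9]+))?$", label))[[1]]
      if (length(m) == 0L)
        stop("newick parse error: bad leaf label: ", label, call. = FALSE)
      calc_node(as.integer(m[2]), "terminal",
                reuse_of = if (nzchar(m[4])) m[4] else NULL)
    }
  }
  node <- parse_node()
  if (pos <= n && peek() != ";")
    stop("newick parse error: trailing input", call. = FALSE)
  node
}

#' Parse a serialized calculation forest
#'
#' @param text Output of [serialize_forest()].
#' @param format `"newick"` or `"json"`.
#' @return A `calc_forest`.
#' @export
parse_forest <- function(text, format = c("newick", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    x <- jsonlite::fromJSON(text, simplifyVector = FALSE)
    return(new_forest(x$condition, x$representation,
                      lapply(x$roots, list_to_node),
                      unlist(x$screen_digits), unlist(x$stored_digits)))
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  hdr <- regmatches(lines[1], regexec(
    "^\\[&condition=([A-Za-z]+),representation=([a-z]+),screen=([0-9.]+),stored=([0-9.]*)\\]$",
    lines[1]))[[1]]
  if (length(hdr) != 5L)
    stop("newick parse error: bad header line", call. = FALSE)
  digits_of <- function(s) if (nzchar(s)) as.integer(strsplit(s, ".", fixed = TRUE)[[1]])
                           else integer(0)
  roots <- lapply(lines[-1], parse_newick_node)
  new_forest(hdr[2], hdr[3], roots, digits_of(hdr[4]), digits_of(hdr[5]))
}

#' Structural equality of two forests
#'
#' Compares condition, representation, digit sets, and the full recursive
#' node structure (values, kinds, operations, reuse links).
#'
#' @param a,b `calc_forest` objects.
#' @return Logical.
#' @export
forests_equal <- function(a, b) {
  identical(serialize_forest(a, "json"), serialize_forest(b, "json"))
}
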