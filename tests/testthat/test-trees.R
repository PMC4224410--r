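test_that("elementary arithmetic rules follow the task instructions", {
  expect_equal(add_with_carry_rule(3, 7), list(value = 10L, stored = 0L))
  expect_equal(add_with_carry_rule(2, 3), list(value = 5L, stored = 5L))
  expect_equal(add_with_carry_rule(9, 9), list(value = 18L, stored = 8L))
  expect_equal(abs_sub(3, 7), 4L)
  expect_equal(abs_sub(5, 5), 0L)
  expect_equal(abs_sub(2, 4), 2L)
  expect_error(add_with_carry_rule(10, 3), "digit")
  expect_error(abs_sub(2.5, 3), "digit")
})

test_that("Simple forests hold the two independent calculations", {
  cases <- list(list(d = c(3, 7), vals = c(10, 4), stored = c(0, 4)),
                list(d = c(1, 9), vals = c(10, 8), stored = c(0, 8)),
                list(d = c(4, 9), vals = c(13, 5), stored = c(3, 5)))
  for (cs in cases) {
    f <- build_simple(cs$d[1], cs$d[2])
    expect_length(f$roots, 2)
    expect_equal(vapply(f$roots, `[[`, integer(1), "value"), cs$vals)
    expect_equal(f$stored_digits, sort(as.integer(cs$stored)))
  }
  expect_error(build_simple(7, 3), "increasing")
})

test_that("Linear trees compute the third term with the difference re-entering", {
  cases <- list(list(d = c(3, 7), root = 11, stored = c(4, 1)),
                list(d = c(1, 4), root = 7, stored = c(3, 7)),
                list(d = c(2, 9), root = 16, stored = c(7, 6)))
  for (cs in cases) {
    f <- build_linear(cs$d[1], cs$d[2])
    expect_length(f$roots, 1)
    expect_equal(f$roots[[1]]$value, as.integer(cs$root))
    expect_equal(f$stored_digits, sort(as.integer(cs$stored)))
    # left subtree is the subtraction, right child the re-entering 2nd term
    expect_equal(f$roots[[1]]$children[[1]]$op, "abs_sub")
    expect_equal(f$roots[[1]]$children[[2]]$value, as.integer(cs$d[2]))
  }
})

test_that("Quad trees nest the subordinate sequence and reuse its 2nd term", {
  cases <- list(
    list(d = c(2, 4, 9), s = c(2, 5), cd = 3, root = 8, stored = c(3, 8)),
    list(d = c(1, 4, 9), s = c(3, 5), cd = 2, root = 7, stored = c(2, 7)),
    list(d = c(1, 3, 7), s = c(2, 4), cd = 2, root = 6, stored = c(2, 6)))
  for (cs in cases) {
    f <- build_quad(cs$d[1], cs$d[2], cs$d[3])
    root <- f$roots[[1]]
    cd_node <- root$children[[1]]
    expect_equal(root$value, as.integer(cs$root))
    expect_equal(cd_node$value, as.integer(cs$cd))
    expect_equal(vapply(cd_node$children, `[[`, integer(1), "value"),
                 as.integer(cs$s))
    expect_equal(f$stored_digits, sort(as.integer(cs$stored)))
    # the reused subordinate second term is a terminal with a reuse link
    reused <- root$children[[2]]
    expect_equal(reused$kind, "terminal")
    expect_equal(reused$reuse_of, cd_node$children[[2]]$id)
  }
  expect_error(build_quad(4, 2, 9), "increasing")
})

test_that("Match forests store all five digits without any Merge", {
  f <- build_match(c(3, 7, 2, 4, 9))
  expect_length(f$roots, 5)
  expect_true(all(vapply(f$roots, `[[`, character(1), "kind") == "terminal"))
  expect_equal(f$stored_digits, sort(c(3L, 7L, 2L, 4L, 9L)))
  # storage is order-free
  g <- build_match(c(9, 4, 2, 7, 3))
  expect_equal(g$stored_digits, f$stored_digits)
  expect_error(build_match(c(1, 1, 2, 3, 4)), "distinct")
})

test_that("flatten re-lists every elementary calculation with fresh tokens", {
  fl <- flatten(build_linear(3, 7))
  expect_equal(fl$representation, "flat")
  expect_length(fl$roots, 2)
  expect_equal(lapply(fl$roots, function(r)
    c(r$children[[1]]$value, r$children[[2]]$value, r$value)),
    list(c(3L, 7L, 4L), c(4L, 7L, 11L)))
  fq <- flatten(build_quad(2, 4, 9))
  expect_equal(lapply(fq$roots, function(r)
    c(r$children[[1]]$value, r$children[[2]]$value, r$value)),
    list(c(2L, 4L, 2L), c(4L, 9L, 5L), c(2L, 5L, 3L), c(3L, 5L, 8L)))
  fm <- flatten(build_match(c(1, 2, 4, 6, 9)))
  expect_equal(fm$representation, "flat")
  expect_length(fm$roots, 5)
  expect_error(flatten(fq), "hierarchical")
})

test_that("flatten preserves the multiset of elementary calculations", {
  for (dg in sample_stimuli()) {
    for (cond in c("Simple", "Linear", "Quad")) {
      h <- build_trial_forest(cond, dg)
      expect_equal(oracle_calc_multiset(flatten(h)), oracle_calc_multiset(h))
    }
  }
})

test_that("closed forms hold over the whole valid stimulus space", {
  for (dg in all_valid_stimuli()) {
    lin <- build_linear(dg[1], dg[2])
    expect_equal(lin$roots[[1]]$value, 2L * dg[2] - dg[1])
    qd <- build_quad(dg[3], dg[4], dg[5])
    s1 <- dg[4] - dg[3]; s2 <- dg[5] - dg[4]
    expect_equal(qd$roots[[1]]$value, 2L * s2 - s1)
  }
})

test_that("all node values are non-negative and display digits are 0-9", {
  for (dg in sample_stimuli()) {
    for (cond in CONDITIONS) {
      h <- build_trial_forest(cond, dg)
      for (f in list(h, flatten(h))) {
        for (node in oracle_all_nodes(f)) {
          expect_gte(node$value, 0)
          expect_true(node$display_digit %in% 0:9)
          expect_equal(node$display_digit, node$value %% 10L)
          if (node$kind == "nonterminal") {
            expect_length(node$children, 2)
            expect_true(node$op %in% c("add", "abs_sub"))
          } else {
            expect_length(node$children, 0)
            expect_equal(node$op, "none")
          }
        }
      }
    }
  }
})

test_that("sequence continuations match the task's worked progressions", {
  expect_equal(linear_terms(3, 7, 5), c(3, 7, 11, 15, 19))
  expect_equal(quadratic_terms(2, 4, 9, 5), c(2, 4, 9, 17, 28))
  expect_equal(quadratic_terms(1, 2, 5, 5), c(1, 2, 5, 10, 17))
})

test_that("serialization round-trips in both formats", {
  forests <- list(build_simple(3, 7), build_linear(3, 7),
                  build_quad(2, 4, 9), flatten(build_quad(2, 4, 9)),
                  build_match(c(1, 2, 3, 4, 5)),
                  build_trial_forest("Quad", c(3, 7, 2, 4, 9)))
  for (f in forests) {
    for (fmt in c("newick", "json")) {
      expect_true(forests_equal(f, parse_forest(serialize_forest(f, fmt),
                                                fmt)))
    }
  }
  nw <- serialize_forest(build_simple(3, 7), "newick")
  expect_match(nw, "\\(3,7\\)10:add", fixed = FALSE)
  expect_match(nw, "\\(3,7\\)4:abs_sub", fixed = FALSE)
  expect_length(strsplit(serialize_forest(build_match(1:5 * 0 + c(1, 2, 3, 4, 5)),
                                          "newick"), "\n")[[1]], 6)
  expect_error(serialize_forest(build_simple(3, 7), "xml"))
})

test_that("trial records expose condition, digits, storage and answer", {
  rec <- trial_record(build_quad(2, 4, 9))
  expect_equal(rec$condition, "Quad")
  expect_equal(rec$answer, 8L)
  expect_equal(rec$stored, c(3L, 8L))
  expect_true(is.na(trial_record(build_match(c(1, 2, 4, 6, 9)))$answer))
})
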