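# Parser and desugarer.

top_level_counts <- function(ast) {
  counts <- c(module_def = 0L, agent_def = 0L, invoke = 0L)
  walk <- function(nd) {
    switch(nd$kind,
      scoped = {
        if (nd$def$kind %in% names(counts)) {
          counts[[nd$def$kind]] <<- counts[[nd$def$kind]] + 1L
        }
        walk(nd$body)
      },
      parallel = {
        walk(nd$left)
        walk(nd$right)
      },
      invoke = counts[["invoke"]] <<- counts[["invoke"]] + 1L,
      NULL)
  }
  walk(ast)
  counts
}

test_that("basic rules parse, in ASCII and in the typeset glyphs", {
  ast <- lbsk_parse("A -> {0.1} B")
  expect_identical(ast$kind, "rule")
  expect_identical(ast$fwd$kind, "rate_const")
  expect_equal(ast$fwd$value, 0.1)
  expect_identical(length(ast$lhs), 1L)
  expect_identical(ast$lhs[[1]]$expr$kind, "ident")

  expect_identical(lbsk_parse("A → {0.1} B"), ast)
  expect_identical(
    lbsk_parse("c ↔ c⟨P{f˜1}⟩"),
    lbsk_parse("c <-> c<P{f~1}>"))
})

test_that("the empty program parses to nil", {
  expect_identical(lbsk_parse("")$kind, "nil")
  expect_identical(lbsk_parse("  // only a comment\n")$kind, "nil")
})

test_that("the full MAPK listing parses with the expected structure", {
  ast <- lbsk_parse(fixture("mapk")$source)
  counts <- top_level_counts(ast)
  expect_identical(counts[["module_def"]], 1L)
  expect_identical(counts[["agent_def"]], 7L)
  expect_identical(counts[["invoke"]], 5L)
  # the outer cycle module contains the two nested modules
  expect_identical(ast_count(ast, "module_def"), 3L)
})

test_that("every in-print example program parses without error", {
  for (nm in fixture_names()) {
    expect_no_error(lbsk_parse(fixture(nm)$source))
  }
})

test_that("syntax errors carry a position and a reason", {
  err <- tryCatch(lbsk_parse("agent A = new {x"), error = function(e) e)
  expect_s3_class(err, "lbsk_parse_error")
  expect_match(conditionMessage(err), "line")
  expect_error(lbsk_parse("A -> B -> C"), class = "lbsk_parse_error")
  expect_error(lbsk_parse("A{x, x} -> A{x}"), regexp = "duplicate site",
               class = "lbsk_parse_error")
  expect_error(lbsk_parse("cell[ A -> B"), class = "lbsk_parse_error")
})

test_that("reversible rules desugar to a pair of directed rules", {
  ast <- lbsk_desugar(lbsk_parse("c000 <->{2}{3} c000<P2{f~1}>"))
  expect_identical(ast$kind, "parallel")
  expect_identical(ast$left$kind, "rule")
  expect_identical(ast$right$kind, "rule")
  expect_equal(ast$left$fwd$value, 2)
  expect_equal(ast$right$fwd$value, 3)
  # directions mirror each other
  expect_identical(ast$left$lhs, ast$right$rhs)
  expect_identical(ast$left$rhs, ast$right$lhs)
  # omitted rates default to 1
  both <- lbsk_desugar(lbsk_parse("A <-> B"))
  expect_equal(both$left$fwd$value, 1)
  expect_equal(both$right$fwd$value, 1)
})

test_that("agent literals desugar to updates and 'as' bindings hoist", {
  ast <- lbsk_desugar(lbsk_parse("Shc{Y318~p} -> Shc{Y318~u}"))
  lhs <- ast$lhs[[1]]$expr
  expect_identical(lhs$kind, "update")
  expect_identical(lhs$target, "Shc")
  expect_identical(lhs$base$kind, "ident")
  # inside an update, an omitted internal state is the identity and an
  # omitted link is free
  entry <- lhs$sites[[1]]
  expect_identical(entry$internal$kind, "value")
  expect_identical(entry$link$kind, "free")
  bare <- lbsk_desugar(lbsk_parse("Raf{x} -> Raf{x!1}"))
  expect_identical(bare$lhs[[1]]$expr$sites[[1]]$internal$kind, "identity")

  # `as` on either side becomes a definition scoping the remainder
  hoisted <- lbsk_desugar(lbsk_parse(
    "k{m} + s{m~u} -> k{m!1}-s{m~u!1} as c; c -> c<s{m~p!e}>"))
  expect_identical(hoisted$kind, "scoped")
  expect_identical(hoisted$def$kind, "agent_def")
  expect_identical(hoisted$def$ids, "c")
})

test_that("a new without a name takes the defining identifier", {
  ast <- lbsk_desugar(lbsk_parse("agent Shc = new {PTB:(u p), Y318:(u p)};"))
  expect_identical(ast$def$expr$kind, "new_agent")
  expect_identical(ast$def$expr$name, "Shc")
  expect_error(lbsk_desugar(lbsk_parse("agent a, b = A{x}; ")),
               regexp = "alias", class = "lbsk_elab_error")
})

test_that("desugaring is idempotent", {
  for (nm in c("mapk", "chemotaxis", "complex_update", "nondet_mek_erk")) {
    once <- lbsk_desugar(lbsk_parse(fixture(nm)$source))
    expect_identical(lbsk_desugar(once), once)
  }
})

test_that("parse . format . parse is the identity on syntax trees", {
  for (nm in fixture_names()) {
    ast <- lbsk_parse(fixture(nm)$source)
    expect_identical(lbsk_parse(lbsk_format(ast)), ast)
  }
  for (seed in 1:10) {
    src <- random_model(seed, n_agents = 3L, n_modules = 2L,
                        max_depth = 2L)$source
    ast <- lbsk_parse(src)
    expect_identical(lbsk_parse(lbsk_format(ast)), ast)
  }
})
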