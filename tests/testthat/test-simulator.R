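# Embedding enumeration and the Gillespie simulator.

test_that("embedding counts on the worked examples", {
  mix <- mixture_from("agent Raf = new {x};", "init Raf{x~u} 10")
  pat <- parse_pattern("Raf{x}")
  pat[[1]]$sites[[1]]$link <- lbskappa:::link_free()
  expect_identical(find_embeddings(pat, mix)$count, 10L)

  mix2 <- mixture_from(
    "agent A = new {s}; agent B = new {t};",
    "init A{s~u!1}-B{t~u!1} 3 | init A{s~u} 2")
  dimer <- parse_pattern("A{s!1}-B{t!1}")
  expect_identical(find_embeddings(dimer, mix2)$count, 3L)
  freeA <- parse_pattern("A{s}")
  freeA[[1]]$sites[[1]]$link <- lbskappa:::link_free()
  expect_identical(find_embeddings(freeA, mix2)$count, 2L)

  # a pattern constraining an internal state no agent carries matches nothing
  mix3 <- mixture_from("agent MEK = new {S222};", "init MEK{S222~p} 5")
  expect_identical(find_embeddings(parse_pattern("MEK{S222~u}"), mix3)$count, 0L)
})

test_that("embedding counts equal the brute-force all-injections oracle", {
  cases <- list(
    list(defs = "agent A = new {s}; agent B = new {t};",
         init = "init A{s~u!1}-B{t~u!1} 2 | init A{s~u} 2 | init B{t~p} 1",
         pats = c("A{s!1}-B{t!1}", "A{s}", "B{t~p}", "A{s}-A{s}")),
    list(defs = "agent P = new {f:(0 1), x:(0 1), y:(0 1)};",
         init = paste0("init ",
                       paste(sprintf("P{f~0, x~0!%d, y~0!%d}", 0:4, c(1:4, 0)),
                             collapse = "-"), " 1;"),
         pats = c("P{y!1}-P{x!1}", "P{f~0}", "P{x!1}-P{y!1, x!2}-P{y!2}"))
  )
  for (case in cases) {
    mix <- mixture_from(case$defs, case$init)
    for (p in case$pats) {
      pat <- parse_pattern(p)
      expect_identical(find_embeddings(pat, mix)$count,
                       as.integer(oracle_embeddings(pat, mix)),
                       label = p)
    }
  }
})

test_that("trajectories are reproducible under a fixed seed", {
  k <- lbsk_compile(phospho_with_inits(20L))
  t1 <- ssa(k, tmax = 2, seed = 11, observables = c(pMEK = "MEK{S222~p}"))
  t2 <- ssa(k, tmax = 2, seed = 11, observables = c(pMEK = "MEK{S222~p}"))
  expect_identical(t1$time, t2$time)
  expect_identical(t1$pMEK, t2$pMEK)
  expect_identical(attr(t1, "seed"), 11L)
})

test_that("an empty rule set gives a flat trajectory of the inits", {
  k <- lbsk_compile("agent A = new {}; init A 5")
  tr <- ssa(k, tmax = 10, seed = 1, observables = c(A = "A"))
  expect_identical(nrow(tr), 1L)
  expect_equal(tr$A, 5)
  expect_identical(attr(tr, "status"), "exhausted")
})

test_that("phosphorylation without a phosphatase is monotone", {
  k <- lbsk_compile(phospho_with_inits(30L))
  tr <- ssa(k, tmax = 10, seed = 3, observables = c(pMEK = "MEK{S222~p}"))
  expect_true(all(diff(tr$time) > 0))
  expect_true(all(diff(tr$pMEK) >= 0))
})

test_that("rules that neither create nor delete agents conserve mass", {
  src <- paste(fixture("chemotaxis")$source, "|", ring_init(34, ident = "P1"))
  k <- lbsk_compile(src)
  tr <- ssa(k, tmax = 5, seed = 5, observables = c(P = "P"),
            max_events = 200)
  expect_gt(nrow(tr), 1L) # some flips happened
  expect_true(all(tr$P == 34L))
  # mixture invariants hold after the events
  expect_true(lbskappa:::check_mixture(attr(tr, "final_mixture"),
                                       k$signatures))
})

test_that("agent creation and deletion work through gene expression", {
  src <- paste(fixture("gene_expression_compartments")$source, "|
    cell[ nucleus[ init gene 1 | init rnap 1 ] ]")
  k <- lbsk_compile(src)
  tr <- ssa(k, tmax = 3, seed = 2,
            observables = list(mRNA = "mRNA", MEK = "MEK"))
  expect_true(any(tr$mRNA > 0) || any(tr$MEK > 0))
  expect_true(lbskappa:::check_mixture(attr(tr, "final_mixture"),
                                       k$signatures))
})

test_that("the death process decays and zero activity terminates early", {
  k <- lbsk_compile(death_model(15L, 0.5))
  tr <- ssa(k, tmax = 1e3, seed = 4, observables = c(A = "A"))
  expect_identical(attr(tr, "status"), "exhausted")
  expect_equal(tail(tr$A, 1L), 0)
  expect_true(all(diff(tr$A) == -1L))
})

test_that("the mixture size cap is enforced with a clear error", {
  expect_error(
    kappa_mixture(lbsk_compile("agent A = new {}; init A 50"),
                  max_agents = 10),
    regexp = "cap", class = "lbsk_sim_error")
})
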