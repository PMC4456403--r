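# The Kappa backend: site-expression primitives, link encoding,
# linearisation, translation, well-typedness, writer.

site_variants <- function() {
  internals <- list(int_value("u"), int_value("p"), int_wildcard(),
                    int_identity())
  links <- list(link_free(), link_bound(), link_any(), link_identity(),
                link_label(1L, ""), link_label(2L, "01"))
  out <- list()
  for (i in internals) for (l in links) {
    out[[length(out) + 1L]] <- list(internal = i, link = l)
  }
  out
}
int_value <- lbskappa:::int_value
int_wildcard <- lbskappa:::int_wildcard
int_identity <- lbskappa:::int_identity
link_free <- lbskappa:::link_free
link_bound <- lbskappa:::link_bound
link_any <- lbskappa:::link_any
link_identity <- lbskappa:::link_identity
link_label <- lbskappa:::link_label

test_that("the default site expression is a double wildcard, for any type", {
  for (type in list(c("u", "p"), c("0", "1"), "gdp")) {
    d <- default_site(type)
    expect_identical(d$internal$kind, "wildcard")
    expect_identical(d$link$kind, "any")
    expect_true(typecheck_site(d, type))
  }
})

test_that("site update overwrites except under the identity", {
  u_free <- list(internal = int_value("u"), link = link_free())
  got <- update_site(u_free, list(internal = int_value("p"),
                                  link = link_identity()))
  expect_identical(got$internal$v, "p")
  expect_identical(got$link$kind, "free")

  bound <- list(internal = int_value("p"), link = link_label(1L, "b"))
  kept <- update_site(bound, list(internal = int_value("u"),
                                  link = link_identity()))
  expect_identical(kept$internal$v, "u")
  expect_identical(kept$link, link_label(1L, "b"))

  for (x in site_variants()) {
    idn <- list(internal = int_identity(), link = link_identity())
    expect_identical(update_site(x, idn), x)        # identity is neutral
    for (y in site_variants()) {
      once <- update_site(x, y)
      expect_identical(update_site(once, y), once)  # right-absorbing
    }
  }
})

test_that("site typing admits exactly the declared internal values", {
  expect_true(typecheck_site(list(internal = int_value("gdp"),
                                  link = link_free()), c("gtp", "gdp")))
  expect_true(typecheck_site(list(internal = int_wildcard(),
                                  link = link_free()), c("0", "1")))
  expect_false(typecheck_site(list(internal = int_value("p"),
                                   link = link_free()), c("0", "1")))
})

test_that("sealing prepends the namespace of link labels and nothing else", {
  s <- list(internal = int_value("u"), link = link_label(1L, ""))
  expect_identical(seal_site(s, "0")$link$ns, "0")
  twice <- seal_site(seal_site(s, "1"), "0")
  expect_identical(twice$link$ns, "01")
  for (x in site_variants()) {
    sealed <- seal_site(x, "10")
    expect_identical(sealed$internal, x$internal)
    if (x$link$kind != "label") {
      expect_identical(sealed$link, x$link)
    } else {
      expect_identical(sealed$link$k, x$link$k)
      expect_identical(sealed$link$ns, paste0("10", x$link$ns))
    }
  }
})

test_that("link encoding is injective over small label universes", {
  # one single-site agent per (k, namespace) pair; pairs must separate
  universe <- expand.grid(k = 1:3, ns = c("", "0", "1", "00", "01", "10", "11"),
                          stringsAsFactors = FALSE)
  agents <- lapply(seq_len(nrow(universe)), function(i) {
    list(name = "A", sites = list(list(
      name = "x", internal = NA_character_,
      link = link_label(universe$k[[i]], universe$ns[[i]]))))
  })
  enc <- lbskappa:::enc_links(c(agents, agents)) # each pair twice
  ks <- vapply(enc, function(a) a$sites[[1]]$link$k, 0L)
  first <- ks[seq_len(nrow(universe))]
  expect_identical(first, seq_len(nrow(universe)))         # first-occurrence order
  expect_identical(ks, c(first, first))                    # injective, stable
})

test_that("site linearisation follows byte order and drops no-ops", {
  mk <- function(nm) list(type = c("u", "p"), internal = int_value("u"),
                          link = link_free())
  sites <- list(S222 = mk(), S218 = mk(), t = mk())
  out <- lbskappa:::kap_sites(sites)
  expect_identical(vapply(out, function(s) s$name, ""),
                   c("S218", "S222", "t"))
  expect_identical(lbskappa:::kap_sites(list()), list())
  # random site-name sets against the sorting oracle
  for (seed in 1:5) {
    set.seed(seed)
    nms <- unique(replicate(8, paste(sample(c(LETTERS, letters, 0:9), 4),
                                     collapse = "")))
    sites <- setNames(lapply(nms, function(n) mk()), nms)
    out <- vapply(lbskappa:::kap_sites(sites), function(s) s$name, "")
    expect_identical(out, sort(nms, method = "radix"))
  }
  # unconstrained sites are dropped; types are discarded
  dropped <- lbskappa:::kap_sites(list(
    a = list(type = c("u", "p"), internal = int_wildcard(), link = link_any()),
    n = list(type = c("gtp", "gdp"), internal = int_value("gdp"),
             link = link_free())))
  expect_length(dropped, 1L)
  expect_identical(dropped[[1]]$name, "n")
  expect_identical(dropped[[1]]$internal, "gdp")
  expect_null(dropped[[1]]$type)
})

test_that("rules translate with per-side label pairing enforced", {
  k <- lbsk_compile(fixture("intro_phospho")$source)
  r1 <- k$rules[[1]]
  expect_length(r1$lhs, 2L)
  expect_length(r1$rhs, 2L)
  rhs_links <- unlist(lapply(r1$rhs, function(a) {
    vapply(a$sites, function(s) if (s$link$kind == "label") s$link$k else NA_integer_,
           0L)
  }))
  expect_identical(sort(rhs_links[!is.na(rhs_links)]), c(1L, 1L))

  # degradation rules have an empty product list
  deg <- lbsk_compile("agent S = new {}; S -> ")
  expect_length(deg$rules[[1]]$rhs, 0L)

  # a label occurring once on a side is a dangling bond
  expect_error(lbsk_compile("agent A = new {x}; A{x!1} -> A{x}"),
               regexp = "exactly twice", class = "lbsk_kappa_error")
})

test_that("initial conditions must be ground with positive copy numbers", {
  expect_error(lbsk_parse("init A 0"), class = "lbsk_parse_error")
  expect_error(lbsk_compile("agent A = new {x}; init A 5"),
               regexp = "not ground", class = "lbsk_kappa_error")
  expect_error(lbsk_compile("agent A = new {x}; init A{x~u!_} 5"),
               regexp = "not ground", class = "lbsk_kappa_error")
  ok <- lbsk_compile("agent A = new {x}; init A{x~u} 5")
  expect_length(ok$inits, 1L)
  expect_identical(ok$inits[[1]]$count, 5L)
})

test_that("program composition is union on rules, concatenation on inits", {
  k <- lbsk_compile("agent A = new {x}; A{x~u} -> A{x~p}| init A{x~u} 3")
  expect_identical(kappa_canonical(kappa_compose(k, kappa_nil())),
                   kappa_canonical(k))
  doubled <- kappa_compose(k, k)
  expect_length(doubled$rules, 1L) # set union
  expect_length(doubled$inits, 2L) # list concatenation
})

test_that("the KaSim writer emits signatures, rules and inits deterministically", {
  k <- lbsk_compile(fixture("intro_phospho")$source)
  text <- write_kasim(k)
  lines <- strsplit(text, "\n")[[1]]
  expect_length(grep("^%agent:", lines), 2L)
  expect_length(grep("^'", lines), 3L)
  expect_identical(write_kasim(k), text)

  empty <- lbsk_compile("")
  expect_length(grep("^'", strsplit(write_kasim(empty), "\n")[[1]]), 0L)

  nd <- write_kasim(lbsk_compile(fixture("nondet_mek_erk")$source))
  rule_lines <- grep("^'", strsplit(nd, "\n")[[1]], value = TRUE)
  for (nm in c("MEK1", "MEK2", "ERK1", "ERK2")) {
    expect_true(any(grepl(paste0(nm, "\\("), rule_lines)), label = nm)
  }

  withinit <- lbsk_compile("agent A = new {x}; init A{x~u} 7")
  expect_match(write_kasim(withinit), "%init: 7 A\\(x~u, comp~top\\)")
})

test_that("every compiled fixture passes an independent well-typedness check", {
  for (nm in fixture_names()) {
    fx <- fixture(nm)
    k <- lbsk_compile(fx$source, allow_scripts = fx$needs_scripts)
    expect_true(assert_well_typed(k), label = nm)
  }
})
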