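# Elaboration: updates, choice, modules and subtyping, compartments, rates.

test_that("the phosphorylate module elaborates to the three flat rules", {
  ir <- lbsk_elaborate(lbsk_parse(fixture("intro_phospho")$source))
  expect_length(ir$rules, 3L)
  expect_length(ir$inits, 0L)
})

test_that("the nil program elaborates to nothing", {
  ir <- lbsk_elaborate(lbsk_parse(""))
  expect_length(ir$rules, 0L)
  expect_length(ir$inits, 0L)
})

test_that("updates touch only the addressed agent and the mentioned sites", {
  k <- lbsk_compile("
    agent P1, P2, P3 = new P{f:(0 1), x:(0 1), y:(0 1), s};
    agent c000 = P1{f~0, y!1}-P2{x!1, f~0, y!2, s}-P3{x!2, f~0};
    c000 -> c000<P2{f~1}>")
  canon <- kappa_canonical(k)
  expect_length(canon, 1L)
  expect_identical(canon,
    "P{f~0, y!1}-P{f~0, s, x!1, y!2}-P{f~0, x!2} -> P{f~0, y!1}-P{f~1, s, x!1, y!2}-P{f~0, x!2} @ 1")
})

test_that("an empty update is the identity", {
  k <- lbsk_compile("agent A = new {x}; A -> A<A>")
  r <- k$rules[[1]]
  expect_identical(lbskappa:::canon_side(r$lhs), lbskappa:::canon_side(r$rhs))
})

test_that("updating a complex and composing reproduces the printed Ras rule", {
  fx <- fixture("complex_update")
  k <- lbsk_compile(fx$source)
  expect_identical(kappa_canonical(k), sort(fx$golden, method = "radix"))
})

test_that("choice expands to the cartesian product of concrete rules", {
  fx <- fixture("nondet_mek_erk")
  k <- lbsk_compile(fx$source)
  expect_length(k$rules, 4L)
  expect_identical(kappa_canonical(k), sort(fx$golden, method = "radix"))

  k3 <- lbsk_compile("
    agent A1 = new {x}; agent A2 = new {x};
    agent B1 = new {x}; agent B2 = new {x};
    agent D1 = new {x}; agent D2 = new {x};
    agent Ca = A1 or A2; agent Cb = B1 or B2; agent Cd = D1 or D2;
    Ca + Cb + Cd -> ")
  expect_length(k3$rules, 8L)

  same <- lbsk_compile("agent A = new {x}; agent C = A or A; C -> ")
  expect_length(same$rules, 1L)
})

test_that("choice expansion count equals the product of branch counts", {
  for (seed in 1:5) {
    for (depth in 1:3) {
      rm <- random_model(seed, n_agents = 4L, n_modules = 0L,
                         max_depth = depth)
      k <- lbsk_compile(rm$source)
      expect_length(k$rules, 2L^depth)
    }
  }
})

test_that("module invocation equals the hand-inlined body", {
  inlined <- lbsk_compile("
    agent Raf = new {x, y};
    agent MEK = new {t, S218, S222};
    Raf{x} + MEK{S222~u} -> Raf{x!1}-MEK{S222~u!1}|
    Raf{x!1}-MEK{S222~u!1} -> Raf{x!1}-MEK{S222~p!1}|
    Raf{x!1}-MEK{S222!1} -> Raf{x} + MEK{S222}")
  modular <- lbsk_compile(fixture("intro_phospho")$source)
  expect_identical(kappa_canonical(modular), kappa_canonical(inlined))
})

test_that("a module with a nil body yields nothing regardless of actuals", {
  k <- lbsk_compile("
    module noop(agent k:{m}, s:{n}){ nil };
    agent A = new {x};
    agent B = new {y};
    noop(A:{x}, B:{y})")
  expect_length(k$rules, 0L)
  expect_length(k$inits, 0L)
})

test_that("complex-valued actuals exercise subtyping at both levels", {
  # the kinase slot receives a state-constrained agent (cf. the MAPK layers)
  k <- lbsk_compile(fixture("mapk")$source)
  expect_length(k$rules, 30L)
  canon <- kappa_canonical(k)
  # layer 2: phospho-Raf binds MEK on S218 while staying phosphorylated
  expect_true(any(grepl("Raf\\{n~p\\} \\+ MEK\\{S218~u\\}", canon)))
  # the identity link update keeps the enzyme-substrate bond
  expect_true(any(grepl(
    "Ras\\{n!1\\}-Raf\\{n~u!1\\} -> Ras\\{n!1\\}-Raf\\{n~p!1\\}", canon)))
})

test_that("link labels in sibling invocations never alias", {
  ir <- lbsk_elaborate(lbsk_parse("
    module bind(agent k:{m}, s:{n}){ k{m} + s{n} -> k{m!1}-s{n!1} };
    agent A = new {x};
    agent B = new {y};
    bind(A:{x}, B:{y})|
    bind(A:{x}, B:{y})"))
  labels <- unique(unlist(lapply(ir$rules, function(r) {
    unlist(lapply(c(r$lhs, r$rhs), function(v) {
      lapply(v, function(p) {
        vapply(p$sites, function(s) {
          if (s$link$kind == "label") paste0(s$link$k, "@", s$link$ns)
          else NA_character_
        }, "")
      })
    }))
  })))
  labels <- labels[!is.na(labels)]
  expect_length(labels, 2L) # one namespaced label 1 per invocation
})

test_that("body labels do not capture labels carried by actual parameters", {
  k <- lbsk_compile("
    agent A = new {x, w};
    agent B = new {y};
    agent C = new {z};
    agent c = A{x!1}-B{y!1};
    module attach(agent c2: A{w}){ c2 + C{z} -> c2<A{w!1}>-C{z!1} };
    attach(c:A{w})")
  expect_length(k$rules, 1L)
  rhs <- lbskappa:::canon_side(k$rules[[1]]$rhs)
  # the pre-existing A-B bond and the new A-C bond use distinct labels
  expect_identical(rhs, "A{w!1, x!2}-B{y!2}-C{z!1}")
})

test_that("compartment locations resolve to root-to-leaf paths", {
  k <- lbsk_compile(fixture("gene_expression_compartments")$source)
  comp_of <- function(agents, name) {
    for (a in agents) {
      if (a$name == name) {
        for (s in a$sites) if (s$name == "comp") return(s$internal)
      }
    }
    NA_character_
  }
  transport <- Filter(function(r) {
    length(r$lhs) == 1L && r$lhs[[1]]$name == "mRNA" &&
      length(r$rhs) == 1L && r$rhs[[1]]$name == "mRNA"
  }, k$rules)
  expect_length(transport, 1L)
  expect_identical(comp_of(transport[[1]]$lhs, "mRNA"), "cell.nucleus")
  expect_identical(comp_of(transport[[1]]$rhs, "mRNA"), "cell")

  # top-level agents live at the "top" token
  top <- lbsk_compile("agent A = new {}; A -> ")
  expect_identical(comp_of(top$rules[[1]]$lhs, "A"), "top")

  # doubly nested expression location equals the transport LHS path
  nested <- lbsk_compile("
    comp cell; comp nucleus inside cell;
    agent A = new {};
    cell[ nucleus[A] -> nucleus[A] ]")
  expect_identical(comp_of(nested$rules[[1]]$lhs, "A"), "cell.nucleus")
})

test_that("rate expressions evaluate with module-scoped identifiers", {
  k <- lbsk_compile(fixture("chemotaxis")$source)
  fwd <- sort(vapply(k$rules, function(r) r$rate, 0))
  # per flips instantiation (k = 1, then k = 10): forward r1*k in
  # {1,1,1,100} and {10,10,10,1000}, reverse {200,2,2,2} twice
  expect_equal(fwd, sort(c(1, 1, 1, 100, 10, 10, 10, 1000,
                           200, 2, 2, 2, 200, 2, 2, 2)))
  expect_error(lbsk_compile("A -> {missing} B"), regexp = "unbound rate",
               class = "lbsk_elab_error")
})

test_that("elaboration rejects ill-formed models with clear errors", {
  expect_error(lbsk_compile("A -> B"), regexp = "undefined agent",
               class = "lbsk_elab_error")
  expect_error(lbsk_compile("agent A = new {x:(0 1)}; A{x~p} -> "),
               regexp = "not declared", class = "lbsk_elab_error")
  expect_error(lbsk_compile("
    agent A = new {x};
    agent c = A{x!1}-A{x!1};
    c -> c<A{x~u}>"), regexp = "ambiguous", class = "lbsk_elab_error")
  expect_error(lbsk_compile("agent A = new {}; cell[ A -> ]"),
               regexp = "not declared", class = "lbsk_elab_error")
  expect_error(lbsk_compile("
    module bind(agent k:{m}, s:{n}){ nil };
    agent A = new {x};
    bind(A:{x})"), regexp = "expects", class = "lbsk_elab_error")
  expect_error(lbsk_compile("
    module bind(agent k:{m:(a b)}){ nil };
    agent A = new {x:(0 1)};
    bind(A:{x})"), regexp = "type mismatch", class = "lbsk_elab_error")
})

test_that("parallel composition is associative with nil as identity", {
  p1 <- "agent A = new {x}; A{x~u} -> A{x~p}"
  p2 <- "agent B = new {y}; B{y~u} -> B{y~p}"
  left <- lbsk_compile(sprintf("%s| %s| nil", p1, p2))
  right <- lbsk_compile(sprintf("nil| %s| %s", p1, p2))
  expect_identical(kappa_canonical(left), kappa_canonical(right))
})
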