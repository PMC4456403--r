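# Fixture library: the worked models shipped with the package (transcribed
# with documented corrections) plus generators
# for ring initial conditions and randomised models with known expansion
# counts.

fixture_table <- function() {
  list(
    intro_phospho = list(expected_rules = 3L, golden = "intro_phospho.txt",
                         needs_scripts = FALSE),
    gene_expression_compartments = list(expected_rules = 4L, golden = NULL,
                                        needs_scripts = FALSE),
    complex_update = list(expected_rules = 2L, golden = "complex_update.txt",
                          needs_scripts = FALSE),
    nondet_mek_erk = list(expected_rules = 4L, golden = "nondet_mek_erk.txt",
                          needs_scripts = FALSE),
    chemotaxis = list(expected_rules = 16L, golden = NULL,
                      needs_scripts = FALSE),
    mapk = list(expected_rules = 30L, golden = NULL, needs_scripts = FALSE),
    mapk_single_cycle = list(expected_rules = 6L, golden = NULL,
                             needs_scripts = FALSE),
    insulin_excerpt = list(expected_rules = 6L, golden = NULL,
                           needs_scripts = FALSE),
    script_variants = list(expected_rules = 100L, golden = NULL,
                           needs_scripts = TRUE),
    script_ring = list(expected_rules = 0L, golden = NULL,
                       needs_scripts = TRUE)
  )
}

#' Names of the shipped fixture models
#' @export
fixture_names <- function() names(fixture_table())

#' Load a fixture model
#'
#' Returns the source text of one of the shipped models together with its
#' expectations: the number of directed flat rules it compiles to, and (for
#' the models whose flat expansion is printed in full) the canonical golden
#' expansion.
#'
#' @param name One of [fixture_names()].
#' @return A list with `name`, `source` (text), `path`, `expected_rules`,
#'   `golden` (canonical rule strings or NULL) and `needs_scripts`.
#' @examples
#' fx <- fixture("intro_phospho")
#' k <- lbsk_compile(fx$source)
#' length(k$rules) # 3
#' @export
fixture <- function(name) {
  tab <- fixture_table()
  if (!name %in% names(tab)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  entry <- tab[[name]]
  path <- system.file("extdata", "fixtures", paste0(name, ".lbsk"),
                      package = "lbskappa", mustWork = TRUE)
  golden <- NULL
  if (!is.null(entry$golden)) {
    gpath <- system.file("extdata", "golden", entry$golden,
                         package = "lbskappa", mustWork = TRUE)
    golden <- readLines(gpath, warn = FALSE)
    golden <- golden[nzchar(golden)]
  }
  list(name = name,
       source = paste(readLines(path, warn = FALSE), collapse = "\n"),
       path = path,
       expected_rules = entry$expected_rules,
       golden = golden,
       needs_scripts = entry$needs_scripts)
}

#' Compile a fixture
#'
#' Convenience wrapper: loads and compiles a fixture (enabling scripts when
#' the fixture needs them).
#'
#' @inheritParams fixture
#' @return A `kappa_program`.
#' @export
compile_fixture <- function(name) {
  fx <- fixture(name)
  lbsk_compile(fx$source, allow_scripts = fx$needs_scripts)
}

#' Ring initial-condition text
#'
#' Generates a single `init` statement describing one closed ring of `n`
#' protomer agents `P`, each bound x-to-y to its neighbour with link labels
#' taken modulo `n` — the programmatic counterpart of the embedded ring
#' script fixture.  All internal states are ground (f~0, s~u, x~0, y~0).
#'
#' @param n Number of protomers (at least 3).
#' @param ident Identifier of the protomer agent to reference (an agent with
#'   sites f, x, y and s must be bound to it in the enclosing model; the
#'   chemotaxis model binds the aliases P1, P2, P3).
#' @return A string: `init P{...}-...-P{...} 1;`
#' @export
ring_init <- function(n, ident = "P") {
  if (!is.numeric(n) || n != floor(n) || n < 3) {
    stop("a ring needs at least 3 protomers", call. = FALSE)
  }
  i <- seq_len(n)
  paste0("init ",
         paste(sprintf("%s{f~0, s~u, x~0!%d, y~0!%d}", ident,
                       i %% n, (i + 1) %% n),
               collapse = "-"),
         " 1;")
}

#' Generate a random well-formed model with a known expansion count
#'
#' Produces model text exercising `new` definitions, literal updates,
#' parameterised modules, binary choice agents and a compartment, with the
#' number of directed flat rules known by construction:
#' `2 * n_modules` rules from bind/unbind module instantiations plus
#' `2 ^ max_depth` rules from one degradation rule over `max_depth` binary
#' choice agents.
#'
#' @param seed Integer seed.
#' @param n_agents Number of `new` agent definitions (>= 2).
#' @param n_modules Number of two-rule module instantiations.
#' @param max_depth Number of binary choice agents in the final rule.
#' @return A list with `source` (text) and `expected_rules`.
#' @export
random_model <- function(seed = 1L, n_agents = 4L, n_modules = 2L,
                         max_depth = 2L) {
  stopifnot(n_agents >= 2L, n_modules >= 0L, max_depth >= 1L)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)

  agent_names <- paste0("A", seq_len(n_agents))
  sites <- lapply(seq_len(n_agents), function(i) {
    k <- sample(1:3, 1L)
    nm <- paste0("s", seq_len(k))
    typed <- stats::runif(k) < 0.3
    list(names = nm, decl = paste(ifelse(typed, paste0(nm, ":(0 1)"), nm),
                                  collapse = ", "))
  })
  defs <- vapply(seq_len(n_agents), function(i) {
    sprintf("agent %s = new {%s};", agent_names[[i]], sites[[i]]$decl)
  }, "")

  mods <- character()
  for (m in seq_len(n_modules)) {
    ij <- sample(n_agents, 2L, replace = TRUE)
    si <- sample(sites[[ij[[1L]]]]$names, 1L)
    sj <- sample(sites[[ij[[2L]]]]$names, 1L)
    mods <- c(mods, sprintf(paste0(
      "module mod%d(agent k:{m}, s:{n}){\n",
      "  k{m} + s{n} -> k{m!1}-s{n!1}|\n",
      "  k{m!1}-s{n!1} -> k{m} + s{n}\n",
      "};\n",
      "mod%d(%s:{%s}, %s:{%s})|"),
      m, m, agent_names[[ij[[1L]]]], si, agent_names[[ij[[2L]]]], sj))
  }

  choices <- character()
  for (d in seq_len(max_depth)) {
    ij <- sample(n_agents, 2L, replace = FALSE)
    choices <- c(choices, sprintf("agent C%d = %s or %s;", d,
                                  agent_names[[ij[[1L]]]],
                                  agent_names[[ij[[2L]]]]))
  }
  degrade <- sprintf("cell[\n  %s ->\n]",
                     paste(paste0("C", seq_len(max_depth)), collapse = " + "))

  src <- paste(c("comp cell;", defs, mods, choices, degrade), collapse = "\n")
  list(source = src, expected_rules = 2L * n_modules + 2L^max_depth)
}
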