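# Elaboration: evaluates a desugared program down to normal-form rules and
# initial populations.
#
# A *value* is a list of protomers (one protomer per atomic agent in a
# complex).  A protomer carries a relative compartment path, the unique id of
# its `new` definition, its declared agent name, the identifier it was
# defined with, the alias it was referenced through, and a full typed site
# assignment.  Identifiers bind to *sets* of values: non-deterministic
# (`or`) agents are sets with more than one element and rules mentioning
# them expand to the cartesian product of concrete rules.
#
# Link labels written in a module body are stamped with the invocation's
# namespace (a bit-string extended at every module invocation), so labels in
# a body can never capture labels carried by actual-parameter values, which
# keep the namespace of the scope that created them.

new_ctx <- function(allow_scripts = FALSE, max_rules = 100000L) {
  ctx <- new.env(parent = emptyenv())
  ctx$uid <- 0L
  ctx$inv <- 0L
  ctx$nrules <- 0L
  ctx$registry <- list()      # uid -> list(name, defid, sig)
  ctx$allow_scripts <- allow_scripts
  ctx$max_rules <- max_rules
  ctx
}

empty_env <- function() {
  list(agents = list(), rates = list(), comps = list(), compalias = list(),
       mods = list(), renames = list(), path = character(), ns = "",
       scriptEnv = "")
}

protomer <- function(uid, name, defid, alias, sites, path = character()) {
  list(path = path, uid = uid, name = name, defid = defid, alias = alias,
       sites = sites)
}

to_bits <- function(i) {
  if (i == 0L) return("0")
  bits <- character()
  while (i > 0L) {
    bits <- c(as.character(i %% 2L), bits)
    i <- i %/% 2L
  }
  paste(bits, collapse = "")
}

#' Elaborate a desugared program to normal-form rules and inits
#'
#' Traverses the tree threading an environment of agent, compartment, rate
#' and module bindings; module invocations are expanded with the
#' formal-to-actual renaming implied by their annotations (agent subtyping:
#' the actual may carry extra agents and sites), non-deterministic agents
#' multiply rules out, and compartment locations prefix agent paths.
#'
#' @param ast A desugared tree ([lbsk_desugar()]); sugared input is accepted
#'   and desugared first.
#' @param allow_scripts Evaluate embedded `script`/`scriptdef` blocks
#'   (R code, sandboxed)?  Off by default.
#' @return An object of class `lbsk_ir`: `rules` (normal-form rules:
#'   `lhs`/`rhs` lists of values, `rate`, `label`), `inits` (value + copy
#'   number), and `agents` (the registry of `new` definitions).
#' @export
lbsk_elaborate <- function(ast, allow_scripts = FALSE) {
  ast <- lbsk_desugar(ast)
  ctx <- new_ctx(allow_scripts = allow_scripts)
  out <- elab(ast, empty_env(), ctx)
  structure(list(rules = out$rules, inits = out$inits,
                 agents = ctx$registry),
            class = "lbsk_ir")
}

#' @export
print.lbsk_ir <- function(x, ...) {
  cat(sprintf("<lbsk ir: %d rules, %d inits, %d agents>\n",
              length(x$rules), length(x$inits), length(x$agents)))
  invisible(x)
}

empty_out <- function() list(rules = list(), inits = list())
combine_out <- function(a, b) {
  list(rules = c(a$rules, b$rules), inits = c(a$inits, b$inits))
}

# The definition/parallel spine of a program is walked iteratively so that
# long scoped chains (e.g. script-generated definition lists) do not grow
# the call stack; only genuinely nested structure (module bodies, located
# blocks, left operands) recurses.
elab <- function(nd, env, ctx) {
  out <- empty_out()
  repeat {
    switch(nd$kind,
      nil = return(out),
      scoped = {
        env <- bind_def(nd$def, env, ctx)
        nd <- nd$body
      },
      scriptdef = {
        env$scriptEnv <- collect_scriptdef(nd$code, env$scriptEnv)
        nd <- nd$body
      },
      script = {
        if (!isTRUE(ctx$allow_scripts)) {
          stop(errorCondition(
            "script error: embedded scripts are disabled; enable allow_scripts",
            class = c("lbsk_script_error", "lbsk_error")))
        }
        text <- run_script(nd$code, env$scriptEnv)
        nd <- splice_program(lbsk_desugar(lbsk_parse(text)), nd$body)
      },
      parallel = {
        out <- combine_out(out, elab(nd$left, env, ctx))
        nd <- nd$right
      },
      located = {
        id <- resolve_comp_id(nd$comp, env)
        check_comp_step(id, env$path, env)
        env$path <- c(env$path, id)
        nd <- nd$body
      },
      rule = return(combine_out(out, elab_rule(nd, env, ctx))),
      invoke = return(combine_out(out, elab_invoke(nd, env, ctx))),
      init = return(combine_out(out, elab_init(nd, env, ctx))),
      lbsk_elab_error(sprintf("unexpected node '%s'", nd$kind))
    )
  }
}

# --- definitions -------------------------------------------------------------

bind_def <- function(def, env, ctx) {
  switch(def$kind,
    agent_def = {
      if (def$expr$kind == "new_agent") {
        base <- elab_new(def$expr, env, ctx, defid = def$ids[[1L]])
        for (id in def$ids) {
          p <- base[[1L]][[1L]]
          p$alias <- id
          env$agents[[id]] <- list(list(p))
        }
      } else {
        set <- elab_expr_set(def$expr, env, ctx)
        env$agents[[def$ids[[1L]]]] <- set
      }
      env
    },
    comp_def = {
      parent <- def$parent
      if (!is.null(parent)) {
        if (is.null(env$comps[[parent]]) && !identical(parent, def$id)) {
          # parent must already be declared
          lbsk_elab_error(sprintf(
            "compartment '%s' declared inside undeclared compartment '%s'",
            def$id, parent))
        }
        # cycle check: walk up the parent chain
        seen <- def$id
        at <- parent
        while (!is.null(at)) {
          if (at %in% seen) {
            lbsk_elab_error(sprintf("cycle in the compartment hierarchy at '%s'",
                                    at))
          }
          seen <- c(seen, at)
          at <- env$comps[[at]]
          if (is.character(at) && is.na(at)) at <- NULL
        }
      }
      env$comps[[def$id]] <- parent %||% NA_character_
      env
    },
    rate_def = {
      env$rates[[def$id]] <- eval_rate(def$expr, env)
      env
    },
    module_def = {
      fids <- c(def$formals$comps,
                vapply(def$formals$agents, function(f) f$id, ""),
                def$formals$rates)
      if (anyDuplicated(fids)) {
        lbsk_elab_error(sprintf(
          "module '%s' binds formal '%s' twice", def$id,
          fids[duplicated(fids)][[1L]]))
      }
      env$mods[[def$id]] <- list(formals = def$formals, body = def$body,
                                 env = env)
      env
    }
  )
}

elab_new <- function(e, env, ctx, defid = NULL) {
  ctx$uid <- ctx$uid + 1L
  uid <- paste0("a", ctx$uid)
  defid <- defid %||% e$name
  sites <- lapply(e$sig, function(values) {
    list(type = values, internal = int_wildcard(), link = link_any())
  })
  names(sites) <- names(e$sig)
  ctx$registry[[uid]] <- list(name = e$name, defid = defid, sig = e$sig)
  list(list(protomer(uid, e$name, defid, NA_character_, sites)))
}

# --- agent expressions -------------------------------------------------------

elab_expr_set <- function(e, env, ctx) {
  switch(e$kind,
    new_agent = elab_new(e, env, ctx),
    ident = {
      set <- env$agents[[e$id]]
      if (is.null(set)) {
        lbsk_elab_error(sprintf("undefined agent identifier '%s'", e$id))
      }
      set
    },
    update = {
      base <- elab_expr_set(e$base, env, ctx)
      lapply(base, function(v) apply_update(v, e$target, e$sites, env))
    },
    compose = {
      ls <- elab_expr_set(e$left, env, ctx)
      rs <- elab_expr_set(e$right, env, ctx)
      out <- list()
      for (vl in ls) for (vr in rs) out[[length(out) + 1L]] <- c(vl, vr)
      out
    },
    choice = {
      out <- do.call(c, lapply(choice_branches(e), elab_expr_set,
                               env = env, ctx = ctx))
      out[!duplicated(vapply(out, value_key, ""))]
    },
    loc_expr = {
      id <- resolve_comp_id(e$comp, env)
      set <- elab_expr_set(e$body, env, ctx)
      lapply(set, function(v) lapply(v, function(p) {
        p$path <- c(id, p$path)
        p
      }))
    },
    lbsk_elab_error(sprintf("unexpected node '%s' in agent expression", e$kind))
  )
}

value_key <- function(v) {
  paste(vapply(v, function(p) {
    paste(p$uid, p$alias, paste(p$path, collapse = "."),
          paste(vapply(names(p$sites), function(nm) {
            s <- p$sites[[nm]]
            paste0(nm, "=", site_key(s))
          }, ""), collapse = ","))
  }, ""), collapse = ";")
}

site_key <- function(s) {
  i <- switch(s$internal$kind, value = s$internal$v, wildcard = "?", "!eps")
  l <- switch(s$link$kind, free = ".", bound = "_", any = "?",
              label = paste0(s$link$k, "@", s$link$ns), "!eps")
  paste0(i, "/", l)
}

# The backend update function applied through the agent-expression update
# operator: the middle protomer of a complex can be addressed by alias.
apply_update <- function(value, target, entries, env) {
  rn <- env$renames[[target]]
  tgt <- if (!is.null(rn)) rn$target else target
  sitemap <- if (!is.null(rn)) rn$sites else NULL
  hits <- which(vapply(value, function(p) {
    identical(p$alias, tgt) || identical(p$name, tgt)
  }, TRUE))
  if (length(hits) == 0L) {
    lbsk_elab_error(sprintf("update target '%s' matches no agent in the value",
                            tgt))
  }
  if (length(hits) > 1L) {
    lbsk_elab_error(sprintf(
      "update target '%s' is ambiguous (%d matching agents); use aliases",
      tgt, length(hits)))
  }
  p <- value[[hits]]
  for (entry in entries) {
    nm <- entry$name
    if (!is.null(sitemap) && nm %in% names(sitemap)) nm <- sitemap[[nm]]
    if (!nm %in% names(p$sites)) {
      lbsk_elab_error(sprintf("agent '%s' has no site '%s'", tgt, nm))
    }
    old <- p$sites[[nm]]
    internal <- if (entry$internal$kind == "identity") old$internal
                else entry$internal
    link <- if (entry$link$kind == "identity") {
      old$link
    } else if (entry$link$kind == "label") {
      link_label(entry$link$k, env$ns)
    } else {
      entry$link
    }
    if (internal$kind == "value" && !internal$v %in% old$type) {
      lbsk_elab_error(sprintf(
        "internal state '%s' is not declared for site '%s' of '%s' (allowed: %s)",
        internal$v, nm, p$name, paste(old$type, collapse = ", ")))
    }
    p$sites[[nm]] <- list(type = old$type, internal = internal, link = link)
  }
  value[[hits]] <- p
  value
}

# --- rules -------------------------------------------------------------------

collect_expr_idents <- function(e) {
  out <- character()
  work <- list(e)
  while (length(work)) {
    x <- work[[length(work)]]
    work[[length(work)]] <- NULL
    switch(x$kind,
      ident = out <- c(out, x$id),
      update = work[[length(work) + 1L]] <- x$base,
      compose = ,
      choice = {
        work[[length(work) + 1L]] <- x$left
        work[[length(work) + 1L]] <- x$right
      },
      loc_expr = work[[length(work) + 1L]] <- x$body,
      NULL)
  }
  out
}

elab_rule <- function(nd, env, ctx) {
  refs <- unique(unlist(lapply(c(nd$lhs, nd$rhs),
                               function(t) collect_expr_idents(t$expr))))
  choice_ids <- refs[vapply(refs, function(id) {
    length(env$agents[[id]] %||% list()) > 1L
  }, TRUE)]
  rate <- eval_rate(nd$fwd %||% rate_const(1), env)

  combos <- list(list())
  for (id in choice_ids) {
    branches <- env$agents[[id]]
    combos <- unlist(lapply(combos, function(cmb) {
      lapply(seq_along(branches), function(i) c(cmb, setNames(list(i), id)))
    }), recursive = FALSE)
  }

  rules <- list()
  for (cmb in combos) {
    env2 <- env
    for (id in names(cmb)) {
      env2$agents[[id]] <- env$agents[[id]][cmb[[id]]]
    }
    lhs_sets <- lapply(nd$lhs, function(t) elab_expr_set(t$expr, env2, ctx))
    rhs_sets <- lapply(nd$rhs, function(t) elab_expr_set(t$expr, env2, ctx))
    for (pick in cross_indices(c(lhs_sets, rhs_sets))) {
      nl <- length(lhs_sets)
      lhs <- lapply(seq_len(nl), function(i) lhs_sets[[i]][[pick[[i]]]])
      rhs <- lapply(seq_along(rhs_sets),
                    function(i) rhs_sets[[i]][[pick[[nl + i]]]])
      ctx$nrules <- ctx$nrules + 1L
      if (ctx$nrules > ctx$max_rules) {
        lbsk_elab_error(sprintf("rule expansion exceeds %d rules", ctx$max_rules))
      }
      label <- paste0(if (nzchar(env$ns)) paste0("b", env$ns, ".") else "",
                      "r", ctx$nrules)
      rules[[length(rules) + 1L]] <- list(
        lhs = lapply(lhs, absolutise, env = env),
        rhs = lapply(rhs, absolutise, env = env),
        rate = rate, label = label)
    }
  }
  list(rules = rules, inits = list())
}

cross_indices <- function(sets) {
  # all index combinations, one per set; empty set list -> one empty pick
  lens <- vapply(sets, length, 0L)
  if (any(lens == 0L)) lbsk_elab_error("empty expansion in a rule")
  picks <- list(integer())
  for (l in lens) {
    picks <- unlist(lapply(picks, function(p) {
      lapply(seq_len(l), function(i) c(p, i))
    }), recursive = FALSE)
  }
  picks
}

absolutise <- function(value, env) {
  lapply(value, function(p) {
    full <- c(env$path, p$path)
    if (length(p$path)) {
      at <- env$path
      for (id in p$path) {
        check_comp_step(id, at, env)
        at <- c(at, id)
      }
    }
    p$path <- full
    p
  })
}

resolve_comp_id <- function(id, env) env$compalias[[id]] %||% id

check_comp_step <- function(id, parent_path, env) {
  decl <- env$comps[[id]]
  if (is.null(decl)) {
    lbsk_elab_error(sprintf("compartment '%s' is used but not declared", id))
  }
  declared_parent <- if (is.na(decl)) NULL else decl
  actual_parent <- if (length(parent_path)) parent_path[[length(parent_path)]]
                   else NULL
  if (!identical(declared_parent, actual_parent)) {
    lbsk_elab_error(sprintf(
      "compartment '%s' is declared %s but used %s",
      id,
      if (is.null(declared_parent)) "at top level"
      else paste0("inside '", declared_parent, "'"),
      if (is.null(actual_parent)) "at top level"
      else paste0("inside '", actual_parent, "'")))
  }
  invisible(TRUE)
}

elab_init <- function(nd, env, ctx) {
  set <- elab_expr_set(nd$expr, env, ctx)
  if (length(set) != 1L) {
    lbsk_elab_error("a non-deterministic agent cannot be an initial condition")
  }
  list(rules = list(),
       inits = list(list(value = absolutise(set[[1L]], env), count = nd$count)))
}

# --- rates -------------------------------------------------------------------

eval_rate <- function(r, env) {
  v <- switch(r$kind,
    rate_const = r$value,
    rate_ident = {
      val <- env$rates[[r$id]]
      if (is.null(val)) {
        lbsk_elab_error(sprintf("unbound rate identifier '%s'", r$id))
      }
      val
    },
    rate_binop = {
      l <- eval_rate(r$left, env)
      rr <- eval_rate(r$right, env)
      if (r$op == "*") l * rr else l / rr
    },
    lbsk_elab_error("malformed rate expression")
  )
  if (!is.finite(v) || v < 0) {
    lbsk_elab_error(sprintf("rate evaluates to %s; rates must be non-negative",
                            v))
  }
  v
}

# --- module invocation -------------------------------------------------------

elab_invoke <- function(nd, env, ctx) {
  mod <- env$mods[[nd$module]]
  if (is.null(mod)) {
    lbsk_elab_error(sprintf("undefined module '%s'", nd$module))
  }
  f <- mod$formals
  nc <- length(f$comps)
  na <- length(f$agents)
  nr <- length(f$rates)
  if (length(nd$actuals) != nc + na + nr) {
    lbsk_elab_error(sprintf(
      "module '%s' expects %d arguments (%d compartments, %d agents, %d rates) but got %d",
      nd$module, nc + na + nr, nc, na, nr, length(nd$actuals)))
  }

  ctx$inv <- ctx$inv + 1L
  env_body <- mod$env
  env_body$renames <- list()
  env_body$path <- env$path
  env_body$ns <- paste0(env$ns, to_bits(ctx$inv))
  env_body$scriptEnv <- env$scriptEnv

  idx <- 1L
  for (cid in f$comps) {
    a <- nd$actuals[[idx]]
    idx <- idx + 1L
    if (!identical(a$kind, "ident_actual")) {
      lbsk_elab_error(sprintf(
        "compartment parameter '%s' of module '%s' needs a compartment identifier",
        cid, nd$module))
    }
    env_body$compalias[[cid]] <- resolve_comp_id(a$id, env)
  }

  for (fa in f$agents) {
    a <- nd$actuals[[idx]]
    idx <- idx + 1L
    if (identical(a$kind, "ident_actual")) a <- actual_agent(ast_ident(a$id), NULL)
    if (!identical(a$kind, "agent_actual")) {
      lbsk_elab_error(sprintf(
        "agent parameter '%s' of module '%s' needs an agent expression",
        fa$id, nd$module))
    }
    bind_agent_actual(fa, a, nd$module, env, env_body, ctx) -> env_body
  }

  for (rid in f$rates) {
    a <- nd$actuals[[idx]]
    idx <- idx + 1L
    val <- if (identical(a$kind, "rate_actual")) {
      eval_rate(a$expr, env)
    } else if (identical(a$kind, "ident_actual")) {
      eval_rate(rate_ident(a$id), env)
    } else {
      lbsk_elab_error(sprintf(
        "rate parameter '%s' of module '%s' needs a rate expression",
        rid, nd$module))
    }
    env_body$rates[[rid]] <- val
  }

  elab(mod$body, env_body, ctx)
}

bind_agent_actual <- function(fa, a, modname, env, env_body, ctx) {
  set <- elab_expr_set(a$expr, env, ctx)
  if (length(set) != 1L) {
    lbsk_elab_error(sprintf(
      "a non-deterministic agent cannot be passed to module '%s'", modname))
  }
  value <- set[[1L]]
  env_body$agents[[fa$id]] <- list(value)

  f_items <- fa$ann
  if (is.null(f_items) || length(f_items) == 0L) return(env_body)
  a_items <- a$ann
  if (is.null(a_items)) {
    needs_sites <- any(vapply(f_items, function(it) length(it$sites) > 0L, TRUE))
    if (!needs_sites) return(env_body)
    lbsk_elab_error(sprintf(
      "actual for parameter '%s' of module '%s' needs an annotation",
      fa$id, modname))
  }
  if (length(a_items) != length(f_items)) {
    lbsk_elab_error(sprintf(
      "annotation for parameter '%s' of module '%s' lists %d agents; %d expected",
      fa$id, modname, length(a_items), length(f_items)))
  }

  for (j in seq_along(f_items)) {
    fi <- f_items[[j]]
    ai <- a_items[[j]]
    f_name <- fi$name %||% fa$id
    key <- ai$name %||% expr_base_ident(a$expr)
    rn <- if (!is.null(key)) env$renames[[key]] else NULL
    target <- if (!is.null(rn)) {
      rn$target
    } else if (!is.null(key)) {
      key
    } else if (length(value) == 1L) {
      value[[1L]]$name
    } else {
      lbsk_elab_error(sprintf(
        "annotation item %d for parameter '%s' needs an agent name", j, fa$id))
    }
    a_sites <- vapply(ai$sites, function(s) s$name, "")
    if (!is.null(rn) && length(a_sites)) {
      a_sites <- vapply(a_sites, function(s) {
        if (s %in% names(rn$sites)) rn$sites[[s]] else s
      }, "")
    }
    if (length(a_sites) != length(fi$sites)) {
      lbsk_elab_error(sprintf(
        "annotation item '%s' for parameter '%s' lists %d sites; %d expected",
        target, fa$id, length(a_sites), length(fi$sites)))
    }
    hits <- which(vapply(value, function(p) {
      identical(p$alias, target) || identical(p$name, target)
    }, TRUE))
    if (length(hits) != 1L) {
      lbsk_elab_error(sprintf(
        "annotation agent '%s' matches %d agents in the actual for '%s'",
        target, length(hits), fa$id))
    }
    p <- value[[hits]]
    f_sitenames <- vapply(fi$sites, function(s) s$name, "")
    for (k in seq_along(a_sites)) {
      snm <- a_sites[[k]]
      if (!snm %in% names(p$sites)) {
        lbsk_elab_error(sprintf(
          "annotation names missing site '%s' on agent '%s'", snm, target))
      }
      f_type <- fi$sites[[k]]$type
      if (!is.null(f_type) && !setequal(f_type, p$sites[[snm]]$type)) {
        lbsk_elab_error(sprintf(
          "site type mismatch for '%s.%s': formal declares (%s), actual has (%s)",
          target, snm, paste(f_type, collapse = " "),
          paste(p$sites[[snm]]$type, collapse = " ")))
      }
    }
    env_body$renames[[f_name]] <- list(target = target,
                                       sites = setNames(a_sites, f_sitenames))
  }
  env_body
}

expr_base_ident <- function(e) {
  switch(e$kind,
    ident = e$id,
    update = expr_base_ident(e$base),
    loc_expr = expr_base_ident(e$body),
    NULL
  )
}

# --- scripts -----------------------------------------------------------------

# Replace the hole at the end of a script-produced program with the
# continuation.  The hole has no syntax: it is the trailing nil of the
# rightmost definition/parallel spine.  Iterative: the spine is unzipped,
# the continuation attached, and the spine rebuilt.
splice_program <- function(ast, cont) {
  steps <- list()
  nd <- ast
  repeat {
    done <- FALSE
    switch(nd$kind,
      scoped = {
        steps[[length(steps) + 1L]] <- list(kind = "scoped", def = nd$def)
        nd <- nd$body
      },
      parallel = {
        steps[[length(steps) + 1L]] <- list(kind = "parallel", left = nd$left)
        nd <- nd$right
      },
      script = {
        steps[[length(steps) + 1L]] <- list(kind = "script", code = nd$code)
        nd <- nd$body
      },
      scriptdef = {
        steps[[length(steps) + 1L]] <- list(kind = "scriptdef", code = nd$code)
        nd <- nd$body
      },
      done <- TRUE
    )
    if (done) break
  }
  acc <- if (nd$kind == "nil") {
    cont
  } else if (cont$kind == "nil") {
    nd
  } else {
    ast_parallel(nd, cont)
  }
  for (step in rev(steps)) {
    acc <- switch(step$kind,
      scoped = ast_scoped(step$def, acc),
      parallel = ast_parallel(step$left, acc),
      script = ast_script(step$code, acc),
      scriptdef = ast_scriptdef(step$code, acc)
    )
  }
  acc
}
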