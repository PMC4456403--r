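# Desugaring rewrites the parsed AST into the core abstract syntax:
#  * reversible rules become the parallel composition of two directed rules;
#  * `as` bindings become agent definitions hoisted in front of the rule and
#    scoping over the remainder of the block;
#  * agent literals `Id{...}` become updates `Id<Id{...}>`;
#  * a `new` without a name inherits the identifier it is assigned to;
#  * omitted site-expression components are made explicit: inside an update's
#    site assignments an omitted internal state is the identity (the state is
#    untouched) and an omitted link is the free link (the link is rewritten);
#    the identity link must be requested explicitly with `!e`.
# The pass is idempotent.

lbsk_elab_error <- function(msg) {
  stop(errorCondition(paste0("elaboration error: ", msg),
                      class = c("lbsk_elab_error", "lbsk_error")))
}

#' Desugar an LBS-kappa syntax tree
#'
#' @param ast A tree from [lbsk_parse()].
#' @return The desugared tree: no reversible rules, no `as` bindings, no
#'   agent literals, no omitted site-expression components.
#' @export
lbsk_desugar <- function(ast) {
  ds_prog(ast)
}

# The scoped/parallel spine is flattened, each step desugared, and the
# spine rebuilt right-nested; this keeps recursion depth proportional to
# genuine nesting (module bodies, located blocks), not to program length.
ds_prog <- function(nd) {
  steps <- list()
  repeat {
    done <- FALSE
    switch(nd$kind,
      scoped = {
        steps[[length(steps) + 1L]] <- list(kind = "def", def = ds_def(nd$def))
        nd <- nd$body
      },
      parallel = {
        steps[[length(steps) + 1L]] <- list(kind = "stmt", stmt = nd$left)
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
      {
        if (nd$kind != "nil") {
          steps[[length(steps) + 1L]] <- list(kind = "stmt", stmt = nd)
        }
        done <- TRUE
      }
    )
    if (done) break
  }
  acc <- ast_nil()
  for (step in rev(steps)) {
    acc <- switch(step$kind,
      def = ast_scoped(step$def, acc),
      script = ast_script(step$code, acc),
      scriptdef = ast_scriptdef(step$code, acc),
      stmt = ds_stmt(step$stmt, acc)
    )
  }
  acc
}

ds_stmt <- function(stmt, rest) {
  if (stmt$kind == "rule") {
    hoisted <- extract_as(stmt)
    rule <- split_reversible(hoisted$rule)
    core <- if (rest$kind == "nil") rule else ast_parallel(rule, rest)
    for (def in rev(hoisted$defs)) core <- ast_scoped(def, core)
    return(core)
  }
  left <- switch(stmt$kind,
    located = ast_located(stmt$comp, ds_prog(stmt$body)),
    init = ast_init(ds_expr(stmt$expr), stmt$count),
    invoke = ds_invoke(stmt),
    nil = ,
    scoped = ,
    parallel = ,
    script = ,
    scriptdef = ds_prog(stmt),
    lbsk_elab_error(sprintf("unexpected node '%s' in program position",
                            stmt$kind))
  )
  if (rest$kind == "nil") left else ast_parallel(left, rest)
}

extract_as <- function(rule) {
  defs <- list()
  strip <- function(terms) {
    lapply(terms, function(term) {
      expr <- ds_expr(term$expr)
      if (!is.null(term$as)) {
        defs[[length(defs) + 1L]] <<- ast_agent_def(term$as, expr)
        expr <- ast_ident(term$as)
      }
      list(expr = expr, as = NULL)
    })
  }
  lhs <- strip(rule$lhs)
  rhs <- strip(rule$rhs)
  list(defs = defs,
       rule = ast_rule(lhs, rhs, fwd = rule$fwd, rev = rule$rev,
                       reversible = rule$reversible))
}

split_reversible <- function(rule) {
  fwd <- rule$fwd %||% rate_const(1)
  if (!isTRUE(rule$reversible)) {
    return(ast_rule(rule$lhs, rule$rhs, fwd = fwd))
  }
  bwd <- rule$rev %||% rate_const(1)
  ast_parallel(
    ast_rule(rule$lhs, rule$rhs, fwd = fwd),
    ast_rule(rule$rhs, rule$lhs, fwd = bwd)
  )
}

ds_invoke <- function(nd) {
  actuals <- lapply(nd$actuals, function(a) {
    if (identical(a$kind, "agent_actual")) {
      actual_agent(ds_expr(a$expr), a$ann)
    } else {
      a
    }
  })
  ast_invoke(nd$module, actuals)
}

ds_def <- function(def) {
  switch(def$kind,
    agent_def = {
      expr <- def$expr
      if (length(def$ids) > 1L && expr$kind != "new_agent") {
        lbsk_elab_error(sprintf(
          "alias list '%s' is only allowed on a 'new' agent definition",
          paste(def$ids, collapse = ", ")))
      }
      if (expr$kind == "new_agent" && is.null(expr$name)) {
        expr <- ast_new_agent(def$ids[[1L]], expr$sig)
      }
      ast_agent_def(def$ids, ds_expr(expr))
    },
    module_def = ast_module_def(def$id, def$formals, ds_prog(def$body)),
    def
  )
}

# A choice expression parses left-nested; flatten its spine iteratively so
# a wide `or` chain (e.g. 100 script-generated variants) does not recurse.
choice_branches <- function(e) {
  rights <- list()
  while (e$kind == "choice") {
    rights[[length(rights) + 1L]] <- e$right
    e <- e$left
  }
  c(list(e), rev(rights))
}

rebuild_choice <- function(branches) {
  acc <- branches[[1L]]
  for (b in branches[-1L]) acc <- ast_choice(acc, b)
  acc
}

ds_expr <- function(e) {
  if (e$kind == "choice") {
    return(rebuild_choice(lapply(choice_branches(e), ds_expr)))
  }
  switch(e$kind,
    new_agent = {
      if (is.null(e$name)) {
        lbsk_elab_error("'new' without an agent name is only allowed in a definition")
      }
      e
    },
    ident = e,
    literal = ast_update(ast_ident(e$id), e$id, fill_sites(e$sites)),
    update = ast_update(ds_expr(e$base), e$target, fill_sites(e$sites)),
    compose = ast_compose(ds_expr(e$left), ds_expr(e$right)),
    choice = ast_choice(ds_expr(e$left), ds_expr(e$right)),
    loc_expr = ast_loc_expr(e$comp, ds_expr(e$body)),
    lbsk_elab_error(sprintf("unexpected node '%s' in agent expression", e$kind))
  )
}

fill_sites <- function(entries) {
  lapply(entries, function(s) {
    site_entry(s$name,
               internal = s$internal %||% int_identity(),
               link = s$link %||% link_free())
  })
}
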