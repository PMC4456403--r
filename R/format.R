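# Pretty-printer emitting the ASCII dialect.  Parsing the printed text gives
# back the same tree (after desugaring both sides if the tree was desugared:
# the identity internal state and the free link have no concrete spelling and
# print as omissions).

num_str <- function(v) {
  s <- as.character(v)
  if (identical(as.numeric(s), as.numeric(v))) s else sprintf("%.17g", v)
}

#' Format an LBS-kappa syntax tree as source text
#'
#' @param ast A tree from [lbsk_parse()] or [lbsk_desugar()].
#' @return A single string of ASCII concrete syntax.
#' @export
lbsk_format <- function(ast) {
  fmt_prog(ast)
}

fmt_prog <- function(nd) {
  switch(nd$kind,
    nil = "",
    parallel = {
      l <- fmt_prog(nd$left)
      r <- fmt_prog(nd$right)
      if (!nzchar(r)) l else paste0(l, "|\n", r)
    },
    scoped = {
      body <- fmt_prog(nd$body)
      paste0(fmt_def(nd$def), ";", if (nzchar(body)) paste0("\n", body) else "")
    },
    located = paste0(nd$comp, "[\n", fmt_prog(nd$body), "\n]"),
    script = {
      body <- fmt_prog(nd$body)
      paste0("script {", nd$code, "};",
             if (nzchar(body)) paste0("\n", body) else "")
    },
    scriptdef = {
      body <- fmt_prog(nd$body)
      paste0("scriptdef {", nd$code, "};",
             if (nzchar(body)) paste0("\n", body) else "")
    },
    init = paste0("init ", fmt_expr(nd$expr), " ", nd$count),
    invoke = paste0(nd$module, "(",
                    paste(vapply(nd$actuals, fmt_actual, ""), collapse = ", "),
                    ")"),
    rule = fmt_rule(nd),
    stop("cannot format node of kind ", nd$kind)
  )
}

fmt_rule <- function(nd) {
  arrow <- if (isTRUE(nd$reversible)) "<->" else "->"
  rates <- ""
  if (!is.null(nd$fwd)) rates <- paste0("{", fmt_rate(nd$fwd), "}")
  if (!is.null(nd$rev)) {
    if (!nzchar(rates)) rates <- "{1}"
    rates <- paste0(rates, "{", fmt_rate(nd$rev), "}")
  }
  lhs <- paste(vapply(nd$lhs, fmt_term, ""), collapse = " + ")
  rhs <- paste(vapply(nd$rhs, fmt_term, ""), collapse = " + ")
  trimws(paste0(lhs, " ", arrow, rates, " ", rhs))
}

fmt_term <- function(term) {
  out <- fmt_expr(term$expr)
  if (!is.null(term$as)) out <- paste0(out, " as ", term$as)
  out
}

fmt_actual <- function(a) {
  switch(a$kind,
    rate_actual = fmt_rate(a$expr),
    ident_actual = a$id,
    agent_actual = {
      if (is.null(a$ann)) {
        fmt_expr(a$expr)
      } else {
        paste0(fmt_expr(a$expr), ":", fmt_ann(a$ann))
      }
    }
  )
}

fmt_def <- function(def) {
  switch(def$kind,
    agent_def = paste0("agent ", paste(def$ids, collapse = ", "), " = ",
                       fmt_expr(def$expr)),
    comp_def = paste0("comp ", def$id,
                      if (!is.null(def$parent)) paste0(" inside ", def$parent)
                      else ""),
    rate_def = paste0("rate ", def$id, " = ", fmt_rate(def$expr)),
    module_def = paste0("module ", def$id, "(", fmt_formals(def$formals),
                        "){\n", fmt_prog(def$body), "\n}")
  )
}

fmt_formals <- function(formals) {
  groups <- character()
  if (length(formals$comps)) {
    groups <- c(groups, paste0("comp ", paste(formals$comps, collapse = ", ")))
  }
  if (length(formals$agents)) {
    entries <- vapply(formals$agents, function(f) {
      if (is.null(f$ann)) f$id else paste0(f$id, ":", fmt_ann(f$ann))
    }, "")
    groups <- c(groups, paste0("agent ", paste(entries, collapse = ", ")))
  }
  for (r in formals$rates) groups <- c(groups, paste0("rate ", r))
  paste(groups, collapse = "; ")
}

fmt_ann <- function(ann) {
  paste(vapply(ann, function(item) {
    sites <- if (length(item$sites)) {
      paste0("{", paste(vapply(item$sites, function(s) {
        if (is.null(s$type)) s$name
        else paste0(s$name, ":(", paste(s$type, collapse = " "), ")")
      }, ""), collapse = ", "), "}")
    } else ""
    paste0(item$name %||% "", sites)
  }, ""), collapse = "-")
}

fmt_expr <- function(e) {
  switch(e$kind,
    new_agent = paste0("new ", e$name %||% "", "{", fmt_sig(e$sig), "}"),
    ident = e$id,
    literal = paste0(e$id, "{", fmt_sites(e$sites), "}"),
    update = paste0(fmt_expr(e$base), "<", e$target,
                    if (length(e$sites)) paste0("{", fmt_sites(e$sites), "}")
                    else "", ">"),
    compose = paste0(fmt_expr(e$left), "-", fmt_expr(e$right)),
    choice = paste0(fmt_expr(e$left), " or ", fmt_expr(e$right)),
    loc_expr = paste0(e$comp, "[", fmt_expr(e$body), "]")
  )
}

fmt_sig <- function(sig) {
  paste(vapply(names(sig), function(nm) {
    if (identical(sig[[nm]], c("u", "p"))) nm
    else paste0(nm, ":(", paste(sig[[nm]], collapse = " "), ")")
  }, ""), collapse = ", ")
}

fmt_sites <- function(entries) {
  paste(vapply(entries, function(s) {
    internal <- if (is.null(s$internal)) "" else switch(s$internal$kind,
      value = paste0("~", s$internal$v),
      wildcard = "~?",
      identity = "")
    link <- if (is.null(s$link)) "" else switch(s$link$kind,
      free = "",
      bound = "!_",
      any = "?",
      identity = "!e",
      label = paste0("!", s$link$k))
    paste0(s$name, internal, link)
  }, ""), collapse = ", ")
}

fmt_rate <- function(r) {
  switch(r$kind,
    rate_const = num_str(r$value),
    rate_ident = r$id,
    rate_binop = paste0(fmt_rate(r$left), r$op, fmt_rate(r$right))
  )
}
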